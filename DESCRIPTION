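Package: fodm
Title: Fuzzy Oil Drop Analysis of Protein Hydrophobicity Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the fuzzy oil drop (FOD) model and its
    environment-modified extension (FOD-M) for protein structures. Reduces a
    structure to per-residue effective atoms, fits an axis-aligned 3D Gaussian
    envelope, and computes the theoretical (T), observed (O) and uniform (R)
    hydrophobicity distributions together with the Kullback-Leibler based
    relative distance statistic RD. The FOD-M layer blends the Gaussian with
    its complement through an environment factor K, located by a grid scan of
    the divergence between the observed and blended distributions. Includes a
    step-wise core-elimination procedure, target-versus-model comparison
    utilities for structure-prediction assessment (delta RD / delta K, GDT_TS
    correlation, RD binning), and a synthetic structure generator with known
    ground truth for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'hydro-scale.R'
    'structure-io.R'
    'fod-core.R'
    'fod-m.R'
    'casp-compare.R'
    'synthetic.R'
    'pipeline.R'
    'show-methods.R'
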