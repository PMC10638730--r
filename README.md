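# fodm — fuzzy oil drop analysis of protein hydrophobicity distributions

`fodm` asks a simple structural question quantitatively: *does a protein
arrange its hydrophobicity like a micelle?* Soluble globular proteins bury
hydrophobic residues in a central core and expose polar residues to water;
membrane and otherwise environment-adapted proteins do not. The package
implements the fuzzy oil drop (FOD) model of that arrangement and its
modified form (FOD-M), which quantifies how strongly a non-aqueous
environment has shaped a structure. It is aimed at structural
bioinformaticians assessing experimental structures, domains, and predicted
models (e.g. CASP submissions).

## The model

Each residue is reduced to an **effective atom**, the mean position of its
heavy atoms. Three per-residue distributions (each normalized to unit sum)
are compared:

- **T** (theoretical): an axis-aligned 3D Gaussian spanning the molecule,
  `T_i ∝ exp(−x_i²/2σ_x²) exp(−y_i²/2σ_y²) exp(−z_i²/2σ_z²)`,
  the idealised micelle — maximal hydrophobicity at the centre.
- **O** (observed): pairwise hydrophobic interactions,
  `O_i ∝ Σ_j (H_i^r + H_j^r) · w(r_ij/c)`, where `H^r` is the intrinsic
  hydrophobicity of each residue type, and `w` is a polynomial damping
  function falling from 1 at contact to 0 at the cutoff `c` (9 Å default).
- **R** (reference): uniform `1/N` — no core at all.

Distances between distributions are measured by divergence entropy
(Kullback–Leibler, in bits), and combined into the **relative distance**

```
RD = D_KL(O|T) / ( D_KL(O|T) + D_KL(O|R) )
```

`RD < 0.5` indicates a hydrophobic core. The FOD-M extension blends the
Gaussian with its complement (`max(T) − T`, normalized) through an
**environment factor K**:

```
M(K) = [ T + K · (T_max − T)_n ]_n
```

`K = 0` is a pure aqueous micelle; large `K` approaches the inverted,
membrane-like arrangement. The working `K` of a structure is the grid value
minimising `D_KL(O|M(K))`. Supporting tools: step-wise elimination of the
worst `|T − O|` deviations to expose the soluble core, per-residue
deficit/excess calls, target-vs-model comparison (ΔRD, ΔK, discordant
segments), RD/GDT_TS correlation and RD-range binning for model populations,
and a seeded synthetic-structure generator with known ground truth.

## Worked example

```r
library(fodm)

# a synthetic micelle-like globule of 100 residues (known ground truth)
ch <- synthChain(synthSpec(nResidues = 100, mode = "micelle", seed = 3))
a  <- fodAnalysis(ch)
a
#> FODAnalysis of 100 residues
#> GaussianEnvelope: sigma = (5.64, 5.28, 3.94) A
#> FOD summary (N = 100): D_KL(O|T) = 0.1105, D_KL(O|R) = 0.5385 bits
#>   RD = 0.170 -> hydrophobic core present (RD < 0.5)
#> Environment-factor scan: optimal K = 0.1, D_KL(O|M) = 0.1067 bits (grid of 51)
```

The observed distribution sits much closer to the Gaussian than to uniform
(0.11 vs 0.54 bits), giving RD = 0.170 — a clear hydrophobic core — and an
environment factor of 0.1, i.e. essentially aqueous conditions. Comparing
against a membrane-like ("inverted") structure of the same size:

```r
mem <- synthChain(synthSpec(nResidues = 100, mode = "inverted", seed = 3))
compareStructures(ch, mem)
#> Target vs model comparison over 100 paired residues
#>   target: RD = 0.170, K = 0.1
#>   model:  RD = 0.906, K = 5.0
#>   delta (model - target): RD +0.736, K +4.9
#>   discordant segments: 0
```

Real structures enter through `analyzeStructure("file.pdb", chain = "A",
ranges = "115-130,152-228")`, which refits the orientation and envelope to
the selected domain. Per-residue output: `profileTable()` /
`writeProfileTable()`. A command-line wrapper with `profile`, `scan-k`,
`eliminate`, `compare` and `synth` subcommands is installed at
`system.file("scripts", "fod.R", package = "fodm")`.

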