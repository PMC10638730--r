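---
title: "The fuzzy oil drop model in fodm: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy oil drop model in fodm: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model and its assumptions

The fuzzy oil drop (FOD) model idealises a soluble globular protein as a
hydrophobic micelle: hydrophobicity is maximal at the centre of the molecule
and decays smoothly towards the polar surface. `fodm` encodes that ideal as
an axis-aligned 3D Gaussian ("the drop") evaluated at one point per residue
— the *effective atom*, the unweighted mean of the residue's heavy-atom
positions. Three normalized per-residue distributions are compared:

* **T** — the Gaussian evaluated at the effective atoms (the idealised
  micelle);
* **O** — the hydrophobicity actually generated by pairwise inter-residue
  interactions: each pair within a cutoff `c` contributes the sum of the two
  residues' intrinsic hydrophobicities, damped by a polynomial
  `w(x) = 1 − ½(7x² − 9x⁴ + 5x⁶ − x⁸)`, `x = r/c`, which falls from 1 at
  contact to 0 at the cutoff;
* **R** — uniform `1/N`, the state with no core whatsoever.

Divergence entropy `D_KL(P|Q) = Σ P_i log₂(P_i/Q_i)` (bits) measures how far
O sits from each reference, and the relative distance
`RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))` places the structure on a [0, 1]
scale: 0 is a perfect micelle, 1 is coreless, and RD < 0.5 is read as "a
hydrophobic core is present".

The modified model (FOD-M) acknowledges that many proteins fold in
environments that are not bulk water. The membrane-adapted ideal is the
complement of the drop, `(max(T) − T)` normalized (hydrophobic outside,
polar channel inside), and real structures are treated as a consensus

`M(K) = [ T + K · (max(T) − T)_n ]_n`

with both the complement and the blend normalized (the two subscripts). The
environment factor `K ≥ 0` is not fitted continuously: it is the point of an
ascending grid minimising `D_KL(O|M(K))`, which matches how the quantity is
reported (one decimal) and keeps the estimate robust to the shallow,
occasionally multi-modal shape of the divergence curve.

Assumptions worth keeping in mind: a single compact body (one Gaussian; no
multi-domain mixture — analyse domains separately via range specs), residues
as points, hydrophobicity as a single intrinsic scalar per residue type, and
no solvent-accessibility or secondary-structure terms.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| interaction cutoff `c` | 9.0 | Å | classical value for this damped pairwise interaction function; beyond ~9 Å residue side chains no longer make hydrophobic contact |
| envelope divisor | 3 | — | σ per axis = (max abs coordinate)/3, so the whole molecule lies inside the 3σ support of the drop |
| σ floor | 0.5 | Å | keeps flat/degenerate clouds (and single points) well-defined |
| K grid | 0–5, step 0.1 | — | reported K values run from 0 to ~4 for strongly adapted structures; 0.1 matches reporting precision |
| D_KL clamp | 1e-10 | — | T is strictly positive but O and the complement can contain exact zeros; entries are clamped then renormalized |
| elimination threshold | 0.5 | RD | the core criterion itself |
| elimination budget | 50% | of N | prevents pathological erosion of the whole chain |
| H^r scale | Kyte–Doolittle, min–max normalized to [0, 1] | — | reproducible, widely used default; any two-column file can be swapped in via `loadHydroScale()` |

Because O is normalized, the H^r scale only matters through its relative
spacing — multiplying the scale by a constant changes nothing (this is a
tested invariant). The scale is nevertheless the main source of numeric
drift when comparing RD/K values against published per-structure numbers
computed with a different (unpublished) scale; agreement at the printed
precision should only be expected when the original scale file is supplied.

## Orientation and the envelope

The Gaussian is axis-aligned, so the molecule must be brought into a
canonical frame first. `orientChain()` centres the effective-atom cloud and
rotates it onto its principal axes (largest variance on x). Principal-axis
alignment was chosen over alternatives (e.g. the longest inter-atom
diagonal) because it is deterministic, invariant under rigid motion, and
directly optimises the fit between the cloud's second moments and an
axis-aligned Gaussian. The sign ambiguity of each principal axis is resolved
by forcing the most extreme point on that axis positive; pairwise distances
(and hence O) are untouched by any of this. Domain selections are oriented
and enveloped on their own — a domain cut from a larger chain gets a fresh
frame and fresh sigmas, rather than inheriting the whole-chain profile.

Degenerate inputs: an all-coincident cloud has no principal axes and is
rejected; a perfectly uniform T has no complement, so K > 0 is undefined for
it and reported as an error; RD is undefined (and errors) only when O, T and
R all coincide. During step-wise elimination the uniform reference is
recomputed as `1/n` over the reduced length at every step, which keeps RD
well-defined throughout; ties in `|T − O|` break toward the lowest residue
index; if a reduced sub-chain reaches the state where O, T and R coincide,
it is treated as perfect agreement (RD 0) and the loop stops.

## The synthetic generator: what it emulates and what it does not

`synthSpec()` / `synthProfiles()` / `synthChain()` generate test systems
with known ground truth. Effective-atom positions are drawn from a Gaussian
with per-axis standard deviations (8, 6, 5) Å — a mildly prolate globule
with a radius of gyration near 11 Å, typical of a single domain of ~100
residues — and the defaults used throughout the tests are chains of 100
residues, 20 replicate seeds, and additive observation noise of sd 0.002
(profile units, i.e. a few percent of a typical profile value; 0.005 for the
coarser robustness checks).

At the *profile* level the generative law is the blend itself:
`O = M(T, K_true)` plus truncated Gaussian noise. This makes the
environment-factor estimator exactly self-consistent — on noiseless input
the scan recovers every grid K exactly, and under the default noise the mean
absolute recovery error stays within one grid step (both are tested).

At the *chain* level residue types are assigned by rank: the residues with
the highest target hydrophobicity get the most hydrophobic amino acids
(micelle mode) or the least (inverted mode). Only the ordering is
controlled, because micelle-likeness is an ordering property. A consequence
worth stating plainly: intermediate blend factors cannot be encoded
geometrically this way. The blend `M(T, K)` is a monotone increasing
transform of T whenever `K < Σ(max(T) − T_i)` (≈ 3 for n = 100), so a
blend-mode chain has exactly the same amino-acid ranks as a micelle-mode
chain, and the K recovered from its geometry stays near 0 until the ordering
flips. End-to-end chain tests therefore assert the qualitative contrast —
micelle-mode globules give median RD < 0.5, inverted-mode give median
RD > 0.5, and a micelle/inverted pair gives positive ΔRD and ΔK — while
exact K arithmetic is tested at the profile level where the generative law
applies.

The generator also does not emulate: backbone connectivity or realistic
bond geometry, side chains and packing, sequence correlations, secondary
structure, or crystallographic artefacts (altlocs, missing residues, B
factors). Passing tests on synthetic globules therefore demonstrate the
correctness of the statistics and the pipeline plumbing, not that any
particular real protein will show a given RD; real-structure behaviour
additionally depends on the H^r scale and the quality of the experimental
coordinates.

## Target-versus-model comparison

CASP-style models share the target's residue numbering, so pairing is by
residue-number intersection (no sequence alignment); a model covering less
than 80% of the target is rejected rather than silently compared. Each side
then gets a fully independent analysis — own orientation, own envelope, own
profiles — and deltas are model minus target, which makes the comparison
anti-symmetric under swapping (tested). Discordant segments are maximal runs
of ≥ 3 consecutive residues whose |T − O| deviation differs between model
and target by more than the 90th percentile of the per-residue differences;
both the run length and the quantile are explicit, configurable heuristics —
the underlying visual convention they mimic was never published as a rule.
The population-level utilities are deliberately plain: Pearson correlation
between RD and GDT_TS (Spearman via argument), and half-open RD bins of
width 0.1 with the final bin closed so RD = 1 is counted.

## Known limitations

* Published per-structure RD and K values are reproducible only
  approximately with the default scale, cutoff and σ rule (none of which
  were published alongside those values); the package treats them as
  configuration, not constants.
* Single chains only: no multi-chain complexes in the K analysis, no
  nucleic acids, no ligands (HETATM records are dropped on reading).
* K is a grid estimate; no continuous optimisation, and no statistical
  uncertainty is attached to RD or K.
* GDT_TS is consumed from external score tables, never computed.

```{r example}
ch <- synthChain(synthSpec(nResidues = 100, mode = "micelle", seed = 3))
fodAnalysis(ch)
```
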