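setMethod("show", "EffectiveAtomChain", function(object) {
  r <- object@residues
  cat("EffectiveAtomChain with", nrow(r), "residues",
      sprintf("(chain %s, %d-%d)\n", r$chain[1], min(r$resno), max(r$resno)))
})

setMethod("show", "GaussianEnvelope", function(object) {
  cat(sprintf("GaussianEnvelope: sigma = (%.2f, %.2f, %.2f) A\n",
              object@sigmas[1], object@sigmas[2], object@sigmas[3]))
})

setMethod("show", "HydroProfile", function(object) {
  cat(sprintf("HydroProfile [%s], %d residues, max %.4f\n",
              object@role, length(object@values), max(object@values)))
})

setMethod("show", "FODSummary", function(object) {
  cat(sprintf("FOD summary (N = %d): D_KL(O|T) = %.4f, D_KL(O|R) = %.4f bits\n",
              object@nResidues, object@dklOT, object@dklOR))
  cat(sprintf("  RD = %.3f -> %s\n", object@rd,
              if (object@rd < 0.5) "hydrophobic core present (RD < 0.5)"
              else "no hydrophobic core (RD >= 0.5)"))
})

setMethod("show", "MResult", function(object) {
  cat(sprintf("Environment-factor scan: optimal K = %.1f, D_KL(O|M) = %.4f bits (grid of %d)\n",
              object@k, object@dklOM, nrow(object@scan)))
})

setMethod("show", "EliminationResult", function(object) {
  cat(sprintf("Step-wise elimination: %d residue(s) removed, final RD = %.3f\n",
              length(object@removed), object@finalRd))
})

setMethod("show", "FODAnalysis", function(object) {
  cat("FODAnalysis of", length(object@chain), "residues\n")
  show(object@envelope)
  show(object@summary)
  show(object@mResult)
})

setMethod("show", "ComparisonReport", function(object) {
  cat("Target vs model comparison over", length(object@target@chain),
      "paired residues\n")
  cat(sprintf("  target: RD = %.3f, K = %.1f\n",
              object@target@summary@rd, object@target@mResult@k))
  cat(sprintf("  model:  RD = %.3f, K = %.1f\n",
              object@model@summary@rd, object@model@mResult@k))
  cat(sprintf("  delta (model - target): RD %+.3f, K %+.1f\n",
              object@deltaRd, object@deltaK))
  cat(sprintf("  discordant segments: %d\n", nrow(object@discordant)))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf("SynthSpec: %d residues, mode %s (K = %s), noise sd %.3g, seed %d\n",
              object@nResidues, object@mode,
              format(.effectiveK(object)), object@noiseSd, object@seed))
})
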