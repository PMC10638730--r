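#' Full FOD-M analysis of one chain
#'
#' Convenience pipeline: orient the chain on its principal axes, fit the
#' Gaussian envelope, compute the theoretical, observed and uniform
#' distributions, the divergence summary (RD), and scan the environment
#' factor K.
#'
#' @param chain an [EffectiveAtomChain].
#' @param scale H^r scale (see [loadHydroScale]).
#' @param cutoff interaction cutoff in Angstrom.
#' @param divisor envelope divisor (see [estimateEnvelope]).
#' @param grid K grid (see [optimizeK]).
#' @param orient orient the chain first (default TRUE; set FALSE if the
#'   coordinates are already centred and axis-aligned).
#' @return a [FODAnalysis].
#' @examples
#' ch <- synthChain(synthSpec(nResidues = 60, mode = "micelle", seed = 3))
#' a <- fodAnalysis(ch)
#' rd(a); optimalK(a)
#' @export
fodAnalysis <- function(chain, scale = defaultHydroScale(), cutoff = 9.0,
                        divisor = 3, grid = seq(0, 5, by = 0.1),
                        orient = TRUE) {
  stopifnot(is(chain, "EffectiveAtomChain"))
  if (orient) chain <- orientChain(chain)
  env <- estimateEnvelope(chain, divisor = divisor)
  tp <- theoreticalProfile(chain, env)
  op <- observedProfile(chain, scale = scale, cutoff = cutoff)
  rp <- uniformProfile(chain)
  summ <- relativeDistance(op, tp, rp)
  mres <- optimizeK(tp, op, grid = grid)
  new("FODAnalysis", chain = chain, envelope = env,
      tProfile = tp, oProfile = op, rProfile = rp,
      summary = summ, mResult = mres)
}

#' Analyse a structure file end to end
#'
#' Reads a PDB/mmCIF file, selects a chain and optional residue ranges
#' (domains get their own orientation and envelope refit), and runs
#' [fodAnalysis].
#'
#' @param path structure file.
#' @param chain chain id.
#' @param ranges residue range spec, `""` for the whole chain.
#' @param ... passed to [fodAnalysis].
#' @return a [FODAnalysis].
#' @export
analyzeStructure <- function(path, chain = "A", ranges = "", ...) {
  fodAnalysis(loadStructure(path, chain = chain, ranges = ranges), ...)
}

#' Per-residue profile table of an analysis
#'
#' @param analysis a [FODAnalysis].
#' @return data.frame with columns `residue_number`, `aa`, `T`, `O`, `R`,
#'   `M`, `T_minus_O`.
#' @export
profileTable <- function(analysis) {
  stopifnot(is(analysis, "FODAnalysis"))
  r <- analysis@chain@residues
  data.frame(residue_number = r$resno,
             aa = r$resid,
             T = analysis@tProfile@values,
             O = analysis@oProfile@values,
             R = analysis@rProfile@values,
             M = analysis@mResult@mProfile@values,
             T_minus_O = analysis@tProfile@values - analysis@oProfile@values,
             stringsAsFactors = FALSE)
}

#' Write the per-residue profile table as TSV
#'
#' @param analysis a [FODAnalysis].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(analysis, path) {
  utils::write.table(profileTable(analysis), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
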