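.residueKey <- function(chain) {
  r <- chain@residues
  paste0(r$resno, "|", trimws(r$insert))
}

.subsetChain <- function(chain, idx) {
  new("EffectiveAtomChain",
      residues = chain@residues[idx, , drop = FALSE],
      coords = chain@coords[idx, , drop = FALSE])
}

#' Compare a target structure with a predicted model
#'
#' Pairs the two chains by residue number (CASP models share the target
#' numbering; no sequence alignment is attempted), requires the intersection
#' to cover at least `minCoverage` of the target, and runs the full FOD-M
#' analysis independently on each structure: orientation, envelope fit,
#' T/O/R profiles, RD and the environment-factor scan. Deltas are model
#' minus target. The per-residue |T - O| deviation tracks of the two
#' structures are compared, and maximal runs of at least `minRun` residues
#' whose track difference exceeds the `quantile` quantile are flagged as
#' discordant segments - regions where the model fails to reproduce the
#' hydrophobicity arrangement of the target.
#'
#' @param target,model [EffectiveAtomChain]s of the experimental structure
#'   and the prediction.
#' @param scale H^r scale (see [loadHydroScale]).
#' @param cutoff interaction cutoff in Angstrom.
#' @param divisor envelope divisor (see [estimateEnvelope]).
#' @param grid K grid (see [optimizeK]).
#' @param minCoverage minimal fraction of target residues that must pair.
#' @param quantile,minRun discordant-segment heuristic parameters.
#' @return a [ComparisonReport].
#' @export
compareStructures <- function(target, model, scale = defaultHydroScale(),
                              cutoff = 9.0, divisor = 3,
                              grid = seq(0, 5, by = 0.1),
                              minCoverage = 0.8,
                              quantile = 0.9, minRun = 3L) {
  stopifnot(is(target, "EffectiveAtomChain"), is(model, "EffectiveAtomChain"))
  tk <- .residueKey(target)
  mk <- .residueKey(model)
  common <- intersect(tk, mk)
  if (length(common) < minCoverage * length(tk))
    stop("alignment failure: only ", length(common), " of ", length(tk),
         " target residues paired (need ", round(100 * minCoverage), "%)")
  tSub <- .subsetChain(target, match(common, tk))
  mSub <- .subsetChain(model, match(common, mk))

  ta <- fodAnalysis(tSub, scale = scale, cutoff = cutoff, divisor = divisor,
                    grid = grid)
  ma <- fodAnalysis(mSub, scale = scale, cutoff = cutoff, divisor = divisor,
                    grid = grid)

  devT <- abs(ta@tProfile@values - ta@oProfile@values)
  devM <- abs(ma@tProfile@values - ma@oProfile@values)
  diff <- abs(devM - devT)
  track <- data.frame(label = ta@tProfile@labels,
                      dev_target = devT, dev_model = devM, diff = diff,
                      stringsAsFactors = FALSE)

  thr <- stats::quantile(diff, quantile, names = FALSE)
  hot <- diff > thr
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- runs$values & runs$lengths >= minRun
  discordant <- data.frame(start = starts[sel], end = ends[sel],
                           length = runs$lengths[sel])

  new("ComparisonReport", target = ta, model = ma,
      deltaRd = ma@summary@rd - ta@summary@rd,
      deltaK = ma@mResult@k - ta@mResult@k,
      diffTrack = track, discordant = discordant)
}

#' Correlate model RD with GDT_TS over a model population
#'
#' Pearson (default) or Spearman correlation between the FOD relative
#' distance of each model and its GDT_TS score. A negative coefficient means
#' models drifting away from the micelle-like arrangement score worse.
#'
#' @param records data.frame with numeric columns `rd` and `gdt_ts`
#'   (e.g. assembled from [readScoresTable] plus per-model analyses).
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
correlateRdGdt <- function(records, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!all(c("rd", "gdt_ts") %in% names(records)))
    stop("records must have columns rd and gdt_ts")
  rd <- as.numeric(records$rd)
  gdt <- as.numeric(records$gdt_ts)
  if (length(rd) < 3L) stop("need at least 3 records")
  if (stats::sd(rd) == 0 || stats::sd(gdt) == 0)
    stop("undefined correlation: zero variance in rd or gdt_ts")
  stats::cor(rd, gdt, method = method)
}

#' Bin RD values into fixed-width ranges
#'
#' Histogram of a model or target population over RD ranges, as used to show
#' which part of the [0, 1] scale a prediction method populates. Bins are
#' half-open [lo, lo + width) with the final bin closed so RD = 1 is counted.
#'
#' @param rd numeric RD values in [0, 1], or a data.frame with an `rd` column.
#' @param width bin width (default 0.1).
#' @return named integer vector of counts, one per bin, summing to the input size.
#' @export
binByRd <- function(rd, width = 0.1) {
  if (is.data.frame(rd)) rd <- rd$rd
  rd <- as.numeric(rd)
  if (!(is.numeric(width) && length(width) == 1L && width > 0))
    stop("bin width must be positive")
  if (any(!is.finite(rd)) || any(rd < 0 | rd > 1))
    stop("all RD values must lie in [0, 1]")
  nbin <- ceiling(1 / width - 1e-9)
  idx <- pmin(floor(rd / width) + 1L, nbin)  # maps 1.0 into the final bin
  counts <- tabulate(idx, nbins = nbin)
  lo <- (seq_len(nbin) - 1L) * width
  names(counts) <- sprintf("[%.1f,%.1f%s", lo, pmin(lo + width, 1),
                           c(rep(")", nbin - 1L), "]"))
  counts
}

#' Read an external GDT_TS scores table
#'
#' GDT_TS is consumed as input (computed by the assessors), never derived
#' here. The table is TSV with header columns `target`, `model`, `gdt_ts`.
#'
#' @param path TSV file path.
#' @return data.frame with columns target, model, gdt_ts.
#' @export
readScoresTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target", "model", "gdt_ts")
  if (!all(need %in% names(tab)))
    stop("scores table must have header columns: ", paste(need, collapse = ", "))
  tab$gdt_ts <- as.numeric(tab$gdt_ts)
  if (any(!is.finite(tab$gdt_ts)) || any(tab$gdt_ts < 0 | tab$gdt_ts > 100))
    stop("gdt_ts values must be numeric in [0, 100]")
  tab[need]
}
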