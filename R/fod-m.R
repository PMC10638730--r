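#' Inverted (membrane-complement) distribution
#'
#' The idealised hydrophobicity arrangement of a membrane-embedded system is
#' the complement of the Gaussian drop: hydrophobic residues exposed, polar
#' residues central. Computed as max(T) - T_i, normalized to unit sum. A
#' perfectly uniform T has a zero complement and is rejected.
#'
#' @param t theoretical profile ([HydroProfile] or numeric).
#' @return a [HydroProfile] with role `"inverted"`.
#' @examples
#' profileValues(invertedProfile(c(0.5, 0.3, 0.2)))  # 0.0 0.4 0.6
#' @export
invertedProfile <- function(t) {
  tv <- .profileNumeric(t)
  labels <- if (is(t, "HydroProfile")) t@labels else NULL
  raw <- max(tv) - tv
  if (sum(raw) <= 0)
    stop("degenerate complement: theoretical profile is uniform")
  .newProfile(raw, "inverted", labels)
}

#' Environment-modified (M) distribution
#'
#' Blend of the Gaussian drop with its complement: M_i is proportional to
#' T_i + K * complement_i, where the complement is normalized before blending
#' and the blend is normalized after (two nested normalisations). K = 0
#' recovers T (pure aqueous environment); large K approaches the inverted
#' distribution (membrane-like environment).
#'
#' @param t theoretical profile ([HydroProfile] or numeric).
#' @param k environment factor, K >= 0.
#' @return a [HydroProfile] with role `"M"`.
#' @examples
#' profileValues(modifiedProfile(c(0.5, 0.3, 0.2), 1))  # 0.25 0.35 0.40
#' @export
modifiedProfile <- function(t, k) {
  if (!(is.numeric(k) && length(k) == 1L && is.finite(k) && k >= 0))
    stop("environment factor K must be a single non-negative number")
  tv <- .profileNumeric(t)
  labels <- if (is(t, "HydroProfile")) t@labels else NULL
  if (k == 0) return(.newProfile(tv, "M", labels))
  inv <- profileValues(invertedProfile(t))
  .newProfile(tv + k * inv, "M", labels)
}

#' Locate the environment factor K by grid scan
#'
#' Scans K over an ascending grid, computing D_KL(O | M(T, K)) at each point,
#' and returns the grid K with the minimal divergence (ties resolved toward
#' smaller K, i.e. the weaker environmental modification). The full scan is
#' kept for plotting.
#'
#' @param t,o theoretical and observed profiles (aligned, equal length).
#' @param grid ascending K grid (default 0 to 5 in steps of 0.1, covering the
#'   range reported for strongly membrane-adapted structures).
#' @return an [MResult].
#' @examples
#' tp <- c(0.5, 0.3, 0.2)
#' op <- profileValues(modifiedProfile(tp, 0.7))
#' optimalK(optimizeK(tp, op))  # 0.7
#' @export
optimizeK <- function(t, o, grid = seq(0, 5, by = 0.1)) {
  if (length(grid) < 1L) stop("K grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("K grid must be ascending")
  if (any(grid < 0)) stop("K grid must be non-negative")
  tv <- .profileNumeric(t)
  ov <- .profileNumeric(o)
  if (length(tv) != length(ov)) stop("profiles must be aligned")
  dkl <- vapply(grid, function(k)
    klDivergence(ov, modifiedProfile(t, k)), numeric(1))
  best <- which.min(dkl)  # first minimum = smallest k on an ascending grid
  new("MResult", k = grid[best], mProfile = modifiedProfile(t, grid[best]),
      dklOM = dkl[best],
      scan = data.frame(k = grid, dkl_om = dkl))
}

#' Step-wise elimination towards the hydrophobic core
#'
#' Repeatedly removes the residue with the greatest |T_i - O_i| deviation
#' (ties: lowest index), renormalizes the reduced T and O and recomputes RD
#' against a uniform reference over the reduced length, until RD drops below
#' `threshold` or `maxFraction` of the positions have been removed. The
#' surviving sub-chain is the micelle-like part responsible for solubility.
#'
#' @param t,o aligned theoretical and observed profiles, length >= 2.
#' @param threshold RD threshold in (0, 1), default 0.5 (core criterion).
#' @param maxFraction maximal fraction of positions that may be removed.
#' @return an [EliminationResult].
#' @export
eliminateCore <- function(t, o, threshold = 0.5, maxFraction = 0.5) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1))
    stop("threshold must lie strictly between 0 and 1")
  tv <- .profileNumeric(t)
  ov <- .profileNumeric(o)
  if (length(tv) != length(ov)) stop("profiles must be aligned")
  if (length(tv) < 2L) stop("need at least two positions")
  labels <- if (is(t, "HydroProfile")) t@labels else as.character(seq_along(tv))

  budget <- floor(maxFraction * length(tv))
  # a reduced chain where O, T and R all coincide has no divergence left to
  # resolve: treat as perfect agreement (RD 0) so the loop terminates
  currentRd <- function(tv, ov)
    tryCatch(
      relativeDistance(ov / sum(ov), tv / sum(tv),
                       rep(1 / length(tv), length(tv)))@rd,
      error = function(e) 0)
  rdNow <- currentRd(tv, ov)
  removed <- character(0)
  steps <- data.frame(removed = character(0), rd = numeric(0),
                      stringsAsFactors = FALSE)
  while (rdNow >= threshold && length(removed) < budget) {
    i <- which.max(abs(tv / sum(tv) - ov / sum(ov)))  # ties: lowest index
    removed <- c(removed, labels[i])
    tv <- tv[-i]; ov <- ov[-i]; labels <- labels[-i]
    rdNow <- currentRd(tv, ov)
    steps <- rbind(steps, data.frame(removed = removed[length(removed)],
                                     rd = rdNow, stringsAsFactors = FALSE))
  }
  new("EliminationResult", removed = removed, finalRd = rdNow, steps = steps)
}

#' Classify per-residue deviations of O from T
#'
#' Residues where the observed hydrophobicity falls short of the theoretical
#' value show a hydrophobicity deficit (often ligand-binding cavities or
#' active centres); residues exceeding it show an excess (often
#' protein-protein interfaces). `minMagnitude` sets a dead band around zero
#' below which a deviation is called neutral.
#'
#' @param t,o aligned theoretical and observed profiles.
#' @param minMagnitude non-negative dead-band half-width (default 0: pure sign).
#' @return character vector of `"deficit"`, `"excess"`, `"neutral"` per residue.
#' @export
classifyDeviations <- function(t, o, minMagnitude = 0) {
  if (!(is.numeric(minMagnitude) && length(minMagnitude) == 1L &&
        minMagnitude >= 0))
    stop("minMagnitude must be non-negative")
  tv <- .profileNumeric(t)
  ov <- .profileNumeric(o)
  if (length(tv) != length(ov)) stop("profiles must be aligned")
  out <- rep("neutral", length(tv))
  out[ov < tv - minMagnitude] <- "deficit"
  out[ov > tv + minMagnitude] <- "excess"
  out
}
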