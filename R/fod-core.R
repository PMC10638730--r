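.newProfile <- function(values, role, labels = NULL) {
  s <- sum(values)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize profile: non-positive total")
  if (is.null(labels)) labels <- as.character(seq_along(values))
  new("HydroProfile", values = as.numeric(values) / s, role = role,
      labels = as.character(labels))
}

.chainLabels <- function(chain) {
  r <- chain@residues
  paste0(r$resno, trimws(r$insert), ":", r$resid)
}

#' Theoretical (T) hydrophobicity distribution
#'
#' Evaluates the axis-aligned 3D Gaussian envelope at each residue's
#' effective-atom position and normalizes to unit sum. This is the idealised
#' micelle-like arrangement: maximal hydrophobicity at the centre of the
#' drop, decaying towards the surface.
#'
#' @param chain an [EffectiveAtomChain], oriented consistently with `env`.
#' @param env a [GaussianEnvelope].
#' @return a [HydroProfile] with role `"T"`.
#' @examples
#' ch <- effectiveAtomChain(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
#' env <- new("GaussianEnvelope", center = c(0, 0, 0), sigmas = c(3, 3, 3))
#' round(profileValues(theoreticalProfile(ch, env)), 4)  # 0.4519 0.2741 0.2741
#' @export
theoreticalProfile <- function(chain, env) {
  stopifnot(is(chain, "EffectiveAtomChain"), is(env, "GaussianEnvelope"))
  d <- sweep(chain@coords, 2L, env@center)
  logg <- -(d^2) %*% (1 / (2 * env@sigmas^2))
  raw <- exp(logg - max(logg))  # stable for far-flung points
  .newProfile(raw, "T", .chainLabels(chain))
}

# distance-damping weight of the pairwise hydrophobic interaction
# (Levitt-style polynomial in (r/c)^2, 1 at contact, 0 at the cutoff)
.interactionWeight <- function(r, cutoff) {
  x <- r / cutoff
  w <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^8)
  w[r > cutoff] <- 0
  w
}

#' Observed (O) hydrophobicity distribution
#'
#' The actual per-residue hydrophobicity resulting from pairwise inter-residue
#' interaction: each pair within the cutoff contributes the sum of the two
#' intrinsic hydrophobicities, damped by a polynomial that falls from 1 at
#' contact to 0 at the cutoff distance. The self pair is included by default
#' (its weight is 1); because the profile is normalized this only matters
#' when residues interact unevenly.
#'
#' @param chain an [EffectiveAtomChain].
#' @param scale named H^r vector, see [loadHydroScale]; must cover every
#'   residue type present.
#' @param cutoff interaction cutoff distance in Angstrom (default 9.0).
#' @param includeSelf include the i = j term (default TRUE).
#' @return a [HydroProfile] with role `"O"`.
#' @export
observedProfile <- function(chain, scale = defaultHydroScale(), cutoff = 9.0,
                            includeSelf = TRUE) {
  stopifnot(is(chain, "EffectiveAtomChain"))
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0))
    stop("cutoff must be a positive distance")
  resid <- chain@residues$resid
  h <- unname(scale[resid])
  if (anyNA(h))
    stop("residue type(s) absent from hydrophobicity scale: ",
         paste(unique(resid[is.na(h)]), collapse = ", "))
  dm <- as.matrix(stats::dist(chain@coords))
  w <- .interactionWeight(dm, cutoff)
  if (!includeSelf) diag(w) <- 0
  hsum <- outer(h, h, `+`)
  raw <- rowSums(hsum * w)
  .newProfile(raw, "O", .chainLabels(chain))
}

#' Uniform reference (R) distribution
#'
#' The no-core reference: hydrophobicity spread evenly over the chain,
#' 1/N per residue.
#'
#' @param n chain length (N >= 1) or an [EffectiveAtomChain].
#' @return a [HydroProfile] with role `"R"`.
#' @export
uniformProfile <- function(n) {
  labels <- NULL
  if (is(n, "EffectiveAtomChain")) {
    labels <- .chainLabels(n)
    n <- length(n)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("empty chain: N must be at least 1")
  .newProfile(rep(1 / n, n), "R", labels)
}

.profileNumeric <- function(p) {
  if (is(p, "HydroProfile")) p@values else as.numeric(p)
}

#' Kullback-Leibler divergence between two profiles, in bits
#'
#' Divergence entropy sum P_i log2(P_i / Q_i). Entries below `clamp`
#' (default 1e-10) in either profile are raised to `clamp` and the profiles
#' renormalized before evaluation, so observed profiles containing exact
#' zeros remain comparable (the theoretical Gaussian is strictly positive,
#' but an observed or complement profile need not be).
#'
#' @param p,q profiles ([HydroProfile] or numeric vectors of equal length).
#' @param clamp lower clamp applied to both distributions.
#' @return divergence in bits (non-negative).
#' @examples
#' klDivergence(c(0.5, 0.5), c(0.9, 0.1))  # 0.7369656
#' @export
klDivergence <- function(p, q, clamp = 1e-10) {
  pv <- .profileNumeric(p)
  qv <- .profileNumeric(q)
  if (length(pv) != length(qv))
    stop("profiles have different lengths (", length(pv), " vs ", length(qv), ")")
  pv <- pmax(pv, clamp); pv <- pv / sum(pv)
  qv <- pmax(qv, clamp); qv <- qv / sum(qv)
  sum(pv * log2(pv / qv))
}

#' Relative distance RD of an observed distribution
#'
#' RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R)) locates the observed
#' distribution between the idealised Gaussian (RD = 0) and the uniform
#' no-core reference (RD = 1). RD < 0.5 indicates the presence of a
#' hydrophobic core.
#'
#' @param o,t,r observed, theoretical and uniform profiles (equal length).
#' @return a [FODSummary].
#' @examples
#' s <- relativeDistance(c(0.40, 0.35, 0.25), c(0.5, 0.3, 0.2), rep(1/3, 3))
#' rd(s)  # 0.531
#' @export
relativeDistance <- function(o, t, r = uniformProfile(length(.profileNumeric(o)))) {
  dot <- klDivergence(o, t)
  dor <- klDivergence(o, r)
  denom <- dot + dor
  if (denom <= 0)
    stop("undefined RD: O, T and R coincide (zero total divergence)")
  new("FODSummary", dklOT = dot, dklOR = dor, rd = dot / denom,
      nResidues = length(.profileNumeric(o)))
}
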