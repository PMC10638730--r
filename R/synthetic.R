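#' Specification of a synthetic structure
#'
#' Bundle of generator parameters: chain length, the generative Gaussian
#' envelope, the environment mode, and the noise level. `mode = "micelle"`
#' emulates an aqueous micelle-like globule (observed follows the Gaussian,
#' K = 0); `"inverted"` a membrane-like system (observed follows the
#' complement; internally a very large K); `"blend"` an intermediate
#' environment at `kTrue`. All draws are reproducible from `seed`.
#'
#' @slot nResidues chain length (>= 2).
#' @slot sigmas generative per-axis standard deviations in Angstrom.
#' @slot mode "micelle", "inverted" or "blend".
#' @slot kTrue environment factor used in blend mode.
#' @slot noiseSd standard deviation of additive observation noise.
#' @slot seed integer RNG seed.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(nResidues = "integer", sigmas = "numeric", mode = "character",
                 kTrue = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nResidues < 2L) msg <- c(msg, "nResidues must be at least 2")
    if (length(object@sigmas) != 3L || any(object@sigmas <= 0))
      msg <- c(msg, "sigmas must be three positive numbers")
    if (!object@mode %in% c("micelle", "inverted", "blend"))
      msg <- c(msg, "mode must be micelle, inverted or blend")
    if (!is.finite(object@kTrue) || object@kTrue < 0)
      msg <- c(msg, "kTrue must be non-negative")
    if (!is.finite(object@noiseSd) || object@noiseSd < 0)
      msg <- c(msg, "noiseSd must be non-negative")
    if (is.null(msg)) TRUE else msg
  }
)

#' @param nResidues,sigmas,mode,kTrue,noiseSd,seed see slots above. The
#'   default envelope (8, 6, 5 Angstrom) gives a mildly prolate globule with
#'   a radius of gyration near 11 Angstrom, typical of a ~100-residue
#'   single-domain protein.
#' @return a [SynthSpec].
#' @rdname SynthSpec-class
#' @export
synthSpec <- function(nResidues = 100, sigmas = c(8, 6, 5),
                      mode = c("micelle", "inverted", "blend"),
                      kTrue = 0, noiseSd = 0, seed = 1) {
  mode <- match.arg(mode)
  new("SynthSpec", nResidues = as.integer(nResidues), sigmas = as.numeric(sigmas),
      mode = mode, kTrue = as.numeric(kTrue), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# run code with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.effectiveK <- function(spec) {
  switch(spec@mode, micelle = 0, inverted = 1000, blend = spec@kTrue)
}

.synthCoords <- function(spec) {
  matrix(stats::rnorm(3L * spec@nResidues,
                      sd = rep(spec@sigmas, each = spec@nResidues)),
         ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}

#' Generate a (T, O) profile pair with known ground truth
#'
#' Samples effective-atom positions from the spec's Gaussian envelope,
#' evaluates the theoretical distribution there, and derives the observed
#' distribution by the generative law O = M(T, K) plus optional additive
#' Gaussian noise (truncated at zero, then renormalized). In micelle mode
#' K = 0 so the noiseless observed equals the theoretical distribution.
#'
#' @param spec a [SynthSpec].
#' @return list with elements `t` and `o` ([HydroProfile]s) and `kTrue`.
#' @examples
#' p <- synthProfiles(synthSpec(nResidues = 50, mode = "blend",
#'                              kTrue = 0.4, seed = 7))
#' optimalK(optimizeK(p$t, p$o))  # 0.4
#' @export
synthProfiles <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  .withSeed(spec@seed, {
    coords <- .synthCoords(spec)
    chain <- effectiveAtomChain(coords)
    env <- new("GaussianEnvelope", center = c(0, 0, 0), sigmas = spec@sigmas)
    tProf <- theoreticalProfile(chain, env)
    k <- .effectiveK(spec)
    ov <- profileValues(modifiedProfile(tProf, k))
    if (spec@noiseSd > 0) {
      ov <- pmax(ov + stats::rnorm(length(ov), sd = spec@noiseSd), 0)
      if (sum(ov) <= 0) stop("noise wiped out the observed profile")
    }
    list(t = tProf,
         o = .newProfile(ov, "O", tProf@labels),
         kTrue = k)
  })
}

#' Generate a synthetic effective-atom chain
#'
#' Samples the same point cloud as [synthProfiles] and assigns amino-acid
#' types by rank: the residues with the highest generative target
#' hydrophobicity receive the most hydrophobic amino acids of `scale`
#' (micelle mode), or the least hydrophobic ones (inverted mode); blend mode
#' ranks against the blended distribution at `kTrue`. Only the ordering of
#' intrinsic hydrophobicities is controlled, which is what micelle-likeness
#' depends on; the observed profile of the returned chain is then computed
#' from real pairwise geometry by [observedProfile], not copied from the
#' generative law.
#'
#' @param spec a [SynthSpec].
#' @param scale H^r scale used for the rank assignment.
#' @return an [EffectiveAtomChain] with assigned residue types.
#' @export
synthChain <- function(spec, scale = defaultHydroScale()) {
  stopifnot(is(spec, "SynthSpec"))
  .withSeed(spec@seed, {
    coords <- .synthCoords(spec)
    chain <- effectiveAtomChain(coords)
    env <- new("GaussianEnvelope", center = c(0, 0, 0), sigmas = spec@sigmas)
    tv <- profileValues(theoreticalProfile(chain, env))
    targetV <- switch(spec@mode,
      micelle = tv,
      inverted = profileValues(invertedProfile(tv)),
      blend = profileValues(modifiedProfile(tv, spec@kTrue)))
    aaSorted <- names(sort(scale))  # ascending H^r
    n <- spec@nResidues
    rk <- rank(targetV, ties.method = "first")
    aa <- aaSorted[ceiling(rk / n * length(aaSorted))]
    effectiveAtomChain(coords, resid = aa)
  })
}

#' Write a chain as a CA-only PDB file
#'
#' One CA atom per residue at the effective-atom position, so that re-reading
#' the file with [loadStructure] reproduces the chain exactly (up to the
#' 0.001 Angstrom precision of the fixed-width PDB coordinate fields).
#'
#' @param chain an [EffectiveAtomChain].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChainPDB <- function(chain, path) {
  stopifnot(is(chain, "EffectiveAtomChain"))
  r <- chain@residues
  n <- nrow(r)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(chain@coords)),
                   type = rep("ATOM", n),
                   resno = r$resno, resid = r$resid, chain = r$chain,
                   insert = ifelse(nzchar(r$insert), r$insert, NA),
                   eleno = seq_len(n), elety = rep("CA", n),
                   o = rep(1, n), b = rep(0, n),
                   elesy = rep("C", n))
  invisible(path)
}
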