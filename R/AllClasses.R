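#' @import methods
NULL

#' EffectiveAtomChain: per-residue effective-atom representation of a chain
#'
#' Each residue of a selected protein chain is reduced to a single point, the
#' unweighted mean of its heavy-atom coordinates ("effective atom"). Residue
#' identity (chain id, residue number, insertion code, 3-letter code) is kept
#' alongside so profiles can be reported per residue.
#'
#' @slot residues data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter amino-acid code), one row per residue, in sequence order.
#' @slot coords numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @exportClass EffectiveAtomChain
setClass("EffectiveAtomChain",
  representation(residues = "data.frame", coords = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@residues)
    if (n < 1L) msg <- c(msg, "chain must contain at least one residue")
    if (!identical(nrow(object@coords), n))
      msg <- c(msg, "exactly one coordinate row per residue is required")
    if (!identical(ncol(object@coords), 3L))
      msg <- c(msg, "coords must have three columns (x, y, z)")
    if (n >= 1L && !all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
    need <- c("chain", "resno", "insert", "resid")
    if (!all(need %in% names(object@residues)))
      msg <- c(msg, paste("residues must have columns:", paste(need, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  }
)

#' GaussianEnvelope: axis-aligned 3D Gaussian spanning the protein body
#'
#' Parameters of the Gaussian "drop" used for the theoretical hydrophobicity
#' distribution: a centre and one standard deviation per coordinate axis.
#'
#' @slot center numeric(3), centre in Angstrom.
#' @slot sigmas numeric(3), strictly positive per-axis standard deviations (Angstrom).
#' @exportClass GaussianEnvelope
setClass("GaussianEnvelope",
  representation(center = "numeric", sigmas = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
    if (length(object@sigmas) != 3L) msg <- c(msg, "sigmas must have length 3")
    if (length(object@sigmas) == 3L && !all(is.finite(object@sigmas) & object@sigmas > 0))
      msg <- c(msg, "all sigmas must be strictly positive and finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' HydroProfile: normalized per-residue hydrophobicity distribution
#'
#' A non-negative per-residue vector summing to one, tagged with its role in
#' the model: theoretical (`"T"`), observed (`"O"`), uniform reference (`"R"`),
#' the Gaussian complement (`"inverted"`), or the environment-blended
#' distribution (`"M"`).
#'
#' @slot values numeric vector, non-negative, sums to 1 (tolerance 1e-9).
#' @slot role one of "T", "O", "R", "inverted", "M".
#' @slot labels character residue labels aligned with an [EffectiveAtomChain].
#' @exportClass HydroProfile
setClass("HydroProfile",
  representation(values = "numeric", role = "character", labels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) < 1L) msg <- c(msg, "profile must be non-empty")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "profile values must be finite and non-negative")
    if (abs(sum(object@values) - 1) > 1e-9)
      msg <- c(msg, "profile values must sum to 1 (tolerance 1e-9)")
    if (!(length(object@role) == 1L &&
          object@role %in% c("T", "O", "R", "inverted", "M")))
      msg <- c(msg, "role must be one of T, O, R, inverted, M")
    if (length(object@labels) != length(object@values))
      msg <- c(msg, "labels must align with values")
    if (is.null(msg)) TRUE else msg
  }
)

#' FODSummary: divergence statistics of an observed distribution
#'
#' Holds D_KL(O|T) and D_KL(O|R) in bits and the relative distance
#' RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R)). RD < 0.5 indicates a
#' hydrophobic core (O closer to the Gaussian than to uniform).
#'
#' @slot dklOT numeric, D_KL(O|T) in bits, non-negative.
#' @slot dklOR numeric, D_KL(O|R) in bits, non-negative.
#' @slot rd numeric in [0, 1].
#' @slot nResidues integer, chain length the statistics refer to.
#' @exportClass FODSummary
setClass("FODSummary",
  representation(dklOT = "numeric", dklOR = "numeric", rd = "numeric",
                 nResidues = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@dklOT < -1e-12) msg <- c(msg, "dklOT must be non-negative")
    if (object@dklOR < -1e-12) msg <- c(msg, "dklOR must be non-negative")
    if (object@rd < -1e-12 || object@rd > 1 + 1e-12)
      msg <- c(msg, "rd must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' MResult: environment-factor scan result
#'
#' Result of scanning the environment factor K over a grid: the blended
#' distribution M(K) minimising D_KL(O|M), the divergence at the optimum, and
#' the full scan for plotting.
#'
#' @slot k optimal environment factor (grid point with minimal divergence;
#'   ties resolved toward smaller K).
#' @slot mProfile [HydroProfile] of role "M" at the optimal K.
#' @slot dklOM divergence D_KL(O|M) in bits at the optimum.
#' @slot scan data.frame with columns `k` and `dkl_om` covering the full grid.
#' @exportClass MResult
setClass("MResult",
  representation(k = "numeric", mProfile = "HydroProfile", dklOM = "numeric",
                 scan = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!(length(object@k) == 1L && is.finite(object@k) && object@k >= 0))
      msg <- c(msg, "k must be a single non-negative number")
    if (!all(c("k", "dkl_om") %in% names(object@scan)))
      msg <- c(msg, "scan must have columns k and dkl_om")
    if (nrow(object@scan) > 0 &&
        object@dklOM > min(object@scan$dkl_om) + 1e-12)
      msg <- c(msg, "dklOM must be the scan minimum")
    if (is.null(msg)) TRUE else msg
  }
)

#' EliminationResult: step-wise hydrophobic-core extraction
#'
#' Record of repeatedly removing the residue with the largest |T - O|
#' deviation until the remaining chain satisfies RD < threshold or the
#' removal budget is exhausted.
#'
#' @slot removed character, residue labels in removal order.
#' @slot finalRd RD of the surviving sub-chain.
#' @slot steps data.frame with columns `removed` and `rd` (RD after each removal).
#' @exportClass EliminationResult
setClass("EliminationResult",
  representation(removed = "character", finalRd = "numeric", steps = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@removed))
      msg <- c(msg, "removed positions must be distinct")
    if (!identical(nrow(object@steps), length(object@removed)))
      msg <- c(msg, "steps must have one row per removed position")
    if (is.null(msg)) TRUE else msg
  }
)

#' FODAnalysis: full single-structure analysis
#'
#' Container tying together the oriented chain, its Gaussian envelope, the
#' T/O/R profiles, the divergence summary and the environment-factor scan.
#'
#' @slot chain oriented [EffectiveAtomChain].
#' @slot envelope [GaussianEnvelope].
#' @slot tProfile,oProfile,rProfile the three [HydroProfile]s.
#' @slot summary [FODSummary].
#' @slot mResult [MResult].
#' @exportClass FODAnalysis
setClass("FODAnalysis",
  representation(chain = "EffectiveAtomChain", envelope = "GaussianEnvelope",
                 tProfile = "HydroProfile", oProfile = "HydroProfile",
                 rProfile = "HydroProfile", summary = "FODSummary",
                 mResult = "MResult"))

#' ComparisonReport: target-versus-model FOD comparison
#'
#' Full FOD-M analyses of a target structure and a predicted model over their
#' shared residues, with deltas (model minus target), the per-residue |T - O|
#' tracks, and segments where the model fails to reproduce the target's
#' hydrophobicity arrangement.
#'
#' @slot target,model [FODAnalysis] of each structure.
#' @slot deltaRd,deltaK model value minus target value.
#' @slot diffTrack data.frame with per-residue columns `label`,
#'   `dev_target`, `dev_model` (|T - O| each) and `diff` (absolute difference
#'   of the two tracks).
#' @slot discordant data.frame of maximal runs (columns `start`, `end`,
#'   `length`, 1-based positions along the aligned chain) where `diff` exceeds
#'   its upper quantile for at least `minRun` consecutive residues.
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(target = "FODAnalysis", model = "FODAnalysis",
                 deltaRd = "numeric", deltaK = "numeric",
                 diffTrack = "data.frame", discordant = "data.frame"))
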