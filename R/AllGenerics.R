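#' Accessors for FOD result objects
#'
#' Small generics giving read access to the slots of the S4 result classes:
#' `rd()`, `dklOT()`, `dklOR()` on summaries and analyses; `optimalK()`,
#' `kScan()` on K-scan results and analyses; `profileValues()`,
#' `profileRole()`, `profileLabels()` on profiles; `chainCoords()`,
#' `residueLabels()`, `residueTable()` on chains; `envelopeCenter()`,
#' `envelopeSigmas()` on envelopes.
#'
#' @param x an object of the matching class.
#' @return the slot value (numeric, character, matrix or data.frame).
#' @name fodm-accessors
#' @rdname fodm-accessors
#' @examples
#' p <- uniformProfile(4)
#' profileValues(p)
#' profileRole(p)
NULL

#' @rdname fodm-accessors
#' @export
setGeneric("rd", function(x) standardGeneric("rd"))

#' @rdname fodm-accessors
#' @export
setGeneric("dklOT", function(x) standardGeneric("dklOT"))

#' @rdname fodm-accessors
#' @export
setGeneric("dklOR", function(x) standardGeneric("dklOR"))

#' @rdname fodm-accessors
#' @export
setGeneric("optimalK", function(x) standardGeneric("optimalK"))

#' @rdname fodm-accessors
#' @export
setGeneric("kScan", function(x) standardGeneric("kScan"))

#' @rdname fodm-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname fodm-accessors
#' @export
setGeneric("profileRole", function(x) standardGeneric("profileRole"))

#' @rdname fodm-accessors
#' @export
setGeneric("profileLabels", function(x) standardGeneric("profileLabels"))

#' @rdname fodm-accessors
#' @export
setGeneric("chainCoords", function(x) standardGeneric("chainCoords"))

#' @rdname fodm-accessors
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname fodm-accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname fodm-accessors
#' @export
setGeneric("envelopeCenter", function(x) standardGeneric("envelopeCenter"))

#' @rdname fodm-accessors
#' @export
setGeneric("envelopeSigmas", function(x) standardGeneric("envelopeSigmas"))

setMethod("profileValues", "HydroProfile", function(x) x@values)
setMethod("profileRole", "HydroProfile", function(x) x@role)
setMethod("profileLabels", "HydroProfile", function(x) x@labels)

setMethod("chainCoords", "EffectiveAtomChain", function(x) x@coords)
setMethod("residueTable", "EffectiveAtomChain", function(x) x@residues)
setMethod("residueLabels", "EffectiveAtomChain", function(x) {
  r <- x@residues
  paste0(r$chain, ":", r$resno, trimws(r$insert), ":", r$resid)
})

setMethod("envelopeCenter", "GaussianEnvelope", function(x) x@center)
setMethod("envelopeSigmas", "GaussianEnvelope", function(x) x@sigmas)

setMethod("rd", "FODSummary", function(x) x@rd)
setMethod("dklOT", "FODSummary", function(x) x@dklOT)
setMethod("dklOR", "FODSummary", function(x) x@dklOR)

setMethod("optimalK", "MResult", function(x) x@k)
setMethod("kScan", "MResult", function(x) x@scan)

setMethod("rd", "FODAnalysis", function(x) x@summary@rd)
setMethod("dklOT", "FODAnalysis", function(x) x@summary@dklOT)
setMethod("dklOR", "FODAnalysis", function(x) x@summary@dklOR)
setMethod("optimalK", "FODAnalysis", function(x) x@mResult@k)
setMethod("kScan", "FODAnalysis", function(x) x@mResult@scan)

#' @rdname fodm-accessors
#' @export
setMethod("length", "EffectiveAtomChain", function(x) nrow(x@residues))

#' @rdname fodm-accessors
#' @export
setMethod("length", "HydroProfile", function(x) length(x@values))
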