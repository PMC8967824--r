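#' @name szdpd-accessors
#' @title Accessors for szdpd classes
#' @description Slot accessors for [Spectrum-class], [EncodedStack-class],
#'   [PrecisionConfig-class] and [MiniAirdRun-class] objects.
#' @param object a szdpd object.
#' @return The corresponding slot value.
NULL

#' @rdname szdpd-accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))
#' @rdname szdpd-accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname szdpd-accessors
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))
#' @rdname szdpd-accessors
#' @export
setGeneric("msLevel", function(object) standardGeneric("msLevel"))
#' @rdname szdpd-accessors
#' @export
setGeneric("precursorWindow", function(object) standardGeneric("precursorWindow"))
#' @rdname szdpd-accessors
#' @export
setGeneric("peaksCount", function(object) standardGeneric("peaksCount"))
#' @rdname szdpd-accessors
#' @export
setGeneric("decimalPlaces", function(object) standardGeneric("decimalPlaces"))
#' @rdname szdpd-accessors
#' @export
setGeneric("quantScale", function(object) standardGeneric("quantScale"))
#' @rdname szdpd-accessors
#' @export
setGeneric("layerExponent", function(object) standardGeneric("layerExponent"))
#' @rdname szdpd-accessors
#' @export
setGeneric("spectrumCount", function(object) standardGeneric("spectrumCount"))
#' @rdname szdpd-accessors
#' @export
setGeneric("peaksPerLayer", function(object) standardGeneric("peaksPerLayer"))
#' @rdname szdpd-accessors
#' @export
setGeneric("acquisitionMode", function(object) standardGeneric("acquisitionMode"))
#' @rdname szdpd-accessors
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname szdpd-accessors
#' @export
setMethod("mz", "Spectrum", function(object) object@mz)
#' @rdname szdpd-accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@intensity)
#' @rdname szdpd-accessors
#' @export
setMethod("rtime", "Spectrum", function(object) object@rt)
#' @rdname szdpd-accessors
#' @export
setMethod("msLevel", "Spectrum", function(object) object@msLevel)
#' @rdname szdpd-accessors
#' @export
setMethod("precursorWindow", "Spectrum", function(object) {
    if (length(object@precursorWindow)) object@precursorWindow else NULL
})
#' @rdname szdpd-accessors
#' @export
setMethod("peaksCount", "Spectrum", function(object) length(object@mz))

#' @rdname szdpd-accessors
#' @export
setMethod("decimalPlaces", "PrecisionConfig", function(object) object@decimalPlaces)
#' @rdname szdpd-accessors
#' @export
setMethod("quantScale", "PrecisionConfig", function(object) object@scale)

#' @rdname szdpd-accessors
#' @export
setMethod("layerExponent", "EncodedStack", function(object) object@layerExponent)
#' @rdname szdpd-accessors
#' @export
setMethod("spectrumCount", "EncodedStack", function(object) object@spectrumCount)
#' @rdname szdpd-accessors
#' @export
setMethod("peaksPerLayer", "EncodedStack", function(object) object@peaksPerLayer)

#' @rdname szdpd-accessors
#' @export
setMethod("acquisitionMode", "MiniAirdRun", function(object) object@meta$mode)
#' @rdname szdpd-accessors
#' @export
setMethod("nSpectra", "MiniAirdRun", function(object) object@meta$totalSpectra)
#' @rdname szdpd-accessors
#' @export
setMethod("decimalPlaces", "MiniAirdRun", function(object)
    object@meta$precision$decimalPlaces)
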