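#' Precision configuration for m/z quantization
#'
#' Maps a decimal-place count \code{dp} to the integer scale \eqn{10^{dp}}
#' used to quantize m/z values. Supported precisions are 4, 5 and 6 decimal
#' places; 4 dp corresponds to roughly 1 ppm relative accuracy on a
#' low-mass ion and 5 dp to 0.1 ppm.
#'
#' @slot decimalPlaces integer, one of 4, 5, 6.
#' @slot scale numeric, always \code{10^decimalPlaces}.
#' @slot ppmLabel human-readable ppm equivalence (NA where not conventional).
#' @exportClass PrecisionConfig
setClass("PrecisionConfig", representation(
    decimalPlaces = "integer",
    scale = "numeric",
    ppmLabel = "character"
))

setValidity("PrecisionConfig", function(object) {
    dp <- object@decimalPlaces
    if (length(dp) != 1 || !(dp %in% c(4L, 5L, 6L)))
        return("decimalPlaces must be one of 4, 5, 6")
    if (length(object@scale) != 1 || object@scale != 10^dp)
        return("scale must equal 10^decimalPlaces")
    TRUE
})

#' Construct a PrecisionConfig
#'
#' @param decimalPlaces number of decimal places kept in stored m/z values
#'   (4, 5 or 6). Defaults to 5, the precision at which stored data are in
#'   practice indistinguishable from the original floats in downstream
#'   chromatogram building.
#' @return A [PrecisionConfig-class] object.
#' @examples
#' precisionConfig(4)   # scale 10000, ~1 ppm
#' @export
precisionConfig <- function(decimalPlaces = 5L) {
    if (length(decimalPlaces) != 1 || is.na(decimalPlaces) ||
        !(as.numeric(decimalPlaces) %in% c(4, 5, 6)))
        stopConfig("precision must be 4, 5 or 6 decimal places, got '%s'",
                   paste(decimalPlaces, collapse = ","))
    dp <- as.integer(decimalPlaces)
    lab <- c(`4` = "1 ppm", `5` = "0.1 ppm", `6` = NA_character_)[[as.character(dp)]]
    new("PrecisionConfig", decimalPlaces = dp, scale = 10^dp, ppmLabel = lab)
}

setMethod("show", "PrecisionConfig", function(object) {
    cat(sprintf("PrecisionConfig: %d decimal places (scale %g%s)\n",
                object@decimalPlaces, object@scale,
                if (is.na(object@ppmLabel)) "" else paste0(", ~", object@ppmLabel)))
})

#' A single mass spectrum (centroid peak list)
#'
#' One scan: retention time, MS level, optional precursor isolation window,
#' and paired m/z / intensity arrays with m/z sorted non-decreasing.
#'
#' @slot rt retention time in seconds.
#' @slot msLevel 1 (survey) or 2 (fragment).
#' @slot precursorWindow numeric(0) for MS1, or c(lower, upper) m/z bounds
#'   in Daltons of the precursor isolation window for MS2.
#' @slot mz numeric, non-decreasing m/z values in Daltons.
#' @slot intensity numeric, same length as mz.
#' @exportClass Spectrum
setClass("Spectrum", representation(
    rt = "numeric",
    msLevel = "integer",
    precursorWindow = "numeric",
    mz = "numeric",
    intensity = "numeric"
))

setValidity("Spectrum", function(object) {
    if (length(object@rt) != 1 || is.na(object@rt) || object@rt < 0)
        return("rt must be a single non-negative number (seconds)")
    if (length(object@msLevel) != 1 || !(object@msLevel %in% c(1L, 2L)))
        return("msLevel must be 1 or 2")
    if (length(object@mz) != length(object@intensity))
        return("mz and intensity must have the same length")
    if (anyNA(object@mz) || (length(object@mz) && any(!is.finite(object@mz))))
        return("mz values must be finite")
    if (is.unsorted(object@mz))
        return("mz must be non-decreasing (use sortSpectrum)")
    if (object@msLevel == 2L) {
        w <- object@precursorWindow
        if (length(w) != 2 || anyNA(w) || w[1] > w[2])
            return("MS2 spectra need precursorWindow = c(lower, upper) with lower <= upper")
    } else if (length(object@precursorWindow) != 0) {
        return("MS1 spectra must not carry a precursorWindow")
    }
    TRUE
})

#' Construct a Spectrum
#'
#' @param mz non-decreasing m/z values (Daltons).
#' @param intensity intensities, same length as `mz`.
#' @param rt retention time in seconds.
#' @param msLevel 1 or 2.
#' @param precursorWindow for MS2, `c(lower, upper)` isolation bounds.
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum(c(100.1, 200.2), c(10, 20), rt = 1.5)
#' @export
Spectrum <- function(mz = numeric(), intensity = numeric(), rt = 0,
                     msLevel = 1L, precursorWindow = NULL) {
    new("Spectrum",
        rt = as.numeric(rt), msLevel = as.integer(msLevel),
        precursorWindow = if (is.null(precursorWindow)) numeric()
                          else as.numeric(precursorWindow),
        mz = as.numeric(mz), intensity = as.numeric(intensity))
}

setMethod("show", "Spectrum", function(object) {
    cat(sprintf("Spectrum: MS%d, rt %.3f s, %d peaks",
                object@msLevel, object@rt, length(object@mz)))
    if (object@msLevel == 2L)
        cat(sprintf(", window [%.4f, %.4f]",
                    object@precursorWindow[1], object@precursorWindow[2]))
    cat("\n")
})

#' One encoded stack of spectra
#'
#' The compressed unit of Stack-ZDPD: up to \eqn{2^n} same-level (and, for
#' MS2, same-window) spectra merged into one sorted quantized m/z array.
#' Payload slots hold the compressed byte strings; metadata slots record
#' what is needed to take the stack apart again.
#'
#' @slot layerExponent n; the stack holds up to 2^n spectra and each peak's
#'   tag occupies n bits.
#' @slot spectrumCount actual number of spectra in this stack (<= 2^n).
#' @slot peaksPerLayer integer vector, peaks contributed by each spectrum.
#' @slot mzPayload compressed merged m/z array (delta + PFor + zlib).
#' @slot tagPayload zlib-compressed bit-packed tag array (empty when n = 0).
#' @slot intensityPayload zlib-compressed intensities in merged order,
#'   little-endian IEEE floats.
#' @slot intensityWidth bytes per stored intensity (4 or 8).
#' @exportClass EncodedStack
setClass("EncodedStack", representation(
    layerExponent = "integer",
    spectrumCount = "integer",
    peaksPerLayer = "integer",
    mzPayload = "raw",
    tagPayload = "raw",
    intensityPayload = "raw",
    intensityWidth = "integer"
))

setValidity("EncodedStack", function(object) {
    n <- object@layerExponent
    if (length(n) != 1 || is.na(n) || n < 0 || n > 16)
        return("layerExponent must be in 0..16")
    k <- object@spectrumCount
    if (length(k) != 1 || is.na(k) || k < 1 || k > 2^n)
        return("spectrumCount must be in 1..2^layerExponent")
    if (length(object@peaksPerLayer) != k)
        return("peaksPerLayer must have one entry per spectrum")
    if (anyNA(object@peaksPerLayer) || any(object@peaksPerLayer < 0))
        return("peaksPerLayer entries must be non-negative")
    if (!(object@intensityWidth %in% c(4L, 8L)))
        return("intensityWidth must be 4 or 8 bytes")
    TRUE
})

setMethod("show", "EncodedStack", function(object) {
    cat(sprintf(
        "EncodedStack: %d spectra (capacity 2^%d), %d peaks; payloads mz=%dB tag=%dB intensity=%dB\n",
        object@spectrumCount, object@layerExponent, sum(object@peaksPerLayer),
        length(object@mzPayload), length(object@tagPayload),
        length(object@intensityPayload)))
})

#' Handle on a mini-Aird run (JSON index + binary block file)
#'
#' Returned by [readRunMetadata()]; holds the parsed, validated index and
#' the paths needed for random access.
#'
#' @slot jsonPath path of the JSON index file.
#' @slot binPath path of the binary block file.
#' @slot meta parsed index (nested list mirroring the JSON schema).
#' @slot index data.frame mapping global spectrum id to (block, stack,
#'   layer) coordinates.
#' @exportClass MiniAirdRun
setClass("MiniAirdRun", representation(
    jsonPath = "character",
    binPath = "character",
    meta = "list",
    index = "data.frame"
))

setMethod("show", "MiniAirdRun", function(object) {
    m <- object@meta
    cat(sprintf("MiniAirdRun (%s): %d spectra, %d blocks, %s mode, %d dp\n",
                m$format, m$totalSpectra, length(m$blocks), m$mode,
                m$precision$decimalPlaces))
})
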