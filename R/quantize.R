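#' Quantize m/z values to integers at a fixed decimal precision
#'
#' Multiplies each m/z by \code{10^dp} and rounds half up (half away from
#' zero), matching exact decimal arithmetic: a value whose decimal
#' representation ends exactly on a half step (e.g. 123.45675 at 4 dp)
#' always rounds up, even when its closest binary double sits marginally
#' below the half step. Values within 1e-5 of a half step after scaling are
#' routed through digit-string rounding of their shortest decimal
#' representation; everything else takes the fast floating-point path.
#'
#' @param mzv numeric vector of m/z values (Daltons), finite, non-negative,
#'   non-decreasing.
#' @param cfg a [PrecisionConfig-class].
#' @return numeric vector of exact integers (stored as doubles; values at
#'   6 dp can exceed the 32-bit range, which the codec handles by keeping
#'   the first merged value as a varint and compressing only the deltas).
#' @examples
#' quantizeMz(c(1.0, 123.45675), precisionConfig(4))  # 10000, 1234568
#' @seealso [dequantizeMz()], [sortSpectrum()]
#' @export
quantizeMz <- function(mzv, cfg) {
    stopifnot(is(cfg, "PrecisionConfig"))
    if (length(mzv) == 0) return(numeric())
    mzv <- as.numeric(mzv)
    bad <- which(!is.finite(mzv) | mzv < 0)
    if (length(bad))
        stopInvalidInput("m/z value at index %d is %s (must be finite and >= 0)",
                         bad[1],
                         if (is.finite(mzv[bad[1]])) "negative" else "non-finite")
    dec <- which(diff(mzv) < 0)
    if (length(dec))
        stopInvalidInput(
            "m/z array decreases at index %d; input must be sorted (see sortSpectrum)",
            dec[1] + 1)

    f <- mzv * cfg@scale
    q <- floor(f + 0.5)
    # values scaled to near a .5 boundary: decide by decimal digits, not by
    # the binary double, so half-way decimals round up deterministically
    frac <- f - floor(f)
    boundary <- which(abs(frac - 0.5) < 1e-5)
    if (length(boundary))
        q[boundary] <- roundHalfUpDecimal(mzv[boundary], cfg@decimalPlaces)
    q
}

# Exact decimal round-half-up of x at dp decimal places, via the shortest
# decimal representation R prints for the double (<= 15 significant digits).
roundHalfUpDecimal <- function(x, dp) {
    s <- format(x, scientific = FALSE, digits = 15, trim = TRUE)
    vapply(s, function(one) {
        parts <- strsplit(one, ".", fixed = TRUE)[[1]]
        intpart <- parts[1]
        fracpart <- if (length(parts) > 1) parts[2] else ""
        if (nchar(fracpart) < dp + 1)
            fracpart <- paste0(fracpart, strrep("0", dp + 1 - nchar(fracpart)))
        keep <- substr(fracpart, 1, dp)
        nextDigit <- substr(fracpart, dp + 1, dp + 1)
        base <- as.numeric(paste0(intpart, keep))
        if (nextDigit >= "5") base + 1 else base
    }, numeric(1), USE.NAMES = FALSE)
}

#' Reverse m/z quantization
#'
#' Divides quantized integers by the configured scale. For any original
#' value x that quantized to q, \code{abs(q/scale - x) <= 0.5 * 10^-dp}.
#'
#' @param q numeric vector of quantized integers.
#' @param cfg a [PrecisionConfig-class].
#' @return numeric m/z values in Daltons.
#' @examples
#' dequantizeMz(c(10000, 1234568), precisionConfig(4))
#' @export
dequantizeMz <- function(q, cfg) {
    stopifnot(is(cfg, "PrecisionConfig"))
    as.numeric(q) / cfg@scale
}

#' Sort a peak list by m/z, keeping intensities paired
#'
#' Stable sort: peaks with equal m/z keep their original relative order.
#'
#' @param mzv m/z values.
#' @param intensityv intensities, same length.
#' @return list with sorted `mz` and co-sorted `intensity`.
#' @examples
#' sortSpectrum(c(2, 1), c(10, 20))
#' @export
sortSpectrum <- function(mzv, intensityv) {
    if (length(mzv) != length(intensityv))
        stopInvalidInput("mz and intensity lengths differ (%d vs %d)",
                         length(mzv), length(intensityv))
    o <- order(mzv, method = "radix")  # radix sort is stable
    list(mz = as.numeric(mzv)[o], intensity = as.numeric(intensityv)[o])
}

#' Round-trip doubles through their stored intensity width
#'
#' Intensities are stored as little-endian IEEE floats of 4 or 8 bytes;
#' this helper applies the same narrowing, so callers can predict the
#' exact stored values.
#'
#' @param x numeric vector.
#' @param width bytes per stored value (4 narrows to float32, 8 is exact).
#' @return numeric vector after the store/load round trip.
#' @export
storedIntensity <- function(x, width = 4L) {
    if (!(width %in% c(4L, 8L))) stopConfig("intensity width must be 4 or 8")
    if (width == 8L) return(as.numeric(x))
    readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
            "numeric", size = 4L, n = length(x), endian = "little")
}
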