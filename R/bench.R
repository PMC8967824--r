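# Desk-scale benchmarking: layer sweep (how does total size move with the
# stack exponent n) and the raw / zlib-only / ZDPD / Stack-ZDPD
# decomposition. Sizes are only reported for configurations that pass a
# decode-identity check -- the size of a broken encoding is meaningless.
# Wall-clock times are recorded for information but never asserted.

#' Sweep the layer exponent over one homogeneous block
#'
#' For each n, partitions the block into `ceiling(count / 2^n)` stacks,
#' encodes them, verifies decode identity (quantized m/z and stored
#' intensities exact), and reports segment byte sizes and ratios. At n = 0
#' every spectrum is its own stack -- plain ZDPD -- and the tag segment is
#' empty.
#'
#' @param spectra list of [Spectrum-class] objects, all one MS level (and
#'   isolation window).
#' @param cfg a [PrecisionConfig-class].
#' @param nValues layer exponents to sweep. Default 0:10.
#' @param intensityWidth stored intensity bytes.
#' @return data.frame with one row per n: `n`, `mzBytes`, `tagBytes`,
#'   `intensityBytes`, `totalBytes`, `ratioVsRaw`, `ratioVsN0`,
#'   `encodeSeconds`, `decodeSeconds`, `encodeOk`, `decodeOk`.
#' @export
layerSweep <- function(spectra, cfg, nValues = 0:10, intensityWidth = 4L) {
    stopifnot(is(cfg, "PrecisionConfig"), length(spectra) >= 1)
    lv <- vapply(spectra, msLevel, integer(1))
    if (length(unique(lv)) != 1)
        stopInvalidInput("layer sweep needs a homogeneous (single MS level) block")

    width <- as.integer(intensityWidth)
    qRef <- lapply(spectra, function(s) quantizeMz(mz(s), cfg))
    iRef <- lapply(spectra, function(s) storedIntensity(intensity(s), width))
    totalPeaks <- sum(lengths(qRef))
    rawBytes <- (8 + width) * totalPeaks

    rows <- lapply(nValues, function(n) {
        row <- list(n = as.integer(n), mzBytes = NA_real_, tagBytes = NA_real_,
                    intensityBytes = NA_real_, totalBytes = NA_real_,
                    ratioVsRaw = NA_real_, ratioVsN0 = NA_real_,
                    encodeSeconds = NA_real_, decodeSeconds = NA_real_,
                    encodeOk = FALSE, decodeOk = FALSE)
        chunks <- split(seq_along(spectra), ceiling(seq_along(spectra) / 2^n))
        t0 <- proc.time()[["elapsed"]]
        stacks <- tryCatch(lapply(chunks, function(idx)
            encodeStack(spectra[idx], cfg, n = n, intensityWidth = width)),
            szdpdError = function(e) NULL)
        if (is.null(stacks)) return(row)
        row$encodeOk <- TRUE
        row$encodeSeconds <- proc.time()[["elapsed"]] - t0

        t0 <- proc.time()[["elapsed"]]
        ok <- tryCatch({
            all(vapply(seq_along(chunks), function(ci) {
                idx <- chunks[[ci]]
                dec <- decodeStack(stacks[[ci]], cfg)
                all(vapply(seq_along(idx), function(j) {
                    identical(quantizeMz(mz(dec[[j]]), cfg), qRef[[idx[j]]]) &&
                        identical(intensity(dec[[j]]), iRef[[idx[j]]])
                }, logical(1)))
            }, logical(1)))
        }, szdpdError = function(e) FALSE)
        row$decodeSeconds <- proc.time()[["elapsed"]] - t0
        if (!ok) return(row)
        row$decodeOk <- TRUE

        row$mzBytes <- sum(vapply(stacks, function(s) length(s@mzPayload), numeric(1)))
        row$tagBytes <- sum(vapply(stacks, function(s) length(s@tagPayload), numeric(1)))
        row$intensityBytes <- sum(vapply(stacks, function(s)
            length(s@intensityPayload), numeric(1)))
        row$totalBytes <- row$mzBytes + row$tagBytes + row$intensityBytes
        row$ratioVsRaw <- row$totalBytes / rawBytes
        row
    })
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    if (0 %in% df$n && isTRUE(df$decodeOk[df$n == 0]))
        df$ratioVsN0 <- df$totalBytes / df$totalBytes[df$n == 0]
    rownames(df) <- NULL
    df
}
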