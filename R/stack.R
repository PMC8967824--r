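# The Stack-ZDPD core: merge quantized m/z arrays of up to 2^n spectra
# into one sorted array plus an n-bit-per-peak tag array; carry intensities
# through aligned to the merged order.

#' Merge the quantized m/z arrays of several spectra
#'
#' Multiset union of the per-spectrum sorted arrays into one globally
#' sorted array. Ties across layers are broken by ascending layer index
#' (stable), which pins the encoded bytes.
#'
#' @param layers list of sorted numeric vectors (quantized m/z), one per
#'   spectrum ("layer").
#' @return list with `merged` (sorted union), `tags` (0-based source layer
#'   of each merged element) and `permutation` (merged position of each
#'   element of the concatenated input, for aligning intensities).
#' @examples
#' mergeSpectra(list(c(10, 20), c(15, 25)))
#' @export
mergeSpectra <- function(layers) {
    if (!is.list(layers) || length(layers) < 1)
        stopInvalidInput("need a non-empty list of layers")
    for (i in seq_along(layers)) {
        if (is.unsorted(layers[[i]]))
            stopInvalidInput("layer %d is not sorted non-decreasing", i)
    }
    lens <- lengths(layers)
    values <- unlist(layers, use.names = FALSE)
    if (is.null(values)) values <- numeric()
    layer <- rep.int(seq_along(layers), lens)
    o <- order(values, layer, method = "radix")  # stable, layer breaks ties
    perm <- integer(length(o))
    perm[o] <- seq_along(o)
    list(merged = values[o], tags = layer[o] - 1L, permutation = perm)
}

#' Scatter a merged array back into per-spectrum arrays
#'
#' Exact inverse of [mergeSpectra()] on the m/z side.
#'
#' @param merged sorted numeric vector.
#' @param tags integer vector, 0-based source layer of each element.
#' @param spectrumCount number of layers to reconstruct (empty layers come
#'   back as empty vectors).
#' @return list of `spectrumCount` sorted numeric vectors.
#' @export
scatterMerged <- function(merged, tags, spectrumCount) {
    if (length(merged) != length(tags))
        stopFormat("merged array and tag array lengths differ (%d vs %d)",
                   length(merged), length(tags))
    if (length(tags) && (min(tags) < 0 || max(tags) >= spectrumCount))
        stopFormat("tag value out of range [0, %d)", spectrumCount)
    f <- factor(tags, levels = 0:(spectrumCount - 1))
    unname(split(as.numeric(merged), f))
}

#' Bit-pack a tag array (pre-zlib stream)
#'
#' Packs each tag into `n` bits, LSB-first, giving exactly
#' `ceiling(length(tags) * n / 8)` bytes. At n = 8 every tag is exactly one
#' byte, the layout at which the zlib layer on top compresses best. n = 0
#' (single-layer stack) needs no tags and yields an empty stream.
#'
#' @param tags integer vector, all in `[0, 2^n)`.
#' @param n bit width, 0..16.
#' @return raw vector, the uncompressed packed stream.
#' @seealso [packTags()] for the zlib-wrapped payload.
#' @export
packTagsRaw <- function(tags, n) {
    if (length(n) != 1 || is.na(n) || n < 0 || n > 16)
        stopInvalidInput("tag bit width must be in 0..16, got %s", format(n))
    n <- as.integer(n)
    if (length(tags) && (min(tags) < 0 || max(tags) >= 2^n))
        stopRange("tag value %d does not fit in %d bits",
                  max(tags), n)
    if (n == 0L || length(tags) == 0) return(raw(0))
    .cpp_pack_bits(as.integer(tags), n)
}

#' Pack and zlib-compress a tag array
#'
#' @inheritParams packTagsRaw
#' @return raw vector: zlib stream over the packed bits; fully empty for
#'   n = 0.
#' @export
packTags <- function(tags, n) {
    pre <- packTagsRaw(tags, n)
    if (n == 0) return(raw(0))
    memCompress(pre, type = "gzip")
}

#' Unpack a tag payload
#'
#' @param payload raw vector from [packTags()].
#' @param count number of tags to recover.
#' @param n bit width used when packing.
#' @return integer vector of `count` tags.
#' @export
unpackTags <- function(payload, count, n) {
    if (n == 0) {
        if (length(payload) != 0)
            stopFormat("tag payload must be empty for single-layer stacks")
        return(integer(count))
    }
    if (count == 0) return(integer(0))
    pre <- zlibInflate(payload)
    need <- ceiling(count * n / 8)
    if (length(pre) != need)
        stopFormat("packed tag stream has %d bytes, expected %d",
                   length(pre), need)
    tryCatch(.cpp_unpack_bits(pre, as.numeric(count), as.integer(n)),
             error = function(e) stopFormat("%s", conditionMessage(e)))
}

#' Encode a stack of spectra with Stack-ZDPD
#'
#' Quantizes each spectrum's m/z array, merges all layers into one sorted
#' integer array, and produces the three payloads of an
#' [EncodedStack-class]: the delta+PFor+zlib compressed merged m/z, the
#' bit-packed zlib-compressed tag array, and the intensities serialized in
#' merged order (so one tag array drives both scatters, and an m/z window
#' is a contiguous slice for XIC work).
#'
#' @param spectra list of [Spectrum-class] objects, all the same MS level,
#'   and for MS2 all from the same isolation window (compared after
#'   rounding to 4 decimals); at most `2^n` of them.
#' @param cfg a [PrecisionConfig-class].
#' @param n layer exponent; the stack capacity is `2^n`. 8 by default
#'   (256-spectrum stacks, byte-wide tags).
#' @param intensityWidth stored bytes per intensity: 4 (float32, the mzML
#'   convention; doubles are narrowed, a documented lossy step) or 8.
#' @return an [EncodedStack-class].
#' @seealso [decodeStack()]
#' @export
encodeStack <- function(spectra, cfg, n = 8L, intensityWidth = 4L) {
    stopifnot(is(cfg, "PrecisionConfig"))
    if (!is.list(spectra) || length(spectra) < 1)
        stopInvalidInput("need at least one spectrum")
    if (length(n) != 1 || n < 0 || n > 16)
        stopInvalidInput("layer exponent must be in 0..16")
    n <- as.integer(n)
    if (length(spectra) > 2^n)
        stopCapacity("%d spectra exceed stack capacity 2^%d = %d",
                     length(spectra), n, 2^n)
    if (!(intensityWidth %in% c(4L, 8L)))
        stopConfig("intensity width must be 4 or 8 bytes")

    lv <- vapply(spectra, msLevel, integer(1))
    if (length(unique(lv)) != 1)
        stopInvalidInput("all spectra in a stack must share one MS level")
    if (lv[1] == 2L) {
        wins <- vapply(spectra, function(s) {
            w <- precursorWindow(s)
            paste(round(w, 4), collapse = ":")
        }, character(1))
        if (length(unique(wins)) != 1)
            stopInvalidInput("MS2 spectra in a stack must share one isolation window")
    }

    qlist <- lapply(spectra, function(s) quantizeMz(mz(s), cfg))
    m <- mergeSpectra(qlist)
    intsConcat <- unlist(lapply(spectra, intensity), use.names = FALSE)
    if (is.null(intsConcat)) intsConcat <- numeric()
    intMerged <- numeric(length(intsConcat))
    intMerged[m$permutation] <- intsConcat

    new("EncodedStack",
        layerExponent = n,
        spectrumCount = length(spectra),
        peaksPerLayer = as.integer(lengths(qlist)),
        mzPayload = encodeSortedArray(m$merged),
        tagPayload = packTags(m$tags, n),
        intensityPayload = memCompress(
            writeBin(intMerged, raw(), size = as.integer(intensityWidth),
                     endian = "little"),
            type = "gzip"),
        intensityWidth = as.integer(intensityWidth))
}

#' Decode a stack back into spectra
#'
#' Exact inverse of [encodeStack()] at the quantized-integer level: the
#' returned m/z values are the dequantized merged integers, and the
#' intensities are bit-identical to what was stored.
#'
#' The stack payloads carry no retention times, MS level or isolation
#' window (the container's JSON index does); supply them here to label the
#' reconstructed spectra, or accept the defaults for payload-level work.
#'
#' @param es an [EncodedStack-class].
#' @param cfg the [PrecisionConfig-class] used at encode time. Decoding
#'   with a different scale shifts every m/z by exactly the scale ratio.
#' @param rt optional retention times (seconds), one per spectrum.
#' @param msLevel MS level to stamp on the spectra (1 or 2).
#' @param precursorWindow for MS2: a single `c(lower, upper)` window, or a
#'   list with one window per spectrum.
#' @return list of [Spectrum-class] objects, one per stored layer.
#' @export
decodeStack <- function(es, cfg, rt = NULL, msLevel = 1L,
                        precursorWindow = NULL) {
    stopifnot(is(es, "EncodedStack"), is(cfg, "PrecisionConfig"))
    k <- es@spectrumCount
    total <- sum(es@peaksPerLayer)

    merged <- decodeSortedArray(es@mzPayload)
    if (length(merged) != total)
        stopFormat("merged m/z has %d values but peaksPerLayer sums to %d",
                   length(merged), total)
    tags <- unpackTags(es@tagPayload, total, es@layerExponent)
    if (length(tags) && max(tags) >= k)
        stopFormat("tag value %d out of range for %d spectra", max(tags), k)
    counts <- tabulate(tags + 1L, nbins = k)
    if (!identical(as.integer(counts), as.integer(es@peaksPerLayer)))
        stopFormat("per-layer peak counts from tags disagree with peaksPerLayer")

    qlist <- scatterMerged(merged, tags, k)

    intRaw <- zlibInflate(es@intensityPayload)
    if (length(intRaw) != total * es@intensityWidth)
        stopFormat("intensity payload has %d bytes, expected %d",
                   length(intRaw), total * es@intensityWidth)
    intMerged <- readBin(intRaw, "numeric", size = es@intensityWidth,
                         n = total, endian = "little")
    f <- factor(tags, levels = 0:(k - 1))
    ilist <- unname(split(intMerged, f))

    if (is.null(rt)) rt <- rep(0, k)
    if (length(rt) != k)
        stopInvalidInput("rt must have one value per spectrum (%d), got %d",
                         k, length(rt))
    winFor <- function(i) {
        if (is.null(precursorWindow)) NULL
        else if (is.list(precursorWindow)) precursorWindow[[i]]
        else precursorWindow
    }
    lapply(seq_len(k), function(i) {
        Spectrum(mz = dequantizeMz(qlist[[i]], cfg),
                 intensity = ilist[[i]],
                 rt = rt[i], msLevel = msLevel,
                 precursorWindow = winFor(i))
    })
}
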