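# Reversible compression of sorted unsigned integer arrays:
# delta encoding -> PFor-style patched bit packing -> zlib (RFC 1950).
# The byte-level layout is pinned in docs/format.md.

# Bounded zlib inflate for untrusted payloads; truncated or corrupt
# streams raise a format error (base memDecompress retries with ever
# larger buffers on truncated input, which is unsafe on corrupt files).
zlibInflate <- function(b) {
    if (!is.raw(b)) stopFormat("zlib payload must be a raw vector")
    tryCatch(.cpp_zlib_inflate(b),
             error = function(e) stopFormat("%s", conditionMessage(e)))
}

#' Delta-encode a sorted unsigned-integer array
#'
#' @param v numeric vector of non-decreasing non-negative integers.
#' @return list with class `DeltaArray`: `first` (numeric(0) for empty
#'   input) and `deltas` (successive differences, all >= 0).
#' @examples
#' deltaEncode(c(3, 7, 7, 10))
#' @export
deltaEncode <- function(v) {
    v <- as.numeric(v)
    dec <- which(diff(v) < 0)
    if (length(dec))
        stopInvalidInput("input decreases at index %d; delta encoding needs a sorted array",
                         dec[1] + 1)
    structure(list(
        first = if (length(v)) v[1] else numeric(),
        deltas = if (length(v) > 1) diff(v) else numeric()
    ), class = "DeltaArray")
}

#' Invert delta encoding by cumulative sum
#'
#' @param d a `DeltaArray` as returned by [deltaEncode()].
#' @return the original sorted numeric vector.
#' @export
deltaDecode <- function(d) {
    if (length(d$first) == 0) return(numeric())
    cumsum(c(d$first, d$deltas))
}

#' PFor-encode an unsigned-integer array
#'
#' Patched frame-of-reference coding on 32-bit lanes: values are split
#' into miniblocks of 128; each miniblock is bit-packed at the width that
#' minimizes total bytes, with larger values patched in as
#' (position-delta, high-bits) varint exceptions.
#'
#' @param v numeric vector of integers in `[0, 2^32)`.
#' @return raw vector, a self-delimiting payload decodable by [pforDecode()].
#' @examples
#' length(pforEncode(rep(0, 128)))  # all-zero miniblock has no packed area
#' @export
pforEncode <- function(v) {
    tryCatch(.cpp_pfor_encode(as.numeric(v)), error = function(e) {
        if (grepl("2\\^32", conditionMessage(e)))
            stopRange("%s", conditionMessage(e))
        stopInvalidInput("%s", conditionMessage(e))
    })
}

#' Decode a PFor payload
#'
#' @param payload raw vector produced by [pforEncode()].
#' @return numeric vector of the original integers.
#' @export
pforDecode <- function(payload) {
    if (!is.raw(payload)) stopFormat("pfor payload must be a raw vector")
    res <- tryCatch(.cpp_pfor_decode(payload, 0L),
                    error = function(e) stopFormat("%s", conditionMessage(e)))
    if (res$next_offset != length(payload))
        stopFormat("trailing garbage after pfor payload (byte %d of %d)",
                   res$next_offset, length(payload))
    res$values
}

#' Compress a sorted integer array (the ZDPD m/z pipeline)
#'
#' Serializes length, first value (as a varint, so 6-dp quantized m/z
#' above the 32-bit range is representable) and the PFor-coded deltas,
#' then applies a zlib outer layer. A delta of 2^32 or more is a hard
#' error: it would mean a gap above ~4000 Da at 6 dp.
#'
#' @param v numeric vector, non-decreasing non-negative integers.
#' @return raw vector (zlib stream).
#' @seealso [decodeSortedArray()]
#' @export
encodeSortedArray <- function(v) {
    d <- deltaEncode(v)
    L <- length(v)
    body <- .cpp_varint_encode(L)
    if (L > 0) {
        if (d$first >= 2^53)
            stopRange("first value %g exceeds 2^53", d$first)
        body <- c(body, .cpp_varint_encode(d$first), pforEncode(d$deltas))
    }
    memCompress(body, type = "gzip")
}

#' Decompress a sorted integer array
#'
#' @param b raw vector produced by [encodeSortedArray()].
#' @return numeric vector of non-decreasing integers.
#' @export
decodeSortedArray <- function(b) {
    if (!is.raw(b)) stopFormat("payload must be a raw vector")
    body <- zlibInflate(b)
    hd <- tryCatch(.cpp_varint_decode(body, 0L),
                   error = function(e) stopFormat("%s", conditionMessage(e)))
    L <- hd$value
    if (L == 0) {
        if (hd$next_offset != length(body))
            stopFormat("trailing bytes after empty-array header")
        return(numeric())
    }
    fv <- tryCatch(.cpp_varint_decode(body, as.integer(hd$next_offset)),
                   error = function(e) stopFormat("%s", conditionMessage(e)))
    res <- tryCatch(.cpp_pfor_decode(body, as.integer(fv$next_offset)),
                    error = function(e) stopFormat("%s", conditionMessage(e)))
    if (res$next_offset != length(body))
        stopFormat("trailing garbage after delta payload")
    deltas <- res$values
    if (length(deltas) != L - 1)
        stopFormat("delta count %d does not match declared length %d",
                   length(deltas), L)
    cumsum(c(fv$value, deltas))
}
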