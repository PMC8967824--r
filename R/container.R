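# The mini-Aird on-disk format: <stem>.mini-aird.json (index, authoritative
# for all offsets) + <stem>.mini-aird.bin (concatenated stack payload
# segments in the order mz | tag | intensity). Schema: docs/mini-aird-schema.json.

FORMAT_VERSION <- "mini-aird-1"

miniAirdPaths <- function(stem) {
    c(json = paste0(stem, ".mini-aird.json"),
      bin = paste0(stem, ".mini-aird.bin"))
}

#' Write an encoded run to a mini-Aird file pair
#'
#' Lays the stack payload segments out back to back in the binary file and
#' records every offset/length, retention time and spectrum id in the JSON
#' index, so readers can seek without scanning. Writing is atomic: files
#' appear only after both have been fully written.
#'
#' @param blocks list of encoded blocks. Each block is a list with
#'   `msLevel`, `precursorWindow` (NULL for MS1 and for DDA MS2 blocks,
#'   which carry per-stack windows instead), `layerExponent`, and `stacks`:
#'   a list of entries `list(stack = <EncodedStack>, rt = <numeric>,
#'   spectrumIds = <integer>, windows = <list or NULL>)`.
#' @param cfg the run's [PrecisionConfig-class].
#' @param mode acquisition mode, `"DDA"` or `"DIA"`.
#' @param pathStem output path stem; `<stem>.mini-aird.json` and
#'   `<stem>.mini-aird.bin` are written.
#' @param source free-text provenance (e.g. the source mzML path).
#' @param intensityWidth stored intensity width in bytes (4 or 8).
#' @return named character vector with the `json` and `bin` paths.
#' @seealso [readRunMetadata()]
#' @export
writeRun <- function(blocks, cfg, mode, pathStem, source = "",
                     intensityWidth = 4L) {
    stopifnot(is(cfg, "PrecisionConfig"))
    if (!(mode %in% c("DDA", "DIA")))
        stopInvalidInput("mode must be 'DDA' or 'DIA'")

    segments <- list()
    offset <- 0
    blockMeta <- list()
    totalSpectra <- 0

    for (bi in seq_along(blocks)) {
        blk <- blocks[[bi]]
        stackMeta <- list()
        for (si in seq_along(blk$stacks)) {
            entry <- blk$stacks[[si]]
            es <- entry$stack
            if (!is(es, "EncodedStack"))
                stopInvalidInput("block %d stack %d is not an EncodedStack", bi, si)
            if (length(entry$rt) != es@spectrumCount ||
                length(entry$spectrumIds) != es@spectrumCount)
                stopInvalidInput(
                    "block %d stack %d: rt/spectrumIds must match spectrumCount", bi, si)
            if (es@layerExponent != blk$layerExponent)
                stopInvalidInput("block %d stack %d: layer exponent mismatch", bi, si)
            seg <- c(es@mzPayload, es@tagPayload, es@intensityPayload)
            segments[[length(segments) + 1]] <- seg
            sm <- list(
                offset = offset,
                mzLength = length(es@mzPayload),
                tagLength = length(es@tagPayload),
                intensityLength = length(es@intensityPayload),
                spectrumCount = es@spectrumCount,
                peaksPerLayer = as.integer(es@peaksPerLayer),
                rt = as.numeric(entry$rt),
                spectrumIds = as.integer(entry$spectrumIds)
            )
            if (!is.null(entry$windows))
                sm$windows <- lapply(entry$windows, as.numeric)
            stackMeta[[si]] <- sm
            offset <- offset + length(seg)
            totalSpectra <- totalSpectra + es@spectrumCount
        }
        rtAll <- unlist(lapply(stackMeta, `[[`, "rt"))
        if (length(rtAll) > 1 && any(diff(rtAll) <= 0))
            stopInvalidInput("block %d: retention times are not strictly increasing", bi)
        blockMeta[[bi]] <- list(
            blockId = bi - 1L,
            msLevel = blk$msLevel,
            precursorWindow = if (is.null(blk$precursorWindow)) NULL
                              else as.numeric(blk$precursorWindow),
            layerExponent = as.integer(blk$layerExponent),
            stacks = stackMeta
        )
    }

    paths <- miniAirdPaths(pathStem)
    meta <- list(
        format = FORMAT_VERSION,
        precision = list(decimalPlaces = cfg@decimalPlaces, scale = cfg@scale),
        mode = mode,
        source = source,
        intensityWidth = as.integer(intensityWidth),
        binaryFile = basename(paths[["bin"]]),
        totalSpectra = totalSpectra,
        blocks = blockMeta
    )

    dir <- dirname(paths[["bin"]])
    if (!dir.exists(dir)) stopIO("output directory does not exist: %s", dir)
    tmpBin <- tempfile(tmpdir = dir)
    tmpJson <- tempfile(tmpdir = dir)
    ok <- FALSE
    on.exit(if (!ok) unlink(c(tmpBin, tmpJson)), add = TRUE)

    con <- file(tmpBin, "wb")
    tryCatch({
        for (seg in segments) writeBin(seg, con)
    }, finally = close(con))
    if (file.size(tmpBin) != offset)
        stopFormat("internal consistency error: wrote %d bytes, descriptors say %d",
                   file.size(tmpBin), offset)
    jsonlite::write_json(meta, tmpJson, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    file.rename(tmpBin, paths[["bin"]])
    file.rename(tmpJson, paths[["json"]])
    ok <- TRUE
    paths
}

requireField <- function(x, field, where) {
    if (is.null(x[[field]]))
        stopFormat("mini-aird index: required field '%s' missing in %s", field, where)
    x[[field]]
}

#' Open a mini-Aird run
#'
#' Parses and validates the JSON index, checks offsets for overlap, and
#' builds the global-spectrum-id lookup used by [readSpectrum()].
#'
#' @param jsonPath path to the `.mini-aird.json` index.
#' @return a [MiniAirdRun-class] handle.
#' @export
readRunMetadata <- function(jsonPath) {
    if (!file.exists(jsonPath)) stopIO("no such file: %s", jsonPath)
    meta <- tryCatch(jsonlite::fromJSON(jsonPath, simplifyVector = FALSE),
                     error = function(e) stopFormat("index is not valid JSON: %s",
                                                    conditionMessage(e)))
    fmt <- requireField(meta, "format", "top level")
    if (!identical(fmt, FORMAT_VERSION))
        stopVersion("unsupported format version '%s' (this reader handles '%s')",
                    fmt, FORMAT_VERSION)
    for (f in c("precision", "mode", "intensityWidth", "binaryFile",
                "totalSpectra", "blocks"))
        requireField(meta, f, "top level")
    requireField(meta$precision, "decimalPlaces", "precision")

    binPath <- file.path(dirname(jsonPath), meta$binaryFile)
    if (!file.exists(binPath)) stopIO("binary block file missing: %s", binPath)

    ids <- integer(); bcol <- integer(); scol <- integer(); lcol <- integer()
    prevEnd <- 0
    for (bi in seq_along(meta$blocks)) {
        blk <- meta$blocks[[bi]]
        for (f in c("blockId", "msLevel", "layerExponent", "stacks"))
            requireField(blk, f, sprintf("block %d", bi))
        for (si in seq_along(blk$stacks)) {
            st <- blk$stacks[[si]]
            for (f in c("offset", "mzLength", "tagLength", "intensityLength",
                        "spectrumCount", "peaksPerLayer", "rt", "spectrumIds"))
                requireField(st, f, sprintf("block %d stack %d", bi, si))
            if (st$offset < prevEnd)
                stopFormat("overlapping stack segments at block %d stack %d", bi, si)
            prevEnd <- st$offset + st$mzLength + st$tagLength + st$intensityLength
            sids <- as.integer(unlist(st$spectrumIds))
            k <- length(sids)
            if (k != st$spectrumCount)
                stopFormat("block %d stack %d: spectrumIds length != spectrumCount",
                           bi, si)
            ids <- c(ids, sids)
            bcol <- c(bcol, rep.int(bi, k))
            scol <- c(scol, rep.int(si, k))
            lcol <- c(lcol, seq_len(k))
        }
    }
    if (file.size(binPath) != prevEnd)
        stopFormat("binary file has %d bytes but index accounts for %d",
                   file.size(binPath), prevEnd)
    if (anyDuplicated(ids))
        stopFormat("spectrum id %d appears in more than one stack",
                   ids[anyDuplicated(ids)])
    if (length(ids) != meta$totalSpectra)
        stopFormat("index lists %d spectra but totalSpectra says %d",
                   length(ids), meta$totalSpectra)

    index <- data.frame(id = ids, block = bcol, stack = scol, layer = lcol)
    new("MiniAirdRun", jsonPath = jsonPath, binPath = binPath,
        meta = meta, index = index)
}

runPrecision <- function(run) precisionConfig(run@meta$precision$decimalPlaces)

stackDescriptor <- function(run, blockId, stackIndex) {
    blocks <- run@meta$blocks
    if (length(blockId) != 1 || blockId < 0 || blockId >= length(blocks))
        stopLookup("no block %s in this run (have %d blocks)",
                   format(blockId), length(blocks))
    blk <- blocks[[blockId + 1]]
    if (length(stackIndex) != 1 || stackIndex < 1 ||
        stackIndex > length(blk$stacks))
        stopLookup("block %d has %d stacks; no stack %s",
                   blockId, length(blk$stacks), format(stackIndex))
    list(block = blk, stack = blk$stacks[[stackIndex]])
}

# Seek + bounded read of one stack's three payload segments.
readStackPayloads <- function(run, blk, st) {
    con <- file(run@binPath, "rb")
    on.exit(close(con))
    seek(con, where = st$offset, origin = "start")
    total <- st$mzLength + st$tagLength + st$intensityLength
    seg <- readBin(con, "raw", n = total)
    if (length(seg) != total)
        stopFormat("binary file truncated: wanted %d bytes at offset %.0f",
                   total, st$offset)
    list(mz = seg[seq_len(st$mzLength)],
         tag = seg[st$mzLength + seq_len(st$tagLength)],
         intensity = seg[st$mzLength + st$tagLength + seq_len(st$intensityLength)])
}

rebuildStack <- function(run, blk, st) {
    p <- readStackPayloads(run, blk, st)
    new("EncodedStack",
        layerExponent = as.integer(blk$layerExponent),
        spectrumCount = as.integer(st$spectrumCount),
        peaksPerLayer = as.integer(unlist(st$peaksPerLayer)),
        mzPayload = p$mz, tagPayload = p$tag, intensityPayload = p$intensity,
        intensityWidth = as.integer(run@meta$intensityWidth))
}

stackWindows <- function(blk, st) {
    if (!is.null(st$windows)) lapply(st$windows, as.numeric)
    else if (!is.null(blk$precursorWindow)) as.numeric(blk$precursorWindow)
    else NULL
}

#' Random-access read of one stack
#'
#' Reads only that stack's byte range from the binary file (one seek, one
#' bounded read) and decodes it.
#'
#' @param run a [MiniAirdRun-class].
#' @param blockId 0-based block id.
#' @param stackIndex 1-based stack index within the block.
#' @return list of [Spectrum-class] objects.
#' @export
readStack <- function(run, blockId, stackIndex) {
    stopifnot(is(run, "MiniAirdRun"))
    d <- stackDescriptor(run, blockId, stackIndex)
    es <- rebuildStack(run, d$block, d$stack)
    decodeStack(es, runPrecision(run),
                rt = as.numeric(unlist(d$stack$rt)),
                msLevel = as.integer(d$block$msLevel),
                precursorWindow = stackWindows(d$block, d$stack))
}

#' Random-access read of one spectrum by global id
#'
#' @param run a [MiniAirdRun-class].
#' @param spectrumId 0-based global spectrum id (original acquisition
#'   order).
#' @return a [Spectrum-class].
#' @export
readSpectrum <- function(run, spectrumId) {
    stopifnot(is(run, "MiniAirdRun"))
    if (length(spectrumId) != 1)
        stopLookup("spectrumId must be a single id")
    row <- run@index[match(spectrumId, run@index$id), ]
    if (is.na(row$block))
        stopLookup("no spectrum with id %s in this run", format(spectrumId))
    spectra <- readStack(run, row$block - 1L, row$stack)
    spectra[[row$layer]]
}

#' Decode every spectrum of a run, in global id order
#'
#' @param run a [MiniAirdRun-class].
#' @return list of [Spectrum-class] objects ordered by global spectrum id.
#' @export
readAllSpectra <- function(run) {
    stopifnot(is(run, "MiniAirdRun"))
    out <- vector("list", nSpectra(run))
    for (bi in seq_along(run@meta$blocks)) {
        blk <- run@meta$blocks[[bi]]
        for (si in seq_along(blk$stacks)) {
            sp <- readStack(run, bi - 1L, si)
            sids <- as.integer(unlist(blk$stacks[[si]]$spectrumIds))
            out[sids + 1L] <- sp
        }
    }
    out
}

# Decode a stack only to its merged arrays (no per-spectrum objects):
# the XIC path slices the sorted merged array and aggregates by tag.
decodeStackArrays <- function(run, blk, st) {
    p <- readStackPayloads(run, blk, st)
    merged <- decodeSortedArray(p$mz)
    total <- length(merged)
    tags <- unpackTags(p$tag, total, as.integer(blk$layerExponent))
    intRaw <- zlibInflate(p$intensity)
    w <- as.integer(run@meta$intensityWidth)
    list(merged = merged, tags = tags,
         intensity = readBin(intRaw, "numeric", size = w, n = total,
                             endian = "little"),
         rt = as.numeric(unlist(st$rt)),
         spectrumCount = as.integer(st$spectrumCount))
}

#' Extract an ion chromatogram
#'
#' Sums, for every selected spectrum, the intensities of peaks with m/z in
#' `mzCenter * (1 +/- tolPpm * 1e-6)`. The m/z window is located by binary
#' search in each stack's merged sorted array and resolved to spectra via
#' the tag array; individual spectra are never materialized. Spectra with
#' no matching peak contribute intensity 0 at their retention time.
#'
#' @param run a [MiniAirdRun-class].
#' @param mzCenter target m/z in Daltons.
#' @param tolPpm tolerance in parts per million (> 0).
#' @param rtRange optional `c(min, max)` retention-time filter in seconds.
#' @param msLevel 1 for an MS1 XIC; 2 for a fragment XIC, in which case
#'   `window` selects the isolation window.
#' @param window for MS2: `c(lower, upper)` isolation window identifying
#'   the block (matched after rounding to 4 decimals).
#' @return data.frame with columns `rt` and `intensity`, ordered by rt.
#' @export
extractXic <- function(run, mzCenter, tolPpm, rtRange = NULL, msLevel = 1L,
                       window = NULL) {
    stopifnot(is(run, "MiniAirdRun"))
    if (length(tolPpm) != 1 || !is.finite(tolPpm) || tolPpm <= 0)
        stopInvalidInput("tolPpm must be a single positive number")
    if (msLevel == 2L && is.null(window))
        stopInvalidInput("an MS2 XIC needs the isolation window (window = c(lower, upper))")

    cfg <- runPrecision(run)
    lo <- mzCenter * (1 - tolPpm * 1e-6)
    hi <- mzCenter * (1 + tolPpm * 1e-6)
    loQ <- lo * cfg@scale
    hiQ <- hi * cfg@scale

    key <- function(w) paste(round(as.numeric(w), 4), collapse = ":")
    rts <- numeric(); ints <- numeric()
    for (blk in run@meta$blocks) {
        if (blk$msLevel != msLevel) next
        if (msLevel == 2L) {
            bw <- blk$precursorWindow
            if (is.null(bw) || !identical(key(bw), key(window))) next
        }
        for (st in blk$stacks) {
            a <- decodeStackArrays(run, blk, st)
            s <- numeric(a$spectrumCount)
            i0 <- findInterval(loQ, a$merged, left.open = TRUE) + 1L
            i1 <- findInterval(hiQ, a$merged)
            if (i1 >= i0) {
                sel <- i0:i1
                agg <- rowsum(a$intensity[sel], a$tags[sel])
                s[as.integer(rownames(agg)) + 1L] <- agg[, 1]
            }
            rts <- c(rts, a$rt)
            ints <- c(ints, s)
        }
    }
    o <- order(rts)
    res <- data.frame(rt = rts[o], intensity = ints[o])
    if (!is.null(rtRange))
        res <- res[res$rt >= rtRange[1] & res$rt <= rtRange[2], , drop = FALSE]
    rownames(res) <- NULL
    res
}
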