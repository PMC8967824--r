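test_that("merge/scatter are exact inverses with stable tie-breaks", {
    m <- mergeSpectra(list(c(10, 20), c(15, 25)))
    expect_identical(m$merged, c(10, 15, 20, 25))
    expect_identical(m$tags, c(0L, 1L, 0L, 1L))
    expect_identical(scatterMerged(m$merged, m$tags, 2),
                     list(c(10, 20), c(15, 25)))

    one <- mergeSpectra(list(c(7, 8)))
    expect_identical(one$merged, c(7, 8))
    expect_identical(one$tags, c(0L, 0L))

    ties <- mergeSpectra(list(5, 5, 5))
    expect_identical(ties$tags, c(0L, 1L, 2L))  # ascending layer on ties

    expect_identical(scatterMerged(numeric(0), integer(0), 4),
                     list(numeric(0), numeric(0), numeric(0), numeric(0)))
    expect_error(scatterMerged(c(1, 2), c(0L, 5L), 2),
                 class = "szdpdFormatError")
    expect_error(mergeSpectra(list(c(2, 1))), "layer 1",
                 class = "szdpdInvalidInputError")

    set.seed(31)
    layers <- lapply(1:256, function(i) randomSortedArray(sample(0:50, 1)))
    m <- mergeSpectra(layers)
    expect_false(is.unsorted(m$merged))
    expect_identical(scatterMerged(m$merged, m$tags, 256), layers)
    # permutation aligns concatenated positions with merged positions
    concat <- unlist(layers)
    expect_identical(m$merged[m$permutation], concat)
})

test_that("tag packing obeys the exact pre-zlib size law and bit order", {
    # bit-order oracle: explicit per-bit loop
    pre <- packTagsRaw(c(0L, 1L, 0L, 1L), 1)
    expect_identical(pre, as.raw(0x0a))  # 0b00001010
    expect_identical(pre, naivePackBits(c(0, 1, 0, 1), 1))

    expect_identical(packTagsRaw(c(0L, 0L), 0), raw(0))
    expect_identical(packTags(c(0L, 0L), 0), raw(0))

    # byte-per-tag at n = 8
    set.seed(5)
    tags <- sample(0:255, 1000, replace = TRUE)
    expect_identical(length(packTagsRaw(tags, 8)), 1000L)

    for (n in 0:16) {
        count <- 137
        tg <- sample(0:(max(1, 2^n - 1)), count, replace = TRUE)
        if (n == 0) tg <- rep(0L, count)
        pre <- packTagsRaw(tg, n)
        expect_identical(length(pre), as.integer(ceiling(count * n / 8)))
        expect_identical(unpackTags(packTags(tg, n), count, n),
                         as.integer(tg))
        if (n > 0)
            expect_identical(naiveUnpackBits(pre, count, n), as.numeric(tg))
    }

    expect_error(packTagsRaw(c(0L, 4L), 2), class = "szdpdRangeError")
    expect_error(unpackTags(packTags(0:3, 2), 10, 2),
                 class = "szdpdFormatError")
})

test_that("stacks round-trip losslessly at the integer level", {
    cfg <- precisionConfig(5)
    set.seed(77)
    mkSpec <- function(peaks, rt, lvl = 1L, win = NULL)
        Spectrum(sort(runif(peaks, 400, 1200)), rlnorm(peaks, 8, 1),
                 rt = rt, msLevel = lvl, precursorWindow = win)

    # k = 1 (degenerate ZDPD), k = 2, k at full default capacity
    expectStackRoundTrip(list(mkSpec(40, 0)), cfg, n = 0L)
    expectStackRoundTrip(list(mkSpec(30, 0), mkSpec(35, 1)), cfg, n = 1L)
    big <- lapply(1:256, function(i) mkSpec(sample(10:40, 1), i - 1))
    es <- expectStackRoundTrip(big, cfg, n = 8L)
    # byte-per-tag claim at n = 8: pre-zlib tag stream is one byte per peak
    expect_identical(length(memDecompress(es@tagPayload, type = "gzip")),
                     as.integer(sum(peaksPerLayer(es))))

    # empty spectra occupy layers and survive
    withEmpty <- list(mkSpec(10, 0), Spectrum(rt = 1), mkSpec(5, 2))
    es <- expectStackRoundTrip(withEmpty, cfg, n = 2L)
    expect_identical(peaksPerLayer(es), c(10L, 0L, 5L))
    one <- encodeStack(list(Spectrum(rt = 0)), cfg, n = 0L)
    dec <- decodeStack(one, cfg)
    expect_identical(peaksCount(dec[[1]]), 0L)

    # duplicate quantized m/z within one spectrum is preserved
    dup <- Spectrum(c(500.000001, 500.000002), c(1, 2), rt = 0)
    es <- encodeStack(list(dup), cfg, n = 0L)
    expect_identical(mz(decodeStack(es, cfg)[[1]]), c(500.0, 500.0))

    # 64-bit intensity mode keeps doubles exact
    s <- mkSpec(25, 0)
    es <- encodeStack(list(s), cfg, n = 0L, intensityWidth = 8L)
    expect_identical(intensity(decodeStack(es, cfg)[[1]]), intensity(s))
})

test_that("stack encoding validates level, window and capacity", {
    cfg <- precisionConfig(5)
    s1 <- Spectrum(500, 1, rt = 0, msLevel = 1L)
    s2 <- Spectrum(500, 1, rt = 1, msLevel = 2L, precursorWindow = c(400, 600))
    s3 <- Spectrum(500, 1, rt = 2, msLevel = 2L, precursorWindow = c(600, 800))
    expect_error(encodeStack(list(s1, s2), cfg, n = 1L),
                 class = "szdpdInvalidInputError")
    expect_error(encodeStack(list(s2, s3), cfg, n = 1L),
                 class = "szdpdInvalidInputError")
    expect_error(encodeStack(list(s1, s1, s1), cfg, n = 1L),
                 class = "szdpdCapacityError")
})

test_that("decode rejects corrupt payloads instead of returning partial data", {
    cfg <- precisionConfig(5)
    set.seed(13)
    spectra <- lapply(1:4, function(i)
        Spectrum(sort(runif(30, 400, 1200)), rlnorm(30, 8, 1), rt = i - 1))
    es <- encodeStack(spectra, cfg, n = 2L)

    trunc <- es
    trunc@mzPayload <- es@mzPayload[seq_len(length(es@mzPayload) - 5)]
    expect_error(decodeStack(trunc, cfg), class = "szdpdFormatError")

    badTag <- es
    badTag@tagPayload <- es@tagPayload[seq_len(length(es@tagPayload) - 3)]
    expect_error(decodeStack(badTag, cfg), class = "szdpdFormatError")

    badCounts <- es
    badCounts@peaksPerLayer <- rev(es@peaksPerLayer) + 1L
    expect_error(decodeStack(badCounts, cfg), class = "szdpdFormatError")

    # decoding with the wrong scale shifts m/z by exactly the scale ratio
    dec5 <- decodeStack(es, precisionConfig(5))
    dec4 <- decodeStack(es, precisionConfig(4))
    expect_equal(mz(dec4[[1]]), mz(dec5[[1]]) * 10, tolerance = 1e-12)
})
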