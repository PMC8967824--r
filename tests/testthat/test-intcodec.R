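test_that("delta coding is exact and validates sortedness", {
    d <- deltaEncode(c(3, 7, 7, 10))
    expect_identical(d$first, 3)
    expect_identical(d$deltas, c(4, 0, 3))
    expect_identical(deltaDecode(d), c(3, 7, 7, 10))

    s <- deltaEncode(5)
    expect_identical(s$first, 5)
    expect_length(s$deltas, 0)

    e <- deltaEncode(numeric(0))
    expect_length(e$first, 0)
    expect_identical(deltaDecode(e), numeric(0))

    expect_error(deltaEncode(c(3, 2)), class = "szdpdInvalidInputError")

    set.seed(21)
    for (i in 1:200) {
        v <- randomSortedArray(sample(0:400, 1))
        expect_identical(deltaDecode(deltaEncode(v)), v)
    }
})

test_that("pfor round-trips exhaustively on a small alphabet", {
    # every array of length <= 3 over values {0..7}
    for (len in 0:3) {
        grids <- if (len == 0) list(numeric(0)) else {
            g <- do.call(expand.grid, rep(list(0:7), len))
            lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
        }
        for (v in grids)
            expect_identical(pforDecode(pforEncode(v)), v)
    }
})

test_that("pfor structural properties match the documented layout", {
    # all-zero miniblock: bit width byte 0, no packed area, 0 exceptions
    p <- pforEncode(rep(0, 128))
    # magic(4) + version(1) + varint count(2) + bwidth(1) + varint nexc(1)
    expect_identical(length(p), 9L)
    expect_identical(as.integer(p[8]), 0L)   # bit width 0
    expect_identical(as.integer(p[9]), 0L)   # no exceptions

    # 127 ones + one large outlier: cost-minimal width is 1 bit with
    # exactly one exception (verified against brute-force cost search)
    v <- c(rep(1, 127), 2^20)
    costs <- vapply(0:32, function(b) {
        exc <- v[v >= 2^b]
        excB <- sum(vapply(exc, function(x) {
            hi <- x %/% 2^b
            1 + max(1, ceiling(log2(hi + 1) / 7))
        }, numeric(1)))
        128 * b / 8 + 1 + excB
    }, numeric(1))
    expect_identical(which.min(costs) - 1L, 1L)
    p <- pforEncode(v)
    expect_identical(as.integer(p[8]), 1L)            # chosen width 1
    expect_identical(as.integer(p[8 + 16 + 1]), 1L)   # one exception
    expect_identical(pforDecode(p), v)

    # a constant input array reaches pfor as all-zero deltas and costs
    # O(L/128) header bytes only (2 per miniblock: width + exception count)
    L <- 128 * 50
    d <- deltaEncode(rep(7, L))
    expect_identical(d$deltas, rep(0, L - 1))
    expect_lt(length(pforEncode(d$deltas)), 16 + (L / 128) * 4)
})

test_that("pfor round-trips at scale, mixing small values and large outliers", {
    set.seed(99)
    for (i in 1:400) {
        len <- sample(0:1000, 1)
        v <- floor(runif(len, 0, 50))
        nOut <- min(len, rpois(1, 2))
        if (nOut > 0)
            v[sample(len, nOut)] <- floor(runif(nOut, 2^28, 2^31))
        expect_identical(pforDecode(pforEncode(v)), v)
    }
    expect_error(pforEncode(2^32), class = "szdpdRangeError")
})

test_that("optimized decoder agrees with the naive per-bit reference decoder", {
    set.seed(123)
    corpora <- c(
        list(numeric(0), rep(0, 128), rep(1, 130), c(rep(1, 127), 2^20),
             0:300, rep(2^31 - 1, 129)),
        lapply(1:60, function(i) {
            len <- sample(1:400, 1)
            v <- floor(runif(len, 0, 2^sample(c(3, 8, 16, 24), 1)))
            if (runif(1) < 0.5) v[sample(len, 1)] <- floor(runif(1, 0, 2^31))
            v
        }))
    for (v in corpora) {
        p <- pforEncode(v)
        expect_identical(naivePforDecode(p), as.numeric(v))
        expect_identical(pforDecode(p), as.numeric(v))
    }
})

test_that("corrupt payloads raise format errors, never silent wrong data", {
    v <- c(rep(1, 127), 2^20, 5, 5, 9)
    p <- pforEncode(v)
    # header corruption
    for (i in 1:5) {
        bad <- p
        bad[i] <- xor(bad[i], as.raw(0xFF))
        expect_error(pforDecode(bad), class = "szdpdFormatError")
    }
    # truncation at every prefix must error (or decode-verify against v)
    for (cut in c(5, 8, 10, length(p) - 1)) {
        expect_error(pforDecode(p[seq_len(cut)]), class = "szdpdFormatError")
    }
    expect_error(pforDecode(c(p, as.raw(0))), class = "szdpdFormatError")
})

test_that("encodeSortedArray composes delta, pfor and zlib reversibly", {
    expect_identical(decodeSortedArray(encodeSortedArray(numeric(0))),
                     numeric(0))
    expect_identical(decodeSortedArray(encodeSortedArray(42)), 42)

    set.seed(17)
    for (i in 1:100) {
        v <- randomSortedArray(sample(0:2000, 1))
        expect_identical(decodeSortedArray(encodeSortedArray(v)), v)
    }

    # first value above 2^32 (6-dp territory) survives via the varint path
    big <- cumsum(c(1.1e10, floor(runif(500, 0, 1000))))
    expect_identical(decodeSortedArray(encodeSortedArray(big)), big)

    # a near-constant-gap array must beat zlib over its raw 4-byte encoding
    gaps <- sample(c(100, 101), 1e4, replace = TRUE)
    v <- cumsum(gaps)
    rawBytes <- writeBin(as.integer(v %% 2^31), raw(), size = 4,
                         endian = "little")
    expect_lt(length(encodeSortedArray(v)),
              length(memCompress(rawBytes, type = "gzip")))
})
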