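test_that("an empty run writes a valid, readable file pair", {
    stem <- file.path(tempdir(), "empty-run")
    paths <- writeRun(list(), precisionConfig(5), "DDA", stem)
    expect_identical(file.size(paths[["bin"]]), 0)
    run <- readRunMetadata(paths[["json"]])
    expect_identical(nSpectra(run), 0L)
    expect_identical(extractXic(run, 500, 20),
                     data.frame(rt = numeric(0), intensity = numeric(0)))
})

test_that("write -> read round-trips the whole run and its index", {
    fx <- smallDiaFixture()
    run <- fx$run
    expect_identical(nSpectra(run), length(fx$gen$spectra))
    expect_identical(acquisitionMode(run), "DIA")

    # JSON offsets re-derived from segment lengths match stored offsets
    off <- 0
    for (blk in run@meta$blocks) for (st in blk$stacks) {
        expect_equal(st$offset, off)
        off <- off + st$mzLength + st$tagLength + st$intensityLength
    }
    expect_equal(file.size(run@binPath), off)

    # byte determinism: encoding the same run twice is bit-identical
    stem2 <- file.path(tempdir(), "small-dia-again")
    plan <- organizeBlocks(fx$gen$spectra, "DIA", n = 3L)
    enc <- szdpd:::encodePlannedBlocks(fx$gen$spectra, plan, fx$cfg)
    p2 <- writeRun(enc, fx$cfg, "DIA", stem2)
    expect_identical(readBin(run@binPath, "raw", file.size(run@binPath)),
                     readBin(p2[["bin"]], "raw", file.size(p2[["bin"]])))
})

test_that("random access equals the corresponding slice of a full decode", {
    fx <- smallDiaFixture()
    run <- fx$run
    full <- readAllSpectra(run)
    expect_length(full, nSpectra(run))

    for (bi in seq_along(run@meta$blocks)) {
        blk <- run@meta$blocks[[bi]]
        for (si in seq_along(blk$stacks)) {
            got <- readStack(run, bi - 1L, si)
            ids <- as.integer(unlist(blk$stacks[[si]]$spectrumIds))
            for (j in seq_along(ids)) {
                want <- full[[ids[j] + 1L]]
                expect_identical(mz(got[[j]]), mz(want))
                expect_identical(intensity(got[[j]]), intensity(want))
                expect_identical(rtime(got[[j]]), rtime(want))
                expect_identical(msLevel(got[[j]]), msLevel(want))
            }
        }
    }

    # first stack of the MS1 block is MS1-only
    ms1 <- readStack(run, 0L, 1L)
    expect_true(all(vapply(ms1, msLevel, integer(1)) == 1L))

    # per-id random access, including rt/window provenance
    for (id in c(0L, 5L, nSpectra(run) - 1L)) {
        s <- readSpectrum(run, id)
        orig <- fx$gen$spectra[[id + 1L]]
        expect_identical(rtime(s), rtime(orig))
        expect_identical(msLevel(s), msLevel(orig))
        ref <- storedSpectrum(orig, fx$cfg)
        expect_equal(mz(s), ref$mz, tolerance = 1e-12)
        expect_identical(intensity(s), ref$intensity)
    }

    expect_error(readStack(run, 99L, 1L), class = "szdpdLookupError")
    expect_error(readStack(run, 0L, 999L), class = "szdpdLookupError")
    expect_error(readSpectrum(run, -1L), class = "szdpdLookupError")
})

test_that("the index is validated on read", {
    fx <- smallDiaFixture()
    meta <- jsonlite::fromJSON(fx$run@jsonPath, simplifyVector = FALSE)

    rewrite <- function(m) {
        p <- tempfile(tmpdir = dirname(fx$run@jsonPath), fileext = ".mini-aird.json")
        jsonlite::write_json(m, p, auto_unbox = TRUE, digits = NA, null = "null")
        p
    }

    m <- meta; m$format <- "mini-aird-99"
    expect_error(readRunMetadata(rewrite(m)), class = "szdpdVersionError")

    m <- meta; m$precision <- NULL
    expect_error(readRunMetadata(rewrite(m)), "precision",
                 class = "szdpdFormatError")

    m <- meta; m$blocks[[1]]$stacks[[2]]$offset <- 1
    expect_error(readRunMetadata(rewrite(m)), class = "szdpdFormatError")

    expect_error(readRunMetadata(tempfile()), class = "szdpdIOError")
})

test_that("XIC equals a brute-force scan and is monotone in tolerance", {
    fx <- smallDiaFixture()
    run <- fx$run
    full <- readAllSpectra(run)
    lv <- vapply(full, msLevel, integer(1))
    keys <- rep(NA_character_, length(full))
    keys[lv == 2L] <- vapply(full[lv == 2L], function(s)
        paste(round(precursorWindow(s), 4), collapse = ":"), character(1))
    windows <- fx$gen$truth$windows

    set.seed(2024)
    for (q in 1:40) {
        mzc <- runif(1, 420, 1180)
        ppm <- runif(1, 10, 5000)
        if (q %% 2 == 0) {
            got <- extractXic(run, mzc, ppm, msLevel = 1L)
            want <- bruteXic(full[lv == 1L], mzc, ppm)
        } else {
            w <- windows[[sample(length(windows), 1)]]
            got <- extractXic(run, mzc, ppm, msLevel = 2L, window = w)
            sel <- !is.na(keys) & keys == paste(round(w, 4), collapse = ":")
            want <- bruteXic(full[sel], mzc, ppm)
        }
        expect_equal(got, want, tolerance = 1e-12)
    }

    # widening the tolerance never decreases any XIC point
    mzc <- 700
    prev <- extractXic(run, mzc, 5, msLevel = 1L)
    for (ppm in c(50, 500, 5000, 50000)) {
        cur <- extractXic(run, mzc, ppm, msLevel = 1L)
        expect_true(all(cur$intensity >= prev$intensity - 1e-9))
        prev <- cur
    }

    # rt filtering
    rtAll <- extractXic(run, mzc, 1000, msLevel = 1L)
    rtWin <- extractXic(run, mzc, 1000, msLevel = 1L,
                        rtRange = c(2, 6))
    expect_equal(rtWin, rtAll[rtAll$rt >= 2 & rtAll$rt <= 6, ],
                 ignore_attr = TRUE)

    expect_error(extractXic(run, mzc, 20, msLevel = 2L),
                 class = "szdpdInvalidInputError")
    expect_error(extractXic(run, mzc, -1), class = "szdpdInvalidInputError")
})
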