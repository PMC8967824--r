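test_that("acquisition mode detection follows the window pattern", {
    dia <- generateRun(generatorConfig(mode = "DIA", nMs1Spectra = 6L,
                                       basePeakCount = 20L,
                                       diaWindowCount = 4L, seed = 3L))
    expect_identical(as.character(detectMode(dia$spectra)), "DIA")

    dda <- generateRun(generatorConfig(mode = "DDA", nMs1Spectra = 6L,
                                       basePeakCount = 20L, seed = 3L))
    expect_identical(as.character(detectMode(dda$spectra)), "DDA")

    ms1only <- Filter(function(s) msLevel(s) == 1L, dda$spectra)
    expect_identical(as.character(detectMode(ms1only)), "DDA")

    # AIF-style: one wide repeating window is DIA
    aif <- lapply(1:9, function(i) {
        if (i %% 3 == 1) Spectrum(500, 1, rt = i)
        else Spectrum(300, 1, rt = i, msLevel = 2L,
                      precursorWindow = c(400, 1200))
    })
    expect_identical(as.character(detectMode(aif)), "DIA")
})

test_that("block organization partitions every spectrum exactly once", {
    gen <- generateRun(generatorConfig(mode = "DIA", nMs1Spectra = 12L,
                                       basePeakCount = 20L,
                                       diaWindowCount = 4L, seed = 8L))
    plan <- organizeBlocks(gen$spectra, "DIA", n = 2L)
    expect_identical(plan$mode, "DIA")
    # 1 MS1 block + 4 window blocks
    expect_length(plan$blocks, 5L)
    allIds <- unlist(lapply(plan$blocks, function(b) unlist(b$stackIds)))
    expect_setequal(allIds, seq_along(gen$spectra) - 1L)
    expect_false(anyDuplicated(allIds) > 0)
    # 12 MS1 spectra at n = 2 -> stacks of 4, 4, 4
    expect_identical(lengths(plan$blocks[[1]]$stackIds), c(4L, 4L, 4L))

    # ceil(count / 2^n) stack arithmetic: 600 spectra at n = 8 -> 256/256/88
    fake <- lapply(seq_len(600) - 1L, function(i) Spectrum(500, 1, rt = i))
    p600 <- organizeBlocks(fake, "DDA", n = 8L)
    expect_identical(lengths(p600$blocks[[1]]$stackIds), c(256L, 256L, 88L))
})

test_that("DDA MS2 spectra stay unstacked under their triggering MS1 scan", {
    gen <- generateRun(generatorConfig(mode = "DDA", nMs1Spectra = 5L,
                                       basePeakCount = 30L, ddaTopN = 3L,
                                       seed = 14L))
    plan <- organizeBlocks(gen$spectra, "DDA", n = 8L)
    ms2blocks <- Filter(function(b) b$msLevel == 2L, plan$blocks)
    expect_length(ms2blocks, 5L)  # one group per triggering MS1
    for (b in ms2blocks) {
        expect_identical(b$layerExponent, 0L)
        expect_true(all(lengths(b$stackIds) == 1L))  # plain ZDPD path
        expect_length(b$stackIds, 3L)
    }
    # DDA MS2 path bit-equals the stack codec at n = 0
    s <- gen$spectra[[2]]
    cfg <- precisionConfig(5)
    enc <- szdpd:::encodePlannedBlocks(gen$spectra, plan, cfg)
    direct <- encodeStack(list(s), cfg, n = 0L)
    viaPlan <- enc[[2]]$stacks[[1]]$stack
    expect_identical(viaPlan@mzPayload, direct@mzPayload)
    expect_identical(viaPlan@tagPayload, direct@tagPayload)
    expect_identical(viaPlan@intensityPayload, direct@intensityPayload)
})

test_that("convert -> read-back reproduces spectra within the quantization bound", {
    gen <- generateRun(generatorConfig(mode = "DIA", nMs1Spectra = 8L,
                                       basePeakCount = 50L,
                                       diaWindowCount = 2L, seed = 19L))
    mzml <- tempfile(fileext = ".mzML")
    writeMzmlFixture(gen$spectra, mzml)
    stem <- file.path(tempdir(), "conv-run")
    rep <- convertMzml(mzml, stem, cfg = precisionConfig(5), n = 3L)
    expect_identical(rep$mode, "DIA")
    expect_identical(rep$nSpectra, length(gen$spectra))

    run <- readRunMetadata(rep$paths$json)
    dec <- readAllSpectra(run)
    for (i in seq_along(gen$spectra)) {
        err <- abs(mz(dec[[i]]) - mz(gen$spectra[[i]]))
        expect_true(all(err <= 0.5e-5 + 1e-12))
        expect_identical(intensity(dec[[i]]),
                         storedIntensity(intensity(gen$spectra[[i]])))
        expect_equal(rtime(dec[[i]]), rtime(gen$spectra[[i]]),
                     tolerance = 1e-9)
    }

    # report segment bytes sum to the binary file size
    segSum <- sum(vapply(rep$blockSegments, function(b)
        b$mzBytes + b$tagBytes + b$intensityBytes, numeric(1)))
    expect_equal(segSum, as.numeric(file.size(rep$paths$bin)))

    # the compression table regenerated from the files alone matches
    expect_equal(compressionReport(stem), rep$compression, tolerance = 1e-12)

    # empty mzML converts to a valid empty run
    e <- tempfile(fileext = ".mzML")
    writeMzmlFixture(list(), e)
    rep0 <- convertMzml(e, file.path(tempdir(), "empty-conv"))
    expect_identical(rep0$nSpectra, 0L)
    run0 <- readRunMetadata(rep0$paths$json)
    expect_identical(nSpectra(run0), 0L)
})
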