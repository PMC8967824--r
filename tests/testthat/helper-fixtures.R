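# Shared seeded fixtures, built once per test session.

.fixtures <- new.env(parent = emptyenv())

# Small DIA run with several stacks per block (fast; structural tests).
smallDiaFixture <- function() {
    if (is.null(.fixtures$small)) {
        gen <- generateRun(generatorConfig(
            mode = "DIA", nMs1Spectra = 20L, basePeakCount = 60L,
            diaWindowCount = 3L, extraPeakRate = 5, seed = 11L))
        cfg <- precisionConfig(5L)
        stem <- file.path(tempdir(), "small-dia")
        plan <- organizeBlocks(gen$spectra, "DIA", n = 3L)
        enc <- szdpd:::encodePlannedBlocks(gen$spectra, plan, cfg)
        writeRun(enc, cfg, "DIA", stem)
        .fixtures$small <- list(
            gen = gen, cfg = cfg, stem = stem,
            run = readRunMetadata(paste0(stem, ".mini-aird.json")))
    }
    .fixtures$small
}

# Full-size study-condition DIA run: generator defaults (256 MS1 cycles,
# 4 windows, p = 0.9, jitter 2e-4 Da, seed 42), encoded at n = 8, dp = 5.
studyDiaFixture <- function() {
    if (is.null(.fixtures$study)) {
        gen <- generateRun(generatorConfig())
        cfg <- precisionConfig(5L)
        stem <- file.path(tempdir(), "study-dia")
        plan <- organizeBlocks(gen$spectra, "DIA", n = 8L)
        enc <- szdpd:::encodePlannedBlocks(gen$spectra, plan, cfg)
        writeRun(enc, cfg, "DIA", stem)
        run <- readRunMetadata(paste0(stem, ".mini-aird.json"))
        .fixtures$study <- list(
            gen = gen, cfg = cfg, stem = stem, run = run,
            decoded = readAllSpectra(run))
    }
    .fixtures$study
}

randomSortedArray <- function(len, maxGap = 1e5) {
    if (len == 0) return(numeric(0))
    cumsum(floor(runif(len, 0, maxGap)))
}
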