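# Seeded generator of TOF-like synthetic runs. The generative model
# realizes the property Stack-ZDPD exploits: adjacent spectra of the same
# level (or isolation window) share most of their m/z values, so the
# merged array has small, repetitive deltas. Each level/window has a fixed
# table of M base centroids; every scan re-observes base peak j with
# probability p at the base m/z plus Gaussian jitter, and adds a Poisson
# number of uniform decoy peaks (decoys are the realistic worst case for
# tag-array entropy).

#' Configuration for the synthetic run generator
#'
#' @param mode `"DIA"` (default) or `"DDA"`.
#' @param nMs1Spectra number of survey scans (= cycles). Default 256, one
#'   full default stack.
#' @param basePeakCount M, size of the persistent centroid table per
#'   level/window. Default 500.
#' @param presenceProb p, probability that a base peak appears in a given
#'   scan. Default 0.9 (high adjacent-spectrum similarity, TOF-like).
#' @param mzJitterSd centroid jitter standard deviation in Daltons.
#'   Default 2e-4 (sub-ppm at m/z 400+, typical of recalibrated TOF
#'   centroids).
#' @param extraPeakRate Poisson mean of uniform decoy peaks per scan.
#'   Default 25.
#' @param mzRange m/z interval for base and decoy peaks. Default
#'   c(400, 1200).
#' @param intensityMeanLog,intensitySdLog log-normal intensity parameters.
#'   Defaults log(1e4) and 1.
#' @param cycleTime seconds per acquisition cycle. Default 1.
#' @param diaWindowCount number of DIA isolation windows. Default 4.
#' @param ddaTopN MS2 scans triggered per DDA cycle. Default 5.
#' @param seed integer seed; same (config, seed) gives a bit-identical
#'   run.
#' @return a validated `GeneratorConfig` list.
#' @export
generatorConfig <- function(mode = c("DIA", "DDA"), nMs1Spectra = 256L,
                            basePeakCount = 500L, presenceProb = 0.9,
                            mzJitterSd = 2e-4, extraPeakRate = 25,
                            mzRange = c(400, 1200),
                            intensityMeanLog = log(1e4), intensitySdLog = 1,
                            cycleTime = 1, diaWindowCount = 4L, ddaTopN = 5L,
                            seed = 42L) {
    mode <- match.arg(mode)
    if (is.na(presenceProb) || presenceProb < 0 || presenceProb > 1)
        stopConfig("presenceProb must be in [0, 1]")
    if (length(mzRange) != 2 || mzRange[1] >= mzRange[2] || mzRange[1] < 0)
        stopConfig("mzRange must be c(lo, hi) with 0 <= lo < hi")
    if (nMs1Spectra < 0 || basePeakCount < 0 || extraPeakRate < 0 ||
        mzJitterSd < 0 || cycleTime <= 0)
        stopConfig("counts and rates must be non-negative, cycleTime positive")
    if (diaWindowCount < 1 || ddaTopN < 1)
        stopConfig("diaWindowCount and ddaTopN must be >= 1")
    structure(list(
        mode = mode, nMs1Spectra = as.integer(nMs1Spectra),
        basePeakCount = as.integer(basePeakCount),
        presenceProb = presenceProb, mzJitterSd = mzJitterSd,
        extraPeakRate = extraPeakRate, mzRange = as.numeric(mzRange),
        intensityMeanLog = intensityMeanLog, intensitySdLog = intensitySdLog,
        cycleTime = cycleTime, diaWindowCount = as.integer(diaWindowCount),
        ddaTopN = as.integer(ddaTopN), seed = as.integer(seed)
    ), class = "GeneratorConfig")
}

#' Expected peaks per synthetic spectrum
#'
#' @param cfg a `GeneratorConfig`.
#' @return `basePeakCount * presenceProb + extraPeakRate`.
#' @export
expectedPeaksPerSpectrum <- function(cfg) {
    cfg$basePeakCount * cfg$presenceProb + cfg$extraPeakRate
}

# Deterministic sub-seed per scan index, kept below 2^31.
scanSeed <- function(seed, i) {
    (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

drawSpectrum <- function(base, cfg, subSeed) {
    set.seed(subSeed)
    present <- runif(length(base)) < cfg$presenceProb
    mzv <- base[present] + rnorm(sum(present), 0, cfg$mzJitterSd)
    nExtra <- rpois(1, cfg$extraPeakRate)
    mzv <- c(mzv, runif(nExtra, cfg$mzRange[1], cfg$mzRange[2]))
    mzv <- pmax(mzv, 0)
    ity <- rlnorm(length(mzv), cfg$intensityMeanLog, cfg$intensitySdLog)
    srt <- sortSpectrum(mzv, ity)
    srt
}

#' Generate a seeded synthetic run
#'
#' DIA: each cycle emits one MS1 scan followed by one MS2 scan per
#' isolation window (windows tile the m/z range). DDA: each cycle emits
#' one MS1 scan and `ddaTopN` MS2 scans on precursors sampled from that
#' scan's peaks (1 Da isolation). Retention times advance by
#' `cycleTime / scansPerCycle` per scan.
#'
#' @param cfg a `GeneratorConfig` from [generatorConfig()].
#' @return list with `spectra` (list of [Spectrum-class] in acquisition
#'   order) and `truth` (mode, window map, base peak tables, config).
#' @export
generateRun <- function(cfg) {
    stopifnot(inherits(cfg, "GeneratorConfig"))
    set.seed(cfg$seed)
    ms1base <- sort(runif(cfg$basePeakCount, cfg$mzRange[1], cfg$mzRange[2]))

    windows <- NULL
    ms2base <- list()
    if (cfg$mode == "DIA") {
        edges <- seq(cfg$mzRange[1], cfg$mzRange[2],
                     length.out = cfg$diaWindowCount + 1)
        windows <- lapply(seq_len(cfg$diaWindowCount),
                          function(w) c(edges[w], edges[w + 1]))
        ms2base <- lapply(seq_len(cfg$diaWindowCount), function(w)
            sort(runif(cfg$basePeakCount, cfg$mzRange[1], cfg$mzRange[2])))
    }

    scansPerCycle <- if (cfg$mode == "DIA") 1L + cfg$diaWindowCount
                     else 1L + cfg$ddaTopN
    dt <- cfg$cycleTime / scansPerCycle

    spectra <- list()
    scan <- 0L
    for (cyc in seq_len(cfg$nMs1Spectra)) {
        s1 <- drawSpectrum(ms1base, cfg, scanSeed(cfg$seed, scan))
        spectra[[length(spectra) + 1]] <- Spectrum(
            mz = s1$mz, intensity = s1$intensity, rt = scan * dt, msLevel = 1L)
        scan <- scan + 1L

        if (cfg$mode == "DIA") {
            for (w in seq_len(cfg$diaWindowCount)) {
                sw <- drawSpectrum(ms2base[[w]], cfg, scanSeed(cfg$seed, scan))
                spectra[[length(spectra) + 1]] <- Spectrum(
                    mz = sw$mz, intensity = sw$intensity, rt = scan * dt,
                    msLevel = 2L, precursorWindow = windows[[w]])
                scan <- scan + 1L
            }
        } else {
            set.seed(scanSeed(cfg$seed, scan) + 1)
            pool <- if (length(s1$mz)) s1$mz else
                runif(cfg$ddaTopN, cfg$mzRange[1], cfg$mzRange[2])
            prec <- sample(pool, cfg$ddaTopN, replace = length(pool) < cfg$ddaTopN)
            for (t in seq_len(cfg$ddaTopN)) {
                st <- drawSpectrum(numeric(0), cfg, scanSeed(cfg$seed, scan))
                spectra[[length(spectra) + 1]] <- Spectrum(
                    mz = st$mz, intensity = st$intensity, rt = scan * dt,
                    msLevel = 2L,
                    precursorWindow = c(prec[t] - 0.5, prec[t] + 0.5))
                scan <- scan + 1L
            }
        }
    }

    list(spectra = spectra,
         truth = list(mode = cfg$mode, windows = windows,
                      ms1BasePeaks = ms1base, ms2BasePeaks = ms2base,
                      config = cfg))
}
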