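# Independent reference implementations used as oracles. Deliberately
# naive: per-bit loops, digit-string arithmetic, linear scans.

# --- varint / PFor reference decoder (pure R, bit by bit) ----------------

naiveVarint <- function(bytes, pos) {
    x <- 0
    shift <- 0
    repeat {
        b <- as.integer(bytes[pos])
        pos <- pos + 1
        x <- x + (b %% 128) * 2^shift
        if (b < 128) break
        shift <- shift + 7
    }
    list(value = x, pos = pos)
}

naivePforDecode <- function(payload) {
    stopifnot(rawToChar(payload[1:4]) == "PFR1", as.integer(payload[5]) == 1)
    bits <- as.integer(rawToBits(payload))  # LSB-first within each byte
    pos <- 6
    r <- naiveVarint(payload, pos); L <- r$value; pos <- r$pos
    out <- numeric(0)
    while (length(out) < L) {
        b <- as.integer(payload[pos]); pos <- pos + 1
        block <- numeric(128)
        if (b > 0) {
            bitstart <- (pos - 1) * 8
            for (i in 1:128) {
                v <- 0
                for (k in 0:(b - 1))
                    v <- v + bits[bitstart + (i - 1) * b + k + 1] * 2^k
                block[i] <- v
            }
            pos <- pos + 128 * b / 8
        }
        r <- naiveVarint(payload, pos); nexc <- r$value; pos <- r$pos
        at <- 0
        if (nexc > 0) for (e in 1:nexc) {
            r <- naiveVarint(payload, pos); pd <- r$value; pos <- r$pos
            r <- naiveVarint(payload, pos); hi <- r$value; pos <- r$pos
            at <- if (e == 1) pd else at + pd
            block[at + 1] <- block[at + 1] + hi * 2^b
        }
        out <- c(out, block[seq_len(min(128, L - length(out)))])
    }
    out
}

# --- bit-order oracle for tag packing (explicit per-bit loop) -----------

naivePackBits <- function(values, n) {
    if (n == 0 || !length(values)) return(raw(0))
    nbits <- length(values) * n
    bits <- integer(ceiling(nbits / 8) * 8)
    pos <- 0
    for (v in values) {
        for (k in 0:(n - 1)) {
            bits[pos + 1] <- (v %/% 2^k) %% 2
            pos <- pos + 1
        }
    }
    packBits(as.raw(bits), type = "raw")
}

naiveUnpackBits <- function(bytes, count, n) {
    bits <- as.integer(rawToBits(bytes))
    vapply(seq_len(count), function(i) {
        sum(bits[(i - 1) * n + seq_len(n)] * 2^(0:(n - 1)))
    }, numeric(1))
}

# --- exact decimal quantization oracle ----------------------------------
# Operates on decimal digit strings, so the expected value is computed by
# integer arithmetic with no floating point involved.

oracleQuantizeString <- function(s, dp) {
    vapply(s, function(one) {
        parts <- strsplit(one, ".", fixed = TRUE)[[1]]
        ip <- parts[1]
        fp <- if (length(parts) > 1) parts[2] else ""
        if (nchar(fp) < dp + 1) fp <- paste0(fp, strrep("0", dp + 1 - nchar(fp)))
        base <- as.numeric(paste0(ip, substr(fp, 1, dp)))
        rest <- substr(fp, dp + 1, nchar(fp))
        if (substr(rest, 1, 1) >= "5") base + 1 else base
    }, numeric(1), USE.NAMES = FALSE)
}

# Random decimal strings with bounded digit counts (so the double
# representation round-trips the digits exactly).
randomDecimalStrings <- function(m, maxIntDigits = 4, maxFracDigits = 8) {
    vapply(seq_len(m), function(i) {
        ni <- sample(1:maxIntDigits, 1)
        nf <- sample(0:maxFracDigits, 1)
        ip <- paste(c(sample(1:9, 1), sample(0:9, ni - 1, replace = TRUE)),
                    collapse = "")
        if (nf == 0) ip
        else paste0(ip, ".", paste(sample(0:9, nf, replace = TRUE), collapse = ""))
    }, character(1))
}

# --- brute-force XIC over decoded spectra -------------------------------

bruteXic <- function(spectra, mzCenter, tolPpm, rtRange = NULL) {
    lo <- mzCenter * (1 - tolPpm * 1e-6)
    hi <- mzCenter * (1 + tolPpm * 1e-6)
    rt <- vapply(spectra, rtime, numeric(1))
    ity <- vapply(spectra, function(s) {
        sel <- mz(s) >= lo & mz(s) <= hi
        sum(intensity(s)[sel])
    }, numeric(1))
    o <- order(rt)
    res <- data.frame(rt = rt[o], intensity = ity[o])
    if (!is.null(rtRange))
        res <- res[res$rt >= rtRange[1] & res$rt <= rtRange[2], , drop = FALSE]
    rownames(res) <- NULL
    res
}

# Stored representation of a spectrum (what a lossless-at-integer-level
# round trip must reproduce exactly).
storedSpectrum <- function(s, cfg, width = 4L) {
    list(mz = dequantizeMz(quantizeMz(mz(s), cfg), cfg),
         intensity = storedIntensity(intensity(s), width))
}

expectStackRoundTrip <- function(spectra, cfg, n, width = 4L) {
    es <- encodeStack(spectra, cfg, n = n, intensityWidth = width)
    dec <- decodeStack(es, cfg, rt = vapply(spectra, rtime, numeric(1)),
                       msLevel = msLevel(spectra[[1]]),
                       precursorWindow = precursorWindow(spectra[[1]]))
    expect_length(dec, length(spectra))
    for (i in seq_along(spectra)) {
        ref <- storedSpectrum(spectra[[i]], cfg, width)
        expect_identical(quantizeMz(mz(dec[[i]]), cfg),
                         quantizeMz(ref$mz, cfg))
        expect_identical(intensity(dec[[i]]), ref$intensity)
    }
    invisible(es)
}
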