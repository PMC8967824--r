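---
title: "Stack-ZDPD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stack-ZDPD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szdpd)
```

## The problem

Centroided mass spectrometry runs are dominated by their m/z arrays:
every scan carries a sorted list of floating-point mass-to-charge values,
and in mzML those arrays are base64-encoded text, inflating files far
beyond the information they carry. Two observations make much better
compression possible. First, instrument precision is finite: keeping 4–6
decimal places (roughly 1 ppm to 0.01 ppm on small ions) loses nothing a
downstream tool can use, and turns each array into sorted integers.
Second, *adjacent spectra of the same kind look alike*. On
time-of-flight instruments especially, consecutive survey scans — or
consecutive fragment scans from the same DIA isolation window — re-observe
largely the same centroids with sub-ppm jitter.

## The codec

ZDPD compresses one quantized array: delta-encode the sorted integers,
pack the deltas with a patched frame-of-reference (PFor) integer codec,
and wrap the result in zlib. Stack-ZDPD exploits inter-spectrum
similarity by first **merging** the quantized arrays of up to $2^n$
same-level (same-window) spectra into one globally sorted array, then
running the same delta → PFor → zlib pipeline once. Because similar
spectra interleave tightly, the merged deltas are far smaller and far
more repetitive than per-spectrum deltas, which is exactly what a
bit-packing codec rewards.

Merging destroys spectrum boundaries, so each merged element carries a
*tag*: the index of its source spectrum within the stack, an integer in
$[0, 2^n)$ occupying exactly $n$ bits. Tags are bit-packed
(`ceiling(peaks * n / 8)` bytes, a law the tests assert exactly) and
zlib-compressed. Reconstruction scatters the merged array by tag;
restricted to one tag value, the merged order is the original sorted
order, so the round trip is exact at the integer level. The m/z cost of
stacking shrinks with $n$ while the tag cost grows roughly linearly with
$n$, so total size is U-shaped in $n$; at $n = 8$ each tag is exactly one
byte, a layout the byte-oriented zlib layer handles gracefully, and 256-spectrum
stacks are the shipped default (`encodeStack(..., n = 8)`).

Intensities are carried through **in merged order** as little-endian
IEEE floats (4 bytes by default, 8 on request). The published format
this package is modeled on does not document its intensity layout; we
chose merged order deliberately, as our own design: the single tag array
then drives both the m/z and the intensity scatter, and an m/z window is
one contiguous slice of both arrays, which is what the XIC path uses.
Narrowing doubles to float32 is the one lossy step besides quantization
and mirrors common mzML practice; it is applied identically on every
path, so stored intensities round-trip bit-exactly.

## The PFor variant

The literature leaves "PFor" underspecified (the reference
implementation this family of formats binds is a C++ library with many
schemes), so this package pins its own, documented to bit precision in
`docs/format.md`: miniblocks of 128 values; per miniblock a bit width
$b \in [0, 32]$ chosen by brute-force cost minimization; values with
high bits beyond $b$ stored as patched exceptions
(position-delta varint, high-bits varint); LSB-first packing; a varint
`first` value so 6-dp quantized m/z above $2^{32}$ survives while deltas
stay in 32-bit lanes (a delta $\ge 2^{32}$ would mean a >4000 Da gap at
6 dp and is rejected as corrupt). There is deliberately **no
frame-of-reference base subtraction** per miniblock: the codec always
runs after delta encoding, where values are already small, and the
simpler layout is easier to verify — the test suite checks the optimized
decoder against a naive per-bit reference decoder and checks the chosen
width against an independent cost search. Byte compatibility with any
published SDK is a non-goal; correctness-first scalar code is the point,
not SIMD throughput.

## Quantization and rounding

`quantizeMz` computes `round_half_up(mz * 10^dp)` with decimal
semantics: a value whose decimal representation ends exactly on a half
step (e.g. 123.45675 at 4 dp) rounds up even when its nearest binary
double sits marginally below the half step. The fast path is
`floor(x * scale + 0.5)`; only values landing within $10^{-5}$ of a .5
boundary after scaling are re-examined via digit-string rounding of
their shortest decimal representation. The error bound
$|q/\mathrm{scale} - x| \le 0.5 \times 10^{-dp}$ is analytic and asserted
over randomized sweeps at all three supported precisions; supported
`dp` values are fixed to {4, 5, 6} and anything else is rejected. The
default is 5 dp — at that precision stored data are, in practice,
indistinguishable from the original floats in downstream chromatogram
building, while 4 dp trades a little fidelity for size.

## Container and acquisition modes

A run is a JSON index plus a binary block file (`docs/format.md`,
`docs/mini-aird-schema.json`). Spectra are reordered from acquisition
order into blocks: all MS1 scans together; DIA MS2 scans grouped by
isolation window (rounded to 4 decimals before grouping, because mzML
precursor records jitter below that); DDA MS2 scans grouped under their
triggering MS1 scan — the most recent preceding survey scan in file
order, since the optional `spectrumRef` attribute cannot be relied on.
DDA MS2 groups are small and their members dissimilar (different
precursors), so they are stored unstacked ($n = 0$, one spectrum per
stack, empty tag payload); DIA blocks stack at the configured $n$. The
JSON keeps retention times, global spectrum ids (0-based acquisition
order, so provenance survives the reorder) and, for DDA MS2 stacks,
per-layer precursor windows; random access is one seek plus one bounded
read per stack. XIC queries binary-search the merged sorted array of
each relevant stack and aggregate intensities by tag, never
materializing spectra; the tests hold this path equal to a per-spectrum
linear scan over 100 random queries.

Acquisition-mode detection is heuristic by construction: a run is called
DIA when its distinct rounded windows form a small set, each observed at
least three times, repeating cyclically (≥ 90% positional agreement, so
occasional dropped scans do not flip the call); everything else,
including MS1-only runs, takes the DDA plan. An all-in-one (AIF) run
presents as a single wide repeating window and is correctly treated as
one-window DIA. The decision and its evidence are attached to the
returned value.

## The synthetic generator

Tests and benchmarks run on seeded synthetic runs, not downloads. Each
MS level / window owns a fixed table of $M$ base centroids drawn
uniformly over the m/z range; every scan re-observes base peak $j$ with
probability $p$ at the base position plus $N(0, \sigma^2)$ jitter, and
adds a Poisson number of uniformly placed decoy peaks — decoys are the
realistic worst case for tag-array entropy, since they interleave
arbitrarily. Intensities are log-normal; retention times advance by a
fixed per-scan step; the per-scan RNG substream is derived
deterministically from (seed, scan index), so runs are bit-reproducible
under a seed.

Defaults were chosen once to emulate a TOF-like DIA run at desk scale:
256 MS1 cycles, $M = 500$, $p = 0.9$, $\sigma = 2\times10^{-4}$ Da,
25 decoys/scan, m/z 400–1200, 4 isolation windows, seed 42 — a
256-spectrum block of ~475-peak spectra whose adjacent-spectrum overlap
is the regime stacking is designed for. The generator reproduces the
*property* the codec exploits, not mass spectrometry: there are no
isotope envelopes, charge states or chromatographic peak shapes, and
window-to-window fragment populations are independent. Passing tests
therefore demonstrate codec correctness on any sorted input and a
stacking benefit in the high-similarity regime; they do not certify
compression ratios on any particular instrument's files. On these study
conditions the package measures a ~22% size reduction of Stack-ZDPD over
per-spectrum ZDPD (`scripts/acceptance.R` recomputes this), of the same
order as the ~30% reported for real TOF data by the format's authors;
the sweep optimum lands at $n = 7$–8 depending on seed, and only "the
optimum is a stacked configuration" is asserted, not its exact position.

## Numerical and degenerate-input choices

* Ties in the merge (equal quantized m/z across layers) break by
  ascending layer index, stably — required for bit-identical re-encoding,
  which the container tests assert.
* Duplicate quantized m/z within one spectrum is preserved as repeated
  values (delta 0); no peak merging.
* Empty spectra occupy a layer with a zero peak count and survive the
  round trip; an empty run writes a valid index and a 0-byte binary.
* A partial final stack keeps the block's declared $n$ (uniform decode
  path); `spectrumCount` records the true layer count.
* Corrupt payloads (bad magic, truncation, tag/count mismatch,
  out-of-range tags) raise classed format errors, never partial output;
  decoding with the wrong precision shifts m/z by exactly the scale
  ratio, a documented hazard covered by a test.
* `EncodedStack` payloads carry no retention times or windows — those
  belong to the container index — so `decodeStack` accepts them as
  arguments when spectra need labeling outside a container.
* zlib is used at R's built-in default level (6); encoding is therefore
  deterministic and the same run encodes to bit-identical files.

## Problem sizes

The test suite enumerates all 585 PFor inputs over a small alphabet,
runs on the order of $10^4$ randomized round trips across the codec
stages, and exercises the container and XIC paths on a 1280-spectrum
(256 MS1 + 4×256 MS2, ~600k peaks) seeded DIA run; `scripts/acceptance.R`
regenerates that run, converts it through the full mzML → mini-Aird
path and reports the compression, accuracy and agreement numbers it
measures. These sizes were chosen as the smallest at which the
stacking benefit and the law-of-large-numbers generator checks are
stable across seeds.

## Known limitations

* mzML support is a documented subset (float arrays, zlib or no
  compression, MS levels 1–2); Numpress-coded arrays are rejected with
  the offending CV term named. Vendor raw files, SRM/MRM/PRM modes and
  chromatogram lists are out of scope.
* The container is not byte-compatible with any published SDK; it is a
  self-contained, documented format for this package.
* Only m/z-window XICs are indexed; there is no columnar chromatogram
  store and no cross-stack delta prediction.
* Lossy intensity quantization ladders are out of scope; intensity
  fidelity is exactly float32 (or float64) of the input.
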