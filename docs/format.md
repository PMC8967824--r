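# mini-Aird / Stack-ZDPD byte-level format

All multi-byte integers are little-endian. "varint" is unsigned LEB128:
7 value bits per byte, LSB group first, high bit set on continuation
bytes. "zlib" is an RFC 1950 stream (`78 9c` header at the default
compression level 6).

## 1. PFor payload (`pforEncode`)

Patched frame-of-reference coding of unsigned integers `< 2^32` in
miniblocks of 128 values.

```
magic      4 bytes   "PFR1"
version    1 byte    0x01
count      varint    number of encoded values
miniblocks           ceil(count / 128) of them, back to back
```

Each miniblock:

```
bit_width  1 byte    b in 0..32, chosen per miniblock to minimize
                     16*b + bytes(exception area)
packed     16*b bytes  low b bits of each of the 128 lane values
                     (final partial miniblock is padded with zeros;
                     `count` truncates on decode)
exc_count  varint    number of exceptions E
exceptions E pairs   (varint pos_delta, varint high_bits)
```

A value `v` with `v >> b != 0` is an exception: its low `b` bits sit in
the packed area and `high_bits = v >> b` is patched back in on decode as
`v = packed | (high_bits << b)`. `pos_delta` is the 0-based lane position
for the first exception and the distance to the previous exception's
position after that.

Bit packing order: the packed area is a single bitstream, value after
value, LSB first within each byte (equivalently: LSB-first within
little-endian 32-bit words). Bit `j` of the stream is bit `j % 8` of byte
`j / 8`.

## 2. Sorted-array payload (`encodeSortedArray`) — the ZDPD m/z pipeline

```
zlib(
  length   varint    element count L
  first    varint    v[0]            (only when L > 0; may exceed 2^32,
                                      e.g. 6-dp quantized m/z)
  deltas   PFor payload of v[i+1] - v[i]   (L-1 values; only when L > 0)
)
```

Deltas must each be `< 2^32`; a larger delta is rejected (it would mean a
gap above ~4000 Da at 6 decimal places).

## 3. Tag payload (`packTags`)

`n`-bit tags (0-based source-spectrum indices within the stack), packed
LSB-first into exactly `ceil(count * n / 8)` bytes, then zlib-compressed.
At `n = 8` every tag is exactly one byte before zlib. At `n = 0`
(single-layer stack) the payload is fully empty (zero bytes, no zlib
framing).

## 4. Intensity payload

Intensities in **merged order** (aligned with the merged m/z array, so
the one tag array drives both scatters), serialized as little-endian
IEEE floats of 4 bytes (default; doubles are narrowed) or 8 bytes, then
zlib-compressed.

## 5. Container

A run is a file pair:

* `<stem>.mini-aird.json` — the index, schema
  `docs/mini-aird-schema.json`, format version `"mini-aird-1"`. It is
  authoritative for every offset and length.
* `<stem>.mini-aird.bin` — for each stack, in index order, the segments
  `mz_payload | tag_payload | intensity_payload` concatenated with no
  in-band framing.

Blocks group same-level spectra (MS1 block; one MS2 block per DIA
isolation window, rounded to 4 decimals; one unstacked MS2 block per DDA
trigger group). Retention times, spectrum ids, per-layer peak counts and
(for DDA MS2) per-layer precursor windows live in the JSON, so
enumeration and XIC time-axis construction need no payload decode.
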