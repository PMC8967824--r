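#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Patched frame-of-reference codec over 32-bit unsigned lanes.
// Values travel between R and C++ as doubles holding exact integers
// (R has no native uint32/uint64 vector type).
//
// Payload layout (little-endian throughout, see docs/format.md):
//   magic "PFR1" | version 0x01 | varint element_count |
//   per miniblock of 128 values:
//     u8 bit_width b | 16*b bytes packed low bits (LSB-first bitstream) |
//     varint exception_count | exception_count x (varint pos_delta, varint high_bits)

static const int MINIBLOCK = 128;
static const unsigned char PFOR_VERSION = 1;

static inline void put_varint(std::vector<unsigned char>& out, uint64_t x) {
    while (x >= 0x80) {
        out.push_back((unsigned char)((x & 0x7F) | 0x80));
        x >>= 7;
    }
    out.push_back((unsigned char)x);
}

static inline int varint_len(uint64_t x) {
    int n = 1;
    while (x >= 0x80) { x >>= 7; ++n; }
    return n;
}

static uint64_t get_varint(const unsigned char* buf, size_t len, size_t& pos) {
    uint64_t x = 0;
    int shift = 0;
    for (;;) {
        if (pos >= len)
            stop("payload truncated at byte %d while reading varint", (int)pos);
        unsigned char b = buf[pos++];
        x |= (uint64_t)(b & 0x7F) << shift;
        if (!(b & 0x80)) break;
        shift += 7;
        if (shift > 63)
            stop("corrupt varint at byte %d", (int)pos);
    }
    return x;
}

static std::vector<uint64_t> as_u32_values(const NumericVector& v, const char* what) {
    size_t L = v.size();
    std::vector<uint64_t> vals(L);
    for (size_t i = 0; i < L; ++i) {
        double x = v[i];
        if (!R_finite(x) || x < 0)
            stop("%s: non-finite or negative value at index %d", what, (int)(i + 1));
        if (x != std::floor(x))
            stop("%s: non-integer value at index %d", what, (int)(i + 1));
        if (x >= 4294967296.0)
            stop("%s: value at index %d is >= 2^32", what, (int)(i + 1));
        vals[i] = (uint64_t)x;
    }
    return vals;
}

// [[Rcpp::export(name = ".cpp_pfor_encode")]]
RawVector cpp_pfor_encode(NumericVector v) {
    std::vector<uint64_t> vals = as_u32_values(v, "pfor");
    size_t L = vals.size();

    std::vector<unsigned char> out;
    out.reserve(16 + L * 2);
    out.push_back('P'); out.push_back('F'); out.push_back('R'); out.push_back('1');
    out.push_back(PFOR_VERSION);
    put_varint(out, L);

    for (size_t start = 0; start < L; start += MINIBLOCK) {
        size_t m = std::min((size_t)MINIBLOCK, L - start);

        // brute-force cost minimisation over candidate bit widths
        int best_b = 32;
        size_t best_cost = (size_t)-1;
        for (int b = 0; b <= 32; ++b) {
            size_t cost = (size_t)MINIBLOCK * b / 8;
            size_t nexc = 0, exc_bytes = 0;
            uint64_t prev = 0;
            bool first = true;
            for (size_t i = 0; i < m; ++i) {
                uint64_t hi = vals[start + i] >> b;
                if (hi != 0) {
                    uint64_t pd = first ? (uint64_t)i : (uint64_t)i - prev;
                    exc_bytes += varint_len(pd) + varint_len(hi);
                    prev = (uint64_t)i;
                    first = false;
                    ++nexc;
                }
            }
            cost += varint_len(nexc) + exc_bytes;
            if (cost < best_cost) { best_cost = cost; best_b = b; }
        }

        out.push_back((unsigned char)best_b);
        size_t packed_off = out.size();
        out.resize(packed_off + (size_t)MINIBLOCK * best_b / 8, 0);
        uint64_t mask = (best_b == 0) ? 0ULL : ((best_b == 32) ? 0xFFFFFFFFULL
                                                               : ((1ULL << best_b) - 1));
        size_t bitpos = 0;
        for (int i = 0; i < MINIBLOCK; ++i) {
            uint64_t val = ((size_t)i < m) ? (vals[start + i] & mask) : 0ULL;
            for (int k = 0; k < best_b; ++k) {
                if (val & (1ULL << k))
                    out[packed_off + (bitpos >> 3)] |= (unsigned char)(1u << (bitpos & 7));
                ++bitpos;
            }
        }

        std::vector<unsigned char> excbuf;
        size_t nexc = 0;
        uint64_t prev = 0;
        bool first = true;
        for (size_t i = 0; i < m; ++i) {
            uint64_t hi = vals[start + i] >> best_b;
            if (hi != 0) {
                uint64_t pd = first ? (uint64_t)i : (uint64_t)i - prev;
                put_varint(excbuf, pd);
                put_varint(excbuf, hi);
                prev = (uint64_t)i;
                first = false;
                ++nexc;
            }
        }
        put_varint(out, nexc);
        out.insert(out.end(), excbuf.begin(), excbuf.end());
    }

    return RawVector(out.begin(), out.end());
}

// Decodes one pfor payload starting at 0-based byte `offset`; returns the
// values and the offset one past the payload (so callers can embed payloads
// in larger streams).
// [[Rcpp::export(name = ".cpp_pfor_decode")]]
List cpp_pfor_decode(RawVector payload, int offset) {
    const unsigned char* buf = RAW(payload);
    size_t len = payload.size();
    size_t pos = (size_t)offset;

    if (pos + 5 > len)
        stop("payload truncated at byte %d (header)", (int)pos);
    if (buf[pos] != 'P' || buf[pos + 1] != 'F' || buf[pos + 2] != 'R' || buf[pos + 3] != '1')
        stop("bad magic at byte %d: not a pfor payload", (int)pos);
    if (buf[pos + 4] != PFOR_VERSION)
        stop("unsupported pfor payload version %d", (int)buf[pos + 4]);
    pos += 5;

    uint64_t L = get_varint(buf, len, pos);
    if (L > (uint64_t)len * 8 * 8 + 8)  // coarse sanity bound against corrupt counts
        stop("implausible element count %.0f at byte %d", (double)L, (int)pos);

    NumericVector out((R_xlen_t)L);
    std::vector<uint64_t> block(MINIBLOCK);

    size_t emitted = 0;
    while (emitted < L) {
        if (pos >= len)
            stop("payload truncated at byte %d (miniblock header)", (int)pos);
        int b = buf[pos++];
        if (b > 32)
            stop("corrupt miniblock bit width %d at byte %d", b, (int)(pos - 1));
        size_t packed_bytes = (size_t)MINIBLOCK * b / 8;
        if (pos + packed_bytes > len)
            stop("payload truncated at byte %d (packed area)", (int)pos);

        std::fill(block.begin(), block.end(), 0ULL);
        size_t bitpos = 0;
        for (int i = 0; i < MINIBLOCK; ++i) {
            uint64_t val = 0;
            for (int k = 0; k < b; ++k) {
                if (buf[pos + (bitpos >> 3)] & (1u << (bitpos & 7)))
                    val |= (1ULL << k);
                ++bitpos;
            }
            block[i] = val;
        }
        pos += packed_bytes;

        uint64_t nexc = get_varint(buf, len, pos);
        if (nexc > (uint64_t)MINIBLOCK)
            stop("corrupt exception count %.0f at byte %d", (double)nexc, (int)pos);
        uint64_t at = 0;
        for (uint64_t e = 0; e < nexc; ++e) {
            uint64_t pd = get_varint(buf, len, pos);
            uint64_t hi = get_varint(buf, len, pos);
            at = (e == 0) ? pd : at + pd;
            if (at >= (uint64_t)MINIBLOCK)
                stop("corrupt exception position %.0f at byte %d", (double)at, (int)pos);
            block[at] |= hi << b;
        }

        size_t take = std::min((size_t)MINIBLOCK, (size_t)(L - emitted));
        for (size_t i = 0; i < take; ++i) {
            if (block[i] >= 4294967296.0)
                stop("decoded value exceeds 2^32 (corrupt exception area)");
            out[emitted + i] = (double)block[i];
        }
        emitted += take;
    }

    return List::create(_["values"] = out, _["next_offset"] = (double)pos);
}

// LSB-first fixed-width bit packing (tag arrays; nbits in 1..16).
// [[Rcpp::export(name = ".cpp_pack_bits")]]
RawVector cpp_pack_bits(IntegerVector values, int nbits) {
    if (nbits < 1 || nbits > 16)
        stop("bit width must be in 1..16, got %d", nbits);
    size_t L = values.size();
    size_t nbytes = (L * (size_t)nbits + 7) / 8;
    RawVector out(nbytes);
    unsigned char* buf = RAW(out);
    std::fill(buf, buf + nbytes, 0);
    uint32_t lim = 1u << nbits;
    size_t bitpos = 0;
    for (size_t i = 0; i < L; ++i) {
        int v = values[i];
        if (v == NA_INTEGER || v < 0 || (uint32_t)v >= lim)
            stop("tag value at index %d does not fit in %d bits", (int)(i + 1), nbits);
        for (int k = 0; k < nbits; ++k) {
            if (v & (1 << k))
                buf[bitpos >> 3] |= (unsigned char)(1u << (bitpos & 7));
            ++bitpos;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_unpack_bits")]]
IntegerVector cpp_unpack_bits(RawVector bytes, double count, int nbits) {
    if (nbits < 1 || nbits > 16)
        stop("bit width must be in 1..16, got %d", nbits);
    if (count < 0)
        stop("count must be non-negative");
    size_t L = (size_t)count;
    size_t need = (L * (size_t)nbits + 7) / 8;
    if ((size_t)bytes.size() < need)
        stop("packed tag stream has %d bytes, need %d for %d values of %d bits",
             (int)bytes.size(), (int)need, (int)L, nbits);
    const unsigned char* buf = RAW(bytes);
    IntegerVector out((R_xlen_t)L);
    size_t bitpos = 0;
    for (size_t i = 0; i < L; ++i) {
        int v = 0;
        for (int k = 0; k < nbits; ++k) {
            if (buf[bitpos >> 3] & (1u << (bitpos & 7)))
                v |= (1 << k);
            ++bitpos;
        }
        out[i] = v;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_varint_encode")]]
RawVector cpp_varint_encode(double x) {
    if (!R_finite(x) || x < 0 || x != std::floor(x) || x > 9007199254740992.0)
        stop("varint: value must be a non-negative integer below 2^53");
    std::vector<unsigned char> out;
    put_varint(out, (uint64_t)x);
    return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".cpp_varint_decode")]]
List cpp_varint_decode(RawVector payload, int offset) {
    size_t pos = (size_t)offset;
    uint64_t x = get_varint(RAW(payload), payload.size(), pos);
    if (x > 9007199254740992ULL)
        stop("varint value exceeds 2^53");
    return List::create(_["value"] = (double)x, _["next_offset"] = (double)pos);
}

#include <zlib.h>

// Safe zlib (RFC 1950) inflate: a truncated or corrupt stream raises an
// error instead of the unbounded retry-with-larger-buffer loop that a
// Z_BUF_ERROR can otherwise trigger.
// [[Rcpp::export(name = ".cpp_zlib_inflate")]]
RawVector cpp_zlib_inflate(RawVector input) {
    if (input.size() == 0)
        stop("zlib stream is empty");
    z_stream strm;
    std::memset(&strm, 0, sizeof(strm));
    if (inflateInit(&strm) != Z_OK)
        stop("zlib inflateInit failed");
    std::vector<unsigned char> out;
    std::vector<unsigned char> buf(1 << 16);
    strm.next_in = (Bytef*)RAW(input);
    strm.avail_in = (uInt)input.size();
    int ret = Z_OK;
    for (;;) {
        strm.next_out = buf.data();
        strm.avail_out = (uInt)buf.size();
        ret = inflate(&strm, Z_NO_FLUSH);
        if (ret != Z_OK && ret != Z_STREAM_END) {
            inflateEnd(&strm);
            stop("zlib inflate failed: corrupt or truncated stream (code %d)", ret);
        }
        out.insert(out.end(), buf.data(), buf.data() + (buf.size() - strm.avail_out));
        if (ret == Z_STREAM_END) break;
        if (strm.avail_in == 0 && strm.avail_out != 0) {
            inflateEnd(&strm);
            stop("zlib stream truncated");
        }
    }
    bool trailing = strm.avail_in != 0;
    inflateEnd(&strm);
    if (trailing)
        stop("trailing bytes after zlib stream end");
    return RawVector(out.begin(), out.end());
}
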