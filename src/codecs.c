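#include "fapack.h"
#include <zlib.h>

/* 2-bit DNA packing: A=0, C=1, G=2, T=3, symbol j in bits 2*(j%4) of byte
   j/4 (first symbol in the least-significant bits). */

static signed char DNA_CODE[256];
static int code_ready = 0;

static void build_code(void) {
    memset(DNA_CODE, -1, sizeof(DNA_CODE));
    DNA_CODE['A'] = 0;
    DNA_CODE['C'] = 1;
    DNA_CODE['G'] = 2;
    DNA_CODE['T'] = 3;
    code_ready = 1;
}

SEXP C_pack_dna(SEXP sym_) {
    if (!code_ready) build_code();
    const unsigned char *p = RAW(sym_);
    R_xlen_t n = XLENGTH(sym_);
    if (n % 4 != 0) Rf_error("pack_dna() requires a multiple of 4 symbols");
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, n / 4));
    unsigned char *o = RAW(out);
    for (R_xlen_t i = 0; i < n / 4; i++) {
        unsigned b = 0;
        for (int j = 0; j < 4; j++) {
            int c = DNA_CODE[p[4 * i + j]];
            if (c < 0)
                Rf_error("pack_dna(): non-ACGT byte 0x%02x at position %lld",
                         p[4 * i + j], (long long)(4 * i + j + 1));
            b |= (unsigned)c << (2 * j);
        }
        o[i] = (unsigned char)b;
    }
    UNPROTECT(1);
    return out;
}

/* table-driven decode: one 256-entry byte -> 4-symbol lookup */
static uint32_t DNA_LUT[256];
static int lut_ready = 0;

static void build_lut(void) {
    const char sym[4] = {'A', 'C', 'G', 'T'};
    for (int b = 0; b < 256; b++) {
        unsigned char s[4];
        for (int j = 0; j < 4; j++) s[j] = (unsigned char)sym[(b >> (2 * j)) & 3];
        memcpy(&DNA_LUT[b], s, 4);
    }
    lut_ready = 1;
}

SEXP C_unpack_dna(SEXP packed_, SEXP n_symbols_) {
    if (!lut_ready) build_lut();
    const unsigned char *p = RAW(packed_);
    R_xlen_t np = XLENGTH(packed_);
    double nd = Rf_asReal(n_symbols_);
    R_xlen_t n = (R_xlen_t)nd;
    if (n < 0 || n > 4 * np) Rf_error("unpack_dna(): n_symbols exceeds packed data");
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, n));
    unsigned char *o = RAW(out);
    R_xlen_t full = n / 4;
    for (R_xlen_t i = 0; i < full; i++) memcpy(o + 4 * i, &DNA_LUT[p[i]], 4);
    if (n % 4) {
        unsigned char tmp[4];
        memcpy(tmp, &DNA_LUT[p[full]], 4);
        memcpy(o + 4 * full, tmp, n % 4);
    }
    UNPROTECT(1);
    return out;
}

/* bit packing, LSB-first, zero padding */
SEXP C_pack_bits(SEXP bits_) {
    const int *b = LOGICAL(bits_);
    R_xlen_t n = XLENGTH(bits_);
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, (n + 7) / 8));
    unsigned char *o = RAW(out);
    memset(o, 0, XLENGTH(out));
    for (R_xlen_t i = 0; i < n; i++)
        if (b[i] == 1) o[i >> 3] |= (unsigned char)(1u << (i & 7));
    UNPROTECT(1);
    return out;
}

SEXP C_unpack_bits(SEXP bytes_, SEXP nbits_) {
    const unsigned char *p = RAW(bytes_);
    double nd = Rf_asReal(nbits_);
    R_xlen_t n = (R_xlen_t)nd;
    if (n < 0 || n > 8 * XLENGTH(bytes_))
        Rf_error("corrupt metadata: bit count exceeds packed bytes");
    SEXP out = PROTECT(Rf_allocVector(LGLSXP, n));
    int *o = LOGICAL(out);
    for (R_xlen_t i = 0; i < n; i++) o[i] = (p[i >> 3] >> (i & 7)) & 1;
    UNPROTECT(1);
    return out;
}

SEXP C_crc32(SEXP data_) {
    uLong crc = crc32(0L, Z_NULL, 0);
    R_xlen_t n = XLENGTH(data_), off = 0;
    const unsigned char *p = RAW(data_);
    while (off < n) {
        uInt chunk = (n - off > 0x40000000) ? 0x40000000u : (uInt)(n - off);
        crc = crc32(crc, p + off, chunk);
        off += chunk;
    }
    return Rf_ScalarReal((double)crc);
}

/* LEB128 varints over non-negative 32-bit values */
SEXP C_encode_varints(SEXP vals_) {
    const int *v = INTEGER(vals_);
    R_xlen_t n = XLENGTH(vals_);
    unsigned char *buf = (unsigned char *)R_alloc(n * 5 + 1, 1);
    R_xlen_t o = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        if (v[i] == NA_INTEGER || v[i] < 0)
            Rf_error("varint values must be non-negative integers");
        uint32_t x = (uint32_t)v[i];
        while (x >= 0x80) {
            buf[o++] = (unsigned char)(x | 0x80);
            x >>= 7;
        }
        buf[o++] = (unsigned char)x;
    }
    SEXP out = PROTECT(Rf_allocVector(RAWSXP, o));
    memcpy(RAW(out), buf, o);
    UNPROTECT(1);
    return out;
}

SEXP C_decode_varints(SEXP data_) {
    const unsigned char *p = RAW(data_);
    R_xlen_t n = XLENGTH(data_);
    int *buf = (int *)R_alloc(n > 0 ? n : 1, sizeof(int));
    R_xlen_t o = 0, i = 0;
    while (i < n) {
        uint64_t x = 0;
        int shift = 0;
        for (;;) {
            if (i >= n) Rf_error("corrupt metadata: truncated varint");
            unsigned char b = p[i++];
            x |= (uint64_t)(b & 0x7f) << shift;
            if (!(b & 0x80)) break;
            shift += 7;
            if (shift > 31) Rf_error("corrupt metadata: varint overflow");
        }
        if (x > 0x7fffffff) Rf_error("corrupt metadata: varint overflow");
        buf[o++] = (int)x;
    }
    SEXP out = PROTECT(Rf_allocVector(INTSXP, o));
    memcpy(INTEGER(out), buf, o * sizeof(int));
    UNPROTECT(1);
    return out;
}
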