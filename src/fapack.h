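#ifndef FAPACK_H
#define FAPACK_H

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>
#include <string.h>

#define REP8(b) ((uint64_t)0x0101010101010101ULL * (uint64_t)(b))
#define HI8     ((uint64_t)0x8080808080808080ULL)
#define LO7     ((uint64_t)0x7f7f7f7f7f7f7f7fULL)

/* load 8 bytes as a little-endian 64-bit word (byte 0 = least significant) */
static inline uint64_t fp_load64(const unsigned char *p) {
    uint64_t w;
    memcpy(&w, p, 8);
#if defined(__BYTE_ORDER__) && (__BYTE_ORDER__ == __ORDER_BIG_ENDIAN__)
    w = __builtin_bswap64(w);
#endif
    return w;
}

/* exact per-lane zero-byte mask: 0x80 in every lane whose byte is 0x00.
   No cross-lane carries: (x & 0x7f..) + 0x7f.. never overflows a lane. */
static inline uint64_t fp_zero_lanes(uint64_t x) {
    uint64_t y = ((x & LO7) + LO7) | x;
    return ~y & HI8;
}

static inline int fp_word_is_acgt(uint64_t w) {
    uint64_t m = fp_zero_lanes(w ^ REP8('A')) | fp_zero_lanes(w ^ REP8('C')) |
                 fp_zero_lanes(w ^ REP8('G')) | fp_zero_lanes(w ^ REP8('T'));
    return m == HI8;
}

static inline int fp_word_is_nnn(uint64_t w) { return w == REP8('N'); }

/* least index (0..7) of a 0x0A byte, or -1 */
static inline int fp_word_find_eol(uint64_t w) {
    uint64_t m = fp_zero_lanes(w ^ REP8(0x0A));
    if (m == 0) return -1;
    return __builtin_ctzll(m) >> 3;
}

SEXP C_is_acgt_word(SEXP word_);
SEXP C_find_eol_in_word(SEXP word_);
SEXP C_scan_boundary(SEXP tail_);
SEXP C_detect_line_length(SEXP data_, SEXP start_);
SEXP C_classify_segments(SEXP sym_);
SEXP C_extract_case_flags(SEXP sym_);
SEXP C_parse_block(SEXP data_, SEXP in_header_);
SEXP C_unparse_block(SEXP records_, SEXP segments_, SEXP line_length_,
                     SEXP raw_, SEXP dna_, SEXP mix_, SEXP flags_);
SEXP C_pack_dna(SEXP sym_);
SEXP C_unpack_dna(SEXP packed_, SEXP n_symbols_);
SEXP C_pack_bits(SEXP bits_);
SEXP C_unpack_bits(SEXP bytes_, SEXP nbits_);
SEXP C_crc32(SEXP data_);
SEXP C_encode_varints(SEXP vals_);
SEXP C_decode_varints(SEXP data_);
SEXP C_zstd_compress(SEXP data_, SEXP level_, SEXP window_log_, SEXP ldm_);
SEXP C_zstd_decompress(SEXP blob_, SEXP expected_);

#endif
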