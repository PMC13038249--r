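#include "fapack.h"

SEXP C_is_acgt_word(SEXP word_) {
    if (TYPEOF(word_) != RAWSXP || XLENGTH(word_) != 8)
        Rf_error("is_acgt_word() requires exactly 8 bytes");
    uint64_t w = fp_load64(RAW(word_));
    return Rf_ScalarLogical(fp_word_is_acgt(w));
}

SEXP C_find_eol_in_word(SEXP word_) {
    if (TYPEOF(word_) != RAWSXP || XLENGTH(word_) != 8)
        Rf_error("find_eol_in_word() requires exactly 8 bytes");
    uint64_t w = fp_load64(RAW(word_));
    int i = fp_word_find_eol(w);
    return Rf_ScalarInteger(i < 0 ? NA_INTEGER : i + 1); /* 1-based for R */
}

/* scanning right-to-left: TRUE iff a '>' is met before any 0x0A */
SEXP C_scan_boundary(SEXP tail_) {
    const unsigned char *p = RAW(tail_);
    R_xlen_t n = XLENGTH(tail_);
    for (R_xlen_t i = n - 1; i >= 0; i--) {
        if (p[i] == 0x0A) return Rf_ScalarLogical(0);
        if (p[i] == '>')  return Rf_ScalarLogical(1);
    }
    return Rf_ScalarLogical(0);
}

/* line length of the sequence region starting at `start` (0-based offset):
   distance between the first two EOLs when the bytes between them are still
   part of the same sequence run (no intervening header start); with a sole
   EOL, the distance from `start` to it; 0 when no EOL is found. */
int fp_detect_line_length(const unsigned char *p, R_xlen_t n, R_xlen_t start) {
    R_xlen_t e1 = -1;
    for (R_xlen_t i = start; i < n; i++)
        if (p[i] == 0x0A) { e1 = i; break; }
    if (e1 < 0) return 0;
    /* region ends if a header opens right after the first EOL */
    if (e1 + 1 >= n || p[e1 + 1] == '>') return (int)(e1 - start);
    for (R_xlen_t i = e1 + 1; i < n; i++)
        if (p[i] == 0x0A) return (int)(i - e1 - 1);
    return (int)(e1 - start);
}

SEXP C_detect_line_length(SEXP data_, SEXP start_) {
    const unsigned char *p = RAW(data_);
    R_xlen_t n = XLENGTH(data_);
    double s1 = Rf_asReal(start_);
    R_xlen_t start = (R_xlen_t)s1 - 1; /* R callers are 1-based */
    if (start < 0 || start > n)
        Rf_error("start offset out of range");
    return Rf_ScalarInteger(fp_detect_line_length(p, n, start));
}
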