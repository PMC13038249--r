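#include "fapack.h"

/* ---- parse_block -------------------------------------------------------
 *
 * One pass over a raw block turns it into:
 *   - an ordered list of layout records: RAW(byte_length) entries copied
 *     verbatim (headers, non-conforming EOLs) and SEQ(n_symbols, first_span,
 *     n_eols_removed) entries describing EOL-stripped sequence runs;
 *   - typed segments (DNA / NNN / MIX) over the concatenated, uppercased
 *     sequence symbols of the block, DNA and NNN lengths being multiples
 *     of 8 on a fixed 8-byte word grid;
 *   - payload streams (raw bytes, DNA symbols, MIX symbols) and a
 *     lowercase-flag bitmask with one bit per sequence symbol.
 *
 * Invariant: sum(RAW byte_length) + sum(SEQ n_symbols + n_eols_removed)
 * equals the block length, so unparse_block can rebuild it byte-exactly.
 */

#define FP_MAX_BLOCK 1073741824 /* 1 GiB: all counts stay within int range */

#define KIND_RAW 0
#define KIND_SEQ 1
#define SEG_DNA 0
#define SEG_NNN 1
#define SEG_MIX 2

typedef struct {
    int *v;
    R_xlen_t n, cap; /* in ints */
} ivec;

static void ivec_init(ivec *a) {
    a->cap = 64;
    a->n = 0;
    a->v = (int *)R_alloc(a->cap, sizeof(int));
}

static void ivec_push4(ivec *a, int x0, int x1, int x2, int x3) {
    if (a->n + 4 > a->cap) {
        R_xlen_t nc = a->cap * 2;
        a->v = (int *)S_realloc((char *)a->v, nc, a->cap, sizeof(int));
        a->cap = nc;
    }
    a->v[a->n++] = x0;
    a->v[a->n++] = x1;
    a->v[a->n++] = x2;
    a->v[a->n++] = x3;
}

static void ivec_push2(ivec *a, int x0, int x1) {
    if (a->n + 2 > a->cap) {
        R_xlen_t nc = a->cap * 2;
        a->v = (int *)S_realloc((char *)a->v, nc, a->cap, sizeof(int));
        a->cap = nc;
    }
    a->v[a->n++] = x0;
    a->v[a->n++] = x1;
}

/* append a RAW record, merging with an adjacent preceding RAW record */
static void push_raw(ivec *rec, int len) {
    if (rec->n >= 4 && rec->v[rec->n - 4] == KIND_RAW)
        rec->v[rec->n - 3] += len;
    else
        ivec_push4(rec, KIND_RAW, len, 0, 0);
}

int fp_detect_line_length(const unsigned char *p, R_xlen_t n, R_xlen_t start);

/* word-grid segment classification over uppercased, EOL-free symbols */
static void classify(const unsigned char *sym, R_xlen_t n, ivec *segs) {
    int cur_type = -1;
    R_xlen_t cur_len = 0;
    R_xlen_t nwords = n / 8;
    for (R_xlen_t w = 0; w < nwords; w++) {
        uint64_t x = fp_load64(sym + 8 * w);
        int t = fp_word_is_acgt(x) ? SEG_DNA : (fp_word_is_nnn(x) ? SEG_NNN : SEG_MIX);
        if (t == cur_type) {
            cur_len += 8;
        } else {
            if (cur_len > 0) ivec_push2(segs, cur_type, (int)cur_len);
            cur_type = t;
            cur_len = 8;
        }
    }
    R_xlen_t rem = n - 8 * nwords; /* sub-word tail is always MIX */
    if (rem > 0) {
        if (cur_type == SEG_MIX) {
            cur_len += rem;
        } else {
            if (cur_len > 0) ivec_push2(segs, cur_type, (int)cur_len);
            cur_type = SEG_MIX;
            cur_len = rem;
        }
    }
    if (cur_len > 0) ivec_push2(segs, cur_type, (int)cur_len);
}

SEXP C_classify_segments(SEXP sym_) {
    const unsigned char *sym = RAW(sym_);
    R_xlen_t n = XLENGTH(sym_);
    if (n > FP_MAX_BLOCK) Rf_error("input too large");
    ivec segs;
    ivec_init(&segs);
    classify(sym, n, &segs);
    R_xlen_t m = segs.n / 2;
    SEXP out = PROTECT(Rf_allocMatrix(INTSXP, (int)m, 2));
    int *po = INTEGER(out);
    for (R_xlen_t i = 0; i < m; i++) {
        po[i] = segs.v[2 * i];
        po[m + i] = segs.v[2 * i + 1];
    }
    UNPROTECT(1);
    return out;
}

SEXP C_extract_case_flags(SEXP sym_) {
    const unsigned char *p = RAW(sym_);
    R_xlen_t n = XLENGTH(sym_);
    SEXP up = PROTECT(Rf_allocVector(RAWSXP, n));
    SEXP fl = PROTECT(Rf_allocVector(LGLSXP, n));
    unsigned char *u = RAW(up);
    int *f = LOGICAL(fl);
    for (R_xlen_t i = 0; i < n; i++) {
        unsigned char b = p[i];
        int low = (b >= 'a' && b <= 'z');
        u[i] = low ? (unsigned char)(b - 32) : b;
        f[i] = low;
    }
    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, up);
    SET_VECTOR_ELT(out, 1, fl);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, Rf_mkChar("symbols"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("flags"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

SEXP C_parse_block(SEXP data_, SEXP in_header_) {
    const unsigned char *p = RAW(data_);
    R_xlen_t n = XLENGTH(data_);
    if (n == 0) Rf_error("parse_block() requires a non-empty block");
    if (n > FP_MAX_BLOCK) Rf_error("block larger than 1 GiB is not supported");
    int in_header = Rf_asLogical(in_header_);

    unsigned char *sym = (unsigned char *)R_alloc(n, 1);
    unsigned char *orig = (unsigned char *)R_alloc(n, 1); /* pre-uppercase */
    unsigned char *rawp = (unsigned char *)R_alloc(n, 1);
    R_xlen_t nflagbytes = (n + 7) / 8;
    unsigned char *flags = (unsigned char *)R_alloc(nflagbytes, 1);
    memset(flags, 0, nflagbytes);
    R_xlen_t nsym_total = 0, nraw = 0;

    ivec rec, segs;
    ivec_init(&rec);
    ivec_init(&segs);

    R_xlen_t pos = 0;

    /* tail of a header begun in the previous block: RAW through its EOL */
    if (in_header) {
        R_xlen_t e = 0;
        while (e < n && p[e] != 0x0A) e++;
        R_xlen_t end = (e < n) ? e + 1 : n;
        memcpy(rawp + nraw, p, end);
        nraw += end;
        push_raw(&rec, (int)end);
        pos = end;
    }

    /* one line length per block, measured on the first sequence region */
    R_xlen_t q = pos;
    while (q < n && p[q] == '>') { /* q is always at a line start here */
        while (q < n && p[q] != 0x0A) q++;
        if (q < n) q++;
    }
    int L = (q < n) ? fp_detect_line_length(p, n, q) : 0;

    int at_line_start = 1; /* pos follows an EOL (or block start) */
    while (pos < n) {
        if (at_line_start && p[pos] == '>') {
            /* header line, RAW including its trailing EOL */
            R_xlen_t st = pos;
            while (pos < n && p[pos] != 0x0A) pos++;
            if (pos < n) pos++;
            memcpy(rawp + nraw, p + st, pos - st);
            nraw += pos - st;
            push_raw(&rec, (int)(pos - st));
            continue;
        }
        /* sequence run */
        R_xlen_t nsyms = 0, phase = 0;
        int first_span = 0, k = 0;
        int open = 1, pending_eol = 0;
        while (pos < n && open) {
            unsigned char b = p[pos];
            if (b == 0x0A) {
                int conform = (L > 0) &&
                              ((k == 0 && phase <= (R_xlen_t)L) ||
                               (k > 0 && phase == (R_xlen_t)L));
                if (conform) {
                    if (k == 0) first_span = (int)phase;
                    k++;
                    phase = 0;
                    pos++;
                    at_line_start = 1;
                    if (pos >= n || p[pos] == '>') open = 0;
                } else {
                    /* inconsistent wrap: keep this EOL verbatim */
                    open = 0;
                    pending_eol = 1;
                }
            } else {
                int low = (b >= 'a' && b <= 'z');
                if (low) flags[nsym_total >> 3] |= (unsigned char)(1u << (nsym_total & 7));
                orig[nsym_total] = b;
                sym[nsym_total++] = low ? (unsigned char)(b - 32) : b;
                nsyms++;
                phase++;
                pos++;
                at_line_start = 0;
            }
        }
        if (nsyms > 0 || k > 0)
            ivec_push4(&rec, KIND_SEQ, (int)nsyms, first_span, k);
        if (pending_eol) {
            rawp[nraw++] = 0x0A;
            push_raw(&rec, 1);
            pos++;
            at_line_start = 1;
        }
    }

    classify(sym, nsym_total, &segs);

    /* MIX keeps its original case verbatim; case flags are meaningful only
       at DNA/NNN positions, so clear the bits under MIX segments (keeps
       the flag stream near-zero entropy on non-FASTA input) */
    {
        R_xlen_t off = 0, msegs = segs.n / 2;
        for (R_xlen_t i = 0; i < msegs; i++) {
            int len = segs.v[2 * i + 1];
            if (segs.v[2 * i] == SEG_MIX)
                for (R_xlen_t b = off; b < off + len; b++)
                    flags[b >> 3] &= (unsigned char)~(1u << (b & 7));
            off += len;
        }
    }

    /* split symbols into per-type payloads */
    R_xlen_t ndna = 0, nmix = 0, m = segs.n / 2;
    for (R_xlen_t i = 0; i < m; i++) {
        if (segs.v[2 * i] == SEG_DNA) ndna += segs.v[2 * i + 1];
        else if (segs.v[2 * i] == SEG_MIX) nmix += segs.v[2 * i + 1];
    }
    SEXP dna = PROTECT(Rf_allocVector(RAWSXP, ndna));
    SEXP mix = PROTECT(Rf_allocVector(RAWSXP, nmix));
    {
        unsigned char *pd = RAW(dna), *pm = RAW(mix);
        R_xlen_t off = 0;
        for (R_xlen_t i = 0; i < m; i++) {
            int t = segs.v[2 * i], len = segs.v[2 * i + 1];
            if (t == SEG_DNA) {
                memcpy(pd, sym + off, len);
                pd += len;
            } else if (t == SEG_MIX) {
                memcpy(pm, orig + off, len);
                pm += len;
            }
            off += len;
        }
    }

    R_xlen_t krec = rec.n / 4;
    SEXP records = PROTECT(Rf_allocMatrix(INTSXP, (int)krec, 4));
    int *pr = INTEGER(records);
    for (R_xlen_t i = 0; i < krec; i++)
        for (int j = 0; j < 4; j++) pr[j * krec + i] = rec.v[4 * i + j];

    SEXP segments = PROTECT(Rf_allocMatrix(INTSXP, (int)m, 2));
    int *ps = INTEGER(segments);
    for (R_xlen_t i = 0; i < m; i++) {
        ps[i] = segs.v[2 * i];
        ps[m + i] = segs.v[2 * i + 1];
    }

    SEXP rawpay = PROTECT(Rf_allocVector(RAWSXP, nraw));
    memcpy(RAW(rawpay), rawp, nraw);
    R_xlen_t nfb = (nsym_total + 7) / 8;
    SEXP flagpay = PROTECT(Rf_allocVector(RAWSXP, nfb));
    memcpy(RAW(flagpay), flags, nfb);

    const char *names[] = {"records",  "segments",    "line_length", "raw_payload",
                           "dna_payload", "mix_payload", "case_flags", "n_symbols", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, names));
    SET_VECTOR_ELT(out, 0, records);
    SET_VECTOR_ELT(out, 1, segments);
    SET_VECTOR_ELT(out, 2, Rf_ScalarInteger(L));
    SET_VECTOR_ELT(out, 3, rawpay);
    SET_VECTOR_ELT(out, 4, dna);
    SET_VECTOR_ELT(out, 5, mix);
    SET_VECTOR_ELT(out, 6, flagpay);
    SET_VECTOR_ELT(out, 7, Rf_ScalarInteger((int)nsym_total));
    UNPROTECT(7);
    return out;
}

/* ---- unparse_block: exact inverse -------------------------------------- */

SEXP C_unparse_block(SEXP records_, SEXP segments_, SEXP line_length_,
                     SEXP raw_, SEXP dna_, SEXP mix_, SEXP flags_) {
    int *rec = INTEGER(records_);
    R_xlen_t krec = Rf_nrows(records_);
    int *seg = INTEGER(segments_);
    R_xlen_t m = Rf_nrows(segments_);
    int L = Rf_asInteger(line_length_);
    const unsigned char *rawp = RAW(raw_), *dnap = RAW(dna_), *mixp = RAW(mix_);
    const unsigned char *flags = RAW(flags_);
    R_xlen_t nraw = XLENGTH(raw_), ndna = XLENGTH(dna_), nmix = XLENGTH(mix_);
    R_xlen_t nflagbits = 8 * XLENGTH(flags_);

    int64_t outlen = 0;
    for (R_xlen_t i = 0; i < krec; i++) {
        int kind = rec[i], a = rec[krec + i], c = rec[3 * krec + i];
        if (a < 0 || c < 0) Rf_error("corrupt block metadata: negative length");
        outlen += (kind == KIND_RAW) ? a : (int64_t)a + c;
    }
    if (outlen > FP_MAX_BLOCK) Rf_error("corrupt block metadata: block too large");

    SEXP out = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)outlen));
    unsigned char *o = RAW(out);
    R_xlen_t oo = 0, ri = 0, di = 0, mi = 0, fbit = 0;
    R_xlen_t seg_i = 0, seg_off = 0;

    for (R_xlen_t i = 0; i < krec; i++) {
        int kind = rec[i], a = rec[krec + i], fs = rec[2 * krec + i], k = rec[3 * krec + i];
        if (kind == KIND_RAW) {
            if (ri + a > nraw) Rf_error("corrupt block metadata: raw stream exhausted");
            memcpy(o + oo, rawp + ri, a);
            ri += a;
            oo += a;
            continue;
        }
        /* SEQ record */
        if (k > 1 && L < 1)
            Rf_error("corrupt block metadata: multiple EOLs with zero line length");
        if (k > 0 && (fs < 0 || (int64_t)fs + (int64_t)(k - 1) * L > a))
            Rf_error("corrupt block metadata: EOL phase exceeds record symbols");
        int emitted = 0;
        for (int s = 0; s <= a; s++) {
            while (emitted < k && (int64_t)s == (int64_t)fs + (int64_t)emitted * L) {
                o[oo++] = 0x0A;
                emitted++;
            }
            if (s == a) break;
            if (seg_off == (seg_i < m ? seg[m + seg_i] : -1)) {
                seg_i++;
                seg_off = 0;
            }
            while (seg_i < m && seg[m + seg_i] == 0) seg_i++;
            if (seg_i >= m) Rf_error("corrupt block metadata: segment stream exhausted");
            unsigned char ch;
            switch (seg[seg_i]) {
            case SEG_DNA:
                if (di >= ndna) Rf_error("corrupt block metadata: DNA stream exhausted");
                ch = dnap[di++];
                break;
            case SEG_NNN:
                ch = 'N';
                break;
            default:
                if (mi >= nmix) Rf_error("corrupt block metadata: MIX stream exhausted");
                ch = mixp[mi++];
                break;
            }
            seg_off++;
            if (fbit >= nflagbits) Rf_error("corrupt block metadata: case-flag stream exhausted");
            if (flags[fbit >> 3] & (1u << (fbit & 7)))
                if (ch >= 'A' && ch <= 'Z') ch |= 0x20;
            fbit++;
            o[oo++] = ch;
        }
        if (emitted != k) Rf_error("corrupt block metadata: EOL count mismatch");
    }
    int64_t total_seg = 0;
    for (R_xlen_t i = 0; i < m; i++) total_seg += seg[m + i];
    if (ri != nraw || di != ndna || mi != nmix || fbit != total_seg)
        Rf_error("corrupt block metadata: unconsumed payload bytes");
    UNPROTECT(1);
    return out;
}
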