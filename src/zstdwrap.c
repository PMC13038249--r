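#include "fapack.h"
#include <zstd.h>

/* Backend compression: standard zstd frames with the content-size field
   set, so third-party tooling can inspect individual streams. Level,
   window log and long-distance matching come from the backend profile. */

SEXP C_zstd_compress(SEXP data_, SEXP level_, SEXP window_log_, SEXP ldm_) {
    const unsigned char *p = RAW(data_);
    size_t n = (size_t)XLENGTH(data_);
    int level = Rf_asInteger(level_);
    int wlog = Rf_asInteger(window_log_);
    int ldm = Rf_asLogical(ldm_);

    ZSTD_CCtx *cctx = ZSTD_createCCtx();
    if (!cctx) Rf_error("zstd: cannot create compression context");
    ZSTD_CCtx_setParameter(cctx, ZSTD_c_compressionLevel, level);
    ZSTD_CCtx_setParameter(cctx, ZSTD_c_contentSizeFlag, 1);
    if (ldm) ZSTD_CCtx_setParameter(cctx, ZSTD_c_enableLongDistanceMatching, 1);
    if (wlog > 0) ZSTD_CCtx_setParameter(cctx, ZSTD_c_windowLog, wlog);

    size_t cap = ZSTD_compressBound(n);
    unsigned char *buf = (unsigned char *)R_alloc(cap, 1);
    size_t r = ZSTD_compress2(cctx, buf, cap, p, n);
    ZSTD_freeCCtx(cctx);
    if (ZSTD_isError(r)) Rf_error("zstd compression failed: %s", ZSTD_getErrorName(r));

    SEXP out = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)r));
    memcpy(RAW(out), buf, r);
    UNPROTECT(1);
    return out;
}

SEXP C_zstd_decompress(SEXP blob_, SEXP expected_) {
    const unsigned char *p = RAW(blob_);
    size_t n = (size_t)XLENGTH(blob_);
    double ed = Rf_asReal(expected_);
    if (ed < 0 || ed > 1e15) Rf_error("invalid expected size");
    size_t expected = (size_t)ed;

    unsigned long long fsize = ZSTD_getFrameContentSize(p, n);
    if (fsize == ZSTD_CONTENTSIZE_ERROR)
        Rf_error("archive corruption: not a zstd frame");
    if (fsize != ZSTD_CONTENTSIZE_UNKNOWN && fsize != expected)
        Rf_error("archive corruption: frame size %llu, expected %llu", fsize,
                 (unsigned long long)expected);

    SEXP out = PROTECT(Rf_allocVector(RAWSXP, (R_xlen_t)expected));
    size_t r = ZSTD_decompress(RAW(out), expected, p, n);
    if (ZSTD_isError(r))
        Rf_error("archive corruption: %s", ZSTD_getErrorName(r));
    if (r != expected)
        Rf_error("archive corruption: decompressed %llu bytes, expected %llu",
                 (unsigned long long)r, (unsigned long long)expected);
    UNPROTECT(1);
    return out;
}
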