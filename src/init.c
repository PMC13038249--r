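#include "fapack.h"
#include <R_ext/Rdynload.h>

#define CALLDEF(name, n) {#name, (DL_FUNC)&name, n}

static const R_CallMethodDef CallEntries[] = {
    CALLDEF(C_is_acgt_word, 1),
    CALLDEF(C_find_eol_in_word, 1),
    CALLDEF(C_scan_boundary, 1),
    CALLDEF(C_detect_line_length, 2),
    CALLDEF(C_classify_segments, 1),
    CALLDEF(C_extract_case_flags, 1),
    CALLDEF(C_parse_block, 2),
    CALLDEF(C_unparse_block, 7),
    CALLDEF(C_pack_dna, 1),
    CALLDEF(C_unpack_dna, 2),
    CALLDEF(C_pack_bits, 1),
    CALLDEF(C_unpack_bits, 2),
    CALLDEF(C_crc32, 1),
    CALLDEF(C_encode_varints, 1),
    CALLDEF(C_decode_varints, 1),
    CALLDEF(C_zstd_compress, 4),
    CALLDEF(C_zstd_decompress, 2),
    {NULL, NULL, 0}};

void R_init_fastapack(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
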