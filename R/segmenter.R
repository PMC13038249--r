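# Block segmenter: turns one raw input block (plus its boundary context)
# into an ordered layout of RAW/SEQ records, typed DNA/NNN/MIX segments,
# uppercased symbol payloads and a lowercase-flag bitmask -- and inverts
# that parse byte-exactly.
#
# Byte conventions: ASCII, EOL is 0x0A (LF) only, header sentinel '>'.
# 0x0D (CR) is never treated as EOL; CRLF input keeps its CR bytes as
# ordinary (MIX) symbols and still round-trips.

SEG_TYPES <- c("DNA", "NNN", "MIX")
REC_KINDS <- c("RAW", "SEQ")

#' Word-parallel 8-byte classification primitives
#'
#' `is_acgt_word()` reports whether all 8 bytes of a word are one of the
#' uppercase nucleotides `A`, `C`, `G`, `T`; `find_eol_in_word()` returns
#' the position of the first EOL byte (0x0A) in the word. Both operate on
#' a single 64-bit word with a constant number of bitwise operations
#' (SIMD-within-a-register), the trick that makes block classification
#' run at memory speed. They are exposed so their word-parallel results
#' can be checked against naive per-byte scans.
#'
#' @param word Raw vector of exactly 8 bytes.
#' @return `is_acgt_word()`: a logical scalar. `find_eol_in_word()`: the
#'   1-based index of the first 0x0A byte, or `NA_integer_` if absent.
#' @examples
#' is_acgt_word(charToRaw("ACGTACGT"))
#' is_acgt_word(charToRaw("ACGTNCGT"))
#' find_eol_in_word(charToRaw("AC\nGTACG"))
#' @export
is_acgt_word <- function(word) {
  stopifnot(is.raw(word), length(word) == 8L)
  .Call(C_is_acgt_word, word)
}

#' @rdname is_acgt_word
#' @export
find_eol_in_word <- function(word) {
  stopifnot(is.raw(word), length(word) == 8L)
  .Call(C_find_eol_in_word, word)
}

#' Does a block start inside a header line?
#'
#' Scans the tail of the previous block right-to-left. If a `>` byte is
#' met before any EOL, the next block begins inside a header line whose
#' remainder must be copied verbatim. If neither byte occurs in the
#' previous block at all, the context falls back to `FALSE`: a header
#' line longer than a whole block degrades to ordinary content, which is
#' still reconstructed losslessly. The scan is capped at one block.
#'
#' @param prev_tail Raw vector: byte suffix (up to one full block) of the
#'   preceding block; use `raw(0)` for the first block.
#' @return Logical scalar: `TRUE` iff the following block starts inside a
#'   header line.
#' @examples
#' scan_boundary_context(charToRaw(">chr1 some description"))
#' scan_boundary_context(charToRaw(">chr1\nACGTACGT"))
#' @export
scan_boundary_context <- function(prev_tail) {
  stopifnot(is.raw(prev_tail))
  .Call(C_scan_boundary, prev_tail)
}

#' Detect the line length of a block's first sequence region
#'
#' The per-block line length is the distance between the first two EOL
#' characters of the first sequence region (both bordering sequence
#' data); with a sole EOL it is the distance from `start` to that EOL,
#' and 0 when the region contains no EOL (no EOL removal for the block).
#'
#' @param block Raw vector of block bytes.
#' @param start 1-based offset of the first sequence byte.
#' @return Integer line length (0 means no EOL removal).
#' @examples
#' detect_line_length(charToRaw("ACGT\nACGT\nAC\n"), 1)
#' detect_line_length(charToRaw("ACGTACGT"), 1)
#' @export
detect_line_length <- function(block, start = 1L) {
  stopifnot(is.raw(block))
  .Call(C_detect_line_length, block, as.numeric(start))
}

#' Uppercase sequence symbols and extract case flags
#'
#' Soft-masked (lowercase) letters are uppercased and remembered as one
#' flag per symbol so the original case can be restored exactly,
#' including lowercase `n` runs. Non-letter bytes pass through with a
#' zero flag.
#'
#' @param symbols Raw vector of sequence bytes (no EOLs).
#' @return List with `symbols` (uppercased raw vector, same length) and
#'   `flags` (logical vector, `TRUE` where the original was lowercase).
#' @examples
#' extract_case_flags(charToRaw("acgTN"))
#' @export
extract_case_flags <- function(symbols) {
  stopifnot(is.raw(symbols))
  .Call(C_extract_case_flags, symbols)
}

#' Partition uppercased symbols into DNA / NNN / MIX segments
#'
#' Greedy left-to-right scan in 8-byte words on a fixed word grid: a
#' maximal run of ACGT-only words becomes a DNA segment, a maximal run
#' of all-`N` words an NNN segment, and everything else -- including
#' sub-word remainders at run boundaries and the tail -- coalesces into
#' MIX segments. DNA and NNN lengths are therefore always multiples of
#' 8; segment lengths sum to `length(symbols)`.
#'
#' @param symbols Raw vector of uppercased, EOL-free sequence bytes.
#' @return Data frame with columns `type` (`"DNA"`, `"NNN"`, `"MIX"`)
#'   and `length` (integer).
#' @examples
#' classify_segments(charToRaw(strrep("A", 13)))
#' classify_segments(charToRaw("ACGTRYKM"))
#' @export
classify_segments <- function(symbols) {
  stopifnot(is.raw(symbols))
  m <- .Call(C_classify_segments, symbols)
  data.frame(type = SEG_TYPES[m[, 1L] + 1L], length = m[, 2L])
}

#' Parse one raw block into its typed layout
#'
#' The core analysis step of the compressor. Header lines (a `>` at a
#' line start, plus the remainder of a header begun in the previous
#' block) become RAW records copied verbatim including their EOLs.
#' Sequence bytes are uppercased with case flags extracted; EOLs at
#' positions conforming to the block's detected line length are removed
#' and counted per SEQ record, while non-conforming EOLs (a changed wrap
#' width, short middle lines) terminate the record and are kept verbatim
#' in a RAW record. The concatenated sequence symbols are classified
#' into DNA/NNN/MIX segments. Any byte content parses; non-FASTA input
#' degenerates to MIX/RAW and still round-trips.
#'
#' The flag bitmask keeps one bit per sequence symbol, but bits are set
#' only under DNA and NNN segments: MIX payload is stored in its
#' original case (its bits are zero), so arbitrary binary content adds
#' no flag entropy while soft-masked DNA and `n`-runs still restore
#' exactly.
#'
#' @param data Raw vector, the block's bytes (non-empty).
#' @param starts_in_header Logical, from [scan_boundary_context()];
#'   `FALSE` for the first block.
#' @return An object of class `fa_parsed_block`: a list with `records`
#'   (integer matrix: kind 0=RAW/1=SEQ, n_bytes/n_symbols, first_span,
#'   n_eols_removed), `segments` (integer matrix: type 0/1/2, length),
#'   `line_length`, `raw_payload`, `dna_payload`, `mix_payload`,
#'   `case_flags` (bit-packed raw, LSB-first) and `n_symbols`.
#' @seealso [unparse_block()] for the exact inverse.
#' @examples
#' p <- parse_block(charToRaw(">s\nACGTACGT\nACGTACGT\n"))
#' p$line_length
#' identical(unparse_block(p), charToRaw(">s\nACGTACGT\nACGTACGT\n"))
#' @export
parse_block <- function(data, starts_in_header = FALSE) {
  stopifnot(is.raw(data), length(data) > 0L, is.logical(starts_in_header))
  p <- .Call(C_parse_block, data, starts_in_header)
  class(p) <- "fa_parsed_block"
  p
}

#' Reconstruct a block's original bytes from its parsed layout
#'
#' Replays the layout records in order: RAW records copy verbatim bytes;
#' SEQ records emit symbols drawn from the DNA/NNN/MIX payloads in
#' segment order, restore lowercase from the case flags, and re-insert
#' an EOL after `first_span` symbols and then after every `line_length`
#' symbols until `n_eols_removed` EOLs have been emitted.
#'
#' @param parsed An `fa_parsed_block`, or any list with the same fields
#'   (as reassembled from a decoded archive block).
#' @return Raw vector: exactly the original block bytes.
#' @export
unparse_block <- function(parsed) {
  .Call(
    C_unparse_block, parsed$records, parsed$segments,
    parsed$line_length, parsed$raw_payload, parsed$dna_payload,
    parsed$mix_payload, parsed$case_flags
  )
}

#' @export
print.fa_parsed_block <- function(x, ...) {
  k <- nrow(x$records)
  cat(
    "<fa_parsed_block> ", k, " record(s), ", nrow(x$segments),
    " segment(s), line_length=", x$line_length,
    ", symbols=", x$n_symbols, "\n",
    sep = ""
  )
  invisible(x)
}
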