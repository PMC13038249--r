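# Bit-level codecs for the typed streams: 2-bit DNA packing, LSB-first
# bit packing for case flags, and the run-length representation of
# N-runs (lengths only, zero payload bytes).

#' Pack DNA symbols at two bits per base
#'
#' Code assignment is alphabetical (`A`=0, `C`=1, `G`=2, `T`=3); symbol
#' `j` occupies bits `2*(j %% 4)` of byte `j %/% 4`, i.e. the first
#' symbol of each group sits in the least-significant bits. Segment
#' lengths being multiples of 8 guarantees whole output bytes in the
#' pipeline.
#'
#' @param symbols Raw vector over exactly `A`,`C`,`G`,`T`; length a
#'   multiple of 4.
#' @return Raw vector of `length(symbols)/4` packed bytes.
#' @examples
#' pack_dna(charToRaw("ACGT")) # 0xe4
#' @export
pack_dna <- function(symbols) {
  stopifnot(is.raw(symbols))
  .Call(C_pack_dna, symbols)
}

#' Unpack 2-bit packed DNA
#'
#' Table-driven inverse of [pack_dna()]: a 256-entry byte-to-4-symbol
#' lookup expands packed bytes back to `ACGT` characters.
#'
#' @param packed Raw vector produced by [pack_dna()].
#' @param n_symbols Number of symbols to emit (at most `4 * length(packed)`).
#' @return Raw vector of `n_symbols` nucleotide bytes.
#' @examples
#' rawToChar(unpack_dna(as.raw(0xe4), 4))
#' @export
unpack_dna <- function(packed, n_symbols) {
  stopifnot(is.raw(packed))
  .Call(C_unpack_dna, packed, as.numeric(n_symbols))
}

#' Pack and unpack bit flags
#'
#' LSB-first: bit `i` maps to bit `i %% 8` of byte `i %/% 8`; padding
#' bits are zero. Used for the per-symbol lowercase (soft-masking)
#' flags, padded to a whole byte per block.
#'
#' @param flags Logical vector.
#' @param bytes Raw vector of packed bits.
#' @param n_bits Number of bits to recover; must not exceed
#'   `8 * length(bytes)`.
#' @return `pack_bits()`: a raw vector of `ceiling(length(flags)/8)`
#'   bytes. `unpack_bits()`: a logical vector of length `n_bits`.
#' @examples
#' pack_bits(c(TRUE, rep(FALSE, 7))) # 0x01
#' unpack_bits(as.raw(0x01), 1)
#' @export
pack_bits <- function(flags) {
  stopifnot(is.logical(flags), !anyNA(flags))
  .Call(C_pack_bits, flags)
}

#' @rdname pack_bits
#' @export
unpack_bits <- function(bytes, n_bits) {
  stopifnot(is.raw(bytes))
  .Call(C_unpack_bits, bytes, as.numeric(n_bits))
}

#' Run-length representation of N-runs
#'
#' NNN segments carry no payload bytes at all: only their lengths are
#' kept (one entry per NNN segment, in segment order), and decoding
#' re-emits the `N` bytes. Lengths are positive multiples of 8 by
#' construction of the segmenter's word grid.
#'
#' @param segments A segment table: either the integer matrix of an
#'   `fa_parsed_block` or the data frame from [classify_segments()].
#' @param lengths Integer vector of N-run lengths.
#' @return `encode_nnn()`: integer vector of NNN segment lengths.
#'   `decode_nnn()`: raw vector of `sum(lengths)` `N` bytes.
#' @examples
#' decode_nnn(16)
#' @export
encode_nnn <- function(segments) {
  if (is.data.frame(segments)) {
    lens <- segments$length[segments$type == "NNN"]
  } else {
    lens <- segments[segments[, 1L] == 1L, 2L]
  }
  lens <- as.integer(lens)
  if (any(lens <= 0L) || any(lens %% 8L != 0L)) {
    stop("corrupt metadata: NNN lengths must be positive multiples of 8")
  }
  lens
}

#' @rdname encode_nnn
#' @export
decode_nnn <- function(lengths) {
  lengths <- as.integer(lengths)
  if (any(lengths <= 0L) || any(lengths %% 8L != 0L)) {
    stop("corrupt metadata: NNN lengths must be positive multiples of 8")
  }
  rep(as.raw(78L), sum(lengths)) # 'N'
}
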