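# Naive per-byte oracles and generators shared across test files.
# The oracles deliberately avoid the package's word-parallel code paths.

ACGT_INTS <- as.integer(charToRaw("ACGT"))

naive_is_acgt_word <- function(w) {
  all(as.integer(w) %in% ACGT_INTS)
}

naive_find_eol_in_word <- function(w) {
  i <- which(w == as.raw(10L))
  if (length(i)) i[[1L]] else NA_integer_
}

# deterministic random bytes without touching the session RNG state
rand_bytes <- function(n, seed) {
  fastapack:::with_seed(seed, as.raw(sample.int(256L, n, replace = TRUE) - 1L))
}

# words over the adversarial alphabet {A,C,G,T,N,a,0x0A,0x00}
word_alphabet <- as.raw(c(65L, 67L, 71L, 84L, 78L, 97L, 10L, 0L))

rand_words <- function(n_words, seed, alphabet = NULL) {
  fastapack:::with_seed(seed, {
    if (is.null(alphabet)) {
      as.raw(sample.int(256L, 8L * n_words, replace = TRUE) - 1L)
    } else {
      alphabet[sample.int(length(alphabet), 8L * n_words, replace = TRUE)]
    }
  })
}

# independent byte-level reconstruction of a parsed block, written in
# plain R against the documented layout semantics (never calls the
# package's unparse path)
oracle_reconstruct <- function(p) {
  seg <- p$segments
  sym <- raw(0)
  di <- 1L
  mi <- 1L
  for (i in seq_len(nrow(seg))) {
    len <- seg[i, 2L]
    sym <- c(sym, switch(seg[i, 1L] + 1L,
      {
        s <- p$dna_payload[seq.int(di, length.out = len)]
        di <- di + len
        s
      },
      rep(charToRaw("N"), len),
      {
        s <- p$mix_payload[seq.int(mi, length.out = len)]
        mi <- mi + len
        s
      }
    ))
  }
  nbits <- length(sym)
  flag <- if (nbits > 0) as.logical(rawToBits(p$case_flags))[seq_len(nbits)] else logical(0)
  upper <- sym >= as.raw(65) & sym <= as.raw(90)
  low <- flag & upper
  if (any(low)) sym[low] <- as.raw(bitwOr(as.integer(sym[low]), 32L))

  out <- raw(0)
  ri <- 1L
  si <- 1L
  L <- p$line_length
  rec <- p$records
  for (i in seq_len(nrow(rec))) {
    if (rec[i, 1L] == 0L) { # RAW
      len <- rec[i, 2L]
      out <- c(out, p$raw_payload[seq.int(ri, length.out = len)])
      ri <- ri + len
    } else { # SEQ
      nsym <- rec[i, 2L]
      fs <- rec[i, 3L]
      k <- rec[i, 4L]
      body <- if (nsym > 0) sym[seq.int(si, length.out = nsym)] else raw(0)
      si <- si + nsym
      eol_after <- if (k > 0) fs + (seq_len(k) - 1L) * L else integer(0)
      piece <- raw(0)
      prev <- 0L
      for (e in eol_after) {
        if (e > prev) piece <- c(piece, body[seq.int(prev + 1L, e)])
        piece <- c(piece, as.raw(10L))
        prev <- e
      }
      if (nsym > prev) piece <- c(piece, body[seq.int(prev + 1L, nsym)])
      out <- c(out, piece)
    }
  }
  out
}

# conservation + word-grid structural checks on one parsed block
check_block_structure <- function(p, n_bytes) {
  rec <- p$records
  raw_bytes <- sum(rec[rec[, 1L] == 0L, 2L])
  seq_bytes <- sum(rec[rec[, 1L] == 1L, 2L] + rec[rec[, 1L] == 1L, 4L])
  seg <- p$segments
  dna_nnn <- seg[seg[, 1L] != 2L, 2L]
  list(
    conserved = (raw_bytes + seq_bytes) == n_bytes,
    grid = all(dna_nnn %% 8L == 0L),
    dna_alphabet = all(as.integer(p$dna_payload) %in% ACGT_INTS),
    symbols = sum(seg[, 2L]) == p$n_symbols
  )
}

expect_roundtrip <- function(x, config = pipeline_config()) {
  s <- fa_compress(x, config = config)
  expect_identical(fa_decompress(s$archive)$data, x)
  invisible(s)
}
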