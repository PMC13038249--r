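test_that("word classifiers follow their contracts on fixed examples", {
  expect_true(is_acgt_word(charToRaw("ACGTACGT")))
  expect_false(is_acgt_word(charToRaw("ACGTNCGT")))
  expect_false(is_acgt_word(charToRaw("acgtacgt"))) # lowercase is non-ACGT
  expect_error(is_acgt_word(charToRaw("ACGT")))

  expect_identical(find_eol_in_word(charToRaw("AC\nGTACG")), 3L)
  expect_identical(find_eol_in_word(charToRaw("ACGTACGT")), NA_integer_)
  expect_identical(find_eol_in_word(as.raw(rep(10L, 8L))), 1L) # first match wins
})

test_that("word classifiers agree with naive per-byte oracles", {
  n <- 20000L
  for (alpha in list(NULL, word_alphabet)) {
    words <- rand_words(n, seed = if (is.null(alpha)) 101L else 102L, alpha)
    m <- matrix(words, nrow = 8L)
    got_acgt <- logical(n)
    want_acgt <- logical(n)
    got_eol <- integer(n)
    want_eol <- integer(n)
    for (i in seq_len(n)) {
      w <- m[, i]
      got_acgt[i] <- is_acgt_word(w)
      want_acgt[i] <- naive_is_acgt_word(w)
      got_eol[i] <- find_eol_in_word(w)
      want_eol[i] <- naive_find_eol_in_word(w)
    }
    expect_identical(got_acgt, want_acgt)
    expect_identical(got_eol, want_eol)
  }
})

test_that("boundary context scan finds '>' before EOL, with total fallbacks", {
  expect_true(scan_boundary_context(charToRaw(">chr1 some description")))
  expect_false(scan_boundary_context(charToRaw(">chr1\nACGTACGT")))
  expect_false(scan_boundary_context(charToRaw("ACGTACGT"))) # neither found
  expect_false(scan_boundary_context(raw(0)))
  # a mid-content '>' with no later EOL still flags header context
  expect_true(scan_boundary_context(charToRaw("AC\nGT>partial head")))
})

test_that("line length is the distance between successive sequence EOLs", {
  expect_identical(detect_line_length(charToRaw("ACGT\nACGT\nAC\n")), 4L)
  expect_identical(detect_line_length(charToRaw("ACGTACGT")), 0L)
  # block beginning mid-line: the second gap defines the width
  expect_identical(detect_line_length(charToRaw("GT\nACGT\nACGT\n")), 4L)
  # sole EOL: distance from start
  expect_identical(detect_line_length(charToRaw("ACGTA\n")), 5L)
  # region ends at a header: only the first gap counts
  expect_identical(detect_line_length(charToRaw("ACG\n>h\nACGTACGT\n")), 3L)
})

test_that("case extraction uppercases and flags exactly", {
  r <- extract_case_flags(charToRaw("acgTN"))
  expect_identical(r$symbols, charToRaw("ACGTN"))
  expect_identical(r$flags, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  r <- extract_case_flags(charToRaw("ACGT"))
  expect_identical(r$symbols, charToRaw("ACGT"))
  expect_false(any(r$flags))
  r <- extract_case_flags(charToRaw("nnnn")) # soft-masked N-run
  expect_identical(r$symbols, charToRaw("NNNN"))
  expect_true(all(r$flags))
  # non-letters map to themselves with a zero flag
  r <- extract_case_flags(as.raw(c(0x00, 0x3e, 0x7a)))
  expect_identical(r$symbols, as.raw(c(0x00, 0x3e, 0x5a)))
  expect_identical(r$flags, c(FALSE, FALSE, TRUE))
})

test_that("segment classification rounds DNA/NNN down to the 8-byte grid", {
  s <- classify_segments(charToRaw(paste0(strrep("A", 16), strrep("N", 16))))
  expect_identical(s$type, c("DNA", "NNN"))
  expect_identical(s$length, c(16L, 16L))

  s <- classify_segments(charToRaw(strrep("A", 13)))
  expect_identical(s$type, c("DNA", "MIX"))
  expect_identical(s$length, c(8L, 5L))

  # IUPAC ambiguity codes are neither ACGT-only nor N-only
  s <- classify_segments(charToRaw("ACGTRYKM"))
  expect_identical(s$type, "MIX")
  expect_identical(s$length, 8L)

  # adjacent MIX runs merge
  s <- classify_segments(charToRaw(paste0("ACGTRYKM", "NNNNNNNR", strrep("C", 8))))
  expect_identical(s$type, c("MIX", "DNA"))
  expect_identical(s$length, c(16L, 8L))
})

test_that("parse_block produces the documented layout on FASTA examples", {
  p <- parse_block(charToRaw(">s\nACGTACGT\nACGTACGT\n"))
  expect_identical(p$records, matrix(c(0L, 3L, 0L, 0L, 1L, 16L, 8L, 2L),
    nrow = 2, byrow = TRUE
  ))
  expect_identical(p$segments, matrix(c(0L, 16L), nrow = 1))
  expect_identical(p$line_length, 8L)
  expect_identical(unparse_block(p), charToRaw(">s\nACGTACGT\nACGTACGT\n"))
  expect_identical(oracle_reconstruct(p), charToRaw(">s\nACGTACGT\nACGTACGT\n"))

  # single short line: L inferred from the sole EOL
  p <- parse_block(charToRaw(">s\nACGTA\n"))
  expect_identical(p$records, matrix(c(0L, 3L, 0L, 0L, 1L, 5L, 5L, 1L),
    nrow = 2, byrow = TRUE
  ))
  expect_identical(p$segments, matrix(c(2L, 5L), nrow = 1))
  expect_identical(p$line_length, 5L)
  expect_identical(oracle_reconstruct(p), charToRaw(">s\nACGTA\n"))

  # non-FASTA bytes degenerate to one MIX-covered SEQ record
  x <- as.raw((17L * seq_len(256L)) %% 256L)
  x <- x[x != as.raw(10L) & x != as.raw(62L)]
  p <- parse_block(x)
  expect_identical(p$records[, 1L], 1L)
  expect_identical(sum(p$segments[p$segments[, 1] == 2L, 2L]), length(x))
  expect_identical(unparse_block(p), x)
})

test_that("a header begun in the previous block is copied raw to its EOL", {
  p <- parse_block(charToRaw("der tail\nACGTACGT\n"), starts_in_header = TRUE)
  expect_identical(p$records[1L, ], c(0L, 9L, 0L, 0L))
  expect_identical(unparse_block(p), charToRaw("der tail\nACGTACGT\n"))
  # no EOL at all: the whole block is one RAW record
  p <- parse_block(charToRaw("still header"), starts_in_header = TRUE)
  expect_identical(p$records, matrix(c(0L, 12L, 0L, 0L), nrow = 1))
})

test_that("non-conforming EOLs are kept verbatim in RAW records", {
  # wrap width changes 4 -> 6 mid-record
  x <- charToRaw(">h\nACGT\nACGT\nACGTGT\nAC\n")
  p <- parse_block(x)
  expect_identical(unparse_block(p), x)
  expect_identical(oracle_reconstruct(p), x)
  expect_true(sum(p$records[, 1L] == 0L) >= 2L) # header RAW + EOL RAW
})

test_that("parse/unparse round-trips and conserves structure on fuzzed input", {
  cases <- list()
  for (seed in 1:25) {
    cases[[length(cases) + 1L]] <- generate_fasta(corpus_spec(
      seed = seed, n_records = 1L + seed %% 4L,
      total_bases = 200 * seed,
      line_width = c(60L, 70L, 13L)[1L + seed %% 3L],
      width_mode = c("fixed", "per_record", "irregular")[1L + seed %% 3L],
      softmask_rate = 0.004, n_run_rate = 0.002, ambiguity_rate = 0.002
    ))
  }
  for (seed in 26:35) {
    cases[[length(cases) + 1L]] <- rand_bytes(500 * (seed - 25L), seed)
  }
  # mutated FASTA: random bytes spliced into a clean file
  base <- generate_fasta(corpus_spec(seed = 500L, total_bases = 4000))
  for (seed in 36:45) {
    y <- base
    idx <- fastapack:::with_seed(seed, sample.int(length(y), 40L))
    y[idx] <- rand_bytes(40L, seed + 1000L)
    cases[[length(cases) + 1L]] <- y
  }
  for (ctx in c(FALSE, TRUE)) {
    for (x in cases) {
      p <- parse_block(x, starts_in_header = ctx)
      expect_identical(unparse_block(p), x)
      st <- check_block_structure(p, length(x))
      expect_true(st$conserved)
      expect_true(st$grid)
      expect_true(st$dna_alphabet)
      expect_true(st$symbols)
    }
  }
})

test_that("lowercase runs (including soft-masked n) survive exactly", {
  x <- charToRaw(">m\nacgtacgtnnnnnnnnACGTNNNNacgtACGT\n")
  p <- parse_block(x)
  expect_identical(unparse_block(p), x)
  expect_identical(oracle_reconstruct(p), x)
  # NNN contributes zero payload bytes even when soft-masked
  expect_true(any(p$segments[, 1L] == 1L))
})
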