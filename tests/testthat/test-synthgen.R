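fasta_lines <- function(x) strsplit(rawToChar(x), "\n", fixed = TRUE)[[1]]

test_that("generation is a pure function of the spec", {
  sp <- corpus_spec(
    seed = 5L, n_records = 3L, total_bases = 9000,
    softmask_rate = 0.01, n_run_rate = 0.01, ambiguity_rate = 0.01,
    width_mode = "irregular"
  )
  expect_identical(generate_fasta(sp), generate_fasta(sp))
  sp2 <- sp
  sp2$seed <- 6L
  expect_false(identical(generate_fasta(sp), generate_fasta(sp2)))
  # the caller's RNG state is untouched
  set.seed(123)
  before <- .Random.seed
  invisible(generate_fasta(sp))
  expect_identical(.Random.seed, before)
})

test_that("structural spec fields are honoured", {
  x <- generate_fasta(corpus_spec(seed = 1L, n_records = 1L, total_bases = 0))
  expect_match(rawToChar(x), "^>r0 .+\n$") # header-only record

  x <- generate_fasta(corpus_spec(seed = 2L, n_records = 5L, total_bases = 5000))
  lines <- fasta_lines(x)
  expect_identical(sum(startsWith(lines, ">")), 5L)
  seq_lines <- lines[!startsWith(lines, ">")]
  expect_true(all(nchar(seq_lines) <= 60L))
  expect_identical(sum(nchar(seq_lines)), 5000L)

  x <- generate_fasta(corpus_spec(seed = 3L, total_bases = 500, trailing_newline = FALSE))
  expect_false(x[length(x)] == as.raw(10L))

  x <- generate_fasta(corpus_spec(seed = 4L, total_bases = 600, header_length = 0L))
  expect_identical(fasta_lines(x)[1], ">r0")

  x <- generate_fasta(corpus_spec(seed = 5L, total_bases = 2000, alphabet = "protein"))
  body <- paste(fasta_lines(x)[-1], collapse = "")
  expect_true(all(strsplit(body, "")[[1]] %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
})

test_that("redundant collections mutate each copy at the requested rate", {
  n_copies <- 50L
  nb <- 5000L
  mu <- 0.001
  x <- generate_fasta(corpus_spec(
    seed = 8L, total_bases = nb, redundancy_copies = n_copies,
    mutation_rate = mu, header_length = 4L
  ))
  lines <- fasta_lines(x)
  expect_identical(sum(startsWith(lines, ">")), n_copies)
  recs <- split(lines[!startsWith(lines, ">")], cumsum(startsWith(lines, ">"))[!startsWith(lines, ">")])
  seqs <- vapply(recs, paste, "", collapse = "")
  expect_true(all(nchar(seqs) == nb))
  m <- do.call(rbind, lapply(seqs, function(s) utf8ToInt(s)))
  # majority vote recovers the base genome; per-copy mismatches ~ Binom(nb, mu)
  base <- apply(m, 2L, function(col) as.integer(names(which.max(table(col)))))
  mism <- rowSums(m != rep(base, each = nrow(m)))
  total <- sum(mism)
  expected <- n_copies * nb * mu
  expect_gt(total, expected - 3 * sqrt(expected))
  expect_lt(total, expected + 3 * sqrt(expected))
})

test_that("GC content and run-length statistics match the spec", {
  nb <- 2e6
  mean_len <- 16
  sp <- corpus_spec(
    seed = 13L, total_bases = nb, gc_fraction = 0.41,
    n_run_rate = 0.007, n_run_mean_len = mean_len,
    softmask_rate = 0.007, softmask_mean_len = mean_len
  )
  x <- generate_fasta(sp)
  txt <- rawToChar(x)
  body <- gsub("\n", "", substr(txt, as.integer(regexpr("\n", txt)) + 1L, nchar(txt)))
  ch <- strsplit(body, "")[[1]]
  expect_identical(length(ch), as.integer(nb))
  acgt <- ch[toupper(ch) %in% c("A", "C", "G", "T")]
  gc <- mean(toupper(acgt) %in% c("G", "C"))
  se <- sqrt(0.41 * 0.59 / length(acgt))
  expect_lt(abs(gc - 0.41), 3 * se)

  for (mask in list(toupper(ch) == "N", ch %in% letters)) {
    r <- rle(mask)
    runs <- r$lengths[r$values]
    expect_gte(length(runs), 1e4)
    expect_lt(abs(mean(runs) - mean_len) / mean_len, 0.10)
  }
})

test_that("contradictory specs are rejected", {
  expect_error(corpus_spec(n_records = 0L, total_bases = 100), "invalid spec")
  expect_error(corpus_spec(gc_fraction = 1.5), "invalid spec")
  expect_error(corpus_spec(softmask_rate = -0.1), "invalid spec")
  expect_error(corpus_spec(line_width = 0L), "invalid spec")
  expect_error(corpus_spec(mutation_rate = 1), "invalid spec")
})

test_that("adversarial kinds exhibit their defining feature", {
  B <- 65536
  expect_identical(generate_adversarial("empty", B), raw(0))

  x <- generate_adversarial("no_trailing_eol", B)
  expect_false(x[length(x)] == as.raw(10L))

  x <- generate_adversarial("header_spanning_block", B)
  gt <- which(x == charToRaw(">"))
  last_gt <- max(gt[gt <= B])
  expect_gte(last_gt, B - 10L) # '>' within 10 bytes of the boundary
  eols_between <- which(x[last_gt:(B + 1)] == as.raw(10L))
  expect_length(eols_between, 0L) # boundary byte is inside the header line

  x <- generate_adversarial("line_spanning_block", B)
  expect_gt(length(x), 2 * B)
  around <- x[(B - 70):(B + 70)]
  expect_true(any(around != as.raw(10L))) # a sequence line crosses the cut

  x <- generate_adversarial("crlf", B)
  eol <- which(x == as.raw(10L))
  expect_true(all(x[eol - 1L] == as.raw(13L)))

  x <- generate_adversarial("all_N", B)
  body <- x[-(1:3)]
  expect_true(all(body %in% as.raw(c(78L, 10L))))

  x <- generate_adversarial("giant_header", B)
  expect_gt(which(x == as.raw(10L))[1], B) # first EOL beyond one block

  x <- generate_adversarial("width_change_mid_sequence", B)
  p <- parse_block(x)
  expect_gte(sum(p$records[, 1L] == 0L), 2L) # suffix re-routed through RAW
  expect_identical(unparse_block(p), x)
})

test_that("tar output is a valid USTAR archive of the member files", {
  specs <- lapply(1:3, function(i) corpus_spec(seed = i, n_records = 2L, total_bases = 3000))
  x <- generate_tar_like(specs)
  tf <- tempfile(fileext = ".tar")
  on.exit(unlink(tf))
  writeBin(x, tf)
  listed <- untar(tf, list = TRUE, tar = "internal")
  expect_identical(listed, sprintf("rec%03d.fa", 1:3))
  exdir <- tempfile()
  untar(tf, exdir = exdir, tar = "internal")
  got <- readBin(file.path(exdir, "rec001.fa"), "raw", 1e6)
  expect_identical(got, generate_fasta(specs[[1]]))
  unlink(exdir, recursive = TRUE)
})

test_that("write_corpus records matching digests in the manifest", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  specs <- lapply(1:2, function(i) corpus_spec(seed = i, total_bases = 1000))
  man <- write_corpus(specs, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (e in man) {
    bytes <- readBin(file.path(dir, e$file), "raw", e$bytes + 10)
    expect_identical(length(bytes), as.integer(e$bytes))
    expect_identical(fa_crc32(bytes), e$crc32)
  }
})
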