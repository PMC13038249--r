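test_that("archive headers round-trip over random valid field values", {
  for (seed in 1:30) {
    vals <- fastapack:::with_seed(seed, list(
      bs = 2^sample(16:24, 1L),
      dna = sample(c(TRUE, FALSE), 1L),
      isz = sample(0:1e6, 1L),
      nb = sample(0:500, 1L),
      lvl = sample(1:19, 1L),
      ldm = sample(c(TRUE, FALSE), 1L),
      wl = sample(10:27, 1L),
      ck = sample(c(TRUE, FALSE), 1L)
    ))
    h <- archive_header(
      block_size = vals$bs, dna_backend = vals$dna, input_size = vals$isz,
      n_blocks = vals$nb, checksum = vals$ck,
      profile = backend_profile(vals$lvl, vals$ldm, vals$wl)
    )
    bytes <- write_archive_header(h)
    expect_length(bytes, 28L)
    expect_identical(read_archive_header(bytes), h)
  }
})

test_that("malformed archives raise explicit, located errors", {
  x <- generate_fasta(corpus_spec(seed = 2L, total_bases = 3000))
  a <- fa_compress(x)$archive

  bad <- a
  bad[2L] <- as.raw(0x51)
  expect_error(fa_decompress(bad), "bad magic")

  bad <- a
  bad[5L] <- as.raw(99L)
  expect_error(fa_decompress(bad), "unsupported archive format version 99")

  expect_error(fa_decompress(a[1:10]), "truncated")
  expect_error(fa_decompress(a[1:40]), "block 1")
  expect_error(fa_decompress(c(a, as.raw(0L))), "trailing")

  # flip one byte inside the stored DNA payload: the per-block checksum
  # catches the silent content change and names the failing block
  a2 <- fa_compress(generate_fasta(corpus_spec(
    seed = 6L, total_bases = 6000, header_length = 0L
  )))$archive
  bad <- a2
  bad[length(bad) - 200L] <- xor(bad[length(bad) - 200L], as.raw(0x80))
  expect_error(fa_decompress(bad), "block 1")
})

test_that("an empty input yields a header-only archive that decodes to nothing", {
  s <- fa_compress(raw(0))
  expect_identical(s$blocks, 0L)
  expect_length(s$archive, 28L)
  h <- read_archive_header(s$archive)
  expect_identical(h$input_size, 0)
  expect_identical(fa_decompress(s$archive)$data, raw(0))
})

test_that("block metadata serialization is the identity on parsed structure", {
  cases <- c(
    lapply(1:10, function(seed) {
      generate_fasta(corpus_spec(
        seed = seed, n_records = 1L + seed %% 3L, total_bases = 999 * seed,
        softmask_rate = 0.01, n_run_rate = 0.005,
        width_mode = c("fixed", "irregular")[1L + seed %% 2L]
      ))
    }),
    lapply(11:15, function(seed) rand_bytes(4000L, seed))
  )
  for (x in cases) {
    p <- parse_block(x)
    m <- deserialize_block_metadata(serialize_block_metadata(p))
    expect_identical(m$records, p$records)
    expect_identical(m$segments, p$segments)
    expect_identical(m$line_length, p$line_length)
    expect_identical(m$n_symbols, p$n_symbols)
  }
})

test_that("corrupt metadata varints are rejected, not misread", {
  expect_error(
    fastapack:::decode_varints(as.raw(rep(0xff, 5L))),
    "varint overflow"
  )
  expect_error(
    fastapack:::decode_varints(as.raw(c(0x81))),
    "truncated varint"
  )
  expect_error(deserialize_block_metadata(raw(0)), "corrupt")
  # internally inconsistent metadata (symbol counts vs segments)
  p <- parse_block(charToRaw(">s\nACGTACGT\n"))
  p$records[2L, 2L] <- 7L
  expect_error(deserialize_block_metadata(serialize_block_metadata(p)), "corrupt")
})

test_that("block records serialize to the documented stream layout", {
  x <- generate_fasta(corpus_spec(seed = 3L, total_bases = 2000, softmask_rate = 0.01))
  rec <- encode_block(x, dna_backend = FALSE)
  bytes <- write_block_record(rec)
  back <- read_block_record(c(bytes, as.raw(1:3)), 1L, checksum = TRUE, index = 1L)
  expect_identical(back$offset, length(bytes) + 1)
  expect_identical(back$record$original_length, as.numeric(length(x)))
  expect_identical(back$record$crc, rec$crc)
  for (s in names(rec$streams)) {
    expect_identical(back$record$streams[[s]]$ulen, as.numeric(rec$streams[[s]]$ulen))
    expect_identical(back$record$streams[[s]]$data, rec$streams[[s]]$data)
    expect_identical(back$record$streams[[s]]$compressed, rec$streams[[s]]$compressed)
  }
  expect_identical(decode_block(back$record, archive_header()), x)
})

test_that("block size validation enforces the power-of-two range", {
  expect_error(archive_header(block_size = 1023), "power of two")
  expect_error(archive_header(block_size = 65536 + 1), "power of two")
  expect_error(archive_header(block_size = 2^31), "power of two")
  expect_silent(archive_header(block_size = 65536))
})
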