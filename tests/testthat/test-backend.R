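test_that("backend streams round-trip, including the empty frame", {
  expect_identical(decompress_stream(compress_stream(raw(0)), 0), raw(0))
  x <- rand_bytes(262144L, 7L)
  expect_identical(decompress_stream(compress_stream(x), length(x)), x)
  # corrupt frame header surfaces as archive corruption
  blob <- compress_stream(x)
  blob[2L] <- xor(blob[2L], as.raw(0xff))
  expect_error(decompress_stream(blob, length(x)), "corrupt")
  # size mismatch against the frame's declared content size
  blob <- compress_stream(x)
  expect_error(decompress_stream(blob, length(x) + 5), "corrupt")
})

test_that("a repeated motif collapses under long-distance matching", {
  motif <- rand_bytes(1024L, 42L)
  x <- rep(motif, 4096L) # 4 MiB
  blob <- compress_stream(x, backend_profile())
  expect_lt(length(blob), length(x) / 100)
  expect_identical(decompress_stream(blob, length(x)), x)
})

test_that("the probe threshold is inclusive at exactly the factor 1.25", {
  expect_true(probe_decision(1000, 800)) # ratio 1.25 -> on
  expect_false(probe_decision(1000, 801)) # just below -> off
  expect_true(probe_decision(1250, 1000))
  expect_false(probe_decision(1249, 1000))
})

test_that("probe on real bytes is deterministic and boundary-inclusive", {
  unit <- fastapack:::with_seed(31L, charToRaw("ACGT")[sample.int(4L, 20000L, replace = TRUE)])
  packed <- pack_dna(c(unit, unit, unit)) # mildly redundant sample
  d1 <- probe_dna(packed)
  d2 <- probe_dna(packed)
  expect_identical(d1, d2)
  # with the threshold set to the measured ratio the decision flips on
  # exactly at the boundary and off just above it
  expect_true(probe_dna(packed, threshold = d1$probe_ratio)$dna_backend)
  expect_false(probe_dna(packed, threshold = d1$probe_ratio * (1 + 1e-9))$dna_backend)
})

test_that("packed uniform-random DNA fails the probe across seeds", {
  for (seed in 1:5) {
    sym <- fastapack:::with_seed(seed, charToRaw("ACGT")[sample.int(4L, 200000L, replace = TRUE)])
    d <- probe_dna(pack_dna(sym))
    expect_false(d$dna_backend)
    expect_lt(d$probe_ratio, 1.05)
  }
})

test_that("packed DNA of a redundant collection passes the probe", {
  x <- generate_fasta(corpus_spec(
    seed = 9L, total_bases = 20000, redundancy_copies = 200L,
    mutation_rate = 0.001
  ))
  p <- parse_block(x[seq_len(min(length(x), 4 * 1024^2))])
  d <- probe_dna(pack_dna(p$dna_payload))
  expect_true(d$dna_backend)
  expect_gt(d$probe_ratio, 1.25)
})

test_that("the DNA-stream flag matches the global decision in every block", {
  cfg <- pipeline_config(block_size = 65536)
  for (force in c(TRUE, FALSE)) {
    cfg$dna_backend <- force
    x <- generate_fasta(corpus_spec(seed = 77L, total_bases = 200000))
    s <- fa_compress(x, config = cfg)
    insp <- fa_inspect(s$archive)
    dna_rows <- insp$blocks[insp$blocks$stream == "dna" & insp$blocks$uncompressed > 0, ]
    expect_gt(nrow(dna_rows), 1L)
    expect_true(all(dna_rows$backend == force))
    expect_identical(insp$header$dna_backend, force)
  }
})
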