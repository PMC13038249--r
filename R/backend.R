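# General-purpose backend compression of streams (zstd), and the
# adaptive first-block probe that decides -- once per archive -- whether
# the packed DNA stream is backend-compressed at all.

#' Backend compression profile
#'
#' Defaults follow the design point of the method: zstd level 1 with
#' long-distance matching enabled and a window log of 22 (the window
#' then covers the default 4 MiB block).
#'
#' @param level zstd compression level (default 1: speed-oriented).
#' @param long_matching Enable long-distance matching so far-apart
#'   redundancy (e.g. near-identical genome copies) is found.
#' @param window_log Match window of `2^window_log` bytes; must cover
#'   the block size.
#' @return A list of class `fa_backend_profile`.
#' @export
backend_profile <- function(level = 1L, long_matching = TRUE, window_log = 22L) {
  level <- as.integer(level)
  window_log <- as.integer(window_log)
  stopifnot(
    length(level) == 1L, !is.na(level),
    isTRUE(long_matching) || isFALSE(long_matching),
    length(window_log) == 1L, window_log >= 10L, window_log <= 27L
  )
  structure(
    list(level = level, long_matching = long_matching, window_log = window_log),
    class = "fa_backend_profile"
  )
}

#' Backend-compress / decompress a stream
#'
#' Streams are stored as standard zstd frames with the content-size
#' field enabled, so `decompress_stream()` can verify the expected size
#' before and after decoding and third-party tooling can inspect them.
#'
#' @param data Raw vector to compress (may be empty).
#' @param profile A [backend_profile()].
#' @param blob Raw vector holding one zstd frame.
#' @param expected_size Decompressed size the frame must yield.
#' @return Raw vector (compressed frame, or decompressed bytes).
#' @examples
#' x <- charToRaw(strrep("ACGT", 100))
#' identical(decompress_stream(compress_stream(x), length(x)), x)
#' @export
compress_stream <- function(data, profile = backend_profile()) {
  stopifnot(is.raw(data), inherits(profile, "fa_backend_profile"))
  .Call(
    C_zstd_compress, data, profile$level, profile$window_log,
    profile$long_matching
  )
}

#' @rdname compress_stream
#' @export
decompress_stream <- function(blob, expected_size) {
  stopifnot(is.raw(blob))
  .Call(C_zstd_decompress, blob, as.numeric(expected_size))
}

#' Probe decision rule
#'
#' The backend is applied to the DNA stream iff trial compression
#' reduces the packed size by at least the threshold factor:
#' `packed_size >= threshold * compressed_size`. The comparison is
#' inclusive, so a ratio of exactly 1.25 turns the backend on.
#'
#' @param packed_size Size in bytes of the packed DNA sample.
#' @param compressed_size Its size after trial backend compression.
#' @param threshold Required reduction factor (default 1.25).
#' @return Logical: apply the backend to the DNA stream archive-wide?
#' @examples
#' probe_decision(1000, 800) # ratio 1.25 exactly -> TRUE
#' probe_decision(1000, 801) # just below -> FALSE
#' @export
probe_decision <- function(packed_size, compressed_size, threshold = 1.25) {
  stopifnot(packed_size >= 0, compressed_size > 0, threshold > 0)
  packed_size >= threshold * compressed_size
}

#' Probe the packed DNA stream of the first block
#'
#' Runs one trial backend compression on the accumulated packed DNA of
#' the earliest block(s) and fixes, for the whole archive, whether the
#' DNA stream is backend-compressed. Redundant collections (e.g. many
#' near-identical virus genomes) pass the probe and shrink multi-fold;
#' the packed DNA of a low-redundancy genome is essentially
#' incompressible, fails it, and is then stored without the backend
#' pass at full speed.
#'
#' @param packed_first Raw vector: packed DNA accumulated from the
#'   earliest block(s).
#' @param profile A [backend_profile()].
#' @param threshold Reduction factor required to enable the backend
#'   (default 1.25, compared inclusively).
#' @return List with `dna_backend` (logical) and `probe_ratio`
#'   (packed size / whole-frame compressed size; `NA` for empty input).
#' @export
probe_dna <- function(packed_first, profile = backend_profile(), threshold = 1.25) {
  stopifnot(is.raw(packed_first))
  if (length(packed_first) == 0L) {
    return(list(dna_backend = FALSE, probe_ratio = NA_real_))
  }
  blob <- compress_stream(packed_first, profile)
  list(
    dna_backend = probe_decision(length(packed_first), length(blob), threshold),
    probe_ratio = length(packed_first) / length(blob)
  )
}
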