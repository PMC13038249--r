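# End-to-end compression / decompression over fixed-size blocks.
#
# Scheduling contract: work on block i may not begin before block i - t
# has completed, which also guarantees the previous block's bytes are
# available for the boundary scan. The executor here is serial (block
# i - 1 always completes first), which satisfies the contract for every
# t >= 1; archives are a pure function of (input bytes, config), so the
# thread count never changes the output file. Block records are written
# strictly in index order.

FP_PROBE_MIN <- 4096 # packed-DNA bytes required before the probe runs

#' Pipeline configuration
#'
#' @param block_size Block size in bytes; power of two between 64 KiB
#'   and 1 GiB. Default 4 MiB.
#' @param threads Worker count `t` of the scheduling contract (`t >= 1`).
#'   Output bytes are independent of `t` by design; the bundled executor
#'   is serial and satisfies the block-dependency contract for any `t`.
#' @param probe_threshold Reduction factor the first-block DNA probe
#'   must reach to enable backend compression of the DNA stream
#'   (inclusive, default 1.25).
#' @param backend A [backend_profile()].
#' @param checksum Store a CRC-32 of each block's original bytes.
#' @param dna_backend `NULL` (default) to decide via the probe, or
#'   `TRUE`/`FALSE` to force the decision.
#' @return A list of class `fa_config`.
#' @export
pipeline_config <- function(block_size = 4 * 1024^2, threads = 4L,
                            probe_threshold = 1.25,
                            backend = backend_profile(), checksum = TRUE,
                            dna_backend = NULL) {
  threads <- as.integer(threads)
  stopifnot(
    length(threads) == 1L, !is.na(threads), threads >= 1L,
    is.numeric(probe_threshold), probe_threshold > 0,
    inherits(backend, "fa_backend_profile"),
    is.null(dna_backend) || isTRUE(dna_backend) || isFALSE(dna_backend)
  )
  structure(
    list(
      block_size = validate_block_size(block_size),
      threads = threads,
      probe_threshold = probe_threshold,
      backend = backend,
      checksum = isTRUE(checksum),
      dna_backend = dna_backend
    ),
    class = "fa_config"
  )
}

# parse + pack one block; everything up to (but excluding) the backend
# pass, so blocks can be buffered while the probe decision is pending
prepare_block <- function(data, starts_in_header, config) {
  parsed <- parse_block(data, starts_in_header)
  list(
    parsed = parsed,
    dna_packed = .Call(C_pack_dna, parsed$dna_payload),
    meta = serialize_block_metadata(parsed),
    crc = if (config$checksum) fa_crc32(data) else NULL,
    original_length = length(data)
  )
}

# store-uncompressed escape: a stream is never stored larger than verbatim
encode_stream_payload <- function(data, profile) {
  if (length(data) == 0L) {
    return(list(ulen = 0, data = raw(0), compressed = FALSE))
  }
  blob <- compress_stream(data, profile)
  if (length(blob) >= length(data)) {
    list(ulen = length(data), data = data, compressed = FALSE)
  } else {
    list(ulen = length(data), data = blob, compressed = TRUE)
  }
}

finish_block <- function(prep, dna_backend, config) {
  pr <- config$backend
  dna <- if (length(prep$dna_packed) == 0L) {
    list(ulen = 0, data = raw(0), compressed = FALSE)
  } else if (dna_backend) {
    # the probe decision applies uniformly to every block's DNA stream
    list(
      ulen = length(prep$dna_packed),
      data = compress_stream(prep$dna_packed, pr), compressed = TRUE
    )
  } else {
    list(ulen = length(prep$dna_packed), data = prep$dna_packed, compressed = FALSE)
  }
  list(
    original_length = prep$original_length,
    crc = prep$crc,
    streams = list(
      metadata = encode_stream_payload(prep$meta, pr),
      raw = encode_stream_payload(prep$parsed$raw_payload, pr),
      dna = dna,
      mix = encode_stream_payload(prep$parsed$mix_payload, pr),
      flags = encode_stream_payload(prep$parsed$case_flags, pr)
    )
  )
}

#' Encode / decode a single block
#'
#' `encode_block()` runs the whole per-block path (parse, pack, backend)
#' and returns a structured block record; `decode_block()` inverts it
#' using nothing but the record itself and the archive header -- block
#' independence is what enables parallel decompression.
#'
#' @param data Raw vector: the block's original bytes.
#' @param starts_in_header Boundary context from [scan_boundary_context()].
#' @param dna_backend The archive-wide DNA backend decision.
#' @param config A [pipeline_config()].
#' @param record A block record (from `encode_block()` or
#'   [read_block_record()]).
#' @param header The [archive_header()] governing the record.
#' @param index Block index for error messages.
#' @return `encode_block()`: a block record list. `decode_block()`: the
#'   block's original bytes.
#' @export
encode_block <- function(data, starts_in_header = FALSE, dna_backend = FALSE,
                         config = pipeline_config()) {
  finish_block(prepare_block(data, starts_in_header, config), dna_backend, config)
}

#' @rdname encode_block
#' @export
decode_block <- function(record, header, index = NA) {
  fetch <- function(name) {
    st <- record$streams[[name]]
    if (st$ulen == 0) {
      raw(0)
    } else if (st$compressed) {
      decompress_stream(st$data, st$ulen)
    } else {
      if (length(st$data) != st$ulen) {
        stop("corrupt archive: stream length mismatch in block ", index)
      }
      st$data
    }
  }
  meta <- deserialize_block_metadata(fetch("metadata"))
  n_dna <- sum(meta$segments[meta$segments[, 1L] == 0L, 2L])
  dna_packed <- fetch("dna")
  if (length(dna_packed) * 4 != n_dna) {
    stop("corrupt archive: DNA stream size mismatch in block ", index)
  }
  flags <- fetch("flags")
  if (length(flags) != ceiling(meta$n_symbols / 8)) {
    stop("corrupt archive: case-flag stream size mismatch in block ", index)
  }
  bytes <- .Call(
    C_unparse_block, meta$records, meta$segments, meta$line_length,
    fetch("raw"), unpack_dna(dna_packed, n_dna), fetch("mix"), flags
  )
  if (length(bytes) != record$original_length) {
    stop("corrupt archive: block ", index, " length mismatch")
  }
  if (!is.null(record$crc) && fa_crc32(bytes) != record$crc) {
    stop("corrupt archive: checksum mismatch in block ", index)
  }
  bytes
}

#' Compress a file or raw vector into an archive
#'
#' Processes the input in `block_size` chunks. Per block: boundary scan
#' against the previous block, parse into typed records/segments, 2-bit
#' DNA packing, case-flag packing, metadata serialization, then backend
#' compression of the metadata, raw, mix and flag streams (with a
#' store-uncompressed escape). The packed DNA stream is probed once --
#' on the first block(s) holding at least 4 KiB of packed DNA -- and the
#' resulting decision applies to every block. Blocks are buffered only
#' until that decision is fixed, then streamed out in index order.
#'
#' Zero-length input produces a valid empty archive that decompresses
#' to zero bytes.
#'
#' @param input File path or raw vector.
#' @param output File path for the archive, or `NULL` to return the
#'   archive bytes in the summary (`$archive`).
#' @param config A [pipeline_config()].
#' @return (Invisibly) an `fa_summary` list: `blocks`, `input_size`,
#'   `output_size`, `ratio` (input/output), `dna_backend`,
#'   `probe_ratio`, and `archive` (raw) when `output` is `NULL`.
#' @examples
#' x <- generate_fasta(corpus_spec(seed = 1, total_bases = 5000))
#' s <- fa_compress(x)
#' s$ratio
#' identical(fa_decompress(s$archive)$data, x)
#' @export
fa_compress <- function(input, output = NULL, config = pipeline_config()) {
  x <- as_input_bytes(input)
  n <- length(x)
  B <- config$block_size
  n_blocks <- if (n == 0) 0L else as.integer((n + B - 1) %/% B)

  decision <- config$dna_backend
  probe_ratio <- NA_real_
  probed <- !is.null(decision)
  acc <- list()
  acc_len <- 0
  pending <- list()
  chunks <- vector("list", n_blocks)
  n_done <- 0L
  emit <- function(prep) {
    n_done <<- n_done + 1L
    chunks[[n_done]] <<- write_block_record(finish_block(prep, decision, config))
  }

  prev <- raw(0)
  for (i in seq_len(n_blocks)) {
    lo <- (i - 1) * B + 1
    hi <- min(n, i * B)
    blk <- x[lo:hi]
    ctx <- if (i == 1L) FALSE else scan_boundary_context(prev)
    prev <- blk
    prep <- prepare_block(blk, ctx, config)
    if (!probed) {
      acc_len <- acc_len + length(prep$dna_packed)
      acc[[length(acc) + 1L]] <- prep$dna_packed
      pending[[length(pending) + 1L]] <- prep
      if (acc_len >= FP_PROBE_MIN) {
        pd <- probe_dna(concat_raw(acc), config$backend, config$probe_threshold)
        decision <- pd$dna_backend
        probe_ratio <- pd$probe_ratio
        probed <- TRUE
        for (p in pending) emit(p)
        pending <- list()
        acc <- list()
      }
    } else {
      emit(prep)
    }
  }
  if (!probed || is.null(decision)) {
    # probe floor never reached: default to no DNA backend
    decision <- if (is.null(config$dna_backend)) FALSE else config$dna_backend
    for (p in pending) emit(p)
  }

  header <- write_archive_header(archive_header(
    block_size = B, dna_backend = decision, input_size = n,
    n_blocks = n_blocks, profile = config$backend,
    checksum = config$checksum
  ))
  archive <- c(header, concat_raw(chunks))
  if (!is.null(output)) {
    writeBin(archive, output)
  }
  out <- structure(
    list(
      blocks = n_blocks, input_size = n, output_size = length(archive),
      ratio = n / length(archive), dna_backend = decision,
      probe_ratio = probe_ratio
    ),
    class = "fa_summary"
  )
  if (is.null(output)) out$archive <- archive
  invisible(out)
}

#' Decompress an archive
#'
#' Reads the header, then decodes every block record independently (in
#' index order), verifying per-block CRC-32 checksums, per-block
#' lengths, and the total decompressed size against the header.
#'
#' @param input Archive file path or raw vector.
#' @param output File path for the decompressed bytes, or `NULL` to
#'   return them in the summary (`$data`).
#' @param config A [pipeline_config()] (only `threads` is relevant;
#'   output is independent of it).
#' @return (Invisibly) an `fa_summary` list: `blocks`, `input_size`
#'   (decompressed bytes), `output_size` (archive bytes), `ratio`,
#'   `dna_backend`, and `data` (raw) when `output` is `NULL`.
#' @export
fa_decompress <- function(input, output = NULL, config = pipeline_config()) {
  a <- as_input_bytes(input, "archive")
  header <- read_archive_header(a)
  offset <- FP_HEADER_SIZE + 1
  parts <- vector("list", header$n_blocks)
  for (i in seq_len(header$n_blocks)) {
    br <- read_block_record(a, offset, checksum = header$checksum, index = i)
    offset <- br$offset
    parts[[i]] <- decode_block(br$record, header, index = i)
  }
  if (offset != length(a) + 1) {
    stop("corrupt archive: ", length(a) - offset + 1, " trailing bytes")
  }
  data <- concat_raw(parts)
  if (length(data) != header$input_size) {
    stop(
      "corrupt archive: decompressed ", length(data),
      " bytes, header declares ", header$input_size
    )
  }
  if (!is.null(output)) {
    writeBin(data, output)
  }
  out <- structure(
    list(
      blocks = header$n_blocks, input_size = length(data),
      output_size = length(a), ratio = length(data) / length(a),
      dna_backend = header$dna_backend, probe_ratio = NA_real_
    ),
    class = "fa_summary"
  )
  if (is.null(output)) out$data <- data
  invisible(out)
}

#' Verify an archive without writing output
#'
#' Fully decodes every block and checks all checksums and sizes;
#' errors name the failing block.
#'
#' @param input Archive file path or raw vector.
#' @return (Invisibly) a list with `ok`, `blocks` and `input_size`.
#' @export
fa_verify <- function(input) {
  s <- fa_decompress(input, output = NULL)
  invisible(list(ok = TRUE, blocks = s$blocks, input_size = s$input_size))
}

#' Inspect an archive
#'
#' Reports the header, per-block stream sizes and flags, and the
#' aggregated segment-type histogram (count and total symbols per
#' DNA/NNN/MIX type) without reconstructing any block payloads beyond
#' the metadata streams.
#'
#' @param input Archive file path or raw vector.
#' @return A list of class `fa_inspect` with `header`, `blocks` (data
#'   frame: per-block stream sizes and compression flags) and
#'   `segments` (data frame: histogram over segment types).
#' @export
fa_inspect <- function(input) {
  a <- as_input_bytes(input, "archive")
  header <- read_archive_header(a)
  offset <- FP_HEADER_SIZE + 1
  rows <- vector("list", header$n_blocks)
  seg_count <- c(DNA = 0, NNN = 0, MIX = 0)
  seg_symbols <- c(DNA = 0, NNN = 0, MIX = 0)
  for (i in seq_len(header$n_blocks)) {
    br <- read_block_record(a, offset, checksum = header$checksum, index = i)
    offset <- br$offset
    st <- br$record$streams
    meta_bytes <- if (st$metadata$compressed) {
      decompress_stream(st$metadata$data, st$metadata$ulen)
    } else {
      st$metadata$data
    }
    meta <- deserialize_block_metadata(meta_bytes)
    if (nrow(meta$segments) > 0) {
      tp <- SEG_TYPES[meta$segments[, 1L] + 1L]
      for (t in SEG_TYPES) {
        seg_count[t] <- seg_count[t] + sum(tp == t)
        seg_symbols[t] <- seg_symbols[t] + sum(meta$segments[tp == t, 2L])
      }
    }
    sizes <- vapply(st, function(s) length(s$data), numeric(1))
    ulens <- vapply(st, function(s) as.numeric(s$ulen), numeric(1))
    comp <- vapply(st, function(s) isTRUE(s$compressed), logical(1))
    rows[[i]] <- data.frame(
      block = i, original_length = br$record$original_length,
      stream = FP_STREAMS, uncompressed = ulens, stored = sizes,
      backend = comp, row.names = NULL
    )
  }
  structure(
    list(
      header = header,
      blocks = do.call(rbind, rows),
      segments = data.frame(
        type = SEG_TYPES, n_segments = as.numeric(seg_count),
        total_symbols = as.numeric(seg_symbols), row.names = NULL
      )
    ),
    class = "fa_inspect"
  )
}

#' @export
print.fa_summary <- function(x, ...) {
  cat(
    "blocks: ", x$blocks, "  input: ", x$input_size, " B  archive: ",
    x$output_size, " B  ratio: ", sprintf("%.3f", x$ratio),
    "  dna_backend: ", x$dna_backend,
    if (!is.na(x$probe_ratio)) sprintf("  probe_ratio: %.3f", x$probe_ratio),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.fa_inspect <- function(x, ...) {
  h <- x$header
  cat(
    "archive: version ", h$format_version, ", block_size ", h$block_size,
    ", blocks ", h$n_blocks, ", input_size ", h$input_size,
    ", dna_backend ", h$dna_backend, ", checksum ", h$checksum, "\n",
    sep = ""
  )
  cat("segment histogram:\n")
  print(x$segments)
  invisible(x)
}
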