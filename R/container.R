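# Byte-exact archive serialization. The full layout (field offsets, bit
# orders, varint encoding, stream order) is documented in docs/FORMAT.md;
# the conventions fixed here are normative for the format.

FP_MAGIC <- as.raw(c(0x46, 0x50, 0x41, 0x4b)) # "FPAK"
FP_VERSION <- 1L
FP_HEADER_SIZE <- 28L
FP_STREAMS <- c("metadata", "raw", "dna", "mix", "flags")
FP_MIN_BLOCK <- 65536
FP_MAX_BLOCK <- 2^30

validate_block_size <- function(block_size) {
  bs <- suppressWarnings(as.numeric(block_size))
  if (length(bs) != 1L || is.na(bs) || bs < FP_MIN_BLOCK || bs > FP_MAX_BLOCK ||
    2^round(log2(bs)) != bs) {
    stop(
      "block_size must be a power of two between 64 KiB and 1 GiB, got ",
      block_size
    )
  }
  bs
}

#' Construct an archive header
#'
#' Global archive metadata: magic bytes, format version, block size, the
#' archive-wide DNA backend decision, the backend profile, the total
#' decompressed size and the checksum mode.
#'
#' @param block_size Block size in bytes (power of two, 64 KiB .. 1 GiB).
#' @param dna_backend Logical: is the packed DNA stream backend-compressed?
#' @param input_size Total decompressed output length in bytes.
#' @param n_blocks Number of block records that follow the header.
#' @param profile A [backend_profile()].
#' @param checksum Logical: per-block CRC-32 of the original bytes.
#' @return A list of class `fa_archive_header`.
#' @export
archive_header <- function(block_size = 4 * 1024^2, dna_backend = FALSE,
                           input_size = 0, n_blocks = 0,
                           profile = backend_profile(), checksum = TRUE) {
  structure(
    list(
      format_version = FP_VERSION,
      block_size = validate_block_size(block_size),
      dna_backend = isTRUE(dna_backend),
      profile = profile,
      input_size = as.numeric(input_size),
      n_blocks = as.numeric(n_blocks),
      checksum = isTRUE(checksum)
    ),
    class = "fa_archive_header"
  )
}

#' Serialize / parse the archive header
#'
#' `write_archive_header()` emits the fixed 28-byte header;
#' `read_archive_header()` parses and validates it, raising explicit
#' errors on a bad magic, an unsupported format version, or truncation.
#'
#' @param header An [archive_header()].
#' @param bytes Raw vector holding at least the first 28 archive bytes.
#' @return A raw vector of 28 bytes, or the parsed `fa_archive_header`.
#' @export
write_archive_header <- function(header) {
  stopifnot(inherits(header, "fa_archive_header"))
  flags <- as.integer(header$dna_backend) + 2L * as.integer(header$checksum)
  c(
    FP_MAGIC,
    as.raw(c(
      FP_VERSION, flags, header$profile$level, header$profile$window_log,
      as.integer(header$profile$long_matching), 0L, 0L, 0L
    )),
    u32_to_raw(header$block_size),
    u64_to_raw(header$input_size),
    u32_to_raw(header$n_blocks)
  )
}

#' @rdname write_archive_header
#' @export
read_archive_header <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < FP_HEADER_SIZE) {
    stop("truncated archive: no complete header (", length(bytes), " bytes)")
  }
  if (!identical(bytes[1:4], FP_MAGIC)) {
    stop("not an archive: bad magic bytes")
  }
  version <- as.integer(bytes[5L])
  if (version != FP_VERSION) {
    stop("unsupported archive format version ", version)
  }
  flags <- as.integer(bytes[6L])
  archive_header(
    block_size = raw_to_u32(bytes, 13L),
    dna_backend = bitwAnd(flags, 1L) == 1L,
    input_size = raw_to_u64(bytes, 17L),
    n_blocks = raw_to_u32(bytes, 25L),
    profile = backend_profile(
      level = as.integer(bytes[7L]),
      long_matching = as.integer(bytes[9L]) == 1L,
      window_log = as.integer(bytes[8L])
    ),
    checksum = bitwAnd(flags, 2L) == 2L
  )
}

#' Serialize block metadata
#'
#' The metadata stream encodes, as a flat LEB128 varint sequence, the
#' block's line length, its layout records (RAW byte length, or SEQ
#' symbol count / first span / removed-EOL count) and its typed segment
#' list (which carries the NNN run lengths implicitly).
#' `deserialize_block_metadata()` reproduces the structural fields of
#' the parsed block exactly.
#'
#' @param parsed An `fa_parsed_block` (or decoded equivalent).
#' @param bytes Raw vector: an uncompressed metadata stream.
#' @return A raw vector, or a list with `records`, `segments`,
#'   `line_length`, `n_symbols`.
#' @export
serialize_block_metadata <- function(parsed) {
  rec <- parsed$records
  seg <- parsed$segments
  k <- nrow(rec)
  rec_ints <- vector("list", k)
  for (i in seq_len(k)) {
    rec_ints[[i]] <- if (rec[i, 1L] == 0L) {
      c(0L, rec[i, 2L])
    } else {
      c(1L, rec[i, 2L], rec[i, 3L], rec[i, 4L])
    }
  }
  ints <- c(
    parsed$line_length, k, unlist(rec_ints, use.names = FALSE),
    nrow(seg), as.vector(t(seg))
  )
  encode_varints(ints)
}

#' @rdname serialize_block_metadata
#' @export
deserialize_block_metadata <- function(bytes) {
  v <- decode_varints(bytes)
  bad <- function() stop("corrupt metadata: malformed block metadata")
  if (length(v) < 2L) bad()
  line_length <- v[1L]
  k <- v[2L]
  i <- 3L
  rec <- matrix(0L, nrow = k, ncol = 4L)
  for (r in seq_len(k)) {
    if (i > length(v)) bad()
    kind <- v[i]
    if (kind == 0L) {
      if (i + 1L > length(v)) bad()
      rec[r, ] <- c(0L, v[i + 1L], 0L, 0L)
      i <- i + 2L
    } else if (kind == 1L) {
      if (i + 3L > length(v)) bad()
      rec[r, ] <- c(1L, v[i + 1L], v[i + 2L], v[i + 3L])
      i <- i + 4L
    } else {
      bad()
    }
  }
  if (i > length(v)) bad()
  m <- v[i]
  i <- i + 1L
  if (length(v) != i + 2L * m - 1L) bad()
  seg <- matrix(v[seq.int(i, length.out = 2L * m)], ncol = 2L, byrow = TRUE)
  if (m > 0L && (any(seg[, 1L] > 2L) || any(seg[, 2L] < 0L))) bad()
  n_symbols <- sum(rec[rec[, 1L] == 1L, 2L])
  if (sum(seg[, 2L]) != n_symbols) bad()
  list(
    records = rec, segments = seg, line_length = line_length,
    n_symbols = n_symbols
  )
}

#' Serialize / read one block record
#'
#' A block record holds the block's original length, presence and
#' backend-compression flags for its five streams (fixed order:
#' metadata, raw, dna, mix, flags -- the decoder needs metadata first),
#' an optional CRC-32 of the original block bytes, and the per-stream
#' (uncompressed length, stored length, payload) triples.
#'
#' @param record A list with `original_length`, `crc` (double or `NULL`)
#'   and `streams`: a named list (names from the fixed stream order) of
#'   `list(ulen =, data =, compressed =)`; streams with `ulen == 0` are
#'   absent.
#' @param archive Raw vector holding the whole archive.
#' @param offset 1-based offset of the record's first byte.
#' @param checksum Logical: does the record carry a CRC-32 field?
#' @param index Block index used in error messages (1-based).
#' @return `write_block_record()`: a raw vector.
#'   `read_block_record()`: a list with the parsed `record` and the
#'   `offset` just past it.
#' @export
write_block_record <- function(record) {
  present <- 0L
  compressed <- 0L
  chunks <- list()
  for (s in seq_along(FP_STREAMS)) {
    st <- record$streams[[FP_STREAMS[s]]]
    if (is.null(st) || st$ulen == 0) next
    present <- bitwOr(present, bitwShiftL(1L, s - 1L))
    if (isTRUE(st$compressed)) {
      compressed <- bitwOr(compressed, bitwShiftL(1L, s - 1L))
    }
    chunks[[length(chunks) + 1L]] <-
      c(u32_to_raw(st$ulen), u32_to_raw(length(st$data)), st$data)
  }
  c(
    u32_to_raw(record$original_length),
    as.raw(c(present, compressed)),
    if (!is.null(record$crc)) u32_to_raw(record$crc),
    concat_raw(chunks)
  )
}

#' @rdname write_block_record
#' @export
read_block_record <- function(archive, offset, checksum = TRUE, index = NA) {
  n <- length(archive)
  need <- function(k) {
    if (offset + k - 1 > n) {
      stop("truncated archive: block ", index, " ends prematurely")
    }
  }
  need(6L)
  original_length <- raw_to_u32(archive, offset)
  present <- as.integer(archive[offset + 4L])
  compressed <- as.integer(archive[offset + 5L])
  offset <- offset + 6L
  crc <- NULL
  if (checksum) {
    need(4L)
    crc <- raw_to_u32(archive, offset)
    offset <- offset + 4L
  }
  streams <- stats::setNames(vector("list", length(FP_STREAMS)), FP_STREAMS)
  for (s in seq_along(FP_STREAMS)) {
    bit <- bitwShiftL(1L, s - 1L)
    if (bitwAnd(present, bit) == 0L) {
      streams[[s]] <- list(ulen = 0, data = raw(0), compressed = FALSE)
      next
    }
    need(8L)
    ulen <- raw_to_u32(archive, offset)
    slen <- raw_to_u32(archive, offset + 4L)
    offset <- offset + 8L
    need(slen)
    data <- if (slen > 0) {
      archive[seq.int(offset, length.out = slen)]
    } else {
      raw(0)
    }
    offset <- offset + slen
    streams[[s]] <- list(
      ulen = ulen, data = data,
      compressed = bitwAnd(compressed, bit) != 0L
    )
  }
  list(
    record = list(
      original_length = original_length, crc = crc, streams = streams
    ),
    offset = offset
  )
}
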