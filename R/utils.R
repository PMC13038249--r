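# Internal byte-level helpers for the container format. All multi-byte
# integers in the archive are little-endian; u64 values are handled as
# doubles (exact below 2^53, far beyond any supported input size).

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  stopifnot(all(x >= 0), all(x < 2^32))
  as.raw(c(rbind(
    x %% 256,
    x %/% 256 %% 256,
    x %/% 65536 %% 256,
    x %/% 16777216 %% 256
  )))
}

raw_to_u32 <- function(r, off = 1L) {
  sum(as.integer(r[off:(off + 3L)]) * c(1, 256, 65536, 16777216))
}

u64_to_raw <- function(x) {
  x <- as.numeric(x)
  stopifnot(x >= 0, x < 2^53)
  b <- numeric(8)
  for (i in 1:8) {
    b[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(b)
}

raw_to_u64 <- function(r, off = 1L) {
  sum(as.numeric(r[off:(off + 7L)]) * 256^(0:7))
}

# Accept a file path or a raw vector wherever bytes are expected.
as_input_bytes <- function(x, arg = "input") {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("cannot read ", arg, ": no such file: ", x)
    return(readBin(x, "raw", n = file.size(x)))
  }
  stop(arg, " must be a raw vector or a file path")
}

concat_raw <- function(chunks) {
  if (length(chunks) == 0L) return(raw(0))
  unlist(chunks, use.names = FALSE)
}

#' CRC-32 checksum of a raw vector
#'
#' Plain zlib CRC-32, used for the per-block integrity checksums in the
#' archive and for fixture digests in corpus manifests.
#'
#' @param data Raw vector.
#' @return The checksum as a double (value in `[0, 2^32)`).
#' @examples
#' fa_crc32(charToRaw("ACGT"))
#' @export
fa_crc32 <- function(data) {
  stopifnot(is.raw(data))
  .Call(C_crc32, data)
}

encode_varints <- function(vals) .Call(C_encode_varints, as.integer(vals))
decode_varints <- function(data) .Call(C_decode_varints, data)
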