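# Deterministic generator of synthetic FASTA corpora and adversarial
# inputs. Generation is a pure function of the spec: the same seed
# always yields the same bytes, and the caller's RNG state is left
# untouched (R's own Mersenne-Twister stream, explicitly seeded, no
# global state leaks).

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

NUC_RAW <- charToRaw("ACGT")
AMBIG_RAW <- charToRaw("RYKMSWBDHV")
AA_RAW <- charToRaw("ACDEFGHIKLMNPQRSTVWY")

#' Specification of a synthetic FASTA corpus
#'
#' Captures every structural feature the compressor exploits:
#' multi-record layout, header lengths, line widths (regular or not),
#' soft-masked (lowercase) runs, N-runs, IUPAC ambiguity symbols, and
#' redundant collections of mutated genome copies.
#'
#' Rates are per base: `softmask_rate` / `n_run_rate` give the expected
#' number of run starts per base (runs are laid out non-overlapping;
#' lengths are geometric with the requested mean), `ambiguity_rate` the
#' per-base probability of an IUPAC ambiguity code outside N-runs. With
#' `redundancy_copies > 0` the corpus is a collection: one base genome
#' of `total_bases` and that many copies, each with independent
#' substitutions at `mutation_rate` per base. For the protein alphabet
#' the nucleotide-specific fields (GC, N-runs, ambiguity, redundancy)
#' are ignored.
#'
#' @param seed Integer seed; same spec + seed give identical bytes.
#' @param n_records Number of records (ignored when
#'   `redundancy_copies > 0`).
#' @param total_bases Total sequence length, split ~evenly over records
#'   (or the base-genome length of a redundant collection).
#' @param header_length Length of the random description after the
#'   record id (0 for bare ids).
#' @param line_width Target wrap width in symbols.
#' @param width_mode `"fixed"` (every line `line_width`),
#'   `"per_record"` (one random width per record) or `"irregular"`
#'   (every line a random width).
#' @param gc_fraction Probability mass on G+C.
#' @param softmask_rate,softmask_mean_len Lowercase-run starts per base
#'   and geometric mean run length.
#' @param n_run_rate,n_run_mean_len N-run starts per base and geometric
#'   mean run length (means are rounded up to multiples of 8 of at
#'   least 8 only by chance, not by construction).
#' @param ambiguity_rate Per-base probability of an IUPAC ambiguity
#'   symbol (R, Y, K, M, S, W, B, D, H, V).
#' @param redundancy_copies Number of mutated copies of the base genome
#'   (0 = no redundancy structure).
#' @param mutation_rate Per-base substitution probability per copy.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param trailing_newline Keep the final EOL byte?
#' @return A list of class `fa_corpus_spec`.
#' @export
corpus_spec <- function(seed = 1L, n_records = 1L, total_bases = 10000,
                        header_length = 16L, line_width = 60L,
                        width_mode = c("fixed", "per_record", "irregular"),
                        gc_fraction = 0.41, softmask_rate = 0,
                        softmask_mean_len = 500, n_run_rate = 0,
                        n_run_mean_len = 200, ambiguity_rate = 0,
                        redundancy_copies = 0L, mutation_rate = 0.001,
                        alphabet = c("nucleotide", "protein"),
                        trailing_newline = TRUE) {
  width_mode <- match.arg(width_mode)
  alphabet <- match.arg(alphabet)
  n_records <- as.integer(n_records)
  total_bases <- as.numeric(total_bases)
  if (is.na(n_records) || n_records < 0L) stop("invalid spec: n_records < 0")
  if (is.na(total_bases) || total_bases < 0) stop("invalid spec: total_bases < 0")
  if (n_records == 0L && total_bases > 0 && redundancy_copies == 0L) {
    stop("invalid spec: total_bases > 0 requires at least one record")
  }
  if (line_width < 1L) stop("invalid spec: line_width < 1")
  if (gc_fraction < 0 || gc_fraction > 1) stop("invalid spec: gc_fraction")
  if (mutation_rate < 0 || mutation_rate >= 1) stop("invalid spec: mutation_rate")
  if (softmask_rate < 0 || n_run_rate < 0 || ambiguity_rate < 0 ||
    softmask_rate > 1 || n_run_rate > 1 || ambiguity_rate > 1) {
    stop("invalid spec: rates must lie in [0, 1]")
  }
  if (softmask_mean_len < 1 || n_run_mean_len < 1) {
    stop("invalid spec: run mean lengths must be >= 1")
  }
  structure(
    list(
      seed = as.integer(seed), n_records = n_records,
      total_bases = total_bases, header_length = as.integer(header_length),
      line_width = as.integer(line_width), width_mode = width_mode,
      gc_fraction = gc_fraction, softmask_rate = softmask_rate,
      softmask_mean_len = softmask_mean_len, n_run_rate = n_run_rate,
      n_run_mean_len = n_run_mean_len, ambiguity_rate = ambiguity_rate,
      redundancy_copies = as.integer(redundancy_copies),
      mutation_rate = mutation_rate, alphabet = alphabet,
      trailing_newline = isTRUE(trailing_newline)
    ),
    class = "fa_corpus_spec"
  )
}

# non-overlapping runs: starts sampled at `rate` per base, geometric
# lengths with the requested mean; overlapping or truncated candidates
# are dropped so realized run lengths keep the sampled distribution
sample_runs <- function(n, rate, mean_len) {
  k <- stats::rbinom(1L, size = as.integer(min(n, .Machine$integer.max)), prob = rate)
  if (k == 0L) {
    return(list(start = integer(0), len = integer(0)))
  }
  start <- sort(sample.int(n, min(k, n)))
  len <- 1L + stats::rgeom(length(start), prob = 1 / mean_len)
  keep <- logical(length(start))
  last_end <- 0
  for (i in seq_along(start)) {
    if (start[i] > last_end + 1 && start[i] + len[i] - 1 <= n) {
      keep[i] <- TRUE
      last_end <- start[i] + len[i] - 1
    }
  }
  list(start = start[keep], len = len[keep])
}

mark_runs <- function(n, runs) {
  m <- logical(n)
  for (i in seq_along(runs$start)) {
    m[seq.int(runs$start[i], length.out = runs$len[i])] <- TRUE
  }
  m
}

# one record's sequence as uppercase symbols + lowercase mask
gen_sequence <- function(nb, spec) {
  if (nb == 0) {
    return(list(sym = raw(0), lower = logical(0)))
  }
  if (spec$alphabet == "protein") {
    sym <- AA_RAW[sample.int(20L, nb, replace = TRUE)]
  } else {
    p <- c(
      (1 - spec$gc_fraction) / 2, spec$gc_fraction / 2,
      spec$gc_fraction / 2, (1 - spec$gc_fraction) / 2
    )
    sym <- NUC_RAW[sample.int(4L, nb, replace = TRUE, prob = p)]
    if (spec$n_run_rate > 0) {
      nmask <- mark_runs(nb, sample_runs(nb, spec$n_run_rate, spec$n_run_mean_len))
      sym[nmask] <- as.raw(78L) # 'N'
    } else {
      nmask <- logical(nb)
    }
    if (spec$ambiguity_rate > 0) {
      amb <- stats::runif(nb) < spec$ambiguity_rate & !nmask
      if (any(amb)) {
        sym[amb] <- AMBIG_RAW[sample.int(10L, sum(amb), replace = TRUE)]
      }
    }
  }
  lower <- if (spec$softmask_rate > 0) {
    mark_runs(nb, sample_runs(nb, spec$softmask_rate, spec$softmask_mean_len))
  } else {
    logical(nb)
  }
  list(sym = sym, lower = lower)
}

apply_case <- function(sym, lower) {
  if (any(lower)) {
    sym[lower] <- as.raw(bitwOr(as.integer(sym[lower]), 32L))
  }
  sym
}

# insert one EOL after every `lens[i]` symbols (lens sums to length(s))
wrap_raw <- function(s, lens) {
  k <- length(lens)
  if (k == 0L) {
    return(raw(0))
  }
  out <- raw(length(s) + k)
  eol_pos <- cumsum(lens) + seq_len(k)
  out[eol_pos] <- as.raw(10L)
  out[-eol_pos] <- s
  out
}

line_lengths <- function(nb, width) {
  if (nb == 0) {
    return(integer(0))
  }
  k <- nb %/% width
  rem <- nb - k * width
  c(rep.int(as.integer(width), k), if (rem > 0) as.integer(rem))
}

record_widths <- function(spec, nb) {
  switch(spec$width_mode,
    fixed = line_lengths(nb, spec$line_width),
    per_record = line_lengths(
      nb,
      sample.int(spec$line_width, 1L) + spec$line_width %/% 2L
    ),
    irregular = {
      lens <- integer(0)
      left <- nb
      lo <- max(1L, spec$line_width %/% 2L)
      hi <- spec$line_width + spec$line_width %/% 2L
      while (left > 0) {
        w <- min(left, sample.int(hi - lo + 1L, 1L) + lo - 1L)
        lens <- c(lens, as.integer(w))
        left <- left - w
      }
      lens
    }
  )
}

rand_desc <- function(len) {
  if (len <= 0L) {
    return("")
  }
  pool <- c(letters, LETTERS, 0:9, "_", ".")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic FASTA corpus
#'
#' Deterministic per seed: the same [corpus_spec()] always produces the
#' identical byte stream. Every structural feature of the spec (record
#' count, wrap widths, soft-masked and N runs, ambiguity codes,
#' redundant mutated copies, trailing newline) is honoured.
#'
#' @param spec A [corpus_spec()].
#' @return Raw vector: the FASTA file's bytes.
#' @examples
#' x <- generate_fasta(corpus_spec(seed = 7, n_records = 2, total_bases = 200))
#' cat(substr(rawToChar(x), 1, 40))
#' @export
generate_fasta <- function(spec) {
  stopifnot(inherits(spec, "fa_corpus_spec"))
  with_seed(spec$seed, {
    redundant <- spec$redundancy_copies > 0L && spec$alphabet == "nucleotide"
    if (redundant) {
      base <- gen_sequence(spec$total_bases, spec)
      n_rec <- spec$redundancy_copies
    } else {
      n_rec <- spec$n_records
      sizes <- if (n_rec > 0) {
        s <- rep.int(spec$total_bases %/% n_rec, n_rec)
        extra <- spec$total_bases - sum(s)
        if (extra > 0) s[seq_len(extra)] <- s[seq_len(extra)] + 1
        s
      } else {
        numeric(0)
      }
    }
    parts <- vector("list", n_rec)
    for (r in seq_len(n_rec)) {
      if (redundant) {
        sym <- base$sym
        lower <- base$lower
        ints <- as.integer(sym)
        mut <- which(stats::runif(length(sym)) < spec$mutation_rate &
          ints %in% as.integer(NUC_RAW))
        if (length(mut)) {
          old <- match(ints[mut], as.integer(NUC_RAW))
          sym[mut] <- NUC_RAW[1L + (old - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L]
        }
      } else {
        sq <- gen_sequence(sizes[r], spec)
        sym <- sq$sym
        lower <- sq$lower
      }
      header <- charToRaw(paste0(
        ">r", r - 1L,
        if (spec$header_length > 0L) paste0(" ", rand_desc(spec$header_length)),
        "\n"
      ))
      body <- wrap_raw(apply_case(sym, lower), record_widths(spec, length(sym)))
      parts[[r]] <- c(header, body)
    }
    out <- concat_raw(parts)
    if (!spec$trailing_newline && length(out) > 0L &&
      out[length(out)] == as.raw(10L)) {
      out <- out[-length(out)]
    }
    out
  })
}

ADVERSARIAL_KINDS <- c(
  "no_trailing_eol", "header_spanning_block", "line_spanning_block",
  "crlf", "all_N", "binary", "empty", "giant_header",
  "width_change_mid_sequence"
)

#' Generate adversarial inputs
#'
#' Each kind provably exhibits, relative to `block_size`, one feature
#' the parser must survive: a missing final EOL, a header or sequence
#' line spanning a block boundary, CRLF line endings (CR is content
#' here, never EOL), an all-N file, arbitrary binary bytes, empty
#' input, a header line longer than a whole block, and a wrap-width
#' change in the middle of a record.
#'
#' @param kind One of `"no_trailing_eol"`, `"header_spanning_block"`,
#'   `"line_spanning_block"`, `"crlf"`, `"all_N"`, `"binary"`,
#'   `"empty"`, `"giant_header"`, `"width_change_mid_sequence"`.
#' @param block_size Block size the input is adversarial against.
#' @return Raw vector (deterministic for a given kind and block size).
#' @export
generate_adversarial <- function(kind = ADVERSARIAL_KINDS,
                                 block_size = 65536) {
  kind <- match.arg(kind)
  B <- as.numeric(block_size)
  line <- function(ch, w) c(rep(charToRaw(ch), w), as.raw(10L))
  switch(kind,
    empty = raw(0),
    no_trailing_eol = generate_fasta(corpus_spec(
      seed = 421L, n_records = 2L, total_bases = 900,
      trailing_newline = FALSE
    )),
    header_spanning_block = {
      # byte index B (1-based B+1) must lie inside a header line
      k <- (B - 10 - 3 - 1) %/% 60
      r <- B - 5 - 3 - 60 * k - 1 # short line so header 2 starts at B-5 (0-based)
      h2 <- charToRaw(">spanning header crossing the block boundary right here\n")
      c(
        charToRaw(">h\n"),
        concat_raw(replicate(k, line("A", 59), simplify = FALSE)),
        line("C", r - 1), h2,
        concat_raw(replicate(20, line("G", 59), simplify = FALSE))
      )
    },
    line_spanning_block = {
      nb <- 2 * B %/% 70 * 70 + 35
      c(
        charToRaw(">x\n"),
        wrap_raw(
          with_seed(77L, NUC_RAW[sample.int(4L, nb, replace = TRUE)]),
          line_lengths(nb, 70L)
        )
      )
    },
    crlf = {
      x <- generate_fasta(corpus_spec(seed = 55L, n_records = 3L, total_bases = 3000))
      i <- which(x == as.raw(10L))
      out <- raw(length(x) + length(i))
      cr_pos <- i + seq_along(i) - 1L
      out[cr_pos] <- as.raw(13L)
      out[-cr_pos] <- x
      out
    },
    all_N = {
      nb <- B + B %/% 4
      c(charToRaw(">n\n"), wrap_raw(rep(as.raw(78L), nb), line_lengths(nb, 60L)))
    },
    binary = with_seed(1237L, as.raw(sample.int(256L, B %/% 4 + 1237, replace = TRUE) - 1L)),
    giant_header = c(
      charToRaw(">"), rep(charToRaw("h"), B + 100), as.raw(10L),
      line("A", 59), line("C", 59)
    ),
    width_change_mid_sequence = {
      s <- with_seed(99L, NUC_RAW[sample.int(4L, 1300L, replace = TRUE)])
      c(
        charToRaw(">w\n"),
        wrap_raw(s[1:600], line_lengths(600, 60L)),
        wrap_raw(s[601:1300], line_lengths(700, 70L))
      )
    }
  )
}

# minimal USTAR writer so tar inputs can be synthesized deterministically
tar_entry <- function(name, data) {
  h <- raw(512L)
  put <- function(s, off) {
    b <- charToRaw(s)
    h[off + seq_along(b)] <<- b
  }
  put(name, 0L)
  put(sprintf("%07o", 420L), 100L) # mode 0644
  put(sprintf("%07o", 0L), 108L)
  put(sprintf("%07o", 0L), 116L)
  put(sprintf("%011o", length(data)), 124L)
  put(sprintf("%011o", 0L), 136L)
  put("        ", 148L) # checksum computed over spaces
  h[157L] <- charToRaw("0") # regular file
  put("ustar", 257L)
  put("00", 263L)
  chk <- sum(as.integer(h))
  put(sprintf("%06o", chk), 148L)
  h[155L] <- as.raw(0L)
  h[156L] <- charToRaw(" ")
  pad <- (512L - length(data) %% 512L) %% 512L
  c(h, data, raw(pad))
}

#' Generate a tar archive of synthetic FASTA files
#'
#' Concatenates USTAR entries (one per spec) plus the terminating zero
#' blocks -- a byte-accurate tar stream built deterministically, used to
#' check that compression still works well on tar'ed FASTA collections.
#'
#' @param specs List of [corpus_spec()]s, one per member file.
#' @return Raw vector: the tar archive bytes.
#' @export
generate_tar_like <- function(specs) {
  entries <- lapply(seq_along(specs), function(i) {
    tar_entry(sprintf("rec%03d.fa", i), generate_fasta(specs[[i]]))
  })
  c(concat_raw(entries), raw(1024L))
}

#' Write a corpus to disk with a JSON manifest
#'
#' Generates each spec, writes the FASTA files into `dir`, and records
#' spec fields plus a CRC-32 digest of every file in
#' `manifest.json`.
#'
#' @param specs List of [corpus_spec()]s.
#' @param dir Output directory (created if needed).
#' @return (Invisibly) the manifest as a list.
#' @export
write_corpus <- function(specs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(specs), function(i) {
    x <- generate_fasta(specs[[i]])
    f <- sprintf("corpus%03d.fa", i)
    writeBin(x, file.path(dir, f))
    c(list(file = f, bytes = length(x), crc32 = fa_crc32(x)),
      unclass(specs[[i]]))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(entries)
}
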