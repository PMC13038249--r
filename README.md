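# fastapack

Block-based lossless compression of FASTA files — and of arbitrary byte
streams — for people who move genomes around: sequence archives,
pipelines that read and write FASTA constantly, and collections of
near-identical genomes (virus strains, assemblies) where
general-purpose compressors leave most of the redundancy on the table
or take minutes to find it.

## The method

The input is processed in fixed-size blocks (default *B* = 4 MiB; the
last block may be shorter). Each block is parsed into four kinds of
content:

- **DNA** — runs containing only `A`, `C`, `G`, `T` after uppercasing,
  detected 8 bytes at a time with word-parallel (SWAR) bit tests and
  rounded down to a multiple of 8. Packed at 2 bits per base.
- **NNN** — runs of `N` (assembly gaps). Only their lengths are kept;
  the payload is zero bytes.
- **MIX** — everything else in the sequence body (IUPAC ambiguity
  codes, protein letters, stray bytes), kept verbatim.
- **RAW** — header lines and any line break that does not fit the
  block's wrapping model, copied byte-for-byte.

Regular line wrapping is modelled by a single per-block line length
(the distance between successive EOLs); conforming EOLs are removed
and re-inserted on decompression, while an inconsistent suffix keeps
its EOLs verbatim. Soft-masking survives as a one-bit-per-symbol
lowercase mask. Everything reconstructs bit-exactly: non-FASTA input
simply degenerates to MIX/RAW, so the tool is lossless on *any* bytes
(tar archives of FASTA included).

Streams are then optionally passed through zstd (level 1,
long-distance matching, window log 22). Metadata, RAW, MIX and the
case-flag mask always are (with a store-uncompressed escape so no
stream ever grows); the dominant packed-DNA stream is **probed once**,
on the first block(s) with at least 4 KiB of packed DNA: only if trial
compression shrinks it by at least a factor 1.25 is the backend applied
to the DNA stream of the whole archive. Redundant collections therefore
collapse multi-fold, while the essentially incompressible packed DNA of
a single genome skips the extra pass entirely.

Blocks obey a scheduling contract (block *i* may not start before
block *i − t* has finished, records are written in index order), and
archives are a pure function of input and configuration — the worker
count never changes a byte. Every block record decodes independently,
which is what makes parallel decompression possible. The container
layout is specified byte-exactly in [`docs/FORMAT.md`](docs/FORMAT.md).

## Worked example

```r
library(fastapack)

# a synthetic 100 kb soft-masked genome with N-runs, wrapped at 60
x <- generate_fasta(corpus_spec(seed = 42, n_records = 2, total_bases = 100000,
                                softmask_rate = 0.002, n_run_rate = 0.001))
s <- fa_compress(x, config = pipeline_config(block_size = 65536))
s
#> blocks: 2  input: 101710 B  archive: 22789 B  ratio: 4.463  dna_backend: FALSE  probe_ratio: 0.999

fa_inspect(s$archive)$segments
#>   type n_segments total_symbols
#> 1  DNA         80         83496
#> 2  NNN         74         15376
#> 3  MIX        140          1128

identical(fa_decompress(s$archive)$data, x)
#> [1] TRUE
```

Read it as: the two 64 KiB blocks held 83,496 DNA symbols (packed to
2 bits each), 15,376 `N`s (stored as 74 run lengths, zero payload), and
1,128 mixed symbols kept verbatim; EOL removal plus packing gives a
4.46× reduction. The probe ratio of 0.999 says trial zstd could not
shrink the packed random-ish DNA, so the backend stayed off for the DNA
stream. On a redundant collection (e.g. 200 near-identical 20 kb
genomes) the same probe reports a ratio around 46, turns the backend
on, and the archive lands near 165× smaller than the input.

A command-line wrapper is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fastapack", package = "fastapack"))')
Rscript "$CLI" compress genome.fa genome.fpk -b 4M
Rscript "$CLI" decompress genome.fpk roundtrip.fa
Rscript "$CLI" verify genome.fpk
Rscript "$CLI" inspect genome.fpk
```

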