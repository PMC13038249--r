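---
title: "Block-based FASTA compression: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based FASTA compression: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastapack)
```

## The model

FASTA is text: a `>` header line followed by sequence lines, usually of
one fixed width, over a tiny alphabet dominated by `A`, `C`, `G`, `T`,
with `N` gap runs and lowercase soft-masking. `fastapack` exploits
exactly these regularities and nothing else — there is no statistical
modelling of the sequence itself. Three transforms carry the whole
ratio:

1. **2-bit packing.** Runs of pure `ACGT` (after uppercasing) cost 2
   bits per base instead of 8. Runs are found on a fixed 8-byte word
   grid with single-instruction-per-word bit tests, so DNA and N-run
   lengths are always multiples of 8; sub-word remainders fall into the
   verbatim MIX class. The grid costs at most 7 + 7 symbols of
   "lost" packing per run boundary — negligible for genome-scale runs —
   and buys branch-free classification.
2. **EOL removal.** One line length per block, measured as the distance
   between the first two EOLs of the block's first sequence region.
   Conforming EOLs are deleted and reconstructed arithmetically from
   three integers per sequence record (symbol count, first span,
   EOL count). Any non-conforming EOL ends the record and is stored
   verbatim, so irregular wrapping costs ratio, never correctness.
3. **N-run and case extraction.** N-runs store lengths only; letter
   case is one flag bit per symbol (packed LSB-first, padded per
   block), so soft-masking survives without doubling the alphabet.

Everything that fits none of these classes is copied raw. That single
fallback makes the compressor total: arbitrary binary input parses as
MIX/RAW and round-trips bit-exactly, which the test suite fuzzes
aggressively.

A fourth, optional transform is general-purpose: streams are handed to
zstd (level 1, long-distance matching). For metadata, RAW, MIX and
flags this is always worthwhile or harmless (a store-uncompressed
escape is taken per stream when compression would enlarge it). For the
packed DNA stream — usually the bulk of the archive — it is decided
once per archive by a probe.

## The probe

Packed DNA of a single genome is close to incompressible, and running
zstd over it would only cost time; packed DNA of a redundant
collection (virus strains, repeated assemblies) still collapses
multi-fold. The probe distinguishes the two cases empirically: compress
the packed DNA of the earliest block(s) once, and enable the backend
for the whole archive iff

$$\frac{\text{packed size}}{\text{compressed size}} \ge 1.25 .$$

The comparison is inclusive at exactly 1.25. The probe needs material
to be meaningful, so if the first block yields under 4 KiB of packed
DNA the sample accumulates across subsequent blocks until 4 KiB is
reached; if the whole input never reaches the floor the decision
defaults to off. Blocks are buffered only while the decision is
pending, so the header can be written once. The decision is recorded in
the archive header and applied uniformly — every block's DNA stream
flag equals it, which keeps decoding branch-free and is asserted as an
invariant in the tests.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `block_size` | 4 MiB | unit of independent processing; power of two, 64 KiB–1 GiB. Smaller blocks localize corruption and enable finer parallelism but pay ~30–60 B of record overhead and lose cross-block matches; larger blocks do the opposite. |
| `threads` | 4 | width *t* of the scheduling contract (block *i* waits for block *i − t*). Output bytes never depend on it. |
| `probe_threshold` | 1.25 | reduction factor the DNA probe must reach (inclusive). |
| `backend` level / LDM / window_log | 1 / on / 22 | zstd profile; window log 22 covers the default block so long-distance matching sees the whole block. |
| `checksum` | on | CRC-32 of each block's original bytes; costs 4 B per block, localizes corruption to a block index. |
| `dna_backend` | `NULL` | probe override for testing and forced modes. |

## Degenerate inputs and tie-breaks

- *Empty input* → a 28-byte header-only archive decoding to zero bytes.
- *No EOL in a block* → line length 0; no EOL removal, all EOLs (there
  are none) moot; content still splits into DNA/NNN/MIX.
- *A sole EOL* → the line length is the distance from the region start
  to it, which makes single-line records reconstruct exactly.
- *Header spanning a block boundary* → the boundary scan reads the
  previous block backwards; a `>` met before any EOL flags header
  context and the remainder is copied raw. The scan is capped at one
  block: a header longer than *B* degrades to MIX/RAW content, still
  lossless.
- *`>` at byte 0 of a later block that starts mid-line* → treated as a
  header start (offset 0 counts as a line start). The classification
  may differ from the "true" FASTA reading, but reconstruction is
  byte-exact either way, which is the contract that matters.
- *CR bytes* — EOL is strictly 0x0A. CRLF files keep their CRs as MIX
  content; the 8-byte word containing a CR simply fails the ACGT test.
- *Corruption* — every error path names the failing block; stream size
  mismatches, varint overflows, truncation, bad magic and version are
  all distinct errors.

Two layout conventions were genuinely open and are fixed as follows:
bit order is LSB-first everywhere (2-bit codes and flag bits) and the
DNA code assignment is alphabetical (A=0, C=1, G=2, T=3) — arbitrary
but normative for the container (see `docs/FORMAT.md`). MIX payload is
stored in its *original* case with flag bits set only under DNA/NNN
segments: flagging MIX symbols would add up to ~0.5 bit/symbol of
irreducible flag entropy on non-FASTA input (lowercase-letter bytes
appear at ~10% rate in uniform bytes), violating the bounded-expansion
guarantee, while storing MIX verbatim loses nothing.

## The worker model

The scheduling contract — block *i* may not start before block *i − t*
finishes, records emitted in index order — is what the format and the
tests pin down; it guarantees the previous block's bytes are available
for the boundary scan and bounds look-back memory to *t* blocks. The
executor in this package is serial, which satisfies the contract for
every *t ≥ 1*; a concurrent executor would be a drop-in replacement
precisely because archives are already defined to be independent of
*t* (ordered write-out was chosen over completion-order write-out to
keep archives reproducible and therefore testable). Compression and
decompression currently assemble the archive in memory, which is
comfortable at the multi-megabyte scale the package targets.

## What the synthetic generator does and does not emulate

`corpus_spec()`/`generate_fasta()` produce, deterministically per
seed, the structural features the compressor keys on: multi-record
files, fixed/per-record/irregular wrap widths, header length, GC
content, geometric soft-mask and N runs (laid out non-overlapping so
realized lengths keep the sampled distribution), IUPAC ambiguity
symbols, protein records, missing trailing newlines, and redundant
collections (one base genome, many copies with independent
substitution mutations). `generate_tar_like()` wraps corpora in real
USTAR entries; `generate_adversarial()` builds targeted pathologies
(block-spanning headers and lines, CRLF, all-N, giant headers, width
changes, binary, empty).

What it does *not* emulate: biological repeat families, chromosome
structure, indels in redundant copies, quality data, or realistic
header grammars. Passing the fuzz suite therefore demonstrates
*losslessness and format correctness* on the structural envelope of
real FASTA, and ratio behaviour on idealized inputs; it does not
predict ratios on real genomes, where repeat content and masking
patterns differ.

## Test and script problem sizes

The suite fuzzes ~1,070 synthetic FASTA fixtures (mostly 1–25 kB,
ten ≥ 220 kB for multi-block coverage), 100 binary blobs and all nine
adversarial kinds, each at block sizes 64 KiB / 1 MiB / 4 MiB and
worker counts 1 and 4; word-level classifiers are checked against
naive per-byte oracles on 10^6 random words plus adversarial-alphabet
words. Ratio properties use an 8 MiB random-ACGT FASTA (2-bit bound
≈ 61/15 ≈ 4.07 with EOL removal; measured ratio must exceed 3.8), an
8 MiB all-N file (archive ≤ 10 KiB), and a 200-copy 20 kb collection
at 0.1% mutation (probe on, ratio pinned near the package's own first
measured value). These sizes were chosen to exercise every multi-block
code path while keeping the default test run fast.

## Known limitations

- Whole-archive memory residency during (de)compression; no streaming
  sink yet.
- One line length per block: files that interleave wrap widths at fine
  grain pay ratio (EOLs kept raw), as do protein files (no packing —
  MIX plus backend only).
- No random access below block granularity, no encryption, no
  dictionary training, and no byte compatibility with other FASTA
  archive formats.
- The 8-byte grid forgoes up to 14 packable symbols per run boundary
  by design.
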