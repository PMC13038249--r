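# Archive container format, version 1

Normative byte-level layout of the `fastapack` archive. All multi-byte
integers are little-endian. "varint" means unsigned LEB128: seven value
bits per byte, least-significant group first, high bit set on every
byte except the last; values are limited to 32 bits and decoders must
reject longer encodings (varint overflow).

An archive is:

    ArchiveHeader (28 bytes)
    BlockRecord * n_blocks        (strictly in block-index order)

## ArchiveHeader

| offset | size | field                                            |
|-------:|-----:|--------------------------------------------------|
|      0 |    4 | magic `46 50 41 4B` ("FPAK")                     |
|      4 |    1 | format_version (= 1)                             |
|      5 |    1 | flags: bit 0 = dna_backend, bit 1 = crc32        |
|      6 |    1 | backend level (zstd compression level)           |
|      7 |    1 | backend window_log                               |
|      8 |    1 | backend long-distance matching (0/1)             |
|      9 |    3 | reserved, zero                                   |
|     12 |    4 | u32 block_size (power of two, 64 KiB .. 1 GiB)   |
|     16 |    8 | u64 input_size (total decompressed length)       |
|     24 |    4 | u32 n_blocks                                     |

`dna_backend` records the archive-wide probe decision; every block's
DNA stream carries the matching compressed flag. An empty input is a
bare header with `input_size = 0`, `n_blocks = 0`.

## BlockRecord

| size | field                                                         |
|-----:|---------------------------------------------------------------|
|    4 | u32 original_length (this block's decompressed byte count)    |
|    1 | presence bitmask (bit *s* = stream *s* present)               |
|    1 | compressed bitmask (bit *s* = stream *s* is a zstd frame)     |
|    4 | u32 crc32 of the block's original bytes (iff header bit 1)    |
|  ... | per present stream, in order: u32 uncompressed_length,        |
|      | u32 stored_length, then stored_length payload bytes           |

Stream order (bit positions 0..4): **metadata, raw, dna, mix, flags**.
Metadata comes first because the decoder needs it to interpret the
rest. A stream whose uncompressed length is zero is absent (presence
bit 0, nothing stored). Compressed streams are standard zstd frames
with the content-size field set; stored (uncompressed) streams appear
when compression would not shrink them — the store-uncompressed escape
that bounds archive expansion.

Every block record is self-contained: together with the header it
decodes to exactly `original_length` bytes, independently of all other
blocks (parallel decompression).

## Metadata stream (after decompression)

A flat varint sequence:

    line_length
    n_records
    per record:
        kind (0 = RAW, 1 = SEQ)
        RAW:  byte_length
        SEQ:  n_symbols  first_span  n_eols_removed
    n_segments
    per segment:
        type (0 = DNA, 1 = NNN, 2 = MIX)
        length

Invariants a decoder must verify:
`sum(RAW byte_length) + sum(SEQ n_symbols + n_eols_removed) ==
original_length`; `sum(segment length) == sum(SEQ n_symbols)`;
DNA/NNN segment lengths are multiples of 8; NNN segments have no
payload anywhere (their lengths here are the run-length code).

## Stream payloads

- **raw** — verbatim bytes of RAW records (headers including their
  trailing EOL, plus non-conforming EOL bytes), concatenated in record
  order.
- **dna** — 2-bit packed nucleotides of DNA segments in segment order.
  Code assignment A=0, C=1, G=2, T=3; symbol *j* of the stream occupies
  bits `2*(j mod 4)` and `2*(j mod 4)+1` of byte `j div 4` (first
  symbol in the least-significant bits). Uncompressed length is
  `sum(DNA segment lengths) / 4` exactly.
- **mix** — MIX segment bytes verbatim, original case, in segment
  order.
- **flags** — one bit per sequence symbol (over all SEQ records of the
  block, in symbol order), bit *i* stored LSB-first in byte `i div 8`;
  set bits mark symbols that were ASCII lowercase in the input and are
  only ever set under DNA/NNN segments (MIX is stored in original
  case). Padded with zero bits to a whole byte per block.

## Reconstruction

Replay records in order. RAW records copy from the raw stream. A SEQ
record emits `n_symbols` symbols drawn from the segment sequence (DNA
from the unpacked dna stream, NNN as `N` bytes, MIX from the mix
stream), lowercasing a symbol when its flag bit is set, and inserts an
EOL (0x0A) after `first_span` symbols and then after every
`line_length` symbols until `n_eols_removed` EOLs have been emitted.
EOL is strictly 0x0A; 0x0D is ordinary content.
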