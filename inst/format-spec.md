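# The fastar archive format, version 1

A fastar archive is a **raw container** compressed with a **seekable zstd
frame store**. All multi-byte integers are little-endian. Offsets and
lengths are 64-bit unsigned ("u64"); lengths of short variable fields are
32-bit unsigned ("u32"). Raw-container offsets remain valid after
compression because every read is translated through the seek table.

## Outer layer: seekable zstd

The on-disk file is a sequence of independent zstd frames followed by one
skippable frame holding the seek table, exactly as in the public zstd
seekable format:

```
[zstd frame 1] ... [zstd frame k]
0x184D2A5E u32      skippable frame magic
size       u32      = 8*k + 9
k times:
  compressed_size   u32
  uncompressed_size u32
k          u32      seek table footer: frame count
descriptor u8       0x00 (no per-frame checksums)
0x8F92EAB1 u32      seekable magic
```

Every frame holds `frame_size` uncompressed bytes (default 1 MiB; minimum
4096), except the last, which may be shorter. Any stock zstd decoder
decompresses the whole file; the seek table enables ranged reads.

## Raw container

```
Block 1 - header (14 bytes)
  magic            4 bytes  "FArc"
  version          u8       1
  flags            u8       bit0 complete, bit1 contains_rna,
                            bit2 contains_protein
  seq_header_ptr   u64      offset of block 3 (0 while incomplete)

Block 2 - per-sequence data, one entry per record, in FASTA order
  payload          ceil(length * bits / 8) bytes, bit-packed
  md5              16 bytes (CRAM/BAM-compatible digest of the
                            uppercased rendered sequence)

Block 3 - per-sequence headers (at seq_header_ptr)
  n_records        u64
  n_records times:
    name_len u32, name bytes (UTF-8, no whitespace)
    desc_len u32, description bytes (may be empty)
    alphabet u8   0 = NUC2 (2-bit), 1 = NUC4 (4-bit), 2 = PROT5 (5-bit)
    rna_flag u8   render U instead of T on decode
    length   u64  symbol count
    data_ptr u64  offset of this record's payload in block 2
    n_block_count u64, then (start u64, length u64) per N run
    m_block_count u64, then (start u64, length u64) per soft-mask run

Block 4 - metadata trailer
  crc32            4 bytes: CRC32 (zlib polynomial) of every preceding
                   raw-container byte, stored in digest hex order
```

Run-block starts are 0-based; runs are maximal, sorted and
non-overlapping. N-blocks appear only for 2-bit sequences (N has an
in-band code in the 4-bit alphabet); the payload packs the placeholder
base A under each N run. Soft-mask (lowercase) information lives only in
the m-blocks — the payload is case-free.

## Symbol code tables (most-significant-bits-first packing)

* **NUC2** (2 bits): A=0, C=1, G=2, T/U=3.
* **NUC4** (4 bits): A,C,G,T/U,R,Y,S,W,K,M,B,D,H,V,N = 0..14; 15 reserved.
* **PROT5** (5 bits): the 20 standard amino acids in alphabetical order
  (A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y = 0..19), then B=20, Z=21,
  X=22, J=23, U=24, O=25, `*`=26, `-`=27; 28..31 reserved.

T and U share one code; the per-sequence `rna_flag` selects the rendered
letter. 5-bit codes cross byte boundaries as a contiguous bit stream.

## Two-phase conversion

During conversion a compressed image with `complete = 0` and
`seq_header_ptr = 0` is on disk while data blocks are produced. The
finalized container (pointer patched, flag set, CRC32 appended) then
atomically replaces it. Readers must refuse sequence data access — but may
report metadata — when `complete = 0`.
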