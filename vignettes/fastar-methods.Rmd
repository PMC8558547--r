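---
title: "Inside fastar: the archive model, its guarantees, and how they are tested"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside fastar: the archive model, its guarantees, and how they are tested}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

FASTA is the lingua franca for polymeric sequence data, but it is large,
carries no integrity information, and needs side-car files — the `.fai`
index for random access and the `.dict` sequence dictionary for
CRAM/GATK/Picard-style tooling — that must be regenerated whenever the
FASTA changes and silently go stale when they are not. General-purpose
compressors fix the size problem but break random access and the side-car
workflow entirely.

`fastar` treats the archive as the single source of truth and derives
everything else from it on demand. The FASTA text, its fai index, the
sequence dictionary and a UCSC TwoBit image are all *pure functions* of
the archive (plus a line width), so they cannot drift out of sync — there
is simply no stored copy to go stale. Random access is preserved because
the archive is compressed in independently decodable frames behind a seek
table.

```{r}
library(fastar)
```

## The encoding model

Each sequence is classified into the narrowest of three alphabet classes
and bit-packed accordingly:

| class | bits/symbol | covers |
|-------|-------------|--------|
| `NUC2` | 2 | plain DNA/RNA over A, C, G, T or U, N |
| `NUC4` | 4 | the 15-letter IUPAC nucleotide code |
| `PROT5` | 5 | 20 amino acids + B, Z, X, J, U, O, `*`, `-` |

Three pieces of information are deliberately stored *outside* the packed
payload:

* **Case (soft-masking).** Lowercase runs are kept as run-length
  `(start, length)` mask blocks; the payload is case-free. This is what
  makes "masking virtually disabled" possible: rendering uppercase costs
  nothing because case was never in the payload to begin with.
* **N runs in 2-bit sequences.** Two bits cannot represent five symbols,
  so N runs are recorded as N-blocks and a placeholder base (A) is packed
  in their place. The 4-bit alphabet has an in-band code for N.
* **T versus U.** Both letters share one code; a per-sequence RNA flag
  chooses the rendered letter. A nucleotide sequence mixing T and U is
  rejected at encode time: it could not be reconstructed byte-exactly,
  and silently rewriting one letter into the other would corrupt data —
  we considered classifying such input as IUPAC instead, and chose the
  loud error because round-trip fidelity is the format's core promise.
  (T and U are distinct residues in the protein alphabet and unaffected.)

```{r}
p <- encode_sequence("toy", "acgtNNNNacGT")
p
decode_subsequence(p, 0, p$length)                    # byte-exact round trip
decode_subsequence(p, 2, 10, apply_mask = FALSE)      # ranged, mask off
```

Symbol code tables and the MSB-first bit order are fixed and documented in
`inst/format-spec.md`. The container layout is our own (the field has no
standard here); byte-level compatibility with other archive tools is not
claimed, while the *views* (FASTA, fai, dict, TwoBit) are standard formats
checked against independent readers.

## The container and its integrity story

The raw container is: a 14-byte header (magic, version, flags, pointer to
the sequence-header block), per-sequence payloads each followed
immediately by a 16-byte MD5, the sequence-header block, and a CRC32
trailer over everything before it.

Two integrity mechanisms serve different questions:

* **CRC32 (whole file).** "Is this file exactly what was written?" —
  cheap, detects any byte-level damage, verified by `archive_crc32()` or
  `fastar check`.
* **Per-sequence MD5 (CRAM/BAM convention).** The digest of the
  uppercased, whitespace-free sequence — the `M5` tag convention used to
  identify reference sequences across the SAM/CRAM ecosystem. Deep
  verification (`verify_archive(deep = TRUE)`, `fastar check --md5`)
  recomputes it per sequence and therefore *localizes* corruption to a
  sequence rather than merely detecting it. For 2-bit sequences the
  digest is computed over the rendered symbols (N restored, RNA rendering
  applied, mask off), never over the placeholder bases — otherwise the
  stored digest would not match what `samtools dict` computes for the
  rendered FASTA and CRAM interoperability would break.

Conversion is two-phase: while payloads are being written, the on-disk
image carries `complete = FALSE`; the finalized archive (pointers patched,
CRC appended) atomically replaces it. An interrupted conversion is
therefore always detectable, and `open_archive()` refuses data access to
incomplete files while still allowing metadata inspection. The transient
phase-1 image is compressed at a fast zstd level since it exists only for
the duration of the conversion; the final image uses the configured level.

## Seekable compression and the cost model

The whole raw container is compressed as a series of independent zstd
frames (default 1 MiB of raw bytes each, configurable; minimum 4 KiB)
followed by a seek-table skippable frame, following the public zstd
seekable format — a stock zstd decoder decompresses an archive as-is.
Serving `length` bytes from raw coordinates can touch at most
`floor(length / frame_size) + 2` frames, so the work of a ranged read is
proportional to the request plus at most two boundary frames, not to the
archive size. `decompress_range()`, `render_fasta_range()` and
`extract_region()` all report `frames_touched` so this contract is
testable, and the test suite asserts it over thousands of random requests.

Two consequences of frame independence are worth knowing:

* Compression ratio degrades slightly as frames shrink (less context per
  frame), and redundancy *between* distant frames is invisible to the
  compressor. The default of 1 MiB frames at zstd level 19 favours ratio
  for write-once/read-many archives while keeping worst-case read
  latency bounded; neither value is sacred, both are per-archive options.
* A corrupted compressed byte destroys (at most) one frame, which deep
  verification then pins to the sequences overlapping that frame.

## The virtual views

`render_fasta()` produces the canonical FASTA rendering: `>` + name
(+ description) per record, sequence wrapped at a configurable width
(default 60 — the original wrapping of the cached file is deliberately not
stored, so the virtual file is deterministic), every line
newline-terminated. `fai_entries()` computes the samtools-style index for
exactly that rendering, and the suite checks `samtools faidx` emits the
identical index. `dict_entries()` emits the SAM header with `SN/LN/M5/UR`
tags; `export_twobit()` re-packs 2-bit DNA into the UCSC TwoBit layout
(refusing RNA/IUPAC/protein records, which TwoBit cannot represent).
Region strings follow samtools semantics: 1-based inclusive, commas
stripped, a lone name meaning the whole sequence, an exact name match
taking precedence over coordinate parsing, and an out-of-range end clamped
to the sequence end.

```{r}
fx <- generate_fasta(seed = 42, n_records = 2, length_range = c(90, 140),
                     alphabet = "NUC2", n_fraction = 0.05, mask_fraction = 0.2)
ar <- tempfile(fileext = ".far")
write_archive(lapply(fx$records, \(r) list(name = r$name, symbols = r$symbols)),
              ar, level = 3)
h <- open_archive(ar)
cat(format_fai(fai_entries(h, 60)))
cat(dict_entries(h, uri = "file:///data/toy.fa"))
extract_region(h, "seq2:5-25")
```

## What the synthetic data does and does not cover

`generate_fasta()` is the package's study-condition generator: seeded,
pure in its spec, returning ground truth (symbols plus exact N- and
mask-run blocks) alongside the text. N and mask runs follow an
alternating geometric model with mean run length 50 — long enough that
runs regularly span compression-frame boundaries (the hard case for
overlay logic), short enough that many runs occur per record. IUPAC and
protein records guarantee at least one symbol outside the narrower
alphabet so a fixture always encodes in the class it was asked for.

What it does **not** emulate: real genome structure — repeat families, GC
skew, chromosome-scale N gaps at telomeres/centromeres, or realistic name
conventions. Passing tests therefore demonstrate format correctness
(round-trips, index arithmetic, digests, bounded-work reads) on
realistic *statistics* of masking and ambiguity, not biological realism,
and say nothing about compression ratios on real genomes beyond the
qualitative sanity checks below.

## Problem sizes and numerical choices

The test and acceptance workloads use sizes chosen to exercise every code
path at desk scale: 1000-symbol sequences for the bits-per-symbol
constants; a 1000-record archive for MD5 byte accounting; 100 seeded
fixtures across alphabets for round-trips and fai/dict conformance; 1000
random regions against a 10 Mbp, 64 KiB-frame archive for the
bounded-work contract; 100 random single-byte corruptions plus 20
truncation points for integrity; and a 5 Mbp DNA fixture with 20%
duplicated segments for the compression sanity check (the archive must
beat gzip of the FASTA and stay at or under 30% of the raw text — at 2
bits per base the payload alone is 25%, so this mostly guards against
container overhead regressions).

Remaining numerical conventions: coordinates are held as R doubles
(exact to 2^53, far beyond any sequence length); empty ranges are legal
everywhere and return empty results; degenerate inputs (empty sequence,
whitespace in names, duplicate record names) are hard errors at encode
time; ties do not arise because all run lists are maximal and sorted by
construction.

## The CLI and the mount question

`run_cli()` (and the `inst/cli/fastar` wrapper) exposes cache / view /
info / check / list / ps / mount over a plain-text user registry
(`$FASTAR_CONFIG_DIR` overrides the location; writes are atomic; mount
records with dead process ids are pruned on load). A FUSE mount layer
would make the views available as literal files, but no maintained FUSE
binding exists for R, so `mount` fails with a clear message pointing at
the equivalent library calls; everything else is fully functional without
it. This is the one part of the toolkit surface that is interface-only.

## Known limitations

* Archives are write-once: there is no in-place append or update, by
  design (the views' sync guarantee assumes immutable content).
* A nucleotide sequence mixing T and U is rejected rather than widened to
  the IUPAC class (see above).
* Frame-independent compression cannot exploit redundancy between distant
  frames; whole-file ratio is traded for random access.
* TwoBit export is limited to what TwoBit can express: DNA only, and
  sequence offsets within the 32-bit limits of that format.
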