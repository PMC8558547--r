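# fastar

Bit-packed, seekable-compressed FASTA archives with always-in-sync
virtual views, for R.

## The problem

FASTA files are the standard carrier for DNA, RNA and protein sequences,
and most tooling around them needs more than the text itself: random
access requires a `.fai` index, CRAM/GATK/Picard-style tools require a
`.dict` sequence dictionary with per-sequence MD5 (`M5`) identifiers, and
none of this survives ordinary compression — gzip breaks random access,
and the side-car files silently go stale whenever they are regenerated
against the wrong FASTA.

`fastar` stores sequences in a single archive that is both small and
randomly accessible, and treats every derived artefact as a view computed
from the archive on demand:

* **Encoding.** Each sequence is packed at 2 bits/symbol (plain DNA/RNA),
  4 bits (IUPAC nucleotide) or 5 bits (protein). Soft-mask case and N
  runs are stored as run-length blocks outside the payload, so masking
  can be "virtually disabled" for free and 2-bit packing survives Ns.
* **Compression.** The whole container is compressed as independent zstd
  frames plus a seek table (the public zstd seekable format). Reading
  `L` bytes touches at most `floor(L / frame_size) + 2` frames — cost is
  proportional to the request, not the archive.
* **Integrity.** Every sequence carries the CRAM/BAM-compatible MD5 of
  its rendered symbols (`M5` convention: uppercased, whitespace-free);
  the file ends in a CRC32 over the whole container. Deep verification
  localizes corruption to the affected sequence.
* **Views.** FASTA text (any line width), the samtools `fai` index for
  exactly that rendering, the SAM `.dict` header, UCSC TwoBit (DNA-only
  archives), and samtools-style region extraction
  (`chr1:1,001-2,000`, 1-based inclusive) — all derived, never stored,
  therefore never out of sync.

The byte-level container layout is documented in
[`inst/format-spec.md`](inst/format-spec.md).

## Worked example

```r
library(fastar)

# a reproducible two-record DNA fixture with Ns and soft-masked runs
fx <- generate_fasta(seed = 42, n_records = 2, length_range = c(90, 140),
                     alphabet = "NUC2", n_fraction = 0.05, mask_fraction = 0.2)
fa <- tempfile(fileext = ".fa"); writeBin(charToRaw(fx$fasta), fa)

ar <- tempfile(fileext = ".far")
write_archive(read_fasta(fa), ar)
#> <archive_summary> /tmp/...far
#>   2 sequence(s); raw container 234 bytes -> 194 compressed (82.9%)
#>   name length alphabet   rna                              md5
#> 1 seq1    138     NUC2 FALSE ea7733e3c9df01f783cfb4f5e144ecc2
#> 2 seq2    131     NUC2 FALSE 24a9c7b88789cce240e6149de7d3b38f
```

Tiny fixtures barely compress (container overhead dominates); a 10 Mbp
chromosome-scale record archives to roughly a quarter of its FASTA size.
The summary lists, per record, the detected alphabet class and the
`M5`-convention digest that CRAM-aware tools will look up.

```r
h <- open_archive(ar)
cat(format_fai(fai_entries(h, 60)))
#> seq1	138	6	60	61
#> seq2	131	153	60	61
cat(dict_entries(h, uri = "file:///data/toy.fa"))
#> @HD	VN:1.6	SO:unsorted
#> @SQ	SN:seq1	LN:138	M5:ea7733e3c9df01f783cfb4f5e144ecc2	UR:file:///data/toy.fa
#> @SQ	SN:seq2	LN:131	M5:24a9c7b88789cce240e6149de7d3b38f	UR:file:///data/toy.fa
```

The fai columns are name, length, byte offset of the first sequence byte,
bases per line and bytes per line — valid for `render_fasta(h, 60)` by
construction, and byte-identical to what `samtools faidx` computes for
that rendering.

```r
extract_region(h, "seq2:5-25")
#> [1] "GAGCACTCCAGTCCAGGCGAG"
#> attr(,"frames_touched")
#> [1] 1

verify_archive(h, deep = TRUE)
#> <verification_report> CRC32 OK
#>   2/2 sequence digest(s) OK
#>   overall: PASS
```

`frames_touched` reports how many compression frames the read had to
decompress — the observable form of the bounded-work guarantee.

### Command line

```sh
fastar=$(Rscript -e 'cat(system.file("cli","fastar",package="fastar"))')
$fastar cache genome.fa --alias genome       # convert + register
$fastar view genome --padding 80 --no-mask   # FASTA to stdout, mask off
$fastar info genome                          # layout, sizes, MD5s
$fastar check genome --md5                   # CRC32 + per-sequence digests
$fastar list                                 # alias, count, format, ratio
```

Exit codes: 0 success, 1 usage/lookup error, 2 integrity failure.

## Scope

Archives are write-once by design. FASTQ/quality data, alignment formats
and a FUSE mount layer are out of scope (the `mount` subcommand explains
itself); the library and CLI cover the same functionality through ranged
views.
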