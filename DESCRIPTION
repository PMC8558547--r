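Package: fastar
Title: Bit-Packed Seekable-Compressed FASTA Archives with Virtual Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Archives FASTA sequence data (DNA, RNA, IUPAC nucleotide and
    protein) into a random-access container: sequences are packed at 2, 4
    or 5 bits per symbol with run-length encoded N and soft-mask blocks,
    every sequence carries a CRAM/BAM-compatible MD5 digest, the file
    carries a CRC32 integrity checksum, and the whole container is
    compressed into independently decodable zstd frames with a seek table
    so arbitrary byte ranges decompress in time proportional to the
    request. FASTA text, samtools fai index, SAM sequence dictionary and
    UCSC TwoBit views are derived from the archive on demand and are
    therefore always in sync; subsequences are addressable with
    samtools-style region strings. Includes a command-line tool for
    caching, viewing, inspecting and verifying archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
SystemRequirements: libzstd
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
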