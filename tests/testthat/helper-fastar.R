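# Shared helpers: fixtures are built in code at test time, nothing is
# downloaded or stored.

fixture_records <- function(fx) {
  lapply(fx$records, function(r)
    list(name = r$name, symbols = r$symbols, description = r$description))
}

# Write an archive for a fixture (modest zstd level: these are throwaway)
make_archive <- function(records, level = 3, frame_size = 2^20,
                         path = tempfile(fileext = ".far"), ...) {
  write_archive(records, path, frame_size = frame_size, level = level, ...)
  path
}

fixture_archive <- function(seed, ..., level = 3, frame_size = 2^20) {
  fx <- generate_fasta(seed, ...)
  list(fx = fx,
       path = make_archive(fixture_records(fx), level = level,
                           frame_size = frame_size))
}

random_raw <- function(n, seed = 1) {
  fastar:::with_seed(seed, as.raw(sample(0:255, n, replace = TRUE)))
}

# compressible raw bytes (text-ish, so zstd has something to do)
compressible_raw <- function(n, seed = 1) {
  fastar:::with_seed(seed, {
    chunk <- charToRaw(paste(sample(c("ACGT", "TTAGGG", "GATTACA", "CCCT"),
                                    2048, replace = TRUE), collapse = ""))
    rep_len(chunk, n)
  })
}

# Minimal independent TwoBit reader used as a conformance oracle for the
# exporter: follows the public file layout (little-endian signature
# 0x1A412743, index of name/offset pairs, per-record nBlocks, maskBlocks,
# 2-bit packed DNA with T=0,C=1,A=2,G=3).
read_twobit_oracle <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  u32 <- function(at) sum(as.integer(b[at + 1:4]) * 256^(0:3))
  stopifnot(u32(0) == 0x1A412743)
  n <- u32(8)
  at <- 16
  index <- list()
  for (i in seq_len(n)) {
    nl <- as.integer(b[at + 1])
    name <- rawToChar(b[at + 1 + seq_len(nl)])
    index[[name]] <- u32(at + 1 + nl)
    at <- at + 5 + nl
  }
  lapply(index, function(off) {
    at <- off
    dna_size <- u32(at); at <- at + 4
    nb <- u32(at); at <- at + 4
    n_starts <- if (nb) vapply(seq_len(nb) - 1, function(i) u32(at + 4 * i), 0) else numeric(0)
    at <- at + 4 * nb
    n_sizes <- if (nb) vapply(seq_len(nb) - 1, function(i) u32(at + 4 * i), 0) else numeric(0)
    at <- at + 4 * nb
    mb <- u32(at); at <- at + 4
    m_starts <- if (mb) vapply(seq_len(mb) - 1, function(i) u32(at + 4 * i), 0) else numeric(0)
    at <- at + 4 * mb
    m_sizes <- if (mb) vapply(seq_len(mb) - 1, function(i) u32(at + 4 * i), 0) else numeric(0)
    at <- at + 4 * mb
    at <- at + 4  # reserved
    packed <- b[at + seq_len(ceiling(dna_size / 4))]
    bits <- matrix(as.integer(rawToBits(packed)), nrow = 8)
    stream <- as.vector(bits[8:1, , drop = FALSE])
    codes <- drop(2^(1:0) %*% matrix(stream[seq_len(2 * dna_size)], nrow = 2))
    chars <- c("T", "C", "A", "G")[codes + 1]
    for (i in seq_along(n_starts)) {
      chars[n_starts[i] + seq_len(n_sizes[i])] <- "N"
    }
    for (i in seq_along(m_starts)) {
      idx <- m_starts[i] + seq_len(m_sizes[i])
      chars[idx] <- tolower(chars[idx])
    }
    paste(chars, collapse = "")
  })
}
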