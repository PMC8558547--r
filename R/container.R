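# The archive container. Raw layout (before seekable compression), all
# integers little-endian, offsets 64-bit; full byte-level description in
# inst/format-spec.md:
#
#   header        magic "FArc" | version u8 | flags u8 | seq_header_ptr u64
#   data blocks   per record: packed payload | 16-byte MD5
#   seq headers   n_records u64, then per record: name, description
#                 (u32-length-prefixed UTF-8), alphabet u8, rna u8,
#                 length u64, data_ptr u64, N-blocks and mask-blocks
#                 (count u64 + (start,length) u64 pairs)
#   trailer       CRC32 of everything above (4 bytes, digest hex order)
#
# The whole raw container is then compressed with the seekable zstd store;
# raw-coordinate pointers stay valid because every read is translated
# through the seek table. Conversion is two-phase: an image with the
# complete flag unset is written first, then the finalized archive
# atomically replaces it, so an interrupted conversion is always detectable.

ARCHIVE_MAGIC <- charToRaw("FArc")
ARCHIVE_VERSION <- 1L
HEADER_BYTES <- 14
FLAG_COMPLETE <- 1L
FLAG_RNA <- 2L
FLAG_PROTEIN <- 4L

.alpha_code_byte <- c(NUC2 = 0L, NUC4 = 1L, PROT5 = 2L)

crc32_raw <- function(r) {
  hex <- formatC(digest::digest(r, algo = "crc32", serialize = FALSE),
                 width = 8, flag = "0")
  as.raw(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
}

.header_raw <- function(complete, rna, protein, ptr) {
  flags <- (if (complete) FLAG_COMPLETE else 0L) +
    (if (rna) FLAG_RNA else 0L) + (if (protein) FLAG_PROTEIN else 0L)
  c(ARCHIVE_MAGIC, as.raw(ARCHIVE_VERSION), as.raw(flags), u64_to_raw(ptr))
}

.runs_raw <- function(runs) {
  c(u64_to_raw(nrow(runs)),
    if (nrow(runs) > 0L) u64_to_raw(as.vector(t(runs))) else raw(0))
}

.entry_raw <- function(p, data_ptr) {
  nm <- charToRaw(p$name)
  ds <- charToRaw(p$description)
  c(u32_to_raw(length(nm)), nm,
    u32_to_raw(length(ds)), ds,
    as.raw(.alpha_code_byte[[p$alphabet]]),
    as.raw(as.integer(p$rna_flag)),
    u64_to_raw(p$length),
    u64_to_raw(data_ptr),
    .runs_raw(p$n_blocks),
    .runs_raw(p$m_blocks))
}

# Accept a named character vector, a list of (name, symbols[, description])
# lists, or a list of packed_sequence objects.
normalize_records <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records)) || any(!nzchar(names(records))))
      stop("character `records` must be named by sequence")
    records <- Map(function(n, s) list(name = n, symbols = s),
                   names(records), unname(records))
  }
  lapply(records, function(r) {
    if (inherits(r, "packed_sequence")) return(r)
    encode_sequence(r$name, r$symbols,
                    description = if (is.null(r$description)) "" else r$description)
  })
}

#' Write a bit-packed, seekable-compressed sequence archive
#'
#' Encodes each record ([encode_sequence()]), lays out the container
#' (header, per-record payload each followed by its 16-byte MD5, sequence
#' header block, CRC32 trailer) and compresses it with the seekable zstd
#' store. The conversion is two-phase: a file whose `complete` flag is
#' unset exists on disk while data blocks are being produced, and the
#' finalized archive replaces it atomically, so a crash mid-conversion
#' leaves a detectably incomplete file rather than silently wrong data.
#'
#' @param records A named character vector of sequences, or a list of
#'   `list(name=, symbols=, description=)`, or a list of `packed_sequence`
#'   objects. Names must be unique.
#' @param out_path Output archive path.
#' @param frame_size Uncompressed bytes per compression frame (default 1 MiB).
#' @param level zstd level for the final archive (default 19).
#' @param .finalize Internal: `FALSE` stops after phase 1, simulating a
#'   conversion interrupted before the sequence headers are written.
#' @return An `archive_summary`: per-record name, length, alphabet and MD5,
#'   plus raw and compressed byte sizes.
#' @export
write_archive <- function(records, out_path, frame_size = 2^20, level = 19L,
                          .finalize = TRUE) {
  packed <- normalize_records(records)
  if (length(packed) == 0L) stop("at least one record is required")
  nms <- vapply(packed, `[[`, "", "name")
  if (anyDuplicated(nms))
    fastar_error(sprintf("duplicate sequence name '%s'", nms[duplicated(nms)][1L]),
                 "fastar_duplicate_name")
  rna <- any(vapply(packed, `[[`, FALSE, "rna_flag"))
  protein <- any(vapply(packed, `[[`, "", "alphabet") == "PROT5")

  data_ptrs <- numeric(length(packed))
  blocks <- vector("list", length(packed))
  at <- HEADER_BYTES
  for (i in seq_along(packed)) {
    data_ptrs[i] <- at
    blocks[[i]] <- c(packed[[i]]$payload, packed[[i]]$md5)
    at <- at + length(blocks[[i]])
  }
  data_raw <- do.call(c, c(blocks, list(raw(0))))

  # phase 1: incomplete image on disk (fast compression; it is transient)
  raw1 <- c(.header_raw(FALSE, rna, protein, 0), data_raw)
  writeBin(compress_stream(raw1, frame_size, level = 1L)$bytes, out_path)
  if (!.finalize) {
    return(.archive_summary(packed, out_path, length(raw1), frame_size,
                            complete = FALSE))
  }

  # phase 2: sequence headers, back-patched pointer, complete flag, CRC32
  seq_hdr <- c(u64_to_raw(length(packed)),
               do.call(c, c(Map(.entry_raw, packed, data_ptrs), list(raw(0)))))
  ptr <- HEADER_BYTES + length(data_raw)
  raw2 <- c(.header_raw(TRUE, rna, protein, ptr), data_raw, seq_hdr)
  raw2 <- c(raw2, crc32_raw(raw2))
  tmp <- tempfile(tmpdir = dirname(out_path), fileext = ".tmp")
  writeBin(compress_stream(raw2, frame_size, level = level)$bytes, tmp)
  file.rename(tmp, out_path)
  .archive_summary(packed, out_path, length(raw2), frame_size, complete = TRUE)
}

.archive_summary <- function(packed, path, raw_size, frame_size, complete) {
  structure(list(
    path = path,
    sequences = data.frame(
      name = vapply(packed, `[[`, "", "name"),
      length = vapply(packed, `[[`, 0, "length"),
      alphabet = vapply(packed, `[[`, "", "alphabet"),
      rna = vapply(packed, `[[`, FALSE, "rna_flag"),
      md5 = vapply(packed, function(p) md5_hex(p$md5), ""),
      stringsAsFactors = FALSE
    ),
    raw_size = raw_size,
    compressed_size = file.info(path)$size,
    frame_size = frame_size,
    complete = complete
  ), class = "archive_summary")
}

#' @export
print.archive_summary <- function(x, ...) {
  cat(sprintf("<archive_summary> %s%s\n", x$path,
              if (!x$complete) " [INCOMPLETE]" else ""))
  cat(sprintf("  %d sequence(s); raw container %s bytes -> %s compressed (%.1f%%)\n",
              nrow(x$sequences), format(x$raw_size), format(x$compressed_size),
              100 * x$compressed_size / x$raw_size))
  print(utils::head(x$sequences, 10))
  if (nrow(x$sequences) > 10) cat(sprintf("  ... %d more\n", nrow(x$sequences) - 10))
  invisible(x)
}

#' Open a sequence archive
#'
#' Validates the magic tag and format version, then loads the sequence
#' header block (names, lengths, alphabets, run-block indices, stored MD5s)
#' through ranged decompression; sequence payloads are never decoded at
#' open time. An archive whose conversion did not finish can be opened for
#' metadata inspection but refuses any data operation.
#'
#' @param path Path to an archive written by [write_archive()].
#' @return An `fastar_archive` handle.
#' @export
open_archive <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  idx <- seekable_index(path)
  cache <- new.env(parent = emptyenv())
  if (idx$raw_size < HEADER_BYTES)
    fastar_error("not an archive: container shorter than its header", "fastar_not_archive")
  hdr <- decompress_range_idx(idx, 0, HEADER_BYTES, cache)$bytes
  if (!identical(hdr[1:4], ARCHIVE_MAGIC))
    fastar_error("not an archive: magic tag mismatch", "fastar_not_archive")
  version <- as.integer(hdr[5])
  if (version != ARCHIVE_VERSION)
    fastar_error(sprintf("unsupported archive version %d", version), "fastar_version")
  flags <- as.integer(hdr[6])
  h <- new.env(parent = emptyenv())
  h$path <- path
  h$idx <- idx
  h$cache <- cache
  h$version <- version
  h$complete <- bitwAnd(flags, FLAG_COMPLETE) != 0L
  h$contains_rna <- bitwAnd(flags, FLAG_RNA) != 0L
  h$contains_protein <- bitwAnd(flags, FLAG_PROTEIN) != 0L
  h$seq_header_ptr <- raw_to_u64(hdr[7:14])
  h$records <- list()
  if (h$complete) h$records <- .parse_seq_headers(h)
  class(h) <- "fastar_archive"
  h
}

.parse_seq_headers <- function(h) {
  idx <- h$idx
  ptr <- h$seq_header_ptr
  if (ptr < HEADER_BYTES || ptr > idx$raw_size - 4)
    fastar_error("sequence header pointer outside container", "fastar_corrupt")
  block <- decompress_range_idx(idx, ptr, idx$raw_size - 4 - ptr, h$cache)$bytes
  cur <- 1L
  take <- function(n) {
    if (n == 0) return(raw(0))
    if (cur + n - 1L > length(block))
      fastar_error("sequence header block truncated", "fastar_corrupt")
    out <- block[cur:(cur + n - 1L)]
    cur <<- cur + as.integer(n)
    out
  }
  n_rec <- raw_to_u64(take(8))
  recs <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    name <- rawToChar(take(raw_to_u32(take(4))))
    desc <- rawToChar(take(raw_to_u32(take(4))))
    alpha <- names(.alpha_code_byte)[as.integer(take(1)) + 1L]
    rna <- as.integer(take(1)) != 0L
    len <- raw_to_u64(take(8))
    data_ptr <- raw_to_u64(take(8))
    read_runs <- function() {
      k <- raw_to_u64(take(8))
      if (k == 0) return(empty_runs())
      matrix(raw_to_u64(take(16 * k)), ncol = 2L, byrow = TRUE,
             dimnames = list(NULL, c("start", "length")))
    }
    nb <- read_runs()
    mb <- read_runs()
    bits <- unname(ALPHABETS[alpha])
    payload_bytes <- ceiling(len * bits / 8)
    if (data_ptr < HEADER_BYTES || data_ptr + payload_bytes + 16 > ptr)
      fastar_error(sprintf("data pointer for '%s' outside the data region", name),
                   "fastar_corrupt")
    md5 <- decompress_range_idx(idx, data_ptr + payload_bytes, 16, h$cache)$bytes
    recs[[i]] <- list(name = name, description = desc, alphabet = alpha,
                      bits_per_symbol = bits, rna_flag = rna, length = len,
                      data_ptr = data_ptr, payload_bytes = payload_bytes,
                      n_blocks = nb, m_blocks = mb, md5 = md5)
  }
  if (cur - 1L != length(block))
    fastar_error("trailing bytes after sequence header block", "fastar_corrupt")
  names(recs) <- vapply(recs, `[[`, "", "name")
  recs
}

#' @export
print.fastar_archive <- function(x, ...) {
  cat(sprintf("<fastar_archive> %s (version %d%s)\n", x$path, x$version,
              if (!x$complete) ", INCOMPLETE" else ""))
  if (x$complete) {
    for (r in utils::head(x$records, 10))
      cat(sprintf("  %s  %s %s%s  %s\n", r$name, format(r$length, big.mark = ","),
                  r$alphabet, if (r$rna_flag) "(RNA)" else "", md5_hex(r$md5)))
    if (length(x$records) > 10) cat(sprintf("  ... %d more\n", length(x$records) - 10))
  }
  invisible(x)
}

#' @export
length.fastar_archive <- function(x) length(x$records)

#' @export
names.fastar_archive <- function(x) {
  vapply(x$records, `[[`, "", "name", USE.NAMES = FALSE)
}

.require_complete <- function(handle) {
  if (!handle$complete)
    fastar_error("archive conversion did not finish (complete flag unset); refusing data access",
                 "fastar_incomplete")
}

archive_record <- function(handle, which) {
  .require_complete(handle)
  r <- if (is.numeric(which)) handle$records[[which]] else handle$records[[as.character(which)]]
  if (is.null(r))
    fastar_error(sprintf("no sequence named '%s' in archive", which), "fastar_lookup")
  r
}

# Decode symbols [start, end) of record `which` straight from the archive;
# only the payload bytes covering the range are decompressed.
archive_decode_range <- function(handle, which, start, end, apply_mask = TRUE) {
  r <- archive_record(handle, which)
  if (start < 0 || end > r$length || start > end)
    fastar_error(sprintf("range [%s,%s) outside '%s' of length %s",
                         format(start), format(end), r$name, format(r$length)),
                 "fastar_range_error")
  if (start == end) return(list(symbols = "", frames_touched = 0L))
  span <- payload_byte_span(start, end, r$bits_per_symbol)
  rr <- decompress_range_idx(handle$idx, r$data_ptr + span$first,
                             span$last - span$first, handle$cache)
  codes <- unpack_codes(rr$bytes, r$bits_per_symbol, span$bit_offset, end - start)
  list(symbols = render_codes(codes, r, start, end, apply_mask),
       frames_touched = rr$frames_touched)
}

#' Verify the whole-file CRC32 of an archive
#'
#' Recomputes the CRC32 checksum over the raw (uncompressed) container,
#' excluding the 4-byte trailer, and compares it with the stored value.
#'
#' @param path Archive path.
#' @return A list with `stored` and `computed` (4 raw bytes each) and
#'   `match`.
#' @export
archive_crc32 <- function(path) {
  idx <- seekable_index(path)
  if (idx$raw_size < HEADER_BYTES + 4)
    fastar_error("container truncated: no CRC32 trailer present", "fastar_truncated")
  raw <- decompress_range_idx(idx, 0, idx$raw_size)$bytes
  stored <- raw[(length(raw) - 3L):length(raw)]
  computed <- crc32_raw(raw[1:(length(raw) - 4L)])
  list(stored = stored, computed = computed, match = identical(stored, computed))
}

#' Read a FASTA file into archive-ready records
#'
#' Thin wrapper around `Biostrings::readBStringSet()` (so gzipped input and
#' arbitrary line wrapping are handled); the name is the header token before
#' the first whitespace, the remainder is kept as the description.
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return A list of `list(name, symbols, description)` records.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    hdr <- headers[i]
    name <- sub("[[:space:]].*$", "", hdr)
    desc <- if (grepl("[[:space:]]", hdr)) sub("^[^[:space:]]+[[:space:]]+", "", hdr) else ""
    list(name = name, symbols = as.character(set[[i]]), description = desc)
  })
}
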