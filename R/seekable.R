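# Seekable zstd store: a raw byte stream is split into fixed-size chunks,
# each compressed as an independent zstd frame, followed by a seek-table
# skippable frame per the public zstd seekable format:
#
#   [frame 1] ... [frame k]
#   [0x184D2A5E u32le][size u32le]             skippable frame header
#   [c_size u32le][d_size u32le] * k           seek table entries
#   [k u32le][descriptor u8][0x8F92EAB1 u32le] seek table footer
#
# Any stock zstd decoder decompresses the whole file (skippable frames are
# ignored); the seek table additionally maps raw offsets to frame
# boundaries so a byte range costs only the frames it overlaps.

SKIPPABLE_MAGIC <- 0x184D2A5E
SEEKABLE_MAGIC <- 0x8F92EAB1
SEEK_FOOTER_BYTES <- 9L

#' Compress a byte stream into independently seekable zstd frames
#'
#' @param raw A raw vector (the uncompressed stream).
#' @param frame_size Uncompressed bytes per frame (>= 4096); the last frame
#'   may be shorter. Default 1 MiB.
#' @param level zstd compression level (default 19; archives are
#'   write-once read-many, so ratio is favoured over speed).
#' @return An object of class `seekable_blob`: a list with `bytes` (the
#'   complete compressed file image), `frame_size` and `entries`, a
#'   two-column matrix of per-frame `(compressed_size, uncompressed_size)`.
#' @seealso [decompress_range()]
#' @export
compress_stream <- function(raw, frame_size = 2^20, level = 19L) {
  stopifnot(is.raw(raw))
  if (frame_size < 4096) stop("`frame_size` must be at least 4096 bytes")
  n <- length(raw)
  k <- if (n == 0L) 0L else as.integer(ceiling(n / frame_size))
  frames <- vector("list", k)
  entries <- matrix(numeric(0), ncol = 2L,
                    dimnames = list(NULL, c("compressed_size", "uncompressed_size")))
  for (i in seq_len(k)) {
    lo <- (i - 1) * frame_size + 1
    hi <- min(n, i * frame_size)
    fr <- .zstd_compress_frame(raw[lo:hi], as.integer(level))
    frames[[i]] <- fr
    entries <- rbind(entries, c(length(fr), hi - lo + 1))
  }
  table_body <- c(
    u32_to_raw(as.vector(t(entries))),
    u32_to_raw(k),
    as.raw(0L),                       # descriptor: no per-frame checksums
    u32_to_raw(SEEKABLE_MAGIC)
  )
  skippable <- c(u32_to_raw(SKIPPABLE_MAGIC), u32_to_raw(length(table_body)), table_body)
  structure(list(
    bytes = c(do.call(c, c(frames, list(raw(0)))), skippable),
    frame_size = frame_size,
    entries = entries
  ), class = "seekable_blob")
}

#' @export
print.seekable_blob <- function(x, ...) {
  cat(sprintf("<seekable_blob> %d frame(s), %s raw -> %s compressed bytes\n",
              nrow(x$entries), format(sum(x$entries[, 2])), format(length(x$bytes))))
  invisible(x)
}

# Parse the seek table of a seekable-zstd file image (raw vector) or file.
# Returns frame geometry without touching compressed frame data.
seekable_index <- function(x) {
  bytes <- if (is.raw(x)) x else read_file_raw(x)
  total <- length(bytes)
  if (total < SEEK_FOOTER_BYTES + 8L)
    fastar_error("not a seekable archive: file too short", "fastar_not_archive")
  footer <- bytes[(total - SEEK_FOOTER_BYTES + 1L):total]
  if (raw_to_u32(footer[6:9]) != SEEKABLE_MAGIC)
    fastar_error("not a seekable archive: seek-table magic missing", "fastar_not_archive")
  k <- raw_to_u32(footer[1:4])
  tbl_start <- total - SEEK_FOOTER_BYTES - 8 * k - 8  # skippable header
  if (tbl_start < 0)
    fastar_error("seek table truncated", "fastar_corrupt")
  if (raw_to_u32(bytes[tbl_start + (1:4)]) != SKIPPABLE_MAGIC)
    fastar_error("seek table skippable-frame magic missing", "fastar_corrupt")
  if (raw_to_u32(bytes[tbl_start + (5:8)]) != 8 * k + SEEK_FOOTER_BYTES)
    fastar_error("seek table size field inconsistent", "fastar_corrupt")
  entries <- if (k == 0) {
    matrix(numeric(0), ncol = 2L)
  } else {
    matrix(raw_to_u32(bytes[(tbl_start + 8L) + seq_len(8 * k)]), ncol = 2L, byrow = TRUE)
  }
  colnames(entries) <- c("compressed_size", "uncompressed_size")
  if (k > 0 && sum(entries[, 1]) != tbl_start)
    fastar_error("seek table does not account for all compressed bytes", "fastar_corrupt")
  frame_size <- if (k > 0) entries[1, 2] else 0
  if (k > 1 && (any(entries[-k, 2] != frame_size) || entries[k, 2] > frame_size))
    fastar_error("seek table frame sizes inconsistent", "fastar_corrupt")
  list(
    bytes = bytes,
    entries = entries,
    frame_size = frame_size,
    comp_starts = c(0, cumsum(entries[, 1])),
    raw_starts = c(0, cumsum(entries[, 2])),
    raw_size = sum(entries[, 2])
  )
}

read_file_raw <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path)
  readBin(path, "raw", n = info$size)
}

# Decompress frame i (1-based) of an indexed blob, with optional cache env.
seekable_frame <- function(idx, i, cache = NULL) {
  key <- as.character(i)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  lo <- idx$comp_starts[i] + 1
  hi <- idx$comp_starts[i + 1]
  out <- .zstd_decompress_frame(idx$bytes[lo:hi], idx$entries[i, 2])
  if (!is.null(cache)) {
    if (length(ls(cache)) >= 16L) rm(list = ls(cache)[1L], envir = cache)
    cache[[key]] <- out
  }
  out
}

#' Read a byte range from a seekable blob without full decompression
#'
#' @param blob A `seekable_blob` from [compress_stream()], a raw vector
#'   holding a seekable-zstd file image, or a file path.
#' @param offset 0-based byte offset into the uncompressed stream.
#' @param length Number of bytes to read.
#' @return A list with `bytes` (the requested raw slice) and
#'   `frames_touched`, the number of compressed frames that had to be
#'   decompressed — at most `floor(length / frame_size) + 2`.
#' @export
decompress_range <- function(blob, offset, length) {
  idx <- if (inherits(blob, "seekable_blob")) seekable_index(blob$bytes)
         else if (is.list(blob) && !is.null(blob$raw_starts)) blob
         else seekable_index(blob)
  decompress_range_idx(idx, offset, length)
}

decompress_range_idx <- function(idx, offset, length, cache = NULL) {
  if (offset < 0 || length < 0 || offset + length > idx$raw_size)
    fastar_error(sprintf("range [%s, +%s) beyond uncompressed size %s",
                         format(offset), format(length), format(idx$raw_size)),
                 "fastar_range_error")
  if (length == 0) return(list(bytes = raw(0), frames_touched = 0L))
  f0 <- findInterval(offset, idx$raw_starts, rightmost.closed = FALSE)
  f1 <- findInterval(offset + length - 1, idx$raw_starts)
  parts <- lapply(f0:f1, function(i) seekable_frame(idx, i, cache))
  joined <- do.call(c, parts)
  lo <- offset - idx$raw_starts[f0]
  list(bytes = joined[(lo + 1):(lo + length)], frames_touched = f1 - f0 + 1L)
}
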