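# Virtual views over an archive: FASTA text, fai index, SAM sequence
# dictionary, UCSC TwoBit, and region extraction. All views are pure
# functions of the archive handle (plus the requested line width), derived
# on demand — there is no stored copy that could drift out of sync.

# Byte geometry of the virtual FASTA at a given line width. The header
# line is ">" + name (+ " " + description); sequence lines are wrapped at
# `line_width` symbols, every line newline-terminated, no CR.
virtual_layout <- function(handle, line_width = 60) {
  stopifnot(inherits(handle, "fastar_archive"))
  .require_complete(handle)
  if (line_width < 1) stop("`line_width` must be positive")
  recs <- handle$records
  name <- vapply(recs, `[[`, "", "name", USE.NAMES = FALSE)
  desc <- vapply(recs, `[[`, "", "description", USE.NAMES = FALSE)
  len <- vapply(recs, `[[`, 0, "length", USE.NAMES = FALSE)
  header_bytes <- nchar(name, type = "bytes") + 2 +
    ifelse(nzchar(desc), nchar(desc, type = "bytes") + 1, 0)
  n_lines <- ceiling(len / line_width)
  seq_bytes <- len + n_lines
  rec_bytes <- header_bytes + seq_bytes
  rec_start <- cumsum(c(0, rec_bytes))[seq_along(recs)]
  list(
    table = data.frame(name = name, length = len, header_bytes = header_bytes,
                       seq_bytes = seq_bytes, rec_start = rec_start,
                       seq_start = rec_start + header_bytes,
                       stringsAsFactors = FALSE),
    line_width = line_width,
    total_bytes = sum(rec_bytes)
  )
}

.header_line <- function(rec) {
  paste0(">", rec$name, if (nzchar(rec$description)) paste0(" ", rec$description) else "", "\n")
}

.wrap_lines <- function(symbols, w) {
  len <- nchar(symbols, type = "bytes")
  starts <- seq(1, len, by = w)
  paste0(paste(substring(symbols, starts, pmin(starts + w - 1, len)), collapse = "\n"), "\n")
}

#' Render the virtual FASTA file of an archive
#'
#' Produces the archive's canonical FASTA rendering: one `>` header line
#' per record followed by the sequence wrapped at `line_width` symbols,
#' every line terminated by a single newline. With `apply_mask = FALSE`
#' soft-masked regions are rendered uppercase ("masking virtually
#' disabled"). The whole view is recomputed from the archive on every
#' call, so it can never be out of sync with the data.
#'
#' @param handle An [open_archive()] handle (archive must be complete).
#' @param line_width Symbols per sequence line (default 60).
#' @param apply_mask Keep soft-mask lowercase (default `TRUE`).
#' @return A raw vector holding the FASTA bytes.
#' @seealso [render_fasta_range()] for ranged reads of the same virtual
#'   file, [fai_entries()] for its index.
#' @export
render_fasta <- function(handle, line_width = 60, apply_mask = TRUE) {
  lay <- virtual_layout(handle, line_width)
  parts <- lapply(unname(handle$records), function(r) {
    seq <- archive_decode_range(handle, r$name, 0, r$length, apply_mask)$symbols
    charToRaw(paste0(.header_line(r), .wrap_lines(seq, line_width)))
  })
  out <- do.call(c, c(parts, list(raw(0))))
  stopifnot(length(out) == lay$total_bytes)
  out
}

#' @rdname render_fasta
#' @param offset 0-based byte offset into the virtual FASTA file.
#' @param length Number of bytes to read.
#' @return `render_fasta_range()` returns a list with `bytes` (raw) and
#'   `frames_touched`: only the compression frames covering the requested
#'   symbols are decompressed, so the cost of a read is proportional to
#'   its size, not to the archive size.
#' @export
render_fasta_range <- function(handle, offset, length, line_width = 60,
                               apply_mask = TRUE) {
  lay <- virtual_layout(handle, line_width)
  if (offset < 0 || length < 0 || offset + length > lay$total_bytes)
    fastar_error(sprintf("range [%s, +%s) beyond virtual FASTA of %s bytes",
                         format(offset), format(length), format(lay$total_bytes)),
                 "fastar_range_error")
  if (length == 0) return(list(bytes = raw(0), frames_touched = 0L))
  tab <- lay$table
  w <- line_width
  touched <- 0L
  parts <- list()
  for (i in seq_len(nrow(tab))) {
    rec <- handle$records[[i]]
    r0 <- tab$rec_start[i]
    r1 <- r0 + tab$header_bytes[i] + tab$seq_bytes[i]
    lo <- max(offset, r0)
    hi <- min(offset + length, r1)
    if (lo >= hi) next
    hdr_raw <- charToRaw(.header_line(rec))
    # header-line part of the overlap
    if (lo < r0 + tab$header_bytes[i]) {
      h_lo <- lo - r0
      h_hi <- min(hi - r0, tab$header_bytes[i])
      parts[[length(parts) + 1L]] <- hdr_raw[(h_lo + 1):h_hi]
    }
    # sequence-area part of the overlap, in seq-area byte coordinates
    s0 <- tab$rec_start[i] + tab$header_bytes[i]
    a <- max(lo, s0) - s0
    b <- hi - s0
    if (b > a) {
      la <- a %/% (w + 1)
      lb <- (b - 1) %/% (w + 1)
      sym0 <- la * w
      sym1 <- min(rec$length, (lb + 1) * w)
      dec <- archive_decode_range(handle, rec$name, sym0, sym1, apply_mask)
      touched <- touched + dec$frames_touched
      chunk <- charToRaw(.wrap_lines(dec$symbols, w))
      parts[[length(parts) + 1L]] <- chunk[(a - la * (w + 1) + 1):(b - la * (w + 1))]
    }
  }
  list(bytes = do.call(c, c(parts, list(raw(0)))), frames_touched = touched)
}

#' fai index entries for the virtual FASTA
#'
#' The samtools-style five-column index (name, length, byte offset of the
#' first sequence byte, bases per line, bytes per line) valid for the
#' virtual FASTA produced by [render_fasta()] at the same `line_width`.
#' Because both are derived from the archive on demand, index and FASTA
#' are in sync by construction.
#'
#' @inheritParams render_fasta
#' @return A data frame with columns `name`, `length`, `offset`,
#'   `linebases`, `linewidth`; serialize with [format_fai()].
#' @export
fai_entries <- function(handle, line_width = 60) {
  lay <- virtual_layout(handle, line_width)
  data.frame(name = lay$table$name, length = lay$table$length,
             offset = lay$table$seq_start, linebases = line_width,
             linewidth = line_width + 1, stringsAsFactors = FALSE)
}

#' @rdname fai_entries
#' @param entries A data frame from `fai_entries()`.
#' @export
format_fai <- function(entries) {
  paste0(paste(entries$name, format(entries$length, scientific = FALSE, trim = TRUE),
               format(entries$offset, scientific = FALSE, trim = TRUE),
               entries$linebases, entries$linewidth, sep = "\t"),
         "\n", collapse = "")
}

#' SAM sequence dictionary for an archive
#'
#' Emits the `.dict` file (a SAM header): an `@HD` line followed by one
#' `@SQ` line per record carrying `SN` (name), `LN` (length), `M5` (the
#' stored CRAM-compatible MD5, hex) and `UR` (a URI for the sequence
#' source), in record order.
#'
#' @param handle An [open_archive()] handle.
#' @param uri The `UR` tag value; defaults to a `file://` URI of the
#'   archive path.
#' @return A character scalar holding the SAM header text.
#' @export
dict_entries <- function(handle, uri = paste0("file://", normalizePath(handle$path))) {
  stopifnot(inherits(handle, "fastar_archive"))
  .require_complete(handle)
  sq <- vapply(unname(handle$records), function(r) {
    sprintf("@SQ\tSN:%s\tLN:%s\tM5:%s\tUR:%s", r$name,
            format(r$length, scientific = FALSE, trim = TRUE), md5_hex(r$md5), uri)
  }, "")
  paste0("@HD\tVN:1.6\tSO:unsorted\n", paste0(sq, "\n", collapse = ""))
}

# ---- TwoBit export -------------------------------------------------------

TWOBIT_SIGNATURE <- 0x1A412743
# UCSC TwoBit base codes: T=0, C=1, A=2, G=3; ours are A=0, C=1, G=2, T=3.
.twobit_from_nuc2 <- c(2L, 1L, 3L, 0L)

#' Export a DNA archive to UCSC TwoBit format
#'
#' Writes a standard TwoBit file (signature `0x1A412743`, little-endian):
#' N-blocks come from the archive's N run-blocks, maskBlocks from its
#' soft-mask run-blocks, and the DNA payload is re-packed at 2 bits per
#' base in TwoBit base order. Only archives consisting exclusively of
#' 2-bit DNA sequences can be exported; RNA, IUPAC-ambiguity and protein
#' records are refused.
#'
#' @param handle An [open_archive()] handle.
#' @param path Optional output file; when given, the blob is also written
#'   there.
#' @return A raw vector holding the TwoBit file image (invisibly when
#'   `path` is given).
#' @export
export_twobit <- function(handle, path = NULL) {
  stopifnot(inherits(handle, "fastar_archive"))
  .require_complete(handle)
  for (r in handle$records) {
    if (r$alphabet != "NUC2" || r$rna_flag)
      fastar_error(sprintf("sequence '%s' is %s%s; TwoBit export supports DNA only",
                           r$name, r$alphabet, if (r$rna_flag) " (RNA)" else ""),
                   "fastar_unsupported_alphabet")
  }
  recs <- handle$records
  n <- length(recs)
  header <- c(u32_to_raw(TWOBIT_SIGNATURE), u32_to_raw(0), u32_to_raw(n), u32_to_raw(0))
  name_raw <- lapply(recs, function(r) charToRaw(r$name))
  index_bytes <- sum(vapply(name_raw, length, 0L) + 5L)
  at <- length(header) + index_bytes
  offsets <- numeric(n)
  bodies <- vector("list", n)
  for (i in seq_len(n)) {
    r <- recs[[i]]
    codes <- unpack_codes(
      decompress_range_idx(handle$idx, r$data_ptr, r$payload_bytes, handle$cache)$bytes,
      2L, 0L, r$length)
    packed <- pack_codes(.twobit_from_nuc2[codes + 1L], 2L)
    body <- c(
      u32_to_raw(r$length),
      u32_to_raw(nrow(r$n_blocks)),
      if (nrow(r$n_blocks)) u32_to_raw(r$n_blocks[, "start"]) else raw(0),
      if (nrow(r$n_blocks)) u32_to_raw(r$n_blocks[, "length"]) else raw(0),
      u32_to_raw(nrow(r$m_blocks)),
      if (nrow(r$m_blocks)) u32_to_raw(r$m_blocks[, "start"]) else raw(0),
      if (nrow(r$m_blocks)) u32_to_raw(r$m_blocks[, "length"]) else raw(0),
      u32_to_raw(0),
      packed
    )
    offsets[i] <- at
    bodies[[i]] <- body
    at <- at + length(body)
  }
  index <- do.call(c, c(lapply(seq_len(n), function(i) {
    c(as.raw(length(name_raw[[i]])), name_raw[[i]], u32_to_raw(offsets[i]))
  }), list(raw(0))))
  blob <- c(header, index, do.call(c, c(bodies, list(raw(0)))))
  if (!is.null(path)) {
    writeBin(blob, path)
    return(invisible(blob))
  }
  blob
}

# ---- regions -------------------------------------------------------------

#' Parse a samtools-style region string
#'
#' Accepts `name`, `name:start` or `name:start-end` with 1-based inclusive
#' coordinates; thousands separators (commas) in coordinates are stripped.
#' A name containing `:` is honoured when it matches a sequence name
#' exactly (checked before any coordinate parsing). A missing end means
#' the sequence end; an end beyond the sequence is clamped to it, matching
#' samtools semantics.
#'
#' @param handle An [open_archive()] handle.
#' @param text The region string, e.g. `"chr1:1,001-2,000"`.
#' @return A `fastar_region`: list with `name`, `start`, `end` (1-based,
#'   inclusive, resolved against the archive).
#' @export
parse_region <- function(handle, text) {
  stopifnot(inherits(handle, "fastar_archive"))
  .require_complete(handle)
  nms <- names(handle)
  if (text %in% nms) {
    len <- handle$records[[text]]$length
    return(structure(list(name = text, start = 1, end = len), class = "fastar_region"))
  }
  m <- regmatches(text, regexec("^(.+):([0-9][0-9,]*)(?:-([0-9][0-9,]*))?$", text))[[1]]
  if (length(m) == 0L)
    fastar_error(sprintf("cannot parse region '%s'", text), "fastar_parse_error")
  name <- m[2]
  if (!(name %in% nms))
    fastar_error(sprintf("no sequence named '%s' in archive", name), "fastar_lookup")
  len <- handle$records[[name]]$length
  start <- as.numeric(gsub(",", "", m[3]))
  end <- if (is.na(m[4]) || !nzchar(m[4])) len else as.numeric(gsub(",", "", m[4]))
  if (start < 1)
    fastar_error(sprintf("region start %s is before position 1", format(start)),
                 "fastar_parse_error")
  if (end < start)
    fastar_error(sprintf("region end %s is before start %s", format(end), format(start)),
                 "fastar_parse_error")
  if (start > len)
    fastar_error(sprintf("region start %s beyond '%s' length %s",
                         format(start), name, format(len)), "fastar_range_error")
  structure(list(name = name, start = start, end = min(end, len)),
            class = "fastar_region")
}

#' @export
print.fastar_region <- function(x, ...) {
  cat(sprintf("<region> %s:%s-%s (%s symbols)\n", x$name, format(x$start),
              format(x$end), format(x$end - x$start + 1)))
  invisible(x)
}

#' Extract a subsequence from an archive
#'
#' Returns the symbols of a region (1-based, inclusive) as a bare string —
#' no newlines, no spaces — decompressing only the frames that cover the
#' requested symbols. This is the library form of the virtual
#' `seq/<name>:<start>-<end>` files.
#'
#' @param handle An [open_archive()] handle.
#' @param region A region string (see [parse_region()]) or a
#'   `fastar_region`.
#' @param apply_mask Keep soft-mask lowercase (default `TRUE`).
#' @return A character string; its `frames_touched` attribute reports how
#'   many compression frames were decompressed to serve the request.
#' @export
extract_region <- function(handle, region, apply_mask = TRUE) {
  if (is.character(region)) region <- parse_region(handle, region)
  stopifnot(inherits(region, "fastar_region"))
  dec <- archive_decode_range(handle, region$name, region$start - 1, region$end,
                              apply_mask)
  structure(dec$symbols, frames_touched = dec$frames_touched)
}

#' @rdname extract_region
#' @param name A sequence name.
#' @return `sequence_length()` returns the symbol count of a sequence (the
#'   "file size in nucleotides" of its virtual `seq/<name>` file).
#' @export
sequence_length <- function(handle, name) {
  archive_record(handle, name)$length
}
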