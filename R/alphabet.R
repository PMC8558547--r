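# Alphabet detection and the bit-packed sequence codec.
#
# Three alphabet classes are supported:
#   NUC2  - 2 bits/symbol, plain DNA/RNA over {A,C,G,T|U,N}; N is stored
#           out-of-band as run-length blocks over a placeholder base.
#   NUC4  - 4 bits/symbol, the 15-letter IUPAC nucleotide code incl. N.
#   PROT5 - 5 bits/symbol, the 20 amino acids plus B,Z,X,J,U,O,*,-.
# Case (soft-masking) is never stored in the payload; lowercase runs live in
# run-length mask blocks so masking can be switched off at render time.

ALPHABETS <- c(NUC2 = 2L, NUC4 = 4L, PROT5 = 5L)

NUC2_LETTERS <- c("A", "C", "G", "T")
NUC4_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")
PROT5_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                   "B", "Z", "X", "J", "U", "O", "*", "-")

# byte-value code tables, NA = not in alphabet (index = byte value + 1)
.code_table <- function(letters, codes) {
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt(paste(letters, collapse = "")) + 1L] <- codes
  tab
}

.codec <- local({
  nuc2 <- .code_table(c("A", "C", "G", "T", "U", "N"), c(0L, 1L, 2L, 3L, 3L, 0L))
  nuc4 <- .code_table(c(NUC4_LETTERS, "U"), c(0:14, 3L))
  prot5 <- .code_table(PROT5_LETTERS, 0:27)
  list(NUC2 = nuc2, NUC4 = nuc4, PROT5 = prot5)
})

# decode letter tables: code -> byte value (uppercase; T by default)
.letters_for <- function(alphabet, rna_flag) {
  base <- switch(alphabet,
    NUC2 = NUC2_LETTERS,
    NUC4 = NUC4_LETTERS,
    PROT5 = PROT5_LETTERS
  )
  if (rna_flag && alphabet %in% c("NUC2", "NUC4")) base[base == "T"] <- "U"
  as.raw(utf8ToInt(paste(base, collapse = "")))
}

.byte_set <- function(letters) utf8ToInt(paste(letters, collapse = ""))

#' Detect the smallest alphabet class covering a sequence
#'
#' Classifies a sequence as plain nucleotide (2-bit), IUPAC nucleotide
#' (4-bit) or protein (5-bit), always choosing the narrowest class that
#' covers every symbol. Evaluation is case-insensitive.
#'
#' @param symbols A single character string holding the sequence.
#' @return A list with `code` (`"NUC2"`, `"NUC4"` or `"PROT5"`),
#'   `bits_per_symbol` (2, 4 or 5) and `rna_flag` (`TRUE` when the sequence
#'   uses U and never T, so decoding renders U).
#' @details A nucleotide sequence mixing both T and U cannot be represented
#'   (they share one symbol code and one of the two would be rewritten on
#'   decode), so it is rejected rather than silently altered. T and U are
#'   distinct residues in the protein alphabet and are unaffected.
#' @examples
#' detect_alphabet("ACGTN")              # 2-bit DNA
#' detect_alphabet("ACGURYN")            # 4-bit IUPAC, RNA
#' detect_alphabet("MKWVTFISLLLLFSSAYS") # 5-bit protein
#' @export
detect_alphabet <- function(symbols) {
  if (!is.character(symbols) || length(symbols) != 1L || is.na(symbols))
    stop("`symbols` must be a single character string")
  if (!nzchar(symbols))
    fastar_error("empty sequence", "fastar_empty_sequence")
  up <- toupper(symbols)
  bv <- as.integer(charToRaw(up))
  present <- which(tabulate(bv + 1L, 256L) > 0L) - 1L

  in_set <- function(letters) all(present %in% .byte_set(letters))
  has <- function(ch) utf8ToInt(ch) %in% present

  if (!in_set(PROT5_LETTERS)) {
    bad <- which(!(bv %in% .byte_set(PROT5_LETTERS)))[1L]
    fastar_error(
      sprintf("invalid symbol '%s' at position %d", substr(symbols, bad, bad), bad),
      "fastar_invalid_symbol"
    )
  }

  nuc_like <- in_set(c(NUC4_LETTERS, "U"))
  if (nuc_like && has("T") && has("U"))
    fastar_error(
      "sequence mixes T and U; a nucleotide sequence must use one of the two",
      "fastar_invalid_symbol"
    )
  rna_flag <- nuc_like && has("U") && !has("T")

  code <-
    if (in_set(c("A", "C", "G", "T", "N")) || in_set(c("A", "C", "G", "U", "N"))) {
      "NUC2"
    } else if (nuc_like) {
      "NUC4"
    } else {
      "PROT5"
    }
  if (code == "PROT5") rna_flag <- FALSE
  list(code = code, bits_per_symbol = unname(ALPHABETS[code]), rna_flag = rna_flag)
}

#' Encode a sequence into its bit-packed form
#'
#' Packs a sequence at 2, 4 or 5 bits per symbol (see [detect_alphabet()]).
#' Lowercase (soft-masked) positions are recorded as run-length mask blocks
#' and the payload itself is case-free; for 2-bit sequences, runs of N are
#' recorded as N-blocks and a placeholder base (A) is packed in their place.
#' The per-sequence MD5 is the CRAM/BAM-style digest of the uppercased
#' sequence.
#'
#' @param name Sequence name; must contain no whitespace.
#' @param symbols A single character string holding the sequence.
#' @param description Optional free-text description (rest of a FASTA header
#'   line); not part of the digest.
#' @return An object of class `packed_sequence`: a list with `name`,
#'   `description`, `alphabet`, `bits_per_symbol`, `rna_flag`, `length`,
#'   `payload` (raw), `n_blocks` and `m_blocks` (two-column numeric matrices
#'   of 0-based `start` and `length`), and `md5` (16 raw bytes).
#' @seealso [decode_subsequence()], [sequence_md5()]
#' @export
encode_sequence <- function(name, symbols, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) || grepl("[[:space:]]", name))
    stop("`name` must be a non-empty string without whitespace")
  det <- detect_alphabet(symbols)
  b <- charToRaw(symbols)
  n <- length(b)
  bv <- as.integer(b)

  m_blocks <- runs_from_flags(bv >= 97L & bv <= 122L)

  up <- toupper(symbols)
  ubv <- as.integer(charToRaw(up))
  codes <- .codec[[det$code]][ubv + 1L]

  n_blocks <- empty_runs()
  if (det$code == "NUC2") {
    n_blocks <- runs_from_flags(ubv == utf8ToInt("N"))
  }

  structure(list(
    name = name,
    description = if (nzchar(description)) description else "",
    alphabet = det$code,
    bits_per_symbol = det$bits_per_symbol,
    rna_flag = det$rna_flag,
    length = as.numeric(n),
    payload = pack_codes(codes, det$bits_per_symbol),
    n_blocks = n_blocks,
    m_blocks = m_blocks,
    md5 = md5_raw(up)
  ), class = "packed_sequence")
}

#' @export
print.packed_sequence <- function(x, ...) {
  cat(sprintf("<packed_sequence> %s: %s symbols, %s (%d bits/symbol)%s\n",
              x$name, format(x$length, big.mark = ","), x$alphabet,
              x$bits_per_symbol, if (x$rna_flag) ", RNA" else ""))
  cat(sprintf("  payload %d bytes, %d N-block(s), %d mask-block(s), MD5 %s\n",
              length(x$payload), nrow(x$n_blocks), nrow(x$m_blocks),
              md5_hex(x$md5)))
  invisible(x)
}

#' Decode a half-open range of a packed sequence
#'
#' Reconstructs symbols `[start, end)` (0-based, end-exclusive) from the
#' packed payload, overlaying N-blocks, applying soft-mask case when
#' requested, and rendering U instead of T for RNA sequences. Only the
#' payload bytes covering the requested range are inspected.
#'
#' @param seq A `packed_sequence` from [encode_sequence()].
#' @param start,end 0-based start (inclusive) and end (exclusive).
#' @param apply_mask Render soft-masked positions in lowercase (`TRUE`,
#'   default) or fold everything to uppercase (`FALSE`).
#' @return A character string of `end - start` symbols.
#' @export
decode_subsequence <- function(seq, start = 0, end = seq$length, apply_mask = TRUE) {
  stopifnot(inherits(seq, "packed_sequence"))
  if (start < 0 || end > seq$length || start > end)
    fastar_error(sprintf("range [%s,%s) outside sequence of length %s",
                         format(start), format(end), format(seq$length)),
                 "fastar_range_error")
  n <- end - start
  if (n == 0) return("")
  span <- payload_byte_span(start, end, seq$bits_per_symbol)
  codes <- unpack_codes(seq$payload[(span$first + 1):span$last],
                        seq$bits_per_symbol, span$bit_offset, n)
  render_codes(codes, seq, start, end, apply_mask)
}

# codes -> character, with N overlay / mask / RNA rendering for the window
# [start, end) that `codes` covers. Shared by the in-memory and archive paths.
render_codes <- function(codes, seq, start, end, apply_mask) {
  lut <- .letters_for(seq$alphabet, seq$rna_flag)
  out <- lut[codes + 1L]
  if (seq$alphabet == "NUC2" && nrow(seq$n_blocks) > 0L) {
    idx <- runs_window_positions(seq$n_blocks, start, end)
    if (length(idx)) out[idx] <- as.raw(utf8ToInt("N"))
  }
  if (apply_mask && nrow(seq$m_blocks) > 0L) {
    idx <- runs_window_positions(seq$m_blocks, start, end)
    if (length(idx)) out[idx] <- as.raw(as.integer(out[idx]) + 32L)
  }
  rawToChar(out)
}

#' Maximal runs of TRUE in a logical vector
#'
#' Returns the maximal runs of `TRUE` as 0-based `(start, length)` rows,
#' sorted and non-adjacent; the representation used for N-blocks and
#' soft-mask blocks. [flags_from_runs()] is the exact inverse.
#'
#' @param flags A logical vector (NA not allowed).
#' @return A two-column numeric matrix with columns `start` and `length`.
#' @export
runs_from_flags <- function(flags) {
  if (length(flags) == 0L) return(empty_runs())
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  matrix(as.numeric(c(starts[keep], r$lengths[keep])), ncol = 2L,
         dimnames = list(NULL, c("start", "length")))
}

#' @rdname runs_from_flags
#' @param runs A run matrix as returned by `runs_from_flags()`.
#' @param n Total vector length to reconstruct.
#' @export
flags_from_runs <- function(runs, n) {
  flags <- rep(FALSE, n)
  if (nrow(runs) > 0L)
    flags[sequence(runs[, "length"], from = runs[, "start"] + 1)] <- TRUE
  flags
}

empty_runs <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "length")))
}

# 1-based positions, relative to window [start, end), covered by runs
runs_window_positions <- function(runs, start, end) {
  if (nrow(runs) == 0L) return(integer(0))
  s <- pmax(runs[, "start"], start)
  e <- pmin(runs[, "start"] + runs[, "length"], end)
  keep <- s < e
  if (!any(keep)) return(integer(0))
  s <- s[keep]; e <- e[keep]
  as.integer(sequence(e - s, from = s - start + 1))
}
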