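# Deterministic synthetic FASTA generation and byte-level corruption,
# so every test and benchmark runs from code with no downloads.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Alternating geometric run/gap model: runs of mean length `mean_run`
# covering about `frac` of the sequence (gap mean = mean_run*(1-f)/f).
# Produces both short runs and runs spanning several compression frames.
.run_flags <- function(n, frac, mean_run = 50) {
  if (frac <= 0 || n == 0L) return(rep(FALSE, n))
  if (frac >= 1) return(rep(TRUE, n))
  mean_gap <- max(1, mean_run * (1 - frac) / frac)
  k <- ceiling(n / (mean_run + mean_gap) * 3) + 10
  runs <- stats::rgeom(k, 1 / mean_run) + 1
  gaps <- stats::rgeom(k, 1 / mean_gap) + 1
  gaps[1] <- stats::rgeom(1, 2 / mean_gap) + 1    # start mid-pattern
  pieces <- as.vector(rbind(gaps, runs))
  flags <- rep(rep(c(FALSE, TRUE), k), pieces)
  while (length(flags) < n) flags <- c(flags, flags)  # defensive; k oversizes
  flags[seq_len(n)]
}

.FIXTURE_SETS <- list(
  NUC2 = list(core = c("A", "C", "G", "T"), rare = character(0)),
  NUC4 = list(core = c("A", "C", "G", "T"),
              rare = c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")),
  PROT5 = list(core = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               rare = c("X", "B", "Z"))
)

#' Generate a deterministic synthetic FASTA fixture
#'
#' Emits reproducible multi-record FASTA text together with its ground
#' truth (per-record symbols and the exact N- and mask-run blocks), for
#' oracle comparisons. N runs and lowercase (soft-mask) runs follow an
#' alternating geometric model with mean run length 50, so runs both
#' shorter than a line and longer than a compression frame occur. The
#' same spec always produces byte-identical output.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param n_records Number of records.
#' @param length_range Two-element `(min, max)` record length in symbols.
#' @param alphabet `"NUC2"`, `"NUC4"`, `"PROT5"` or `"mixed"` (per-record
#'   random choice among the three).
#' @param n_fraction Approximate fraction of N symbols (nucleotide records
#'   only).
#' @param mask_fraction Approximate fraction of soft-masked (lowercase)
#'   symbols.
#' @param line_width FASTA wrap width of the emitted text.
#' @param rna Emit U instead of T (plain-nucleotide records only).
#' @param with_descriptions Attach a free-text description to every other
#'   record header.
#' @return A list with `fasta` (character scalar, the full file text) and
#'   `records`, a list of `list(name, symbols, n_blocks, m_blocks)`.
#' @export
generate_fasta <- function(seed, n_records = 3, length_range = c(500, 2000),
                           alphabet = "NUC2", n_fraction = 0.02,
                           mask_fraction = 0.1, line_width = 60, rna = FALSE,
                           with_descriptions = FALSE) {
  stopifnot(length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            alphabet %in% c(names(.FIXTURE_SETS), "mixed"),
            n_fraction >= 0, n_fraction <= 1, mask_fraction >= 0, mask_fraction <= 1)
  with_seed(seed, {
    records <- lapply(seq_len(n_records), function(i) {
      alpha <- if (alphabet == "mixed")
        sample(names(.FIXTURE_SETS), 1) else alphabet
      len <- if (length_range[1] == length_range[2]) length_range[1]
             else sample(length_range[1]:length_range[2], 1)
      sets <- .FIXTURE_SETS[[alpha]]
      chars <- sample(sets$core, len, replace = TRUE)
      if (length(sets$rare)) {
        hit <- stats::runif(len) < 0.02
        if (!any(hit)) hit[sample(len, 1)] <- TRUE  # keep the class honest
        chars[hit] <- sample(sets$rare, sum(hit), replace = TRUE)
      }
      if (alpha != "PROT5") {
        if (rna && alpha == "NUC2") chars[chars == "T"] <- "U"
        nf <- .run_flags(len, n_fraction)
        chars[nf] <- "N"
      } else {
        nf <- rep(FALSE, len)
      }
      mf <- .run_flags(len, mask_fraction)
      chars[mf] <- tolower(chars[mf])
      name <- sprintf("seq%d", i)
      desc <- if (with_descriptions && i %% 2 == 0)
        sprintf("synthetic %s record %d", alpha, i) else ""
      list(name = name, description = desc, symbols = paste(chars, collapse = ""),
           n_blocks = runs_from_flags(nf),  # runs of N (case-insensitive)
           m_blocks = runs_from_flags(mf))
    })
    fasta <- paste0(vapply(records, function(r) {
      hdr <- paste0(">", r$name,
                    if (nzchar(r$description)) paste0(" ", r$description) else "")
      paste0(hdr, "\n", .wrap_lines(r$symbols, line_width))
    }, ""), collapse = "")
    list(fasta = fasta, records = records)
  })
}

#' Corrupt bytes of a file (for integrity testing)
#'
#' Writes a mutated copy of `path` in which each selected byte is XORed
#' with a nonzero value; the original file is untouched.
#'
#' @param path File to corrupt.
#' @param positions 0-based byte offsets to mutate; when `NULL`, `count`
#'   offsets are drawn uniformly at random.
#' @param count Number of random positions when `positions` is `NULL`.
#' @param seed Seed for the random draws.
#' @param out Output path (default: a tempfile).
#' @return A list with `path` (the mutated copy) and `offsets` (0-based,
#'   sorted).
#' @export
corrupt_bytes <- function(path, positions = NULL, count = 1, seed = 1,
                          out = tempfile(fileext = ".corrupt")) {
  bytes <- read_file_raw(path)
  n <- length(bytes)
  with_seed(seed, {
    if (is.null(positions)) {
      positions <- sample(n, min(count, n)) - 1
    }
    if (any(positions < 0 | positions >= n))
      fastar_error(sprintf("corruption offset beyond file length %d", n),
                   "fastar_range_error")
    positions <- sort(unique(positions))
    xor_with <- as.raw(sample(1:255, length(positions), replace = TRUE))
    bytes[positions + 1] <- as.raw(bitwXor(as.integer(bytes[positions + 1]),
                                           as.integer(xor_with)))
    writeBin(bytes, out)
    list(path = out, offsets = positions)
  })
}
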