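test_that("alphabet detection picks the narrowest covering class", {
  expect_equal(detect_alphabet("ACGTN")[c("code", "rna_flag")],
               list(code = "NUC2", rna_flag = FALSE))
  expect_equal(detect_alphabet("ACGURYN")[c("code", "rna_flag")],
               list(code = "NUC4", rna_flag = TRUE))
  expect_equal(detect_alphabet("MKWVTFISLLLLFSSAYS")[c("code", "rna_flag")],
               list(code = "PROT5", rna_flag = FALSE))
  expect_equal(detect_alphabet("acgun")$code, "NUC2")  # case-insensitive
  expect_true(detect_alphabet("ACGUN")$rna_flag)
  # minimality: plain DNA/RNA is never widened to the IUPAC class,
  # IUPAC is never widened to protein
  expect_equal(detect_alphabet(strrep("ACGT", 50))$code, "NUC2")
  expect_equal(detect_alphabet("ACGTRYN")$code, "NUC4")
  expect_equal(detect_alphabet("DHVKW")$code, "NUC4")
  expect_equal(detect_alphabet("ELVIS")$code, "PROT5")
  expect_equal(detect_alphabet("AC-GT")$code, "PROT5")  # gap forces protein
})

test_that("invalid symbols are rejected with character and position", {
  err <- expect_error(detect_alphabet("ACG?T"), class = "fastar_invalid_symbol")
  expect_match(conditionMessage(err), "'\\?'")
  expect_match(conditionMessage(err), "position 4")
  expect_error(detect_alphabet(""), class = "fastar_empty_sequence")
  # T and U share one stored code, so a nucleotide sequence mixing them
  # could not be reconstructed byte-exactly; protein T/U is fine
  expect_error(detect_alphabet("ACGTU"), class = "fastar_invalid_symbol")
  expect_equal(detect_alphabet("ACGTUE")$code, "PROT5")
})

test_that("encoding packs MSB-first and lifts N and mask runs out of band", {
  p <- encode_sequence("s", "ACGT")
  expect_identical(p$payload, as.raw(0x1B))
  expect_equal(nrow(p$n_blocks), 0)
  expect_equal(nrow(p$m_blocks), 0)

  p <- encode_sequence("s", "ACNNGT")
  expect_equal(unname(p$n_blocks[1, ]), c(2, 2))
  # placeholder A (code 0) is packed where the Ns sit
  expect_identical(p$payload, encode_sequence("s", "ACAAGT")$payload)

  p <- encode_sequence("s", "acGT")
  expect_equal(unname(p$m_blocks[1, ]), c(0, 2))
  expect_error(encode_sequence("bad name", "ACGT"))
})

test_that("payload occupies exactly ceil(n * bits / 8) bytes, pad bits zero", {
  seqs <- list(
    NUC2 = function(n) strrep("A", n),
    NUC4 = function(n) paste0(strrep("R", n - 1), "Y"),
    PROT5 = function(n) paste0(strrep("L", n - 1), "E")
  )
  for (alpha in names(seqs)) {
    bits <- c(NUC2 = 2, NUC4 = 4, PROT5 = 5)[[alpha]]
    for (n in c(1, 2, 7, 8, 9, 63, 64, 1000, 10^6)) {
      p <- encode_sequence("s", seqs[[alpha]](n))
      expect_identical(p$alphabet, alpha)
      expect_identical(length(p$payload), as.integer(ceiling(n * bits / 8)))
    }
  }
  # trailing pad bits are zero: "EEEEE" is protein code 3 (00011) five
  # times, 25 bits MSB-first + 7 zero pad = 18 C6 31 80 (by hand)
  p <- encode_sequence("s", "EEEEE")
  expect_identical(p$payload, as.raw(c(0x18, 0xC6, 0x31, 0x80)))
})

test_that("decode inverts encode byte-exactly across alphabets", {
  p <- encode_sequence("s", "ACNNGT")
  expect_identical(decode_subsequence(p, 1, 5), "CNNG")
  p <- encode_sequence("s", "acGT")
  expect_identical(decode_subsequence(p, 0, 4, apply_mask = FALSE), "ACGT")
  expect_identical(decode_subsequence(p, 0, 4, apply_mask = TRUE), "acGT")

  for (seed in 1:6) {
    fx <- generate_fasta(seed, n_records = 2, length_range = c(50, 400),
                         alphabet = c("NUC2", "NUC4", "PROT5", "mixed",
                                      "NUC2", "NUC4")[seed],
                         n_fraction = 0.1, mask_fraction = 0.2,
                         rna = seed == 5)
    for (r in fx$records) {
      p <- encode_sequence(r$name, r$symbols)
      expect_identical(decode_subsequence(p, 0, p$length, apply_mask = TRUE),
                       r$symbols)
    }
  }
})

test_that("ranged decode equals slicing the full decode", {
  fx <- generate_fasta(42, n_records = 3, length_range = c(800, 1500),
                       alphabet = "mixed", n_fraction = 0.08, mask_fraction = 0.25)
  packed <- lapply(fx$records, function(r) encode_sequence(r$name, r$symbols))
  full <- lapply(packed, function(p) decode_subsequence(p, 0, p$length))
  fastar:::with_seed(99, {
    for (k in 1:500) {
      i <- sample(length(packed), 1)
      p <- packed[[i]]
      start <- sample(0:(p$length - 1), 1)
      end <- sample(start:p$length, 1)
      expect_identical(decode_subsequence(p, start, end),
                       substr(full[[i]], start + 1, end))
    }
  })
  expect_error(decode_subsequence(packed[[1]], 0, packed[[1]]$length + 1),
               class = "fastar_range_error")
})

test_that("RNA sequences render U and round-trip", {
  p <- encode_sequence("r", "ACGUNacgu")
  expect_true(p$rna_flag)
  expect_identical(decode_subsequence(p, 0, 9), "ACGUNacgu")
  expect_identical(decode_subsequence(p, 0, 9, apply_mask = FALSE), "ACGUNACGU")
})

test_that("run blocks are maximal, sorted, and invert exactly", {
  expect_equal(unname(runs_from_flags(c(FALSE, TRUE, TRUE, FALSE, TRUE))),
               matrix(c(1, 4, 2, 1), ncol = 2))
  expect_equal(nrow(runs_from_flags(rep(FALSE, 10))), 0)
  expect_equal(nrow(runs_from_flags(logical(0))), 0)
  fastar:::with_seed(7, {
    for (k in 1:200) {
      flags <- sample(c(TRUE, FALSE), sample(1:80, 1), replace = TRUE)
      runs <- runs_from_flags(flags)
      expect_identical(flags_from_runs(runs, length(flags)), flags)
      if (nrow(runs) > 1) {
        # sorted, non-overlapping, non-adjacent (maximal)
        gaps <- runs[-1, "start"] - (runs[-nrow(runs), "start"] +
                                       runs[-nrow(runs), "length"])
        expect_true(all(gaps >= 1))
      }
    }
  })
})
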