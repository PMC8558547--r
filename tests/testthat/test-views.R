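test_that("virtual FASTA wraps at the requested width", {
  path <- make_archive(list(list(name = "s", symbols = "ACGTACGT")))
  h <- open_archive(path)
  expect_identical(rawToChar(render_fasta(h, 4)), ">s\nACGT\nACGT\n")
  expect_identical(rawToChar(render_fasta(h, 8)), ">s\nACGTACGT\n")
  expect_identical(rawToChar(render_fasta(h, 3)), ">s\nACG\nTAC\nGT\n")
})

test_that("masking can be virtually disabled at render time", {
  path <- make_archive(list(list(name = "s", symbols = "acgtNNacGT")))
  h <- open_archive(path)
  masked <- rawToChar(render_fasta(h, 60))
  unmasked <- rawToChar(render_fasta(h, 60, apply_mask = FALSE))
  expect_identical(masked, ">s\nacgtNNacGT\n")
  expect_identical(unmasked, ">s\nACGTNNACGT\n")
  expect_false(grepl("[a-z]", sub("^>s", "", unmasked)))
})

test_that("ranged render equals slices of the full render, at bounded cost", {
  big <- fixture_archive(61, n_records = 3, length_range = c(40000, 80000),
                         alphabet = "NUC2", n_fraction = 0.03,
                         mask_fraction = 0.2, frame_size = 4096)
  h <- open_archive(big$path)
  full <- render_fasta(h, 60)
  total <- length(full)
  # suffix read: the tail of the virtual file without decoding the rest
  tail_read <- render_fasta_range(h, total - 1000, 1000)
  expect_identical(tail_read$bytes, full[(total - 999):total])
  expect_lte(tail_read$frames_touched, ceiling(1000 * 2 / 8 / 4096) + 2)
  fastar:::with_seed(71, {
    for (k in 1:200) {
      o <- sample(0:(total - 1), 1)
      n <- sample(1:min(5000, total - o), 1)
      rr <- render_fasta_range(h, o, n)
      expect_identical(rr$bytes, full[(o + 1):(o + n)])
    }
  })
  # concatenated chunked reads reproduce the full stream
  chunks <- lapply(seq(0, total - 1, by = 7777), function(o)
    render_fasta_range(h, o, min(7777, total - o))$bytes)
  expect_identical(do.call(c, chunks), full)
  expect_error(render_fasta_range(h, total, 1), class = "fastar_range_error")
})

test_that("fai entries are valid for the rendered FASTA and match samtools", {
  path <- make_archive(list(list(name = "s", symbols = "ACGTACGT")))
  h <- open_archive(path)
  e <- fai_entries(h, 8)
  expect_equal(unname(unlist(e[1, ])), c("s", "8", "3", "8", "9"),
               ignore_attr = TRUE)

  # offset arithmetic: two records, widths that do and do not divide lengths
  for (seed in c(81, 82, 83)) {
    width <- c(60, 7, 80)[seed - 80]
    fx <- generate_fasta(seed, n_records = 3, length_range = c(40, 400),
                         alphabet = "mixed", mask_fraction = 0.2,
                         with_descriptions = TRUE)
    h <- open_archive(make_archive(fixture_records(fx)))
    fasta <- render_fasta(h, width)
    e <- fai_entries(h, width)
    # second offset = first offset + record-1 virtual bytes + record-2 header
    lay <- fastar:::virtual_layout(h, width)
    expect_equal(e$offset[2],
                 e$offset[1] + lay$table$seq_bytes[1] + lay$table$header_bytes[2])
    fastar:::with_seed(seed, {
      for (k in 1:50) {
        i <- sample(nrow(e), 1)
        pos <- sample(0:(e$length[i] - 1), 1)     # 0-based symbol index
        byte_at <- e$offset[i] + (pos %/% e$linebases[i]) * e$linewidth[i] +
          pos %% e$linebases[i]
        expect_identical(rawToChar(fasta[byte_at + 1]),
                         substr(fx$records[[i]]$symbols, pos + 1, pos + 1))
      }
    })
    # samtools writes the identical index for the rendered file
    fa <- tempfile(fileext = ".fa")
    writeBin(fasta, fa)
    expect_equal(system2("samtools", c("faidx", fa)), 0)
    expect_identical(format_fai(e),
                     paste0(paste(readLines(paste0(fa, ".fai")), collapse = "\n"), "\n"))
  }
})

test_that("dict output is a SAM header in record order with stored M5 tags", {
  fx <- generate_fasta(91, n_records = 3, alphabet = "mixed")
  h <- open_archive(make_archive(fixture_records(fx)))
  txt <- dict_entries(h, uri = "file:///data/toy.fa")
  lines <- strsplit(txt, "\n")[[1]]
  expect_match(lines[1], "^@HD\tVN:")
  sq <- lines[-1]
  expect_length(sq, 3)
  expect_true(all(grepl("^@SQ\tSN:[^\t]+\tLN:[0-9]+\tM5:[0-9a-f]{32}\tUR:", sq)))
  expect_equal(sub(".*\tSN:([^\t]+).*", "\\1", sq), names(h))
  expect_equal(sub(".*\tM5:([0-9a-f]+).*", "\\1", sq),
               vapply(h$records, function(r) md5_hex(r$md5), "", USE.NAMES = FALSE))
  expect_equal(sub(".*\tLN:([0-9]+).*", "\\1", sq),
               as.character(vapply(h$records, `[[`, 0, "length")),
               ignore_attr = TRUE)
  # regenerating the view cannot drift: pure function of archive + args
  expect_identical(txt, dict_entries(h, uri = "file:///data/toy.fa"))
  expect_identical(fai_entries(h, 60), fai_entries(h, 60))
})

test_that("TwoBit export round-trips through independent readers", {
  fx <- generate_fasta(95, n_records = 3, length_range = c(200, 3000),
                       alphabet = "NUC2", n_fraction = 0.08, mask_fraction = 0.25)
  h <- open_archive(make_archive(fixture_records(fx)))
  tb <- tempfile(fileext = ".2bit")
  export_twobit(h, tb)

  # rtracklayer: sequence content including Ns
  seqs <- rtracklayer::import(rtracklayer::TwoBitFile(tb))
  expect_equal(names(seqs), names(h))
  for (i in seq_along(fx$records)) {
    expect_identical(toupper(as.character(seqs[[i]])),
                     toupper(fx$records[[i]]$symbols))
  }
  # independent in-test parser: case and Ns both intact
  got <- read_twobit_oracle(tb)
  for (i in seq_along(fx$records)) {
    expect_identical(got[[fx$records[[i]]$name]], fx$records[[i]]$symbols)
  }

  # explicit nBlock mapping
  h2 <- open_archive(make_archive(list(list(name = "s", symbols = "ACNNGT"))))
  blob <- export_twobit(h2)
  oracle <- read_twobit_oracle({f <- tempfile(); writeBin(blob, f); f})
  expect_identical(oracle$s, "ACNNGT")

  # refusal for anything but plain DNA, naming the sequence
  hp <- open_archive(make_archive(list(list(name = "prot1", symbols = "MKWVTE"))))
  err <- expect_error(export_twobit(hp), class = "fastar_unsupported_alphabet")
  expect_match(conditionMessage(err), "prot1")
  hr <- open_archive(make_archive(list(list(name = "rna1", symbols = "ACGU"))))
  expect_error(export_twobit(hr), class = "fastar_unsupported_alphabet")
})

test_that("region strings parse with samtools semantics", {
  recs <- list(list(name = "chr1", symbols = strrep("ACGTT", 600)),
               list(name = "HLA:01", symbols = "ACGTACGT"))
  h <- open_archive(make_archive(recs))
  r <- parse_region(h, "chr1:10-20")
  expect_equal(r[c("name", "start", "end")], list(name = "chr1", start = 10, end = 20))
  expect_equal(r$end - r$start + 1, 11)   # 10th..20th inclusive = 11 symbols
  expect_equal(parse_region(h, "chr1")$end, 3000)
  expect_equal(parse_region(h, "chr1:42")$end, 3000)
  expect_equal(parse_region(h, "chr1:1,001-2,000")[c("start", "end")],
               list(start = 1001, end = 2000))
  # exact-name match wins over coordinate parsing
  expect_equal(parse_region(h, "HLA:01")$name, "HLA:01")
  expect_error(parse_region(h, "chr1:0-5"), class = "fastar_parse_error")
  expect_error(parse_region(h, "chr1:9-5"), class = "fastar_parse_error")
  expect_error(parse_region(h, "chrX:1-5"), class = "fastar_lookup")
  expect_error(parse_region(h, "chr1:4000-4100"), class = "fastar_range_error")
  expect_equal(parse_region(h, "chr1:2999-99999")$end, 3000)  # clamped
})

test_that("extract_region returns bare symbols at bounded cost", {
  fx <- generate_fasta(97, n_records = 1, length_range = c(200000, 200000),
                       alphabet = "NUC2", n_fraction = 0.05, mask_fraction = 0.2)
  h <- open_archive(make_archive(fixture_records(fx), frame_size = 4096))
  sym <- fx$records[[1]]$symbols
  got <- extract_region(h, "seq1:10-20")
  expect_identical(as.character(got), substr(sym, 10, 20))
  expect_identical(as.character(extract_region(h, "seq1")), sym)
  expect_equal(sequence_length(h, "seq1"), 200000)
  expect_error(sequence_length(h, "nope"), class = "fastar_lookup")
  fastar:::with_seed(5, {
    for (k in 1:200) {
      a <- sample(200000, 1)
      b <- sample(a:200000, 1)
      got <- extract_region(h, sprintf("seq1:%d-%d", a, b))
      expect_identical(as.character(got), substr(sym, a, b))
      bytes_needed <- ceiling((b - a + 1) * 2 / 8)
      expect_lte(attr(got, "frames_touched"), ceiling(bytes_needed / 4096) + 2)
    }
  })
  # masking off through the same path
  up <- extract_region(h, "seq1", apply_mask = FALSE)
  expect_identical(as.character(up), toupper(sym))
})
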