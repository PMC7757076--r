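test_that("read_fasta normalizes case, folds ambiguity codes and keeps order", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt", ">s2 description here", "ACRT", ">s3", "AC", "GT"), p)
  expect_message(read_fasta(p), "folded 1")
  g <- suppressMessages(read_fasta(p))
  expect_s3_class(g, "GenomeSequences")
  expect_identical(names(g), c("s1", "s2", "s3"))
  expect_identical(unclass(g)[["s1"]], "ACGT")
  expect_identical(unclass(g)[["s2"]], "ACNT")   # R -> N
  expect_identical(unclass(g)[["s3"]], "ACGT")   # wrapped record
  expect_identical(attr(g, "folded"), 1L)
})

test_that("read_fasta rejects duplicate names and empty records", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC", ">s1", "GG"), p)
  expect_error(read_fasta(p), "duplicate name s1")
  p2 <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "", ">s2", "ACGT"), p2)
  expect_error(read_fasta(p2), "empty sequence")
})

test_that("RepeatMasker .out parsing: coordinates, strand, class mapping", {
  ann <- suppressWarnings(read_repeatmasker_out(rm_out_fixture()))
  # 1-based inclusive 101..200 becomes 0-based half-open [100, 200)
  expect_equal(ann$start[1], 100)
  expect_equal(ann$end[1], 200)
  expect_equal(ann$repeat_class[1], "LINE")
  expect_equal(ann$strand[2], "-")          # 'C' strand code
  expect_equal(ann$repeat_class[2], "LTR")
  expect_equal(ann$repeat_class[3], "SimpleRepeat")
  # unmatched class falls back to Unknown with a warning
  expect_warning(read_repeatmasker_out(rm_out_fixture()), "Unknown")
  expect_equal(ann$repeat_class[5], "Unknown")
  # hand-computed per-class bp totals on the fixture
  bp <- tapply(ann$end - ann$start, ann$repeat_class, sum)
  expect_equal(bp[["LINE"]], 100)
  expect_equal(bp[["LTR"]], 100)
  expect_equal(bp[["SimpleRepeat"]], 100)
  expect_equal(bp[["Satellite"]], 60)
  expect_equal(bp[["Unknown"]], 30)
})

test_that("RepeatMasker parser skips malformed rows and errors above 10%", {
  lines <- readLines(rm_out_fixture())
  p <- tempfile(); writeLines(c(lines, rep("garbage row", 20)), p)
  expect_error(suppressWarnings(read_repeatmasker_out(p)), "> 10%")
  p2 <- tempfile()
  # exactly one malformed row among 20 good ones
  good <- rep(lines[4:8], 4)
  writeLines(c(lines[1:3], good, "garbage"), p2)
  expect_warning(
    expect_warning(ann <- read_repeatmasker_out(p2), "skipped 1 malformed"),
    "Unknown")
  expect_equal(nrow(ann), 20)
})

test_that("rows on sequences absent from the companion assembly are rejected", {
  g <- gs(s1 = "ACGTACGT")
  expect_message(
    ann <- suppressWarnings(read_repeatmasker_out(rm_out_fixture(), genome = g)),
    "rejected 3")
  expect_true(all(ann$seq_name == "s1"))
})

test_that("BED round-trip preserves intervals and labels", {
  iv <- data.frame(seq_name = c("s1", "s2"), start = c(100L, 0L),
                   end = c(200L, 50L), label = c("LTR", "LINE"),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".bed")
  write_bed(iv, p)
  expect_identical(readLines(p)[1], "s1\t100\t200\tLTR\t0\t+")
  back <- read_bed(p)
  expect_equal(back[, c("seq_name", "start", "end", "label", "strand")],
               iv[, c("seq_name", "start", "end", "label", "strand")])
  # empty list -> empty file
  p2 <- tempfile(fileext = ".bed")
  write_bed(iv[0, ], p2)
  expect_length(readLines(p2), 0)
  # invalid interval errors before writing
  bad <- data.frame(seq_name = "s1", start = 10L, end = 10L, label = "x")
  expect_error(write_bed(bad, tempfile()), "invalid interval")
})

test_that("reports carry a provenance comment header", {
  p <- tempfile(fileext = ".tsv")
  write_report_tsv(data.frame(a = 1), p, config = analysis_config(),
                   inputs = "in.fa")
  l <- readLines(p)
  expect_match(l[1], "^# gapscope .*config=[0-9a-f]+.*in\\.fa")
  expect_identical(l[2], "a")
})
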