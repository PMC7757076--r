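test_that("find_gaps reports maximal N-runs with terminal flags", {
  g <- gs(s = "AANNNNAA")
  expect_equal(find_gaps(g, 1)[, c("start", "end", "terminal")],
               data.frame(start = 2L, end = 6L, terminal = FALSE))
  expect_equal(nrow(find_gaps(g, 11)), 0)    # the longer-than-10-bp rule
  g2 <- gs(s = "NNACGT")
  fg <- find_gaps(g2, 1)
  expect_equal(fg$start, 0L)
  expect_equal(fg$end, 2L)
  expect_true(fg$terminal)
})

test_that("split_contigs cuts at long N-runs only", {
  g <- gs(s = paste0("AA", strrep("N", 25), "GG"))
  ct <- split_contigs(g, 25)
  expect_equal(ct$start, c(0L, 27L))
  expect_equal(ct$end, c(2L, 29L))
  g2 <- gs(s = paste0("AA", strrep("N", 10), "GG"))
  ct2 <- split_contigs(g2, 25)
  expect_equal(ct2$start, 0L)
  expect_equal(ct2$end, 14L)   # short run retained inside the contig
  g3 <- gs(s = "ACGT")
  expect_equal(split_contigs(g3, 25)$end, 4L)
})

test_that("nx_statistic matches its examples and rejects bad input", {
  expect_equal(nx_statistic(c(6, 5, 4, 3, 2), 50), 5)
  expect_equal(nx_statistic(10, 50), 10)
  expect_equal(nx_statistic(c(6, 5, 4, 3, 2), 100), 2)
  expect_error(nx_statistic(numeric(0), 50), "empty")
})

test_that("assembly_summary counts and conserves totals", {
  g <- gs(s = paste0("AA", strrep("N", 25), "GGGG"))
  st <- assembly_summary(g)
  expect_equal(st$scaffold_count, 1)
  expect_equal(st$contig_count, 2)
  expect_equal(st$gap_count, 1)
  expect_equal(st$gap_bp, 25)
  expect_equal(st$total_len, 31)
  expect_equal(st$total_len_no_n, 6)
  expect_equal(st$total_len_no_n + st$gap_bp, st$total_len)
  g2 <- gs(a = "ACGT", b = "ACGTACGT")
  expect_equal(assembly_summary(g2)$scaffold_n50, 8)
  # all-N scaffold contributes no contigs
  g3 <- gs(a = "ACGTACGT", b = strrep("N", 30))
  expect_warning(st3 <- assembly_summary(g3), "no contigs")
  expect_equal(st3$contig_count, 1)
})

test_that("missing_fraction follows the N-free size formula, sign kept", {
  mk <- function(no_n) structure(list(total_len_no_n = no_n), class = "AssemblyStats")
  expect_equal(missing_fraction(mk(900), mk(1000)), 10.0)
  expect_equal(missing_fraction(mk(1000), mk(1000)), 0.0)
  expect_warning(v <- missing_fraction(mk(1030), mk(1000)), "negative")
  expect_equal(v, -3.0)
  expect_error(missing_fraction(mk(1), mk(0)), "> 0")
})

test_that("simplified LAI is full-length LTR bp over all LTR bp", {
  ann <- repeat_annotation(data.frame(
    seq_name = "s", start = c(0L, 1000L), end = c(200L, 1800L),
    strand = "+", repeat_class = "LTR", family = "x",
    full_length = c(TRUE, FALSE)))
  expect_equal(lai_simplified(ann), 100 * 200 / 1000)
  ann2 <- ann; ann2$full_length <- TRUE
  expect_equal(lai_simplified(ann2), 100)
  noltr <- repeat_annotation(data.frame(
    seq_name = "s", start = 0L, end = 10L, strand = "+",
    repeat_class = "LINE", family = "x"))
  expect_warning(v <- lai_simplified(noltr), "undefined")
  expect_true(is.na(v))
})

test_that("contig count equals scaffolds plus internal gaps at split_n = 1", {
  set.seed(404)
  for (i in 1:25) {
    n_scf <- sample(1:4, 1)
    seqs <- vapply(seq_len(n_scf), function(j) {
      s <- random_dna_str(sample(50:200, 1))
      for (k in seq_len(sample(0:4, 1))) {
        p <- sample(nchar(s) - 10, 1)
        s <- paste0(substr(s, 1, p), strrep("N", sample(1:8, 1)),
                    substr(s, p + 1, nchar(s)))
      }
      s
    }, character(1))
    names(seqs) <- paste0("s", seq_len(n_scf))
    g <- gs(seqs)
    gaps <- find_gaps(g, 1)
    internal <- sum(!gaps$terminal)
    ct <- split_contigs(g, 1)
    # terminal runs shave scaffold ends; internal runs add one contig each
    expect_equal(nrow(ct), n_scf + internal)
  }
})
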