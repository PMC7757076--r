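test_that("exact substrings align with full identity and coverage", {
  set.seed(101)
  t <- random_dna_str(3000)
  q <- substr(t, 1001, 1500)
  h <- align_local(c(q = q), c(t1 = t))
  expect_gte(nrow(h), 1)
  top <- h[1, ]
  expect_equal(top$identity, 100)
  expect_equal(top$query_coverage, 100)
  expect_equal(top$strand, "+")
  expect_equal(c(top$tstart, top$tend), c(1000L, 1500L))
  expect_lt(top$evalue, 1e-20)
})

test_that("reverse-complement queries flip strand and preserve span and score", {
  set.seed(102)
  t <- random_dna_str(2500)
  q <- substr(t, 501, 900)
  qr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  hf <- align_local(c(q = q), c(t1 = t))[1, ]
  hr <- align_local(c(q = qr), c(t1 = t))[1, ]
  expect_equal(hr$strand, "-")
  expect_equal(c(hr$tstart, hr$tend), c(hf$tstart, hf$tend))
  expect_equal(hr$score, hf$score)
})

test_that("identity arithmetic: 11 mismatches in 500 bp fails a 98% filter", {
  set.seed(103)
  t <- random_dna_str(4000)
  q <- substr(t, 2001, 2500)
  v <- strsplit(q, "")[[1]]
  pos <- seq(20, 480, length.out = 11)   # scattered, no adjacent pairs
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  q2 <- paste(v, collapse = "")
  h <- align_local(c(q = q2), c(t1 = t))[1, ]
  expect_equal(h$matches, 489)
  expect_equal(h$aligned_cols, 500)
  expect_equal(h$identity, 100 * 489 / 500)
  expect_equal(nrow(filter_hits(h, analysis_config())), 0)
})

test_that("filter_hits keeps boundary hits, is idempotent, preserves order", {
  cfg <- analysis_config()
  hits <- data.frame(identity = c(98.0, 97.9, 99.5),
                     query_coverage = c(90.0, 99, 89.9),
                     evalue = c(1e-21, 0, 1e-30))
  kept <- filter_hits(hits, cfg)
  expect_equal(nrow(kept), 1)           # boundary-inclusive: 98 / 90 / <=1e-20
  expect_equal(kept$identity, 98.0)
  expect_identical(filter_hits(kept, cfg), kept)
  expect_identical(filter_hits(hits[0, ], cfg), hits[0, ])
})

test_that("seed-and-extend equals a full Smith-Waterman oracle on mutated pairs", {
  set.seed(104)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  p11 <- align_params(k = 11)
  for (i in 1:40) {
    t <- random_dna_str(sample(600:2000, 1))
    a <- sample(50:(nchar(t) - 400), 1)
    L <- sample(250:380, 1)
    q <- substr(t, a, a + L - 1)
    v <- strsplit(q, "")[[1]]
    for (p in sample(length(v), sample(0:7, 1)))
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    if (runif(1) < 0.5) {                 # one short indel
      p <- sample(length(v) - 6, 1)
      if (runif(1) < 0.5) v <- append(v, strsplit(random_dna_str(3), "")[[1]], p)
      else v <- v[-(p:(p + 2))]
    }
    q <- paste(v, collapse = "")
    h <- align_local(c(q = q), c(t1 = t), p11)
    sw <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2))
    expect_equal(max(h$score), sw)
  }
})

test_that("translated search finds planted exons on both strands", {
  set.seed(105)
  prot <- paste(sample(gapscope:::AA20, 90, TRUE), collapse = "")
  nt <- gapscope:::back_translate(prot)
  g <- gs(s1 = paste0(random_dna_str(1000), nt, random_dna_str(1000)),
          s2 = paste0(random_dna_str(503), gapscope:::revcomp_chr(nt),
                      random_dna_str(700)))
  h <- translated_search(c(ex = prot), g)
  h1 <- h[h$target_name == "s1", ][1, ]
  h2 <- h[h$target_name == "s2", ][1, ]
  expect_equal(h1$identity, 100)
  expect_equal(h1$strand, "+")
  expect_equal(c(h1$tstart, h1$tend), c(1000L, 1270L))
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$tstart, h2$tend), c(503L, 773L))
  expect_error(translated_search(c(x = strrep("A1", 20)), g), "non-amino-acid")
})

test_that("an in-frame insertion yields one gapped hit matching the DP oracle", {
  set.seed(106)
  prot <- paste(sample(gapscope:::AA20, 80, TRUE), collapse = "")
  nt <- gapscope:::back_translate(prot)
  # 9 bp (3 codon) in-frame insertion mid-exon
  ins <- gapscope:::back_translate("WYD")
  nt2 <- paste0(substr(nt, 1, 120), ins, substr(nt, 121, nchar(nt)))
  g <- gs(s1 = paste0(random_dna_str(600), nt2, random_dna_str(600)))
  h <- translated_search(c(ex = prot), g)
  expect_equal(nrow(h), 1)
  expect_gte(h$gap_opens[1], 1)
  cnt <- gapscope:::parse_cigar(h$cigar[1])
  expect_equal(unname(cnt["M"] + cnt["I"]), 80)   # aligned query residues
  # full dynamic-programming oracle on the translated frame
  frame_prot <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(unclass(g)[["s1"]], 1, 1509))))
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  sw <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot), Biostrings::AAString(frame_prot),
    type = "local", substitutionMatrix = env$BLOSUM62,
    gapOpening = 11, gapExtension = 1))
  expect_equal(h$score[1], sw)
})

test_that("queries shorter than the seed are skipped with a warning", {
  expect_warning(h <- align_local(c(q = "ACGTACGT"), c(t = random_dna_str(100))),
                 "shorter than the seed")
  expect_equal(nrow(h), 0)
})

test_that("outfmt-6 import converts coordinates and minus-strand encoding", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t98.5\t200\t3\t0\t1\t200\t501\t700\t1e-50\t350",
               "q1\ts1\t95.0\t100\t5\t1\t50\t149\t900\t801\t1e-20\t150"), p)
  h <- read_blast_tab(p, query_lengths = c(q1 = 200))
  expect_equal(h$qstart[1], 0L)
  expect_equal(c(h$tstart[1], h$tend[1]), c(500L, 700L))
  expect_equal(h$strand[1], "+")
  expect_equal(h$strand[2], "-")
  expect_equal(c(h$tstart[2], h$tend[2]), c(800L, 900L))
  expect_equal(h$query_coverage[1], 100)
})
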