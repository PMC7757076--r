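test_that("generation is byte-identical under one seed and differs across seeds", {
  cfg <- tiny_sim_config(seed = 21)
  t1 <- build_truth_genome(cfg)
  t2 <- build_truth_genome(cfg)
  expect_identical(unclass(t1$genome), unclass(t2$genome))
  expect_identical(t1$repeats, t2$repeats)
  d1 <- derive_draft(t1)
  d2 <- derive_draft(t2)
  expect_identical(unclass(d1$draft), unclass(d2$draft))
  t3 <- build_truth_genome(tiny_sim_config(seed = 22))
  expect_false(identical(unclass(t1$genome), unclass(t3$genome)))
})

test_that("the W chromosome hits its repeat-density target", {
  truth <- default_truth()
  w <- truth$repeats[truth$repeats$seq_name == "chrW", , drop = FALSE]
  dens <- 100 * gapscope:::merged_bp(w) / seq_lengths(truth$genome)[["chrW"]]
  expect_gte(dens, 68)
  expect_lte(dens, 72)
})

test_that("microchromosomes realize their configured GC within binomial bounds", {
  truth <- default_truth()
  for (nm in grep("^micro", names(truth$genome), value = TRUE)) {
    s <- Biostrings::DNAString(unclass(truth$genome)[[nm]])
    f <- Biostrings::letterFrequency(s, c("G", "C"))
    gc <- 100 * sum(f) / length(s)
    expect_gte(gc, 57)
    expect_lte(gc, 63)
  }
})

test_that("planted LTR elements carry near-identical terminal repeats", {
  truth <- default_truth()
  cfg <- truth$cfg
  full <- truth$repeats[truth$repeats$repeat_class == "LTR" &
                          gapscope:::isTRUE_vec(truth$repeats$full_length), ]
  expect_gte(nrow(full), 5)
  r <- full[1, ]
  s <- substr(unclass(truth$genome)[[r$seq_name]], r$start + 1, r$end)
  left <- substr(s, 1, cfg$ltr_tr_len)
  right <- substr(s, nchar(s) - cfg$ltr_tr_len + 1, nchar(s))
  ident <- mean(strsplit(left, "")[[1]] == strsplit(right, "")[[1]])
  expect_gte(ident, 0.99)
})

test_that("contig map reconstructs the truth exactly at mutation rate zero", {
  truth <- build_truth_genome(tiny_sim_config(seed = 23))
  d <- derive_draft(truth)
  for (i in seq_len(nrow(d$contig_map))) {
    m <- d$contig_map[i, ]
    got <- substr(unclass(d$draft)[[m$scaffold]], m$d_start + 1, m$d_end)
    want <- substr(unclass(truth$genome)[[m$t_seq]], m$t_start + 1, m$t_end)
    expect_identical(got, want)
  }
  # gap intervals in the draft are the inserted N runs
  gaps <- find_gaps(d$draft, 1)
  expect_equal(nrow(gaps), nrow(d$gap_truth))
  expect_true(all(gaps$length == truth$cfg$gap_n_len))
})

test_that("a satellite-only break bias yields satellite gap causes", {
  bias <- c(LINE = 0, SINE = 0, LTR = 0, DNA = 0, Satellite = 1,
            SimpleRepeat = 0, LowComplexity = 0, rRNA = 0, Unknown = 0,
            Other = 0)
  cfg <- tiny_sim_config(seed = 24, break_bias = bias, n_breaks = 6,
                         n_background_breaks = 0, n_compound = 0)
  truth <- build_truth_genome(cfg)
  d <- derive_draft(truth)
  gt <- d$gap_truth[is.na(d$gap_truth$expect), ]
  # the gene-split break is planted unconditionally and is NoRepeat
  causes <- gt$cause[gt$cause != "NoRepeat"]
  expect_true(length(causes) >= 3)
  expect_true(all(causes == "Satellite"))
})

test_that("coverage simulation follows the ploidy factors with Poisson noise", {
  contigs <- data.frame(contig = c("a", "z", "w", "p"), length = 50000L,
                        class = c("macro", "Z", "W", "PAR"),
                        stringsAsFactors = FALSE)
  f <- simulate_coverage(contigs, 30, "female", seed = 9)
  m <- simulate_coverage(contigs, 30, "male", seed = 9)
  expect_equal(f$mean_depth[1], 30, tolerance = 0.1)
  expect_equal(f$mean_depth[2], 15, tolerance = 0.1)   # Z female half
  expect_equal(m$mean_depth[2], 30, tolerance = 0.1)
  expect_equal(m$mean_depth[3], 0)                     # W male absent
  expect_equal(f$mean_depth[4], 30, tolerance = 0.1)   # PAR diploid
  # determinism under seed
  expect_identical(f, simulate_coverage(contigs, 30, "female", seed = 9))
})

test_that("infeasible repeat mixes are rejected before generation", {
  # percent validation at configuration time
  mix <- list(macro = c(LTR = 60, Satellite = 30),
              micro = c(LTR = 4), Z = c(LTR = 4), W = c(Satellite = 35))
  expect_error(tiny_sim_config(seed = 25, repeat_mix = mix), "<= 80")
  # valid percents that still overflow the chromosome with wide spacing
  mix$macro <- c(Satellite = 75)
  expect_error(
    build_truth_genome(tiny_sim_config(seed = 25, repeat_mix = mix,
                                       min_feature_gap = 2500)),
    "overflow|infeasible")
})
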