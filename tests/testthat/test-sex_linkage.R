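mk_cov <- function(n_auto = 30, extras = NULL, depth = 30) {
  base <- data.frame(contig = paste0("a", seq_len(n_auto)),
                     length = 20000L,
                     mean_depth_female = depth * (1 + rnorm(n_auto, 0, 0.02)),
                     mean_depth_male = depth * (1 + rnorm(n_auto, 0, 0.02)),
                     stringsAsFactors = FALSE)
  rbind(base, extras)
}

test_that("coverage-ratio rules call Z, W and PAR/autosome correctly", {
  set.seed(501)
  extras <- data.frame(
    contig = c("z1", "w1", "p1"), length = 20000L,
    mean_depth_female = c(15, 15, 29.1),
    mean_depth_male = c(30, 0.6, 30.3), stringsAsFactors = FALSE)
  calls <- classify_sex_linkage(mk_cov(extras = extras))
  expect_equal(calls$call[calls$contig == "z1"], "Z")
  expect_equal(calls$call[calls$contig == "w1"], "W")
  expect_equal(calls$call[calls$contig == "p1"], "PAR_or_Autosome")
  expect_true(all(calls$call[startsWith(calls$contig, "a")] == "PAR_or_Autosome"))
  # out-of-window contigs stay Unclassified
  odd <- data.frame(contig = "x1", length = 20000L,
                    mean_depth_female = 2, mean_depth_male = 60)
  calls2 <- classify_sex_linkage(mk_cov(extras = odd))
  expect_equal(calls2$call[calls2$contig == "x1"], "Unclassified")
})

test_that("the homology route forces Z above the 60% fraction, strictly", {
  set.seed(502)
  extras <- data.frame(contig = c("h1", "h2"), length = 20000L,
                       mean_depth_female = c(30, 30),
                       mean_depth_male = c(30, 30), stringsAsFactors = FALSE)
  cov <- mk_cov(extras = extras)
  calls <- classify_sex_linkage(cov, z_hom = c(h1 = 0.61, h2 = 0.60))
  expect_equal(calls$call[calls$contig == "h1"], "Z")
  expect_equal(calls$call[calls$contig == "h2"], "PAR_or_Autosome")
})

test_that("calls are invariant under a global depth rescaling", {
  set.seed(503)
  extras <- data.frame(contig = c("z1", "w1"), length = 20000L,
                       mean_depth_female = c(15, 15.2),
                       mean_depth_male = c(29.5, 0.1), stringsAsFactors = FALSE)
  cov <- mk_cov(extras = extras)
  c1 <- classify_sex_linkage(cov)
  cov2 <- cov
  cov2$mean_depth_female <- cov2$mean_depth_female * 7.3
  cov2$mean_depth_male <- cov2$mean_depth_male * 7.3
  c2 <- classify_sex_linkage(cov2)
  expect_equal(c1$call, c2$call)
})

test_that("degenerate inputs are rejected", {
  set.seed(504)
  expect_error(classify_sex_linkage(mk_cov(n_auto = 10)), "at least 20")
  cov <- mk_cov()
  cov$mean_depth_female <- 0
  expect_error(classify_sex_linkage(cov), "degenerate")
})

test_that("chimeric scaffolds mix sex-linked and autosomal contigs", {
  comp <- data.frame(
    scaffold = c("s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    contig = paste0("c", 1:7),
    call = c("W", "PAR_or_Autosome", "Z", "Z", "Unclassified",
             "PAR_or_Autosome", "PAR_or_Autosome"),
    stringsAsFactors = FALSE)
  expect_equal(flag_chimeric_scaffolds(comp), "s1")
})

test_that("homology fraction covers verbatim slices fully and noise not at all", {
  set.seed(505)
  z <- random_dna_str(30000)
  zg <- gs(chrZ = z)
  piece <- substr(z, 5001, 13000)
  expect_gte(homology_fraction(piece, zg), 0.99)
  expect_lte(homology_fraction(random_dna_str(5000), zg), 0.01)
})

test_that("simulated coverage recovers >= 98% of contig calls at 10 kb", {
  d0 <- default_draft()
  cov <- coverage_table(d0, depth = 30)
  calls <- classify_sex_linkage(cov)
  expected <- ifelse(d0$contigs$class %in% c("Z", "W"), d0$contigs$class,
                     "PAR_or_Autosome")
  big <- d0$contigs$length >= 10000
  expect_gte(mean((calls$call == expected)[big]), 0.98)
  # ploidy factors: W contigs get no male reads, half female depth
  wrows <- simulate_coverage(d0$contigs, 30, "male", seed = 5)
  expect_true(all(wrows$mean_depth[d0$contigs$class == "W"] == 0))
})
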