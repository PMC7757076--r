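mk_gaps <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(scaffold = r[[1]], start = r[[2]], end = r[[3]],
               length = r[[3]] - r[[2]], terminal = FALSE,
               stringsAsFactors = FALSE)))
}

mk_rep <- function(df) {
  df$strand <- "+"; df$family <- "x"
  repeat_annotation(df)
}

test_that("adjacency window is inclusive to 100 bp and strict at 101", {
  cfg <- analysis_config()
  gaps <- mk_gaps(list("s", 1000L, 1100L))
  near <- mk_rep(data.frame(seq_name = "s", start = 850L, end = 950L,
                            repeat_class = "LTR"))       # distance 50
  expect_equal(classify_adjacency(gaps, near, cfg)$label, "LTR")
  far <- mk_rep(data.frame(seq_name = "s", start = 800L, end = 899L,
                           repeat_class = "LTR"))        # distance 101
  expect_equal(classify_adjacency(gaps, far, cfg)$label, "NoRepeat")
  at100 <- mk_rep(data.frame(seq_name = "s", start = 800L, end = 900L,
                             repeat_class = "LTR"))      # distance 100
  expect_equal(classify_adjacency(gaps, at100, cfg)$label, "LTR")
})

test_that("nearest repeat wins among several classes; multiset is preserved", {
  cfg <- analysis_config()
  gaps <- mk_gaps(list("s", 1000L, 1100L))
  reps <- mk_rep(data.frame(seq_name = "s",
                            start = c(930L, 1160L), end = c(990L, 1220L),
                            repeat_class = c("LTR", "Satellite")))
  out <- classify_adjacency(gaps, reps, cfg)   # distances 10 and 60
  expect_equal(out$label, "LTR")
  expect_equal(out$n_classes, 2L)
  expect_setequal(strsplit(out$classes, ",")[[1]], c("LTR", "Satellite"))
  # distance tie (both overlap): larger overlap wins
  reps2 <- mk_rep(data.frame(seq_name = "s",
                             start = c(1050L, 1060L), end = c(1070L, 1120L),
                             repeat_class = c("LINE", "Satellite")))
  expect_equal(classify_adjacency(gaps, reps2, cfg)$label, "Satellite")
})

test_that("flank extraction arithmetic and skip conditions", {
  cfg <- analysis_config()
  s <- random_dna_str(2000)
  s2 <- paste0(substr(s, 1, 1000), strrep("N", 100), substr(s, 1101, 2000))
  g <- gs(s = s2)
  gap <- find_gaps(g, 1)[1, ]
  fl <- extract_flanks(gap, g, cfg)
  expect_equal(fl$status, "ok")
  expect_equal(fl$left, substr(s2, 501, 1000))
  expect_equal(fl$right, substr(s2, 1101, 1600))
  # left side shorter than the flank
  g2 <- gs(s = paste0(random_dna_str(200), strrep("N", 100), random_dna_str(800)))
  expect_equal(extract_flanks(find_gaps(g2, 1)[1, ], g2, cfg)$status, "skip")
  # flank mostly N (adjacent second gap)
  g3 <- gs(s = paste0(random_dna_str(800), strrep("N", 100),
                      random_dna_str(150), strrep("N", 400),
                      random_dna_str(800)))
  gaps3 <- find_gaps(g3, 1)
  expect_equal(extract_flanks(gaps3[1, ], g3, cfg)$status, "skip")
  # terminal gaps skip
  g4 <- gs(s = paste0(strrep("N", 50), random_dna_str(1500)))
  expect_equal(extract_flanks(find_gaps(g4, 1)[1, ], g4, cfg)$status, "skip")
  expect_equal(extract_flanks(find_gaps(g4, 1)[1, ], g4, cfg)$reason,
               "terminal_gap")
})

test_that("place_gap implements the unambiguous-liftover rules", {
  set.seed(201)
  cfg <- analysis_config()
  ref_seq <- random_dna_str(6000)
  ref <- gs(chr1 = ref_seq, chr2 = random_dna_str(3000))
  # identity liftover: draft = reference with [2500, 2800) excised
  draft <- gs(d = paste0(substr(ref_seq, 1, 2500), strrep("N", 100),
                         substr(ref_seq, 2801, 6000)))
  gap <- find_gaps(draft, 1)[1, ]
  fl <- extract_flanks(gap, draft, cfg)
  pl <- place_gap(gap, fl, ref, cfg)
  expect_equal(pl$status, "placed")
  expect_equal(pl$placement$target_name, "chr1")
  expect_equal(c(pl$placement$proj_start, pl$placement$proj_end),
               c(2500L, 2800L))
  expect_equal(pl$placement$orientation, "+")
  # left flank duplicated in the reference -> ambiguous
  dupref <- gs(chr1 = ref_seq,
               chr2 = paste0(random_dna_str(1000), substr(ref_seq, 2001, 2500),
                             random_dna_str(1000)))
  pl2 <- place_gap(gap, fl, dupref, cfg)
  expect_equal(pl2$status, "not_scorable")
  expect_equal(pl2$reason, "ambiguous")
  # flanks on different reference sequences
  splitref <- gs(chr1 = substr(ref_seq, 1, 2500),
                 chr2 = substr(ref_seq, 2801, 6000))
  pl3 <- place_gap(gap, fl, splitref, cfg)
  expect_equal(pl3$status, "not_scorable")
  expect_equal(pl3$reason, "different_scaffolds")
  # only one flank present
  oneref <- gs(chr1 = paste0(substr(ref_seq, 1, 2500), random_dna_str(3000)))
  pl4 <- place_gap(gap, fl, oneref, cfg)
  expect_equal(pl4$status, "not_scorable")
  expect_equal(pl4$reason, "one_flank_only")
  # no homology at all
  pl5 <- place_gap(gap, fl, gs(chr1 = random_dna_str(5000)), cfg)
  expect_equal(pl5$status, "not_scorable")
  expect_equal(pl5$reason, "no_homology")
  # span guard
  cfg2 <- analysis_config(max_projected_span = 200L)
  expect_warning(pl6 <- place_gap(gap, fl, ref, cfg2), "max_projected_span")
  expect_equal(pl6$reason, "span_exceeded")
})

test_that("content classification follows the single/complex/reference-gap rules", {
  cfg <- analysis_config()
  pl <- list(target_name = "chr1", proj_start = 1000L, proj_end = 2000L)
  no_gaps <- data.frame(scaffold = character(), start = integer(),
                        end = integer())
  sat <- mk_rep(data.frame(seq_name = "chr1", start = 1200L, end = 1600L,
                           repeat_class = "Satellite"))
  expect_equal(classify_content(pl, sat, no_gaps, cfg)$label, "Satellite")
  two <- mk_rep(data.frame(seq_name = "chr1", start = c(1100L, 1700L),
                           end = c(1300L, 1900L),
                           repeat_class = c("LTR", "SimpleRepeat")))
  expect_equal(classify_content(pl, two, no_gaps, cfg)$label, "Complex")
  none <- mk_rep(data.frame(seq_name = "chr1", start = 5000L, end = 5100L,
                            repeat_class = "LTR"))
  expect_equal(classify_content(pl, none, no_gaps, cfg)$label, "NoRepeat")
  refgap <- data.frame(scaffold = "chr1", start = 1500L, end = 1600L)
  out <- classify_content(pl, sat, refgap, cfg)
  expect_equal(out$label, "NotScorable")
  expect_equal(out$reason, "maps_to_reference_gap")
})

test_that("repeat recovery is a merged-bp ratio with duplication flagging", {
  draft <- mk_rep(data.frame(seq_name = "s", start = c(0L, 100000L),
                             end = c(80000L, 220000L),
                             repeat_class = c("LTR", "LINE")))
  ref <- mk_rep(data.frame(seq_name = "s", start = c(0L, 100000L),
                           end = c(100000L, 200000L),
                           repeat_class = c("LTR", "LINE")))
  expect_warning(rec <- repeat_recovery(draft, ref), "haplotype")
  expect_equal(rec$recovery[rec$repeat_class == "LTR"], 0.80)
  expect_equal(rec$recovery[rec$repeat_class == "LINE"], 1.20)
  expect_true(rec$over_one[rec$repeat_class == "LINE"])
  expect_equal(rec$recovery[rec$repeat_class == "Satellite"], NA_real_)
  expect_equal(rec$recovery[rec$repeat_class == "SimpleRepeat"], NA_real_)
})

test_that("label tabulation reports both denominators", {
  adj <- c(rep("LTR", 4), rep("SimpleRepeat", 3), rep("NotScorable", 3))
  tab <- tabulate_figure_labels(adj, adj)
  a <- tab$adjacency
  expect_equal(a$n[a$label == "LTR"], 4L)
  expect_equal(a$prop_all[a$label == "LTR"], 0.4)
  expect_equal(a$prop_scorable[a$label == "LTR"], 4 / 7)
  expect_equal(a$prop_all[a$label == "NotScorable"], 0.3)
  expect_true(is.na(a$prop_scorable[a$label == "NotScorable"]))
  expect_equal(sum(a$n), 10L)
  empty <- tabulate_figure_labels(character(0), character(0))
  expect_true(all(is.na(empty$adjacency$prop_all)))
})
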