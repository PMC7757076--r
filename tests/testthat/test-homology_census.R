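test_that("merge_hits unions overlapping spans but keeps abutting apart", {
  h <- data.frame(target_name = "s", tstart = c(100L, 250L), tend = c(300L, 400L))
  expect_equal(merge_hits(h), data.frame(seq_name = "s", start = 100L, end = 400L))
  ab <- data.frame(target_name = "s", tstart = c(100L, 200L), tend = c(200L, 300L))
  expect_equal(nrow(merge_hits(ab)), 2)
  two <- data.frame(target_name = c("a", "b"), tstart = c(0L, 0L), tend = c(10L, 10L))
  expect_equal(nrow(merge_hits(two)), 2)
  # idempotent; merged bp never exceeds input bp
  m <- merge_hits(h)
  again <- merge_hits(data.frame(target_name = m$seq_name, tstart = m$start,
                                 tend = m$end))
  expect_equal(again, m)
  expect_lte(sum(m$end - m$start), sum(h$tend - h$tstart))
})

test_that("insertion-free hit length counts query-bearing columns times three", {
  # 90 query residues with one 3-residue target insertion: 270 nt
  expect_equal(hit_query_length(data.frame(cigar = "60M3D30M")), 270L)
  expect_equal(hit_query_length(data.frame(cigar = "80M")), 240L)
  expect_equal(hit_query_length(data.frame(cigar = "40M5I35M")), 240L)
  expect_error(hit_query_length(data.frame(cigar = NA_character_)), "no edit trace")
})

test_that("exon census counts planted paralogs and enforces the strict bound", {
  set.seed(401)
  prot <- paste(sample(gapscope:::AA20, 90, TRUE), collapse = "")
  mk_par <- function(div) {
    p <- gapscope:::mutate_protein(prot, div)
    gapscope:::back_translate(p)
  }
  spacer <- function() random_dna_str(sample(200:300, 1))
  # three full paralogs plus one truncated to exactly 80 residues (240 nt);
  # the stop codon pins the truncation boundary
  trunc80 <- paste0(gapscope:::back_translate(substr(prot, 1, 80)), "TAA")
  g <- gs(s = paste0(random_dna_str(800), mk_par(0.03), spacer(),
                     gapscope:::revcomp_chr(mk_par(0.05)), spacer(),
                     mk_par(0.02), spacer(), trunc80, random_dna_str(800)))
  qset <- exon_query_set("exon2", c(q = prot), 270, 240)
  cen <- exon_census(qset, g)
  # hits of exactly 240 nt insertion-free length are dropped (strictly longer)
  expect_equal(cen$census, 3)
  # lowering the bound to 239 admits the truncated copy
  qset2 <- exon_query_set("exon2", c(q = prot), 270, 239)
  expect_equal(exon_census(qset2, g)$census, 4)
  # back-validation hook filters merged intervals before counting
  cen3 <- exon_census(qset, g, validate = function(nm, s, e) s > 1500)
  expect_lt(cen3$census, 3)
})

test_that("paralogs separated by short spacers stay distinct intervals", {
  set.seed(402)
  prot <- paste(sample(gapscope:::AA20, 90, TRUE), collapse = "")
  nt <- gapscope:::back_translate(prot)
  g <- gs(s = paste0(random_dna_str(600), nt, random_dna_str(50), nt,
                     random_dna_str(600)))
  qset <- exon_query_set("exon2", c(q = prot), 270, 240)
  expect_equal(exon_census(qset, g)$census, 2)
})

test_that("gene presence classifies complete, partial and absent models", {
  set.seed(403)
  prot <- paste(sample(gapscope:::AA20, 200, TRUE), collapse = "")
  nt <- gapscope:::back_translate(prot)
  full <- gs(s = paste0(random_dna_str(500), nt, random_dna_str(500)))
  cfg <- analysis_config()
  gp <- gene_presence(c(g1 = prot), full, cfg)
  expect_equal(gp$status, "Complete")
  expect_equal(gp$aligned_fraction, 100)
  expect_equal(gp$similarity, 100)
  # middle 40% replaced by a gap: Partial
  cut <- paste0(substr(nt, 1, 180), strrep("N", 100), substr(nt, 421, 600))
  part <- gs(s = paste0(random_dna_str(500), cut, random_dna_str(500)))
  gp2 <- gene_presence(c(g1 = prot), part, cfg)
  expect_equal(gp2$status, "Partial")
  expect_lt(gp2$aligned_fraction, 95)
  # absent
  gp3 <- gene_presence(c(g1 = prot), gs(s = random_dna_str(2000)), cfg)
  expect_equal(gp3$status, "Absent")
  expect_equal(gp3$aligned_fraction, 0)
})

test_that("gene presence is Complete for every planted gene on the truth genome", {
  truth <- default_truth()
  gp <- gene_presence(setNames(truth$genes$protein, truth$genes$gene_id),
                      truth$genome)
  expect_true(all(gp$status == "Complete"))
  expect_equal(gp$scaffold, truth$genes$seq_name)
})
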