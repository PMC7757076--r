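# Seeded generator of avian-like truth genomes, repeat annotations,
# fragmented drafts with known gap causes, and sex-resolved coverage tables.
#
# The generator is the test substrate for the whole pipeline: every planted
# feature is annotated, every draft gap records the feature that caused it,
# and the draft-to-truth coordinate map reconstructs the truth exactly at
# mutation rate zero.

#' Simulation configuration
#'
#' Defaults emulate an avian-like genome at desk scale: AT-rich
#' macrochromosomes (GC 42%), GC-rich microchromosomes (GC 60%), a Z, and a
#' repeat-rich W (~70% repeats, satellite-dominated), with LTR elements
#' carrying near-identical 800 bp terminal repeats, 5'-truncated LINEs
#' (geometric truncation, p = 0.4, from the 3' end), ~170 bp satellite units,
#' simple repeats, DNA transposons, a tandem cluster of 12 exon paralogs on a
#' microchromosome, a handful of single-copy genes, and one duplicated 500 bp
#' segment planted to create an ambiguous-flank liftover case.
#'
#' @param n_macro,n_micro Numbers of macro/microchromosomes.
#' @param macro_len,micro_len,z_len,w_len Chromosome lengths (bp).
#' @param par_len Pseudoautosomal prefix shared verbatim by Z and W (bp).
#' @param macro_gc,micro_gc,w_gc Background GC percents per chromosome class.
#' @param include_sex Generate Z and W.
#' @param w_repeat_target Target repeat percent on W.
#' @param repeat_mix Named list (`macro`, `micro`, `Z`, `W`) of per-class
#'   target percents; `NULL` for the documented defaults.
#' @param ltr_len,ltr_tr_len Full LTR element and terminal-repeat lengths.
#' @param satellite_unit Satellite monomer length (bp).
#' @param line_full_len Full-length LINE consensus length (bp).
#' @param line_trunc_p Geometric truncation parameter.
#' @param n_exon_paralogs Tandem exon paralogs planted.
#' @param exon_len_aa Exon length in residues (90 = 270 nt).
#' @param n_genes Single-copy genes planted.
#' @param gene_len_aa Gene length in residues.
#' @param mutation_rate Per-base substitution rate applied to the draft only.
#' @param break_bias Named per-class relative break odds; `NULL` for
#'   defaults biased towards satellites, LTR elements and simple repeats.
#' @param gap_n_len N-run length inserted at each draft break.
#' @param n_breaks Target number of feature breaks.
#' @param n_background_breaks Breaks in plain background (NoRepeat gaps).
#' @param n_compound Adjacent-feature compounds planted (Complex gaps).
#' @param min_feature_gap Minimum background spacing between planted blocks.
#' @param seed Integer seed; every stage derives its own stream from it.
#' @return List with class `"SimulationConfig"`.
#' @export
simulation_config <- function(n_macro = 4L, n_micro = 4L,
                              macro_len = 500000L, micro_len = 100000L,
                              z_len = 300000L, w_len = 150000L,
                              par_len = 10000L,
                              macro_gc = 42, micro_gc = 60, w_gc = 45,
                              include_sex = TRUE, w_repeat_target = 70,
                              repeat_mix = NULL,
                              ltr_len = 8000L, ltr_tr_len = 800L,
                              satellite_unit = 170L,
                              line_full_len = 5000L, line_trunc_p = 0.4,
                              n_exon_paralogs = 12L, exon_len_aa = 90L,
                              n_genes = 5L, gene_len_aa = 200L,
                              mutation_rate = 0,
                              break_bias = NULL, gap_n_len = 100L,
                              n_breaks = 240L, n_background_breaks = 25L,
                              n_compound = 6L, min_feature_gap = 250L,
                              seed = 1L) {
  if (is.null(repeat_mix)) {
    repeat_mix <- list(
      macro = c(LTR = 6, LINE = 5, Satellite = 5, SimpleRepeat = 3, DNA = 2),
      micro = c(LTR = 4, LINE = 4, Satellite = 4, SimpleRepeat = 4),
      Z     = c(LTR = 6, LINE = 5, Satellite = 5, SimpleRepeat = 3, DNA = 2),
      W     = c(Satellite = 35, LTR = 20, LINE = 15))
  }
  # scale the W mix to the configured repeat target
  wsum <- sum(repeat_mix$W)
  if (wsum > 0) repeat_mix$W <- repeat_mix$W * (w_repeat_target / wsum)
  for (nm in names(repeat_mix)) {
    mix <- repeat_mix[[nm]]
    if (any(mix < 0 | mix > 100) || sum(mix) > 80)
      stop("repeat_mix for ", nm, " must be percents summing to <= 80")
  }
  if (is.null(break_bias))
    break_bias <- c(LINE = 1.5, SINE = 1, LTR = 3, DNA = 1, Satellite = 3,
                    SimpleRepeat = 2, LowComplexity = 1, rRNA = 1,
                    Unknown = 1, Other = 1)
  cfg <- list(n_macro = as.integer(n_macro), n_micro = as.integer(n_micro),
              macro_len = as.integer(macro_len), micro_len = as.integer(micro_len),
              z_len = as.integer(z_len), w_len = as.integer(w_len),
              par_len = as.integer(par_len),
              macro_gc = macro_gc, micro_gc = micro_gc, w_gc = w_gc,
              include_sex = isTRUE(include_sex),
              w_repeat_target = w_repeat_target, repeat_mix = repeat_mix,
              ltr_len = as.integer(ltr_len), ltr_tr_len = as.integer(ltr_tr_len),
              satellite_unit = as.integer(satellite_unit),
              line_full_len = as.integer(line_full_len), line_trunc_p = line_trunc_p,
              n_exon_paralogs = as.integer(n_exon_paralogs),
              exon_len_aa = as.integer(exon_len_aa),
              n_genes = as.integer(n_genes), gene_len_aa = as.integer(gene_len_aa),
              mutation_rate = mutation_rate, break_bias = break_bias,
              gap_n_len = as.integer(gap_n_len), n_breaks = as.integer(n_breaks),
              n_background_breaks = as.integer(n_background_breaks),
              n_compound = as.integer(n_compound),
              min_feature_gap = as.integer(min_feature_gap),
              seed = as.integer(seed))
  stopifnot(all(unlist(cfg[c("macro_len", "micro_len", "gap_n_len")]) > 0))
  class(cfg) <- "SimulationConfig"
  cfg
}

# One RNG stream per (seed, stage) so adding stages never perturbs the draws
# of earlier stages.
stage_seed <- function(seed, stage) {
  h <- 5381
  for (b in utf8ToInt(stage)) h <- (h * 33 + b) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 97771) * 104729) %% 2147483647)
}

with_stage <- function(seed, stage, expr) {
  set.seed(stage_seed(seed, stage))
  expr
}

rand_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((100 - gc) / 200, gc / 200, gc / 200, (100 - gc) / 200)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_dna <- function(s, rate) {
  n <- nchar(s)
  if (rate <= 0 || n == 0) return(s)
  k <- rbinom(1, n, rate)
  if (k == 0) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    if (v[p] == "N") next
    v[p] <- sample(setdiff(bases, v[p]), 1)
  }
  paste(v, collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

codon_table <- function() {
  b <- c("T", "C", "A", "G")
  # third position varies fastest, matching the amino-acid string below
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aa <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  split(codons, aa)
}

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

mutate_protein <- function(p, rate) {
  v <- strsplit(p, "")[[1]]
  k <- rbinom(1, length(v), rate)
  if (k > 0) {
    pos <- sample.int(length(v), k)
    for (i in pos) v[i] <- sample(setdiff(AA20, v[i]), 1)
  }
  paste(v, collapse = "")
}

back_translate <- function(protein, tab = codon_table()) {
  v <- strsplit(protein, "")[[1]]
  paste(vapply(v, function(a) {
    cs <- tab[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# ---- feature factories ------------------------------------------------------
# Each factory returns list(seq, ann = data.frame(rel_start, rel_end, strand,
# repeat_class, family, full_length), kind, class, unit_len)

new_block <- function(seq, class, family, kind = "repeat", strand = "+",
                      full_length = NA, unit_len = NA_integer_,
                      ann = NULL, tag = NA_character_, breakable = TRUE) {
  if (is.null(ann))
    ann <- data.frame(rel_start = 0L, rel_end = nchar(seq), strand = strand,
                      repeat_class = class, family = family,
                      full_length = full_length, stringsAsFactors = FALSE)
  list(seq = seq, ann = ann, kind = kind, class = class,
       unit_len = unit_len, tag = tag, breakable = breakable)
}

make_ltr_full <- function(cfg, id) {
  tr <- rand_dna(cfg$ltr_tr_len, 48)
  tr2 <- mutate_dna(tr, 0.004)  # terminal repeats >= 99% identical
  internal <- rand_dna(cfg$ltr_len - 2L * cfg$ltr_tr_len, 46)
  new_block(paste0(tr, internal, tr2), "LTR", paste0("ERVK-sim", id),
            full_length = TRUE)
}

make_ltr_fragment <- function(cfg, id, size) {
  elem <- paste0(rand_dna(cfg$ltr_tr_len, 48),
                 rand_dna(cfg$ltr_len - 2L * cfg$ltr_tr_len, 46),
                 rand_dna(cfg$ltr_tr_len, 48))
  size <- max(300L, min(size, nchar(elem)))
  start <- sample.int(nchar(elem) - size + 1L, 1)
  new_block(substr(elem, start, start + size - 1L), "LTR",
            paste0("ERVK-simfrag", id), full_length = FALSE)
}

make_line_copy <- function(cfg, consensus, id, size = NA) {
  # 5'-truncated: copies keep the 3' end
  full <- nchar(consensus)
  keep <- if (is.na(size)) min(full, (1L + rgeom(1, cfg$line_trunc_p)) * 800L)
          else max(300L, min(size, full))
  s <- substr(consensus, full - keep + 1L, full)
  s <- mutate_dna(s, runif(1, 0.03, 0.10))
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") s <- revcomp_chr(s)
  new_block(s, "LINE", "CR1-sim", strand = strand,
            full_length = keep == full)
}

make_satellite <- function(cfg, id, size) {
  unit <- rand_dna(cfg$satellite_unit, 50)
  n_units <- max(6L, as.integer(round(size / cfg$satellite_unit)))
  copies <- vapply(seq_len(n_units), function(i) mutate_dna(unit, runif(1, 0, 0.02)),
                   character(1))
  new_block(paste(copies, collapse = ""), "Satellite", paste0("Sat-sim", id),
            unit_len = cfg$satellite_unit)
}

make_simple_repeat <- function(cfg, id, size) {
  motif <- rand_dna(sample(2:6, 1), 50)
  reps <- max(50L, as.integer(ceiling(size / nchar(motif))))
  s <- mutate_dna(strrep(motif, reps), 0.005)
  new_block(substr(s, 1, size), "SimpleRepeat", paste0("(", motif, ")n"))
}

make_dna_copy <- function(cfg, consensus, id, size = NA) {
  s <- if (is.na(size)) consensus
       else substr(consensus, 1, max(300L, min(size, nchar(consensus))))
  new_block(mutate_dna(s, runif(1, 0.03, 0.08)), "DNA", "hAT-sim")
}

# repeat blocks sized to reach each class target within +/- 2 percentage
# points of the chromosome length
plan_repeat_blocks <- function(cfg, mix, chrom_len, consensi) {
  blocks <- list()
  id <- 0L
  for (cl in names(mix)) {
    target <- mix[[cl]] / 100 * chrom_len
    got <- 0
    while (got < target - 0.002 * chrom_len) {
      id <- id + 1L
      remaining <- target - got
      b <- switch(cl,
        LTR = if (remaining >= cfg$ltr_len && runif(1) < 0.6)
                make_ltr_full(cfg, id)
              else make_ltr_fragment(cfg, id, as.integer(min(remaining, 3000))),
        LINE = make_line_copy(cfg, consensi$line, id,
                              size = if (remaining < 900) as.integer(remaining) else NA),
        Satellite = make_satellite(cfg, id,
                                   as.integer(min(remaining, sample(2000:5000, 1)))),
        SimpleRepeat = make_simple_repeat(cfg, id,
                                          as.integer(max(400, min(remaining, sample(400:1200, 1))))),
        DNA = make_dna_copy(cfg, consensi$dna, id,
                            size = if (remaining < 1800) as.integer(remaining) else NA),
        stop("no factory for repeat class ", cl))
      blocks[[length(blocks) + 1L]] <- b
      got <- got + nchar(b$seq)
    }
  }
  blocks
}

make_compound <- function(cfg, consensi, id) {
  # simple repeat immediately adjacent to a LINE fragment: a Complex cause
  a <- make_simple_repeat(cfg, paste0("cmp", id), 600L)
  b <- make_line_copy(cfg, consensi$line, paste0("cmp", id), size = 1200L)
  spacer <- rand_dna(10L, 45)
  seq <- paste0(a$seq, spacer, b$seq)
  ann <- rbind(
    data.frame(rel_start = 0L, rel_end = nchar(a$seq), strand = "+",
               repeat_class = "SimpleRepeat", family = a$ann$family[1],
               full_length = NA, stringsAsFactors = FALSE),
    data.frame(rel_start = nchar(a$seq) + 10L, rel_end = nchar(seq),
               strand = b$ann$strand[1], repeat_class = "LINE",
               family = b$ann$family[1], full_length = NA,
               stringsAsFactors = FALSE))
  new_block(seq, "Complex", "compound", kind = "compound", ann = ann)
}

make_exon_cluster <- function(cfg) {
  tab <- codon_table()
  consensus <- rand_protein(cfg$exon_len_aa)
  paralogs <- list(); seqs <- character(0)
  parts <- character(0)
  ann <- NULL
  off <- 0L
  for (i in seq_len(cfg$n_exon_paralogs)) {
    prot <- mutate_protein(consensus, runif(1, 0.02, 0.08))
    nt <- back_translate(prot, tab)
    strand <- if (i %% 2 == 0) "-" else "+"
    planted <- if (strand == "-") revcomp_chr(nt) else nt
    parts <- c(parts, planted)
    paralogs[[i]] <- data.frame(rel_start = off, rel_end = off + nchar(planted),
                                strand = strand, paralog_id = paste0("par", i),
                                protein = prot, stringsAsFactors = FALSE)
    off <- off + nchar(planted)
    if (i < cfg$n_exon_paralogs) {
      sp <- rand_dna(sample(150:300, 1), 50)
      parts <- c(parts, sp)
      off <- off + nchar(sp)
    }
  }
  seq <- paste(parts, collapse = "")
  queries <- c(consensus = consensus,
               variant1 = mutate_protein(consensus, 0.04),
               variant2 = mutate_protein(consensus, 0.04))
  b <- new_block(seq, "ExonCluster", "MHC-like", kind = "exon_cluster",
                 ann = data.frame(rel_start = integer(), rel_end = integer(),
                                  strand = character(), repeat_class = character(),
                                  family = character(), full_length = logical(),
                                  stringsAsFactors = FALSE),
                 breakable = FALSE)
  b$paralogs <- do.call(rbind, paralogs)
  b$queries <- queries
  b
}

make_gene <- function(cfg, id, tab) {
  prot <- rand_protein(cfg$gene_len_aa)
  nt <- back_translate(prot, tab)
  b <- new_block(nt, "Gene", paste0("gene", id), kind = "gene",
                 ann = data.frame(rel_start = integer(), rel_end = integer(),
                                  strand = character(), repeat_class = character(),
                                  family = character(), full_length = logical(),
                                  stringsAsFactors = FALSE),
                 tag = paste0("gene", id), breakable = FALSE)
  b$protein <- prot
  b
}

# interleave blocks with random background gaps summing exactly to the free
# space; returns list(seq, placed = data.frame(start,end,i))
assemble_blocks <- function(blocks, total_len, min_gap, gc) {
  sizes <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  n <- length(blocks)
  free <- total_len - sum(sizes)
  if (free < (n + 1L) * min_gap)
    stop("infeasible repeat mix: planted features overflow the chromosome")
  ord <- if (n > 1) sample.int(n) else seq_len(n)
  u <- runif(n + 1L)
  extra <- floor((free - (n + 1L) * min_gap) * u / sum(u))
  slack <- (free - (n + 1L) * min_gap) - sum(extra)
  extra[n + 1L] <- extra[n + 1L] + slack
  gaps <- min_gap + extra
  parts <- character(0)
  placed <- data.frame(start = integer(n), end = integer(n), i = ord)
  off <- 0L
  for (j in seq_len(n)) {
    parts <- c(parts, rand_dna(gaps[j], gc))
    off <- off + gaps[j]
    b <- blocks[[ord[j]]]
    placed$start[j] <- off
    placed$end[j] <- off + nchar(b$seq)
    parts <- c(parts, b$seq)
    off <- off + nchar(b$seq)
  }
  parts <- c(parts, rand_dna(gaps[n + 1L], gc))
  list(seq = paste(parts, collapse = ""), placed = placed)
}

#' Build a synthetic truth genome
#'
#' Deterministic under the config seed (every stage has its own derived
#' stream). Background sequence is drawn per chromosome-class GC; repeats are
#' planted to hit the per-class targets within about 2 percentage points;
#' every planted feature is annotated. Exon paralogs form a tandem cluster on
#' the first microchromosome with 2-8% per-paralog divergence; one duplicated
#' 500 bp segment (planted on two macrochromosomes) creates an
#' ambiguous-flank liftover case; adjacent-feature compounds create Complex
#' gap causes; Z and W share an identical pseudoautosomal prefix.
#'
#' @param cfg [simulation_config()].
#' @return List with class `"SyntheticTruth"`: `genome`, `repeats`,
#'   `features` (breakable feature table), `exon_paralogs`, `exon_queries`,
#'   `genes`, `chromosome_table`, `par`, `dup`, `cfg`.
#' @export
build_truth_genome <- function(cfg = simulation_config()) {
  seed <- cfg$seed
  tab <- codon_table()
  consensi <- with_stage(seed, "consensi", list(
    line = rand_dna(cfg$line_full_len, 44),
    dna = paste0("CAGGGTTGACGTGAAACC", rand_dna(1964, 42), "GGTTTCACGTCAACCCTG")))

  chroms <- data.frame(name = character(), class = character(), len = integer(),
                       gc = numeric(), stringsAsFactors = FALSE)
  add <- function(df, name, class, len, gc)
    rbind(df, data.frame(name = name, class = class, len = as.integer(len),
                         gc = gc, stringsAsFactors = FALSE))
  for (i in seq_len(cfg$n_macro))
    chroms <- add(chroms, paste0("macro", i), "macro", cfg$macro_len, cfg$macro_gc)
  for (i in seq_len(cfg$n_micro))
    chroms <- add(chroms, paste0("micro", i), "micro", cfg$micro_len, cfg$micro_gc)
  if (cfg$include_sex) {
    chroms <- add(chroms, "chrZ", "Z", cfg$z_len, cfg$macro_gc)
    chroms <- add(chroms, "chrW", "W", cfg$w_len, cfg$w_gc)
  }

  # special blocks, assigned round-robin to macrochromosomes
  specials <- with_stage(seed, "specials", {
    out <- list()
    cluster <- make_exon_cluster(cfg)
    out[["micro1"]] <- list(cluster)
    genes <- lapply(seq_len(cfg$n_genes), function(i) make_gene(cfg, i, tab))
    hosts <- c(paste0("macro", seq_len(cfg$n_macro)),
               paste0("micro", seq_len(max(0, cfg$n_micro - 1)) + 1L))
    for (i in seq_along(genes)) {
      h <- hosts[(i - 1L) %% length(hosts) + 1L]
      out[[h]] <- c(out[[h]], list(genes[[i]]))
    }
    dup_seq <- rand_dna(500, 45)
    src_host <- if (cfg$n_macro >= 2) "macro2" else "macro1"
    dest_host <- if (cfg$n_macro >= 3) "macro3" else "macro1"
    out[[src_host]] <- c(out[[src_host]],
                         list(new_block(dup_seq, "Dup", "dup", kind = "dup_src",
                                        ann = NULL, tag = "dup", breakable = FALSE)))
    out[[dest_host]] <- c(out[[dest_host]],
                          list(new_block(dup_seq, "Dup", "dup", kind = "dup_dest",
                                         ann = NULL, tag = "dup", breakable = FALSE)))
    # compounds spread over macrochromosomes
    for (i in seq_len(cfg$n_compound)) {
      h <- paste0("macro", (i - 1L) %% cfg$n_macro + 1L)
      out[[h]] <- c(out[[h]], list(make_compound(cfg, consensi, i)))
    }
    out
  })
  # the dup blocks annotate nothing; fix their ann frames
  for (h in names(specials))
    specials[[h]] <- lapply(specials[[h]], function(b) {
      if (b$kind %in% c("dup_src", "dup_dest"))
        b$ann <- b$ann[0, , drop = FALSE]
      b
    })

  genome <- list()
  ann_rows <- list()
  feat_rows <- list()
  paralog_rows <- NULL
  gene_rows <- list()
  dup_rows <- list()
  exon_queries <- NULL

  for (r in seq_len(nrow(chroms))) {
    nm <- chroms$name[r]; cl <- chroms$class[r]
    L <- chroms$len[r]; gc <- chroms$gc[r]
    mix <- cfg$repeat_mix[[cl]]
    par_off <- if (cl %in% c("Z", "W") && cfg$include_sex) cfg$par_len else 0L
    # targets are percents of the whole chromosome; the repeat-free PAR
    # prefix is excluded from planting space, so rescale onto what remains
    if (par_off > 0) mix <- mix * (L / (L - par_off))
    blocks <- with_stage(seed, paste0("plan_", nm),
                         plan_repeat_blocks(cfg, as.list(mix), L - par_off, consensi))
    blocks <- c(blocks, specials[[nm]])
    asm <- with_stage(seed, paste0("asm_", nm),
                      assemble_blocks(blocks, L - par_off, cfg$min_feature_gap, gc))
    prefix <- if (par_off > 0) {
      if (cl == "Z") with_stage(seed, "par", rand_dna(par_off, gc))
      else substr(genome[["chrZ"]], 1L, par_off)  # W copies the Z PAR
    } else ""
    genome[[nm]] <- paste0(prefix, asm$seq)
    for (j in seq_len(nrow(asm$placed))) {
      b <- blocks[[asm$placed$i[j]]]
      s0 <- asm$placed$start[j] + par_off
      if (nrow(b$ann)) {
        a <- b$ann
        a$seq_name <- nm
        a$start <- s0 + a$rel_start
        a$end <- s0 + a$rel_end
        ann_rows[[length(ann_rows) + 1L]] <-
          a[, c("seq_name", "start", "end", "strand", "repeat_class",
                "family", "full_length")]
      }
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        seq_name = nm, start = s0, end = s0 + nchar(b$seq), kind = b$kind,
        class = b$class, unit_len = b$unit_len,
        breakable = b$breakable && b$kind %in% c("repeat", "compound"),
        stringsAsFactors = FALSE)
      if (b$kind == "exon_cluster") {
        p <- b$paralogs
        p$seq_name <- nm
        p$start <- s0 + p$rel_start
        p$end <- s0 + p$rel_end
        paralog_rows <- p[, c("seq_name", "start", "end", "strand",
                              "paralog_id", "protein")]
        exon_queries <- b$queries
      }
      if (b$kind == "gene")
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          seq_name = nm, start = s0, end = s0 + nchar(b$seq),
          gene_id = b$tag, protein = b$protein, stringsAsFactors = FALSE)
      if (b$kind %in% c("dup_src", "dup_dest"))
        dup_rows[[length(dup_rows) + 1L]] <- data.frame(
          seq_name = nm, start = s0, end = s0 + nchar(b$seq), role = b$kind,
          stringsAsFactors = FALSE)
    }
  }

  repeats <- do.call(rbind, ann_rows)
  repeats$divergence <- NA_real_
  features <- do.call(rbind, feat_rows)
  par_df <- if (cfg$include_sex)
    data.frame(seq_name = c("chrZ", "chrW"), start = 0L, end = cfg$par_len,
               stringsAsFactors = FALSE)
  else data.frame(seq_name = character(), start = integer(), end = integer())

  structure(list(
    genome = genome_sequences(unlist(genome), source_path = "synthetic"),
    repeats = repeat_annotation(repeats),
    features = features,
    exon_paralogs = paralog_rows,
    exon_queries = exon_queries,
    genes = do.call(rbind, gene_rows),
    chromosome_table = chroms[, c("name", "class", "len")],
    par = par_df,
    dup = do.call(rbind, dup_rows),
    cfg = cfg), class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", length(x$genome), "chromosomes,",
      sum(seq_lengths(x$genome)), "bp;", nrow(x$repeats), "repeat intervals\n")
  invisible(x)
}

# ---- draft derivation -------------------------------------------------------

#' Derive a fragmented draft with known gap causes
#'
#' Breakpoints are sampled over planted features with odds proportional to
#' `cfg$break_bias`, plus background breaks. At each break the feature is
#' excised (satellite arrays are collapsed, keeping two monomers; other
#' features are deleted whole or keep a short stub; LINE and DNA elements may
#' instead lose their interior) and the flanking contigs are rejoined with
#' `gap_n_len` Ns in truth order. `gap_truth` records the causal class per
#' gap (`Complex` when the excised region spans two classes or more); the
#' gap next to the planted duplication is marked to expect
#' `NotScorable(ambiguous)` and the chimera-join gap (one W contig is moved
#' into the first macrochromosome scaffold, the planted chimeric scaffold)
#' to expect `NotScorable(different_scaffolds)`. Optional per-base mutations
#' are applied to the draft only.
#'
#' @param truth [build_truth_genome()] output.
#' @param cfg [simulation_config()]; defaults to the truth's own config.
#' @return List with class `"DraftTruth"`: `draft`, `gap_truth`,
#'   `contig_map`, `draft_repeats`, `contigs`, `composition`, `cfg`.
#' @export
derive_draft <- function(truth, cfg = truth$cfg) {
  seed <- cfg$seed
  lens <- seq_lengths(truth$genome)
  margin <- cfg$min_feature_gap
  guard <- 1300L  # min distance between excisions / to chromosome ends

  exc <- with_stage(seed, "breaks", {
    rows <- list()
    occupied <- list()  # per chrom matrix of (x0, x1)
    ok_dist <- function(chrom, x0, x1) {
      if (x0 < guard || x1 > lens[[chrom]] - guard) return(FALSE)
      occ <- occupied[[chrom]]
      if (is.null(occ)) return(TRUE)
      all(x0 >= occ[, 2] + guard | x1 <= occ[, 1] - guard)
    }
    near_dup <- function(chrom, x0, x1) {
      d <- truth$dup
      if (is.null(d)) return(FALSE)
      d <- d[d$seq_name == chrom, , drop = FALSE]
      nrow(d) > 0 && any(x0 < d$end + 700 & x1 > d$start - 700)
    }
    push <- function(chrom, x0, x1, expect = NA_character_, forced_cause = NA) {
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_name = chrom, x0 = as.integer(x0), x1 = as.integer(x1),
        expect = expect, forced_cause = forced_cause, stringsAsFactors = FALSE)
      occupied[[chrom]] <<- rbind(occupied[[chrom]], c(x0, x1))
    }

    # 1. the duplication-ambiguity break: left flank is the duplicated segment
    if (!is.null(truth$dup)) {
      src <- truth$dup[truth$dup$role == "dup_src", ]
      push(src$seq_name, src$end, src$end + 200L, expect = "ambiguous")
    }
    # 2. one gene split (40% of its middle excised -> Partial call)
    if (!is.null(truth$genes) && nrow(truth$genes)) {
      g <- truth$genes[1, ]
      glen <- g$end - g$start
      push(g$seq_name, g$start + round(0.3 * glen), g$start + round(0.7 * glen))
    }
    # 3. compounds: always broken, whole joint interval excised
    cmp <- truth$features[truth$features$kind == "compound", , drop = FALSE]
    for (i in seq_len(nrow(cmp)))
      if (ok_dist(cmp$seq_name[i], cmp$start[i], cmp$end[i]))
        push(cmp$seq_name[i], cmp$start[i], cmp$end[i])
    # 4. feature breaks sampled with class bias
    feats <- truth$features[truth$features$breakable &
                              truth$features$kind == "repeat", , drop = FALSE]
    w <- cfg$break_bias[feats$class]
    w[is.na(w)] <- 1
    n_take <- min(cfg$n_breaks, sum(w > 0))
    idx <- if (n_take > 0) sample.int(nrow(feats), n_take, prob = w)
           else integer(0)
    for (i in idx) {
      f <- feats[i, ]
      flen <- f$end - f$start
      if (f$class == "Satellite" && !is.na(f$unit_len) &&
          flen > 2L * f$unit_len + 400L) {
        x0 <- f$start + 2L * f$unit_len   # collapse to two monomers
        x1 <- f$end
      } else if (f$class %in% c("LINE", "DNA") && flen >= 1200L &&
                 runif(1) < 0.5) {
        x0 <- f$start + 300L              # interior loss
        x1 <- f$end - 300L
      } else if (flen >= 600L && runif(1) < 0.7) {
        x0 <- f$start + 150L              # keep a stub at the gap edge
        x1 <- f$end
      } else {
        x0 <- f$start
        x1 <- f$end
      }
      if (ok_dist(f$seq_name, x0, x1) && !near_dup(f$seq_name, x0, x1))
        push(f$seq_name, x0, x1)
    }
    # 5. background breaks (NoRepeat gaps)
    for (i in seq_len(cfg$n_background_breaks)) {
      for (try in 1:50) {
        chrom <- sample(names(lens), 1)
        p <- sample.int(lens[[chrom]] - 2L * guard, 1) + guard
        x0 <- p; x1 <- p + 120L
        ft <- truth$features[truth$features$seq_name == chrom, , drop = FALSE]
        clear <- !nrow(ft) ||
          all(x0 >= ft$end + margin + 700 | x1 <= ft$start - margin - 700)
        # the PAR exists verbatim on both Z and W: flanks there can never
        # lift over uniquely, so background breaks avoid it
        pp <- truth$par[truth$par$seq_name == chrom, , drop = FALSE]
        if (nrow(pp) && any(x0 < pp$end + 700 & x1 > pp$start - 700))
          clear <- FALSE
        if (clear && ok_dist(chrom, x0, x1) && !near_dup(chrom, x0, x1)) {
          push(chrom, x0, x1, forced_cause = "NoRepeat")
          break
        }
      }
    }
    do.call(rbind, rows)
  })

  # causal class of each excision from the truth annotation
  exc$cause <- vapply(seq_len(nrow(exc)), function(i) {
    if (!is.na(exc$forced_cause[i])) return(exc$forced_cause[i])
    rr <- truth$repeats[truth$repeats$seq_name == exc$seq_name[i], , drop = FALSE]
    cls <- unique(rr$repeat_class[rr$start < exc$x1[i] & rr$end > exc$x0[i]])
    if (!length(cls)) "NoRepeat" else if (length(cls) == 1) cls else "Complex"
  }, character(1))

  # per-chromosome kept segments and junction records
  gseq <- unclass(truth$genome)
  scaffolds <- list()
  for (nm in names(gseq)) {
    e <- exc[exc$seq_name == nm, , drop = FALSE]
    e <- e[order(e$x0), , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(e$x0, e$x1)), lens[[nm]])
    starts <- bounds[seq(1, length(bounds), 2)]
    ends <- bounds[seq(2, length(bounds), 2)]
    scaffolds[[paste0("scf_", nm)]] <- list(
      chrom = nm,
      segs = data.frame(t_start = starts, t_end = ends),
      junctions = e)
  }

  # planted chimeric scaffold: move the last W contig into the first
  # macro scaffold (joined across a new gap expecting different_scaffolds)
  if (cfg$include_sex && "scf_chrW" %in% names(scaffolds) &&
      "scf_macro1" %in% names(scaffolds)) {
    wsc <- scaffolds[["scf_chrW"]]
    nseg <- nrow(wsc$segs)
    if (nseg >= 2) {
      moved <- wsc$segs[nseg, , drop = FALSE]
      moved$src_chrom <- "chrW"
      scaffolds[["scf_chrW"]]$segs <- wsc$segs[-nseg, , drop = FALSE]
      scaffolds[["scf_chrW"]]$junctions <- wsc$junctions[-(nseg - 1L), , drop = FALSE]
      m1 <- scaffolds[["scf_macro1"]]
      m1$extra_seg <- moved
      scaffolds[["scf_macro1"]] <- m1
    }
  }

  with_stage(seed, "mutate", NULL)  # reserve the stream position
  draft <- character(0)
  gap_rows <- list(); map_rows <- list(); contig_rows <- list()
  rep_rows <- list()
  set.seed(stage_seed(seed, "mutate"))
  for (sc in names(scaffolds)) {
    info <- scaffolds[[sc]]
    segs <- info$segs
    segs$chrom <- info$chrom
    if (!is.null(info$extra_seg)) {
      ex <- info$extra_seg
      segs <- rbind(segs, data.frame(t_start = ex$t_start, t_end = ex$t_end,
                                     chrom = ex$src_chrom))
    }
    parts <- character(0); off <- 0L
    for (i in seq_len(nrow(segs))) {
      s <- substr(gseq[[segs$chrom[i]]], segs$t_start[i] + 1L, segs$t_end[i])
      if (cfg$mutation_rate > 0) s <- mutate_dna(s, cfg$mutation_rate)
      seg_len <- nchar(s)
      cid <- paste0(sc, ".c", i)
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        scaffold = sc, d_start = off, d_end = off + seg_len,
        t_seq = segs$chrom[i], t_start = segs$t_start[i],
        t_end = segs$t_end[i], strand = "+", contig = cid,
        stringsAsFactors = FALSE)
      # clip repeat annotation into draft coordinates
      rr <- truth$repeats[truth$repeats$seq_name == segs$chrom[i] &
                            truth$repeats$start < segs$t_end[i] &
                            truth$repeats$end > segs$t_start[i], , drop = FALSE]
      if (nrow(rr)) {
        cs <- pmax(rr$start, segs$t_start[i]) - segs$t_start[i] + off
        ce <- pmin(rr$end, segs$t_end[i]) - segs$t_start[i] + off
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          seq_name = sc, start = cs, end = ce, strand = rr$strand,
          repeat_class = rr$repeat_class, family = rr$family,
          full_length = rr$full_length & rr$start >= segs$t_start[i] &
            rr$end <= segs$t_end[i],
          stringsAsFactors = FALSE)
      }
      contig_rows[[length(contig_rows) + 1L]] <- data.frame(
        scaffold = sc, contig = cid, length = seg_len,
        src_chrom = segs$chrom[i], t_start = segs$t_start[i],
        t_end = segs$t_end[i], stringsAsFactors = FALSE)
      parts <- c(parts, s)
      off <- off + seg_len
      if (i < nrow(segs)) {
        if (i <= nrow(info$junctions)) {
          j <- info$junctions[i, ]
          gap_rows[[length(gap_rows) + 1L]] <- data.frame(
            scaffold = sc, start = off, end = off + cfg$gap_n_len,
            src_seq = j$seq_name, src_start = j$x0, src_end = j$x1,
            cause = j$cause, expect = j$expect, stringsAsFactors = FALSE)
        } else {
          gap_rows[[length(gap_rows) + 1L]] <- data.frame(
            scaffold = sc, start = off, end = off + cfg$gap_n_len,
            src_seq = NA_character_, src_start = NA_integer_,
            src_end = NA_integer_, cause = NA_character_,
            expect = "different_scaffolds", stringsAsFactors = FALSE)
        }
        parts <- c(parts, strrep("N", cfg$gap_n_len))
        off <- off + cfg$gap_n_len
      }
    }
    draft[[sc]] <- paste(parts, collapse = "")
  }

  contigs <- do.call(rbind, contig_rows)
  # chromosome class per contig; PAR prefix contigs count as PAR
  cls <- setNames(truth$chromosome_table$class, truth$chromosome_table$name)
  contigs$class <- unname(cls[contigs$src_chrom])
  if (nrow(truth$par)) {
    for (i in seq_len(nrow(truth$par))) {
      p <- truth$par[i, ]
      inpar <- contigs$src_chrom == p$seq_name &
        pmin(contigs$t_end, p$end) - pmax(contigs$t_start, p$start) >
          0.5 * (contigs$t_end - contigs$t_start)
      contigs$class[inpar] <- "PAR"
    }
  }

  dr <- do.call(rbind, rep_rows)
  dr$divergence <- NA_real_
  structure(list(
    draft = genome_sequences(draft, source_path = "synthetic-draft"),
    gap_truth = do.call(rbind, gap_rows),
    contig_map = do.call(rbind, map_rows),
    draft_repeats = repeat_annotation(dr),
    contigs = contigs,
    composition = contigs[, c("scaffold", "contig", "src_chrom", "class")],
    cfg = cfg), class = "DraftTruth")
}

#' @export
print.DraftTruth <- function(x, ...) {
  cat("DraftTruth:", length(x$draft), "scaffolds,", nrow(x$contigs),
      "contigs,", nrow(x$gap_truth), "gaps\n")
  invisible(x)
}

#' Simulate per-contig read depth for one sex
#'
#' Mean depth per contig is `Poisson(length * depth * ploidy) / length` with
#' ploidy factors: autosomes and PAR 1.0 in both sexes; Z 0.5 in the female,
#' 1.0 in the male; W 0.5 in the female, 0 in the male (female-heterogametic
#' ZW system).
#'
#' @param contigs Data frame with `contig`, `length` and `class`
#'   (macro/micro/Z/W/PAR), e.g. `derive_draft()$contigs`.
#' @param depth Haploid-pair baseline depth (reads per base).
#' @param sex `"female"` or `"male"`.
#' @param seed Integer seed.
#' @return Data frame: `contig`, `length`, `mean_depth`.
#' @export
simulate_coverage <- function(contigs, depth = 30, sex = c("female", "male"),
                              seed = 1L) {
  sex <- match.arg(sex)
  stopifnot(depth > 0)
  fac <- vapply(contigs$class, function(cl) {
    switch(cl,
           Z = if (sex == "female") 0.5 else 1.0,
           W = if (sex == "female") 0.5 else 0.0,
           1.0)
  }, numeric(1))
  set.seed(stage_seed(seed, paste0("coverage_", sex)))
  lam <- contigs$length * depth * fac
  data.frame(contig = contigs$contig, length = contigs$length,
             mean_depth = rpois(length(lam), lam) / contigs$length,
             stringsAsFactors = FALSE)
}

#' Combined male/female coverage table for a simulated draft
#'
#' @param draft_truth `DraftTruth`.
#' @param depth Baseline depth.
#' @param seed Integer seed.
#' @return Coverage table as consumed by [classify_sex_linkage()].
#' @export
coverage_table <- function(draft_truth, depth = 30, seed = draft_truth$cfg$seed) {
  f <- simulate_coverage(draft_truth$contigs, depth, "female", seed)
  m <- simulate_coverage(draft_truth$contigs, depth, "male", seed)
  data.frame(contig = f$contig, length = f$length,
             mean_depth_female = f$mean_depth, mean_depth_male = m$mean_depth,
             stringsAsFactors = FALSE)
}
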