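# Built-in local alignment: exact k-mer seeding, ungapped X-drop extension,
# then full affine-gap Smith-Waterman in a window around each seed cluster
# (src/align.cpp).  E-values follow Karlin-Altschul, E = K * m * n *
# exp(-lambda * S), with constants fixed per scoring scheme and documented in
# align_params(); they differ numerically from blastn's gapped estimates by
# no more than about an order of magnitude, which is immaterial at the 1e-20
# regime used for 500 bp flanks.

#' Nucleotide alignment parameters
#'
#' Defaults: seed length 15 (configurable down to 11 for diverged inputs),
#' match +2, mismatch -3, gap open -5, gap extend -2 (a gap of length L costs
#' 5 + 2L, the BLAST convention), Karlin-Altschul K = 0.41 and
#' lambda = 0.625 for these scores.
#'
#' @param k Seed length.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (penalties
#'   negative).
#' @param xdrop X-drop threshold for ungapped extension.
#' @param min_ungapped Minimum ungapped score for a seed cluster to be
#'   extended by DP.
#' @param min_score Minimum raw score of a reported hit.
#' @param max_occ Seeds occurring more often than this in the target are
#'   skipped (repeat soft-masking).
#' @param max_windows Maximum DP windows per query and strand.
#' @param K,lambda Karlin-Altschul constants for the scoring scheme.
#' @return List of parameters.
#' @export
align_params <- function(k = 15L, match = 2L, mismatch = -3L,
                         gap_open = -5L, gap_extend = -2L,
                         xdrop = 40L, min_ungapped = 30L, min_score = 50L,
                         max_occ = 128L, max_windows = 40L,
                         K = 0.41, lambda = 0.625) {
  list(k = as.integer(k), match = as.integer(match),
       mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend), xdrop = as.integer(xdrop),
       min_ungapped = as.integer(min_ungapped),
       min_score = as.integer(min_score), max_occ = as.integer(max_occ),
       max_windows = as.integer(max_windows), K = K, lambda = lambda)
}

#' Protein (translated search) alignment parameters
#'
#' BLOSUM62 scoring with gap open -11 / extend -1 and the matching gapped
#' Karlin-Altschul constants (K = 0.041, lambda = 0.267).
#' @inheritParams align_params
#' @return List of parameters.
#' @export
prot_align_params <- function(k = 4L, gap_open = -11L, gap_extend = -1L,
                              xdrop = 25L, min_ungapped = 35L, min_score = 60L,
                              max_occ = 512L, max_windows = 80L,
                              K = 0.041, lambda = 0.267) {
  list(k = as.integer(k), gap_open = as.integer(gap_open),
       gap_extend = as.integer(gap_extend), xdrop = as.integer(xdrop),
       min_ungapped = as.integer(min_ungapped),
       min_score = as.integer(min_score), max_occ = as.integer(max_occ),
       max_windows = as.integer(max_windows), K = K, lambda = lambda)
}

empty_hits <- function() {
  data.frame(query_name = character(), target_name = character(),
             strand = character(), qstart = integer(), qend = integer(),
             tstart = integer(), tend = integer(), query_length = integer(),
             matches = integer(), mismatches = integer(),
             gap_opens = integer(), aligned_cols = integer(),
             positives = integer(), identity = numeric(),
             query_coverage = numeric(), score = integer(),
             evalue = numeric(), cigar = character(),
             stringsAsFactors = FALSE)
}

finish_hits <- function(raw, qnames, qlens, tnames, total_n, K, lambda) {
  if (!nrow(raw)) return(empty_hits())
  qlen <- qlens[raw$qid]
  out <- data.frame(
    query_name = qnames[raw$qid], target_name = tnames[raw$tid],
    strand = raw$strand, qstart = raw$qstart, qend = raw$qend,
    tstart = raw$tstart, tend = raw$tend, query_length = qlen,
    matches = raw$matches, mismatches = raw$mismatches,
    gap_opens = raw$gap_opens, aligned_cols = raw$aligned_cols,
    positives = raw$positives,
    identity = 100 * raw$matches / raw$aligned_cols,
    query_coverage = 100 * (raw$qend - raw$qstart) / qlen,
    score = raw$score,
    evalue = exp(log(K) + log(qlen) + log(total_n) - lambda * raw$score),
    cigar = raw$cigar, stringsAsFactors = FALSE)
  # ascending e-value; ties: lowest target coordinate, '+' before '-'
  out[order(out$query_name, out$evalue, out$tstart,
            match(out$strand, c("+", "-"))), , drop = FALSE]
}

#' Local nucleotide alignment of queries against a target set
#'
#' Seed-and-extend local alignment of one or more DNA queries against all
#' target sequences, on both strands. Hit coordinates are 0-based half-open;
#' query coordinates always refer to the original (forward) query.
#'
#' @param query Character vector of DNA queries (names optional).
#' @param targets `GenomeSequences` or named character vector.
#' @param params [align_params()].
#' @param both_strands Search the reverse complement too (default TRUE).
#' @return Hit data frame (one row per local alignment) sorted by ascending
#'   e-value within query, with identity and query-coverage percentages,
#'   raw score, e-value and a cigar-like edit trace (M/I/D; for `-` hits the
#'   trace is written along the reverse-complemented query).
#' @export
align_local <- function(query, targets, params = align_params(),
                        both_strands = TRUE) {
  query <- toupper(unclass(query))
  if (is.null(names(query)))
    names(query) <- paste0("query", seq_along(query))
  tseq <- toupper(unclass(targets))
  short <- nchar(query) < params$k
  if (any(short)) {
    warning(sum(short), " query(ies) shorter than the seed length skipped")
    query <- query[!short]
  }
  if (!length(query) || !length(tseq)) return(empty_hits())
  raw <- cpp_align_nt(unname(query), unname(tseq),
                      params$k, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, params$xdrop,
                      params$min_ungapped, params$min_score, params$max_occ,
                      params$max_windows, both_strands)
  finish_hits(raw, names(query), nchar(query), names(tseq),
              sum(as.numeric(nchar(tseq))), params$K, params$lambda)
}

#' Filter alignment hits on identity, coverage and e-value
#'
#' Keeps hits with `identity >= min_identity`, `query_coverage >=
#' min_flank_coverage` and `evalue <= max_evalue`. All three thresholds are
#' inclusive, matching blastn-style cutoff semantics; input order is
#' preserved and the operation is idempotent.
#'
#' @param hits Hit data frame from [align_local()] or [translated_search()].
#' @param cfg [analysis_config()].
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, cfg = analysis_config()) {
  if (!nrow(hits)) return(hits)
  keep <- hits$identity >= cfg$min_identity &
    hits$query_coverage >= cfg$min_flank_coverage &
    hits$evalue <= cfg$max_evalue
  hits[keep, , drop = FALSE]
}

# BLOSUM62 with '*' made impassable so alignments never cross a stop codon:
# translated frames break at stops.
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m[rownames(m) == "*", ] <- -1000L
  m[, colnames(m) == "*"] <- -1000L
  storage.mode(m) <- "integer"
  m
}

# All six reading frames of every target, with bookkeeping to map residue
# coordinates back to forward-strand nucleotide coordinates.
six_frame_translations <- function(targets) {
  tseq <- toupper(unclass(targets))
  rows <- list()
  for (nm in names(tseq)) {
    s <- Biostrings::DNAString(tseq[[nm]])
    rc <- Biostrings::reverseComplement(s)
    L <- length(s)
    for (f in 0:2) {
      for (str in c("+", "-")) {
        src <- if (str == "+") s else rc
        n_cod <- (L - f) %/% 3
        if (n_cod < 1) next
        sub <- Biostrings::subseq(src, start = f + 1L, width = 3L * n_cod)
        aa <- as.character(suppressWarnings(
          Biostrings::translate(sub, if.fuzzy.codon = "X")))
        rows[[length(rows) + 1L]] <-
          list(seq_name = nm, strand = str, frame = f, seq_len = L, prot = aa)
      }
    }
  }
  rows
}

#' Six-frame translated protein search
#'
#' Translates every target in all six reading frames (standard code; stop
#' codons are impassable so frames effectively break at stops) and aligns
#' each protein query locally with BLOSUM62. Hit spans are reported in
#' nucleotide coordinates on the forward strand of the target; query spans in
#' residue coordinates; strand comes from the frame sign.
#'
#' @param protein_query Character vector of protein sequences (>= 20
#'   residues each).
#' @param targets `GenomeSequences` or named character vector of DNA.
#' @param params [prot_align_params()].
#' @return Hit data frame as in [align_local()], plus a `frame` column;
#'   `positives` counts positive-scoring aligned columns.
#' @export
translated_search <- function(protein_query, targets,
                              params = prot_align_params()) {
  protein_query <- toupper(unclass(protein_query))
  if (is.null(names(protein_query)))
    names(protein_query) <- paste0("query", seq_along(protein_query))
  bad <- grepl("[^ARNDCQEGHILKMFPSTWYVBJZX]", protein_query)
  if (any(bad))
    stop("non-amino-acid characters in query ",
         names(protein_query)[which(bad)[1]])
  if (any(nchar(protein_query) < 20))
    stop("protein queries must be at least 20 residues")
  frames <- six_frame_translations(targets)
  if (!length(frames)) return(cbind(empty_hits(), frame = integer()))
  mat <- blosum62_matrix()
  alpha <- paste(colnames(mat), collapse = "")
  raw <- cpp_align_prot(unname(protein_query),
                        vapply(frames, `[[`, character(1), "prot"),
                        alpha, mat, params$k, -params$gap_open,
                        -params$gap_extend, params$xdrop,
                        params$min_ungapped, params$min_score,
                        params$max_occ, params$max_windows)
  if (!nrow(raw)) return(cbind(empty_hits(), frame = integer()))
  fr <- frames
  total_res <- sum(vapply(fr, function(x) nchar(x$prot), numeric(1)))
  qlens <- nchar(protein_query)
  info <- do.call(rbind, lapply(fr, function(x)
    data.frame(seq_name = x$seq_name, strand = x$strand, frame = x$frame,
               seq_len = x$seq_len, stringsAsFactors = FALSE)))
  tinfo <- info[raw$tid, , drop = FALSE]
  nt_start <- ifelse(tinfo$strand == "+",
                     tinfo$frame + 3L * raw$tstart,
                     tinfo$seq_len - (tinfo$frame + 3L * raw$tend))
  nt_end <- ifelse(tinfo$strand == "+",
                   tinfo$frame + 3L * raw$tend,
                   tinfo$seq_len - (tinfo$frame + 3L * raw$tstart))
  qlen <- qlens[raw$qid]
  out <- data.frame(
    query_name = names(protein_query)[raw$qid],
    target_name = tinfo$seq_name, strand = tinfo$strand,
    qstart = raw$qstart, qend = raw$qend,
    tstart = as.integer(nt_start), tend = as.integer(nt_end),
    query_length = qlen,
    matches = raw$matches, mismatches = raw$mismatches,
    gap_opens = raw$gap_opens, aligned_cols = raw$aligned_cols,
    positives = raw$positives,
    identity = 100 * raw$matches / raw$aligned_cols,
    query_coverage = 100 * (raw$qend - raw$qstart) / qlen,
    score = raw$score,
    evalue = exp(log(params$K) + log(qlen) + log(total_res) -
                   params$lambda * raw$score),
    cigar = raw$cigar, frame = tinfo$frame, stringsAsFactors = FALSE)
  out[order(out$query_name, out$evalue, out$tstart,
            match(out$strand, c("+", "-"))), , drop = FALSE]
}

#' Import tabular alignment results (blast outfmt 6 layout)
#'
#' Maps a 12-column tab-separated table (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore; 1-based inclusive
#' coordinates, reversed sstart > send encoding the minus strand) into the
#' hit data frame used by the built-in aligner, so external aligner output
#' can be substituted anywhere hits are consumed.
#'
#' @param path Path to the TSV.
#' @param query_lengths Optional named vector of query lengths for coverage.
#' @return Hit data frame (no cigar; `matches` estimated from pident).
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 columns (outfmt 6)")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- df$sstart > df$send
  tstart <- ifelse(minus, df$send, df$sstart) - 1L
  tend <- ifelse(minus, df$sstart, df$send)
  qlen <- if (is.null(query_lengths)) rep(NA_integer_, nrow(df))
          else unname(query_lengths[df$qseqid])
  data.frame(
    query_name = df$qseqid, target_name = df$sseqid,
    strand = ifelse(minus, "-", "+"),
    qstart = df$qstart - 1L, qend = df$qend,
    tstart = as.integer(tstart), tend = as.integer(tend),
    query_length = qlen,
    matches = as.integer(round(df$pident / 100 * df$length)),
    mismatches = df$mismatch, gap_opens = df$gapopen,
    aligned_cols = df$length, positives = NA_integer_,
    identity = df$pident,
    query_coverage = 100 * (df$qend - df$qstart + 1L) / qlen,
    score = as.integer(round(df$bitscore)), evalue = df$evalue,
    cigar = NA_character_, stringsAsFactors = FALSE)
}
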