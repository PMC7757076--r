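# Multicopy-exon census (tandem gene-family paralogs found by translated
# search) and gene presence/absence calls.

#' Construct an exon query set
#'
#' @param name Set label (e.g. `"exon2"`).
#' @param queries Character vector of protein query sequences (may vary in
#'   length; the length filter uses `query_alignment_length`).
#' @param query_alignment_length Length of the query alignment on the
#'   nucleotide scale (e.g. 270 for a 90-residue exon).
#' @param min_hit_len Minimum insertion-free hit length in bp; hits must be
#'   strictly longer to count (e.g. 240).
#' @return List with class `"ExonQuerySet"`.
#' @export
exon_query_set <- function(name, queries, query_alignment_length, min_hit_len) {
  stopifnot(min_hit_len < query_alignment_length, length(queries) >= 1)
  structure(list(name = name, queries = queries,
                 query_alignment_length = as.integer(query_alignment_length),
                 min_hit_len = as.integer(min_hit_len)),
            class = "ExonQuerySet")
}

#' Merge overlapping hit intervals on the target
#'
#' Unions the target spans per target sequence. Strictly overlapping
#' intervals (sharing at least one base) are merged; abutting intervals are
#' kept separate. Idempotent.
#'
#' @param hits Hit data frame (needs `target_name`, `tstart`, `tend`).
#' @return Sorted, disjoint interval data frame (`seq_name`, `start`, `end`).
#' @export
merge_hits <- function(hits) {
  if (!nrow(hits))
    return(data.frame(seq_name = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  iv <- data.frame(seq_name = hits$target_name, start = hits$tstart,
                   end = hits$tend, stringsAsFactors = FALSE)
  merge_intervals(iv, abutting = FALSE)
}

parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("hit has no edit trace")
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  if (length(n) != length(op)) stop("malformed cigar: ", cigar)
  tapply(n, factor(op, levels = c("M", "I", "D")), sum, default = 0L)
}

#' Insertion-free query length of a hit, in nucleotides
#'
#' Counts alignment columns in which the query has a residue (target
#' insertions excluded) from the hit's edit trace, and converts to
#' nucleotides (3 bp per residue for translated hits).
#'
#' @param hit One hit row (translated search).
#' @param translated Is this a translated (protein-vs-DNA) hit? Default TRUE.
#' @return Length in bp.
#' @export
hit_query_length <- function(hit, translated = TRUE) {
  cnt <- parse_cigar(hit$cigar)
  res <- unname(cnt["M"] + cnt["I"])
  if (translated) 3L * res else res
}

#' Census of a multicopy exon family in an assembly
#'
#' Runs [translated_search()] for every query of the set, keeps hits whose
#' insertion-free length is strictly greater than `min_hit_len`, merges the
#' passing hits of all queries ([merge_hits()]) and counts merged intervals
#' per scaffold and in total. An optional back-validation predicate (one
#' merged interval at a time) is applied before counting.
#'
#' @param qset [exon_query_set()].
#' @param assembly `GenomeSequences`.
#' @param params [prot_align_params()].
#' @param validate Optional `function(seq_name, start, end) -> logical`.
#' @return List: `census` (total count), `per_scaffold` (data frame),
#'   `intervals` (merged intervals).
#' @export
exon_census <- function(qset, assembly, params = prot_align_params(),
                        validate = NULL) {
  if (!length(assembly)) stop("empty assembly")
  hits <- translated_search(qset$queries, assembly, params)
  if (nrow(hits)) {
    qlen_nt <- vapply(seq_len(nrow(hits)), function(i)
      hit_query_length(hits[i, ]), integer(1))
    hits <- hits[qlen_nt > qset$min_hit_len, , drop = FALSE]
  }
  merged <- merge_hits(hits)
  if (!is.null(validate) && nrow(merged)) {
    ok <- vapply(seq_len(nrow(merged)), function(i)
      isTRUE(validate(merged$seq_name[i], merged$start[i], merged$end[i])),
      logical(1))
    merged <- merged[ok, , drop = FALSE]
  }
  per <- if (nrow(merged)) {
    agg <- table(merged$seq_name)
    data.frame(seq_name = names(agg), n = as.integer(agg),
               stringsAsFactors = FALSE)
  } else data.frame(seq_name = character(), n = integer(),
                    stringsAsFactors = FALSE)
  list(census = nrow(merged), per_scaffold = per, intervals = merged)
}

# greedy colinear chain of one gene's hits on one (target, strand):
# take hits by descending score, keep those whose query span does not overlap
# an already kept hit and whose target span stays within max_intron of the
# chain; returns covered query residues, positive columns, aligned columns
chain_hits <- function(h, max_intron = 20000L) {
  h <- h[order(-h$score), , drop = FALSE]
  kept <- h[0, , drop = FALSE]
  for (i in seq_len(nrow(h))) {
    cand <- h[i, ]
    if (nrow(kept)) {
      qov <- any(cand$qstart < kept$qend & cand$qend > kept$qstart)
      near <- all(cand$tstart < kept$tend + max_intron &
                  cand$tend > kept$tstart - max_intron)
      colinear <- all((cand$qstart >= kept$qend) == (if (cand$strand[1] == "+")
        cand$tstart >= kept$tend else cand$tend <= kept$tstart))
      if (qov || !near || !colinear) next
    }
    kept <- rbind(kept, cand)
  }
  kept
}

#' Gene presence/absence calls from protein models
#'
#' For each protein model, translated hits are chained greedily (colinear on
#' one scaffold and strand, introns up to 20 kb) and the best chain is
#' scored. `aligned_fraction` is the percentage of query residues covered;
#' `similarity` the percentage of positive-scoring aligned columns. A gene is
#' `Complete` when at least `cfg$complete_gene_min_len` percent of its length
#' aligns with similarity strictly above `cfg$complete_gene_min_sim`;
#' `Partial` when it aligns but misses either bar; `Absent` without any
#' alignment.
#'
#' @param protein_models Named character vector of protein sequences.
#' @param assembly `GenomeSequences`.
#' @param cfg [analysis_config()].
#' @param params [prot_align_params()].
#' @return Data frame: `gene_id`, `status`, `aligned_fraction`, `similarity`,
#'   `scaffold`.
#' @export
gene_presence <- function(protein_models, assembly, cfg = analysis_config(),
                          params = prot_align_params()) {
  stopifnot(length(protein_models) >= 1)
  if (is.null(names(protein_models)))
    names(protein_models) <- paste0("gene", seq_along(protein_models))
  hits <- translated_search(protein_models, assembly, params)
  out <- data.frame(gene_id = names(protein_models), status = "Absent",
                    aligned_fraction = 0, similarity = NA_real_,
                    scaffold = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(protein_models)) {
    h <- hits[hits$query_name == names(protein_models)[i], , drop = FALSE]
    if (!nrow(h)) next
    best <- NULL; best_score <- -Inf
    for (key in unique(paste(h$target_name, h$strand))) {
      hh <- h[paste(h$target_name, h$strand) == key, , drop = FALSE]
      ch <- chain_hits(hh)
      sc <- sum(ch$score)
      if (sc > best_score) { best <- ch; best_score <- sc }
    }
    qlen <- nchar(protein_models[i])
    covered <- sum(best$qend - best$qstart)
    af <- 100 * covered / qlen
    sim <- 100 * sum(best$positives) / sum(best$aligned_cols)
    status <- if (af >= cfg$complete_gene_min_len && sim > cfg$complete_gene_min_sim)
      "Complete" else "Partial"
    out$status[i] <- status
    out$aligned_fraction[i] <- af
    out$similarity[i] <- sim
    out$scaffold[i] <- best$target_name[1]
  }
  out
}
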