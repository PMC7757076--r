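#' Analysis configuration
#'
#' Thresholds and window sizes used across the gap analyses. Defaults follow
#' common practice for avian draft-versus-reference comparisons: 500 bp gap
#' flanks, a 100 bp repeat-adjacency window, gaps longer than 10 bp only, and
#' flank-alignment filters of 98% identity, 90% query coverage and an e-value
#' of at most 1e-20.
#'
#' @param flank_len Flank length in bp extracted on each side of a gap.
#' @param min_gap_len_analysis Minimum gap length (bp) entering the cause
#'   analyses; the default 11 keeps gaps longer than 10 bp.
#' @param adjacency_window Window (bp) around a gap inside which a repeat
#'   counts as adjacent; distance `<= adjacency_window` qualifies.
#' @param min_identity Minimum percent identity for a flank hit to pass.
#' @param min_flank_coverage Minimum percent query coverage for a flank hit.
#' @param max_evalue Maximum e-value for a flank hit.
#' @param gc_window Window size (bp) for the GC census.
#' @param gc_threshold GC percent threshold (strictly greater-than).
#' @param contig_split_n Minimum N-run length (bp) that splits a scaffold into
#'   contigs (assemblathon convention, 25).
#' @param complete_gene_min_len Minimum percent of a protein model aligned for
#'   a "Complete" gene call.
#' @param complete_gene_min_sim Similarity percent that a "Complete" call must
#'   exceed (strictly).
#' @param z_homology_min Fraction of a contig that must align to the Z query
#'   chromosome (strictly exceeded) for homology-based Z calls.
#' @param max_projected_span Maximum span (bp) allowed between lifted flanks
#'   on the reference.
#' @param rng_seed Integer seed carried in reports.
#' @return A list with class `"gapscope_config"`.
#' @export
analysis_config <- function(flank_len = 500L,
                            min_gap_len_analysis = 11L,
                            adjacency_window = 100L,
                            min_identity = 98.0,
                            min_flank_coverage = 90.0,
                            max_evalue = 1e-20,
                            gc_window = 1000L,
                            gc_threshold = 58.8,
                            contig_split_n = 25L,
                            complete_gene_min_len = 95.0,
                            complete_gene_min_sim = 90.0,
                            z_homology_min = 0.60,
                            max_projected_span = 100000L,
                            rng_seed = 1L) {
  cfg <- list(flank_len = as.integer(flank_len),
              min_gap_len_analysis = as.integer(min_gap_len_analysis),
              adjacency_window = as.integer(adjacency_window),
              min_identity = min_identity,
              min_flank_coverage = min_flank_coverage,
              max_evalue = max_evalue,
              gc_window = as.integer(gc_window),
              gc_threshold = gc_threshold,
              contig_split_n = as.integer(contig_split_n),
              complete_gene_min_len = complete_gene_min_len,
              complete_gene_min_sim = complete_gene_min_sim,
              z_homology_min = z_homology_min,
              max_projected_span = as.integer(max_projected_span),
              rng_seed = as.integer(rng_seed))
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(vapply(cfg[num], function(v) any(v <= 0), logical(1))))
    stop("all thresholds in analysis_config must be strictly positive")
  if (cfg$min_gap_len_analysis < 1L)
    stop("min_gap_len_analysis must be >= 1")
  class(cfg) <- "gapscope_config"
  cfg
}

#' @export
print.gapscope_config <- function(x, ...) {
  cat("gapscope analysis config\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Small stable hash for provenance headers (FNV-1a over the deparsed object).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
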