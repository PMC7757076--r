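# Assembly census: N-run gaps, contig decomposition, Nx statistics,
# missing-assembly fraction and the simplified LTR Assembly Index.

#' Find N-run gaps in an assembly
#'
#' Returns every maximal run of N of length at least `min_len`, with a
#' `terminal` flag for runs touching a scaffold end. Terminal runs count in
#' the gap census but are excluded from the cause analyses downstream (flanks
#' are required on both sides).
#'
#' @param seqs `GenomeSequences`.
#' @param min_len Minimum run length in bp (>= 1). The cause analyses use 11
#'   (gaps longer than 10 bp); the census uses 1.
#' @return Data frame with columns `scaffold`, `start`, `end`, `length`,
#'   `terminal`, sorted by scaffold (input order) then start.
#' @export
find_gaps <- function(seqs, min_len = 1L) {
  stopifnot(min_len >= 1)
  out <- lapply(names(seqs), function(nm) {
    s <- unclass(seqs)[[nm]]
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) return(NULL)
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    keep <- len >= min_len
    if (!any(keep)) return(NULL)
    start <- start[keep]; len <- len[keep]
    data.frame(scaffold = nm, start = start, end = start + len,
               length = len,
               terminal = start == 0L | (start + len) == nchar(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), length = integer(),
                      terminal = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Split scaffolds into contigs at long N-runs
#'
#' Contigs are the scaffold segments between N-runs of length at least
#' `split_n`; shorter N-runs stay inside contigs. The returned intervals are
#' disjoint, sorted, and cover all non-split sequence.
#'
#' @param seqs `GenomeSequences`.
#' @param split_n Minimum N-run length that splits (default 25, the
#'   assemblathon convention).
#' @return Interval data frame (`seq_name`, `start`, `end`).
#' @export
split_contigs <- function(seqs, split_n = 25L) {
  stopifnot(split_n >= 1)
  gaps <- find_gaps(seqs, min_len = split_n)
  out <- lapply(names(seqs), function(nm) {
    len <- nchar(unclass(seqs)[[nm]])
    g <- gaps[gaps$scaffold == nm, , drop = FALSE]
    bounds <- c(0L, as.vector(rbind(g$start, g$end)), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (!any(keep)) {
      warning("scaffold ", nm, " contributes no contigs (all split N)")
      return(NULL)
    }
    data.frame(seq_name = nm, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq_name = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nx length statistic
#'
#' The smallest length L in the descending-sorted list such that sequences of
#' length >= L cover at least x% of the total. `nx_statistic(lengths, 50)` is
#' the familiar N50.
#'
#' @param lengths Positive sequence lengths.
#' @param x Percent in (0, 100].
#' @return Length in bp.
#' @export
nx_statistic <- function(lengths, x = 50) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(all(lengths > 0), x > 0, x <= 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= x / 100 * sum(s))[1]
  s[i]
}

#' Whole-assembly summary statistics
#'
#' Scaffold statistics are computed over whole records; contig statistics
#' over [split_contigs()] with `cfg$contig_split_n`; the gap census counts
#' every maximal N-run (including terminal runs, flagged in the output of
#' [find_gaps()]).
#'
#' @param seqs `GenomeSequences`.
#' @param cfg [analysis_config()].
#' @return A list with class `"AssemblyStats"`: `scaffold_count`,
#'   `contig_count`, `scaffold_n50`, `contig_n50`, `total_len`,
#'   `total_len_no_n`, `gap_count`, `gap_bp`.
#' @export
assembly_summary <- function(seqs, cfg = analysis_config()) {
  if (!length(seqs)) stop("empty assembly")
  slen <- as.numeric(seq_lengths(seqs))
  contigs <- split_contigs(seqs, cfg$contig_split_n)
  clen <- contigs$end - contigs$start
  gaps <- find_gaps(seqs, min_len = 1L)
  gap_bp <- sum(gaps$length)
  out <- list(scaffold_count = length(seqs),
              contig_count = nrow(contigs),
              scaffold_n50 = nx_statistic(slen, 50),
              contig_n50 = if (nrow(contigs)) nx_statistic(clen, 50) else NA_real_,
              total_len = sum(slen),
              total_len_no_n = sum(slen) - gap_bp,
              gap_count = nrow(gaps),
              gap_bp = gap_bp)
  class(out) <- "AssemblyStats"
  out
}

#' @export
print.AssemblyStats <- function(x, ...) {
  cat("Assembly summary\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Missing-assembly fraction relative to a reference
#'
#' `100 * (1 - draft_size / reference_size)` over N-free sizes. A draft
#' larger than the reference yields a negative value, reported as-is with a
#' warning.
#'
#' @param draft,reference `AssemblyStats` objects.
#' @return Percent missing.
#' @export
missing_fraction <- function(draft, reference) {
  if (reference$total_len_no_n <= 0) stop("reference N-free size must be > 0")
  v <- 100 * (1 - draft$total_len_no_n / reference$total_len_no_n)
  if (v < 0) warning("draft larger than reference: missing fraction is negative")
  v
}

#' Simplified LTR Assembly Index
#'
#' The proportion of full-length LTR retrotransposon base pairs over the
#' total LTR retrotransposon base pairs (full-length plus fragments),
#' expressed in percent. Intervals are merged within each full-length flag
#' group before summing. The `full_length` flag must come from the
#' annotation; intact-structure detection is out of scope.
#'
#' @param annot `RepeatAnnotation` with `full_length` flags on LTR rows.
#' @return Percent, or `NA` (with a warning) when the annotation holds no
#'   LTR intervals — an undefined index, distinct from 0.
#' @export
lai_simplified <- function(annot) {
  ltr <- annot[annot$repeat_class == "LTR", , drop = FALSE]
  if (!nrow(ltr)) {
    warning("no LTR intervals: LAI undefined")
    return(NA_real_)
  }
  fl <- merged_bp(ltr[isTRUE_vec(ltr$full_length), , drop = FALSE])
  fr <- merged_bp(ltr[!isTRUE_vec(ltr$full_length), , drop = FALSE])
  100 * fl / (fl + fr)
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE
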