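# GC-rich window census, canonical G-quadruplex motif scan and per-sequence
# feature density.

#' GC-rich window census
#'
#' Non-overlapping consecutive windows per scaffold; the final partial window
#' is kept when it covers at least half of `gc_window`. GC is
#' `100 * (G+C) / (A+C+G+T)` within the window; windows that are more than
#' half N are excluded and counted separately. "Above threshold" is strict
#' (`>`), matching the usual greater-than phrasing of GC census thresholds.
#'
#' @param seqs `GenomeSequences`.
#' @param cfg [analysis_config()] supplying `gc_window` (>= 100 bp) and
#'   `gc_threshold` (percent).
#' @return List: `n_above` (count of windows above threshold), `windows`
#'   (per-window table with `seq_name`, `start`, `end`, `gc`, `n_frac`,
#'   `above`), `n_excluded` (windows more than half N).
#' @export
gc_windows <- function(seqs, cfg = analysis_config()) {
  w <- cfg$gc_window
  stopifnot(w >= 100)
  thr <- cfg$gc_threshold
  tabs <- lapply(names(seqs), function(nm) {
    s <- Biostrings::DNAString(unclass(seqs)[[nm]])
    L <- length(s)
    starts <- seq(1L, L, by = w)
    ends <- pmin(starts + w - 1L, L)
    keep <- (ends - starts + 1L) >= w / 2
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    v <- Biostrings::Views(s, start = starts, end = ends)
    lf <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(lf[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(acgt > 0, 100 * rowSums(lf[, c("C", "G"), drop = FALSE]) / acgt,
                 NA_real_)
    data.frame(seq_name = nm, start = starts - 1L, end = ends,
               gc = gc, n_frac = lf[, "N"] / (ends - starts + 1L),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(seq_name = character(), start = integer(),
                      end = integer(), gc = numeric(), n_frac = numeric(),
                      stringsAsFactors = FALSE)
  excluded <- tab$n_frac > 0.5
  tab$above <- !excluded & !is.na(tab$gc) & tab$gc > thr
  list(n_above = sum(tab$above),
       windows = tab[!excluded, , drop = FALSE],
       n_excluded = sum(excluded))
}

# scan one strand pattern; returns 0-based half-open intervals
g4_scan_pattern <- function(s, pattern) {
  m <- gregexpr(pattern, s, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Canonical G-quadruplex motif scan
#'
#' Greedy left-to-right scan for the canonical quadruplex motif
#' `G{3,}(N{1,7}G{3,}){3,}` on the forward strand and the analogous C-pattern
#' (reported as strand `-`). Loop positions admit A, C, G or T; loop length
#' is capped at `max_loop` (classic Quadparser convention, 7). Overlapping
#' candidates across strands are resolved by earliest start, then longest.
#' This is a sequence-motif scan, not a folding-propensity score; outputs are
#' labelled `g4_canonical` downstream to prevent conflation with scored
#' predictors.
#'
#' @param seqs `GenomeSequences`.
#' @param max_loop Maximum loop length (1-12).
#' @param min_tract Minimum G-tract length (default 3).
#' @return Data frame: `seq_name`, `start`, `end`, `strand`, `n_tracts`,
#'   `sequence`; motifs are non-overlapping.
#' @export
find_g4_motifs <- function(seqs, max_loop = 7L, min_tract = 3L) {
  stopifnot(max_loop >= 1, max_loop <= 12)
  gpat <- sprintf("G{%d,}(?:[ACGT]{1,%d}G{%d,}){3,}", min_tract, max_loop, min_tract)
  cpat <- sprintf("C{%d,}(?:[ACGT]{1,%d}C{%d,}){3,}", min_tract, max_loop, min_tract)
  out <- lapply(names(seqs), function(nm) {
    s <- unclass(seqs)[[nm]]
    gp <- g4_scan_pattern(s, gpat)
    cp <- g4_scan_pattern(s, cpat)
    if (nrow(gp)) gp$strand <- "+"
    if (nrow(cp)) cp$strand <- "-"
    both <- rbind(gp, cp)
    if (!nrow(both)) return(NULL)
    both <- both[order(both$start, -(both$end - both$start)), , drop = FALSE]
    keep <- logical(nrow(both)); last_end <- -1L
    for (i in seq_len(nrow(both))) {
      if (both$start[i] >= last_end) { keep[i] <- TRUE; last_end <- both$end[i] }
    }
    both <- both[keep, , drop = FALSE]
    both$seq_name <- nm
    both$sequence <- substring(s, both$start + 1L, both$end)
    tract <- ifelse(both$strand == "+", "G{3,}", "C{3,}")
    both$n_tracts <- vapply(seq_len(nrow(both)), function(i) {
      m <- gregexpr(tract[i], both$sequence[i])[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1))
    both[, c("seq_name", "start", "end", "strand", "n_tracts", "sequence")]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_tracts = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-sequence feature density
#'
#' Merged feature base pairs divided by sequence length; sequences without
#' features get 0. Features on sequences absent from `seq_lengths` are an
#' error.
#'
#' @param features Interval data frame (`seq_name`, `start`, `end`).
#' @param seq_lens Named vector of sequence lengths (see [seq_lengths()]).
#' @return Named numeric vector of densities in `[0, 1]`.
#' @export
feature_density <- function(features, seq_lens) {
  unknown <- setdiff(unique(features$seq_name), names(seq_lens))
  if (length(unknown)) stop("feature on unknown sequence: ", unknown[1])
  dens <- setNames(numeric(length(seq_lens)), names(seq_lens))
  if (nrow(features)) {
    m <- merge_intervals(features)
    bp <- tapply(m$end - m$start, m$seq_name, sum)
    dens[names(bp)] <- as.numeric(bp) / as.numeric(seq_lens[names(bp)])
  }
  dens
}
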