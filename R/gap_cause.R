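# Gap-cause forensics: (a) which repeats sit next to draft-assembly gaps
# (fragmentation cause) and (b) what the gaps correspond to on a curated
# reference after lifting their flanks over (gap content), plus per-class
# repeat recovery.

# distance between a repeat interval and a gap on the same sequence,
# 0 for overlap or abutment (0-based half-open coordinates)
interval_distance <- function(g_start, g_end, r_start, r_end) {
  ifelse(r_end <= g_start, g_start - r_end,
         ifelse(r_start >= g_end, r_start - g_end, 0L))
}

#' Classify gaps by adjacent repeats
#'
#' For each gap, repeats within `cfg$adjacency_window` bp (distance
#' `<= window` qualifies; 101 bp does not at the default 100) are collected.
#' No adjacent repeat gives `NoRepeat`; one class gives that class; with
#' several classes the class of the repeat nearest to the gap edge wins
#' (distance 0 for overlap), ties broken by larger overlap with the gap, then
#' by the fixed order of [repeat_classes()]. The full class multiset per gap
#' is kept in the `classes` column so alternative tabulations remain
#' recomputable.
#'
#' @param gaps Gap data frame from [find_gaps()] (pass non-terminal gaps of
#'   analysis length; the function classifies what it is given).
#' @param repeats `RepeatAnnotation` on the same assembly.
#' @param cfg [analysis_config()].
#' @return Data frame: `scaffold`, `start`, `end`, `label`, `classes`
#'   (comma-separated multiset), `n_classes`.
#' @export
classify_adjacency <- function(gaps, repeats, cfg = analysis_config()) {
  w <- cfg$adjacency_window
  out <- gaps[, c("scaffold", "start", "end")]
  out$label <- "NoRepeat"
  out$classes <- ""
  out$n_classes <- 0L
  if (!nrow(gaps)) return(out)
  for (nm in unique(gaps$scaffold)) {
    gi <- which(gaps$scaffold == nm)
    rr <- repeats[repeats$seq_name == nm, , drop = FALSE]
    if (!nrow(rr)) next
    # expand by w + 1 and filter on exact distance below (abutment counts as 0)
    g_ir <- IRanges::IRanges(start = gaps$start[gi] - w, end = gaps$end[gi] + w + 1L)
    r_ir <- IRanges::IRanges(start = rr$start + 1L, end = rr$end)
    ov <- IRanges::findOverlaps(g_ir, r_ir)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    d <- interval_distance(gaps$start[gi][qh], gaps$end[gi][qh],
                           rr$start[sh], rr$end[sh])
    keep <- d <= w
    qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
    if (!length(qh)) next
    ovl <- pmax(0L, pmin(gaps$end[gi][qh], rr$end[sh]) -
                     pmax(gaps$start[gi][qh], rr$start[sh]))
    cls <- rr$repeat_class[sh]
    for (q in unique(qh)) {
      sel <- qh == q
      cl <- cls[sel]; dd <- d[sel]; oo <- ovl[sel]
      ord <- order(dd, -oo, match(cl, REPEAT_CLASSES))
      i <- gi[q]
      ucl <- sort(unique(cl))
      out$label[i] <- if (length(ucl) == 1) ucl else cl[ord[1]]
      out$classes[i] <- paste(cl[order(match(cl, REPEAT_CLASSES))], collapse = ",")
      out$n_classes[i] <- length(ucl)
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract gap flanks
#'
#' The left flank is the `flank_len` bases ending at the gap start; the right
#' flank starts at the gap end. A skip signal (`NotScorable`, reason
#' `terminal_gap`) is returned for terminal gaps, when fewer than `flank_len`
#' bases exist on either side, or when a flank is more than half N (an
#' adjacent second gap).
#'
#' @param gap One row of [find_gaps()] output (list or one-row data frame).
#' @param seqs The draft `GenomeSequences`.
#' @param cfg [analysis_config()].
#' @return `list(status = "ok", left =, right =)` or
#'   `list(status = "skip", reason = "terminal_gap")`.
#' @export
extract_flanks <- function(gap, seqs, cfg = analysis_config()) {
  skip <- list(status = "skip", reason = "terminal_gap")
  if (isTRUE(gap$terminal)) return(skip)
  s <- unclass(seqs)[[gap$scaffold]]
  fl <- cfg$flank_len
  if (gap$start < fl || nchar(s) - gap$end < fl) return(skip)
  left <- substr(s, gap$start - fl + 1L, gap$start)
  right <- substr(s, gap$end + 1L, gap$end + fl)
  n_frac <- function(x) (nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))) / nchar(x)
  if (n_frac(left) > 0.5 || n_frac(right) > 0.5) return(skip)
  list(status = "ok", left = left, right = right)
}

# decide a placement from the filtered hits of the two flanks
place_from_hits <- function(gap, left_hits, right_hits, cfg) {
  ns <- function(reason) list(status = "not_scorable", reason = reason)
  nl <- nrow(left_hits); nr <- nrow(right_hits)
  if (nl == 0 && nr == 0) return(ns("no_homology"))
  if (nl == 0 || nr == 0) return(ns("one_flank_only"))
  if (nl > 1 || nr > 1) return(ns("ambiguous"))
  L <- left_hits[1, ]; R <- right_hits[1, ]
  if (L$target_name != R$target_name) return(ns("different_scaffolds"))
  if (L$strand != R$strand) return(ns("orientation_conflict"))
  # projected interval between the gap-proximal ends of the two flank hits
  if (L$strand == "+") { p0 <- L$tend; p1 <- R$tstart }
  else { p0 <- R$tend; p1 <- L$tstart }
  if (p1 < p0) return(ns("orientation_conflict"))
  if (p1 - p0 > cfg$max_projected_span) {
    warning("projected span ", p1 - p0, " exceeds max_projected_span for gap at ",
            gap$scaffold, ":", gap$start)
    return(ns("span_exceeded"))
  }
  list(status = "placed",
       placement = list(gap = gap, left_hit = L, right_hit = R,
                        target_name = L$target_name,
                        proj_start = as.integer(p0), proj_end = as.integer(p1),
                        orientation = L$strand))
}

#' Place a gap on the reference via its flanks
#'
#' Aligns both flanks against the reference with [align_local()] and
#' [filter_hits()] and applies the unambiguous-liftover rules: both flanks
#' must each have exactly one passing hit, on the same reference sequence,
#' same strand, in an order consistent with that strand, within
#' `cfg$max_projected_span`. The projected interval runs between the
#' gap-proximal ends of the two flank hits (exclusive of the hits
#' themselves); flanks that abut on the reference give a zero-length
#' projection.
#'
#' @param gap One gap record (see [extract_flanks()]).
#' @param flanks Result of [extract_flanks()].
#' @param reference Reference `GenomeSequences`.
#' @param cfg [analysis_config()].
#' @param params [align_params()].
#' @param left_hits,right_hits Optional precomputed *filtered* hit frames for
#'   the two flanks (used by the batch driver to avoid re-aligning).
#' @return `list(status = "placed", placement = ...)` or
#'   `list(status = "not_scorable", reason = ...)`.
#' @export
place_gap <- function(gap, flanks, reference, cfg = analysis_config(),
                      params = align_params(),
                      left_hits = NULL, right_hits = NULL) {
  if (!identical(flanks$status, "ok"))
    return(list(status = "not_scorable", reason = flanks$reason))
  if (is.null(left_hits) || is.null(right_hits)) {
    hits <- align_local(c(L = flanks$left, R = flanks$right), reference, params)
    hits <- filter_hits(hits, cfg)
    left_hits <- hits[hits$query_name == "L", , drop = FALSE]
    right_hits <- hits[hits$query_name == "R", , drop = FALSE]
  }
  place_from_hits(gap, left_hits, right_hits, cfg)
}

#' Classify the reference content of a placed gap
#'
#' A projection overlapping a reference N-run is `NotScorable`
#' (`maps_to_reference_gap`); otherwise the repeat classes overlapping the
#' projected interval decide: none is `NoRepeat`, one is that class, two or
#' more is `Complex`.
#'
#' @param placement A placement from [place_gap()] (the `$placement` element).
#' @param ref_repeats `RepeatAnnotation` on the reference.
#' @param ref_gaps [find_gaps()] output for the reference.
#' @param cfg [analysis_config()].
#' @return `list(label =, reason = NA or reason)`.
#' @export
classify_content <- function(placement, ref_repeats, ref_gaps,
                             cfg = analysis_config()) {
  tn <- placement$target_name
  p0 <- placement$proj_start; p1 <- placement$proj_end
  g <- ref_gaps[ref_gaps$scaffold == tn, , drop = FALSE]
  if (nrow(g) && any(g$start < p1 & g$end > p0))
    return(list(label = "NotScorable", reason = "maps_to_reference_gap"))
  rr <- ref_repeats[ref_repeats$seq_name == tn, , drop = FALSE]
  cls <- unique(rr$repeat_class[rr$start < p1 & rr$end > p0])
  if (!length(cls)) return(list(label = "NoRepeat", reason = NA_character_))
  if (length(cls) == 1) return(list(label = cls, reason = NA_character_))
  list(label = "Complex", reason = NA_character_)
}

#' Full gap-content analysis of a draft against a reference
#'
#' Batch driver: finds analysis gaps (longer than
#' `cfg$min_gap_len_analysis - 1` bp, non-terminal), extracts flanks, aligns
#' all flanks in one pass, places each gap and classifies its reference
#' content.
#'
#' @param draft,reference `GenomeSequences`.
#' @param ref_repeats Reference `RepeatAnnotation`.
#' @param cfg [analysis_config()].
#' @param params [align_params()].
#' @return Data frame with one row per analysed gap: coordinates, `status`
#'   (`placed`/`not_scorable`/`skip`), `reason`, content `label`, projected
#'   interval and orientation.
#' @export
gap_content_analysis <- function(draft, reference, ref_repeats,
                                 cfg = analysis_config(),
                                 params = align_params()) {
  gaps <- find_gaps(draft, min_len = cfg$min_gap_len_analysis)
  gaps <- gaps[!gaps$terminal, , drop = FALSE]
  ref_gaps <- find_gaps(reference, min_len = 1L)
  n <- nrow(gaps)
  res <- data.frame(scaffold = gaps$scaffold, start = gaps$start,
                    end = gaps$end, status = rep("skip", n),
                    reason = rep("terminal_gap", n),
                    label = rep("NotScorable", n),
                    proj_seq = NA_character_, proj_start = NA_integer_,
                    proj_end = NA_integer_, orientation = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n) return(res)
  flanks <- vector("list", n)
  queries <- character(0)
  for (i in seq_len(n)) {
    flanks[[i]] <- extract_flanks(gaps[i, ], draft, cfg)
    if (identical(flanks[[i]]$status, "ok")) {
      queries[[paste0("g", i, ".L")]] <- flanks[[i]]$left
      queries[[paste0("g", i, ".R")]] <- flanks[[i]]$right
    }
  }
  hits <- if (length(queries))
    filter_hits(align_local(queries, reference, params), cfg)
  else empty_hits()
  byq <- split(hits, hits$query_name)
  for (i in seq_len(n)) {
    if (!identical(flanks[[i]]$status, "ok")) next
    lh <- byq[[paste0("g", i, ".L")]]
    rh <- byq[[paste0("g", i, ".R")]]
    if (is.null(lh)) lh <- empty_hits()
    if (is.null(rh)) rh <- empty_hits()
    pl <- place_from_hits(gaps[i, ], lh, rh, cfg)
    if (identical(pl$status, "not_scorable")) {
      res$status[i] <- "not_scorable"
      res$reason[i] <- pl$reason
      next
    }
    res$status[i] <- "placed"
    res$reason[i] <- NA_character_
    res$proj_seq[i] <- pl$placement$target_name
    res$proj_start[i] <- pl$placement$proj_start
    res$proj_end[i] <- pl$placement$proj_end
    res$orientation[i] <- pl$placement$orientation
    cc <- classify_content(pl$placement, ref_repeats, ref_gaps, cfg)
    res$label[i] <- cc$label
    if (!is.na(cc$reason)) res$reason[i] <- cc$reason
  }
  res
}

#' Per-class repeat recovery of a draft relative to the reference
#'
#' For every repeat class, the merged repeat base pairs present in the draft
#' divided by the merged base pairs in the reference. Classes absent from the
#' reference are undefined (`NA`); ratios above 1 are allowed and flagged
#' (haplotype duplication).
#'
#' @param draft_repeats,ref_repeats `RepeatAnnotation` objects.
#' @return Data frame: `repeat_class`, `draft_bp`, `ref_bp`, `recovery`,
#'   `over_one`.
#' @export
repeat_recovery <- function(draft_repeats, ref_repeats) {
  if (!nrow(draft_repeats) || !nrow(ref_repeats))
    stop("both annotations must be nonempty")
  cls <- REPEAT_CLASSES
  bp <- function(ann, cl) merged_bp(ann[ann$repeat_class == cl, , drop = FALSE])
  d <- vapply(cls, function(cl) bp(draft_repeats, cl), numeric(1))
  r <- vapply(cls, function(cl) bp(ref_repeats, cl), numeric(1))
  rec <- ifelse(r > 0, d / r, NA_real_)
  out <- data.frame(repeat_class = cls, draft_bp = d, ref_bp = r,
                    recovery = rec, over_one = !is.na(rec) & rec > 1,
                    stringsAsFactors = FALSE)
  if (any(out$over_one))
    warning("recovery > 1 for: ",
            paste(out$repeat_class[out$over_one], collapse = ", "),
            " (possible haplotype duplication)")
  rownames(out) <- NULL
  out
}

#' Tabulate gap-cause and gap-content labels
#'
#' Counts and proportions per label for both analyses. Proportions are
#' reported on two bases: over all gaps and over scorable gaps (label not
#' `NotScorable`), since either denominator is defensible.
#'
#' @param labels_adjacency Character vector of adjacency labels.
#' @param labels_content Character vector of content labels.
#' @return List with data frames `adjacency` and `content`
#'   (`label`, `n`, `prop_all`, `prop_scorable`).
#' @export
tabulate_figure_labels <- function(labels_adjacency, labels_content) {
  one <- function(lab) {
    lev <- GAP_LABELS
    n <- as.integer(table(factor(lab, levels = lev)))
    total <- length(lab)
    scorable <- sum(lab != "NotScorable")
    data.frame(label = lev, n = n,
               prop_all = if (total) n / total else rep(NA_real_, length(lev)),
               prop_scorable = ifelse(lev == "NotScorable", NA_real_,
                                      if (scorable) n / scorable
                                      else rep(NA_real_, length(lev))),
               stringsAsFactors = FALSE)
  }
  list(adjacency = one(labels_adjacency), content = one(labels_content))
}
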