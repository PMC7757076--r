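# Sex-linkage calling from male/female read-depth ratios plus optional
# Z-homology fractions, and chimeric-scaffold flagging.

#' Sex-linkage calling parameters
#'
#' The homology rule (contigs with more than 60% of their sequence aligning
#' to a known Z chromosome are Z candidates) comes from practice; the
#' coverage windows are this package's declared defaults, surfaced in every
#' report: ratio tolerance `t = 0.25` around the expected 0.5 (hemizygous)
#' and 1.0 (diploid) values, and a male-depth ceiling of 0.1 for W calls.
#'
#' @param t Ratio tolerance.
#' @param w_male_max Maximum male depth ratio for a W call.
#' @param z_hom_min Z-homology fraction that must be strictly exceeded.
#' @param min_len Length floor (bp) for contigs entering the autosomal
#'   baseline.
#' @return Parameter list.
#' @export
sexlink_params <- function(t = 0.25, w_male_max = 0.1, z_hom_min = 0.60,
                           min_len = 5000L) {
  list(t = t, w_male_max = w_male_max, z_hom_min = z_hom_min,
       min_len = as.integer(min_len))
}

#' Read a per-contig depth table
#'
#' Tab-separated with header: `contig`, `length`, `mean_depth_female`,
#' `mean_depth_male`.
#'
#' @param path Path to the TSV (may carry '#' comment lines).
#' @return Validated coverage data frame.
#' @export
read_coverage_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("contig", "length", "mean_depth_female", "mean_depth_male")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(duplicated(df$contig))) stop("duplicate contig names")
  if (any(df$mean_depth_female < 0 | df$mean_depth_male < 0))
    stop("negative depths")
  df
}

#' Fraction of a contig covered by alignments to a query chromosome
#'
#' The contig is cut into 1 kb pieces, each aligned locally against the query
#' chromosome; hits passing the identity and e-value filters are mapped back
#' to contig coordinates, merged, and the covered fraction returned.
#'
#' @param contig_seq Single DNA sequence (character).
#' @param query_chrom `GenomeSequences` holding the query chromosome.
#' @param cfg [analysis_config()].
#' @param params [align_params()].
#' @return Fraction in `[0, 1]`.
#' @export
homology_fraction <- function(contig_seq, query_chrom,
                              cfg = analysis_config(),
                              params = align_params()) {
  contig_seq <- toupper(contig_seq)
  L <- nchar(contig_seq)
  stopifnot(L >= 1000)
  starts <- seq(0L, L - 1L, by = 1000L)
  ends <- pmin(starts + 1000L, L)
  keep <- ends - starts >= params$k
  starts <- starts[keep]; ends <- ends[keep]
  chunks <- substring(contig_seq, starts + 1L, ends)
  names(chunks) <- paste0("c", starts)
  hits <- align_local(chunks, query_chrom, params)
  if (!nrow(hits)) return(0)
  hits <- hits[hits$identity >= cfg$min_identity &
                 hits$evalue <= cfg$max_evalue, , drop = FALSE]
  if (!nrow(hits)) return(0)
  off <- as.integer(sub("^c", "", hits$query_name))
  cov <- data.frame(seq_name = "contig", start = off + hits$qstart,
                    end = off + hits$qend)
  merged_bp(cov) / L
}

#' Classify contigs as Z, W or autosomal from coverage ratios
#'
#' The autosomal baseline is the median depth (per sex) over contigs that are
#' not Z-homologous (`z_hom <= z_hom_min` or unknown) and at least `min_len`
#' long — keeping sex chromosomes out of the baseline. Per contig,
#' `f_ratio` and `m_ratio` are depths over the respective baselines. Calls:
#' Z when `z_hom > z_hom_min` or (`f_ratio` within `0.5 +/- t` and `m_ratio`
#' within `1 +/- t`); W when `f_ratio` within `0.5 +/- t` and
#' `m_ratio < w_male_max`; PAR_or_Autosome when both ratios are within
#' `1 +/- t`; otherwise Unclassified. W is tested before Z so female-specific
#' contigs with low male coverage are never absorbed by the Z window.
#'
#' @param cov Coverage data frame (see [read_coverage_table()]).
#' @param z_hom Optional named vector of Z-homology fractions per contig.
#' @param params [sexlink_params()].
#' @return Data frame: `contig`, `call`, `f_ratio`, `m_ratio`, `z_homology`.
#' @export
classify_sex_linkage <- function(cov, z_hom = NULL, params = sexlink_params()) {
  if (nrow(cov) < 20)
    stop("need at least 20 contigs to estimate the autosomal baseline")
  zh <- setNames(rep(NA_real_, nrow(cov)), cov$contig)
  if (!is.null(z_hom)) zh[names(z_hom)] <- z_hom
  base_ok <- (is.na(zh) | zh <= params$z_hom_min) & cov$length >= params$min_len
  f_med <- median(cov$mean_depth_female[base_ok])
  m_med <- median(cov$mean_depth_male[base_ok])
  if (!isTRUE(f_med > 0) || !isTRUE(m_med > 0))
    stop("degenerate autosomal median depth")
  f_ratio <- cov$mean_depth_female / f_med
  m_ratio <- cov$mean_depth_male / m_med
  t <- params$t
  half_f <- abs(f_ratio - 0.5) <= t
  full_f <- abs(f_ratio - 1) <= t
  full_m <- abs(m_ratio - 1) <= t
  call <- rep("Unclassified", nrow(cov))
  call[half_f & m_ratio < params$w_male_max] <- "W"
  is_z <- (!is.na(zh) & zh > params$z_hom_min) | (half_f & full_m)
  call[is_z & call != "W"] <- "Z"
  call[call == "Unclassified" & full_f & full_m] <- "PAR_or_Autosome"
  data.frame(contig = cov$contig, call = call, f_ratio = f_ratio,
             m_ratio = m_ratio, z_homology = unname(zh),
             stringsAsFactors = FALSE)
}

#' Flag chimeric scaffolds mixing sex-linked and autosomal contigs
#'
#' A scaffold is flagged when it contains at least one contig called Z or W
#' and at least one called PAR_or_Autosome; Unclassified contigs are
#' ignored.
#'
#' @param composition Data frame with columns `scaffold`, `contig`, `call`.
#' @return Character vector of flagged scaffold names.
#' @export
flag_chimeric_scaffolds <- function(composition) {
  stopifnot(all(c("scaffold", "contig", "call") %in% names(composition)))
  flagged <- vapply(split(composition, composition$scaffold), function(d)
    any(d$call %in% c("Z", "W")) && any(d$call == "PAR_or_Autosome"),
    logical(1))
  names(flagged)[flagged]
}
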