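# Data model and readers/writers.
#
# Coordinate convention: every interval inside the package is 0-based
# half-open on the forward strand.  Conversions to and from 1-based inclusive
# layouts (RepeatMasker .out, blast outfmt 6) happen only in the readers and
# writers in this file and in read_blast_tab().

#' Construct a GenomeSequences object
#'
#' A named set of uppercase DNA sequences over the alphabet \{A,C,G,T,N\}.
#' Lowercase letters are folded to uppercase and IUPAC ambiguity codes other
#' than N are folded to N (the number of folded bases is kept in the
#' `"folded"` attribute and reported with a message).
#'
#' @param x Named character vector of DNA sequences.
#' @param source_path Optional provenance string.
#' @return A `GenomeSequences` object (named character vector).
#' @export
genome_sequences <- function(x, source_path = NA_character_) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named")
  dup <- names(x)[duplicated(names(x))]
  if (length(dup)) stop("duplicate name ", dup[1])
  if (any(!nzchar(x))) {
    stop("empty sequence for record ",
         names(x)[which(!nzchar(x))[1]])
  }
  x <- toupper(x)
  folded <- sum(nchar(x)) - sum(nchar(gsub("[^ACGTN]", "", x)))
  if (folded > 0) {
    x <- vapply(x, function(s) gsub("[^ACGTN]", "N", s), character(1))
    message("folded ", folded, " ambiguity base(s) to N")
  }
  structure(x, source_path = source_path, folded = folded,
            class = "GenomeSequences")
}

#' @export
print.GenomeSequences <- function(x, ...) {
  cat("GenomeSequences with", length(x), "record(s), total",
      sum(nchar(x)), "bp\n")
  n <- min(length(x), 8L)
  for (i in seq_len(n))
    cat(sprintf("  %-20s %10d bp\n", names(x)[i], nchar(x[[i]])))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Sequence lengths of a GenomeSequences object
#' @param seqs A `GenomeSequences` object or named character vector.
#' @return Named integer vector of lengths.
#' @export
seq_lengths <- function(seqs) setNames(nchar(unclass(seqs)), names(seqs))

#' Read a (multi-)FASTA file
#'
#' Records are normalized per [genome_sequences()]: uppercased, ambiguity
#' codes folded to N. File order is preserved; duplicate names and empty
#' records are hard errors.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A `GenomeSequences` object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  x <- as.character(set)
  # readBStringSet keeps full header lines; use the first token as the name
  names(x) <- sub("\\s.*$", "", names(x))
  genome_sequences(x, source_path = path)
}

#' Write sequences to FASTA
#' @param seqs `GenomeSequences` object.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---- intervals --------------------------------------------------------------

#' Validate an interval data frame
#'
#' Intervals are data frames with columns `seq_name`, `start`, `end` and
#' optionally `strand`, 0-based half-open. When `seqs` is given, bounds are
#' checked against the sequence lengths.
#'
#' @param x Interval data frame.
#' @param seqs Optional `GenomeSequences` for bounds checking.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, seqs = NULL) {
  stopifnot(is.data.frame(x),
            all(c("seq_name", "start", "end") %in% names(x)))
  if (nrow(x)) {
    if (any(x$start < 0) || any(x$end <= x$start))
      stop("invalid interval: need 0 <= start < end")
    if (!is.null(seqs)) {
      len <- seq_lengths(seqs)
      if (any(!x$seq_name %in% names(len)))
        stop("interval on unknown sequence: ",
             setdiff(x$seq_name, names(len))[1])
      if (any(x$end > len[x$seq_name]))
        stop("interval end beyond sequence length")
    }
  }
  invisible(x)
}

# IRanges helper: merge intervals per sequence.  min_gap = 1 merges strictly
# overlapping and abutting ranges; min_gap = 0 merges strictly overlapping
# ranges only (abutting kept separate).
merge_intervals <- function(x, abutting = TRUE) {
  if (!nrow(x)) return(x[, c("seq_name", "start", "end")])
  out <- lapply(split(x, x$seq_name), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = if (abutting) 1L else 0L)
    data.frame(seq_name = d$seq_name[1],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seq_name, out$start), , drop = FALSE]
}

# total merged bp per group
merged_bp <- function(x, abutting = TRUE) {
  m <- merge_intervals(x, abutting = abutting)
  if (!nrow(m)) 0 else sum(m$end - m$start)
}

# ---- repeat annotation ------------------------------------------------------

#' Default repeat class mapping table
#'
#' Maps RepeatMasker class/family strings (the part before "/" or the full
#' string) onto the canonical classes of [repeat_classes()]. The table ships
#' as `inst/extdata/repeat_class_map.tsv` and can be replaced by the caller.
#'
#' @return Data frame with columns `pattern` and `class`.
#' @export
repeat_class_map <- function() {
  path <- system.file("extdata", "repeat_class_map.tsv", package = "gapscope")
  if (nzchar(path) && file.exists(path)) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    # fallback used before installation
    data.frame(pattern = c("LINE", "SINE", "LTR", "DNA", "RC", "Satellite",
                           "Simple_repeat", "Low_complexity", "rRNA", "snRNA",
                           "scRNA", "srpRNA", "tRNA", "Retroposon"),
               class = c("LINE", "SINE", "LTR", "DNA", "DNA", "Satellite",
                         "SimpleRepeat", "LowComplexity", "rRNA", "Other",
                         "Other", "Other", "Other", "Other"),
               stringsAsFactors = FALSE)
  }
}

#' Map annotation class strings to canonical repeat classes
#' @param labels Character vector of RepeatMasker-style class/family strings.
#' @param map Mapping table as from [repeat_class_map()].
#' @return Character vector of canonical classes; unmatched labels map to
#'   `"Unknown"`.
#' @export
map_repeat_class <- function(labels, map = repeat_class_map()) {
  key <- sub("/.*$", "", labels)
  idx <- match(key, map$pattern)
  out <- ifelse(is.na(idx), "Unknown", map$class[idx])
  unknown <- sum(is.na(idx))
  if (unknown > 0)
    warning(unknown, " annotation row(s) with unrecognized class mapped to Unknown")
  out
}

#' Construct a repeat annotation
#'
#' @param df Data frame with columns `seq_name`, `start`, `end`, `strand`,
#'   `repeat_class`, `family`, and optionally `full_length` (logical) and
#'   `divergence` (percent).
#' @return The data frame, sorted by `(seq_name, start)`, with class
#'   `"RepeatAnnotation"`.
#' @export
repeat_annotation <- function(df) {
  need <- c("seq_name", "start", "end", "strand", "repeat_class", "family")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"full_length" %in% names(df)) df$full_length <- NA
  if (!"divergence" %in% names(df)) df$divergence <- NA_real_
  validate_intervals(df)
  bad <- setdiff(unique(df$repeat_class), REPEAT_CLASSES)
  if (length(bad)) stop("unknown repeat class: ", bad[1])
  df <- df[order(df$seq_name, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("RepeatAnnotation", "data.frame")
  df
}

#' Read a RepeatMasker .out file
#'
#' Parses the standard whitespace-delimited .out layout (three header lines),
#' converts 1-based inclusive coordinates to 0-based half-open, maps the
#' class/family column to canonical classes and decodes the `C` strand code
#' to `-`. Malformed rows are skipped with a warning; more than 10% malformed
#' rows is a hard error. When `genome` is supplied, rows on sequences absent
#' from it are rejected with a count.
#'
#' @param path Path to a RepeatMasker .out file.
#' @param genome Optional companion `GenomeSequences`.
#' @param map Class mapping table, see [repeat_class_map()].
#' @return A `RepeatAnnotation` data frame.
#' @export
read_repeatmasker_out <- function(path, genome = NULL, map = repeat_class_map()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^\\s*SW", lines[1])) lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(repeat_annotation(data.frame(seq_name = character(), start = integer(),
                                        end = integer(), strand = character(),
                                        repeat_class = character(), family = character())))
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, function(f) {
    length(f) >= 11 &&
      !is.na(suppressWarnings(as.integer(f[6]))) &&
      !is.na(suppressWarnings(as.integer(f[7]))) &&
      f[9] %in% c("+", "C")
  }, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (n_bad / length(fields) > 0.10)
      stop(n_bad, " of ", length(fields), " rows malformed (> 10%)")
    warning("skipped ", n_bad, " malformed row(s)")
  }
  fields <- fields[ok]
  df <- data.frame(
    seq_name = vapply(fields, `[`, character(1), 5),
    start = vapply(fields, function(f) as.integer(f[6]), integer(1)) - 1L,
    end = vapply(fields, function(f) as.integer(f[7]), integer(1)),
    strand = ifelse(vapply(fields, `[`, character(1), 9) == "C", "-", "+"),
    family = vapply(fields, `[`, character(1), 10),
    raw_class = vapply(fields, `[`, character(1), 11),
    divergence = vapply(fields, function(f) suppressWarnings(as.numeric(f[2])), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    known <- df$seq_name %in% names(genome)
    if (any(!known)) {
      message("rejected ", sum(!known), " row(s) on sequences absent from the assembly")
      df <- df[known, , drop = FALSE]
    }
  }
  df$repeat_class <- map_repeat_class(df$raw_class, map)
  df$raw_class <- NULL
  df$full_length <- NA
  repeat_annotation(df)
}

# ---- BED --------------------------------------------------------------------

#' Write labelled intervals as BED6
#'
#' @param intervals Data frame with `seq_name`, `start`, `end`, a label column
#'   (`label` or `name`), and optionally `strand` and `score`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals)) validate_intervals(intervals)
  lab <- if ("label" %in% names(intervals)) intervals$label
         else if ("name" %in% names(intervals)) intervals$name
         else rep(".", nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand
            else rep(".", nrow(intervals))
  score <- if ("score" %in% names(intervals)) intervals$score
           else rep(0L, nrow(intervals))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(intervals)) {
    writeLines(paste(intervals$seq_name, intervals$start, intervals$end,
                     lab, score, strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED file into an interval data frame
#' @param path Path to a BED3+ file.
#' @return Data frame with `seq_name`, `start`, `end`, `label`, `score`,
#'   `strand` (missing columns filled with defaults).
#' @export
read_bed <- function(path) {
  empty <- data.frame(seq_name = character(), start = integer(), end = integer(),
                      label = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t")
  get <- function(i, default, as = identity)
    vapply(f, function(x) if (length(x) >= i) as(x[i]) else as(default),
           as(default))
  data.frame(seq_name = get(1, ""), start = as.integer(get(2, "0")),
             end = as.integer(get(3, "0")), label = get(4, "."),
             score = as.numeric(get(5, "0")), strand = get(6, "."),
             stringsAsFactors = FALSE)
}

# ---- reports ----------------------------------------------------------------

#' Write a TSV report with a provenance header
#'
#' All tabular outputs carry a single '#'-prefixed comment line with the tool
#' version, a config hash and the input paths, followed by a header line.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Configuration object included in the provenance hash.
#' @param inputs Character vector of input paths.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(df, path, config = NULL, inputs = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gapscope %s; config=%s; inputs=%s",
                     as.character(packageVersion("gapscope")),
                     if (is.null(config)) "-" else config_hash(config),
                     if (length(inputs)) paste(inputs, collapse = ",") else "-"),
             con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}
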