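# Shared fixtures.  The default synthetic run is expensive, so it is built
# once per session and cached; unit tests use small purpose-built inputs.

.gapscope_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .gapscope_cache)) {
    assign(key, builder(), envir = .gapscope_cache)
  }
  get(key, envir = .gapscope_cache)
}

default_truth <- function()
  cached("truth", function() build_truth_genome(simulation_config(seed = 1)))

default_draft <- function()
  cached("draft", function() derive_draft(default_truth()))

default_content <- function()
  cached("content", function() {
    truth <- default_truth()
    gap_content_analysis(default_draft()$draft, truth$genome, truth$repeats)
  })

# small genome for unit tests
tiny_sim_config <- function(seed = 11, ...) {
  args <- list(n_macro = 1, n_micro = 1, macro_len = 60000,
               micro_len = 30000, z_len = 30000, w_len = 25000,
               par_len = 3000, n_breaks = 12, n_background_breaks = 2,
               n_compound = 1, n_genes = 2, n_exon_paralogs = 4, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

gs <- function(...) suppressMessages(genome_sequences(c(...)))

random_dna_str <- function(n, bases = c("A", "C", "G", "T"))
  paste(sample(bases, n, replace = TRUE), collapse = "")

write_tmp_fasta <- function(seqs, width = 60) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  close(con)
  path
}

# a 5-row RepeatMasker .out fixture with hand-computable per-class bp totals
rm_out_fixture <- function() {
  lines <- c(
    "   SW   perc perc perc  query     position in query  matching repeat",
    "score   div. del. ins.  sequence  begin end  (left)  repeat  class/family  begin end (left) ID",
    "",
    " 1306  15.6  6.2  0.0  s1   101  200  (0) +  CR1-X   LINE/CR1       1 100 (0) 1",
    "  500   1.2  0.0  0.0  s1   301  400  (0) C  ERVL-x  LTR/ERVL       1 100 (0) 2",
    "  400   2.0  0.0  0.0  s2    51  150  (0) +  (TA)n   Simple_repeat  1 100 (0) 3",
    "  300   2.0  0.0  0.0  s2   201  260  (0) +  SAT-1   Satellite      1  60 (0) 4",
    "  200   2.0  0.0  0.0  s2   301  330  (0) +  Weird   Banana/Phone   1  30 (0) 5")
  path <- tempfile(fileext = ".out")
  writeLines(lines, path)
  path
}

# brute-force oracles -------------------------------------------------------

# largest L such that sequences of length >= L still cover x% of the total
oracle_nx <- function(lengths, x) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) return(L)
  }
  min(lengths)
}

oracle_gaps <- function(s, min_len) {
  v <- strsplit(s, "")[[1]]
  runs <- rle(v == "N")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values & runs$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             terminal = starts[keep] == 0 | ends[keep] == length(v))
}

oracle_contigs <- function(s, split_n) {
  v <- strsplit(s, "")[[1]]
  runs <- rle(v == "N")
  split_run <- runs$values & runs$lengths >= split_n
  grp <- cumsum(split_run != c(FALSE, head(split_run, -1)))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
  seg_start <- integer(0); seg_end <- integer(0)
  cur <- NA_integer_
  for (i in seq_along(runs$lengths)) {
    if (split_run[i]) {
      if (!is.na(cur)) { seg_start <- c(seg_start, cur); seg_end <- c(seg_end, starts[i]) }
      cur <- NA_integer_
    } else if (is.na(cur)) cur <- starts[i]
  }
  if (!is.na(cur)) { seg_start <- c(seg_start, cur); seg_end <- c(seg_end, length(v)) }
  data.frame(start = seg_start, end = seg_end)
}

# O(n^2) iterative merge: only strictly overlapping intervals coalesce
oracle_merge <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  repeat {
    done <- TRUE
    i <- 1
    while (i < nrow(iv)) {
      if (iv$start[i + 1] < iv$end[i]) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        done <- FALSE
      } else i <- i + 1
    }
    if (done) break
  }
  rownames(iv) <- NULL
  iv
}

# direct overlap-or-abutment intersection (window = 0 adjacency oracle)
oracle_adjacency0 <- function(gap, repeats) {
  sel <- repeats$end >= gap$start & repeats$start <= gap$end
  unique(repeats$repeat_class[sel])
}
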