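# Stage orchestration and report rendering.  Stages read and write files
# under one output directory; `simulate` is the root producer, every other
# stage consumes its outputs (or user-supplied paths in the run config).

write_faa <- function(proteins, path) {
  set <- Biostrings::AAStringSet(unclass(proteins))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write all artefacts of one simulation to a directory
#'
#' Emits `truth.fa`, `draft.fa`, `truth.repeats.bed`, `draft.repeats.bed`,
#' `gap_truth.tsv`, `depth.tsv` (female and male columns), `exons.faa` and
#' `genes.faa`.
#'
#' @param truth `SyntheticTruth`.
#' @param draft `DraftTruth`.
#' @param dir Output directory (created if needed).
#' @param depth Coverage baseline for the simulated depth table.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(truth, draft, dir, depth = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(truth$genome, p("truth.fa"))
  write_fasta(draft$draft, p("draft.fa"))
  rb <- truth$repeats
  rb$label <- rb$repeat_class
  write_bed(rb, p("truth.repeats.bed"))
  db <- draft$draft_repeats
  db$label <- db$repeat_class
  write_bed(db, p("draft.repeats.bed"))
  write_report_tsv(draft$gap_truth, p("gap_truth.tsv"), truth$cfg)
  write_report_tsv(coverage_table(draft, depth = depth), p("depth.tsv"), truth$cfg)
  write_report_tsv(draft$composition, p("composition.tsv"), truth$cfg)
  write_faa(truth$exon_queries, p("exons.faa"))
  write_faa(setNames(truth$genes$protein, truth$genes$gene_id), p("genes.faa"))
  invisible(vapply(c("truth.fa", "draft.fa", "truth.repeats.bed",
                     "draft.repeats.bed", "gap_truth.tsv", "depth.tsv",
                     "composition.tsv", "exons.faa", "genes.faa"), p,
                   character(1)))
}

stage_defs <- function() {
  list(
    simulate = character(0),
    stats = "simulate",
    gapcause = "simulate",
    gc = "simulate",
    g4 = "simulate",
    census = "simulate",
    genes = "simulate",
    sexlink = "simulate")
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order
#' (`simulate -> stats/gapcause/gc/g4/census/genes/sexlink`). A failed stage
#' halts its dependents; independent stages still run. Each output file is
#' recorded in the manifest with an md5 digest, so deterministic reruns can
#' be verified digest-by-digest.
#'
#' @param config List (or path to a JSON file) with optional elements
#'   `sim` (arguments for [simulation_config()]), `analysis` (arguments for
#'   [analysis_config()]), `depth` (coverage baseline) and `draft`/`reference`
#'   /`ref_repeats` paths overriding the simulated inputs.
#' @param stages Character vector of stage names.
#' @param out_dir Output directory.
#' @return The run manifest (list), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), stages = "simulate",
                         out_dir = "gapscope_run") {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defs <- stage_defs()
  unknown <- setdiff(stages, names(defs))
  if (length(unknown)) stop("unknown stage name: ", unknown[1])
  # dependency order, with implied dependencies added
  wanted <- unique(c(unlist(defs[stages]), stages))
  order <- intersect(names(defs), wanted)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scfg <- do.call(simulation_config, as.list(config$sim %||% list()))
  acfg <- do.call(analysis_config, as.list(config$analysis %||% list()))
  depth <- config$depth %||% 30
  p <- function(f) file.path(out_dir, f)

  manifest <- list(tool_version = as.character(packageVersion("gapscope")),
                   config_hash = config_hash(list(scfg, acfg)),
                   stages = list(), warnings = character(0))
  status <- setNames(rep("pending", length(order)), order)

  need <- function(f) {
    path <- config[[f]] %||% p(paste0(f, ".fa"))
    if (!file.exists(path)) stop("missing input: ", path)
    path
  }

  run_one <- function(stage) {
    outs <- character(0)
    if (stage == "simulate") {
      truth <- build_truth_genome(scfg)
      draft <- derive_draft(truth)
      outs <- write_simulation(truth, draft, out_dir, depth = depth)
    } else if (stage == "stats") {
      draft <- read_fasta(need("draft"))
      st <- assembly_summary(draft, acfg)
      df <- as.data.frame(unclass(st))
      if (file.exists(p("truth.fa")) || !is.null(config$reference)) {
        ref <- read_fasta(config$reference %||% p("truth.fa"))
        df$missing_fraction <-
          suppressWarnings(missing_fraction(st, assembly_summary(ref, acfg)))
      }
      outs <- write_report_tsv(df, p("stats.tsv"), acfg)
    } else if (stage == "gapcause") {
      draft <- read_fasta(need("draft"))
      ref <- read_fasta(config$reference %||% p("truth.fa"))
      rb <- read_bed(config$ref_repeats %||% p("truth.repeats.bed"))
      ref_rep <- repeat_annotation(data.frame(
        seq_name = rb$seq_name, start = rb$start, end = rb$end,
        strand = rb$strand, repeat_class = rb$label, family = rb$label,
        stringsAsFactors = FALSE))
      res <- gap_content_analysis(draft, ref, ref_rep, acfg)
      outs <- c(outs, write_report_tsv(res, p("content.tsv"), acfg))
      db <- read_bed(config$draft_repeats %||% p("draft.repeats.bed"))
      draft_rep <- repeat_annotation(data.frame(
        seq_name = db$seq_name, start = db$start, end = db$end,
        strand = db$strand, repeat_class = db$label, family = db$label,
        stringsAsFactors = FALSE))
      gaps <- find_gaps(draft, acfg$min_gap_len_analysis)
      gaps <- gaps[!gaps$terminal, , drop = FALSE]
      adj <- classify_adjacency(gaps, draft_rep, acfg)
      outs <- c(outs, write_report_tsv(adj, p("adjacency.tsv"), acfg))
      placed <- res[res$status == "placed", , drop = FALSE]
      bed <- data.frame(seq_name = placed$proj_seq, start = placed$proj_start,
                        end = pmax(placed$proj_end, placed$proj_start + 1L),
                        label = placed$label, strand = placed$orientation,
                        stringsAsFactors = FALSE)
      outs <- c(outs, write_bed(bed, p("placements.bed")))
      tab <- tabulate_figure_labels(adj$label, res$label)
      jsonlite::write_json(tab, p("summary.json"), dataframe = "rows",
                           auto_unbox = TRUE, na = "null")
      outs <- c(outs, p("summary.json"))
      rec <- repeat_recovery(draft_rep, ref_rep)
      outs <- c(outs, write_report_tsv(rec, p("repeat_recovery.tsv"), acfg))
    } else if (stage == "gc") {
      draft <- read_fasta(need("draft"))
      gw <- gc_windows(draft, acfg)
      outs <- write_report_tsv(gw$windows, p("gc_windows.tsv"), acfg)
    } else if (stage == "g4") {
      draft <- read_fasta(need("draft"))
      g4 <- find_g4_motifs(draft)
      g4$label <- "g4_canonical"
      outs <- write_bed(g4, p("g4_canonical.bed"))
    } else if (stage == "census") {
      draft <- read_fasta(need("draft"))
      qpath <- config$exon_queries %||% p("exons.faa")
      qs <- as.character(Biostrings::readAAStringSet(qpath))
      qlen_nt <- 3L * max(nchar(qs))
      qset <- exon_query_set("exons", qs, qlen_nt,
                             config$min_hit_len %||% as.integer(round(qlen_nt * 0.89)))
      cen <- exon_census(qset, draft)
      outs <- write_report_tsv(cen$per_scaffold, p("census.tsv"), acfg)
    } else if (stage == "genes") {
      draft <- read_fasta(need("draft"))
      gpath <- config$gene_models %||% p("genes.faa")
      gp <- gene_presence(as.character(Biostrings::readAAStringSet(gpath)),
                          draft, acfg)
      outs <- write_report_tsv(gp, p("genes.tsv"), acfg)
    } else if (stage == "sexlink") {
      cov <- read_coverage_table(config$depth_table %||% p("depth.tsv"))
      calls <- classify_sex_linkage(cov)
      outs <- write_report_tsv(calls, p("sexlink.tsv"), acfg)
      comp_path <- config$composition %||% p("composition.tsv")
      if (file.exists(comp_path)) {
        comp <- read.table(comp_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
        comp$call <- calls$call[match(comp$contig, calls$contig)]
        flagged <- flag_chimeric_scaffolds(comp)
        writeLines(flagged, p("chimeric_scaffolds.txt"))
        outs <- c(outs, p("chimeric_scaffolds.txt"))
      }
    }
    outs
  }

  for (stage in order) {
    deps <- defs[[stage]]
    if (length(deps) && any(status[deps] == "failed")) {
      status[stage] <- "halted"
      manifest$stages[[stage]] <- list(status = "halted")
      next
    }
    res <- tryCatch(
      list(ok = TRUE, outs = run_one(stage)),
      error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      status[stage] <- "done"
      digests <- as.list(tools::md5sum(res$outs))
      manifest$stages[[stage]] <- list(status = "done",
                                       outputs = unname(res$outs),
                                       digests = digests)
    } else {
      status[stage] <- "failed"
      manifest$stages[[stage]] <- list(status = "failed", error = res$msg)
      manifest$warnings <- c(manifest$warnings,
                             paste0(stage, ": ", res$msg))
    }
  }
  manifest$ok <- !any(status %in% c("failed", "halted"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
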