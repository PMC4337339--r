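# Pipeline orchestration: qc -> quantify -> dge -> enrich -> qpcr as one
# configured, seeded, logged run writing TSV artifacts.

#' Pipeline configuration
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed; all randomness flows from it.
#' @param comparisons Character vector "LIBA_vs_LIBB"; each side must be
#'   a declared library. Defaults to the six pairwise stage comparisons.
#' @param libraries Declared library ids (stages). Inputs referencing
#'   undeclared libraries fail validation before any computation.
#' @param fdr_method,fdr_cutoff,lfc_cutoff DEG-calling thresholds (see
#'   [dge_test()]).
#' @param pseudocount Pseudocount for the log2 ratio.
#' @param q_cutoff Enrichment Q-value threshold.
#' @param qc QC thresholds ([qc_thresholds()]).
#' @param reference_gene qPCR reference gene id.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            comparisons = c("FCP_vs_AP", "FCP_vs_SGP",
                                            "FCP_vs_BMP", "AP_vs_SGP",
                                            "AP_vs_BMP", "SGP_vs_BMP"),
                            libraries = c("FCP", "AP", "SGP", "BMP"),
                            fdr_method = "BY", fdr_cutoff = 0.001,
                            lfc_cutoff = 1, pseudocount = 1,
                            q_cutoff = 0.05,
                            qc = qc_thresholds(
                              adapter_sequences = default_adapter()),
                            reference_gene = "18S") {
  sides <- unlist(strsplit(comparisons, "_vs_", fixed = TRUE))
  undeclared <- setdiff(sides, libraries)
  if (length(undeclared))
    stop("comparison references undeclared library: ",
         paste(unique(undeclared), collapse = ", "), call. = FALSE)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 comparisons = comparisons, libraries = libraries,
                 fdr_method = fdr_method, fdr_cutoff = fdr_cutoff,
                 lfc_cutoff = lfc_cutoff, pseudocount = pseudocount,
                 q_cutoff = q_cutoff, qc = qc,
                 reference_gene = reference_gene),
            class = "pipeline_config")
}

# rolling polynomial hash (mod 2^31 - 1) of the deparsed config, for
# artifact headers; stability across runs matters, cryptography does not
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL  # analysis parameters only, not where they land
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

artifact_header <- function(config) {
  paste0("biofilmDGE ", as.character(utils::packageVersion("biofilmDGE")),
         " config=", config_hash(config), " seed=", config$seed)
}

#' Run the full synthetic biofilm pipeline
#'
#' Generates the synthetic scenario (counts, annotation, FASTQ fixture,
#' Ct tables) from the configured seed, then runs QC, RPKM
#' quantification, per-comparison differential expression, category
#' enrichment, and qPCR concordance, writing one TSV per artifact into
#' \code{config$outdir}. Every artifact carries a header comment with the
#' package version, config hash and seed; runs are deterministic given
#' the seed. Per-stage counts (reads removed, genes tested, DEGs called,
#' categories significant) are logged via \code{message}.
#'
#' @param config A [pipeline_config()].
#' @param n_qc_reads Size of the FASTQ fixture passed through QC.
#' @return Invisibly, a list with the in-memory artifacts: \code{qc_report},
#'   \code{rpkm}, \code{dge} (list per comparison), \code{enrichment}
#'   (list per comparison vs FCP), \code{concordance},
#'   \code{stage_summary} and \code{paths}.
#' @export
run_pipeline <- function(config, n_qc_reads = 2000) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- artifact_header(config)
  paths <- list()
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  say("pipeline start: seed=", config$seed, " outdir=", config$outdir)
  scen <- simulate_biofilm_scenario(seed = config$seed)

  # --- qc -----------------------------------------------------------------
  fq <- simulate_fastq(n_qc_reads,
                       contamination = c(adapter = 0.05, n_rich = 0.10,
                                         lowqual = 0.15),
                       seed = config$seed)
  qc_res <- filter_fastq(fq$reads, config$qc)
  paths$qc_report <- file.path(config$outdir, "qc_report.tsv")
  write_result_tsv(qc_res$report, paths$qc_report, header = hdr)
  say("qc: ", qc_res$report$input_reads, " reads in, ",
      qc_res$report$clean_reads, " clean (",
      qc_res$report$removed_adapter, " adapter, ",
      qc_res$report$removed_unknown, " unknown-base, ",
      qc_res$report$removed_lowqual, " low-quality removed)")

  # --- quantify -----------------------------------------------------------
  rpkm <- rpkm_matrix(scen$counts, scen$profiles)
  paths$rpkm <- file.path(config$outdir, "rpkm_matrix.tsv")
  write_result_tsv(rpkm, paths$rpkm, header = hdr)
  say("quantify: RPKM for ", nrow(rpkm), " genes x ",
      length(config$libraries), " libraries")

  # --- dge ----------------------------------------------------------------
  deg_tables <- list()
  for (cmp in config$comparisons) {
    sides <- strsplit(cmp, "_vs_", fixed = TRUE)[[1]]
    tbl <- dge_test(scen$counts, scen$profiles, sides[1], sides[2],
                    pseudocount = config$pseudocount,
                    fdr_method = config$fdr_method,
                    fdr_cutoff = config$fdr_cutoff,
                    lfc_cutoff = config$lfc_cutoff)
    deg_tables[[cmp]] <- tbl
    p <- file.path(config$outdir, paste0("dge_", cmp, ".tsv"))
    paths[[paste0("dge_", cmp)]] <- p
    write_result_tsv(tbl, p, header = hdr)
    say("dge ", cmp, ": ", nrow(tbl), " genes tested, ",
        sum(tbl$significant), " DEGs called")
  }
  stage_summary <- summarize_stage_counts(deg_tables)
  paths$stage_summary <- file.path(config$outdir, "stage_summary.tsv")
  write_result_tsv(stage_summary, paths$stage_summary, header = hdr)

  # --- enrich (comparisons against free cells) ----------------------------
  paths$annotation <- file.path(config$outdir, "annotation.gmt")
  write_gmt(scen$annotation, paths$annotation)
  paths$universe <- file.path(config$outdir, "annotation_universe.txt")
  writeLines(scen$annotation$universe, paths$universe)
  enr <- list()
  for (cmp in intersect(config$comparisons, names(scen$truth$enriched_categories))) {
    degs <- deg_tables[[cmp]]$gene_id[deg_tables[[cmp]]$significant]
    etbl <- enrich_categories(degs, scen$annotation,
                              q_cutoff = config$q_cutoff)
    enr[[cmp]] <- etbl
    p <- file.path(config$outdir, paste0("enrichment_", cmp, ".tsv"))
    paths[[paste0("enrichment_", cmp)]] <- p
    write_result_tsv(etbl, p, header = hdr)
    say("enrich ", cmp, ": ", nrow(etbl), " categories tested, ",
        sum(etbl$significant), " significant at Q <= ", config$q_cutoff)
  }

  # --- qpcr concordance ---------------------------------------------------
  panel <- c("Flo11", "Fbp1", "Pck1", "Hsp12", "Mig1", "Gut1")
  ct <- simulate_qpcr(scen$truth, panel, noise_sd = 0.1,
                      seed = config$seed,
                      reference_gene = config$reference_gene)
  paths$ct_table <- file.path(config$outdir, "qpcr_ct.tsv")
  write_result_tsv(ct, paths$ct_table, header = hdr)
  qfc <- qpcr_fold_changes(ct, reference_gene = config$reference_gene)
  ap <- deg_tables[["FCP_vs_AP"]]
  rnaseq_lfc <- setNames(ap$log2_ratio, ap$gene_id)[panel]
  conc <- concordance(rnaseq_lfc, setNames(qfc$log2_fold_change, qfc$gene_id))
  paths$concordance <- file.path(config$outdir, "qpcr_concordance.tsv")
  write_result_tsv(conc$table, paths$concordance, header = hdr)
  say("qpcr: Pearson r = ", formatC(conc$r, digits = 4, format = "f"),
      " over ", conc$n_genes, " genes")

  paths$log <- file.path(config$outdir, "run_log.txt")
  writeLines(c(paste0("# ", hdr), log_lines), paths$log)

  invisible(list(qc_report = qc_res$report, rpkm = rpkm, dge = deg_tables,
                 enrichment = enr, concordance = conc,
                 stage_summary = stage_summary, truth = scen$truth,
                 paths = paths))
}

#' Re-run the enrichment stage from cached DGE output
#'
#' Stage isolation: reads a written DGE table and annotation GMT and
#' reproduces the enrichment table that the full pipeline wrote.
#'
#' @param dge_path Path to a written per-comparison DGE table.
#' @param gmt_path Path to the annotation GMT.
#' @param universe Optional path to the written universe file (one gene
#'   id per line; the pipeline writes \code{annotation_universe.txt}), or
#'   a character vector of gene ids. Defaults to the GMT union.
#' @param q_cutoff Q-value threshold.
#' @return Enrichment table (see [enrich_categories()]).
#' @export
run_enrichment_stage <- function(dge_path, gmt_path, universe = NULL,
                                 q_cutoff = 0.05) {
  tbl <- read_result_tsv(dge_path)
  if (is.character(universe) && length(universe) == 1 && file.exists(universe))
    universe <- readLines(universe)
  annotation <- read_gmt(gmt_path, universe = universe)
  degs <- tbl$gene_id[tbl$significant]
  enrich_categories(degs, annotation, q_cutoff = q_cutoff)
}
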