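#' Build a pipeline configuration
#'
#' All knobs of the end-to-end run, with the method's standard defaults:
#' FDR 0.01 for both the gene filter and the overlap calls, raw p 0.05 for
#' pathway over-representation, FDR 0.01 and minimum size 400 for
#' informative GO terms, and a window grid from 100 to 10000 in steps of
#' 100.
#'
#' @param target_disease disease label used to match drug annotations.
#' @param cell_line cell line whose instances are used (e.g. MCF7 for
#'   breast, HL60 for leukemia, PC3 for prostate).
#' @param tissue_path,tissue_groups_path GDS-style tissue table (+ optional
#'   group sidecar).
#' @param cellline_path,cellline_groups_path untreated cell-line baseline.
#' @param rank_matrix_path,rank_annotation_path compound rank matrix and
#'   instance annotations.
#' @param drug_annotation_path drug annotation table.
#' @param gmt_path gene sets (GMT).
#' @param probe2gene_path optional two-column probe-to-gene TSV.
#' @param fdr_filter,fdr_overlap,pathway_alpha,go_fdr,go_min_size
#'   thresholds (see defaults above).
#' @param k_min,k_max,k_step window grid.
#' @param specificity_mode see [evaluate_k()].
#' @param seed integer seed (used only in simulate mode).
#' @param out_dir optional directory for TSV outputs and the summary.
#' @param simulate if TRUE, ignore paths and run on [simulate_world()].
#' @param sim optional list of [simulation_config()] overrides for
#'   simulate mode.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(target_disease = NULL, cell_line = NULL,
                            tissue_path = NULL, tissue_groups_path = NULL,
                            cellline_path = NULL,
                            cellline_groups_path = NULL,
                            rank_matrix_path = NULL,
                            rank_annotation_path = NULL,
                            drug_annotation_path = NULL, gmt_path = NULL,
                            probe2gene_path = NULL,
                            fdr_filter = 0.01, fdr_overlap = 0.01,
                            pathway_alpha = 0.05, go_fdr = 0.01,
                            go_min_size = 400, k_min = 100, k_max = 10000,
                            k_step = 100,
                            specificity_mode = "negatives_excluded",
                            seed = 1, out_dir = NULL, simulate = FALSE,
                            sim = NULL) {
  cfg <- as.list(environment())
  for (f in c("fdr_filter", "fdr_overlap", "pathway_alpha", "go_fdr")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("'", f, "' must lie in (0, 1)")
  }
  if (k_min > k_max || k_step < 1) stop("invalid window grid")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a DCF key-value file
#'
#' Plain `key: value` markup (Debian-control style, as used by R itself);
#' numeric fields are converted, everything else kept as character.
#'
#' @param path config file.
#' @return [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  d <- read.dcf(path)
  vals <- as.list(stats::setNames(as.vector(d[1L, ]), colnames(d)))
  num <- c("fdr_filter", "fdr_overlap", "pathway_alpha", "go_fdr",
           "go_min_size", "k_min", "k_max", "k_step", "seed")
  for (f in intersect(num, names(vals))) vals[[f]] <- as.numeric(vals[[f]])
  if ("simulate" %in% names(vals))
    vals$simulate <- vals$simulate %in% c("TRUE", "true", "1", "yes")
  do.call(pipeline_config, vals)
}

#' Run the full signature-reversal pipeline
#'
#' Composition of all stages in the method's order: probe collapsing and
#' reference normalization of both platforms, the cross-platform gene
#' filter, disease and compound ranking, the window-size scan and
#' selection per direction, the overlap tests and candidate merge at the
#' selected windows, and gene-set over-representation of the candidate
#' windows. Returns (and optionally writes) a report bundle with a
#' Table-style summary.
#'
#' @param config [pipeline_config()].
#' @param data optional pre-loaded inputs (as produced by
#'   [simulate_world()]): a list with `tissue`, `cellline`, `bank`,
#'   `annotations`, `genesets`, plus optional `probe2gene`. Overrides the
#'   config paths.
#' @return invisible list: `filter`, `disease_ranking`, `compound_lists`,
#'   `scan`, `selected` (per-direction k), `tests`, `candidates`,
#'   `overlap_genes`, `enrichment` (per direction), `pathway_matrix`,
#'   `summary`.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(data)) {
    if (isTRUE(config$simulate)) {
      sim_args <- config$sim %||% list()
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      data <- simulate_world(do.call(simulation_config, sim_args))
      config$target_disease <- config$target_disease %||%
        data$target_disease
      config$cell_line <- config$cell_line %||% data$cell_line
    } else {
      data <- list(
        tissue = read_gds(config$tissue_path, config$tissue_groups_path),
        cellline = read_gds(config$cellline_path,
                            config$cellline_groups_path),
        bank = read_rank_matrix(config$rank_matrix_path,
                                config$rank_annotation_path),
        annotations =
          if (!is.null(config$drug_annotation_path))
            read_drug_annotations(config$drug_annotation_path),
        genesets = if (!is.null(config$gmt_path)) read_gmt(config$gmt_path),
        probe2gene = if (!is.null(config$probe2gene_path)) {
          m <- utils::read.delim(config$probe2gene_path, header = FALSE,
                                 stringsAsFactors = FALSE)
          stats::setNames(m[[2L]], m[[1L]])
        }
      )
    }
  } else if (isTRUE(config$simulate) || !is.null(data$target_disease)) {
    config$target_disease <- config$target_disease %||% data$target_disease
    config$cell_line <- config$cell_line %||% data$cell_line
  }
  p2g <- data$probe2gene

  tissue <- data$tissue
  cellline <- data$cellline
  if (!is.null(p2g)) {
    tissue <- collapse_probes(tissue, p2g)
    cellline <- collapse_probes(cellline, p2g)
  }
  tissue <- normalize_expression(impute_missing(tissue),
                                 reference = "normal")
  cellline <- normalize_expression(impute_missing(cellline),
                                   reference = "untreated_control")

  flt <- filter_common_genes(cellline, tissue,
                             fdr_threshold = config$fdr_filter)
  bank_genes <- if (is.null(p2g)) rownames(data$bank$ranks)
                else unique(p2g[rownames(data$bank$ranks)])
  retained <- intersect(flt$retained, bank_genes)
  if (!length(retained)) stop("no retained genes covered by the rank matrix")

  disease <- rank_disease(tissue, retained)
  compounds <- rank_compound_bank(data$bank, config$cell_line, retained,
                                  probe2gene = p2g)
  if (!length(compounds))
    stop("no compounds with instances in cell line '",
         config$cell_line, "'")

  grid <- seq(config$k_min, config$k_max, by = config$k_step)
  scan <- scan_windows(disease, compounds, data$annotations,
                       config$target_disease, grid = grid,
                       fdr = config$fdr_overlap,
                       specificity_mode = config$specificity_mode)
  k_ucdb <- select_window(scan, "UC_DB")
  k_dcub <- select_window(scan, "DC_UB")

  tests <- test_all_compounds(disease, compounds, k_ucdb, k_dcub,
                              fdr = config$fdr_overlap)
  candidates <- merge_candidates(tests, data$annotations,
                                 config$target_disease)
  ov_genes <- candidate_overlap_genes(disease, compounds, tests)

  enr <- list()
  pw_matrix <- NULL
  if (!is.null(data$genesets) && length(ov_genes)) {
    sig <- tests[tests$significant, , drop = FALSE]
    for (d in c("UC_DB", "DC_UB")) {
      q <- unique(unlist(ov_genes[sig$compound[sig$direction == d]]))
      if (length(q))
        enr[[d]] <- enrich(q, data$genesets, disease$gene_ids,
                           mode = "pathway", alpha = config$pathway_alpha)
    }
    pw_matrix <- compound_pathway_matrix(ov_genes, data$genesets,
                                         disease$gene_ids,
                                         alpha = config$pathway_alpha)
  }

  smry <- attr(candidates, "summary")
  positives <- intersect(
    annotation_positives(data$annotations, config$target_disease),
    names(compounds))
  summary_rows <- c(
    "Total compounds in CMAP" = length(names(compounds)),
    "Compounds that are FDA drugs" =
      sum(data$annotations$fda_approved[
        data$annotations$compound %in% names(compounds)]),
    "FDA drug in CMAP for target disease" = length(positives),
    "Optimized parameter size (UC/DB)" = as.integer(k_ucdb),
    "Optimized parameter size (DC/UB)" = as.integer(k_dcub),
    "Total Predictions (UC/DB)" = smry$n_uc_db,
    "Total Predictions (DC/UB)" = smry$n_dc_ub,
    "Distinct compounds" = smry$n_distinct,
    "Compounds showing duality" = smry$n_duality,
    "Predictions that are FDA drugs" = smry$n_fda,
    "Predicted FDA drugs for target disease" = length(smry$recovered)
  )

  bundle <- list(filter = flt$report, disease_ranking = disease,
                 compound_lists = compounds, scan = scan,
                 selected = c(UC_DB = as.integer(k_ucdb),
                              DC_UB = as.integer(k_dcub)),
                 tests = tests, candidates = candidates,
                 overlap_genes = ov_genes, enrichment = enr,
                 pathway_matrix = pw_matrix, summary = summary_rows)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_filter_report(flt$report, o("filter_report.tsv"))
    write_ranked_list(disease, o("disease_ranking.tsv"))
    write_scan_trace(scan, o("scan_trace.tsv"))
    utils::write.table(as.data.frame(tests), o("overlap_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(candidates), o("candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (d in names(enr))
      write_enrichment(enr[[d]], o(sprintf("enrichment_%s.tsv", d)))
    writeLines(paste(names(summary_rows), summary_rows, sep = "\t"),
               o("summary.txt"))
  }
  invisible(bundle)
}

#' Command-line entry point
#'
#' Usage: `Rscript -e 'sigreverse::sigreverse_main()' --config=cfg.dcf
#' [--out=dir]`. Parses `--key=value` arguments, reads the DCF config and
#' runs [run_pipeline()].
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status 0 on success (invisibly).
#' @export
sigreverse_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  kv <- strsplit(sub("^--", "", args[grepl("^--", args)]), "=", fixed = TRUE)
  opts <- stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  if (is.null(opts["config"]) || is.na(opts["config"]))
    stop("usage: --config=<dcf file> [--out=<dir>]")
  config <- read_pipeline_config(opts[["config"]])
  if (!is.na(opts["out"])) config$out_dir <- opts[["out"]]
  run_pipeline(config)
  invisible(0L)
}
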