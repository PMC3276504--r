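#' Evaluate one window size against the known-drug annotation
#'
#' Runs the overlap tests at window `k` (both directions) and scores the
#' calls against the annotation: sensitivity is the fraction of known
#' positives (compounds FDA-approved for the target disease and present in
#' the bank) identified; specificity is computed on the failed-trial
#' negative class (see `specificity_mode`).
#'
#' @param disease RankedList of the disease signature.
#' @param compounds named list of compound RankedLists.
#' @param k window size applied to both directions.
#' @param annotations [drug_annotations()] table.
#' @param target_disease disease label identifying positives/negatives.
#' @param fdr overlap-test FDR threshold (default 0.01).
#' @param specificity_mode `"negatives_excluded"` (default): fraction of
#'   failed-trial negatives NOT identified, `|neg \ identified| / |neg|`;
#'   `"identified_fraction"`: 1 minus the failed fraction among identified
#'   compounds (the literal alternative reading). With zero negatives both
#'   modes return 1 (vacuous).
#' @return one-row-per-direction data.frame: `k`, `direction`,
#'   `n_significant`, `sensitivity`, `specificity`, `n_duality`,
#'   `recovered` (list column of recovered positives).
#' @export
evaluate_k <- function(disease, compounds, k, annotations, target_disease,
                       fdr = 0.01,
                       specificity_mode = c("negatives_excluded",
                                            "identified_fraction")) {
  specificity_mode <- match.arg(specificity_mode)
  bank <- names(compounds)
  positives <- intersect(annotation_positives(annotations, target_disease),
                         bank)
  if (!length(positives))
    stop("no known positives: supply annotations with at least one ",
         "compound FDA-approved for '", target_disease,
         "' that is present in the compound bank")
  negatives <- intersect(annotation_negatives(annotations, target_disease),
                         bank)
  tests <- test_all_compounds(disease, compounds, k, k, fdr = fdr)
  sig <- tests[tests$significant, , drop = FALSE]
  dual <- intersect(sig$compound[sig$direction == "UC_DB"],
                    sig$compound[sig$direction == "DC_UB"])
  per_dir <- lapply(c("UC_DB", "DC_UB"), function(d) {
    identified <- sig$compound[sig$direction == d]
    sens <- length(intersect(identified, positives)) / length(positives)
    spec <- if (!length(negatives)) 1 else switch(
      specificity_mode,
      negatives_excluded =
        length(setdiff(negatives, identified)) / length(negatives),
      identified_fraction =
        if (!length(identified)) 1
        else 1 - length(intersect(identified, negatives)) / length(identified)
    )
    data.frame(k = k, direction = d, n_significant = length(identified),
               sensitivity = sens, specificity = spec,
               n_duality = length(dual),
               recovered = I(list(intersect(identified, positives))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_dir)
}

#' Scan the window-size grid
#'
#' Evaluates [evaluate_k()] over a grid of window sizes (by default 100 to
#' 10000 in steps of 100, truncated to `floor(N/2)` so the two windows of a
#' list can never overlap).
#'
#' @inheritParams evaluate_k
#' @param grid integer vector of window sizes; default
#'   `seq(100, 10000, by = 100)` intersected with the feasible range.
#' @return data.frame of class `ScanResult` (rows = k x direction) with
#'   attributes `grid`, `fdr`, `specificity_mode`, `target_disease`.
#' @export
scan_windows <- function(disease, compounds, annotations, target_disease,
                         grid = NULL, fdr = 0.01,
                         specificity_mode = "negatives_excluded") {
  n <- length(disease$gene_ids)
  grid <- as.integer(grid %||% seq(100L, 10000L, by = 100L))
  grid <- sort(unique(grid[grid >= 1L & grid <= n %/% 2L]))
  if (!length(grid)) stop("empty window grid for a list of ", n, " genes")
  rows <- lapply(grid, function(k)
    evaluate_k(disease, compounds, k, annotations, target_disease,
               fdr = fdr, specificity_mode = specificity_mode))
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "fdr") <- fdr
  attr(out, "specificity_mode") <- specificity_mode
  attr(out, "target_disease") <- target_disease
  class(out) <- c("ScanResult", "data.frame")
  out
}

#' Select the operating window size for one direction
#'
#' Among window sizes satisfying the feasibility constraints -- nonzero
#' sensitivity (at least one known drug recovered), nonzero duality, and at
#' least one FDR-controlled discovery -- returns the k with maximum
#' specificity; ties are broken by the smallest k. Selection is a pure
#' function of the scan trace.
#'
#' @param scan ScanResult from [scan_windows()].
#' @param direction `"UC_DB"` or `"DC_UB"`.
#' @return selected k (integer) with attribute `"rationale"`, the feasible
#'   subset of the trace.
#' @export
select_window <- function(scan, direction = c("UC_DB", "DC_UB")) {
  direction <- match.arg(direction)
  tr <- scan[scan$direction == direction, , drop = FALSE]
  feasible <- tr$sensitivity > 0 & tr$n_duality > 0 & tr$n_significant > 0
  if (!any(feasible)) {
    stop("no feasible window for ", direction, ": of ", nrow(tr),
         " k values, ", sum(tr$sensitivity > 0), " have sensitivity > 0, ",
         sum(tr$n_duality > 0), " have duality > 0, ",
         sum(tr$n_significant > 0), " have FDR discoveries")
  }
  fe <- tr[feasible, , drop = FALSE]
  fe <- fe[order(-fe$specificity, fe$k), , drop = FALSE]
  structure(as.integer(fe$k[1L]), rationale = fe)
}

#' Write a scan trace as TSV
#' @param scan ScanResult.
#' @param path output path.
#' @export
write_scan_trace <- function(scan, path) {
  out <- as.data.frame(scan)
  out$recovered <- vapply(out$recovered, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
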