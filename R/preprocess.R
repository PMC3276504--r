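#' Impute missing values as the row median within each sample group
#'
#' Sporadic `NA`s (e.g. non-numeric entries in a GDS table) are replaced by
#' the gene's median within the sample's group; if a whole group is missing
#' for a gene, the gene's overall median is used.
#'
#' @param em ExpressionMatrix.
#' @return ExpressionMatrix without `NA`s.
#' @export
impute_missing <- function(em) {
  v <- em$values
  if (!anyNA(v)) return(em)
  for (g in unique(em$groups)) {
    cols <- which(em$groups == g)
    sub <- v[, cols, drop = FALSE]
    na <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na)) {
      med <- apply(sub, 1L, stats::median, na.rm = TRUE)
      sub[na] <- med[na[, 1L]]
      v[, cols] <- sub
    }
  }
  if (anyNA(v)) {
    med <- apply(v, 1L, stats::median, na.rm = TRUE)
    na <- which(is.na(v), arr.ind = TRUE)
    v[na] <- med[na[, 1L]]
  }
  expression_matrix(v, em$groups, em$dataset_id)
}

#' Normalize each gene by its reference-sample mean and SD
#'
#' Puts the cell-line and tissue platforms on a comparable per-gene scale:
#' every row is centered and scaled by the mean and standard deviation of
#' that dataset's reference samples -- `untreated_control` for a cell-line
#' matrix, `normal` for a tissue matrix. Rows whose reference variance is
#' zero are scaled by the dataset-wide median of the positive reference SDs
#' instead.
#'
#' @param em ExpressionMatrix (>= 2 samples).
#' @param reference reference group label; default picks
#'   `"untreated_control"` when present, else `"normal"`.
#' @return normalized ExpressionMatrix.
#' @export
normalize_expression <- function(em, reference = NULL) {
  if (ncol(em$values) < 2L) stop("need at least 2 samples")
  if (is.null(reference)) {
    reference <- if ("untreated_control" %in% em$groups)
      "untreated_control" else "normal"
  }
  ref <- em_samples(em, reference)
  if (!length(ref))
    stop("no reference samples with group '", reference, "'")
  r <- em$values[, ref, drop = FALSE]
  mu <- rowMeans(r)
  sd <- if (length(ref) > 1L)
    sqrt(rowSums((r - mu)^2) / (length(ref) - 1L))
  else rep(0, nrow(r))
  fallback <- stats::median(sd[sd > 0])
  if (!is.finite(fallback) || fallback == 0) fallback <- 1
  zero <- sd == 0
  if (any(zero)) {
    message("normalize_expression: ", sum(zero),
            " zero-variance reference row(s) scaled by median SD")
    sd[zero] <- fallback
  }
  expression_matrix((em$values - mu) / sd, em$groups, em$dataset_id)
}

#' Collapse probe rows to gene symbols
#'
#' Keeps, for each gene, the probe with the highest mean expression across
#' all samples; unmapped probes are dropped (count reported).
#'
#' @param em ExpressionMatrix keyed by probe id.
#' @param probe2gene named character vector, probe id -> gene symbol.
#' @return ExpressionMatrix keyed by gene symbol.
#' @export
collapse_probes <- function(em, probe2gene) {
  probes <- intersect(rownames(em$values), names(probe2gene))
  dropped <- nrow(em$values) - length(probes)
  if (!length(probes)) stop("no probes map to genes")
  if (dropped > 0)
    message("collapse_probes: dropping ", dropped, " unmapped probe(s)")
  v <- em$values[probes, , drop = FALSE]
  gene <- probe2gene[probes]
  means <- rowMeans(v)
  # per gene keep the probe with max mean; ties resolved by probe id order
  ord <- order(gene, -means, probes)
  keep <- ord[!duplicated(gene[ord])]
  v <- v[keep, , drop = FALSE]
  rownames(v) <- unname(gene[keep])
  expression_matrix(v, em$groups, em$dataset_id)
}

#' Remove genes expressed differently between untreated cell line and
#' disease tissue
#'
#' The gene filter that makes the two platforms comparable: genes whose
#' normalized expression differs between the untreated cell-line samples
#' and the disease tissue samples are removed. Per intersecting gene a
#' two-sided Welch t-test is computed, p-values are Benjamini-Hochberg
#' corrected across genes, and genes with `q < fdr_threshold` are removed.
#'
#' @param cellline normalized, probe-collapsed ExpressionMatrix containing
#'   `untreated_control` samples.
#' @param tissue normalized, probe-collapsed ExpressionMatrix containing
#'   `disease` samples.
#' @param fdr_threshold FDR below which a gene is considered differently
#'   expressed (default 0.01).
#' @return list with `retained` (character vector of retained gene ids) and
#'   `report`, a `FilterReport` data.frame (gene, t, p, q, removed) whose
#'   attributes carry the counts (`n_input`, `n_retained`,
#'   `fraction_retained`).
#' @export
filter_common_genes <- function(cellline, tissue, fdr_threshold = 0.01) {
  common <- intersect(rownames(cellline$values), rownames(tissue$values))
  if (!length(common)) stop("no genes shared between the two matrices")
  x <- cellline$values[common, em_samples(cellline, "untreated_control"),
                       drop = FALSE]
  y <- tissue$values[common, em_samples(tissue, "disease"), drop = FALSE]
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("need >=2 untreated_control and >=2 disease samples")
  tt <- .row_welch_t(x, y)
  q <- bh_adjust(tt$p)
  removed <- q < fdr_threshold
  report <- data.frame(gene = common, t = tt$t, p = tt$p, q = q,
                       removed = removed, stringsAsFactors = FALSE,
                       row.names = NULL)
  attr(report, "n_input") <- length(common)
  attr(report, "n_retained") <- sum(!removed)
  attr(report, "fraction_retained") <- mean(!removed)
  class(report) <- c("FilterReport", "data.frame")
  message("filter_common_genes: retained ", sum(!removed), " of ",
          length(common), " genes (",
          round(100 * mean(!removed)), "%) at FDR ", fdr_threshold)
  list(retained = common[!removed], report = report)
}

#' Write a FilterReport as TSV
#' @param report FilterReport.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
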