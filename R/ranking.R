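#' Construct a ranked gene list from signed scores
#'
#' The total ordering both halves of the method consume: index 1 is the
#' most up-regulated gene, the tail the most down-regulated. Ordering is
#' non-increasing in score with ties broken by ascending gene id, so runs
#' are bit-reproducible.
#'
#' @param scores named numeric vector, gene id -> signed score (e.g. a
#'   t-statistic, or minus a mean perturbation rank).
#' @return object of class `RankedList`: list with `gene_ids` (ordered) and
#'   `scores` (aligned with `gene_ids`).
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene id")
  if (anyNA(scores)) stop("scores contain NA")
  ord <- order(-scores, names(scores), method = "radix")
  structure(list(gene_ids = names(scores)[ord],
                 scores = unname(scores)[ord]),
            class = "RankedList")
}

#' @export
print.RankedList <- function(x, ...) {
  n <- length(x$gene_ids)
  cat("RankedList of", n, "genes; top:",
      paste(utils::head(x$gene_ids, 3L), collapse = ", "),
      "... bottom:", paste(utils::tail(x$gene_ids, 3L), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
length.RankedList <- function(x) length(x$gene_ids)

#' Rank disease genes by differential expression (disease vs normal)
#'
#' Per retained gene a Welch t-statistic (disease minus normal) on the
#' tissue matrix; genes sorted descending so the top of the list is the
#' most up-regulated in disease. Zero-variance genes are scored with a
#' variance floor (smallest positive per-gene pooled variance observed).
#'
#' @param tissue ExpressionMatrix with `normal` and `disease` samples.
#' @param retained gene ids to rank (default: all genes in `tissue`).
#' @return RankedList with t-statistics as scores.
#' @export
rank_disease <- function(tissue, retained = NULL) {
  genes <- retained %||% rownames(tissue$values)
  genes <- intersect(genes, rownames(tissue$values))
  if (!length(genes)) stop("no retained genes present in tissue matrix")
  x <- tissue$values[genes, em_samples(tissue, "disease"), drop = FALSE]
  y <- tissue$values[genes, em_samples(tissue, "normal"), drop = FALSE]
  v <- c(apply(x, 1L, stats::var), apply(y, 1L, stats::var))
  floor <- suppressWarnings(min(v[v > 0]))
  if (!is.finite(floor)) floor <- 1
  tt <- .row_welch_t(x, y, var_floor = floor)
  ranked_list(stats::setNames(tt$t, genes))
}

#' Rank genes by a compound's perturbation
#'
#' Collapses probe ranks to genes (best = minimum rank per gene), averages
#' across the compound's instances in the given cell line, restricts to the
#' retained universe and re-ranks. The top of the list is the gene most
#' up-regulated by the compound.
#'
#' @param rm InstanceRankMatrix.
#' @param compound compound name (canonicalized internally).
#' @param cell_line cell line the disease is matched to.
#' @param retained gene ids forming the analysis universe.
#' @param probe2gene optional named character vector probe -> gene; `NULL`
#'   means probe ids already are gene ids.
#' @return RankedList (scores = minus the mean collapsed rank), or `NULL`
#'   with a message when the compound has no instance in the cell line.
#' @export
rank_compound <- function(rm, compound, cell_line, retained,
                          probe2gene = NULL) {
  compound <- .trim_lower(compound)
  sel <- rm$annotations$compound_name == compound &
    rm$annotations$cell_line == cell_line
  if (!any(sel)) {
    message("rank_compound: no instance of '", compound, "' in ",
            cell_line, "; skipped")
    return(NULL)
  }
  inst <- rm$annotations$instance_id[sel]
  r <- rm$ranks[, inst, drop = FALSE]
  gene <- if (is.null(probe2gene)) rownames(r) else probe2gene[rownames(r)]
  keep <- !is.na(gene)
  r <- r[keep, , drop = FALSE]
  gene <- gene[keep]
  # best (minimum) probe rank per gene, per instance, then instance mean
  if (anyDuplicated(gene)) {
    collapsed <- do.call(cbind, lapply(seq_len(ncol(r)), function(j) {
      tapply(r[, j], gene, min)
    }))
    mean_rank <- rowMeans(collapsed)
  } else {
    mean_rank <- stats::setNames(rowMeans(r), gene)
  }
  mean_rank <- mean_rank[names(mean_rank) %in% retained]
  if (!length(mean_rank)) stop("no retained genes covered by rank matrix")
  ranked_list(-mean_rank)
}

#' Rank every compound available in a cell line
#'
#' @inheritParams rank_compound
#' @return named list of RankedList, one per compound with at least one
#'   instance in `cell_line`; compounds without instances are skipped.
#' @export
rank_compound_bank <- function(rm, cell_line, retained, probe2gene = NULL) {
  ann <- rm$annotations[rm$annotations$cell_line == cell_line, , drop = FALSE]
  compounds <- sort(unique(ann$compound_name))
  skipped <- setdiff(unique(rm$annotations$compound_name), compounds)
  if (length(skipped))
    message("rank_compound_bank: ", length(skipped),
            " compound(s) have no instance in ", cell_line)
  out <- lapply(compounds, function(cp)
    rank_compound(rm, cp, cell_line, retained, probe2gene))
  stats::setNames(out, compounds)
}

#' Slice the top-k and bottom-k windows of a ranked list
#'
#' @param rl RankedList.
#' @param k window size; must satisfy `1 <= k <= floor(n/2)` so the two
#'   windows cannot overlap.
#' @return list with `top` and `bottom` character vectors of length `k`.
#' @export
slice_ranked <- function(rl, k) {
  n <- length(rl$gene_ids)
  k <- .assert_scalar_count(k, "k")
  if (k < 1L || k > n %/% 2L)
    stop("k = ", k, " out of range [1, ", n %/% 2L, "] for a list of ",
         n, " genes")
  list(top = rl$gene_ids[seq_len(k)],
       bottom = rl$gene_ids[seq.int(n - k + 1L, n)])
}

#' Write a RankedList as TSV (rank, gene, score)
#' @param rl RankedList.
#' @param path output path.
#' @export
write_ranked_list <- function(rl, path) {
  utils::write.table(
    data.frame(rank = seq_along(rl$gene_ids), gene = rl$gene_ids,
               score = rl$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
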