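#' Gene-set over-representation of a query gene set
#'
#' Hypergeometric upper-tail over-representation of `query` in each set of
#' the collection, against the retained-gene `universe`. Two reporting
#' modes mirror how pathway and GO results are filtered: `"pathway"` keeps
#' sets with raw `p < alpha` (no multiplicity correction); `"go"` keeps
#' "informative" terms, i.e. BH `q < fdr` AND more than `min_size` member
#' genes within the universe.
#'
#' @param query character vector of query genes; must be a subset of
#'   `universe` and non-empty.
#' @param collection [gene_set_collection()]; members are intersected with
#'   the universe.
#' @param universe character vector: the background gene universe.
#' @param mode `"pathway"` or `"go"`.
#' @param alpha raw p-value cut for pathway mode (default 0.05).
#' @param fdr BH q cut for GO mode (default 0.01).
#' @param min_size informative-term size threshold for GO mode (default
#'   400, counted within the universe).
#' @param filter if `FALSE`, return all sets with a `selected` flag instead
#'   of only the selected ones.
#' @return data.frame of class `EnrichmentResult`: `set_id`, `name`,
#'   `n_hits`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `q_value` (NA in pathway mode), `selected`.
#' @export
enrich <- function(query, collection, universe,
                   mode = c("pathway", "go"), alpha = 0.05, fdr = 0.01,
                   min_size = 400, filter = TRUE) {
  mode <- match.arg(mode)
  query <- unique(query)
  if (!length(query)) stop("empty query gene set")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  N <- length(unique(universe))
  n <- length(query)
  members <- lapply(collection$sets, intersect, unique(universe))
  K <- lengths(members)
  hits <- vapply(members, function(m) sum(query %in% m), numeric(1))
  p <- stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(
    set_id = names(collection$sets),
    name = unname(collection$descriptions[names(collection$sets)]),
    n_hits = as.integer(hits), set_size = as.integer(K),
    query_size = n, universe_size = N,
    p_value = p, q_value = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (mode == "go") {
    res$q_value <- bh_adjust(res$p_value)
    res$selected <- res$q_value < fdr & res$set_size > min_size
  } else {
    res$selected <- res$p_value < alpha
  }
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  if (filter) res[res$selected, , drop = FALSE] else res
}

#' Compound-by-pathway perturbation matrix
#'
#' For each identified compound, tests its overlap-gene set against every
#' pathway; a pathway counts as perturbed by the compound when the
#' hypergeometric p-value is below `alpha`. The per-pathway percentage of
#' compounds (the summary plotted in pathway-perturbation figures) is
#' attached as attribute `"percent"`.
#'
#' @param overlap_sets named list compound -> overlap gene set, e.g. from
#'   [candidate_overlap_genes()].
#' @param collection [gene_set_collection()].
#' @param universe background gene universe.
#' @param alpha per-compound pathway p cut (default 0.05).
#' @return logical matrix, compounds x pathways.
#' @export
compound_pathway_matrix <- function(overlap_sets, collection, universe,
                                    alpha = 0.05) {
  if (!length(overlap_sets)) stop("no compound overlap sets supplied")
  rows <- lapply(overlap_sets, function(genes) {
    res <- enrich(genes, collection, universe, mode = "pathway",
                  alpha = alpha, filter = FALSE)
    stats::setNames(res$p_value < alpha, res$set_id)
  })
  sets <- names(collection$sets)
  m <- do.call(rbind, lapply(rows, `[`, sets))
  dimnames(m) <- list(names(overlap_sets), sets)
  attr(m, "percent") <- 100 * colMeans(m)
  m
}

#' Write an enrichment table as TSV
#' @param res EnrichmentResult.
#' @param path output path.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
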