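#' One-sided overlap p-value for two size-k windows
#'
#' Probability that two sets of `k` genes, drawn at random from a
#' background of `N` genes, share at least `x` members:
#' `P(X >= x)` for `X ~ Hypergeometric(N, k, k)`. Equivalent to a one-sided
#' Fisher's exact test on the 2x2 table `[[x, k-x], [k-x, N-2k+x]]`.
#'
#' @param x observed overlap count(s), `0 <= x <= k` (vectorized).
#' @param k window size.
#' @param N background (retained common-gene universe) size; `2k <= N`.
#' @return upper-tail probability in (0, 1].
#' @export
overlap_pvalue <- function(x, k, N) {
  k <- .assert_scalar_count(k, "k")
  N <- .assert_scalar_count(N, "N")
  if (k < 1L) stop("k must be >= 1")
  if (2L * k > N) stop("2k = ", 2L * k, " exceeds background N = ", N)
  if (any(x < 0 | x > k)) stop("overlap x must lie in [0, k]")
  p <- stats::phyper(x - 1, k, N - k, k, lower.tail = FALSE)
  # extreme overlaps underflow double precision; keep p in (0, 1]
  pmax(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  s <- order(p, method = "radix")
  q <- rev(cummin(rev(p[s] * m / seq_len(m))))
  out <- numeric(m)
  out[s] <- pmin(q, 1)
  out
}

#' Test every compound's windowed overlap against the disease signature
#'
#' For each compound two one-sided tests are run: the disease's top-k
#' (up-in-cancer, UC) against the compound's bottom-k (down-by-compound,
#' DB), and the disease's bottom-k (DC) against the compound's top-k (UB).
#' A large UC/DB or DC/UB overlap means the compound pushes
#' disease-perturbed genes back toward normal. BH correction is applied
#' separately within each direction, across compounds.
#'
#' @param disease RankedList of the disease signature.
#' @param compounds named list of compound RankedLists over the same gene
#'   universe (hard error otherwise).
#' @param k_ucdb,k_dcub window sizes for the two directions.
#' @param fdr significance threshold on the BH q-value (default 0.01).
#' @return data.frame of class `OverlapTests` with columns `compound`,
#'   `direction` ("UC_DB"/"DC_UB"), `k`, `overlap`, `background`,
#'   `p_value`, `q_value`, `significant`.
#' @export
test_all_compounds <- function(disease, compounds, k_ucdb, k_dcub,
                               fdr = 0.01) {
  if (!length(compounds)) stop("no compound lists supplied")
  k_ucdb <- .assert_scalar_count(k_ucdb, "k_ucdb")
  k_dcub <- .assert_scalar_count(k_dcub, "k_dcub")
  n <- length(disease$gene_ids)
  for (nm in names(compounds)) {
    cl <- compounds[[nm]]
    if (length(cl$gene_ids) != n ||
        !setequal(cl$gene_ids, disease$gene_ids))
      stop("compound '", nm, "' is ranked over a different gene universe")
  }
  one_direction <- function(k, disease_end, compound_end) {
    dw <- slice_ranked(disease, k)[[disease_end]]
    x <- vapply(compounds, function(cl) {
      cw <- slice_ranked(cl, k)[[compound_end]]
      sum(dw %in% cw)
    }, numeric(1))
    p <- overlap_pvalue(x, k, n)
    data.frame(compound = names(compounds), k = k, overlap = as.integer(x),
               background = n, p_value = p, q_value = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  ucdb <- cbind(direction = "UC_DB",
                one_direction(k_ucdb, "top", "bottom"))
  dcub <- cbind(direction = "DC_UB",
                one_direction(k_dcub, "bottom", "top"))
  out <- rbind(ucdb, dcub)[, c("compound", "direction", "k", "overlap",
                               "background", "p_value", "q_value")]
  out$significant <- out$q_value < fdr
  attr(out, "fdr") <- fdr
  class(out) <- c("OverlapTests", "data.frame")
  out
}

#' Merge per-direction overlap calls into a candidate table
#'
#' Union of compounds significant in either direction, with duality flags
#' (significant in both) and, when annotations are supplied, FDA status and
#' indication matches for the target disease. Compounds significant in
#' neither direction are excluded.
#'
#' @param tests OverlapTests from [test_all_compounds()].
#' @param annotations optional [drug_annotations()] table.
#' @param target_disease optional disease label used to flag recovered
#'   in-use drugs and failed-trial compounds.
#' @return data.frame of class `CandidateTable`; attribute `"summary"`
#'   holds the per-direction totals, distinct and duality counts, the FDA
#'   subset and recovered drugs.
#' @export
merge_candidates <- function(tests, annotations = NULL,
                             target_disease = NULL) {
  sig <- tests[tests$significant, , drop = FALSE]
  ucdb <- sig$compound[sig$direction == "UC_DB"]
  dcub <- sig$compound[sig$direction == "DC_UB"]
  all_cp <- sort(union(ucdb, dcub))
  best_q <- vapply(all_cp, function(cp)
    min(sig$q_value[sig$compound == cp]), numeric(1))
  tab <- data.frame(
    compound = all_cp,
    significant_uc_db = all_cp %in% ucdb,
    significant_dc_ub = all_cp %in% dcub,
    duality = all_cp %in% intersect(ucdb, dcub),
    best_q = unname(best_q),
    stringsAsFactors = FALSE, row.names = NULL
  )
  recovered <- character(0)
  if (!is.null(annotations)) {
    i <- match(tab$compound, annotations$compound)
    tab$fda_approved <- annotations$fda_approved[i]
    if (!is.null(target_disease)) {
      tab$approved_for_target <- tab$compound %in%
        annotation_positives(annotations, target_disease)
      tab$failed_for_target <- tab$compound %in%
        annotation_negatives(annotations, target_disease)
      recovered <- tab$compound[tab$approved_for_target %in% TRUE]
    }
  }
  attr(tab, "summary") <- list(
    n_uc_db = length(ucdb), n_dc_ub = length(dcub),
    n_distinct = nrow(tab), n_duality = sum(tab$duality),
    n_fda = if (!is.null(annotations)) sum(tab$fda_approved %in% TRUE)
            else NA_integer_,
    recovered = recovered
  )
  class(tab) <- c("CandidateTable", "data.frame")
  tab
}

#' Per-candidate overlapping gene sets at the tested windows
#'
#' For every significant (compound, direction) call, the genes shared by
#' the two windows -- the genes the compound is predicted to push back
#' toward normal. Per compound the union over its significant directions is
#' returned; these sets feed the over-representation analysis.
#'
#' @inheritParams merge_candidates
#' @param disease,compounds the ranked lists the tests were computed from.
#' @return named list, compound -> character vector of overlap genes.
#' @export
candidate_overlap_genes <- function(disease, compounds, tests) {
  sig <- tests[tests$significant, , drop = FALSE]
  if (!nrow(sig)) return(list())
  out <- list()
  for (i in seq_len(nrow(sig))) {
    cp <- sig$compound[i]
    k <- sig$k[i]
    genes <- if (sig$direction[i] == "UC_DB") {
      intersect(slice_ranked(disease, k)$top,
                slice_ranked(compounds[[cp]], k)$bottom)
    } else {
      intersect(slice_ranked(disease, k)$bottom,
                slice_ranked(compounds[[cp]], k)$top)
    }
    out[[cp]] <- union(out[[cp]] %||% character(0), genes)
  }
  out
}
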