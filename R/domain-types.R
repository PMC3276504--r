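#' Sample group labels understood by the pipeline
#'
#' Every sample in an expression matrix carries one of these labels:
#' `"normal"` and `"disease"` for tissue cohorts, `"untreated_control"` and
#' `"treated"` for cell-line instances.
#'
#' @export
SAMPLE_GROUPS <- c("normal", "disease", "untreated_control", "treated")

#' Construct an expression matrix with sample group labels
#'
#' The container used for both disease tissue profiles and untreated
#' cell-line baselines: a genes x samples numeric matrix together with a
#' group label per sample. Values are taken as provided (log-scale assumed
#' but not enforced).
#'
#' @param values numeric matrix, genes in rows (rownames = gene/probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups named character vector mapping every sample id to one of
#'   [SAMPLE_GROUPS].
#' @param dataset_id optional dataset accession (e.g. a GDS id) carried as
#'   metadata.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `groups`, `dataset_id`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, c(s1 = "normal", s2 = "normal", s3 = "disease"))
#' @export
expression_matrix <- function(values, groups, dataset_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (gene) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- !groups %in% SAMPLE_GROUPS
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(groups[bad]), collapse = ", "),
         " (allowed: ", paste(SAMPLE_GROUPS, collapse = ", "), ")")
  structure(list(values = values, groups = groups, dataset_id = dataset_id),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$dataset_id)) cat("  dataset:", x$dataset_id, "\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix to a set of genes and/or samples
#' @param em ExpressionMatrix.
#' @param genes,samples character vectors of ids to keep (NULL = keep all).
#' @export
em_subset <- function(em, genes = NULL, samples = NULL) {
  v <- em$values
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  if (!is.null(samples)) v <- v[, intersect(samples, colnames(v)), drop = FALSE]
  expression_matrix(v, em$groups[colnames(v)], em$dataset_id)
}

#' Samples belonging to a given group
#' @param em ExpressionMatrix.
#' @param group one of [SAMPLE_GROUPS].
#' @return character vector of sample ids.
#' @export
em_samples <- function(em, group) {
  names(em$groups)[em$groups == group]
}

#' Construct a per-instance probe rank matrix (CMAP-style)
#'
#' Each column holds one treatment instance: a permutation of `1..P` over
#' the `P` probes, rank 1 = most up-regulated by the compound. Instances are
#' annotated with compound name, cell line and (optionally) dose and batch.
#'
#' @param ranks integer matrix, probes x instances, dimnames required; every
#'   column must be a permutation of `1..nrow(ranks)`.
#' @param annotations data.frame with at least columns `instance_id`,
#'   `compound_name`, `cell_line`; one row per instance. Instances present
#'   in `ranks` but absent from `annotations` are dropped with a warning.
#' @return object of class `InstanceRankMatrix`.
#' @export
instance_rank_matrix <- function(ranks, annotations) {
  if (!is.matrix(ranks)) stop("'ranks' must be a matrix")
  if (is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("'ranks' must have probe and instance names")
  storage.mode(ranks) <- "integer"
  P <- nrow(ranks)
  for (j in seq_len(ncol(ranks))) {
    cj <- ranks[, j]
    if (anyNA(cj) || length(cj) != P || any(sort.int(cj) != seq_len(P)))
      stop("column '", colnames(ranks)[j],
           "' is not a permutation of 1..", P)
  }
  req <- c("instance_id", "compound_name", "cell_line")
  if (!all(req %in% names(annotations)))
    stop("annotations must contain columns: ", paste(req, collapse = ", "))
  annotations$instance_id <- as.character(annotations$instance_id)
  annotations$compound_name <- .trim_lower(annotations$compound_name)
  if (any(!nzchar(annotations$compound_name)) ||
      any(!nzchar(as.character(annotations$cell_line))))
    stop("every instance needs a non-empty compound_name and cell_line")
  unannotated <- setdiff(colnames(ranks), annotations$instance_id)
  if (length(unannotated)) {
    warning("dropping ", length(unannotated),
            " instance(s) without annotation: ",
            paste(utils::head(unannotated, 5L), collapse = ", "))
    ranks <- ranks[, setdiff(colnames(ranks), unannotated), drop = FALSE]
  }
  annotations <- annotations[match(colnames(ranks), annotations$instance_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(ranks = ranks, annotations = annotations),
            class = "InstanceRankMatrix")
}

#' @export
print.InstanceRankMatrix <- function(x, ...) {
  cat("InstanceRankMatrix:", nrow(x$ranks), "probes x", ncol(x$ranks),
      "instances;", length(unique(x$annotations$compound_name)),
      "compounds\n")
  invisible(x)
}

#' Construct a gene-set collection (GMT-style)
#'
#' @param sets named list of character vectors of member gene ids; member
#'   duplicates are removed, empty sets rejected.
#' @param descriptions optional named character vector of set descriptions.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets)) stop("no usable gene sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("empty gene set(s): ",
    paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets, sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Construct a drug annotation table
#'
#' One row per compound: FDA approval status plus approved and failed-trial
#' indications. Compound names (and indications) are canonicalized by
#' lower-casing and trimming; duplicate compound rows are merged by taking
#' the union of their indications and the OR of approval flags.
#'
#' @param compound character vector of compound names.
#' @param fda_approved logical vector.
#' @param approved_indications,failed_indications character vectors of
#'   semicolon-separated disease labels (empty string = none).
#' @return data.frame of class `drug_annotations` with columns `compound`,
#'   `fda_approved`, `approved_indications`, `failed_indications`.
#' @export
drug_annotations <- function(compound, fda_approved,
                             approved_indications = "",
                             failed_indications = "") {
  compound <- .trim_lower(compound)
  if (any(!nzchar(compound))) stop("empty compound name")
  n <- length(compound)
  df <- data.frame(
    compound = compound,
    fda_approved = as.logical(fda_approved),
    approved_indications = .norm_indications(rep_len(approved_indications, n)),
    failed_indications = .norm_indications(rep_len(failed_indications, n)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$compound)) {
    dup <- unique(df$compound[duplicated(df$compound)])
    message("merging ", length(dup), " duplicated compound record(s)")
    df <- do.call(rbind, lapply(split(df, df$compound), function(d) {
      data.frame(
        compound = d$compound[1L],
        fda_approved = any(d$fda_approved),
        approved_indications = .union_indications(d$approved_indications),
        failed_indications = .union_indications(d$failed_indications),
        stringsAsFactors = FALSE
      )
    }))
  }
  df <- df[order(df$compound), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("drug_annotations", "data.frame")
  df
}

.norm_indications <- function(x) {
  x[is.na(x)] <- ""
  vapply(strsplit(as.character(x), ";", fixed = TRUE), function(p) {
    p <- .trim_lower(p)
    paste(sort(unique(p[nzchar(p)])), collapse = ";")
  }, character(1))
}

.union_indications <- function(x) {
  .norm_indications(paste(x, collapse = ";"))
}

.has_indication <- function(ind, disease) {
  disease <- .trim_lower(disease)
  vapply(strsplit(ind, ";", fixed = TRUE),
         function(p) disease %in% p, logical(1))
}

#' Known positives: compounds FDA-approved for a disease
#' @param ann drug_annotations table.
#' @param disease disease label (case-insensitive).
#' @return character vector of compound names.
#' @export
annotation_positives <- function(ann, disease) {
  ann$compound[ann$fda_approved &
                 .has_indication(ann$approved_indications, disease)]
}

#' Known negatives: compounds with failed trials for a disease
#' @inheritParams annotation_positives
#' @export
annotation_negatives <- function(ann, disease) {
  ann$compound[.has_indication(ann$failed_indications, disease)]
}
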