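#' Read a GDS-style expression table
#'
#' Accepts either a SOFT-like file (`^DATASET`/`^SUBSET` metadata lines, the
#' data table between `!dataset_table_begin` and `!dataset_table_end`) or a
#' plain tab-delimited matrix whose header row holds sample ids. Group
#' labels come from embedded `^SUBSET` blocks or from a two-column sidecar
#' file (`sample_id<TAB>group`); the sidecar wins when both are present.
#'
#' Rows that are non-numeric in more than half of the samples are dropped
#' (count reported via `message()`); remaining sporadic non-numeric entries
#' become `NA` and can be imputed with [impute_missing()].
#'
#' @param path path to the expression table.
#' @param group_path optional sidecar file with columns sample id, group.
#' @param group_map optional named character vector translating subset
#'   descriptions (or sidecar labels) into [SAMPLE_GROUPS] labels, e.g.
#'   `c("breast cancer" = "disease")`. Labels already in [SAMPLE_GROUPS]
#'   pass through.
#' @return an [expression_matrix()]; a second column named `IDENTIFIER`
#'   (probe-to-gene symbol map) is attached as attribute `"identifier"`.
#' @export
read_gds <- function(path, group_path = NULL, group_map = NULL) {
  lines <- readLines(path)
  dataset_id <- NULL
  ds <- grep("^\\^DATASET", lines, value = TRUE)
  if (length(ds))
    dataset_id <- trimws(sub("^\\^DATASET\\s*=\\s*", "", ds[1L]))

  # subset blocks: ^SUBSET, then !subset_description and !subset_sample_id
  subset_groups <- character(0)
  starts <- grep("^\\^SUBSET", lines)
  bounds <- c(grep("^\\^", lines), length(lines) + 1L)
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    desc <- sub("^!subset_description\\s*=\\s*", "",
                grep("^!subset_description", block, value = TRUE)[1L])
    ids <- sub("^!subset_sample_id\\s*=\\s*", "",
               grep("^!subset_sample_id", block, value = TRUE)[1L])
    if (is.na(desc) || is.na(ids)) next
    ids <- trimws(strsplit(ids, ",", fixed = TRUE)[[1L]])
    subset_groups[ids] <- trimws(desc)
  }

  tb <- grep("^!dataset_table_begin", lines)
  te <- grep("^!dataset_table_end", lines)
  table_lines <- if (length(tb) && length(te)) {
    lines[(tb[1L] + 1L):(te[1L] - 1L)]
  } else {
    lines[!grepl("^[\\^!#]", lines) & nzchar(lines)]
  }
  if (length(table_lines) < 2L) stop("no data table found in ", path)
  hdr <- strsplit(table_lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr))
    stop("duplicated sample ids in ", path, ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  tab <- utils::read.delim(text = table_lines, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- tab[[1L]]
  tab <- tab[, -1L, drop = FALSE]
  identifier <- NULL
  if (ncol(tab) && toupper(names(tab)[1L]) == "IDENTIFIER") {
    identifier <- stats::setNames(tab[[1L]], ids)
    tab <- tab[, -1L, drop = FALSE]
  }
  if (anyDuplicated(colnames(tab)))
    stop("duplicated sample ids in ", path, ": ",
         paste(unique(colnames(tab)[duplicated(colnames(tab))]),
               collapse = ", "))
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab)), nrow = nrow(tab),
           dimnames = list(ids, colnames(tab))))
  bad_frac <- rowMeans(is.na(vals))
  drop <- bad_frac > 0.5
  if (any(drop)) {
    message("read_gds: dropping ", sum(drop),
            " row(s) non-numeric in >50% of samples")
    vals <- vals[!drop, , drop = FALSE]
    if (!is.null(identifier)) identifier <- identifier[rownames(vals)]
  }

  groups <- subset_groups
  if (!is.null(group_path)) {
    g <- utils::read.delim(group_path, header = FALSE,
                           stringsAsFactors = FALSE)
    groups <- stats::setNames(trimws(g[[2L]]), trimws(g[[1L]]))
  }
  if (!is.null(group_map)) {
    mapped <- !is.na(match(groups, names(group_map)))
    groups[mapped] <- group_map[groups[mapped]]
  }
  unlabeled <- setdiff(colnames(vals), names(groups))
  if (length(unlabeled))
    stop("samples without a group label: ",
         paste(unlabeled, collapse = ", "))
  em <- expression_matrix(vals, groups, dataset_id)
  attr(em, "identifier") <- identifier
  em
}

#' Write an ExpressionMatrix as a SOFT-like GDS table
#'
#' Emits a `^DATASET` header, one `^SUBSET` block per group, and the data
#' table between the usual begin/end markers. [read_gds()] round-trips the
#' result.
#'
#' @param em ExpressionMatrix.
#' @param path output path.
#' @param digits significant digits for values.
#' @export
write_gds <- function(em, path, digits = 8) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("^DATASET = ", em$dataset_id %||% "UNTITLED"), con)
  for (g in unique(em$groups)) {
    writeLines(c(
      paste0("^SUBSET = ", g),
      paste0("!subset_description = ", g),
      paste0("!subset_sample_id = ",
             paste(names(em$groups)[em$groups == g], collapse = ","))
    ), con)
  }
  writeLines("!dataset_table_begin", con)
  writeLines(paste(c("ID_REF", colnames(em$values)), collapse = "\t"), con)
  body <- apply(signif(em$values, digits), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(em$values), body, sep = "\t"), con)
  writeLines("!dataset_table_end", con)
  invisible(path)
}

#' Read a CMAP-style instance rank matrix plus its annotation table
#'
#' @param path tab-delimited probes x instances integer matrix; first column
#'   probe ids, header row instance ids.
#' @param annotation_path tab-delimited table with header containing at
#'   least `instance_id`, `compound_name`, `cell_line`.
#' @return an [instance_rank_matrix()]. Every column must be a permutation
#'   of `1..P` (hard error naming the offending instance); instances without
#'   annotation are dropped with a warning.
#' @export
read_rank_matrix <- function(path, annotation_path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ranks <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(ranks) <- as.character(tab[[1L]])
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           stringsAsFactors = FALSE)
  instance_rank_matrix(ranks, ann)
}

#' Write an InstanceRankMatrix (matrix + annotation table)
#' @param rm InstanceRankMatrix.
#' @param path,annotation_path output paths.
#' @export
write_rank_matrix <- function(rm, path, annotation_path) {
  df <- data.frame(PROBE_ID = rownames(rm$ranks), rm$ranks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rm$annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, fields `set_id`, `description`,
#' `member...`. Members are deduplicated within a set; lines with fewer than
#' three fields are skipped with a warning; a file yielding zero usable sets
#' is a hard error.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    warning("read_gmt: skipping ", sum(short), " line(s) with <3 fields")
  fields <- fields[!short]
  if (!length(fields)) stop("no usable gene sets in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Write a GeneSetCollection in GMT format
#' @param gsc GeneSetCollection.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]] %||% "", gsc$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug annotation table
#'
#' Tab-delimited with header columns `compound`, `fda_approved` (0/1 or
#' TRUE/FALSE), `approved_indications`, `failed_indications`
#' (semicolon-separated disease labels). Compound names are canonicalized
#' (lower-case, trimmed) and duplicate rows merged by indication union.
#'
#' @param path annotation file.
#' @return a [drug_annotations()] table.
#' @export
read_drug_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("compound", "fda_approved")
  if (!all(req %in% names(tab)))
    stop("annotation file must contain columns: ",
         paste(req, collapse = ", "))
  drug_annotations(
    compound = tab$compound,
    fda_approved = tab$fda_approved %in% c("1", "TRUE", "true", "T"),
    approved_indications = tab$approved_indications %||% "",
    failed_indications = tab$failed_indications %||% ""
  )
}

#' Write a drug annotation table
#' @param ann drug_annotations table.
#' @param path output path.
#' @export
write_drug_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
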