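#' Configuration for the synthetic benchmark world
#'
#' Describes a self-contained world with the statistical structure the
#' method assumes: a two-cohort tissue experiment with a planted set of
#' differentially expressed (DE) genes, a matching cancer-derived cell
#' line, and a bank of compound rank lists -- most random, a few
#' constructed to mirror (reverse) the disease ranking with tunable noise.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_normal,n_disease tissue cohort sizes (default 10 + 10).
#' @param n_control_instances untreated cell-line samples (default 5).
#' @param n_compounds compounds in the bank (default 200).
#' @param n_planted_reversers compounds whose list is the noisy reversed
#'   disease list (default 1).
#' @param reversal_noise fraction of positions of a planted list that are
#'   randomly re-shuffled (default 0.1).
#' @param de_fraction fraction of genes truly differential (default 0.1).
#' @param effect_size mean disease shift of DE genes in SD units
#'   (default 2).
#' @param incompatible_fraction fraction of genes whose cell-line baseline
#'   is shifted away from the tissue (what the gene filter should remove;
#'   default 0.05, shift 4 SD).
#' @param n_failed_negatives non-reverser compounds annotated as failed in
#'   trials for the target disease (default 2).
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 2000, n_normal = 10, n_disease = 10,
                              n_control_instances = 5, n_compounds = 200,
                              n_planted_reversers = 1, reversal_noise = 0.1,
                              de_fraction = 0.1, effect_size = 2,
                              incompatible_fraction = 0.05,
                              n_failed_negatives = 2, seed = 1) {
  cfg <- list(n_genes = .assert_scalar_count(n_genes, "n_genes"),
              n_normal = .assert_scalar_count(n_normal, "n_normal"),
              n_disease = .assert_scalar_count(n_disease, "n_disease"),
              n_control_instances =
                .assert_scalar_count(n_control_instances,
                                     "n_control_instances"),
              n_compounds = .assert_scalar_count(n_compounds, "n_compounds"),
              n_planted_reversers =
                .assert_scalar_count(n_planted_reversers,
                                     "n_planted_reversers"),
              reversal_noise = reversal_noise,
              de_fraction = de_fraction, effect_size = effect_size,
              incompatible_fraction = incompatible_fraction,
              n_failed_negatives =
                .assert_scalar_count(n_failed_negatives,
                                     "n_failed_negatives"),
              seed = as.integer(seed))
  for (f in c("reversal_noise", "de_fraction", "incompatible_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  }
  if (cfg$n_planted_reversers > cfg$n_compounds)
    stop("more planted reversers than compounds")
  structure(cfg, class = "SimulationConfig")
}

# shared hidden state: per-gene baselines, DE assignment, incompatible
# genes. Derived from cfg$seed only, so tissue and cell line agree.
.sim_world_state <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  mu <- stats::rnorm(cfg$n_genes, mean = 8, sd = 1)
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_idx <- sort(sample.int(cfg$n_genes, n_de))
  de_sign <- sample(c(-1L, 1L), n_de, replace = TRUE)
  shift <- numeric(cfg$n_genes)
  shift[de_idx] <- cfg$effect_size * de_sign
  n_inc <- round(cfg$incompatible_fraction * cfg$n_genes)
  inc_idx <- sort(sample.int(cfg$n_genes, n_inc))
  inc_shift <- numeric(cfg$n_genes)
  if (n_inc)
    inc_shift[inc_idx] <- 4 * sample(c(-1, 1), n_inc, replace = TRUE)
  list(genes = genes, mu = mu, shift = shift, de_idx = de_idx,
       inc_idx = inc_idx, inc_shift = inc_shift)
}

#' Simulate the disease tissue experiment
#'
#' Genes are unit-variance Gaussian noise around per-gene baselines
#' (`N(8, 1)`, a log2-intensity-like scale); a `de_fraction` of genes is
#' shifted by `effect_size` SD (random sign) in the disease cohort.
#'
#' @param cfg [simulation_config()].
#' @return ExpressionMatrix with `normal`/`disease` groups; attribute
#'   `"de_truth"` is a data.frame (gene, de, direction).
#' @export
simulate_tissue <- function(cfg) {
  st <- .sim_world_state(cfg)
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_normal + cfg$n_disease
  v <- st$mu + matrix(stats::rnorm(cfg$n_genes * ns), cfg$n_genes, ns)
  disease_cols <- cfg$n_normal + seq_len(cfg$n_disease)
  v[, disease_cols] <- v[, disease_cols] + st$shift
  dimnames(v) <- list(st$genes,
                      c(sprintf("N%02d", seq_len(cfg$n_normal)),
                        sprintf("D%02d", seq_len(cfg$n_disease))))
  groups <- stats::setNames(rep(c("normal", "disease"),
                                c(cfg$n_normal, cfg$n_disease)),
                            colnames(v))
  em <- expression_matrix(v, groups, dataset_id = "SYNTHETIC_TISSUE")
  attr(em, "de_truth") <- data.frame(
    gene = st$genes, de = seq_len(cfg$n_genes) %in% st$de_idx,
    direction = sign(st$shift), stringsAsFactors = FALSE)
  em
}

#' Simulate the untreated cancer cell-line baseline
#'
#' The cell line is cancer-derived, so its baseline mirrors the disease
#' state of the tissue (DE genes carry the same shift); an
#' `incompatible_fraction` of genes additionally gets a 4-SD baseline
#' shift, emulating platform disagreement in the raw data. Note that the
#' reference normalization ([normalize_expression()]) centers each
#' platform on its own reference samples, so a pure baseline offset is
#' absorbed before [filter_common_genes()] sees the data; the filter's
#' operational removable class is genes whose normalized disease
#' displacement is large (see the methods vignette).
#'
#' @param cfg [simulation_config()].
#' @return ExpressionMatrix of `untreated_control` samples; attribute
#'   `"incompatible"` lists the shifted gene ids.
#' @export
simulate_cell_line <- function(cfg) {
  st <- .sim_world_state(cfg)
  set.seed(cfg$seed + 2L)
  ns <- cfg$n_control_instances
  v <- st$mu + st$shift + st$inc_shift +
    matrix(stats::rnorm(cfg$n_genes * ns), cfg$n_genes, ns)
  dimnames(v) <- list(st$genes, sprintf("CTL%02d", seq_len(ns)))
  groups <- stats::setNames(rep("untreated_control", ns), colnames(v))
  em <- expression_matrix(v, groups, dataset_id = "SYNTHETIC_CELLLINE")
  attr(em, "incompatible") <- st$genes[st$inc_idx]
  em
}

#' Simulate the compound rank-list bank
#'
#' `n_planted_reversers` compounds receive the exactly reversed disease
#' ordering with a `reversal_noise` fraction of positions randomly
#' re-shuffled among themselves; all other compounds receive independent
#' uniform permutations. Each compound gets 1-3 identical treatment
#' instances in cell line `"SYN"`.
#'
#' @param cfg [simulation_config()].
#' @param disease_ranking RankedList the planted compounds mirror.
#' @return InstanceRankMatrix; attribute `"truth"` is a data.frame
#'   (compound, planted).
#' @export
simulate_compound_bank <- function(cfg, disease_ranking) {
  set.seed(cfg$seed + 3L)
  genes <- disease_ranking$gene_ids
  n <- length(genes)
  if (n != cfg$n_genes)
    message("simulate_compound_bank: ranking covers ", n, " of ",
            cfg$n_genes, " genes")
  cols <- list()
  ann <- list()
  planted <- logical(cfg$n_compounds)
  for (j in seq_len(cfg$n_compounds)) {
    nm <- sprintf("compound_%03d", j)
    if (j <= cfg$n_planted_reversers) {
      planted[j] <- TRUE
      r <- rev(seq_len(n))          # disease top -> compound bottom
      m <- round(cfg$reversal_noise * n)
      if (m >= 2L) {
        idx <- sample.int(n, m)
        r[idx] <- r[idx][sample.int(m)]
      }
    } else {
      r <- sample.int(n)
    }
    n_inst <- sample.int(3L, 1L)
    ids <- sprintf("%s_i%d", nm, seq_len(n_inst))
    for (id in ids) cols[[id]] <- r
    ann[[j]] <- data.frame(instance_id = ids, compound_name = nm,
                           cell_line = "SYN", dose = "10uM",
                           batch = j %% 5L + 1L, stringsAsFactors = FALSE)
  }
  ranks <- do.call(cbind, cols)
  rownames(ranks) <- genes
  rm <- instance_rank_matrix(ranks, do.call(rbind, ann))
  attr(rm, "truth") <- data.frame(
    compound = sprintf("compound_%03d", seq_len(cfg$n_compounds)),
    planted = planted, stringsAsFactors = FALSE)
  rm
}

#' Simulate drug annotations and gene sets for the synthetic world
#'
#' The first planted reverser is marked FDA-approved for the target
#' disease (the known positive the window scan needs);
#' `n_failed_negatives` random non-reversers are marked as failed in
#' trials for the target. A planted pathway drawn from true DE genes plus
#' uniform decoy sets provides the enrichment fixture.
#'
#' @param cfg [simulation_config()].
#' @param truth list with elements `compounds` (data.frame compound,
#'   planted; from the bank's `"truth"` attribute) and `de` (data.frame
#'   gene, de; from the tissue's `"de_truth"` attribute).
#' @param n_decoy_sets,decoy_size decoy gene sets (default 20 sets of 50).
#' @return list with `annotations` ([drug_annotations()]), `genesets`
#'   ([gene_set_collection()]; planted set id `"PLANTED"`) and
#'   `target_disease` (label `"synthetic carcinoma"`).
#' @export
simulate_annotations <- function(cfg, truth, n_decoy_sets = 20,
                                 decoy_size = 50) {
  set.seed(cfg$seed + 4L)
  target <- "synthetic carcinoma"
  cp <- truth$compounds
  fda <- stats::runif(nrow(cp)) < 0.5
  approved <- rep("", nrow(cp))
  failed <- rep("", nrow(cp))
  pos <- which(cp$planted)[1L]
  if (!is.na(pos)) {
    fda[pos] <- TRUE
    approved[pos] <- target
  }
  nonplanted <- which(!cp$planted)
  neg <- sample(nonplanted, min(cfg$n_failed_negatives, length(nonplanted)))
  failed[neg] <- target
  ann <- drug_annotations(cp$compound, fda, approved, failed)

  genes <- truth$de$gene
  de_genes <- genes[truth$de$de]
  planted_set <- sample(de_genes, min(decoy_size, length(de_genes)))
  sets <- list(PLANTED = planted_set)
  for (i in seq_len(n_decoy_sets))
    sets[[sprintf("DECOY%02d", i)]] <- sample(genes, decoy_size)
  gsc <- gene_set_collection(
    sets, stats::setNames(c("planted pathway",
                            rep("decoy", n_decoy_sets)), names(sets)))
  list(annotations = ann, genesets = gsc, target_disease = target)
}

#' Generate the complete synthetic world in one call
#'
#' Tissue, cell line, disease ranking (over all genes, from the raw
#' tissue), compound bank, annotations and gene sets, with the truth
#' tables, all derived from one seed.
#'
#' @param cfg [simulation_config()].
#' @return list: `tissue`, `cellline`, `bank`, `annotations`, `genesets`,
#'   `target_disease`, `cell_line`, `truth` (list: `de`, `compounds`).
#' @export
simulate_world <- function(cfg) {
  tissue <- simulate_tissue(cfg)
  cellline <- simulate_cell_line(cfg)
  ranking <- rank_disease(tissue)
  bank <- simulate_compound_bank(cfg, ranking)
  truth <- list(de = attr(tissue, "de_truth"),
                compounds = attr(bank, "truth"))
  ann <- simulate_annotations(cfg, truth)
  list(tissue = tissue, cellline = cellline, bank = bank,
       annotations = ann$annotations, genesets = ann$genesets,
       target_disease = ann$target_disease, cell_line = "SYN",
       truth = truth)
}
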