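# A deterministic little world for the scan: 30 compounds over 200 genes,
# compound 1 a perfect reverser annotated as the in-use drug, compound 2 a
# second (unidentifiable) positive, compounds 3-4 failed-trial negatives.
make_scan_world <- function(seed = 17) {
  disease <- rl_from_order(sprintf("g%03d", 1:200))
  bank <- toy_bank(disease, 30, reversers = 1, seed = seed)
  ann <- drug_annotations(
    names(bank),
    fda_approved = c(TRUE, TRUE, rep(FALSE, 28)),
    approved_indications = c("testopathy", "testopathy", rep("", 28)),
    failed_indications = c("", "", "testopathy", "testopathy", rep("", 26))
  )
  list(disease = disease, bank = bank, ann = ann)
}

test_that("evaluate_k scores sensitivity and specificity as fractions", {
  w <- make_scan_world()
  ev <- evaluate_k(w$disease, w$bank, 20, w$ann, "testopathy")
  uc <- ev[ev$direction == "UC_DB", ]
  # positives {cmpd_01, cmpd_02}, identified {cmpd_01} -> sensitivity 0.5
  expect_equal(uc$sensitivity, 0.5)
  expect_equal(uc$recovered[[1]], "cmpd_01")
  # no negative identified -> specificity 1.0
  expect_equal(uc$specificity, 1.0)
  expect_equal(uc$n_duality, 1L)

  # zero positives is a hard error instructing the user
  ann0 <- drug_annotations(names(w$bank), FALSE)
  expect_error(evaluate_k(w$disease, w$bank, 20, ann0, "testopathy"),
               "no known positives")
})

test_that("the two specificity definitions behave as documented", {
  w <- make_scan_world()
  # force an identified negative by replacing cmpd_03 with a reverser
  w$bank$cmpd_03 <- rl_reversed(w$disease)
  ev1 <- evaluate_k(w$disease, w$bank, 20, w$ann, "testopathy",
                    specificity_mode = "negatives_excluded")
  ev2 <- evaluate_k(w$disease, w$bank, 20, w$ann, "testopathy",
                    specificity_mode = "identified_fraction")
  uc1 <- ev1[ev1$direction == "UC_DB", ]
  uc2 <- ev2[ev2$direction == "UC_DB", ]
  expect_equal(uc1$specificity, 0.5)        # 1 of 2 negatives excluded
  # identified = {cmpd_01, cmpd_03}, 1 failed among 2 identified
  expect_equal(uc2$specificity, 1 - 1 / 2)
})

test_that("select_window maximizes specificity with smallest-k ties", {
  trace <- data.frame(
    k = rep(c(10, 20, 30, 40), each = 2),
    direction = rep(c("UC_DB", "DC_UB"), 4),
    n_significant = c(0, 1, 2, 1, 2, 1, 2, 1),
    sensitivity = c(0, 1, 1, 1, 1, 1, 1, 1),
    specificity = c(1, 0.5, 0.9, 0.5, 0.9, 0.5, 0.7, 0.5),
    n_duality = c(1, 1, 1, 1, 1, 1, 1, 1))
  trace$recovered <- I(as.list(rep("d", 8)))
  class(trace) <- c("ScanResult", "data.frame")
  # k=10 infeasible for UC_DB (sensitivity 0 via n_significant 0);
  # specificity ties at k=20 and k=30 -> smaller k wins
  expect_equal(as.integer(select_window(trace, "UC_DB")), 20L)
  # DC_UB: single specificity everywhere -> smallest feasible k
  expect_equal(as.integer(select_window(trace, "DC_UB")), 10L)
  # selection is a pure function of the trace
  expect_equal(as.integer(select_window(trace, "UC_DB")),
               as.integer(select_window(trace, "UC_DB")))

  bad <- trace
  bad$sensitivity <- 0
  expect_error(select_window(bad, "UC_DB"), "no feasible window")
})

test_that("scan + selection matches an exhaustive first-principles oracle", {
  w <- make_scan_world(seed = 4)
  grid <- c(10, 20, 40, 60, 80)
  scan <- scan_windows(w$disease, w$bank, w$ann, "testopathy", grid = grid,
                       fdr = 0.01)
  expect_equal(attr(scan, "grid"), as.integer(grid))
  sel <- select_window(scan, "UC_DB")

  # oracle: recompute everything from slices + phyper + p.adjust
  n <- length(w$disease$gene_ids)
  positives <- c("cmpd_01", "cmpd_02")
  negatives <- c("cmpd_03", "cmpd_04")
  oracle <- sapply(grid, function(k) {
    dtop <- w$disease$gene_ids[1:k]
    dbot <- rev(w$disease$gene_ids)[1:k]
    x_uc <- vapply(w$bank, function(cl)
      sum(dtop %in% rev(cl$gene_ids)[1:k]), numeric(1))
    x_dc <- vapply(w$bank, function(cl)
      sum(dbot %in% cl$gene_ids[1:k]), numeric(1))
    p_uc <- phyper(x_uc - 1, k, n - k, k, lower.tail = FALSE)
    p_dc <- phyper(x_dc - 1, k, n - k, k, lower.tail = FALSE)
    id_uc <- names(w$bank)[p.adjust(p_uc, "BH") < 0.01]
    id_dc <- names(w$bank)[p.adjust(p_dc, "BH") < 0.01]
    c(sens = length(intersect(id_uc, positives)) / length(positives),
      spec = length(setdiff(negatives, id_uc)) / length(negatives),
      dual = length(intersect(id_uc, id_dc)),
      nsig = length(id_uc))
  })
  feasible <- oracle["sens", ] > 0 & oracle["dual", ] > 0 &
    oracle["nsig", ] > 0
  expected_k <- grid[feasible][which.max(oracle["spec", feasible])]
  expect_equal(as.integer(sel), as.integer(expected_k))

  # scan trace agrees with the oracle columns for UC_DB
  uc <- scan[scan$direction == "UC_DB", ]
  expect_equal(uc$sensitivity, unname(oracle["sens", ]))
  expect_equal(uc$specificity, unname(oracle["spec", ]))
  expect_equal(uc$n_duality, unname(as.integer(oracle["dual", ])))
})

test_that("scan trace serializes and the grid truncates to floor(n/2)", {
  w <- make_scan_world()
  scan <- scan_windows(w$disease, w$bank, w$ann, "testopathy",
                       grid = c(50, 100, 150), fdr = 0.01)
  expect_equal(attr(scan, "grid"), c(50L, 100L))  # n = 200 -> k <= 100
  path <- tempfile()
  write_scan_trace(scan, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(scan))
  expect_true("cmpd_01" %in% back$recovered)
})
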