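make_prop_tab <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  tibble::as_tibble(m) |>
    dplyr::mutate(sample_id = ids, .before = 1)
}

test_that("identical prediction and truth give the zero report", {
  set.seed(1)
  m <- t(apply(matrix(runif(15), 5, 3), 1, function(r) r / sum(r)))
  colnames(m) <- c("A", "B", "C")
  tab <- make_prop_tab(m)
  rep <- error_metrics(tab, tab)
  expect_true(all(rep$by_class$mean_error_pct == 0))
  expect_true(all(rep$by_class$rmse_pct == 0))
  expect_identical(rep$overall$mean_abs_error_pct, 0)
  # correlation of identical vectors is 1 (defined: truth varies here)
  expect_true(all(rep$by_class$pearson_r == 1))
})

test_that("constant truth flags correlation undefined, not zero", {
  truth <- make_prop_tab(matrix(c(0.2, 0.2, 0.2,
                                  0.8, 0.8, 0.8), 3, 2,
                                dimnames = list(NULL, c("A", "B"))))
  set.seed(2)
  pred <- truth
  pred$A <- pred$A + c(-0.01, 0, 0.01)
  pred$B <- 1 - pred$A
  rep <- error_metrics(pred, truth)
  expect_true(all(is.na(rep$by_class$pearson_r)))
})

test_that("a uniform +0.01 shift gives exactly 1 percentage point error", {
  set.seed(3)
  m <- t(apply(matrix(runif(12), 4, 3), 1, function(r) r / sum(r)))
  colnames(m) <- c("A", "B", "C")
  truth <- make_prop_tab(m)
  pred <- truth
  for (cl in c("A", "B", "C")) pred[[cl]] <- pred[[cl]] + 0.01
  rep <- suppressWarnings(error_metrics(pred, truth))
  expect_equal(rep$by_class$mean_abs_error_pct, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep$by_class$mean_error_pct, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep$overall$mean_abs_error_pct, 1, tolerance = 1e-12)
})

test_that("metrics on a 5x3 toy match hand-computed definitional values", {
  set.seed(17)
  truth_m <- t(apply(matrix(runif(15), 5, 3), 1, function(r) r / sum(r)))
  pred_m <- truth_m + matrix(rnorm(15, 0, 0.03), 5, 3)
  pred_m <- pmax(pred_m, 0)
  colnames(truth_m) <- colnames(pred_m) <- c("A", "B", "C")
  orc <- oracle_error_table(pred_m, truth_m)

  rep <- error_metrics(make_prop_tab(pred_m), make_prop_tab(truth_m))
  expect_equal(rep$by_class$mean_error_pct, unname(orc$mean_error),
               tolerance = 1e-12)
  expect_equal(rep$by_class$mean_abs_error_pct, unname(orc$mean_abs_error),
               tolerance = 1e-12)
  expect_equal(rep$by_class$rmse_pct, unname(orc$rmse), tolerance = 1e-12)
  expect_equal(rep$overall$mean_abs_error_pct, orc$overall_mean_abs,
               tolerance = 1e-12)
  for (j in 1:3) {
    expect_equal(rep$by_class$pearson_r[j],
                 cor(pred_m[, j], truth_m[, j]), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to simultaneous sample reordering", {
  set.seed(4)
  m <- t(apply(matrix(runif(18), 6, 3), 1, function(r) r / sum(r)))
  colnames(m) <- c("A", "B", "C")
  truth <- make_prop_tab(m)
  pred <- make_prop_tab(pmax(m + rnorm(18, 0, 0.02), 0))
  r1 <- error_metrics(pred, truth)
  perm <- c(4, 1, 6, 2, 5, 3)
  r2 <- error_metrics(pred[perm, ], truth[perm, ])
  expect_equal(r1$by_class, r2$by_class, tolerance = 1e-12)
  # and to truth arriving in a different row order than pred
  r3 <- error_metrics(pred, truth[perm, ])
  expect_equal(r1$by_class, r3$by_class, tolerance = 1e-12)
})

test_that("overall mean equals the sample-count weighted class mean", {
  set.seed(5)
  m <- t(apply(matrix(runif(24), 8, 3), 1, function(r) r / sum(r)))
  colnames(m) <- c("A", "B", "C")
  truth <- make_prop_tab(m)
  pred <- make_prop_tab(pmax(m + rnorm(24, 0, 0.05), 0))
  rep <- error_metrics(pred, truth)
  weighted <- sum(rep$by_class$mean_abs_error_pct * rep$by_class$n) /
    sum(rep$by_class$n)
  expect_equal(rep$overall$mean_abs_error_pct, weighted, tolerance = 1e-12)
})

test_that("mismatched samples or classes produce informative errors", {
  m <- matrix(c(0.5, 0.5, 0.4, 0.6), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  truth <- make_prop_tab(m)
  pred_badcls <- truth
  names(pred_badcls)[3] <- "Z"
  expect_error(error_metrics(pred_badcls, truth), "class mismatch.*Z")
  pred_badsmp <- truth
  pred_badsmp$sample_id[1] <- "ghost"
  expect_error(error_metrics(pred_badsmp, truth), "sample mismatch.*ghost")
})

test_that("recovery_report runs the full pipeline from files", {
  st <- tiny_study()
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  mix_path <- file.path(dir, "mixtures.csv")
  truth_path <- file.path(dir, "truth.csv")
  bundle_dir <- file.path(dir, "bundle")
  write_beta_matrix(st$mixtures$betas, mix_path)
  readr::write_csv(st$mixtures$truth, truth_path)
  save_library_bundle(b, bundle_dir)
  out <- file.path(dir, "report.csv")
  rep <- suppressWarnings(
    recovery_report(mix_path, truth_path, bundle_dir, h = 6, out = out)
  )
  expect_s3_class(rep, "tme_recovery")
  expect_identical(nrow(rep$by_class), 17L)
  expect_true(file.exists(out))
  # deterministic
  rep2 <- suppressWarnings(
    recovery_report(mix_path, truth_path, bundle_dir, h = 6)
  )
  expect_equal(rep$by_class, rep2$by_class, tolerance = 1e-15)
})

test_that("collapsed-class errors are consistent with their subset errors", {
  # a collapsed class's error is the sum of its subsets' signed errors, so
  # its RMSE can never exceed the sum of the subset RMSEs (Minkowski); when
  # subset biases anticorrelate it drops below the worst subset
  st <- tiny_study()
  b <- tiny_bundle()
  res <- suppressWarnings(deconvolve(st$mixtures$betas, b, h = 6))
  tree <- b$tree
  pred6 <- proportions_at(res, 6)[, -2]
  rep6 <- error_metrics(pred6, st$mixtures$truth)
  pred5 <- aggregate_to_layer(res, 6, 5)[, -2]
  rep5 <- error_metrics(pred5, aggregate_truth(st$mixtures$truth, tree, 5))
  for (parent in c("CD4T", "CD8T")) {
    subsets <- hierarchy_leaves_under(tree, parent)
    subset_rmse <- rep6$by_class$rmse_pct[rep6$by_class$class %in% subsets]
    collapsed <- rep5$by_class$rmse_pct[rep5$by_class$class == parent]
    expect_lte(collapsed, sum(subset_rmse) + 1e-9)
    # and the collapsed signed error per sample is the sum over subsets
    e_sub <- rowSums(vapply(subsets, function(cl) {
      rep6$cells$error_pct[rep6$cells$class == cl]
    }, numeric(nrow(pred6))))
    e_par <- rep5$cells$error_pct[rep5$cells$class == parent]
    expect_equal(e_par, e_sub, tolerance = 1e-9)
  }
})
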