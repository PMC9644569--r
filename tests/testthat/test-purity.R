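test_that("iDMC selection matches exhaustive rank-sum enumeration on a toy", {
  # 6 probes, 3 tumor vs 3 normal, tie-free values
  set.seed(31)
  tumor <- matrix(runif(18, 0.5, 0.95), 6, 3,
                  dimnames = list(paste0("cg0", 1:6), paste0("t", 1:3)))
  normal <- matrix(runif(18, 0.05, 0.45), 6, 3,
                   dimnames = list(paste0("cg0", 1:6), paste0("n", 1:3)))
  # make two probes hypo so both directions occur
  tumor[5:6, ] <- tumor[5:6, ] - 0.5
  normal[5:6, ] <- normal[5:6, ] + 0.5

  p_oracle <- vapply(1:6, function(i) {
    oracle_ranksum_p(tumor[i, ], normal[i, ])
  }, 1)
  md <- rowMeans(tumor) - rowMeans(normal)
  ord <- order(p_oracle, -abs(md), rownames(tumor))

  lib <- select_idmc(tumor, normal, n_top = 6, var_threshold = 1e-9)
  expect_identical(lib$entries$probe, rownames(tumor)[ord])
  expect_lt(max(abs(lib$entries$p_value - p_oracle[ord])), 1e-12)
  expect_identical(lib$entries$direction,
                   unname(ifelse(md[ord] > 0, "hyper", "hypo")))
})

test_that("variance filter yields an error when no probe varies", {
  tumor <- matrix(0.5, 20, 4,
                  dimnames = list(sprintf("cg%02d", 1:20), paste0("t", 1:4)))
  normal <- random_beta_matrix(20, 4)
  rownames(normal) <- rownames(tumor)
  expect_error(select_idmc(tumor, normal), "zero candidates")
})

test_that("fewer candidates than n_top yields a shorter library with warning", {
  st <- tiny_study()
  expect_warning(
    lib <- select_idmc(st$tumor, st$normal, n_top = 1e6),
    "candidates"
  )
  expect_lte(nrow(lib$entries), 1e6)
  expect_gt(nrow(lib$entries), 0)
})

test_that("flipping all betas flips directions and keeps the ranking", {
  st <- tiny_study()
  lib <- select_idmc(st$tumor, st$normal, n_top = 100)
  lib_flip <- select_idmc(1 - st$tumor, 1 - st$normal, n_top = 100)
  expect_identical(lib_flip$entries$probe, lib$entries$probe)
  expect_identical(
    lib_flip$entries$direction,
    ifelse(lib$entries$direction == "hyper", "hypo", "hyper")
  )
})

test_that("library construction is deterministic", {
  st <- tiny_study()
  l1 <- select_idmc(st$tumor, st$normal, n_top = 150)
  l2 <- select_idmc(st$tumor, st$normal, n_top = 150)
  expect_identical(l1, l2)
})

test_that("direction transform is beta for hyper and 1-beta for hypo", {
  lib <- structure(list(
    entries = tibble::tibble(
      probe = c("a", "b", "c"),
      direction = c("hyper", "hypo", "hypo"),
      p_value = c(0.01, 0.02, 0.03), mean_diff = c(0.5, -0.5, -0.2)
    ),
    params = list(n_top = 3, var_threshold = 0.005)
  ), class = "idmc_library")
  out <- transform_idmc_betas(c(a = 0.8, b = 0.2, c = 1.0), lib)
  expect_equal(unname(out), c(0.8, 0.8, 0.0))
  # element-wise recomputation on a larger mixed vector
  set.seed(5)
  dirs <- sample(c("hyper", "hypo"), 10, replace = TRUE)
  lib10 <- structure(list(
    entries = tibble::tibble(
      probe = paste0("p", 1:10), direction = dirs,
      p_value = runif(10), mean_diff = runif(10, -1, 1)
    ),
    params = list(n_top = 10, var_threshold = 0.005)
  ), class = "idmc_library")
  b <- setNames(runif(10), paste0("p", 1:10))
  expect_equal(unname(transform_idmc_betas(b, lib10)),
               unname(ifelse(dirs == "hypo", 1 - b, b)))
  # absent probes skipped
  expect_length(transform_idmc_betas(b[1:4], lib10), 4)
})

test_that("purity of a point mass is the mass location", {
  lib <- make_point_lib(20)
  dirs <- lib$entries$direction
  b <- setNames(ifelse(dirs == "hypo", 0.4, 0.6), lib$entries$probe)
  est <- estimate_purity(b, lib)
  expect_lt(abs(est$purity - 0.6), 0.001 + 1e-12)
  expect_identical(est$n_probes_used, 20L)
})

test_that("purity recovers a generative mixture mode and is monotone", {
  lib <- make_point_lib(1000)
  dirs <- lib$entries$direction
  gen <- function(p, seed) {
    set.seed(seed)
    v <- pmin(pmax(rnorm(1000, p, 0.05), 0), 1)
    setNames(ifelse(dirs == "hypo", 1 - v, v), lib$entries$probe)
  }
  est7 <- estimate_purity(gen(0.7, 11), lib)
  expect_lt(abs(est7$purity - 0.7), 0.05)
  est3 <- estimate_purity(gen(0.3, 12), lib)
  est8 <- estimate_purity(gen(0.8, 13), lib)
  expect_lt(est3$purity, est8$purity)
})

test_that("purity needs at least 10 usable probes and stays in [0,1]", {
  lib <- make_point_lib(20)
  b <- setNames(runif(5), lib$entries$probe[1:5])
  expect_error(suppressWarnings(estimate_purity(b, lib)), ">= 10")
  set.seed(3)
  for (i in 1:5) {
    b <- setNames(runif(20), lib$entries$probe)
    est <- suppressWarnings(estimate_purity(b, lib))
    expect_gte(est$purity, 0)
    expect_lte(est$purity, 1)
  }
})

test_that("purity_table returns one row per sample with diagnostics", {
  st <- tiny_study()
  b <- tiny_bundle()
  tab <- purity_table(st$mixtures$betas[, 1:3], b$l1)
  expect_identical(tab$sample_id, colnames(st$mixtures$betas)[1:3])
  expect_true(all(tab$purity >= 0 & tab$purity <= 1))
  expect_true(all(tab$n_probes_used <= nrow(b$l1$entries)))
})
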