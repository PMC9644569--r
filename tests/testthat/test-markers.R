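make_block_panel <- function(n_classes = 3, markers = 6, background = 30,
                             n_per_class = 4, noise = 0.01, seed = 14) {
  set.seed(seed)
  n_probes <- n_classes * markers + background
  probes <- sprintf("cg%04d", seq_len(n_probes))
  classes <- LETTERS[seq_len(n_classes)]
  base <- runif(n_probes, 0.3, 0.7)
  arch <- matrix(base, n_probes, n_classes,
                 dimnames = list(probes, classes))
  for (i in seq_len(n_classes)) {
    block <- ((i - 1) * markers + 1):(i * markers)
    up <- block[seq_len(markers / 2)]
    down <- setdiff(block, up)
    arch[up, i] <- 0.95
    arch[down, i] <- 0.05
  }
  betas <- do.call(cbind, lapply(classes, function(cl) {
    m <- vapply(seq_len(n_per_class), function(j) {
      pmin(pmax(arch[, cl] + rnorm(n_probes, 0, noise), 0), 1)
    }, numeric(n_probes))
    colnames(m) <- paste0(cl, seq_len(n_per_class))
    m
  }))
  rownames(betas) <- probes
  labels <- setNames(rep(classes, each = n_per_class), colnames(betas))
  list(panel = reference_panel(betas, labels), arch = arch,
       blocks = lapply(seq_len(n_classes), function(i) {
         probes[((i - 1) * markers + 1):(i * markers)]
       }))
}

test_that("marker ranking returns the requested split of hyper and hypo", {
  bp <- make_block_panel()
  mk <- rank_class_markers(bp$panel, "A", n_markers = 6)
  expect_identical(nrow(mk), 6L)
  expect_identical(sum(mk$direction == "hyper"), 3L)
  expect_identical(sum(mk$direction == "hypo"), 3L)
  expect_true(all(mk$probe %in% bp$blocks[[1]]))
})

test_that("a perfectly separating probe ranks first among hyper markers", {
  bp <- make_block_panel()
  betas <- bp$panel$betas
  # a probe at 1.0 in A with zero within-class variance, 0.0 elsewhere
  perfect <- matrix(rep(c(1, 0, 0), each = 4), 1, 12,
                    dimnames = list("cg_perfect", colnames(betas)))
  panel2 <- reference_panel(rbind(betas, perfect), bp$panel$labels)
  mk <- rank_class_markers(panel2, "A", n_markers = 6)
  expect_identical(mk$probe[mk$direction == "hyper"][1], "cg_perfect")
})

test_that("marker selection matches an exhaustive one-vs-rest ranking oracle", {
  bp <- make_block_panel(n_classes = 2, markers = 4, background = 22,
                         n_per_class = 4, noise = 0.05, seed = 3)
  panel <- bp$panel
  fit <- fit_moderated_model(
    panel$betas,
    factor(ifelse(panel$labels == "A", "focal", "rest"),
           levels = c("rest", "focal"))
  )
  tab <- fit$table[order(fit$table$p_value, -abs(fit$table$coef),
                         fit$table$probe), ]
  want_hyper <- head(tab$probe[tab$coef > 0], 5)
  want_hypo <- head(tab$probe[tab$coef < 0], 5)
  mk <- rank_class_markers(panel, "A", n_markers = 10)
  expect_identical(mk$probe[mk$direction == "hyper"], want_hyper)
  expect_identical(mk$probe[mk$direction == "hypo"], want_hypo)
})

test_that("marker errors: absent class, too many markers", {
  bp <- make_block_panel()
  expect_error(rank_class_markers(bp$panel, "Z"), "not in panel")
  expect_error(rank_class_markers(bp$panel, "A", n_markers = 1e5),
               "exceeds")
})

test_that("disjoint discriminative blocks give disjoint marker sets", {
  bp <- make_block_panel(n_classes = 4, markers = 8, background = 40,
                         noise = 0.005, seed = 8)
  sets <- lapply(LETTERS[1:4], function(cl) {
    rank_class_markers(bp$panel, cl, n_markers = 8)$probe
  })
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(sets[[i]], sets[[j]]), 0)
  }
})

test_that("layer library collects classes, markers and exact group means", {
  bp <- make_block_panel(n_classes = 3, markers = 6, background = 30)
  lib <- build_layer_library(
    bp$panel, tag = "TOY", focal_children = c("A", "B"),
    collapse_map = c(A = "A", B = "B", C = "Other"),
    n_markers = 6
  )
  expect_identical(lib$classes, c("A", "B", "Other"))
  expect_identical(sum(lib$markers$class == "A"), 6L)
  expect_identical(sum(lib$markers$class == "B"), 6L)
  # mean oracle: straight group-by-class averaging
  betas <- bp$panel$betas
  for (cl in c("A", "B")) {
    want <- rowMeans(betas[lib$probes, bp$panel$labels == cl, drop = FALSE])
    expect_lt(max(abs(lib$means[, cl] - want)), 1e-12)
  }
  want_other <- rowMeans(betas[lib$probes, bp$panel$labels == "C", drop = FALSE])
  expect_lt(max(abs(lib$means[, "Other"] - want_other)), 1e-12)
  # convex hull: per-probe class mean within [min, max] of its samples
  a_samples <- betas[lib$probes, bp$panel$labels == "A", drop = FALSE]
  expect_true(all(lib$means[, "A"] >= apply(a_samples, 1, min) - 1e-12))
  expect_true(all(lib$means[, "A"] <= apply(a_samples, 1, max) + 1e-12))
})

test_that("identical replicates collapse to their shared profile", {
  set.seed(44)
  probes <- sprintf("cg%03d", 1:40)
  prof_a <- setNames(runif(40), probes)
  prof_b <- setNames(runif(40), probes)
  betas <- cbind(a1 = prof_a, a2 = prof_a, a3 = prof_a,
                 b1 = prof_b, b2 = prof_b + 0.001, b3 = prof_b - 0.001)
  betas <- pmin(pmax(betas, 0), 1)
  panel <- reference_panel(betas, c(a1 = "A", a2 = "A", a3 = "A",
                                    b1 = "B", b2 = "B", b3 = "B"))
  lib <- build_layer_library(panel, "TOY", c("A", "B"),
                             c(A = "A", B = "B"), n_markers = 10)
  expect_equal(unname(lib$means[, "A"]),
               unname(betas[lib$probes, "a1"]), tolerance = 1e-15)
})

test_that("layer library errors on label mismatch and missing classes", {
  bp <- make_block_panel()
  expect_error(
    build_layer_library(bp$panel, "TOY", c("A", "Z"),
                        c(A = "A", B = "B", C = "Z2")),
    "no samples"
  )
})

test_that("bundle has 12 libraries across 6 layers and is deterministic", {
  b <- tiny_bundle()
  expect_identical(length(b$layers) + 1L, 12L)  # 11 layer libraries + L1
  expect_setequal(names(b$layers),
                  c("L2", "L3A", "L3B", "L4A", "L4B", "L5A", "L5B",
                    "L5C", "L5D", "L6A", "L6B"))
  expect_setequal(unique(b$tree$libraries$layer), 2:6)
  # class rosters follow the hierarchy (focal children + collapsed sibling)
  expect_setequal(b$layers$L2$classes, c("Immune", "Angiogenic", "Tumor"))
  expect_setequal(b$layers$L3A$classes,
                  c("Epithelial", "Endothelial", "Stromal", "Immune"))
  expect_setequal(b$layers$L5C$classes, c("Bnv", "Bmem", "NK_Tcell"))
  st <- tiny_study()
  b2 <- suppressWarnings(build_bundle(
    st$tumor, st$normal, st$panel, tumor_type = "TOY",
    n_top = 300, n_markers = 20, tree = st$config$tree
  ))
  expect_equal(b2$layers$L4B$means, b$layers$L4B$means, tolerance = 1e-15)
  expect_identical(b2$l1$entries$probe, b$l1$entries$probe)
})

test_that("bundle construction demands full terminal-class coverage", {
  st <- tiny_study()
  drop <- st$panel$labels != "Treg"
  panel <- reference_panel(st$panel$betas[, drop], st$panel$labels[drop])
  expect_error(
    build_bundle(st$tumor, st$normal, panel, tree = st$config$tree),
    "Treg"
  )
})
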