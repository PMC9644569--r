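# Shared small fixtures, built once per test run.

tiny_config <- function(seed = 7, ...) {
  simulation_config(
    n_probes = 2500, n_differential = 800, markers_per_class = 20,
    n_per_class = 3, n_tumor = 8, n_normal = 8, n_mixtures = 6,
    seed = seed, ...
  )
}

.fixture_env <- new.env(parent = emptyenv())

tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_tme_study(tiny_config())
  }
  .fixture_env$study
}

tiny_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    st <- tiny_study()
    .fixture_env$bundle <- suppressWarnings(build_bundle(
      st$tumor, st$normal, st$panel, tumor_type = "TOY",
      n_top = 300, n_markers = 20, tree = st$config$tree
    ))
  }
  .fixture_env$bundle
}

random_beta_matrix <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

make_toy_lib <- function(k = 3, p = 60, seed = 10, tag = "TOY") {
  set.seed(seed)
  means <- matrix(runif(p * k), p, k,
                  dimnames = list(sprintf("cg%03d", seq_len(p)),
                                  LETTERS[seq_len(k)]))
  structure(list(tag = tag, classes = colnames(means),
                 focal_children = colnames(means),
                 probes = rownames(means), means = means,
                 markers = NULL, n_markers = NA),
            class = "layer_library")
}

.rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

make_point_lib <- function(n = 1000) {
  structure(list(
    entries = tibble::tibble(
      probe = sprintf("p%04d", seq_len(n)),
      direction = rep(c("hyper", "hypo"), length.out = n),
      p_value = seq_len(n) * 1e-6, mean_diff = rep(c(0.5, -0.5), length.out = n)
    ),
    params = list(n_top = n, var_threshold = 0.005)
  ), class = "idmc_library")
}


# default-scale study (the generator's own defaults), built at most once
default_study <- function() {
  if (is.null(.fixture_env$default_study)) {
    .fixture_env$default_study <- simulate_tme_study(simulation_config(seed = 17))
  }
  .fixture_env$default_study
}

default_bundle <- function() {
  if (is.null(.fixture_env$default_bundle)) {
    st <- default_study()
    .fixture_env$default_bundle <- suppressWarnings(build_bundle(
      st$tumor, st$normal, st$panel, tumor_type = "synthetic",
      tree = st$config$tree
    ))
  }
  .fixture_env$default_bundle
}

heteroscedastic_matrix <- function(n_probes = 200, n = 8, d0_true = 5,
                                   seed = 21) {
  # per-probe noise scale drawn from a scaled inverse-chi-square, so the
  # empirical-Bayes prior has a finite, estimable d0
  set.seed(seed)
  sd_g <- pmin(0.02 * sqrt(d0_true / rchisq(n_probes, d0_true)), 0.1)
  mu <- runif(n_probes, 0.3, 0.7)
  delta <- runif(n_probes, -0.05, 0.05)
  m <- t(vapply(seq_len(n_probes), function(g) {
    mu[g] + c(rep(0, n / 2), rep(delta[g], n / 2)) + rnorm(n, 0, sd_g[g])
  }, numeric(n)))
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(sprintf("cg%04d", seq_len(n_probes)),
                      sprintf("s%02d", seq_len(n)))
  m
}

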