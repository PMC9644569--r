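# Independent oracles, written from the closed-form definitions.
# These never call the package functions they are used to check.

# ---- moderated-t: step-by-step transcription of the empirical-Bayes
# shrinkage formulas (scaled-F prior fitted by moments on log variances) ----

oracle_trigamma_inverse <- function(x) {
  # trigamma is monotone decreasing on (0, Inf)
  uniroot(function(y) trigamma(y) - x, lower = 1e-8, upper = 1e8,
          tol = 1e-12)$root
}

oracle_moderated_t <- function(betas, group) {
  group <- factor(group)
  D <- model.matrix(~ group)
  n <- ncol(betas)
  p <- ncol(D)
  dg <- n - p
  XtXi <- solve(crossprod(D))
  u <- sqrt(XtXi[2, 2])

  coef <- numeric(nrow(betas))
  s2 <- numeric(nrow(betas))
  for (g in seq_len(nrow(betas))) {
    y <- betas[g, ]
    bhat <- XtXi %*% crossprod(D, y)
    r <- y - D %*% bhat
    coef[g] <- bhat[2]
    s2[g] <- sum(r^2) / dg
  }

  # moment fit of log s2 to log scaled-F
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * oracle_trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  t <- coef / (u * sqrt(s2_post))
  list(coef = coef, s2 = s2, dg = dg, d0 = d0, s0_sq = s0_sq,
       s2_post = s2_post, t = t,
       p = 2 * pt(-abs(t), df = d0 + dg))
}

# ---- exhaustive simplex grid search for the constrained projection ----

oracle_simplex_grid <- function(k, step = 0.01) {
  n <- round(1 / step)
  if (k == 1) return(matrix(1, 1, 1))
  counts <- as.matrix(expand.grid(rep(list(0:n), k - 1)))
  keep <- rowSums(counts) <= n
  counts <- counts[keep, , drop = FALSE]
  W <- cbind(counts, n - rowSums(counts)) / n
  unname(W)
}

# best grid weights minimizing ||y - X w||^2 over the step-0.01 simplex
oracle_grid_projection <- function(y, X, step = 0.01) {
  W <- oracle_simplex_grid(ncol(X), step)
  Q <- crossprod(X)
  cvec <- drop(crossprod(X, y))
  obj <- rowSums((W %*% Q) * W) - 2 * drop(W %*% cvec)
  w <- W[which.min(obj), ]
  names(w) <- colnames(X)
  w
}

# ---- exact two-sided rank-sum p-value by enumeration of all label splits ----

oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled)) # tie-free toys only
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2 # Mann-Whitney U of x
  splits <- combn(nx + ny, nx)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# ---- hand evaluation of the percent error formulas ----

oracle_error_table <- function(pred, truth) {
  # pred/truth: numeric matrices samples x classes on [0,1]
  err <- (pred - truth) * 100
  list(
    mean_error = colMeans(err),
    mean_abs_error = colMeans(abs(err)),
    rmse = sqrt(colMeans(err^2)),
    overall_mean_abs = mean(abs(err))
  )
}

# ---- independent hierarchical cascade using the grid-search projection ----
# Walks the bundle's tree with exhaustive grid projections; shares only the
# layer-1 purity estimates (the quantity under test is the QP cascade).

oracle_cascade <- function(mix, bundle, purity, step = 0.01) {
  tree <- bundle$tree
  defs <- tree$libraries
  out <- lapply(colnames(mix), function(s) {
    y <- mix[, s]
    p <- purity$purity[purity$sample_id == s]
    mass <- c(Tumor = p, Nontumor = 1 - p)
    for (i in seq_len(nrow(defs))) {
      def <- defs[i, ]
      lib <- bundle$layers[[def$tag]]
      shared <- intersect(rownames(lib$means), names(y))
      w <- oracle_grid_projection(y[shared], lib$means[shared, , drop = FALSE],
                                  step = step)
      kids <- def$children[[1]]
      wf <- w[kids]
      rel <- if (sum(wf) > 0) wf / sum(wf) else rep(1 / length(wf), length(wf))
      mass[kids] <- rel * mass[[def$parent]]
    }
    mass
  })
  leaves <- tree$leaves
  m <- do.call(rbind, lapply(out, function(x) x[leaves]))
  tibble::as_tibble(m) |>
    dplyr::mutate(sample_id = colnames(mix), .before = 1)
}
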