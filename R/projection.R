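#' Constrained projection of a mixture profile onto library class means
#'
#' Solves the constrained-projection quadratic program of reference-based
#' deconvolution: minimize `||y - X w||^2` subject to `w >= 0` and
#' `sum(w) = 1`, where `X` is the library's probe-by-class mean-beta matrix
#' restricted to the probes present (non-missing) in `y`. Computation is on
#' the beta scale.
#'
#' The solver enumerates candidate supports exactly for up to 12 classes
#' (each support's equality-constrained least-squares problem is solved via
#' its KKT system; the feasible candidate with the smallest objective is the
#' global optimum of this convex program), and falls back to a primal
#' active-set iteration for larger class counts. Rank-deficient `X` is
#' handled by a tiny ridge on the KKT system with a collinearity warning.
#' Sub-`1e-10` negative round-off weights are clipped to zero and the vector
#' renormalized.
#'
#' With `sum_to_one = FALSE` the equality constraint is relaxed to
#' `sum(w) <= 1` (for comparison only; the cascade renormalizes within each
#' parent anyway).
#'
#' @param y Named numeric vector: one bulk sample's beta values by probe.
#' @param lib A `layer_library` (or any list with `means` probe x class
#'   matrix).
#' @param sum_to_one Keep the equality constraint (default `TRUE`).
#' @return Object of class `projection_result`: list with `weights` (named,
#'   non-negative, summing to 1), `residual_norm`, `n_probes_used`,
#'   `low_coverage`, `collinear`.
#' @export
constrained_projection <- function(y, lib, sum_to_one = TRUE) {
  X <- lib$means
  if (is.null(names(y))) abort("y must be named by probe")
  shared <- intersect(rownames(X), names(y))
  yv <- y[shared]
  keep <- !is.na(yv)
  shared <- shared[keep]
  yv <- as.numeric(yv[keep])
  X <- X[shared, , drop = FALSE]
  k <- ncol(X)
  if (length(shared) < max(10, k + 5)) {
    abort(sprintf("only %d library probes available (need >= %d)",
                  length(shared), max(10, k + 5)))
  }
  low_cov <- length(shared) < 0.5 * nrow(lib$means)
  if (low_cov) {
    warn(sprintf("projection uses %d of %d library probes",
                 length(shared), nrow(lib$means)))
  }

  Q <- crossprod(X)
  cvec <- drop(crossprod(X, yv))
  sol <- .solve_simplex_qp(Q, cvec, equality = sum_to_one)
  w <- sol$w
  w[w < 0] <- 0
  if (sum_to_one) w <- w / sum(w)
  names(w) <- colnames(X)
  rnorm <- sqrt(max(0, sum(yv^2) - 2 * sum(cvec * sol$w) +
                      drop(crossprod(sol$w, Q %*% sol$w))))
  structure(
    list(weights = w, residual_norm = rnorm,
         n_probes_used = length(shared),
         low_coverage = low_cov, collinear = sol$collinear),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result> residual = ", format(x$residual_norm, digits = 4),
      ", ", x$n_probes_used, " probes\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

# minimize 1/2 w'Qw - c'w  s.t.  w >= 0  and (if equality) 1'w = 1
.solve_simplex_qp <- function(Q, cvec, equality = TRUE) {
  k <- length(cvec)
  collinear <- FALSE

  solve_support <- function(S, equality) {
    # equality-constrained LS on support S (w_i = 0 off-support)
    m <- length(S)
    if (equality) {
      A <- rbind(cbind(Q[S, S, drop = FALSE], rep(1, m)),
                 c(rep(1, m), 0))
      b <- c(cvec[S], 1)
    } else {
      A <- Q[S, S, drop = FALSE]
      b <- cvec[S]
    }
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) {
      collinear <<- TRUE
      ridge <- diag(nrow(A)) * (1e-10 * max(1, mean(diag(Q))))
      if (equality) ridge[nrow(A), nrow(A)] <- 0
      sol <- tryCatch(solve(A + ridge, b), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
    }
    w <- numeric(k)
    w[S] <- sol[seq_len(m)]
    w
  }

  objective <- function(w) 0.5 * drop(crossprod(w, Q %*% w)) - sum(cvec * w)

  if (k <= 12) {
    best <- NULL
    best_obj <- Inf
    consider <- function(w) {
      if (is.null(w) || any(w < -1e-10)) return(invisible())
      if (!equality && sum(w) > 1 + 1e-10) return(invisible())
      obj <- objective(pmax(w, 0))
      if (obj < best_obj - 1e-12) {
        best_obj <<- obj
        best <<- w
      }
      invisible()
    }
    if (!equality) consider(numeric(k))
    for (code in seq_len(2^k - 1)) {
      S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
      consider(solve_support(S, equality = TRUE))
      # for the <=1 variant the optimum may sit strictly inside the simplex
      if (!equality) consider(solve_support(S, equality = FALSE))
    }
    if (is.null(best)) abort("QP solver failed on every support")
    if (collinear) warn("collinear library classes; ridge-regularized solve")
    return(list(w = pmax(best, 0), collinear = collinear))
  }

  # active-set iteration for large k
  S <- seq_len(k)
  for (iter in seq_len(100 * k)) {
    w <- solve_support(S, equality = equality)
    if (is.null(w)) abort("QP solver failed (singular KKT system)")
    if (min(w[S]) < -1e-10) {
      S <- setdiff(S, S[which.min(w[S])])
      if (length(S) == 0) abort("QP active set emptied")
      next
    }
    grad <- drop(Q %*% pmax(w, 0)) - cvec
    mu <- if (equality) -mean(grad[S]) else 0
    lambda <- grad + mu
    out <- setdiff(seq_len(k), S)
    if (length(out) == 0 || min(lambda[out]) > -1e-9) {
      if (collinear) warn("collinear library classes; ridge-regularized solve")
      return(list(w = pmax(w, 0), collinear = collinear))
    }
    S <- sort(c(S, out[which.min(lambda[out])]))
  }
  abort("QP active-set iteration did not converge")
}
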