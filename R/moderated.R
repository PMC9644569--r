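#' Per-CpG moderated linear model (empirical-Bayes variance shrinkage)
#'
#' Fits an ordinary least-squares linear model per probe for a two-group
#' contrast (optionally adjusted for covariates), then shrinks the per-probe
#' residual variances toward a common prior fitted by the standard
#' method-of-moments on log residual variances (a scaled-F prior with
#' hyperparameters `d0`, `s0^2`). The moderated t statistic for probe *g* is
#' `t_g = coef_g / (u * s_tilde_g)` with posterior variance
#' `s_tilde_g^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, on `d0 + d_g`
#' degrees of freedom (`u` is the unscaled coefficient standard error).
#' The fit is delegated to limma.
#'
#' @param betas Beta matrix (probes x samples).
#' @param group Two-level factor (or coercible) over the samples; the reported
#'   coefficient is the second level minus the first, on the beta scale.
#' @param covariates Optional data frame of per-sample adjustment covariates
#'   (rows aligned to `colnames(betas)`).
#' @param d0_override Optional prior degrees of freedom to force instead of
#'   the estimated `d0` (use `0` for ordinary t statistics, `Inf` for full
#'   shrinkage to `s0^2`). The prior variance `s0^2` keeps its estimated value.
#' @return Object of class `moderated_fit`: list with `table` (tibble: `probe`,
#'   `coef`, `s2` residual variance, `df_residual`, `s2_post`, `t`, `p_value`),
#'   `d0`, `s0_sq`, `stdev_unscaled` (common coefficient standard-error
#'   factor), and `zero_variance` flag.
#' @examples
#' m <- matrix(runif(200), 20, 10,
#'             dimnames = list(paste0("cg", 1:20), paste0("s", 1:10)))
#' fit <- fit_moderated_model(m, rep(c("a", "b"), each = 5))
#' head(fit$table)
#' @export
fit_moderated_model <- function(betas, group, covariates = NULL,
                                d0_override = NULL) {
  betas <- beta_matrix(betas)
  group <- factor(group)
  if (nlevels(group) != 2) abort("group must have exactly 2 levels")
  if (length(group) != ncol(betas)) abort("group length != number of samples")
  if (min(table(group)) < 2) abort("need >= 2 samples per group")
  df <- data.frame(.group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(betas)) abort("covariate rows != samples")
    df <- cbind(df, covariates)
  }
  design <- model.matrix(~ ., data = df)
  resid_df <- ncol(betas) - ncol(design)
  if (resid_df < 1) abort("zero residual degrees of freedom")

  fit <- limma::lmFit(betas, design)
  s2 <- fit$sigma^2
  zero_var <- all(s2 < 1e-24)
  if (zero_var) {
    warn("all residual variances are zero; moderated t undefined")
    tab <- tibble::tibble(
      probe = rownames(betas),
      coef = fit$coefficients[, 2],
      s2 = s2,
      df_residual = fit$df.residual,
      s2_post = 0,
      t = NA_real_,
      p_value = NA_real_
    )
    return(structure(
      list(table = tab, d0 = NA_real_, s0_sq = NA_real_,
           stdev_unscaled = fit$stdev.unscaled[1, 2],
           zero_variance = TRUE),
      class = "moderated_fit"
    ))
  }

  eb <- limma::eBayes(fit)
  d0 <- eb$df.prior[1]
  s0_sq <- eb$s2.prior[1]
  dg <- fit$df.residual
  if (!is.null(d0_override)) {
    d0 <- d0_override
    if (is.infinite(d0)) {
      s2_post <- rep(s0_sq, length(s2))
    } else {
      s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    }
    u <- fit$stdev.unscaled[, 2]
    tstat <- fit$coefficients[, 2] / (u * sqrt(s2_post))
    dft <- d0 + dg
    pval <- 2 * pt(-abs(tstat), df = dft)
  } else {
    s2_post <- eb$s2.post
    tstat <- eb$t[, 2]
    pval <- eb$p.value[, 2]
  }

  tab <- tibble::tibble(
    probe = rownames(betas),
    coef = fit$coefficients[, 2],
    s2 = s2,
    df_residual = dg,
    s2_post = s2_post,
    t = tstat,
    p_value = pval
  )
  structure(
    list(table = tab, d0 = d0, s0_sq = s0_sq,
         stdev_unscaled = fit$stdev.unscaled[1, 2],
         zero_variance = FALSE),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit> ", nrow(x$table), " probes; d0 = ",
      format(x$d0, digits = 4), ", s0^2 = ",
      format(x$s0_sq, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_moderated_model
#' @param x A `moderated_fit` object.
#' @param ... Unused.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname fit_moderated_model
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$table),
    d0 = x$d0,
    s0_sq = x$s0_sq,
    zero_variance = x$zero_variance
  )
}
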