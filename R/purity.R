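#' Select informative differentially methylated CpGs (iDMCs)
#'
#' Builds the layer-1 tumor-purity library from tumor and matched-normal
#' training beta matrices. Candidate probes are those shared by both matrices
#' whose beta variance across *tumor* samples exceeds `var_threshold`
#' (unbiased, n-1 denominator). Candidates are ranked by two-sided
#' Wilcoxon rank-sum p-value (tumor vs normal) and the top `n_top` kept.
#' Each selected probe is tagged `hyper` when its mean tumor beta exceeds the
#' mean normal beta, `hypo` otherwise. Ties in p are broken by larger absolute
#' tumor-normal mean difference, then probe ID, so the library is a
#' deterministic function of its inputs.
#'
#' @param tumor,normal Beta matrices (probes x samples), >= 2 samples each.
#' @param n_top Number of probes to keep (default 1000). If fewer candidates
#'   survive the variance filter, all are kept with a warning.
#' @param var_threshold Minimum tumor-sample beta variance (default 0.005).
#' @return Object of class `idmc_library`: list with `entries` (tibble
#'   `probe`, `direction`, `p_value`, `mean_diff`) and `params`.
#' @export
select_idmc <- function(tumor, normal, n_top = 1000, var_threshold = 0.005) {
  tumor <- beta_matrix(tumor)
  normal <- beta_matrix(normal)
  if (ncol(tumor) < 2 || ncol(normal) < 2) {
    abort("need >= 2 tumor and >= 2 normal samples")
  }
  shared <- intersect(rownames(tumor), rownames(normal))
  if (length(shared) == 0) abort("no shared probes between tumor and normal")
  tu <- tumor[shared, , drop = FALSE]
  no <- normal[shared, , drop = FALSE]

  tvar <- apply(tu, 1, var)
  cand <- which(!is.na(tvar) & tvar > var_threshold)
  if (length(cand) == 0) {
    abort(sprintf("zero candidates: no probe has tumor beta variance > %g",
                  var_threshold))
  }
  tu <- tu[cand, , drop = FALSE]
  no <- no[cand, , drop = FALSE]

  exact <- min(ncol(tu), ncol(no)) <= 10
  pv <- vapply(seq_len(nrow(tu)), function(i) {
    x <- tu[i, ]
    y <- no[i, ]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
    )
  }, 1)
  mdiff <- rowMeans(tu, na.rm = TRUE) - rowMeans(no, na.rm = TRUE)

  ok <- !is.na(pv)
  tab <- tibble::tibble(
    probe = rownames(tu)[ok],
    p_value = pv[ok],
    mean_diff = unname(mdiff)[ok]
  )
  tab <- tab[order(tab$p_value, -abs(tab$mean_diff), tab$probe), ]
  if (nrow(tab) < n_top) {
    warn(sprintf("only %d candidates pass the variance filter (requested %d)",
                 nrow(tab), n_top))
  }
  tab <- head(tab, n_top)
  tab$direction <- ifelse(tab$mean_diff > 0, "hyper", "hypo")
  structure(
    list(
      entries = tab[, c("probe", "direction", "p_value", "mean_diff")],
      params = list(n_top = n_top, var_threshold = var_threshold)
    ),
    class = "idmc_library"
  )
}

#' @export
print.idmc_library <- function(x, ...) {
  cat("<idmc_library> ", nrow(x$entries), " iDMCs (",
      sum(x$entries$direction == "hyper"), " hyper, ",
      sum(x$entries$direction == "hypo"), " hypo); n_top = ",
      x$params$n_top, ", var_threshold = ", x$params$var_threshold,
      "\n", sep = "")
  invisible(x)
}

#' Direction-transform beta values over an iDMC library
#'
#' Hypermethylated iDMC beta values are kept as-is; hypomethylated iDMC beta
#' values are flipped to `1 - beta`, so that in both cases larger values mean
#' more tumor. Probes absent from `sample_betas` are skipped.
#'
#' @param sample_betas Named numeric vector of beta values for one sample.
#' @param lib An `idmc_library` from [select_idmc()].
#' @return Named numeric vector (one entry per available library probe),
#'   values in `[0, 1]`.
#' @export
transform_idmc_betas <- function(sample_betas, lib) {
  stopifnot(inherits(lib, "idmc_library"))
  if (is.null(names(sample_betas))) abort("sample_betas must be named by probe")
  ent <- lib$entries
  have <- ent$probe %in% names(sample_betas)
  ent <- ent[have, ]
  b <- sample_betas[ent$probe]
  keep <- !is.na(b)
  ent <- ent[keep, ]
  b <- b[keep]
  out <- ifelse(ent$direction == "hypo", 1 - b, b)
  pmin(pmax(out, 0), 1)
}

#' Estimate tumor purity for one sample
#'
#' Applies [transform_idmc_betas()], then estimates a Gaussian-kernel density
#' of the transformed values on a closed grid over `[0, 1]` and reports the
#' grid argmax of the density as the purity. Bandwidth is Silverman's rule of
#' thumb; when the transformed values are (near-)constant the bandwidth falls
#' back to `grid_step` so the mode is still the point mass. Mode ties resolve
#' to the lowest grid value; a `multimodal` flag is set when a second local
#' maximum reaches 95% of the global maximum.
#'
#' @param sample_betas Named numeric vector of beta values for one sample.
#' @param lib An `idmc_library`.
#' @param grid_step Grid resolution on `[0, 1]` (default 0.001).
#' @param bw Optional fixed kernel bandwidth (default: Silverman).
#' @return Object of class `purity_estimate`: list with `purity`,
#'   `n_probes_used`, `multimodal`, `low_coverage` (under half the library
#'   available) and `density` (tibble `x`, `y` for diagnostics).
#' @export
estimate_purity <- function(sample_betas, lib, grid_step = 0.001, bw = NULL) {
  v <- transform_idmc_betas(sample_betas, lib)
  if (length(v) < 10) {
    abort(sprintf("only %d usable iDMC probes (need >= 10)", length(v)))
  }
  low_cov <- length(v) < 0.5 * nrow(lib$entries)
  if (low_cov) {
    warn(sprintf("only %d of %d library probes available",
                 length(v), nrow(lib$entries)))
  }
  if (is.null(bw)) {
    bw <- stats::bw.nrd0(v)
    if (!is.finite(bw) || bw <= 0) bw <- grid_step
  }
  n_grid <- round(1 / grid_step) + 1L
  den <- density(v, bw = bw, kernel = "gaussian",
                 from = 0, to = 1, n = n_grid)
  ymax <- max(den$y)
  mode_idx <- which(den$y == ymax)[1]

  # local maxima for the multi-modality flag
  y <- den$y
  loc <- which(diff(sign(diff(y))) < 0) + 1L
  loc <- union(loc, mode_idx)
  second <- sort(y[loc], decreasing = TRUE)
  multimodal <- length(second) >= 2 && second[2] >= 0.95 * ymax

  structure(
    list(
      purity = den$x[mode_idx],
      n_probes_used = length(v),
      multimodal = multimodal,
      low_coverage = low_cov,
      bw = bw,
      density = tibble::tibble(x = den$x, y = den$y)
    ),
    class = "purity_estimate"
  )
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat("<purity_estimate> purity = ", format(x$purity, digits = 4),
      " (", x$n_probes_used, " probes",
      if (x$multimodal) ", multimodal" else "", ")\n", sep = "")
  invisible(x)
}

#' Tumor purity for every column of a beta matrix
#'
#' @param betas Beta matrix of bulk samples.
#' @inheritParams estimate_purity
#' @return Tibble with columns `sample_id`, `purity`, `n_probes_used`,
#'   `multimodal`.
#' @export
purity_table <- function(betas, lib, grid_step = 0.001, bw = NULL) {
  betas <- beta_matrix(betas)
  purrr::map_dfr(colnames(betas), function(s) {
    est <- estimate_purity(betas[, s], lib, grid_step = grid_step, bw = bw)
    tibble::tibble(
      sample_id = s,
      purity = est$purity,
      n_probes_used = est$n_probes_used,
      multimodal = est$multimodal
    )
  })
}

#' @rdname estimate_purity
#' @param object A `purity_estimate`.
#' @param ... Unused.
#' @method autoplot purity_estimate
#' @export
autoplot.purity_estimate <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$purity, linetype = "dashed") +
    ggplot2::labs(
      x = "transformed iDMC beta", y = "density",
      title = sprintf("Tumor purity = %.3f", object$purity)
    ) +
    ggplot2::theme_minimal()
}
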