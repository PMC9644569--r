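#' Recovery metrics for predicted vs true cell proportions
#'
#' Scores a predicted proportion table against ground truth on the percent
#' scale: per class across samples, the signed error
#' `predicted(%) - true(%)`, its absolute value, the RMSE, and the Pearson
#' correlation (with p-value, descriptive only). The overall summary pools
#' the absolute error over every class x sample cell. Correlation is flagged
#' undefined (`NA`), not zero, when either vector is constant.
#'
#' @param pred,truth Proportion tables: data frames with `sample_id` plus one
#'   numeric column per class, on the `[0, 1]` scale. Must cover the same
#'   samples and classes (any order).
#' @return Object of class `tme_recovery`: list with `by_class` (tibble
#'   `class`, `mean_error_pct`, `mean_abs_error_pct`, `rmse_pct`,
#'   `pearson_r`, `pearson_p`, `n`), `overall` (one-row tibble
#'   `mean_abs_error_pct`, `sd_abs_error_pct`, `rmse_pct`, `n_cells`), and
#'   `cells` (long per-cell tibble for plotting).
#' @export
error_metrics <- function(pred, truth) {
  pred <- tibble::as_tibble(pred)
  truth <- tibble::as_tibble(truth)
  for (nm in c("pred", "truth")) {
    tab <- get(nm)
    if (!"sample_id" %in% names(tab)) {
      abort(paste0(nm, " needs a sample_id column"))
    }
  }
  pred$layer <- NULL
  truth$layer <- NULL
  p_cls <- setdiff(names(pred), "sample_id")
  t_cls <- setdiff(names(truth), "sample_id")
  if (!setequal(p_cls, t_cls)) {
    abort(paste0(
      "class mismatch; pred-only: ",
      paste(setdiff(p_cls, t_cls), collapse = ", "),
      "; truth-only: ",
      paste(setdiff(t_cls, p_cls), collapse = ", ")
    ))
  }
  if (!setequal(pred$sample_id, truth$sample_id) ||
      nrow(pred) != nrow(truth)) {
    abort(paste0(
      "sample mismatch; pred-only: ",
      paste(setdiff(pred$sample_id, truth$sample_id), collapse = ", "),
      "; truth-only: ",
      paste(setdiff(truth$sample_id, pred$sample_id), collapse = ", ")
    ))
  }
  truth <- truth[match(pred$sample_id, truth$sample_id), ]
  classes <- p_cls

  cells <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      sample_id = pred$sample_id,
      class = cl,
      predicted_pct = 100 * pred[[cl]],
      true_pct = 100 * truth[[cl]]
    )
  })
  cells$error_pct <- cells$predicted_pct - cells$true_pct

  by_class <- cells |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      mean_error_pct = mean(.data$error_pct),
      mean_abs_error_pct = mean(abs(.data$error_pct)),
      rmse_pct = sqrt(mean(.data$error_pct^2)),
      pearson_r = .safe_cor(.data$predicted_pct, .data$true_pct),
      pearson_p = .safe_cor_p(.data$predicted_pct, .data$true_pct),
      n = dplyr::n(),
      .groups = "drop"
    )
  by_class <- by_class[match(classes, by_class$class), ]

  overall <- tibble::tibble(
    mean_abs_error_pct = mean(abs(cells$error_pct)),
    sd_abs_error_pct = sd(abs(cells$error_pct)),
    rmse_pct = sqrt(mean(cells$error_pct^2)),
    n_cells = nrow(cells)
  )
  structure(
    list(by_class = by_class, overall = overall, cells = cells),
    class = "tme_recovery"
  )
}

.safe_cor <- function(x, y) {
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

.safe_cor_p <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor.test(x, y)$p.value
}

#' @export
print.tme_recovery <- function(x, ...) {
  cat("<tme_recovery> ", nrow(x$by_class), " classes, ",
      x$overall$n_cells, " cells; overall mean |error| = ",
      format(x$overall$mean_abs_error_pct, digits = 3), "%\n", sep = "")
  print(x$by_class)
  invisible(x)
}

#' @rdname error_metrics
#' @param x,object A `tme_recovery`.
#' @param ... Unused.
#' @method tidy tme_recovery
#' @export
tidy.tme_recovery <- function(x, ...) x$by_class

#' @rdname error_metrics
#' @method glance tme_recovery
#' @export
glance.tme_recovery <- function(x, ...) x$overall

#' @rdname error_metrics
#' @method autoplot tme_recovery
#' @export
autoplot.tme_recovery <- function(object, ...) {
  ggplot2::ggplot(object$cells, ggplot2::aes(
    x = .data$true_pct, y = .data$predicted_pct
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::labs(x = "true proportion (%)", y = "predicted proportion (%)") +
    ggplot2::theme_minimal()
}

#' Deconvolve a fixture cohort and score it against its ground truth
#'
#' Runs [deconvolve()] on a mixtures beta matrix, aggregates the ground-truth
#' terminal proportions to layer `h` via the bundle's hierarchy, and computes
#' [error_metrics()]. Optionally writes the per-class report as CSV.
#'
#' @param mix Beta matrix of mixtures (or path to one).
#' @param truth Ground-truth tibble (`sample_id` + terminal-class columns) or
#'   path to its CSV.
#' @param bundle A `library_bundle` or path to a bundle directory.
#' @param h Layer at which to score (default 6).
#' @param out Optional CSV path for the per-class table.
#' @return A `tme_recovery` (with the `tme_deconvolution` attached as
#'   attribute `"deconvolution"`).
#' @export
recovery_report <- function(mix, truth, bundle, h = 6, out = NULL) {
  if (is.character(mix)) mix <- read_beta_matrix(mix)
  if (is.character(truth)) {
    truth <- readr::read_csv(truth, col_types = readr::cols(
      sample_id = readr::col_character(), .default = readr::col_double()
    ), progress = FALSE)
  }
  if (is.character(bundle)) bundle <- load_library_bundle(bundle)
  res <- deconvolve(mix, bundle, h = h)
  pred <- proportions_at(res, h)
  truth_h <- aggregate_truth(truth, bundle$tree, h)
  rep <- error_metrics(pred, truth_h)
  attr(rep, "deconvolution") <- res
  if (!is.null(out)) readr::write_csv(rep$by_class, out, progress = FALSE)
  rep
}

#' Aggregate terminal-class ground truth to a layer
#'
#' @param truth Tibble `sample_id` + one column per terminal class.
#' @param tree A [tme_hierarchy()].
#' @param h Target layer.
#' @return Tibble `sample_id` + one column per layer-`h` class.
#' @export
aggregate_truth <- function(truth, tree, h) {
  truth <- tibble::as_tibble(truth)
  classes <- hierarchy_classes(tree, h)
  out <- tibble::tibble(sample_id = truth$sample_id)
  leaf_cols <- setdiff(names(truth), "sample_id")
  for (cl in classes) {
    members <- intersect(c(cl, .descendants(tree, cl)), leaf_cols)
    if (length(members) == 0) {
      abort(paste0("truth lacks columns for class ", cl))
    }
    out[[cl]] <- rowSums(truth[, members, drop = FALSE])
  }
  out
}
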