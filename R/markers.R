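#' Rank cell-class-specific hyper- and hypo-methylated marker CpGs
#'
#' One-vs-rest moderated model ([fit_moderated_model()]) for `class_name`
#' against all other samples in the panel; returns the top `n_markers / 2`
#' hypermethylated (positive focal-minus-rest coefficient) and `n_markers / 2`
#' hypomethylated probes, each side ranked by moderated p-value ascending
#' (ties: larger absolute coefficient, then probe ID). If one side runs
#' short, the other side backfills with a warning so the total stays
#' `n_markers`.
#'
#' @param panel A [reference_panel()].
#' @param class_name Focal cell class.
#' @param n_markers Total markers for the class (default 100, i.e. 50 + 50).
#' @return Tibble `probe`, `direction` (`"hyper"`/`"hypo"`), `p_value`,
#'   `coef`, ordered hyper block then hypo block.
#' @export
rank_class_markers <- function(panel, class_name, n_markers = 100) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!class_name %in% panel$labels) {
    abort(paste0("class not in panel: ", class_name))
  }
  if (length(unique(panel$labels)) < 2) abort("panel needs >= 2 classes")
  if (sum(panel$labels == class_name) < 2) {
    abort(paste0("class needs >= 2 samples: ", class_name))
  }
  if (n_markers > nrow(panel$betas)) {
    abort(sprintf("n_markers (%d) exceeds available probes (%d)",
                  n_markers, nrow(panel$betas)))
  }
  group <- factor(ifelse(panel$labels == class_name, "focal", "rest"),
                  levels = c("rest", "focal"))
  fit <- fit_moderated_model(panel$betas, group)
  tab <- fit$table
  tab <- tab[order(tab$p_value, -abs(tab$coef), tab$probe), ]

  n_half <- ceiling(n_markers / 2)
  hyper <- tab[tab$coef > 0, ]
  hypo <- tab[tab$coef < 0, ]
  n_hyper <- min(n_half, nrow(hyper))
  n_hypo <- min(n_markers - n_hyper, nrow(hypo))
  if (n_hyper + n_hypo < n_markers) {
    # hypo side ran short: backfill from hyper
    n_hyper <- min(n_markers - n_hypo, nrow(hyper))
  }
  if (n_hyper + n_hypo < n_markers) {
    abort(sprintf(
      "cannot select %d markers for %s: only %d probes with nonzero contrast",
      n_markers, class_name, nrow(hyper) + nrow(hypo)
    ))
  }
  if (n_hyper != n_half || n_hypo != n_markers - n_half) {
    warn(sprintf(
      "%s: unbalanced marker sides (%d hyper, %d hypo)",
      class_name, n_hyper, n_hypo
    ))
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(head(hyper, n_hyper), direction = "hyper"),
    dplyr::mutate(head(hypo, n_hypo), direction = "hypo")
  )
  out[, c("probe", "direction", "p_value", "coef")]
}

#' Build one layer library
#'
#' Relabels the panel per `collapse_map` (samples whose class is not a key of
#' the map are dropped), ranks `n_markers` markers for every resulting class
#' (focal children and collapsed sibling groups alike, so the constrained
#' projection can see all of them), deduplicates the probe union, and stores
#' per-class mean beta values over the selected probes.
#'
#' @param panel A [reference_panel()] labeled with terminal classes.
#' @param tag Library tag, e.g. `"L3A"`.
#' @param focal_children Class names the library is meant to separate (must
#'   be among the collapsed class names).
#' @param collapse_map Named character vector: original class -> library
#'   class. Classes absent from the map are excluded from the fit.
#' @param n_markers Markers per class (default 100).
#' @return Object of class `layer_library`: list with `tag`, `classes`
#'   (focal children first), `focal_children`, `probes`, `means` (probe x
#'   class matrix), `markers` (tibble `class`, `probe`, `direction`,
#'   `p_value`, `coef`, `rank`).
#' @export
build_layer_library <- function(panel, tag, focal_children, collapse_map,
                                n_markers = 100) {
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(names(collapse_map))) abort("collapse_map must be named")
  if (anyDuplicated(names(collapse_map))) abort("duplicate collapse_map keys")
  keep <- panel$labels %in% names(collapse_map)
  if (!any(keep)) abort("collapse_map matches no panel samples")
  betas <- panel$betas[, keep, drop = FALSE]
  labels <- unname(collapse_map[panel$labels[keep]])
  classes <- unique(c(focal_children, unname(collapse_map)))
  missing_cls <- setdiff(classes, labels)
  if (length(missing_cls) > 0) {
    abort(paste0("no samples for library class: ",
                 paste(missing_cls, collapse = ", ")))
  }
  few <- names(which(table(labels) < 2))
  if (length(few) > 0) {
    abort(paste0("library class needs >= 2 samples: ",
                 paste(few, collapse = ", ")))
  }
  sub <- reference_panel(betas, setNames(labels, colnames(betas)))

  markers <- purrr::map_dfr(classes, function(cl) {
    mk <- rank_class_markers(sub, cl, n_markers = n_markers)
    mk$class <- cl
    mk$rank <- seq_len(nrow(mk))
    mk
  })
  probes <- unique(markers$probe)
  means <- vapply(classes, function(cl) {
    rowMeans(betas[probes, labels == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(length(probes)))
  means <- matrix(means, nrow = length(probes),
                  dimnames = list(probes, classes))

  structure(
    list(tag = tag, classes = classes, focal_children = focal_children,
         probes = probes, means = means,
         markers = markers[, c("class", "probe", "direction",
                               "p_value", "coef", "rank")],
         n_markers = n_markers),
    class = "layer_library"
  )
}

#' @export
print.layer_library <- function(x, ...) {
  cat("<layer_library ", x$tag, "> ", length(x$probes), " probes x ",
      length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
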