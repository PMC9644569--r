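#' Split one parent's mass among its children with one layer library
#'
#' Runs [constrained_projection()] of the sample onto the library, keeps the
#' focal children's weights, renormalizes them among themselves, and scales
#' by the parent's absolute mass. Collapsed (non-focal) class weights exist
#' only to absorb off-target signal and are discarded. If every focal weight
#' is zero the parent mass is split equally among the children with a
#' warning (mass conservation without inventing signal).
#'
#' @param y Named numeric vector of one sample's beta values.
#' @param lib A `layer_library`.
#' @param focal_children Classes to receive mass (default: the library's
#'   own focal children).
#' @param parent_mass Absolute mass of the parent node, in `[0, 1]`.
#' @return Named numeric vector of absolute fractions, one per focal child,
#'   summing to `parent_mass`.
#' @export
deconvolve_layer <- function(y, lib, focal_children = lib$focal_children,
                             parent_mass) {
  stopifnot(parent_mass >= 0, parent_mass <= 1 + 1e-9)
  pr <- constrained_projection(y, lib)
  miss <- setdiff(focal_children, names(pr$weights))
  if (length(miss) > 0) {
    abort(paste0("library lacks focal classes: ", paste(miss, collapse = ", ")))
  }
  wf <- pr$weights[focal_children]
  s <- sum(wf)
  if (s <= 0) {
    warn(sprintf("all focal weights zero in %s; splitting parent mass equally",
                 lib$tag %||% "library"))
    rel <- rep(1 / length(wf), length(wf))
  } else {
    rel <- wf / s
  }
  out <- rel * parent_mass
  names(out) <- focal_children
  out
}

#' Hierarchical tumor-microenvironment deconvolution
#'
#' The full cascade. Layer 1 estimates per-sample tumor purity as the mode of
#' the Gaussian-kernel density over direction-transformed iDMC beta values;
#' the non-tumor mass is `1 - purity`. Layer 2 splits the non-tumor mass
#' between the immune and angiogenic compartments by constrained projection
#' (the L2 library's own tumor weight is discarded: tumor mass comes
#' exclusively from layer 1). Layers 3-6 recursively split each node's mass
#' among its children with the node's library, so children always sum
#' exactly to their parent; classes with no further sub-library are carried
#' forward unchanged.
#'
#' @param mix Beta matrix of bulk samples to deconvolve.
#' @param bundle A `library_bundle` ([build_bundle()] or
#'   [load_library_bundle()]).
#' @param h Deepest layer to resolve, integer 1..6 (6 resolves all 17
#'   terminal classes).
#' @return Object of class `tme_deconvolution`: list with
#'   `proportions` (long tibble `sample_id`, `layer`, `class`, `proportion`;
#'   layers 1..h, each sample-layer row set sums to 1), `purity` (tibble from
#'   [purity_table()]), `h`, `tumor_type`, and `warnings` (character).
#' @examples
#' \dontrun{
#' res <- deconvolve(mix, bundle, h = 6)
#' tidy(res)
#' proportions_at(res, 6)
#' }
#' @export
deconvolve <- function(mix, bundle, h = 6) {
  stopifnot(inherits(bundle, "library_bundle"))
  if (!(length(h) == 1 && h %in% 1:6)) abort("h must be an integer in 1..6")
  mix <- beta_matrix(mix)
  tree <- bundle$tree
  msgs <- character(0)

  pur <- withCallingHandlers(
    purity_table(mix, bundle$l1),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  lib_defs <- tree$libraries
  lib_defs <- lib_defs[lib_defs$layer <= h, , drop = FALSE]

  rows <- purrr::map_dfr(colnames(mix), function(s) {
    y <- mix[, s]
    mass <- c(Tumor = pur$purity[pur$sample_id == s],
              Nontumor = 1 - pur$purity[pur$sample_id == s])
    # walk libraries in layer order; every parent's mass is known before
    # its library runs
    for (i in seq_len(nrow(lib_defs))) {
      def <- lib_defs[i, ]
      kids <- withCallingHandlers(
        deconvolve_layer(
          y, bundle$layers[[def$tag]],
          focal_children = def$children[[1]],
          parent_mass = mass[[def$parent]]
        ),
        warning = function(w) {
          msgs <<- c(msgs, paste0(s, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      mass[names(kids)] <- kids
    }
    # pass-through for single-child nodes (pruned trees)
    for (p in unique(tree$edges$parent)) {
      ch <- hierarchy_children(tree, p)
      if (length(ch) == 1 && p %in% names(mass) && !(ch %in% names(mass))) {
        mass[[ch]] <- mass[[p]]
      }
    }
    purrr::map_dfr(seq_len(h), function(layer) {
      cls <- hierarchy_classes(tree, layer)
      avail <- cls[cls %in% names(mass)]
      tibble::tibble(sample_id = s, layer = layer, class = avail,
                     proportion = unname(mass[avail]))
    })
  })

  structure(
    list(
      proportions = rows,
      purity = pur,
      h = h,
      tree = tree,
      tumor_type = bundle$tumor_type,
      params = bundle$params,
      warnings = unique(msgs)
    ),
    class = "tme_deconvolution"
  )
}

#' @export
print.tme_deconvolution <- function(x, ...) {
  cat("<tme_deconvolution '", x$tumor_type, "'> ",
      length(unique(x$proportions$sample_id)), " samples, layers 1..",
      x$h, "\n", sep = "")
  print(proportions_at(x, x$h))
  invisible(x)
}

#' Wide proportion table for one layer
#'
#' @param res A `tme_deconvolution`.
#' @param layer Layer to extract (default: the deepest computed).
#' @return Tibble: `sample_id`, `layer`, one column per class (canonical
#'   order); rows sum to 1.
#' @export
proportions_at <- function(res, layer = res$h) {
  stopifnot(inherits(res, "tme_deconvolution"))
  if (!layer %in% seq_len(res$h)) {
    abort(sprintf("layer %d not computed (h = %d)", layer, res$h))
  }
  long <- res$proportions[res$proportions$layer == layer, ]
  wide <- tidyr::pivot_wider(long, names_from = "class",
                             values_from = "proportion")
  wide
}

#' Aggregate a deep layer's proportions up the hierarchy
#'
#' Sums the classes of layer `from_h` by subtree membership at layer `to_h`.
#' By construction of the cascade this reproduces the stored shallower table
#' exactly; the utility exists for scoring predictions at coarser resolution.
#'
#' @param res A `tme_deconvolution`.
#' @param from_h Source layer (deeper).
#' @param to_h Target layer, `to_h < from_h`.
#' @return Wide proportion tibble at layer `to_h` (see [proportions_at()]).
#' @export
aggregate_to_layer <- function(res, from_h, to_h) {
  stopifnot(inherits(res, "tme_deconvolution"))
  if (!(to_h < from_h)) abort("to_h must be < from_h")
  if (from_h > res$h) abort(sprintf("layer %d not computed", from_h))
  tree <- res$tree %||% tme_hierarchy()
  from_tab <- proportions_at(res, from_h)
  to_classes <- hierarchy_classes(tree, to_h)
  from_classes <- setdiff(names(from_tab), c("sample_id", "layer"))
  out <- tibble::tibble(sample_id = from_tab$sample_id, layer = to_h)
  for (tc in to_classes) {
    members <- c(tc, .descendants(tree, tc))
    cols <- intersect(from_classes, members)
    if (length(cols) == 0) next
    out[[tc]] <- rowSums(from_tab[, cols, drop = FALSE])
  }
  out
}

.descendants <- function(tree, node) {
  ch <- hierarchy_children(tree, node)
  if (length(ch) == 0) return(character(0))
  c(ch, unlist(lapply(ch, .descendants, tree = tree)))
}

#' @rdname deconvolve
#' @param x,object A `tme_deconvolution`.
#' @param ... Unused.
#' @method tidy tme_deconvolution
#' @export
tidy.tme_deconvolution <- function(x, ...) x$proportions

#' @rdname deconvolve
#' @method glance tme_deconvolution
#' @export
glance.tme_deconvolution <- function(x, ...) {
  tibble::tibble(
    n_samples = length(unique(x$proportions$sample_id)),
    h = x$h,
    tumor_type = x$tumor_type,
    mean_purity = mean(x$purity$purity),
    n_warnings = length(x$warnings)
  )
}

#' @rdname deconvolve
#' @param layer Layer to display.
#' @method autoplot tme_deconvolution
#' @export
autoplot.tme_deconvolution <- function(object, layer = object$h, ...) {
  long <- object$proportions[object$proportions$layer == layer, ]
  cls <- unique(long$class)
  long$class <- factor(long$class, levels = cls)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample_id, y = .data$proportion, fill = .data$class
  )) +
    ggplot2::geom_col(position = "stack", width = 0.85) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = sprintf("TME composition, layer %d", layer)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
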