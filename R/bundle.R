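#' Build a complete tumor-type library bundle
#'
#' Assembles the twelve deconvolution libraries for one tumor type:
#' the layer-1 iDMC purity library from tumor/normal training data
#' ([select_idmc()]), plus the eleven layer libraries L2..L6B
#' ([build_layer_library()]) over the cell-lineage hierarchy.
#'
#' The L2 library needs a `Tumor` reference class. It is built from the tumor
#' training samples whose estimated layer-1 purity falls in the top tertile
#' (at least two samples), which limits contamination of the tumor profile by
#' non-tumor cells; those samples are injected into the panel as class
#' `"Tumor"`.
#'
#' @param tumor,normal Training beta matrices for [select_idmc()].
#' @param cell_panel A [reference_panel()] whose labels are the terminal
#'   cell classes of `tree` (all non-tumor leaves must be present).
#' @param tumor_type Free-text tumor-type tag stored with the bundle.
#' @param n_top,var_threshold Passed to [select_idmc()].
#' @param n_markers Markers per library class (default 100).
#' @param tree Cell-lineage hierarchy (default [tme_hierarchy()]).
#' @return Object of class `library_bundle`: list with `tumor_type`, `l1`
#'   (`idmc_library`), `layers` (named list of `layer_library`, tags
#'   L2..L6B), `tree`, and `params`.
#' @export
build_bundle <- function(tumor, normal, cell_panel, tumor_type = "synthetic",
                         n_top = 1000, var_threshold = 0.005,
                         n_markers = 100, tree = tme_hierarchy()) {
  stopifnot(inherits(cell_panel, "reference_panel"),
            inherits(tree, "tme_hierarchy"))
  non_tumor_leaves <- setdiff(tree$leaves, "Tumor")
  missing_cls <- setdiff(non_tumor_leaves, unique(cell_panel$labels))
  if (length(missing_cls) > 0) {
    abort(paste0("cell panel is missing terminal classes: ",
                 paste(missing_cls, collapse = ", ")))
  }

  l1 <- select_idmc(tumor, normal, n_top = n_top,
                    var_threshold = var_threshold)

  # tumor reference samples: top tertile of training-sample purity
  pur <- purity_table(tumor, l1)
  cut <- stats::quantile(pur$purity, 2 / 3, type = 7)
  top <- pur$sample_id[pur$purity >= cut]
  if (length(top) < 2) {
    top <- pur$sample_id[order(pur$purity, decreasing = TRUE)][1:2]
  }

  shared <- intersect(rownames(cell_panel$betas), rownames(tumor))
  if (length(shared) == 0) abort("cell panel and tumor share no probes")
  aug_betas <- cbind(
    cell_panel$betas[shared, , drop = FALSE],
    tumor[shared, top, drop = FALSE]
  )
  aug_labels <- c(cell_panel$labels,
                  setNames(rep("Tumor", length(top)), top))
  aug_panel <- reference_panel(aug_betas, aug_labels)

  layers <- list()
  for (i in seq_len(nrow(tree$libraries))) {
    def <- tree$libraries[i, ]
    layers[[def$tag]] <- build_layer_library(
      aug_panel,
      tag = def$tag,
      focal_children = def$children[[1]],
      collapse_map = .collapse_map(tree, def$children[[1]],
                                   def$collapsed[[1]]),
      n_markers = n_markers
    )
  }

  structure(
    list(
      tumor_type = tumor_type,
      l1 = l1,
      layers = layers,
      tree = tree,
      params = list(n_top = n_top, var_threshold = var_threshold,
                    n_markers = n_markers,
                    tumor_reference_samples = top)
    ),
    class = "library_bundle"
  )
}

# collapse map for one library: terminal classes under each focal child map
# to the child's name; terminal classes under the non-focal siblings merge
# into one group named by joining the sibling names
.collapse_map <- function(tree, focal_children, collapsed_siblings) {
  cmap <- character(0)
  for (ch in focal_children) {
    lv <- hierarchy_leaves_under(tree, ch)
    cmap[lv] <- ch
  }
  if (length(collapsed_siblings) > 0) {
    grp <- paste(collapsed_siblings, collapse = "_")
    for (sib in collapsed_siblings) {
      lv <- hierarchy_leaves_under(tree, sib)
      cmap[lv] <- grp
    }
  }
  cmap
}

#' @export
print.library_bundle <- function(x, ...) {
  cat("<library_bundle '", x$tumor_type, "'> L1: ", nrow(x$l1$entries),
      " iDMCs; ", length(x$layers), " layer libraries (",
      paste(names(x$layers), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.bundle_format_version <- "1.0"

#' Save / load a library bundle
#'
#' One directory of diff-able delimited text: `meta.json` (tumor tag,
#' construction parameters, format version), `L1.csv` (probe, direction,
#' p-value, mean difference), one `<tag>.csv` per layer library (probe plus
#' per-class mean-beta columns), `markers_<tag>.csv` (marker attribution),
#' and `hierarchy.csv` (parent/child edge list). Doubles are written with
#' full round-trip precision, so save -> load -> save is byte-stable.
#'
#' @param bundle A `library_bundle`.
#' @param dir Directory (created if absent).
#' @return `save_library_bundle()`: `dir` invisibly;
#'   `load_library_bundle()`: the restored `library_bundle`.
#' @export
save_library_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "library_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = .bundle_format_version,
    tumor_type = bundle$tumor_type,
    params = bundle$params,
    layer_tags = names(bundle$layers),
    leaves = bundle$tree$leaves,
    libraries = lapply(seq_len(nrow(bundle$tree$libraries)), function(i) {
      def <- bundle$tree$libraries[i, ]
      list(tag = def$tag, layer = def$layer, parent = def$parent,
           children = def$children[[1]], collapsed = def$collapsed[[1]])
    })
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(bundle$l1$entries, file.path(dir, "L1.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$tree$edges, file.path(dir, "hierarchy.csv"),
                   progress = FALSE)
  for (tag in names(bundle$layers)) {
    lib <- bundle$layers[[tag]]
    means <- tibble::as_tibble(lib$means, rownames = "probe")
    readr::write_csv(means, file.path(dir, paste0(tag, ".csv")),
                     progress = FALSE)
    readr::write_csv(lib$markers, file.path(dir, paste0("markers_", tag, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @rdname save_library_bundle
#' @export
load_library_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    abort(paste0("not a bundle directory (no meta.json): ", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format_version, .bundle_format_version)) {
    abort(sprintf("bundle format version mismatch: found '%s', need '%s'",
                  meta$format_version, .bundle_format_version))
  }
  tags <- meta$layer_tags
  need <- c("L1.csv", "hierarchy.csv", paste0(tags, ".csv"),
            paste0("markers_", tags, ".csv"))
  have <- file.exists(file.path(dir, need))
  if (!all(have)) {
    abort(paste0("bundle directory incomplete, missing: ",
                 paste(need[!have], collapse = ", ")))
  }

  # numeric columns are re-parsed with base strtod (correctly rounded), so
  # save -> load -> save is bit-stable
  read_exact <- function(path, numeric_cols, integer_cols = character(0)) {
    df <- readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    for (cl in numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
    for (cl in integer_cols) df[[cl]] <- as.integer(df[[cl]])
    df
  }

  l1_tab <- read_exact(file.path(dir, "L1.csv"), c("p_value", "mean_diff"))
  l1 <- structure(
    list(entries = l1_tab,
         params = list(n_top = meta$params$n_top,
                       var_threshold = meta$params$var_threshold)),
    class = "idmc_library"
  )

  tree <- tme_hierarchy(leaves = meta$leaves)
  layers <- list()
  lib_meta <- meta$libraries
  if (is.data.frame(lib_meta)) {
    lib_meta <- lapply(seq_len(nrow(lib_meta)), function(i) {
      as.list(lib_meta[i, ])
    })
  }
  names(lib_meta) <- vapply(lib_meta, function(l) l$tag[[1]], "")
  for (tag in tags) {
    means_df <- read_exact(file.path(dir, paste0(tag, ".csv")),
                           numeric_cols = character(0))
    means_df[-1] <- lapply(means_df[-1], as.numeric)
    means <- as.matrix(means_df[, -1, drop = FALSE])
    rownames(means) <- means_df$probe
    markers <- read_exact(file.path(dir, paste0("markers_", tag, ".csv")),
                          numeric_cols = c("p_value", "coef"),
                          integer_cols = "rank")
    lm <- lib_meta[[tag]]
    layers[[tag]] <- structure(
      list(tag = tag, classes = colnames(means),
           focal_children = unlist(lm$children),
           probes = rownames(means), means = means,
           markers = markers, n_markers = meta$params$n_markers),
      class = "layer_library"
    )
  }
  structure(
    list(
      tumor_type = meta$tumor_type,
      l1 = l1,
      layers = layers,
      tree = tree,
      params = meta$params
    ),
    class = "library_bundle"
  )
}
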