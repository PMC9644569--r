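#' The tumor-microenvironment cell-lineage hierarchy
#'
#' Six-layer rooted tree over the tumor microenvironment: tumor cells, the
#' angiogenic/non-immune compartment (epithelial, endothelial, stromal) and the
#' immune compartment, resolved down to seventeen terminal cell classes.
#' Each internal split is handled by one deconvolution library:
#'
#' | tag  | separates                              | within          |
#' |------|----------------------------------------|-----------------|
#' | L1   | Tumor vs non-tumor (purity)            | whole sample    |
#' | L2   | Immune vs Angiogenic                   | non-tumor mass  |
#' | L3A  | Epithelial / Endothelial / Stromal     | Angiogenic      |
#' | L3B  | Lymphoid / Myeloid                     | Immune          |
#' | L4A  | Granulocyte / Mononuclear              | Myeloid         |
#' | L4B  | NK / B cell / T cell                   | Lymphoid        |
#' | L5A  | Neutrophil / Basophil / Eosinophil     | Granulocyte     |
#' | L5B  | Monocyte / Dendritic cell              | Mononuclear     |
#' | L5C  | B naive / B memory                     | B cell          |
#' | L5D  | CD4 T / CD8 T                          | T cell          |
#' | L6A  | CD4 naive / CD4 memory / T regulatory  | CD4 T           |
#' | L6B  | CD8 naive / CD8 memory                 | CD8 T           |
#'
#' @param leaves Optional character vector of terminal classes to keep; the
#'   tree is pruned to the minimal subtree containing them (plus `"Tumor"`,
#'   which is always present). Defaults to all 17 classes.
#' @return An object of class `tme_hierarchy`: a list with `edges`
#'   (tibble `parent`, `child`, child order within parent), `leaves` (terminal
#'   classes in canonical reporting order), `depth` (named integer vector,
#'   layer at which each node first appears as its own class), and `libraries`
#'   (tibble `tag`, `layer`, `parent`, plus list-columns `children` and
#'   `collapsed`, the sibling classes each library absorbs as one group).
#' @examples
#' tr <- tme_hierarchy()
#' tr$leaves
#' hierarchy_classes(tr, 3)
#' @export
tme_hierarchy <- function(leaves = NULL) {
  edges <- tibble::tribble(
    ~parent,       ~child,
    "TME",         "Tumor",
    "TME",         "Nontumor",
    "Nontumor",    "Immune",
    "Nontumor",    "Angiogenic",
    "Angiogenic",  "Epithelial",
    "Angiogenic",  "Endothelial",
    "Angiogenic",  "Stromal",
    "Immune",      "Lymphoid",
    "Immune",      "Myeloid",
    "Myeloid",     "Granulocyte",
    "Myeloid",     "Mononuclear",
    "Lymphoid",    "NK",
    "Lymphoid",    "Bcell",
    "Lymphoid",    "Tcell",
    "Granulocyte", "Neutrophil",
    "Granulocyte", "Basophil",
    "Granulocyte", "Eosinophil",
    "Mononuclear", "Monocyte",
    "Mononuclear", "DC",
    "Bcell",       "Bnv",
    "Bcell",       "Bmem",
    "Tcell",       "CD4T",
    "Tcell",       "CD8T",
    "CD4T",        "CD4nv",
    "CD4T",        "CD4mem",
    "CD4T",        "Treg",
    "CD8T",        "CD8nv",
    "CD8T",        "CD8mem"
  )
  canonical_leaves <- c(
    "Tumor", "Epithelial", "Endothelial", "Stromal",
    "Basophil", "Eosinophil", "Neutrophil", "Monocyte", "DC",
    "Bnv", "Bmem", "CD4nv", "CD4mem", "CD8nv", "CD8mem", "Treg", "NK"
  )

  if (!is.null(leaves)) {
    leaves <- unique(c("Tumor", leaves))
    bad <- setdiff(leaves, canonical_leaves)
    if (length(bad) > 0) {
      abort(paste0("unknown terminal classes: ", paste(bad, collapse = ", ")))
    }
    keep <- character(0)
    for (lf in leaves) {
      node <- lf
      while (length(node) == 1) {
        keep <- c(keep, node)
        node <- edges$parent[edges$child == node]
      }
    }
    keep <- unique(c(keep, "TME"))
    edges <- edges[edges$parent %in% keep & edges$child %in% keep, ]
    # collapse chains: an internal node left with a single child is kept;
    # libraries for single-child nodes are dropped below
    canonical_leaves <- canonical_leaves[canonical_leaves %in% leaves]
  }

  children_of <- function(node) edges$child[edges$parent == node]
  is_leaf <- function(node) length(children_of(node)) == 0

  depth <- c(TME = 0L)
  walk <- function(node, d) {
    for (ch in children_of(node)) {
      depth[[ch]] <<- d
      walk(ch, d + 1L)
    }
  }
  walk("TME", 1L)

  lib_defs <- tibble::tribble(
    ~tag,  ~layer, ~parent,
    "L2",  2L,     "Nontumor",
    "L3A", 3L,     "Angiogenic",
    "L3B", 3L,     "Immune",
    "L4A", 4L,     "Myeloid",
    "L4B", 4L,     "Lymphoid",
    "L5A", 5L,     "Granulocyte",
    "L5B", 5L,     "Mononuclear",
    "L5C", 5L,     "Bcell",
    "L5D", 5L,     "Tcell",
    "L6A", 6L,     "CD4T",
    "L6B", 6L,     "CD8T"
  )
  lib_defs <- lib_defs[lib_defs$parent %in% edges$parent, ]
  lib_defs$children <- lapply(lib_defs$parent, children_of)
  lib_defs$collapsed <- lapply(lib_defs$parent, function(p) {
    gp <- edges$parent[edges$child == p]
    setdiff(children_of(gp), p)
  })
  # a library is only needed where there is something to separate
  lib_defs <- lib_defs[vapply(lib_defs$children, length, 1L) > 1L, ]

  structure(
    list(
      edges = edges,
      leaves = canonical_leaves,
      depth = depth,
      libraries = lib_defs
    ),
    class = "tme_hierarchy"
  )
}

#' @export
print.tme_hierarchy <- function(x, ...) {
  cat("<tme_hierarchy> ", length(x$leaves), " terminal classes, ",
      nrow(x$libraries), " split libraries (+ L1)\n", sep = "")
  invisible(x)
}

hierarchy_children <- function(tree, node) {
  tree$edges$child[tree$edges$parent == node]
}

hierarchy_parent <- function(tree, node) {
  p <- tree$edges$parent[tree$edges$child == node]
  if (length(p) == 0) NA_character_ else p
}

#' Terminal classes below a node
#' @param tree A [tme_hierarchy()] object.
#' @param node Node name.
#' @return Character vector of terminal classes in the node's subtree
#'   (the node itself if terminal).
#' @export
hierarchy_leaves_under <- function(tree, node) {
  ch <- hierarchy_children(tree, node)
  if (length(ch) == 0) return(node)
  unlist(lapply(ch, hierarchy_leaves_under, tree = tree))
}

#' Classes reported at a given layer
#'
#' The "frontier" of the hierarchy at layer `h`: nodes first resolved at
#' layer `h`, plus terminal classes resolved earlier and carried forward.
#' Layer 1 reports `Tumor` and `Nontumor`; layer 6 reports all terminal
#' classes.
#'
#' @param tree A [tme_hierarchy()] object.
#' @param h Layer, integer in 1..6.
#' @return Character vector of class names in canonical order.
#' @export
hierarchy_classes <- function(tree, h) {
  stopifnot(length(h) == 1, h >= 1, h <= 6)
  nodes <- names(tree$depth)
  is_leaf <- vapply(
    nodes, function(n) length(hierarchy_children(tree, n)) == 0, TRUE
  )
  frontier <- nodes[
    (tree$depth == h & nodes != "TME") |
      (is_leaf & tree$depth < h)
  ]
  # order by position of first canonical leaf in each subtree
  key <- vapply(frontier, function(n) {
    min(match(hierarchy_leaves_under(tree, n), tree$leaves))
  }, 1L)
  frontier[order(key)]
}
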