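#' Anatomical hierarchy trees
#'
#' An `anatomy_tree` is a rooted tree of named nodes. Leaves correspond
#' one-to-one with the structure columns of a [volume_table()]; every node
#' carries a `hemisphere` tag (`"left"`, `"right"` or `"bilateral"`). Interior
#' nodes name anatomical concepts (e.g. a bilateral region grouping its left
#' and right leaf structures), which is how a fine atlas segmentation is
#' reduced to a smaller set of bilateral regions.
#'
#' @param name node name.
#' @param children list of child nodes (empty for leaves).
#' @param hemisphere one of `"left"`, `"right"`, `"bilateral"`.
#' @return A list with entries `name`, `hemisphere`, `children`, of class
#'   `anatomy_tree` at the root.
#' @export
anatomy_node <- function(name, children = list(), hemisphere = "bilateral") {
  stopifnot(is.character(name), length(name) == 1,
            hemisphere %in% c("left", "right", "bilateral"))
  structure(list(name = name, hemisphere = hemisphere, children = children),
            class = "anatomy_tree")
}

#' Leaf names under a node
#' @param node an [anatomy_node()].
#' @return character vector of leaf names in depth-first order.
#' @export
tree_leaves <- function(node) {
  if (length(node$children) == 0) return(node$name)
  unlist(lapply(node$children, tree_leaves), use.names = FALSE)
}

#' Find a named node in an anatomy tree
#' @param node root to search from.
#' @param name node name to find.
#' @return the node, or `NULL` if absent.
#' @export
tree_find_node <- function(node, name) {
  if (node$name == name) return(node)
  for (ch in node$children) {
    hit <- tree_find_node(ch, name)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Read / write anatomy trees as JSON
#'
#' Nodes are serialised as `{name, hemisphere, children: [...]}`.
#'
#' @param path file path.
#' @return [read_anatomy_tree()] returns an `anatomy_tree`;
#'   [write_anatomy_tree()] returns `path` invisibly.
#' @export
read_anatomy_tree <- function(path) {
  as_node <- function(x) {
    kids <- lapply(x$children, as_node)
    anatomy_node(x$name, kids, x$hemisphere)
  }
  as_node(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname read_anatomy_tree
#' @param tree an [anatomy_node()] root.
#' @export
write_anatomy_tree <- function(tree, path) {
  strip <- function(node) {
    list(name = node$name, hemisphere = node$hemisphere,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Collapse leaf structures to (bilateral) regions
#'
#' Each target region becomes one output column holding the sum of the
#' volumes of all leaf structures beneath it; left and right homologues are
#' thereby merged and region volumes remain in cubic millimetres. Targets
#' must cover every leaf at most once (no target may be a descendant of
#' another); full coverage is required unless `require_coverage = FALSE`.
#' Output columns are sorted by region name so that results are stable.
#'
#' @param vt a [volume_table()] of raw volumes.
#' @param tree the [anatomy_node()] hierarchy whose leaves match `vt`'s
#'   structure columns.
#' @param target_regions character vector of node names to aggregate to.
#' @param require_coverage logical; if `TRUE` (default) every leaf of the tree
#'   must fall under exactly one target.
#' @return a `volume_table` with one column per target region.
#' @export
aggregate_to_regions <- function(vt, tree, target_regions,
                                 require_coverage = TRUE) {
  stopifnot(inherits(vt, "volume_table"))
  all_leaves <- tree_leaves(tree)
  cols <- structure_names(vt)
  if (!setequal(all_leaves, cols))
    stop("tree leaves and volume-table structure columns differ")
  leaf_sets <- lapply(target_regions, function(nm) {
    node <- tree_find_node(tree, nm)
    if (is.null(node)) stop("target region '", nm, "' is not a tree node")
    tree_leaves(node)
  })
  names(leaf_sets) <- target_regions
  flat <- unlist(leaf_sets, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("target regions overlap: leaf '",
         flat[duplicated(flat)][1], "' is covered more than once")
  if (require_coverage && !setequal(flat, all_leaves))
    stop("target regions do not cover every leaf structure")
  vm <- volume_matrix(vt)
  agg <- vapply(leaf_sets,
                function(ls) rowSums(vm[, ls, drop = FALSE]),
                numeric(nrow(vm)))
  agg <- agg[, order(colnames(agg)), drop = FALSE]
  volume_table(agg, subject_id = vt$subject_id, strain = vt$strain,
               sex = vt$sex, wildtype = attr(vt, "wildtype"),
               standardised = attr(vt, "standardised"))
}

#' Z-score standardise structure volumes
#'
#' Each structure column is centred and scaled to zero mean and unit standard
#' deviation (sample SD, `n - 1` denominator) over all subjects pooled across
#' sexes and strains, so model coefficients downstream are expressed in SD
#' units of that structure. Group structure enters only through the models,
#' never through the standardisation.
#'
#' @param vt a [volume_table()].
#' @return a `volume_table` flagged `standardised`.
#' @export
standardise_volumes <- function(vt) {
  stopifnot(inherits(vt, "volume_table"))
  vm <- volume_matrix(vt)
  sds <- apply(vm, 2, stats::sd)
  if (any(sds == 0))
    stop("constant structure column(s): ",
         paste(colnames(vm)[sds == 0], collapse = ", "))
  z <- scale(vm, center = TRUE, scale = sds)
  volume_table(z, subject_id = vt$subject_id, strain = vt$strain,
               sex = vt$sex, wildtype = attr(vt, "wildtype"),
               standardised = TRUE)
}
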