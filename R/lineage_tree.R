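#' Define a cell-type lineage tree with per-edge differential specs
#'
#' A lineage tree encodes the differentiation hierarchy used by the
#' synthetic-study generator: each edge carries the number of regulatory
#' regions whose methylation propensity shifts between parent and child,
#' and the magnitude of that shift (methylation-fraction units).
#'
#' @param edges data.frame with columns `parent`, `child`, and optionally
#'   `n_shift` (count of shifted regions, default 50) and `shift_mag`
#'   (absolute shift in methylation fraction, default 0.3; the sign is
#'   drawn at random per region unless `shift_sign` is given as -1 or 1).
#' @return An object of class `lineage_tree` with elements `nodes`,
#'   `edges` and `root`.
#' @examples
#' tr <- lineage_tree(data.frame(parent = "A", child = c("B", "C")))
#' tr$root
#' @export
lineage_tree <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges)))
    stop_ml("edges must have 'parent' and 'child' columns")
  if (is.null(edges$n_shift)) edges$n_shift <- 50L
  if (is.null(edges$shift_mag)) edges$shift_mag <- 0.3
  if (is.null(edges$shift_sign)) edges$shift_sign <- NA_real_
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(abs(edges$shift_mag) > 1))
    stop_ml("shift magnitudes must lie in [-1, 1]")
  if (any(edges$n_shift < 0))
    stop_ml("shift counts must be non-negative")
  nodes <- unique(c(edges$parent, edges$child))
  if (anyDuplicated(edges$child))
    stop_ml("cell type '%s' has more than one parent",
            edges$child[duplicated(edges$child)][1])
  root <- setdiff(nodes, edges$child)
  if (length(root) != 1L)
    stop_ml("tree must have exactly one root, found: %s",
            paste(root, collapse = ", "))
  ## acyclicity / connectivity: walk up from every node, must reach root
  parent_of <- stats::setNames(edges$parent, edges$child)
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (cur != root) {
      if (cur %in% seen) stop_ml("cycle detected at cell type '%s'", cur)
      seen <- c(seen, cur)
      if (is.na(parent_of[cur])) stop_ml("node '%s' is disconnected", cur)
      cur <- parent_of[[cur]]
    }
  }
  structure(list(nodes = nodes, edges = edges, root = root),
            class = "lineage_tree")
}

#' Default seven-type hematopoietic lineage tree
#'
#' A reduced-scale hematopoietic hierarchy:
#' HSC -> MPP -> \{CMP -> \{MEP, GMP\}, MLP0 -> CLP\}. Each edge plants
#' `n_shift` differentially methylated regions of magnitude `shift_mag`.
#'
#' @param n_shift regions shifted per edge (default 50)
#' @param shift_mag absolute methylation-fraction shift per region (default 0.3)
#' @return A `lineage_tree`.
#' @export
default_lineage_tree <- function(n_shift = 50L, shift_mag = 0.3) {
  lineage_tree(data.frame(
    parent = c("HSC", "MPP", "CMP", "CMP", "MPP", "MLP0"),
    child  = c("MPP", "CMP", "MEP", "GMP", "MLP0", "CLP"),
    n_shift = as.integer(n_shift),
    shift_mag = shift_mag,
    stringsAsFactors = FALSE
  ))
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("Lineage tree: %d cell types, root %s\n",
              length(x$nodes), x$root))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s  (%d regions shifted by %.3g)\n",
                x$edges$parent[i], x$edges$child[i],
                x$edges$n_shift[i], x$edges$shift_mag[i]))
  invisible(x)
}

## edges ordered parent-before-child for propensity propagation
topo_edges <- function(tree) {
  done <- tree$root
  edges <- tree$edges
  out <- integer(0)
  while (length(out) < nrow(edges)) {
    ready <- which(edges$parent %in% done & !(seq_len(nrow(edges)) %in% out))
    out <- c(out, ready)
    done <- c(done, edges$child[ready])
  }
  edges[out, , drop = FALSE]
}
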