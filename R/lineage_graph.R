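#' Leave-one-class-out cross-prediction matrix
#'
#' For every cell type c, a classifier is trained on all samples of the
#' other classes (same alpha and one-SE lambda rule) and used to predict
#' class probabilities for the withheld samples of c. Row c of the result
#' is the mean probability vector over those samples: it describes which
#' remaining cell types absorb c's probability mass, the basis of the
#' data-driven lineage graph. Rows sum to 1 over the remaining classes;
#' the diagonal is 0 (a class is absent from its own model).
#'
#' @inheritParams train_celltype
#' @param nfolds internal CV folds for lambda selection in each reduced
#'   model.
#' @return object of class `cross_prediction`: square matrix `P` (held-out
#'   class x target class) plus `n_samples` per class.
#' @export
leave_one_class_out <- function(mat, labels, alpha = 0.5, nfolds = 10L,
                                seed = 1L, donors = NULL) {
  x <- if (inherits(mat, "meth_matrix")) mat$beta else as.matrix(mat)
  labels <- factor(labels)
  if (nlevels(labels) < 3L)
    stop_ml("need at least 3 classes (each reduced model needs 2)")
  classes <- levels(labels)
  P <- matrix(0, length(classes), length(classes),
              dimnames = list(held_out = classes, target = classes))
  for (cl in classes) {
    tr <- labels != cl
    if (length(unique(labels[tr])) < 2L)
      stop_ml("removing class '%s' leaves fewer than 2 training classes", cl)
    model <- train_celltype(x[tr, , drop = FALSE], droplevels(labels[tr]),
                            alpha = alpha, nfolds = nfolds,
                            seed = derive_seed(seed, paste0("loco-", cl)),
                            donors = if (is.null(donors)) NULL else donors[tr])
    pr <- predict(model, x[!tr, , drop = FALSE])
    P[cl, model$classes] <- colMeans(pr)
  }
  structure(list(P = P, n_samples = as.integer(table(labels))),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat("Leave-one-class-out cross-prediction matrix (rows = held-out class):\n")
  print(round(x$P, 3))
  invisible(x)
}

#' Build the cell-type lineage graph from cross-prediction propensities
#'
#' Edge weights are the symmetrized cross-prediction propensities
#' w(c, d) = (P(d | c) + P(c | d)) / 2; edges below the pruning threshold
#' are removed (sub-noise probability floor). The directed matrix is kept
#' alongside the symmetrized one.
#'
#' @param cross a `cross_prediction`.
#' @param prune minimum edge weight retained (default 0.05).
#' @return object of class `lineage_graph`: `weights` (symmetric matrix),
#'   `directed`, `edges` (pruned edge list), `prune`, `components`.
#' @export
build_lineage_graph <- function(cross, prune = 0.05) {
  P <- cross$P
  W <- (P + t(P)) / 2
  diag(W) <- 0
  nodes <- rownames(W)
  el <- which(upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(from = nodes[el[, 1L]], to = nodes[el[, 2L]],
                      weight = W[el], stringsAsFactors = FALSE)
  edges <- edges[edges$weight >= prune, , drop = FALSE]
  edges <- edges[order(-edges$weight, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges))
    warning("all edges pruned; the lineage graph is empty", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  structure(list(weights = W, directed = P, edges = edges, prune = prune,
                 nodes = nodes, components = split(nodes, comp$membership)),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat(sprintf("Lineage graph: %d cell types, %d edges >= %.3g (%d component%s)\n",
              length(x$nodes), nrow(x$edges), x$prune,
              length(x$components),
              if (length(x$components) == 1L) "" else "s"))
  print(x$edges, digits = 3)
  invisible(x)
}

#' Maximum-weight spanning tree of a lineage graph
#'
#' Greedy (Kruskal) edge selection over the pruned graph: edges are taken
#' in decreasing weight order (ties broken by the lexicographic node
#' pair), skipping edges that would close a cycle. The result summarizes
#' the cross-prediction network as a testable lineage topology.
#'
#' @param graph a `lineage_graph`.
#' @return data.frame of tree edges (`from`, `to`, `weight`), with
#'   `from < to` lexicographically within each edge.
#' @export
max_spanning_tree <- function(graph) {
  edges <- graph$edges
  nodes <- graph$nodes
  if (length(graph$components) > 1L)
    stop_ml("graph is disconnected; components: %s",
            paste(vapply(graph$components, paste, "", collapse = "+"),
                  collapse = " | "))
  a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
  ord <- order(-edges$weight, a, b)
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(edges))
  for (i in ord) {
    ra <- find(match(a[i], nodes)); rb <- find(match(b[i], nodes))
    if (ra != rb) { parent[ra] <- rb; keep[i] <- TRUE }
  }
  out <- data.frame(from = a[keep], to = b[keep],
                    weight = edges$weight[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) != length(nodes) - 1L)
    stop_ml("spanning tree incomplete (%d edges for %d nodes)",
            nrow(out), length(nodes))
  out
}

#' Write a lineage graph as GraphML and an edge-list TSV
#'
#' @param graph a `lineage_graph`.
#' @param prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @export
write_lineage_graph <- function(graph, prefix) {
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  utils::write.table(graph$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
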