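# Shared fixtures, built in code. The small study (120 regions) backs the
# module tests; the full default study (500 regions) is built lazily by the
# acceptance tests. Both are cached per seed within a test run.

.study_cache <- new.env(parent = emptyenv())

# Simulate a study in memory (no files) and aggregate it to a matrix.
# Pooled samples only, matching the classifier's input in the real design.
build_study <- function(seed, n_regions = 500L, tree = default_lineage_tree(),
                        min_total_reads = 3L) {
  key <- sprintf("s%d_r%d_%s", seed, n_regions,
                 paste(tree$nodes, collapse = ""))
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  params <- sim_params(seed = seed, n_regions = n_regions, single_cells = 0L)
  truth <- simulate_propensities(tree, params)
  sheet <- methlineage:::build_sample_sheet(tree, params)
  agg <- lapply(seq_len(nrow(sheet)), function(i)
    aggregate_to_regions(
      simulate_sample(truth, sheet$cell_type[i], sheet$pool_size[i],
                      seed = methlineage:::derive_seed(params$seed,
                                                      sheet$sample_id[i])),
      truth$catalog, min_total_reads = min_total_reads))
  names(agg) <- sheet$sample_id
  mat <- suppressMessages(assemble_matrix(agg, sheet = sheet))
  res <- list(truth = truth, sheet = sheet, agg = agg, mat = mat,
              params = params, tree = tree)
  .study_cache[[key]] <- res
  res
}

# Hand-built call table (internal 0-based representation).
make_calls <- function(chrom, pos0, m, n) {
  data.frame(chrom = chrom, pos0 = as.integer(pos0), m = as.integer(m),
             n = as.integer(n), stringsAsFactors = FALSE)
}

make_catalog <- function(chrom, start, end, id = NULL, type = NA) {
  id <- id %||% sprintf("%s:%d-%d", chrom, start, end)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             id = id, type = type, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent quadratic-scan aggregation oracle: loop over every
# CpG x region pair, 0-based half-open membership.
oracle_aggregate <- function(calls, catalog, min_total_reads = 3L) {
  beta <- m <- n <- stats::setNames(numeric(nrow(catalog)), catalog$id)
  for (r in seq_len(nrow(catalog))) {
    for (i in seq_len(nrow(calls))) {
      if (calls$chrom[i] == catalog$chrom[r] &&
          calls$pos0[i] >= catalog$start[r] &&
          calls$pos0[i] < catalog$end[r]) {
        m[r] <- m[r] + calls$m[i]
        n[r] <- n[r] + calls$n[i]
      }
    }
    beta[r] <- if (n[r] >= min_total_reads) m[r] / n[r] else NA_real_
  }
  list(beta = beta, m = m, n = n)
}

# Exact two-sided Fisher p by hypergeometric enumeration with lchoose;
# independent of stats::fisher.test / dhyper.
oracle_fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  q <- a + b      # query size (row 1)
  m1 <- a + c     # set size (col 1)
  lo <- max(0L, q + m1 - n); hi <- min(q, m1)
  ks <- lo:hi
  logp <- lchoose(m1, ks) + lchoose(n - m1, q - ks) - lchoose(n, q)
  p <- exp(logp)
  sum(p[p <= p[ks == a] * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of rank
# assignments (no ties assumed).
oracle_wilcoxon_two_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ranks_all <- seq_len(nx + ny)
  w_all <- apply(combs, 2L, function(idx) sum(ranks_all[idx])) -
    nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Naive O(n^3) complete-linkage agglomeration returning sorted merge
# heights.
oracle_complete_linkage_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  d <- as.matrix(stats::dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# All spanning trees of a small complete weighted graph via Pruefer
# sequences; returns the maximum total weight and the best edge set.
oracle_best_spanning_tree <- function(W) {
  n <- nrow(W)
  nodes <- rownames(W)
  from_pruefer <- function(pr) {
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    ptr <- 1L
    pr2 <- pr
    for (v in pr2) {
      leaf <- min(which(degree == 1L))
      edges[ptr, ] <- c(leaf, v); ptr <- ptr + 1L
      degree[leaf] <- 0L; degree[v] <- degree[v] - 1L
    }
    rest <- which(degree == 1L)
    edges[ptr, ] <- rest
    edges
  }
  seqs <- if (n == 2L) list(integer(0)) else {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  best_w <- -Inf; best_edges <- NULL
  for (pr in seqs) {
    e <- from_pruefer(pr)
    w <- sum(W[e])
    if (w > best_w) {
      best_w <- w
      best_edges <- sort(paste(pmin(nodes[e[, 1]], nodes[e[, 2]]),
                               pmax(nodes[e[, 1]], nodes[e[, 2]]),
                               sep = "|"))
    }
  }
  list(weight = best_w, edges = best_edges)
}

planted_edge_keys <- function(tree) {
  sort(paste(pmin(tree$edges$parent, tree$edges$child),
             pmax(tree$edges$parent, tree$edges$child), sep = "|"))
}
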