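#' Mean-adjusted region-set methylation per sample
#'
#' For each sample, the unweighted mean methylation over the regions of a
#' set minus the sample's global CpG methylation mean. The subtraction
#' removes per-sample baseline differences (coverage regime, cell number),
#' so values are comparable across 10-, 50- and 1,000-cell libraries.
#' Values are methylation fractions; multiply by 100 for percentage
#' points. Imputed entries are excluded from the set mean; samples with
#' fewer than `min_regions` genuinely observed regions in the set are
#' flagged low-confidence.
#'
#' @param mat a `meth_matrix` from [assemble_matrix()].
#' @param set_regions character vector of region ids defining the set.
#' @param set_name label carried into the result (used in error messages).
#' @param min_regions low-confidence flag threshold (default 5).
#' @return data.frame with `sample_id`, `set`, `delta`, `n_regions`,
#'   `low_confidence`.
#' @export
mean_adjusted <- function(mat, set_regions, set_name = "set",
                          min_regions = 5L) {
  idx <- which(colnames(mat$beta) %in% set_regions)
  if (!length(idx))
    stop_ml("region set '%s' has no regions in the matrix", set_name)
  b <- mat$beta[, idx, drop = FALSE]
  obs <- !mat$imputed[, idx, drop = FALSE]
  b[!obs] <- NA_real_
  delta <- rowMeans(b, na.rm = TRUE) - mat$gmean
  n_obs <- rowSums(obs)
  data.frame(sample_id = rownames(mat$beta), set = set_name,
             delta = unname(delta), n_regions = unname(n_obs),
             low_confidence = unname(n_obs < min_regions),
             stringsAsFactors = FALSE)
}

#' Differential methylation between two sample groups, per region
#'
#' Welch two-sample t-test on per-sample region methylation, BH-adjusted
#' across all tested regions. A region passes when both the FDR and the
#' effect-size threshold are met: q <= `fdr` and |group mean difference|
#' >= `min_diff` (methylation-fraction units; the default 0.167
#' corresponds to 16.7 percentage points).
#'
#' @param mat a `meth_matrix`.
#' @param group_a,group_b disjoint character vectors of sample ids
#'   (at least 2 each).
#' @param fdr FDR threshold (default 0.05).
#' @param min_diff minimum absolute difference in methylation fraction
#'   (default 0.167).
#' @return data.frame with `region`, `mean_a`, `mean_b`, `diff` (a - b),
#'   `statistic`, `p`, `q`, `pass`, sorted by q then p.
#' @export
diff_regions <- function(mat, group_a, group_b, fdr = 0.05,
                         min_diff = 0.167) {
  if (length(intersect(group_a, group_b)))
    stop_ml("groups overlap: %s",
            paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_ml("need at least 2 samples per group")
  miss <- setdiff(c(group_a, group_b), rownames(mat$beta))
  if (length(miss))
    stop_ml("samples not in matrix: %s", paste(miss, collapse = ", "))
  a <- mat$beta[group_a, , drop = FALSE]
  b <- mat$beta[group_b, , drop = FALSE]
  res <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      ## degenerate: constant within both groups
      c(stat = 0, p = if (mean(x) == mean(y)) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      c(stat = unname(tt$statistic), p = tt$p.value)
    }
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  d <- colMeans(a) - colMeans(b)
  out <- data.frame(region = colnames(a), mean_a = unname(colMeans(a)),
                    mean_b = unname(colMeans(b)), diff = unname(d),
                    statistic = unname(res[, "stat"]),
                    p = unname(res[, "p"]), q = unname(q),
                    pass = unname(q <= fdr & abs(d) >= min_diff),
                    stringsAsFactors = FALSE)
  out[order(out$q, out$p), , drop = FALSE]
}

#' Differential mean-adjusted methylation between groups, per region set
#'
#' Two-sided Wilcoxon rank-sum test on the per-sample mean-adjusted values
#' of each region set (independent groups; signed-rank is not used). The p
#' value is exact when both groups have <= 25 samples and there are no
#' ties, otherwise a normal approximation with continuity correction is
#' used. A set passes when p <= `alpha` and the absolute group difference
#' in mean-adjusted methylation is >= `min_diff` (fractions; default 0.10
#' = 10 percentage points).
#'
#' @param profiles data.frame of [mean_adjusted()] results (possibly for
#'   several sets, long format).
#' @param group_a,group_b sample id vectors, at least 3 each.
#' @param alpha p-value threshold (default 0.05).
#' @param min_diff minimum |difference of group mean deltas| (default 0.10).
#' @return data.frame with `set`, `diff`, `statistic`, `p`, `q` (BH over
#'   sets), `pass`.
#' @export
diff_region_sets <- function(profiles, group_a, group_b, alpha = 0.05,
                             min_diff = 0.10) {
  if (length(intersect(group_a, group_b))) stop_ml("groups overlap")
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop_ml("need at least 3 samples per group")
  sets <- unique(profiles$set)
  res <- lapply(sets, function(s) {
    sub <- profiles[profiles$set == s, ]
    x <- sub$delta[match(group_a, sub$sample_id)]
    y <- sub$delta[match(group_b, sub$sample_id)]
    if (anyNA(x) || anyNA(y))
      stop_ml("set '%s' lacks values for some group samples", s)
    exact <- length(x) <= 25L && length(y) <= 25L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    data.frame(set = s, diff = mean(x) - mean(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$pass <- out$p <= alpha & abs(out$diff) >= min_diff
  out[order(out$p), , drop = FALSE]
}

#' Principal component analysis of a feature matrix, with projection
#'
#' Column-centered PCA via singular value decomposition. Reports
#' per-component and cumulative variance-explained fractions and supports
#' projecting held-out samples onto the fitted components.
#'
#' @param x samples x features numeric matrix without missing values (use
#'   [assemble_matrix()] to obtain a complete matrix).
#' @return object of class `meth_pca`: `scores`, `loadings`, `var_explained`,
#'   `cum_var_explained`, `center`.
#' @export
pca_project <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2L || ncol(x) < 2L)
    stop_ml("PCA needs at least 2 samples and 2 features")
  if (anyNA(x))
    stop_ml("matrix contains missing values; run assemble_matrix() first")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
                 cum_var_explained = cumsum(ve), center = pc$center),
            class = "meth_pca")
}

#' @rdname pca_project
#' @param pca a fitted `meth_pca`.
#' @param newdata samples x features matrix over the same features.
#' @return [project_onto_pca()]: scores of `newdata` on the fitted
#'   components.
#' @export
project_onto_pca <- function(pca, newdata) {
  sweep(as.matrix(newdata), 2L, pca$center) %*% pca$loadings
}

#' @export
print.meth_pca <- function(x, ...) {
  k <- min(5L, length(x$var_explained))
  cat(sprintf("PCA: %d components; first %d explain %.1f%% of variance\n",
              length(x$var_explained), k, 100 * x$cum_var_explained[k]))
  invisible(x)
}

#' Deterministic hierarchical clustering leaf order
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (the heat-map ordering convention); emits the leaf order for export.
#'
#' @param x items x features matrix.
#' @param method linkage (default `"complete"`).
#' @return list with `order` (leaf indexes), `labels`, `merge_heights`,
#'   `hclust` (the stats::hclust object).
#' @export
hcluster_order <- function(x, method = "complete") {
  if (nrow(x) < 2L) stop_ml("need at least 2 items to cluster")
  d <- stats::dist(x, method = "euclidean")
  if (any(!is.finite(d))) stop_ml("non-finite distances")
  hc <- stats::hclust(d, method = method)
  list(order = hc$order, labels = rownames(x), merge_heights = hc$height,
       hclust = hc)
}
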