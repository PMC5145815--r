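make_mat <- function(beta, gmean = NULL) {
  structure(list(beta = beta, n = beta * 0 + 10,
                 cpgs = beta * 0 + 5,
                 imputed = matrix(FALSE, nrow(beta), ncol(beta),
                                  dimnames = dimnames(beta)),
                 gmean = gmean %||% rowMeans(beta),
                 regions = colnames(beta), sheet = NULL),
            class = "meth_matrix")
}

test_that("mean-adjusted methylation is the set mean minus the global mean", {
  beta <- matrix(0.7, 2, 6, dimnames = list(c("s1", "s2"),
                                            sprintf("r%d", 1:6)))
  mat <- make_mat(beta, gmean = c(s1 = 0.7, s2 = 0.7))
  prof <- mean_adjusted(mat, sprintf("r%d", 1:6))
  expect_equal(prof$delta, c(0, 0))
  expect_false(any(prof$low_confidence))

  beta["s1", 1:5] <- 0.80
  mat2 <- make_mat(beta, gmean = c(s1 = 0.70, s2 = 0.70))
  prof2 <- mean_adjusted(mat2, sprintf("r%d", 1:5))
  ## set mean 0.80 vs global 0.70 -> +10 percentage points
  expect_equal(prof2$delta[1], 0.10)
  expect_error(mean_adjusted(mat2, c("x1", "x2"), set_name = "myset"),
               "myset")
  ## fewer than 5 observed regions flags low confidence
  prof3 <- mean_adjusted(mat2, sprintf("r%d", 1:4))
  expect_true(all(prof3$low_confidence))
})

test_that("mean-adjusted values are invariant to a constant baseline shift", {
  set.seed(11)
  beta <- matrix(runif(40, 0.2, 0.6), 4, 10,
                 dimnames = list(sprintf("s%d", 1:4), sprintf("r%d", 1:10)))
  mat <- make_mat(beta, gmean = rowMeans(beta))
  p1 <- mean_adjusted(mat, sprintf("r%d", 1:6))
  mat2 <- make_mat(beta + 0.2, gmean = rowMeans(beta) + 0.2)
  p2 <- mean_adjusted(mat2, sprintf("r%d", 1:6))
  expect_equal(p1$delta, p2$delta)
})

test_that("mean-adjusted profiles match brute-force recomputation from call files", {
  st <- build_study(5L, n_regions = 60L)
  set.seed(5)
  set_ids <- sample(colnames(st$mat$beta), 50)
  prof <- mean_adjusted(st$mat, set_ids, set_name = "fix")
  for (id in sample(st$sheet$sample_id, 5)) {
    calls <- simulate_sample(
      st$truth, st$sheet$cell_type[st$sheet$sample_id == id],
      st$sheet$pool_size[st$sheet$sample_id == id],
      seed = methlineage:::derive_seed(st$params$seed, id))
    gmean <- sum(calls$m) / sum(calls$n)
    vals <- c()
    for (r in set_ids) {
      reg <- st$truth$catalog[st$truth$catalog$id == r, ]
      inside <- calls$chrom == reg$chrom & calls$pos0 >= reg$start &
        calls$pos0 < reg$end
      if (sum(calls$n[inside]) >= 3)
        vals <- c(vals, sum(calls$m[inside]) / sum(calls$n[inside]))
    }
    expect_equal(prof$delta[prof$sample_id == id], mean(vals) - gmean,
                 tolerance = 1e-12)
  }
})

test_that("differential regions require both FDR and effect thresholds", {
  expect_equal(formals(diff_regions)$fdr, 0.05)
  expect_equal(formals(diff_regions)$min_diff, 0.167)
  set.seed(42)
  beta <- matrix(runif(80, 0.3, 0.7), 8, 10,
                 dimnames = list(sprintf("s%d", 1:8), sprintf("r%d", 1:10)))
  mat <- make_mat(beta)
  ## identical groups (same matrix rows duplicated) -> zero passes
  dup <- rbind(beta, beta)
  rownames(dup) <- sprintf("s%d", 1:16)
  mat2 <- make_mat(dup)
  res <- diff_regions(mat2, sprintf("s%d", 1:8), sprintf("s%d", 9:16))
  expect_false(any(res$pass))
  expect_true(all(res$p == 1))
  ## swapping groups negates differences and preserves p
  r1 <- diff_regions(mat, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  r2 <- diff_regions(mat, sprintf("s%d", 5:8), sprintf("s%d", 1:4))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$diff, -r2$diff[match(r1$region, r2$region)])
  ## BH q-values never fall below their p-values and are rank-monotone
  expect_true(all(r1$q >= r1$p - 1e-15))
  expect_true(all(diff(r1$q[order(r1$p)]) >= -1e-15))
  expect_error(diff_regions(mat, c("s1", "s2"), c("s2", "s3")), "overlap")
  expect_error(diff_regions(mat, "s1", c("s2", "s3")), "at least 2")
})

test_that("planted differences are recovered with controlled error", {
  ## 11 vs 11 pooled samples, shift 0.3 in 30 of 120 regions. The fixture
  ## uses 50-cell pools at ~2 reads/CpG: at 10-cell pools and shallower
  ## depth, cell-sampling noise alone caps per-region power below the
  ## recall target (see the methods vignette).
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 30L,
                                shift_mag = 0.3))
  hits <- lapply(1:10, function(seed) {
    pr <- sim_params(seed = seed, n_regions = 120L, donors = 1L,
                     single_cells = 0L,
                     pool_design = data.frame(pool_size = 50L,
                                              replicates = 11L),
                     coverage_mean = c(`50` = 2))
    tru <- simulate_propensities(tr, pr)
    sheet <- methlineage:::build_sample_sheet(tr, pr)
    agg <- lapply(seq_len(nrow(sheet)), function(i)
      aggregate_to_regions(
        simulate_sample(tru, sheet$cell_type[i], sheet$pool_size[i],
                        seed = methlineage:::derive_seed(pr$seed,
                                                        sheet$sample_id[i])),
        tru$catalog))
    names(agg) <- sheet$sample_id
    mat <- suppressMessages(assemble_matrix(agg, sheet = sheet))
    ga <- sheet$sample_id[sheet$cell_type == "A"]
    gb <- sheet$sample_id[sheet$cell_type == "B"]
    res <- diff_regions(mat, ga, gb)
    ## recall over shifts that kept the full 0.3 magnitude after
    ## clipping; false discoveries are regions with no planted shift at
    ## all (clipped shifts are real, smaller, differences)
    full <- unique(tru$shifted$region_id[
      abs(abs(tru$shifted$shift) - 0.3) < 1e-12])
    any_planted <- unique(tru$shifted$region_id[tru$shifted$shift != 0])
    called <- res$region[res$pass]
    c(recall = mean(full %in% called),
      fdp = if (length(called)) mean(!(called %in% any_planted)) else 0)
  })
  hits <- do.call(rbind, hits)
  expect_gte(mean(hits[, "recall"]), 0.9)
  expect_lte(mean(hits[, "fdp"]), 0.1)
})

test_that("region-set Wilcoxon tests use the printed dual threshold", {
  expect_equal(formals(diff_region_sets)$alpha, 0.05)
  expect_equal(formals(diff_region_sets)$min_diff, 0.10)
  prof <- data.frame(sample_id = rep(sprintf("s%d", 1:8), 2),
                     set = rep(c("x", "y"), each = 8),
                     delta = c(rep(0.1, 8), runif(8)))
  res <- diff_region_sets(prof, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_false(any(res$pass[res$set == "x"]))
  expect_error(diff_region_sets(prof, sprintf("s%d", 1:2),
                                sprintf("s%d", 5:8)), "at least 3")
})

test_that("exact Wilcoxon p for 4 vs 4 equals full rank-assignment enumeration", {
  set.seed(33)
  for (i in 1:5) {
    x <- runif(4); y <- runif(4) + i / 10
    prof <- data.frame(sample_id = sprintf("s%d", 1:8), set = "s",
                       delta = c(x, y))
    res <- diff_region_sets(prof, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
    expect_equal(res$p, oracle_wilcoxon_two_sided(x, y), tolerance = 1e-10)
  }
})

test_that("PCA variance fractions match an independent eigendecomposition", {
  set.seed(8)
  x <- matrix(rnorm(20 * 7), 20, 7)
  pca <- pca_project(x)
  ev <- sort(eigen(stats::cov(x), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_equal(pca$var_explained, ev / sum(ev), tolerance = 1e-10)
  ## projecting the training samples returns their scores
  expect_equal(project_onto_pca(pca, x), pca$scores, tolerance = 1e-10)
  ## a rank-1 matrix loads everything on PC1
  r1 <- outer(rnorm(10), rnorm(4))
  expect_equal(pca_project(r1)$var_explained[1], 1, tolerance = 1e-10)
  xm <- x; xm[1, 1] <- NA
  expect_error(pca_project(xm), "assemble_matrix")
})

test_that("complete-linkage clustering matches the naive recursion and is stable", {
  set.seed(21)
  x <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(sprintf("i%d", 1:6), NULL))
  hc <- hcluster_order(x)
  expect_equal(sort(hc$merge_heights), oracle_complete_linkage_heights(x),
               tolerance = 1e-10)
  ## identical rows merge at height zero
  x2 <- rbind(x, x[1, , drop = FALSE])
  expect_equal(min(hcluster_order(x2)$merge_heights), 0)
  ## permuting rows relabels but preserves merge heights
  perm <- sample(6)
  hc2 <- hcluster_order(x[perm, ])
  expect_equal(sort(hc2$merge_heights), sort(hc$merge_heights))
})
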