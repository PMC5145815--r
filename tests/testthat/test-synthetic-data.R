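test_that("lineage tree validation catches malformed topologies", {
  expect_error(lineage_tree(data.frame(parent = c("A", "B"),
                                       child = c("B", "A"))),
               "root")
  expect_error(lineage_tree(data.frame(parent = c("A", "B"),
                                       child = c("B", "B"))),
               "more than one parent")
  tr <- default_lineage_tree()
  expect_setequal(tr$nodes, c("HSC", "MPP", "CMP", "MEP", "GMP",
                              "MLP0", "CLP"))
  expect_identical(tr$root, "HSC")
})

test_that("zero-magnitude shifts leave all cell types identical and seeds reproduce", {
  tr <- default_lineage_tree(shift_mag = 0)
  pr <- sim_params(n_regions = 80L, seed = 42L)
  tru <- simulate_propensities(tr, pr)
  for (ct in tr$nodes)
    expect_equal(tru$propensity[ct, ], tru$propensity["HSC", ])
  tru2 <- simulate_propensities(tr, pr)
  expect_identical(tru, tru2)
})

test_that("a chain edge shifts exactly the requested regions by the stated magnitude", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 50L,
                                shift_mag = 0.3))
  pr <- sim_params(n_regions = 200L, seed = 5L)
  tru <- simulate_propensities(tr, pr)
  dif <- tru$propensity["B", ] - tru$propensity["A", ]
  changed <- names(dif)[dif != 0]
  ## direct count/compare on the emitted ground truth
  expect_length(setdiff(tru$shifted$region_id, changed), 0)
  expect_lte(length(changed), 50L)
  expect_identical(nrow(tru$shifted), 50L)
  ## each planted shift is +/-0.3 before clipping; after clipping the
  ## recorded applied shift matches the propensity difference exactly
  expect_equal(unname(dif[tru$shifted$region_id]), tru$shifted$shift)
  raw_ok <- abs(abs(tru$shifted$shift) - 0.3) < 1e-12 |
    tru$propensity["B", tru$shifted$region_id] %in% c(0, 1)
  expect_true(all(raw_ok))
  ## non-shifted regions are identical between parent and child
  expect_equal(tru$propensity["A", setdiff(names(dif), tru$shifted$region_id)],
               tru$propensity["B", setdiff(names(dif), tru$shifted$region_id)])
})

test_that("shift counts beyond the catalog size name the offending edge", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 500L))
  expect_error(simulate_propensities(tr, sim_params(n_regions = 100L)),
               "A->B")
})

test_that("boundary propensities and error rates behave at the limits", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 0L))
  pr <- sim_params(n_regions = 40L, seed = 9L, eps01 = 0, eps10 = 0)
  tru <- simulate_propensities(tr, pr)
  tru$propensity[, ] <- 1
  s <- simulate_sample(tru, "A", 10L, params = pr, seed = 3L)
  expect_true(all(s$m == s$n))
  tru$propensity[, ] <- 0
  s0 <- simulate_sample(tru, "A", 10L, params = pr, seed = 3L)
  expect_true(all(s0$m == 0L))
})

test_that("pooled region methylation matches the binomial sampling oracle", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 0L))
  pr <- sim_params(n_regions = 60L, seed = 21L, eps01 = 0, eps10 = 0,
                   coverage_mean = c(`1000` = 10))
  tru <- simulate_propensities(tr, pr)
  s <- simulate_sample(tru, "A", 1000L, params = pr, seed = 8L)
  agg <- aggregate_to_regions(s, tru$catalog, min_total_reads = 1L)
  p <- tru$propensity["A", names(agg$beta)]
  se <- sqrt(p * (1 - p) / agg$n)
  ok <- !is.na(agg$beta)
  expect_true(all(abs(agg$beta[ok] - p[ok]) <= 3 * se[ok] + 1e-12))
})

test_that("single-cell dropout controls the covered CpG fraction", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 0L))
  pr <- sim_params(n_regions = 300L, seed = 13L, sc_dropout = 0.9)
  tru <- simulate_propensities(tr, pr)
  s <- simulate_sample(tru, "A", 1L, params = pr, seed = 2L,
                       single_cell = TRUE)
  frac <- nrow(s) / nrow(tru$cpgs)
  se <- sqrt(0.1 * 0.9 / nrow(tru$cpgs))
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("unknown cell types and non-positive pools are rejected", {
  tru <- simulate_propensities(default_lineage_tree(),
                               sim_params(n_regions = 60L))
  expect_error(simulate_sample(tru, "TCELL", 10L), "unknown cell type")
  expect_error(simulate_sample(tru, "HSC", 0L), "positive")
})

test_that("the written study matches the pooled design of 11 pools per donor", {
  pr <- sim_params(n_regions = 40L, seed = 3L, single_cells = 2L)
  out <- withr::local_tempdir()
  st <- simulate_study(default_lineage_tree(n_shift = 10L), pr,
                       file.path(out, "study"))
  sheet <- read_sample_sheet(file.path(out, "study", "sample_sheet.tsv"))
  pooled <- sheet[sheet$n_cells > 1L, ]
  ## 7 cell types x 3 donors x (8 + 2 + 1) pools
  expect_identical(nrow(pooled), 7L * 3L * 11L)
  expect_true(all(table(pooled$cell_type) == 33L))
  expect_identical(sum(sheet$n_cells == 1L), 7L * 2L)
  ## conservation: m <= n in every emitted file
  for (f in list.files(file.path(out, "study", "calls"), full.names = TRUE)) {
    calls <- read_calls(f)
    expect_true(all(calls$m <= calls$n))
  }
  ## region-set database holds per-edge sets plus decoys
  sets <- read_region_sets(file.path(out, "study", "region_sets"))
  expect_identical(sum(grepl("^decoy_", names(sets))), 10L)
  expect_gt(sum(grepl("^edge_", names(sets))), 6L)
})

test_that("zero single cells requested yields a consistent pooled-only sheet", {
  pr <- sim_params(n_regions = 30L, seed = 4L, single_cells = 0L)
  out <- withr::local_tempdir()
  st <- simulate_study(default_lineage_tree(n_shift = 10L), pr,
                       file.path(out, "s"))
  sheet <- read_sample_sheet(file.path(out, "s", "sample_sheet.tsv"))
  expect_identical(nrow(sheet), 7L * 3L * 11L)
  expect_false(any(grepl("_sc", sheet$sample_id)))
})

test_that("larger pools estimate the propensity more precisely than small pools", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 0L))
  pr <- sim_params(n_regions = 80L, seed = 17L,
                   coverage_mean = c(`10` = 2, `1000` = 2))
  tru <- simulate_propensities(tr, pr)
  p <- tru$propensity["A", ]
  err <- function(pool) {
    e <- sapply(1:8, function(r) {
      agg <- aggregate_to_regions(
        simulate_sample(tru, "A", pool, params = pr,
                        seed = methlineage:::derive_seed(1L,
                          sprintf("p%d_%d", pool, r))),
        tru$catalog, min_total_reads = 1L)
      mean(abs(agg$beta - p), na.rm = TRUE)
    })
    mean(e)
  }
  expect_lt(err(1000L), err(10L))
})

test_that("within-region CpG jitter is off by default and fixed per CpG when on", {
  tr <- lineage_tree(data.frame(parent = "A", child = "B", n_shift = 0L))
  pr0 <- sim_params(n_regions = 40L, seed = 6L)
  expect_true(all(simulate_propensities(tr, pr0)$cpgs$jitter == 0))
  prj <- sim_params(n_regions = 40L, seed = 6L, cpg_jitter = 0.1)
  truj <- simulate_propensities(tr, prj)
  expect_gt(stats::sd(truj$cpgs$jitter), 0.05)
  ## the jitter is part of the ground truth: identical across samples
  expect_identical(simulate_propensities(tr, prj)$cpgs$jitter,
                   truj$cpgs$jitter)
})
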