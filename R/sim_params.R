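#' Parameters for the synthetic methylome study generator
#'
#' Encapsulates every knob of the simulated study: the size of the toy
#' regulatory-region catalog, the pooled sampling design (replicate pools
#' per donor), per-read bisulfite error rates and the coverage model.
#'
#' Defaults mirror the sampling design of meta-epigenomic micro-WGBS
#' studies: for every cell type and donor, eight pools of 10 cells, two
#' pools of 50 cells and one pool of 1,000 cells (11 pooled libraries),
#' across 3 donors, plus sparse single-cell profiles. Sequencing depth is
#' deliberately low (about one read per CpG) to reproduce the shallow
#' coverage of small-pool libraries.
#'
#' @param n_regions number of regulatory regions in the toy catalog.
#' @param cpg_rate mean CpGs per region (per region: 1 + Poisson(cpg_rate - 1)).
#' @param root_beta shape parameters (length 2) of the Beta distribution of
#'   root methylation propensities.
#' @param donors number of donors.
#' @param pool_design data.frame with columns `pool_size`, `replicates`;
#'   default eight 10-cell, two 50-cell and one 1,000-cell pool per donor.
#' @param single_cells single-cell profiles per cell type (per donor 1).
#' @param coverage_mean named numeric: mean reads per CpG for each pool
#'   size (names are pool sizes; unlisted sizes fall back to 1) and for
#'   single cells (`"sc"`).
#' @param eps01 probability an unmethylated read is observed methylated
#'   (failed conversion).
#' @param eps10 probability a methylated read is observed unmethylated.
#' @param sc_dropout fraction of CpGs dropped entirely in single-cell mode.
#' @param cpg_jitter standard deviation of a fixed per-CpG Gaussian offset
#'   around the region propensity (default 0: per-CpG propensity equals
#'   the region propensity, which keeps the region-aggregation oracle
#'   exact).
#' @param n_decoy_sets random decoy region sets written to the region-set
#'   database.
#' @param decoy_set_size regions per decoy set.
#' @param seed master seed; all per-sample streams are derived from it, so
#'   adding a sample never perturbs the others.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_regions = 500L,
                       cpg_rate = 8,
                       root_beta = c(2, 2),
                       donors = 3L,
                       pool_design = data.frame(
                         pool_size = c(10L, 50L, 1000L),
                         replicates = c(8L, 2L, 1L)),
                       single_cells = 5L,
                       coverage_mean = c(`10` = 0.8, `50` = 1, `1000` = 1.5,
                                         sc = 1),
                       eps01 = 0.005,
                       eps10 = 0.02,
                       sc_dropout = 0.9,
                       cpg_jitter = 0,
                       n_decoy_sets = 10L,
                       decoy_set_size = 50L,
                       seed = 1L) {
  stopifnot(n_regions >= 1, cpg_rate >= 1, donors >= 1,
            all(pool_design$pool_size >= 1),
            all(pool_design$replicates >= 1))
  for (r in c(eps01, eps10, sc_dropout))
    if (r < 0 || r > 1) stop_ml("rates must lie in [0, 1]")
  structure(list(
    n_regions = as.integer(n_regions), cpg_rate = cpg_rate,
    root_beta = root_beta, donors = as.integer(donors),
    pool_design = pool_design, single_cells = as.integer(single_cells),
    coverage_mean = coverage_mean, eps01 = eps01, eps10 = eps10,
    sc_dropout = sc_dropout, cpg_jitter = cpg_jitter,
    n_decoy_sets = as.integer(n_decoy_sets),
    decoy_set_size = as.integer(decoy_set_size), seed = as.integer(seed)
  ), class = "sim_params")
}

coverage_for <- function(params, pool_size, single_cell = FALSE) {
  cm <- params$coverage_mean
  if (single_cell) return(unname(cm[["sc"]] %||% 1))
  key <- as.character(pool_size)
  if (key %in% names(cm)) unname(cm[[key]]) else 1
}
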