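#' Simulate ground-truth region methylation propensities along a lineage
#'
#' Draws root methylation propensities from a Beta distribution, then walks
#' the lineage tree: every child inherits its parent's propensities and a
#' planted subset of regions is shifted by the edge's magnitude (random
#' sign per region unless fixed), clipped to \[0, 1\]. Also lays out the toy
#' regulatory-region catalog (six regulatory classes) and the CpG positions
#' inside each region. All draws are reproducible from `params$seed`.
#'
#' @param tree a [lineage_tree()].
#' @param params a [sim_params()].
#' @return An object of class `ground_truth`: `propensity` (cell types x
#'   regions matrix), `shifted` (planted differential regions per edge with
#'   sign and applied shift), `catalog`, `cpgs`, `tree`, `params`.
#' @export
simulate_propensities <- function(tree, params) {
  stopifnot(inherits(tree, "lineage_tree"), inherits(params, "sim_params"))
  nr <- params$n_regions
  bad <- tree$edges$n_shift > nr
  if (any(bad))
    stop_ml("edge %s->%s requests %d shifted regions but only %d regions exist",
            tree$edges$parent[bad][1], tree$edges$child[bad][1],
            tree$edges$n_shift[bad][1], nr)

  region_id <- sprintf("R%04d", seq_len(nr))
  catalog <- with_seed(derive_seed(params$seed, "catalog"), {
    per_contig <- 100L
    contig <- sprintf("chr%d", (seq_len(nr) - 1L) %/% per_contig + 1L)
    slot <- (seq_len(nr) - 1L) %% per_contig
    start <- slot * 1000L + 200L
    types <- c("promoter_proximal", "promoter_distal", "ctcf",
               "enhancer", "tfbs", "open_chromatin")
    data.frame(chrom = contig, start = start, end = start + 600L,
               id = region_id,
               type = sample(types, nr, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  cpgs <- with_seed(derive_seed(params$seed, "cpgs"), {
    n_cpg <- 1L + stats::rpois(nr, params$cpg_rate - 1)
    lst <- lapply(seq_len(nr), function(i) {
      pos <- sort(sample.int(600L, n_cpg[i]) - 1L) + catalog$start[i]
      data.frame(chrom = catalog$chrom[i], pos0 = pos,
                 region_id = region_id[i],
                 jitter = if (params$cpg_jitter > 0)
                   stats::rnorm(n_cpg[i], 0, params$cpg_jitter) else
                   rep(0, n_cpg[i]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, lst)
  })

  prop <- matrix(NA_real_, nrow = length(tree$nodes), ncol = nr,
                 dimnames = list(tree$nodes, region_id))
  shifted <- list()
  with_seed(derive_seed(params$seed, "propensities"), {
    prop[tree$root, ] <- stats::rbeta(nr, params$root_beta[1],
                                       params$root_beta[2])
    edges <- topo_edges(tree)
    for (i in seq_len(nrow(edges))) {
      par <- edges$parent[i]; chi <- edges$child[i]
      p <- prop[par, ]
      k <- edges$n_shift[i]
      if (k > 0) {
        idx <- sample.int(nr, k)
        sgn <- if (is.na(edges$shift_sign[i]))
          sample(c(-1, 1), k, replace = TRUE) else rep(edges$shift_sign[i], k)
        raw <- p[idx] + sgn * edges$shift_mag[i]
        new <- pmin(1, pmax(0, raw))
        shifted[[length(shifted) + 1L]] <- data.frame(
          parent = par, child = chi, region_id = region_id[idx],
          sign = sgn, shift = new - p[idx], stringsAsFactors = FALSE)
        p[idx] <- new
      }
      prop[chi, ] <- p
    }
  })
  shifted <- if (length(shifted)) do.call(rbind, shifted) else
    data.frame(parent = character(0), child = character(0),
               region_id = character(0), sign = numeric(0), shift = numeric(0))
  structure(list(propensity = prop, shifted = shifted, catalog = catalog,
                 cpgs = cpgs, tree = tree, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cell types x %d regions (%d CpGs), %d planted shifts\n",
              nrow(x$propensity), ncol(x$propensity), nrow(x$cpgs),
              nrow(x$shifted)))
  invisible(x)
}

#' Simulate one bisulfite methylome sample (pool of cells or single cell)
#'
#' For each cell in the pool and each CpG, the true methylation state is
#' Bernoulli with the region propensity of the sample's cell type. Reads
#' per CpG follow the coverage model (Poisson for pools; Bernoulli CpG
#' dropout followed by zero-truncated Poisson for single cells, so the
#' covered fraction equals 1 - dropout). Each read samples a random cell of
#' the pool — two reads hitting the same cell see the same state — and is
#' then flipped by the bisulfite error rates `eps01`/`eps10`.
#'
#' @param truth a `ground_truth` from [simulate_propensities()].
#' @param cell_type one of the tree's cell types.
#' @param pool_size number of cells in the pool (1 for single cells).
#' @param params a [sim_params()]; defaults to the one inside `truth`.
#' @param seed integer seed for this sample's stream.
#' @param single_cell use the single-cell coverage model (CpG dropout).
#' @return A CpG call table: data.frame with `chrom`, `pos0` (0-based CpG
#'   position), `m` (methylated reads), `n` (total reads), sorted by
#'   position; CpGs with zero reads are omitted.
#' @export
simulate_sample <- function(truth, cell_type, pool_size,
                            params = truth$params, seed = params$seed,
                            single_cell = FALSE) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!cell_type %in% rownames(truth$propensity))
    stop_ml("unknown cell type '%s'", cell_type)
  if (pool_size < 1) stop_ml("pool size must be positive, got %s", pool_size)
  cpgs <- truth$cpgs
  p <- pmin(1, pmax(0, truth$propensity[cell_type, cpgs$region_id] +
                      cpgs$jitter))
  lambda <- coverage_for(params, pool_size, single_cell)
  with_seed(seed, {
    ncpg <- nrow(cpgs)
    if (single_cell) {
      covered <- stats::runif(ncpg) >= params$sc_dropout
      nreads <- integer(ncpg)
      nreads[covered] <- rztpois(sum(covered), lambda)
    } else {
      nreads <- stats::rpois(ncpg, lambda)
    }
    total <- sum(nreads)
    cpg_idx <- rep.int(seq_len(ncpg), nreads)
    cell <- sample.int(pool_size, total, replace = TRUE)
    key <- (cpg_idx - 1) * pool_size + cell
    uk <- !duplicated(key)
    ustate <- stats::rbinom(sum(uk), 1L, p[cpg_idx[uk]])
    state <- ustate[match(key, key[uk])]
    flip <- stats::runif(total)
    obs <- ifelse(state == 1L, flip >= params$eps10, flip < params$eps01)
    keep <- nreads > 0L
    m <- integer(ncpg)
    if (total > 0L) {
      agg <- rowsum(as.integer(obs), cpg_idx)
      m[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out <- data.frame(chrom = cpgs$chrom[keep], pos0 = cpgs$pos0[keep],
                      m = m[keep], n = nreads[keep],
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos0), , drop = FALSE]
  })
}

#' Simulate and write a complete multi-cell-type methylome study
#'
#' Generates ground truth with [simulate_propensities()], then writes one
#' Bismark-coverage-style call file per sample for the full design (every
#' cell type x donor x pool replicate, plus single cells), the sample
#' sheet, the region catalog (BED), a region-set database (one set per
#' lineage edge and shift direction, plus random decoy sets) and the
#' ground-truth tables. Identical seeds yield byte-identical output trees.
#'
#' @inheritParams simulate_propensities
#' @param out_dir output directory (created; must be writable).
#' @return Invisibly, list with `truth`, `sheet` (the sample sheet) and
#'   `dir`.
#' @export
simulate_study <- function(tree, params, out_dir) {
  truth <- simulate_propensities(tree, params)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_ml("cannot create output directory '%s'", out_dir)
  for (d in c("calls", "regions", "region_sets", "truth"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  sheet <- build_sample_sheet(tree, params)
  for (i in seq_len(nrow(sheet))) {
    s <- sheet[i, ]
    calls <- simulate_sample(truth, s$cell_type, s$pool_size,
                             params = params,
                             seed = derive_seed(params$seed, s$sample_id),
                             single_cell = s$n_cells == 1L && s$single_cell)
    write_calls(calls, file.path(out_dir, "calls",
                                 paste0(s$sample_id, ".cov")))
  }
  sheet$file <- file.path("calls", paste0(sheet$sample_id, ".cov"))
  write_sample_sheet(sheet[, c("sample_id", "cell_type", "donor",
                               "pool_size", "n_cells", "source", "file")],
                     file.path(out_dir, "sample_sheet.tsv"))
  write_regions(truth$catalog, file.path(out_dir, "regions", "catalog.bed"))

  ## region-set database: per-edge hypo/hyper sets + random decoys
  cat_by_id <- truth$catalog[match(truth$catalog$id, truth$catalog$id), ]
  for (e in unique(paste(truth$shifted$parent, truth$shifted$child))) {
    pc <- strsplit(e, " ")[[1]]
    sub <- truth$shifted[truth$shifted$parent == pc[1] &
                         truth$shifted$child == pc[2], ]
    for (dir_lab in c("hypo", "hyper")) {
      ids <- sub$region_id[if (dir_lab == "hypo") sub$sign < 0 else sub$sign > 0]
      if (!length(ids)) next
      write_regions(truth$catalog[truth$catalog$id %in% ids, ],
                    file.path(out_dir, "region_sets",
                              sprintf("edge_%s_%s_%s.bed", pc[1], pc[2], dir_lab)))
    }
  }
  with_seed(derive_seed(params$seed, "decoys"), {
    for (k in seq_len(params$n_decoy_sets)) {
      ids <- truth$catalog$id[sample.int(params$n_regions,
                                         min(params$decoy_set_size,
                                             params$n_regions))]
      write_regions(truth$catalog[truth$catalog$id %in% ids, ],
                    file.path(out_dir, "region_sets",
                              sprintf("decoy_%02d.bed", k)))
    }
  })

  write_propensities(truth, file.path(out_dir, "truth", "propensities.tsv"))
  utils::write.table(truth$shifted,
                     file.path(out_dir, "truth", "shifted_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    generator = "methlineage::simulate_study",
    seed = params$seed,
    n_regions = params$n_regions,
    donors = params$donors,
    pool_design = params$pool_design,
    single_cells = params$single_cells,
    eps01 = params$eps01, eps10 = params$eps10,
    sc_dropout = params$sc_dropout,
    cell_types = tree$nodes,
    edges = truth$tree$edges[, c("parent", "child", "n_shift", "shift_mag")],
    n_samples = nrow(sheet))
  jsonlite::write_json(manifest, file.path(out_dir, "truth", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth, sheet = sheet, dir = out_dir))
}

build_sample_sheet <- function(tree, params) {
  rows <- list()
  for (ct in tree$nodes) {
    for (d in seq_len(params$donors)) {
      for (j in seq_len(nrow(params$pool_design))) {
        ps <- params$pool_design$pool_size[j]
        for (r in seq_len(params$pool_design$replicates[j])) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_d%d_n%d_r%d", ct, d, ps, r),
            cell_type = ct, donor = d, pool_size = ps, n_cells = ps,
            source = "PB", single_cell = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    if (params$single_cells > 0L) {
      for (i in seq_len(params$single_cells)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_sc%02d", ct, i),
          cell_type = ct, donor = (i - 1L) %% params$donors + 1L,
          pool_size = 1L, n_cells = 1L, source = "PB", single_cell = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

write_propensities <- function(truth, path) {
  df <- data.frame(cell_type = rownames(truth$propensity),
                   truth$propensity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
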