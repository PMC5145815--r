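#' Aggregate CpG-level calls onto catalog regions
#'
#' Region-level methylation is count-weighted: beta = sum(m) / sum(n) over
#' all CpGs whose 0-based position falls in the half-open region interval.
#' Regions with fewer than `min_total_reads` reads are marked missing.
#' Also returns the sample's global CpG methylation mean (over all CpGs in
#' the call table, not only those inside regions).
#'
#' @param calls CpG call table from [read_calls()] or [simulate_sample()].
#' @param catalog region catalog from [read_regions()] or [make_tiles()].
#' @param min_total_reads minimum summed reads for a region estimate
#'   (default 3; single-read estimates are binary noise).
#' @return list with named vectors `beta` (NA where missing), `m`, `n`,
#'   `cpgs`, and scalar `gmean`.
#' @export
aggregate_to_regions <- function(calls, catalog, min_total_reads = 3L) {
  if (nrow(catalog) == 0L) stop_ml("region catalog is empty")
  nr <- nrow(catalog)
  m <- n <- k <- stats::setNames(numeric(nr), catalog$id)
  if (nrow(calls)) {
    cpg_gr <- GenomicRanges::GRanges(calls$chrom,
      IRanges::IRanges(calls$pos0 + 1L, calls$pos0 + 1L))
    reg_gr <- GenomicRanges::GRanges(catalog$chrom,
      IRanges::IRanges(catalog$start + 1L, catalog$end))
    hits <- GenomicRanges::findOverlaps(cpg_gr, reg_gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      am <- rowsum(calls$m[qi], si)
      an <- rowsum(calls$n[qi], si)
      ak <- rowsum(rep(1L, length(qi)), si)
      idx <- as.integer(rownames(am))
      m[idx] <- am[, 1L]; n[idx] <- an[, 1L]; k[idx] <- ak[, 1L]
    }
  }
  beta <- ifelse(n >= min_total_reads, m / n, NA_real_)
  gmean <- if (nrow(calls) && sum(calls$n) > 0)
    sum(calls$m) / sum(calls$n) else NA_real_
  list(beta = beta, m = m, n = n, cpgs = k, gmean = gmean)
}

#' Tile a toy genome into fixed-width regions
#'
#' Non-overlapping half-open tiles of `width` covering each contig; the
#' last partial tile is kept. The 5-kb default matches the granularity of
#' genome-wide methylation-distribution summaries.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param width tile width in bp (default 5000).
#' @return region catalog data.frame (type `"tile"`).
#' @export
make_tiles <- function(contig_lengths, width = 5000L) {
  if (width <= 0) stop_ml("tile width must be positive")
  if (is.null(names(contig_lengths)))
    stop_ml("contig_lengths must be named")
  out <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq.int(0L, max(0L, len - 1L), by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(width), as.integer(len)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- sprintf("tile_%s_%06d", out$chrom, out$start)
  out$type <- "tile"
  out
}

#' Combine replicate samples into a meta-epigenome consensus entry
#'
#' The consensus level per region pools the raw counts of all replicates
#' (equivalent to aggregating their concatenated call tables); variability
#' is the sample standard deviation of per-replicate region levels over
#' replicates where the level is present.
#'
#' @param agg_list list of [aggregate_to_regions()] results for the
#'   replicates of one cell type.
#' @param min_total_reads coverage threshold for the pooled consensus.
#' @return list with named vectors `consensus`, `sd`, `n_rep` and pooled
#'   counts `m`, `n`.
#' @export
combine_replicates <- function(agg_list, min_total_reads = 3L) {
  if (!length(agg_list)) stop_ml("no replicates to combine")
  m <- Reduce(`+`, lapply(agg_list, `[[`, "m"))
  n <- Reduce(`+`, lapply(agg_list, `[[`, "n"))
  betas <- do.call(rbind, lapply(agg_list, `[[`, "beta"))
  consensus <- ifelse(n >= min_total_reads, m / n, NA_real_)
  sdv <- apply(betas, 2L, function(b) {
    b <- b[!is.na(b)]
    if (length(b) >= 2L) stats::sd(b) else NA_real_
  })
  n_rep <- colSums(!is.na(betas))
  list(consensus = consensus, sd = sdv, n_rep = n_rep, m = m, n = n)
}

#' Assemble the samples x regions methylation matrix
#'
#' Regions missing in more than `max_missing` of the samples are dropped;
#' remaining missing entries are imputed with the per-region mean across
#' samples (neutral for regularized linear models). Which entries were
#' imputed is recorded.
#'
#' @param agg_list named list (by sample id) of [aggregate_to_regions()]
#'   results, all over the same catalog.
#' @param max_missing maximum tolerated fraction of samples missing a
#'   region (default 0.2).
#' @param sheet optional sample sheet carried along (rows matching
#'   `names(agg_list)`).
#' @return An object of class `meth_matrix`: `beta` (imputed, complete),
#'   `n`, `cpgs`, `imputed` (logical mask), `gmean` (per-sample global CpG
#'   mean), `regions` (retained ids), `sheet`.
#' @export
assemble_matrix <- function(agg_list, max_missing = 0.2, sheet = NULL) {
  if (!length(agg_list)) stop_ml("no samples to assemble")
  ids <- names(agg_list)
  if (is.null(ids)) stop_ml("agg_list must be named by sample id")
  beta <- do.call(rbind, lapply(agg_list, `[[`, "beta"))
  nmat <- do.call(rbind, lapply(agg_list, `[[`, "n"))
  kmat <- do.call(rbind, lapply(agg_list, `[[`, "cpgs"))
  rownames(beta) <- rownames(nmat) <- rownames(kmat) <- ids
  miss_frac <- colMeans(is.na(beta))
  keep <- miss_frac <= max_missing
  if (!any(keep))
    stop_ml(paste0("all regions exceed the missingness threshold (%.2f); ",
                   "consider raising max_missing or lowering min_total_reads"),
            max_missing)
  beta <- beta[, keep, drop = FALSE]
  nmat <- nmat[, keep, drop = FALSE]
  kmat <- kmat[, keep, drop = FALSE]
  imputed <- is.na(beta)
  if (any(imputed)) {
    col_mean <- colMeans(beta, na.rm = TRUE)
    idx <- which(imputed, arr.ind = TRUE)
    beta[imputed] <- col_mean[idx[, 2L]]
  }
  structure(list(
    beta = beta, n = nmat, cpgs = kmat, imputed = imputed,
    gmean = vapply(agg_list, `[[`, numeric(1), "gmean"),
    regions = colnames(beta), sheet = sheet
  ), class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d regions (%d imputed entries, %.1f%%)\n",
              nrow(x$beta), ncol(x$beta), sum(x$imputed),
              100 * mean(x$imputed)))
  invisible(x)
}

#' Write / read a `meth_matrix` as a set of TSV files
#'
#' Writes `<prefix>_beta.tsv`, `_n.tsv`, `_cpgs.tsv`, `_imputed.tsv` and
#' `_gmean.tsv` with sample and region headers; missing values are the
#' literal token `NA`. [read_meth_matrix()] restores the object, including
#' the imputation mask, to full double precision.
#'
#' @param mat a `meth_matrix`.
#' @param prefix path prefix for the output files.
#' @export
write_meth_matrix <- function(mat, prefix) {
  wm <- function(x, suff) {
    cols <- lapply(seq_len(ncol(x)), function(j) sprintf("%.17g", x[, j]))
    df <- data.frame(c(list(sample_id = rownames(x)),
                       stats::setNames(cols, colnames(x))),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, paste0(prefix, "_", suff, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wm(mat$beta, "beta"); wm(mat$n, "n"); wm(mat$cpgs, "cpgs")
  utils::write.table(
    data.frame(sample_id = rownames(mat$imputed),
               ifelse(mat$imputed, "1", "0"), check.names = FALSE),
    paste0(prefix, "_imputed.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(mat$gmean),
               gmean = sprintf("%.17g", mat$gmean)),
    paste0(prefix, "_gmean.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_meth_matrix
#' @return [read_meth_matrix()]: the restored `meth_matrix`.
#' @export
read_meth_matrix <- function(prefix) {
  rm_ <- function(suff) {
    df <- utils::read.delim(paste0(prefix, "_", suff, ".tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    x <- as.matrix(df[, -1L, drop = FALSE])
    rownames(x) <- df[[1L]]
    x
  }
  beta <- rm_("beta"); nmat <- rm_("n"); kmat <- rm_("cpgs")
  imputed <- rm_("imputed") == 1
  gdf <- utils::read.delim(paste0(prefix, "_gmean.tsv"),
                           stringsAsFactors = FALSE)
  structure(list(beta = beta, n = nmat, cpgs = kmat, imputed = imputed,
                 gmean = stats::setNames(gdf$gmean, gdf$sample_id),
                 regions = colnames(beta), sheet = NULL),
            class = "meth_matrix")
}
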