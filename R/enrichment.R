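#' Flag universe regions overlapping a region set
#'
#' A universe region is "in" the set iff it overlaps at least one set
#' interval by at least one base (0-based half-open semantics); multiple
#' overlaps count once.
#'
#' @param universe region catalog (the tested regions).
#' @param set data.frame of intervals (`chrom`, `start`, `end`).
#' @return logical vector along `universe` rows.
#' @export
overlap_universe <- function(universe, set) {
  if (nrow(universe) == 0L) stop_ml("universe is empty")
  if (nrow(set) == 0L) return(rep(FALSE, nrow(universe)))
  lv <- unique(c(universe$chrom, set$chrom))
  ugr <- GenomicRanges::GRanges(factor(universe$chrom, lv),
    IRanges::IRanges(universe$start + 1L, universe$end))
  sgr <- GenomicRanges::GRanges(factor(set$chrom, lv),
    IRanges::IRanges(set$start + 1L, set$end))
  IRanges::overlapsAny(ugr, sgr)
}

#' Region-set overlap enrichment via Fisher's exact test
#'
#' For each database set, a 2x2 table is built from the query/set
#' membership of every universe region: a = query regions in the set,
#' b = query regions outside, c = background regions in the set, d = the
#' remainder. The two-sided Fisher exact p (one-sided selectable via
#' `alternative = "greater"`) is BH-adjusted over all database sets. The
#' odds ratio is reported raw (ad/bc, possibly infinite) and with the
#' Haldane-Anscombe 0.5 correction.
#'
#' @param query character vector of region ids, a subset of the universe.
#' @param universe region catalog defining the background.
#' @param database named list of region sets (from [read_region_sets()]).
#' @param alternative `"two.sided"` (default) or `"greater"`/`"less"`.
#' @param q_threshold significance flag threshold (default 0.05).
#' @return data.frame with per-set counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `odds_ratio_corrected`, `p`, `q`, `support` (= a), `significant`,
#'   sorted by q then descending odds ratio.
#' @export
enrich_regions <- function(query, universe, database,
                           alternative = "two.sided", q_threshold = 0.05) {
  if (nrow(universe) == 0L) stop_ml("universe is empty")
  if (!length(query)) stop_ml("query is empty")
  if (!length(database)) stop_ml("region-set database is empty")
  offenders <- setdiff(query, universe$id)
  if (length(offenders))
    stop_ml("query regions not in the universe: %s",
            paste(utils::head(offenders, 5L), collapse = ", "))
  in_query <- universe$id %in% query
  res <- lapply(names(database), function(nm) {
    flags <- overlap_universe(universe, database[[nm]])
    a <- sum(in_query & flags); b <- sum(in_query & !flags)
    cc <- sum(!in_query & flags); d <- sum(!in_query & !flags)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                            alternative = alternative)$p.value
    or_raw <- (a * d) / (b * cc)
    or_cor <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    data.frame(set = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = or_raw, odds_ratio_corrected = or_cor,
               p = p, support = a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_threshold
  out[order(out$q, -out$odds_ratio_corrected), , drop = FALSE]
}
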