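#' Read a Bismark-coverage-style CpG methylation call file
#'
#' Expected columns (tab-separated): chromosome, start (1-based), end,
#' methylation percentage, count methylated, count unmethylated. Positions
#' are converted to the package-internal 0-based convention at this
#' boundary and records are sorted by (chrom, position). Records with zero
#' total reads are dropped with a message. Strand is assumed to have been
#' merged upstream.
#'
#' @param path path to the coverage file.
#' @return data.frame with columns `chrom`, `pos0` (0-based), `m`, `n`.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop_ml("call file '%s' does not exist", path)
  lines <- readLines(path)
  if (!length(lines)) {
    warning(sprintf("call file '%s' is empty", path), call. = FALSE)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      m = integer(0), n = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop_ml("malformed call record at line %d of '%s' (expected 6 fields, got %d)",
            which(nf != 6L)[1], path, nf[nf != 6L][1])
  tab <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(tab[, 2L]))
  m <- suppressWarnings(as.integer(tab[, 5L]))
  u <- suppressWarnings(as.integer(tab[, 6L]))
  bad <- which(is.na(pos1) | is.na(m) | is.na(u))
  if (length(bad))
    stop_ml("malformed call record at line %d of '%s'", bad[1], path)
  neg <- which(m < 0L | u < 0L)
  if (length(neg))
    stop_ml("negative read count at line %d of '%s'", neg[1], path)
  n <- m + u
  zero <- n == 0L
  if (any(zero))
    message(sprintf("read_calls: dropped %d zero-coverage records from '%s'",
                    sum(zero), path))
  out <- data.frame(chrom = tab[!zero, 1L], pos0 = pos1[!zero] - 1L,
                    m = m[!zero], n = n[!zero], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  if (anyDuplicated(paste(out$chrom, out$pos0)))
    stop_ml("duplicate CpG position in '%s'", path)
  rownames(out) <- NULL
  out
}

#' Write a CpG call table in Bismark coverage format
#'
#' @param calls data.frame with `chrom`, `pos0`, `m`, `n` (internal 0-based).
#' @param path output path.
#' @export
write_calls <- function(calls, path) {
  stopifnot(all(c("chrom", "pos0", "m", "n") %in% names(calls)))
  if (any(calls$m > calls$n)) stop_ml("methylated count exceeds total count")
  pos1 <- calls$pos0 + 1L
  pct <- ifelse(calls$n > 0, 100 * calls$m / calls$n, 0)
  lines <- sprintf("%s\t%d\t%d\t%.6f\t%d\t%d", calls$chrom, pos1, pos1,
                   pct, calls$m, calls$n - calls$m)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a region catalog
#'
#' BED coordinates are 0-based half-open and are kept as such internally.
#' Column 4 (if present) is the region id, column 5 the region type label.
#' Missing ids are synthesized from coordinates. Overlapping regions are
#' permitted and loaded verbatim.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `id`, `type`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_ml("BED file '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop_ml("malformed BED record at line %d of '%s'",
            which(lengths(parts) < 3L)[1], path)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.integer(vapply(parts, `[[`, "", 2L))
  end <- as.integer(vapply(parts, `[[`, "", 3L))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop_ml("invalid interval at line %d of '%s': %s", bad[1], path,
            lines[bad[1]])
  id <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 4L) parts[[i]][4L] else
      sprintf("%s:%d-%d", chrom[i], start[i], end[i]), "")
  type <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 5L) parts[[i]][5L] else NA_character_, "")
  if (anyDuplicated(id))
    stop_ml("duplicate region id '%s' in '%s'", id[duplicated(id)][1], path)
  data.frame(chrom = chrom, start = start, end = end, id = id, type = type,
             stringsAsFactors = FALSE)
}

#' Write a region catalog as BED (0-based, half-open)
#' @param regions data.frame with `chrom`, `start`, `end`, `id` and
#'   optionally `type`.
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  type <- regions$type %||% rep(NA_character_, nrow(regions))
  lines <- ifelse(is.na(type),
                  sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                          regions$end, regions$id),
                  sprintf("%s\t%d\t%d\t%s\t%s", regions$chrom, regions$start,
                          regions$end, regions$id, type))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directory of BED files as a named region-set database
#'
#' Each `.bed` file becomes one named interval set; the set name is the
#' file stem.
#'
#' @param dir directory containing BED files.
#' @return named list of region data.frames.
#' @export
read_region_sets <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (!length(files)) stop_ml("no BED files found in '%s'", dir)
  sets <- lapply(files, read_regions)
  names(sets) <- sub("\\.bed$", "", basename(files))
  sets
}

#' Read / write the sample sheet
#'
#' Tab-separated with at least `sample_id`, `cell_type`, `donor`,
#' `pool_size`. Sample ids must be unique; if a `file` column is present,
#' every referenced call file must exist relative to the sheet.
#'
#' @param path sheet path.
#' @param check_files verify referenced call files exist.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "donor", "pool_size")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop_ml("sample sheet '%s' lacks columns: %s", path,
            paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop_ml("duplicate sample id '%s' in sheet",
            sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (check_files && !is.null(sheet$file)) {
    paths <- file.path(dirname(path), sheet$file)
    gone <- !file.exists(paths)
    if (any(gone))
      stop_ml("call file '%s' referenced by sample '%s' does not exist",
              sheet$file[gone][1], sheet$sample_id[gone][1])
  }
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
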