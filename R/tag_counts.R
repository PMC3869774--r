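#' Tag-count matrix for an age-staged SAGE experiment
#'
#' Container for raw SuperSAGE tag counts: one row per gene, one column per
#' age stage (sequencing library), plus the per-library tag totals used for
#' tags-per-million normalization. Library totals may exceed the column sums
#' because a library can contain tags not assigned to any gene.
#'
#' @param counts Non-negative integer matrix, genes x stages, with rownames
#'   giving unique gene identifiers.
#' @param stage_days Strictly increasing integer vector of age-stage labels
#'   (days of growth), one per column of `counts`.
#' @param library_totals Positive numeric vector of per-stage library sizes
#'   (total tag counts). Defaults to the column sums of `counts`.
#' @return An object of class `"tag_counts"`: a list with elements `counts`,
#'   `stage_days` and `library_totals`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2, dimnames = list(c("g1", "g2"), NULL))
#' tc <- tag_counts(m, stage_days = c(6, 14))
#' dim(tc)
#' @export
tag_counts <- function(counts, stage_days, library_totals = colSums(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("'counts' must have unique rownames (gene identifiers)")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("'counts' must contain non-negative integers only")
  stage_days <- as.integer(stage_days)
  if (length(stage_days) != ncol(counts))
    stopf("length(stage_days) (%d) != ncol(counts) (%d)",
          length(stage_days), ncol(counts))
  if (length(stage_days) == 0L) stopf("at least one age stage is required")
  if (is.unsorted(stage_days, strictly = TRUE))
    stopf("'stage_days' must be strictly increasing")
  library_totals <- as.double(library_totals)
  if (length(library_totals) != ncol(counts) || any(library_totals <= 0))
    stopf("'library_totals' must be positive, one per stage")
  if (any(library_totals < colSums(counts) - 1e-8))
    stopf("'library_totals' must be >= the per-stage column sums")
  storage.mode(counts) <- "integer"
  colnames(counts) <- paste0("day_", stage_days)
  structure(
    list(counts = counts, stage_days = stage_days,
         library_totals = library_totals),
    class = "tag_counts")
}

#' @export
dim.tag_counts <- function(x) dim(x$counts)

#' @export
print.tag_counts <- function(x, ...) {
  cat(sprintf("tag_counts: %d genes x %d age stages (days %s)\n",
              nrow(x$counts), length(x$stage_days),
              paste(x$stage_days, collapse = ", ")))
  cat(sprintf("library totals: %s\n",
              paste(format(x$library_totals, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Read and write tag-count tables
#'
#' The on-disk format is a plain TSV: an optional metadata line
#' `# library_totals<TAB>t1<TAB>t2...`, a header line `gene_id<TAB>day_6...`,
#' then one row per gene with integer counts. Writing then reading reproduces
#' the object exactly. Malformed input (ragged rows, duplicate gene ids,
#' negative or non-integer cells) is rejected with the offending line number.
#'
#' @param path Path of the TSV file.
#' @return `load_counts()` returns a [tag_counts()] object; `write_counts()`
#'   returns `path` invisibly.
#' @export
load_counts <- function(path) {
  if (!file.exists(path)) stopf("count file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty count file: %s", path)
  totals <- NULL
  offset <- 0L
  if (startsWith(lines[1L], "#")) {
    meta <- strsplit(sub("^#\\s*", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
    if (identical(meta[1L], "library_totals"))
      totals <- as.double(meta[-1L])
    offset <- 1L
  }
  header <- strsplit(lines[offset + 1L], "\t", fixed = TRUE)[[1L]]
  days <- as.integer(sub("^day_", "", header[-1L]))
  if (anyNA(days))
    stopf("header must label stage columns as day_<d>, got: %s",
          paste(header[-1L], collapse = ", "))
  body <- lines[-seq_len(offset + 1L)]
  body <- body[nzchar(body)]
  n_col <- length(header)
  cells <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != n_col))
    stopf("ragged row at line %d: expected %d fields, found %d",
          which(lens != n_col)[1L] + offset + 1L, n_col,
          lens[which(lens != n_col)[1L]])
  ids <- vapply(cells, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("duplicate gene id '%s' at line %d",
          ids[which(duplicated(ids))[1L]],
          which(duplicated(ids))[1L] + offset + 1L)
  vals <- suppressWarnings(
    vapply(cells, function(r) as.double(r[-1L]), double(n_col - 1L)))
  vals <- if (n_col == 2L) matrix(vals, nrow = 1L) else vals
  bad <- which(apply(vals, 2L, function(v)
    anyNA(v) || any(v < 0) || any(v != round(v))))
  if (length(bad))
    stopf("non-integer or negative count at line %d",
          bad[1L] + offset + 1L)
  m <- t(vals)
  rownames(m) <- ids
  if (is.null(totals)) totals <- colSums(m)
  tag_counts(m, stage_days = days, library_totals = totals)
}

#' @rdname load_counts
#' @param x A [tag_counts()] object.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "tag_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# library_totals",
                     format(x$library_totals, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(x$counts)), collapse = "\t"), con)
  body <- apply(x$counts, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(x$counts), body, sep = "\t"), con)
  invisible(path)
}
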