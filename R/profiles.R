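#' Expression-profile library
#'
#' A set of real-valued expression profiles over an ordered day vector,
#' produced from a [tag_counts()] object by [normalize_tpm()] and transformed
#' in place by [filter_missing()], [smooth_all()] and [standardize()]. Every
#' gene of the originating count matrix stays in the container; per-gene
#' status flags record which genes remain in the analysis (`"kept"`) and why
#' the others were dropped (`"removed-missing"`, `"removed-flat"`).
#'
#' @param values Numeric matrix, genes x stages, rownames = gene ids.
#' @param stage_days Integer day labels, one per column.
#' @param scale One of `"tpm"`, `"smoothed"`, `"standardized"`.
#' @param flags Character vector of per-gene status flags (default all
#'   `"kept"`).
#' @return An object of class `"profile_set"`.
#' @export
profile_set <- function(values, stage_days,
                        scale = c("tpm", "smoothed", "standardized"),
                        flags = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values))) stopf("'values' must have gene-id rownames")
  stage_days <- as.integer(stage_days)
  if (length(stage_days) != ncol(values))
    stopf("length(stage_days) != ncol(values)")
  if (is.null(flags)) flags <- rep("kept", nrow(values))
  if (length(flags) != nrow(values)) stopf("one flag per gene required")
  ok <- flags %in% c("kept", "removed-missing", "removed-flat")
  if (!all(ok)) stopf("unknown flag: %s", flags[!ok][1L])
  names(flags) <- rownames(values)
  colnames(values) <- paste0("day_", stage_days)
  structure(list(values = values, stage_days = stage_days, scale = scale,
                 flags = flags),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  tab <- table(factor(x$flags,
                      c("kept", "removed-missing", "removed-flat")))
  cat(sprintf("profile_set (%s): %d genes x %d stages (days %s)\n",
              x$scale, nrow(x$values), length(x$stage_days),
              paste(x$stage_days, collapse = ", ")))
  cat(sprintf("  kept %d | removed-missing %d | removed-flat %d\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

#' Genes currently retained in a profile set
#' @param x A [profile_set()].
#' @return `kept_genes()`: character vector of gene ids flagged `"kept"`;
#'   `kept_values()`: the corresponding sub-matrix of profile values.
#' @export
kept_genes <- function(x) {
  stopifnot(inherits(x, "profile_set"))
  names(x$flags)[x$flags == "kept"]
}

#' @rdname kept_genes
#' @export
kept_values <- function(x) {
  x$values[kept_genes(x), , drop = FALSE]
}

#' Normalize tag counts to tags per million (tpm)
#'
#' Scales each library to a common depth of one million tags:
#' `tpm(g, t) = counts(g, t) / library_total(t) * 1e6 * scale_factor(t)`.
#' The optional per-stage scale factors are a hook for external library-bias
#' corrections; they default to 1. When the library totals equal the column
#' sums and all factors are 1, every tpm column sums to exactly 1e6.
#'
#' @param x A [tag_counts()] object.
#' @param scale_factors Optional positive per-stage multipliers.
#' @return A [profile_set()] with `scale = "tpm"`.
#' @examples
#' m <- matrix(c(2L, 3L), 2, 1, dimnames = list(c("g1", "g2"), NULL))
#' tc <- tag_counts(m, stage_days = 6, library_totals = 10)
#' normalize_tpm(tc)$values  # 200000, 300000
#' @export
normalize_tpm <- function(x, scale_factors = NULL) {
  stopifnot(inherits(x, "tag_counts"))
  if (any(x$library_totals == 0)) stopf("zero library total")
  if (is.null(scale_factors)) scale_factors <- rep(1, length(x$stage_days))
  if (length(scale_factors) != length(x$stage_days) || any(scale_factors <= 0))
    stopf("'scale_factors' must be positive, one per stage")
  f <- 1e6 * scale_factors / x$library_totals
  vals <- sweep(x$counts + 0, 2L, f, `*`)
  profile_set(vals, x$stage_days, scale = "tpm")
}

#' Remove profiles with too many missing values
#'
#' A stage value is treated as missing when the tag was not observed in that
#' library (tpm of 0, i.e. a zero raw count) or when the cell is `NA`. Genes
#' whose missing fraction exceeds `max_missing_fraction` are flagged
#' `"removed-missing"`. With the default 0.25 and seven stages, one missing
#' stage (1/7) is tolerated and two (2/7) are not.
#'
#' @param x A [profile_set()] on the tpm scale.
#' @param max_missing_fraction Maximum tolerated fraction of missing stages,
#'   in `[0, 1]`.
#' @param missing Which cells count as missing: `"zero-or-na"` (default) or
#'   `"na-only"` (only file-level blanks).
#' @return The profile set with updated flags (values unchanged).
#' @export
filter_missing <- function(x, max_missing_fraction = 0.25,
                           missing = c("zero-or-na", "na-only")) {
  stopifnot(inherits(x, "profile_set"))
  missing <- match.arg(missing)
  check_scalar_number(max_missing_fraction, "max_missing_fraction", 0, 1)
  miss <- if (missing == "zero-or-na") {
    is.na(x$values) | x$values == 0
  } else is.na(x$values)
  frac <- rowMeans(miss)
  drop <- frac > max_missing_fraction & x$flags == "kept"
  x$flags[drop] <- "removed-missing"
  x
}

#' Standardize profiles to mean zero and unit standard deviation
#'
#' Each kept profile X is replaced by `(X - mean(X)) / sd(X)` with the sample
#' (n-1) standard deviation, the prerequisite for comparing profile shapes
#' under a Euclidean metric. Zero-variance profiles cannot be standardized
#' and are flagged `"removed-flat"` instead; their values are left untouched.
#'
#' @param x A [profile_set()] on the tpm or smoothed scale.
#' @return A [profile_set()] with `scale = "standardized"`.
#' @examples
#' ps <- profile_set(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", NULL)),
#'                   stage_days = c(6, 9, 10))
#' standardize(ps)$values  # -1 0 1
#' @export
standardize <- function(x) {
  stopifnot(inherits(x, "profile_set"))
  keep <- x$flags == "kept"
  v <- x$values[keep, , drop = FALSE]
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  flat <- s == 0 | !is.finite(s)
  x$flags[keep][flat] <- "removed-flat"
  idx <- which(keep)[!flat]
  x$values[idx, ] <- (v[!flat, , drop = FALSE] - mu[!flat]) / s[!flat]
  x$scale <- "standardized"
  x
}
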