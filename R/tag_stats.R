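#' Audic-Claverie test for a tag count observed in two libraries
#'
#' Exact two-library test for differential tag abundance in digital
#' expression data (SAGE/SuperSAGE). Conditional on the count `x` observed in
#' a library of `n1` tags, the count `y` in an independent library of `n2`
#' tags follows
#' \deqn{p(y \mid x) = \left(\frac{n2}{n1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1 + n2/n1)^{x+y+1}},}
#' a negative-binomial law with size `x + 1` and success probability
#' `n1 / (n1 + n2)`. The two-sided p-value doubles the smaller of the lower
#' and upper tail at `y` (both tails include `y` itself) and is capped at 1.
#' Tail masses are evaluated through [stats::pnbinom()], which works on the
#' log scale internally, so extreme counts do not underflow.
#'
#' @param x,y Non-negative tag counts of one gene in the two libraries
#'   (vectorized).
#' @param n1,n2 Positive library totals (total tags) of the two libraries.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @references Audic S, Claverie JM (1997) The significance of digital gene
#'   expression profiles. Genome Research 7:986-995.
#' @examples
#' audic_claverie_p(0, 0, 1e6, 1e6)   # 1: no evidence either way
#' audic_claverie_p(0, 50, 1e6, 1e6)  # vanishingly small
#' @export
audic_claverie_p <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("library totals must be positive")
  if (any(x != round(x)) || any(y != round(y)))
    stopf("counts must be integers")
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

# Fisher's exact test on the 2x2 table (count vs library remainder);
# vectorized over genes.
fisher_pair_p <- function(x, y, n1, n2) {
  mapply(function(xi, yi) {
    fisher.test(matrix(c(xi, n1 - xi, yi, n2 - yi), 2L))$p.value
  }, x, y)
}

#' Pairwise differential-expression p-values along the age course
#'
#' Computes one p-value per gene for every pair of consecutive age stages
#' (day 6 vs 9, day 9 vs 10, ...) and for the endpoint pair (first vs last
#' day), from the raw counts and the library totals. The consecutive pairs
#' feed [smooth_all()]; the endpoint pair feeds [classify_trends()].
#'
#' @param x A [tag_counts()] object with at least two stages.
#' @param method `"audic-claverie"` (default) or `"fisher-exact"` (2x2 table
#'   of count vs library remainder).
#' @param bh_adjust If `TRUE`, a Benjamini-Hochberg adjusted copy of each
#'   p-value column is attached as attribute `"q_values"`; the raw values are
#'   always what downstream thresholds are applied to.
#' @return An object of class `"pairwise_significance"`: list with `p`
#'   (gene x pair matrix), `pairs` (data.frame of `day_a`, `day_b`),
#'   `stage_days` and `method`. Pair columns are named `"dA_vs_dB"`.
#' @export
pairwise_stage_pvalues <- function(x, method = c("audic-claverie",
                                                 "fisher-exact"),
                                   bh_adjust = FALSE) {
  stopifnot(inherits(x, "tag_counts"))
  method <- match.arg(method)
  days <- x$stage_days
  ns <- length(days)
  if (ns < 2L) stopf("at least two stages are required")
  a <- seq_len(ns - 1L)
  b <- a + 1L
  if (ns > 2L) {          # endpoint pair, unless it is already the only pair
    a <- c(a, 1L)
    b <- c(b, ns)
  }
  pairs <- data.frame(day_a = days[a], day_b = days[b])
  pfun <- switch(method, "audic-claverie" = audic_claverie_p,
                 "fisher-exact" = fisher_pair_p)
  p <- matrix(NA_real_, nrow(x$counts), length(a),
              dimnames = list(rownames(x$counts),
                              sprintf("d%d_vs_d%d", pairs$day_a, pairs$day_b)))
  for (j in seq_along(a)) {
    p[, j] <- pfun(x$counts[, a[j]], x$counts[, b[j]],
                   x$library_totals[a[j]], x$library_totals[b[j]])
  }
  out <- structure(list(p = p, pairs = pairs, stage_days = days,
                        method = method),
                   class = "pairwise_significance")
  if (bh_adjust)
    attr(out, "q_values") <- apply(p, 2L, p.adjust, method = "BH")
  out
}

#' @export
print.pairwise_significance <- function(x, ...) {
  cat(sprintf("pairwise_significance (%s): %d genes, %d stage pairs (%s)\n",
              x$method, nrow(x$p), ncol(x$p),
              paste(colnames(x$p), collapse = ", ")))
  invisible(x)
}

#' Endpoint (first vs last day) p-values
#' @param sig A `"pairwise_significance"` object.
#' @return Named vector of p-values for the first-vs-last stage pair.
#' @export
endpoint_pvalues <- function(sig) {
  stopifnot(inherits(sig, "pairwise_significance"))
  days <- sig$stage_days
  j <- which(sig$pairs$day_a == days[1L] &
               sig$pairs$day_b == days[length(days)])
  if (length(j) == 0L) stopf("endpoint pair missing from significance object")
  sig$p[, j[length(j)]]
}

# consecutive-pair p-value matrix (gene x (n_stages - 1))
consecutive_pvalues <- function(sig) {
  stopifnot(inherits(sig, "pairwise_significance"))
  idx <- which(sig$pairs$day_b - sig$pairs$day_a > 0 &
                 match(sig$pairs$day_a, sig$stage_days) + 1L ==
                 match(sig$pairs$day_b, sig$stage_days))
  sig$p[, idx, drop = FALSE]
}
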