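#' Pearson correlation of an expression profile with chronological age
#'
#' Correlates the per-stage expression values with the literal day vector
#' (e.g. days 6, 9, 10, 11, 12, 13, 14) — not with stage ranks, so unevenly
#' spaced time points weigh in at their true age.
#'
#' @param profile Numeric vector of per-stage expression values.
#' @param days Numeric day vector of the same length (>= 3 stages).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_with_time <- function(profile, days) {
  if (length(profile) != length(days))
    stopf("profile and day vector differ in length")
  if (length(days) < 3L) stopf("at least three stages are required")
  if (sd(profile) == 0)
    stopf("correlation undefined for a constant profile")
  cor(profile, days)
}

#' Classify continuously up- and down-regulated expression profiles
#'
#' A gene is called continuously regulated when its tpm profile correlates
#' strongly with chronological age (|Pearson r| >= `r_threshold`, default
#' 0.7, a conventional cutoff for strong linear correlation) and the
#' differential-expression p-value between the first and the last age stage
#' is at most `p_threshold` (default 1e-10), which screens out weak profiles
#' whose endpoints barely differ. Labels: `"up"` (r >= threshold), `"down"`
#' (r <= -threshold), else `"none"`. Constant profiles have no defined
#' correlation and are labeled `"none"`. Both thresholds are inclusive.
#'
#' @param profiles A [profile_set()] on the tpm scale (post missing-value
#'   filter); only kept genes are classified.
#' @param sig A [pairwise_stage_pvalues()] result containing the endpoint
#'   (first vs last day) pair.
#' @param r_threshold Correlation magnitude threshold.
#' @param p_threshold Endpoint differential-expression p-value threshold.
#' @return An object of class `"trend_calls"`: list with `calls` (data.frame
#'   `gene_id`, `pearson_r`, `endpoint_p`, `label`), `up` and `down`
#'   (character vectors of gene ids), and the thresholds used.
#' @export
classify_trends <- function(profiles, sig, r_threshold = 0.7,
                            p_threshold = 1e-10) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(sig, "pairwise_significance"))
  check_scalar_number(r_threshold, "r_threshold", 0, 1)
  check_scalar_number(p_threshold, "p_threshold", 0, 1)
  genes <- kept_genes(profiles)
  ep <- endpoint_pvalues(sig)
  missing_ep <- setdiff(genes, names(ep))
  if (length(missing_ep))
    stopf("endpoint p-values missing for %d genes (e.g. %s)",
          length(missing_ep), missing_ep[1L])
  v <- kept_values(profiles)
  days <- profiles$stage_days
  sds <- apply(v, 1L, sd)
  r <- rep(NA_real_, length(genes))
  ok <- sds > 0
  r[ok] <- as.vector(cor(t(v[ok, , drop = FALSE]), days))
  ep <- ep[genes]
  label <- rep("none", length(genes))
  label[ok & r >= r_threshold & ep <= p_threshold] <- "up"
  label[ok & r <= -r_threshold & ep <= p_threshold] <- "down"
  calls <- data.frame(gene_id = genes, pearson_r = r, endpoint_p = ep,
                      label = label, row.names = NULL)
  structure(list(calls = calls,
                 up = calls$gene_id[label == "up"],
                 down = calls$gene_id[label == "down"],
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "trend_calls")
}

#' @export
print.trend_calls <- function(x, ...) {
  cat(sprintf(paste0("trend_calls: %d genes (|r| >= %g, endpoint p <= %g): ",
                     "%d up, %d down\n"),
              nrow(x$calls), x$r_threshold, x$p_threshold,
              length(x$up), length(x$down)))
  invisible(x)
}
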