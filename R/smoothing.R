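#' Significance smoothing of one expression profile
#'
#' Replaces expression changes that are not statistically supported by local
#' means, so that only significant stage-to-stage patterns remain. The stages
#' are partitioned into maximal runs connected by non-significant consecutive
#' pairs; every value inside a run is replaced by the run's arithmetic mean.
#' A pair flagged significant keeps its two stages in separate runs, so a
#' fully significant profile is returned unchanged, and a fully
#' non-significant profile collapses to its overall mean (and is removed
#' downstream as change-free).
#'
#' @param values Numeric vector of per-stage expression values.
#' @param significant Logical vector over consecutive stage pairs
#'   (length `length(values) - 1`); `TRUE` = the pair shows significant
#'   differential expression and is left alone.
#' @return Numeric vector of smoothed values, same length as `values`.
#' @examples
#' smooth_profile(c(10, 14, 12, 50, 48, 52, 46),
#'                c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
#' # run means: {10,14,12} -> 12, {50,48,52,46} -> 49
#' @export
smooth_profile <- function(values, significant) {
  if (length(values) != length(significant) + 1L)
    stopf("length(values) must equal length(significant) + 1 (got %d and %d)",
          length(values), length(significant))
  if (anyNA(significant)) stopf("'significant' must not contain NA")
  # run id increments at each significant pair
  run <- cumsum(c(0L, as.integer(significant)))
  means <- vapply(split(values, run), mean, 0)
  as.vector(means[as.character(run)])
}

#' Significance smoothing of a profile library
#'
#' Applies [smooth_profile()] to every kept gene, using the consecutive-pair
#' p-values of `sig` thresholded at `alpha` (p <= alpha means significant,
#' inclusive). Genes whose smoothed profile has zero variance carry no
#' significant expression change; they are flagged `"removed-flat"` and leave
#' the analysis. The retained genes form the cluster profile library passed
#' on to [standardize()] and [fcm()].
#'
#' @param profiles A [profile_set()] (tpm scale).
#' @param sig A [pairwise_stage_pvalues()] result covering the same genes and
#'   stages.
#' @param alpha Significance threshold for a stage-to-stage change
#'   (default 1e-3).
#' @return A [profile_set()] with `scale = "smoothed"` and updated flags.
#' @export
smooth_all <- function(profiles, sig, alpha = 1e-3) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(sig, "pairwise_significance"))
  check_scalar_number(alpha, "alpha", 0, 1)
  pg <- rownames(profiles$values)
  sg <- rownames(sig$p)
  if (!setequal(pg, sg)) {
    diff <- c(setdiff(pg, sg), setdiff(sg, pg))
    stopf("profiles and significance cover different genes: %s%s",
          paste(head(diff, 5L), collapse = ", "),
          if (length(diff) > 5L) sprintf(" (and %d more)", length(diff) - 5L)
          else "")
  }
  if (!identical(profiles$stage_days, sig$stage_days))
    stopf("profiles and significance cover different stages")
  pcons <- consecutive_pvalues(sig)[pg, , drop = FALSE]
  mask <- pcons <= alpha
  keep <- which(profiles$flags == "kept")
  out <- profiles$values
  for (i in keep) {
    out[i, ] <- smooth_profile(profiles$values[i, ], mask[i, ])
  }
  flags <- profiles$flags
  smoothed_var <- apply(out[keep, , drop = FALSE], 1L, var)
  flags[keep][smoothed_var == 0] <- "removed-flat"
  profile_set(out, profiles$stage_days, scale = "smoothed", flags = flags)
}
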