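#' Permutation null for the overlap of two gene sets
#'
#' Monte-Carlo null model for the question "do two down-regulated gene
#' lists, obtained in two studies over partially shared gene universes,
#' share more genes than chance allows?". Each replicate draws `n1` ids
#' without replacement from universe 1 (size `N1`) and `n2` ids from
#' universe 2 (size `N2`), of which `S` ids are common to both universes,
#' and records the intersection size. By default the smaller universe is
#' treated as fully contained in the larger (`S = min(N1, N2)`).
#'
#' @param N1,n1 Size of universe 1 and of the sample drawn from it.
#' @param N2,n2 Size of universe 2 and of the sample drawn from it.
#' @param S Number of genes shared by the two universes
#'   (default `min(N1, N2)`).
#' @param reps Number of random replicates (default 10000).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return An object of class `"overlap_null"`: list with the parameters,
#'   `draws` (per-replicate overlap counts), `mean` and `sd` (sample
#'   standard deviation over the replicates).
#' @examples
#' null <- simulate_overlap_null(10059, 1202, 9704, 556, reps = 2000,
#'                               seed = 7)
#' c(null$mean, null$sd)
#' @export
simulate_overlap_null <- function(N1, n1, N2, n2, S = min(N1, N2),
                                  reps = 10000L, seed = 1L) {
  N1 <- check_count(N1, "N1"); N2 <- check_count(N2, "N2")
  n1 <- check_count(n1, "n1", 0L); n2 <- check_count(n2, "n2", 0L)
  S <- check_count(S, "S", 0L)
  reps <- check_count(reps, "reps")
  if (n1 > N1) stopf("n1 (%d) exceeds N1 (%d)", n1, N1)
  if (n2 > N2) stopf("n2 (%d) exceeds N2 (%d)", n2, N2)
  if (S > min(N1, N2))
    stopf("shared count S (%d) exceeds min(N1, N2) (%d)", S, min(N1, N2))
  draws <- with_seed(seed, {
    # shared genes are ids 1..S in both universes
    vapply(seq_len(reps), function(r) {
      a <- sample.int(N1, n1)
      b <- sample.int(N2, n2)
      hit <- logical(S)
      hit[a[a <= S]] <- TRUE
      sum(hit[b[b <= S]])
    }, 0L)
  })
  structure(list(N1 = N1, n1 = n1, N2 = N2, n2 = n2, S = S, reps = reps,
                 seed = seed, draws = draws, mean = mean(draws),
                 sd = sd(draws)),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(paste0("overlap_null: %d reps of (%d of %d) vs (%d of %d), ",
                     "S = %d shared\n  mean %.2f, sd %.2f\n"),
              x$reps, x$n1, x$N1, x$n2, x$N2, x$S, x$mean, x$sd))
  invisible(x)
}

#' Closed-form moments of the two-universe overlap null
#'
#' Exact mean and standard deviation of the overlap count under the model
#' simulated by [simulate_overlap_null()]. A shared gene is in both samples
#' with probability `p = (n1/N1)(n2/N2)`; a pair of shared genes is jointly
#' in both samples with probability
#' `q = [n1(n1-1)/(N1(N1-1))] [n2(n2-1)/(N2(N2-1))]`, giving
#' `mean = S p` and `var = S p (1 - p) + S (S - 1) (q - p^2)`.
#'
#' @inheritParams simulate_overlap_null
#' @return List with `mean` and `sd`.
#' @export
analytic_overlap_moments <- function(N1, n1, N2, n2, S = min(N1, N2)) {
  if (n1 > N1 || n2 > N2) stopf("sample sizes exceed universe sizes")
  if (S > min(N1, N2))
    stopf("shared count S (%d) exceeds min(N1, N2) (%d)", S, min(N1, N2))
  if (S == 0) return(list(mean = 0, sd = 0))
  p <- (n1 / N1) * (n2 / N2)
  q <- (n1 * (n1 - 1) / (N1 * (N1 - 1))) * (n2 * (n2 - 1) / (N2 * (N2 - 1)))
  v <- S * p * (1 - p) + S * (S - 1) * (q - p^2)
  list(mean = S * p, sd = sqrt(max(v, 0)))
}

#' Z-score of an observed overlap against the permutation null
#'
#' Standardizes the observed overlap count by the null mean and standard
#' deviation; overlaps at least three standard deviations above the mean
#' (inclusive) are flagged significant, the conventional 3-sigma rule for
#' an approximately normal null.
#'
#' @param observed Observed overlap count.
#' @param null An [simulate_overlap_null()] result (or any list with
#'   `mean` and `sd`).
#' @return List with `z` and `significant` (`z >= 3`).
#' @export
overlap_zscore <- function(observed, null) {
  check_scalar_number(observed, "observed")
  if (is.na(null$sd) || null$sd <= 0)
    stopf("degenerate null: standard deviation is zero")
  z <- (observed - null$mean) / null$sd
  list(z = z, significant = z >= 3)
}

#' Intersect two gene lists
#'
#' Case-sensitive exact-id set intersection; duplicates within a list count
#' once and the result is sorted. Inputs may be character vectors or paths
#' to one-id-per-line text files.
#'
#' @param list_a,list_b Character vectors of gene ids, or file paths.
#' @return List with `common` (sorted ids) and `count`.
#' @export
intersect_gene_lists <- function(list_a, list_b) {
  read_one <- function(x) {
    if (length(x) == 1L && is.character(x) && file.exists(x))
      x <- read_gene_list(x)
    unique(as.character(x))
  }
  a <- read_one(list_a)
  b <- read_one(list_b)
  if (length(a) == 0L || length(b) == 0L)
    warning("empty gene list; intersection is empty", call. = FALSE)
  common <- sort(intersect(a, b))
  list(common = common, count = length(common))
}

#' Read/write one-id-per-line gene lists
#' @param path File path.
#' @return `read_gene_list()`: character vector (empty lines dropped).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
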