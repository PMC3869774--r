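# Independent brute-force oracles used to validate the package's
# implementations on tiny instances. These deliberately use naive direct
# computation, not the code paths they check.

# Audic-Claverie conditional law by direct log-space summation over y'.
# p(y'|x) = (N2/N1)^y' (x+y')! / (x! y'! (1+N2/N1)^(x+y'+1))
ac_direct_p <- function(x, y, n1, n2, y_max = 20000L) {
  logp <- function(yy)
    yy * log(n2 / n1) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log(1 + n2 / n1)
  lp <- logp(0:y_max)
  lower <- sum(exp(lp[seq_len(y + 1L)]))
  upper <- sum(exp(lp[(y + 1L):(y_max + 1L)]))
  min(1, 2 * min(lower, upper))
}

# Xie-Beni by naive double loop
xb_naive <- function(x, u, v, m) {
  num <- 0
  for (i in seq_len(nrow(v)))
    for (g in seq_len(nrow(x)))
      num <- num + u[g, i]^m * sum((x[g, ] - v[i, ])^2)
  sep <- Inf
  for (i in seq_len(nrow(v)))
    for (j in seq_len(nrow(v)))
      if (i != j) sep <- min(sep, sum((v[i, ] - v[j, ])^2))
  num / (nrow(x) * sep)
}

# hypergeometric upper tail by exhaustive enumeration of all study sets
hyper_enum_p <- function(universe, term_genes, n, k_obs) {
  sets <- utils::combn(universe, n, simplify = FALSE)
  hits <- vapply(sets, function(s) length(intersect(s, term_genes)) >= k_obs,
                 TRUE)
  mean(hits)
}

# two-cloud fixture: two tight gaussian clouds separated along the first axis
two_clouds <- function(n_per = 30, d = 4, gap = 40, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per),
             matrix(rnorm(n_per * d, 0, sd), n_per))
  x[(n_per + 1):(2 * n_per), 1] <- x[(n_per + 1):(2 * n_per), 1] + gap
  rownames(x) <- sprintf("p%03d", seq_len(2 * n_per))
  x
}

# tiny handmade count fixture
toy_counts <- function() {
  m <- matrix(c(5L, 10L, 0L,
                8L, 12L, 3L,
                2L,  6L, 9L,
                1L,  0L, 4L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), NULL))
  tag_counts(m, stage_days = c(6, 9, 10), library_totals = c(50, 60, 40))
}

# small three-term chain ontology: root <- parent <- child
chain_dag <- function() {
  ontology_dag(ids = c("GO:R", "GO:P", "GO:C"),
               names = c("root", "parent", "child"),
               parents = list("GO:R" = character(0), "GO:P" = "GO:R",
                              "GO:C" = "GO:P"))
}
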