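#' Expression-profile archetypes of the synthetic generator
#'
#' Eight canonical age-course shapes mirroring the pattern classes seen in
#' aging-fungus tag-count data: three decreasing (early, late, terminal
#' drop), three increasing (early, late, steady) and two transient peaks
#' (early, late). Shapes are stored as relative expression levels in
#' `[0, 1]` at the seven canonical stages (days 6, 9, 10, 11, 12, 13, 14)
#' and interpolated linearly when a different day vector is requested.
#' Shapes 1-3 are monotone non-increasing, 4-6 monotone non-decreasing,
#' 7-8 unimodal with an interior maximum.
#'
#' @return A data.frame with `archetype_id`, `shape` (name) and `trend`
#'   (`"down"`, `"up"`, `"none"`); the 8 x 7 relative-level matrix is
#'   attached as attribute `"levels"`.
#' @export
archetype_specs <- function() {
  levels <- rbind(
    "decrease-early"         = c(1, .35, .22, .14, .08, .04, 0),
    "decrease-late"          = c(1, .92, .75, .50, .25, .10, .02),
    "decrease-terminal-drop" = c(1, 1, .97, .92, .82, .60, .05),
    "increase-early"         = c(0, .85, .95, 1, 1, 1, 1),
    "increase-late"          = c(0, 0, .03, .08, .20, .55, 1),
    "increase-steady"        = c(0, .30, .45, .60, .72, .87, 1),
    "peak-early"             = c(.05, 1, .85, .35, .15, .05, .02),
    "peak-late"              = c(.02, .05, .12, .35, .90, 1, .25))
  colnames(levels) <- paste0("day_", c(6, 9, 10, 11, 12, 13, 14))
  out <- data.frame(
    archetype_id = 1:8,
    shape = rownames(levels),
    trend = c("down", "down", "down", "up", "up", "up", "none", "none"),
    row.names = NULL)
  attr(out, "levels") <- levels
  out
}

# relative-level matrix (8 x length(stage_days)), linearly interpolated in
# day units from the canonical 7-stage template
archetype_levels <- function(stage_days) {
  lv <- attr(archetype_specs(), "levels")
  ref <- c(6, 9, 10, 11, 12, 13, 14)
  t(apply(lv, 1L, function(s)
    approx(ref, s, xout = pmin(pmax(stage_days, 6), 14))$y))
}

#' Generate a synthetic age-staged tag-count matrix with known truth
#'
#' Simulates a SuperSAGE-like experiment: each gene follows one of the eight
#' [archetype_specs()] shapes scaled to its own baseline abundance, expected
#' per-stage tpm values are closed to one million per stage (tpm is
#' compositional), and counts are drawn from a negative-binomial law with
#' mean `expected tpm x library_size / 1e6` and the given dispersion
#' (`dispersion = Inf` gives Poisson counts). An optional fraction of genes
#' is flat (amplitude 1: abundance drawn from a low-expression pool, no
#' age trend) to emulate the fluctuation-dominated profiles that
#' significance smoothing is designed to remove, and an optional dropout
#' fraction zeroes 1-3 stages per affected gene to exercise the
#' missing-value filter.
#'
#' @param n_genes Number of genes (> 0).
#' @param stage_days Strictly increasing day vector (default the canonical
#'   7 stages).
#' @param archetype_mix Proportions over the 8 archetypes (sum to 1); genes
#'   are allocated by largest-remainder quota so equal proportions give
#'   exactly equal archetype sizes.
#' @param library_sizes Per-stage total tag counts.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson; `Inf` = Poisson).
#' @param amplitude Fold change over the course for archetype genes.
#' @param base_meanlog,base_sdlog Log-normal parameters of the peak
#'   (course-maximum) tpm of archetype genes; anchoring the baseline at the
#'   peak keeps the mix of rising and falling profiles compositionally
#'   balanced across stages, so the per-stage tpm closure stays close to 1
#'   and flat genes remain flat after closure.
#' @param flat_fraction Fraction of genes that are flat noise.
#' @param flat_meanlog,flat_sdlog Log-normal abundance parameters of the
#'   flat pool.
#' @param dropout_fraction Fraction of genes with 1-3 stages forced to zero.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `counts` (a [tag_counts()] object) and `truth`
#'   (class `"synthetic_truth"`): per-gene `archetype`, `trend`
#'   (up/down/none), `flat`, `dropout_stages`, the expected tpm matrix
#'   `mean_tpm`, and the generator parameters.
#' @export
generate_tag_counts <- function(n_genes,
                                stage_days = c(6, 9, 10, 11, 12, 13, 14),
                                archetype_mix = rep(1 / 8, 8),
                                library_sizes = NULL,
                                dispersion = 200,
                                amplitude = 10,
                                base_meanlog = log(60), base_sdlog = 0.6,
                                flat_fraction = 0,
                                flat_meanlog = log(6), flat_sdlog = 0.6,
                                dropout_fraction = 0,
                                seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  stage_days <- as.integer(stage_days)
  if (length(stage_days) == 0L) stopf("'stage_days' must not be empty")
  if (is.unsorted(stage_days, strictly = TRUE))
    stopf("'stage_days' must be strictly increasing")
  if (length(archetype_mix) != 8L || any(archetype_mix < 0) ||
      abs(sum(archetype_mix) - 1) > 1e-8)
    stopf("'archetype_mix' must be 8 non-negative proportions summing to 1")
  if (is.null(library_sizes))
    # sequencing depth scales with transcriptome size: ~400 tags per gene
    # on average (a 10^4-gene transcriptome in ~4e6-tag libraries), with
    # realistic stage-to-stage depth variation
    library_sizes <- round(n_genes *
                             rep_len(c(430, 370, 460, 350, 400, 450, 360),
                                     length(stage_days)))
  if (length(library_sizes) != length(stage_days) || any(library_sizes <= 0))
    stopf("'library_sizes' must be positive, one per stage")
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      is.na(dispersion) || dispersion <= 0)   # Inf = Poisson limit
    stopf("'dispersion' must be a positive number (Inf for Poisson)")
  check_scalar_number(flat_fraction, "flat_fraction", 0, 1)
  check_scalar_number(dropout_fraction, "dropout_fraction", 0, 1)
  if (amplitude < 1) stopf("'amplitude' must be >= 1")

  ns <- length(stage_days)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  # largest-remainder quota over archetypes
  raw <- archetype_mix * n_genes
  sizes <- floor(raw)
  rem <- n_genes - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  archetype <- rep.int(1:8, sizes)

  with_seed(seed, {
    archetype <- sample(archetype)              # interleave archetypes
    names(archetype) <- gene_ids
    flat <- runif(n_genes) < flat_fraction
    base <- ifelse(flat,
                   rlnorm(n_genes, flat_meanlog, flat_sdlog),
                   rlnorm(n_genes, base_meanlog, base_sdlog))
    lv <- archetype_levels(stage_days)
    rel <- 1 / amplitude + (1 - 1 / amplitude) * lv
    shape <- rel[archetype, , drop = FALSE]
    shape[flat, ] <- 1
    mean_tpm <- base * shape
    # close each stage to 1e6 expected tpm (tpm is compositional). A flat
    # gene means constant RELATIVE abundance, so flat genes are held exactly
    # constant on the closed tpm scale and the archetype pool absorbs the
    # compositional drift of the ensemble.
    A <- colSums(mean_tpm[!flat, , drop = FALSE])
    B <- sum(base[flat])
    if (any(A > 0)) {
      alpha <- 1e6 / (B + mean(A))
      mean_tpm[!flat, ] <- sweep(mean_tpm[!flat, , drop = FALSE], 2L,
                                 alpha * mean(A) / A, `*`)
      mean_tpm[flat, ] <- alpha * mean_tpm[flat, , drop = FALSE]
    } else {
      mean_tpm <- mean_tpm * (1e6 / B)
    }
    dropout_stages <- vector("list", n_genes)
    if (dropout_fraction > 0) {
      hit <- which(runif(n_genes) < dropout_fraction)
      for (i in hit) {
        nd <- sample(1:3, 1L)
        dropout_stages[[i]] <- sort(sample.int(ns, min(nd, ns)))
        mean_tpm[i, dropout_stages[[i]]] <- 0
      }
    }
    mu <- sweep(mean_tpm, 2L, library_sizes / 1e6, `*`)
    cnt <- if (is.infinite(dispersion)) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = dispersion)
    }
    counts <- matrix(cnt, n_genes, ns, dimnames = list(gene_ids, NULL))
    trend <- archetype_specs()$trend[archetype]
    trend[flat] <- "none"
    names(trend) <- gene_ids
    rownames(mean_tpm) <- gene_ids
    colnames(mean_tpm) <- paste0("day_", stage_days)
    names(dropout_stages) <- gene_ids
    truth <- structure(
      list(archetype = archetype, trend = trend, flat = flat,
           dropout_stages = dropout_stages, mean_tpm = mean_tpm,
           base_level = stats::setNames(base, gene_ids),
           seed = seed,
           params = list(n_genes = n_genes, stage_days = stage_days,
                         archetype_mix = archetype_mix,
                         library_sizes = library_sizes,
                         dispersion = dispersion, amplitude = amplitude,
                         flat_fraction = flat_fraction,
                         dropout_fraction = dropout_fraction)),
      class = "synthetic_truth")
    # the realized library contains at least its assigned tags; sampling
    # noise can push a column sum past the nominal depth
    list(counts = tag_counts(counts, stage_days,
                             library_totals = pmax(library_sizes,
                                                   colSums(counts))),
         truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, seed %d; %d flat, %d with dropout\n",
              length(x$archetype), x$seed, sum(x$flat),
              sum(lengths(x$dropout_stages) > 0)))
  print(table(archetype = x$archetype))
  invisible(x)
}

#' Generate a gene-to-GO annotation table with planted enrichment
#'
#' Builds a small rooted ontology (root, four intermediate category nodes,
#' `n_terms` leaf terms) and annotates genes so that the first
#' `min(8, n_terms)` terms are preferentially attached to genes of one
#' archetype each: members of a planted term are drawn without replacement
#' with sampling weight `enrichment_strength` for genes of the mapped
#' archetype and 1 for all others, so `enrichment_strength = 1` is the null
#' of no association. Remaining terms annotate genes uniformly.
#'
#' @param truth A `"synthetic_truth"` object from [generate_tag_counts()].
#' @param n_terms Number of leaf GO terms (>= 1).
#' @param genes_per_term Integer range (length-2) of term sizes.
#' @param enrichment_strength Odds multiplier >= 1 for archetype genes in
#'   planted terms.
#' @param seed Integer seed.
#' @return List with `annotations` (data.frame `gene_id`, `term_id`),
#'   `ontology` (an [ontology_dag()]), and `planted` (data.frame mapping
#'   planted `term_id` to `archetype_id`).
#' @export
generate_annotations <- function(truth, n_terms = 40,
                                 genes_per_term = c(20, 80),
                                 enrichment_strength = 10, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_terms <- check_count(n_terms, "n_terms")
  if (enrichment_strength < 1)
    stopf("'enrichment_strength' must be >= 1 (1 = no planted association)")
  if (length(genes_per_term) != 2L || genes_per_term[1L] > genes_per_term[2L])
    stopf("'genes_per_term' must be an increasing length-2 range")
  genes <- names(truth$archetype)
  n <- length(genes)
  term_ids <- sprintf("GO:%07d", 1000 + seq_len(n_terms))
  cat_ids <- sprintf("GO:%07d", 100 + 1:4)
  root <- "GO:0000001"
  parents <- c(
    stats::setNames(list(character(0)), root),
    stats::setNames(rep(list(root), 4L), cat_ids))
  with_seed(seed, {
    # each leaf under one category; every 5th leaf under two (diamond edges)
    leaf_par <- lapply(seq_len(n_terms), function(i) {
      p <- cat_ids[(i - 1L) %% 4L + 1L]
      if (i %% 5L == 0L) p <- c(p, cat_ids[i %% 4L + 1L])
      p
    })
    parents <- c(parents, stats::setNames(leaf_par, term_ids))
    term_names <- c("biological_process", paste0("category_", 1:4),
                    paste0("synthetic process ", seq_len(n_terms)))
    dag <- ontology_dag(ids = c(root, cat_ids, term_ids),
                        names = term_names, parents = parents)
    n_planted <- min(8L, n_terms)
    planted <- data.frame(term_id = term_ids[seq_len(n_planted)],
                          archetype_id = seq_len(n_planted))
    rng <- seq.int(genes_per_term[1L], genes_per_term[2L])
    sizes <- rng[sample.int(length(rng), n_terms, replace = TRUE)]
    sizes <- pmin(sizes, n)
    ann <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      w <- rep(1, n)
      if (i <= n_planted)
        w[truth$archetype == planted$archetype_id[i]] <- enrichment_strength
      members <- sample(genes, sizes[i], prob = w)
      ann[[i]] <- data.frame(gene_id = members, term_id = term_ids[i])
    }
    annotations <- do.call(rbind, ann)
    annotations <- annotations[order(annotations$gene_id,
                                     annotations$term_id), ]
    rownames(annotations) <- NULL
    list(annotations = annotations, ontology = dag, planted = planted)
  })
}

#' Generate a synthetic BLAST tabular hit file
#'
#' Emits hits in the standard 12-column tabular convention (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Each query gene receives 1-3 hits; a gene selected as "transferable"
#' (probability `frac_significant`) gets at least one hit with an E-value
#' below the conventional 1e-20 annotation-transfer cutoff, all other hits
#' lie above it, so the cutoff is exercised from both sides.
#'
#' @param gene_ids Character vector of query gene ids (or a single integer
#'   `n`, expanded to `g00001...`).
#' @param frac_significant Probability that a gene has a hit passing the
#'   1e-20 cutoff.
#' @param subject_go Optional number of distinct subject proteins; defaults
#'   to one subject per hit.
#' @param seed Integer seed.
#' @return A data.frame with the 12 standard columns.
#' @export
generate_blast_table <- function(gene_ids, frac_significant = 0.4,
                                 subject_go = NULL, seed = 1L) {
  if (is.numeric(gene_ids) && length(gene_ids) == 1L)
    gene_ids <- sprintf("g%05d", seq_len(check_count(gene_ids, "gene_ids")))
  check_scalar_number(frac_significant, "frac_significant", 0, 1)
  with_seed(seed, {
    rows <- lapply(seq_along(gene_ids), function(i) {
      nh <- sample(1:3, 1L)
      ev <- 10^runif(nh, -19, -2)          # non-qualifying hits
      if (runif(1) < frac_significant)
        ev[sample.int(nh, 1L)] <- 10^runif(1, -180, -21)
      len <- sample(80:400, nh, replace = TRUE)
      data.frame(
        qseqid = gene_ids[i],
        sseqid = sprintf("sp|P%05d|", sample.int(99999, nh)),
        pident = round(runif(nh, 30, 99), 2),
        length = len,
        mismatch = sample(0:50, nh, replace = TRUE),
        gapopen = sample(0:5, nh, replace = TRUE),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = ev,
        bitscore = round(runif(nh, 50, 900), 1))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' @rdname generate_blast_table
#' @param hits A 12-column BLAST data.frame.
#' @param path Output path.
#' @export
write_blast_table <- function(hits, path) {
  hits$evalue <- sprintf("%.2e", hits$evalue)
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
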