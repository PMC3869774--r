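test_that("archetype templates honor their declared monotonicity", {
  spec <- archetype_specs()
  lv <- attr(spec, "levels")
  for (i in 1:3) expect_true(all(diff(lv[i, ]) <= 0), label = spec$shape[i])
  for (i in 4:6) expect_true(all(diff(lv[i, ]) >= 0), label = spec$shape[i])
  for (i in 7:8) {            # unimodal with an interior maximum
    peak <- which.max(lv[i, ])
    expect_true(peak > 1 && peak < ncol(lv))
    expect_true(all(diff(lv[i, seq_len(peak)]) >= 0))
    expect_true(all(diff(lv[i, peak:ncol(lv)]) <= 0))
  }
})

test_that("equal seeds give bitwise-identical synthetic data", {
  a <- generate_tag_counts(120, flat_fraction = 0.2, dropout_fraction = 0.1,
                           seed = 33)
  b <- generate_tag_counts(120, flat_fraction = 0.2, dropout_fraction = 0.1,
                           seed = 33)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$archetype, b$truth$archetype)
  c <- generate_tag_counts(120, flat_fraction = 0.2, dropout_fraction = 0.1,
                           seed = 34)
  expect_false(identical(a$counts$counts, c$counts$counts))

  g1 <- generate_annotations(a$truth, seed = 5)
  g2 <- generate_annotations(a$truth, seed = 5)
  expect_identical(g1$annotations, g2$annotations)

  b1 <- generate_blast_table(50, seed = 8)
  b2 <- generate_blast_table(50, seed = 8)
  expect_identical(b1, b2)
})

test_that("generator arguments are validated", {
  expect_error(generate_tag_counts(0), "integer|must be")
  expect_error(generate_tag_counts(10, stage_days = integer(0)), "empty")
  expect_error(generate_tag_counts(10, archetype_mix = rep(1, 8)),
               "summing to 1")
  expect_error(generate_annotations(generate_tag_counts(10)$truth,
                                    enrichment_strength = 0.5), ">= 1")
})

test_that("amplitude 1 with Poisson noise gives depth-scaled flat means", {
  sim <- generate_tag_counts(400, amplitude = 1, dispersion = Inf, seed = 2)
  # every gene's expected tpm is constant across stages
  rng <- apply(sim$truth$mean_tpm, 1, function(v) diff(range(v)) / mean(v))
  expect_lt(max(rng), 1e-12)
  # expected count = mean tpm x library_size / 1e6; check per-stage means
  mu <- sweep(sim$truth$mean_tpm, 2, sim$counts$library_totals / 1e6, `*`)
  expect_lt(max(abs(colMeans(sim$counts$counts) / colMeans(mu) - 1)), 0.05)
})

test_that("per-archetype empirical mean profiles track the generator truth", {
  sim <- generate_tag_counts(1000, seed = 17)
  tpm <- normalize_tpm(sim$counts)
  a <- sim$truth$archetype
  expect_equal(as.vector(table(a)), rep(125L, 8))  # largest-remainder quota
  for (k in 1:8) {
    emp <- colMeans(tpm$values[names(a)[a == k], ])
    spec <- colMeans(sim$truth$mean_tpm[names(a)[a == k], ])
    expect_gt(cor(emp, spec), 0.95)
  }
})

test_that("per-stage column sums stay near the library sizes", {
  sim <- generate_tag_counts(2000, seed = 23)
  libs <- round(2000 * c(430, 370, 460, 350, 400, 450, 360))
  mu <- sweep(sim$truth$mean_tpm, 2, libs / 1e6, `*`)
  nb_se <- sqrt(colSums(mu + mu^2 / 200))
  expect_true(all(abs(colSums(sim$counts$counts) - libs) <= 3 * nb_se))
})

test_that("planted terms annotate their archetype under strong enrichment", {
  sim <- generate_tag_counts(1000, seed = 99)
  gen <- generate_annotations(sim$truth, n_terms = 10,
                              genes_per_term = c(50, 50),
                              enrichment_strength = 10, seed = 1)
  ann <- gen$annotations
  term <- gen$planted$term_id[1]
  members <- ann$gene_id[ann$term_id == term]
  in_arch <- sum(sim$truth$archetype[members] == gen$planted$archetype_id[1])
  # weighted draw: expected ~ 50 * 1250 / 2125 ~ 29 of 50 from the archetype
  expect_gt(in_arch, 15)
  expect_true(all(ann$gene_id %in% names(sim$truth$archetype)))
})

test_that("a null enrichment strength leaves terms unassociated", {
  sim <- generate_tag_counts(1000, seed = 99)
  pvals <- vapply(1:15, function(s) {
    gen <- generate_annotations(sim$truth, n_terms = 8,
                                genes_per_term = c(50, 50),
                                enrichment_strength = 1, seed = s)
    term <- gen$planted$term_id[1]
    members <- gen$annotations$gene_id[gen$annotations$term_id == term]
    k <- sum(sim$truth$archetype[members] == gen$planted$archetype_id[1])
    phyper(k - 1, 50, 950, 125, lower.tail = FALSE)
  }, 0)
  # under the null the planted term should rarely look enriched
  expect_lt(mean(pvals <= 0.01), 0.2)
  expect_gt(median(pvals), 0.05)
})

test_that("the toy ontology is a valid rooted DAG and writes valid OBO", {
  sim <- generate_tag_counts(100, seed = 3)
  gen <- generate_annotations(sim$truth, n_terms = 12, seed = 2)
  dag <- gen$ontology
  expect_s3_class(dag, "ontology_dag")
  expect_equal(dag$roots, "GO:0000001")
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- parse_obo(path)
  expect_setequal(back$ids, dag$ids)
  expect_equal(back$parents[dag$ids], dag$parents[dag$ids])
})

test_that("ancestor propagation gives the root the union of its children", {
  dag <- ontology_dag(ids = c("GO:R", "GO:A", "GO:B"),
                      names = c("root", "a", "b"),
                      parents = list("GO:R" = character(0), "GO:A" = "GO:R",
                                     "GO:B" = "GO:R"))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    term_id = c("GO:A", "GO:B", "GO:A"))
  closed <- propagate_ancestors(ann, dag)
  root_genes <- closed$gene_id[closed$term_id == "GO:R"]
  expect_setequal(root_genes, c("g1", "g2", "g3"))
})

test_that("synthetic homology tables exercise both sides of the cutoff", {
  hits <- generate_blast_table(300, frac_significant = 0.4, seed = 21)
  expect_equal(ncol(hits), 12L)
  expect_true(any(hits$evalue <= 1e-20) && any(hits$evalue > 1e-20))
  passed <- unique(hits$qseqid[hits$evalue <= 1e-20])
  frac <- length(passed) / 300
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 300))

  all_pass <- generate_blast_table(40, frac_significant = 1, seed = 2)
  expect_equal(length(unique(all_pass$qseqid[all_pass$evalue <= 1e-20])), 40L)
  none <- generate_blast_table(40, frac_significant = 0, seed = 2)
  expect_equal(sum(none$evalue <= 1e-20), 0L)
})
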