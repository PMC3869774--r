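prot_go <- data.frame(protein_id = c("P1", "P1", "P2", "P3"),
                      term_id = c("GO:A", "GO:B", "GO:B", "GO:C"))

hit_row <- function(gene, subject, evalue) {
  data.frame(qseqid = gene, sseqid = subject, pident = 90, length = 100,
             mismatch = 1, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
             send = 100, evalue = evalue, bitscore = 200)
}

test_that("annotation transfer honors the inclusive E-value cutoff", {
  hits <- rbind(hit_row("g1", "P1", 1e-30), hit_row("g2", "P1", 1e-10))
  ann <- transfer_annotations(hits, prot_go)
  expect_setequal(ann$term_id[ann$gene_id == "g1"], c("GO:A", "GO:B"))
  expect_false("g2" %in% ann$gene_id)
  # boundary: exactly 1e-20 transfers
  ann2 <- transfer_annotations(hit_row("g3", "P3", 1e-20), prot_go)
  expect_equal(ann2$term_id[ann2$gene_id == "g3"], "GO:C")
})

test_that("multiple qualifying hits union their terms without duplicates", {
  hits <- rbind(hit_row("g1", "P1", 1e-25), hit_row("g1", "P2", 1e-40))
  ann <- transfer_annotations(hits, prot_go)
  expect_equal(sort(ann$term_id[ann$gene_id == "g1"]), c("GO:A", "GO:B"))
})

test_that("scientific-notation E-values parse from tabular files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hits <- rbind(hit_row("g1", "P1", 1e-180), hit_row("g2", "P2", 3e-21))
  write_blast_table(hits, path)
  back <- read_blast_table(path)
  expect_equal(back$evalue, c(1e-180, 3e-21))
  ann <- transfer_annotations(path, prot_go)
  expect_setequal(unique(ann$gene_id), c("g1", "g2"))

  writeLines("g1\tP1\t90", path)
  expect_error(read_blast_table(path), "line 1.*expected 12")
})

test_that("ancestor closure walks chains, is idempotent, dedups diamonds", {
  dag <- chain_dag()
  ann <- data.frame(gene_id = "g1", term_id = "GO:C")
  closed <- propagate_ancestors(ann, dag)
  expect_setequal(closed$term_id, c("GO:C", "GO:P", "GO:R"))
  expect_identical(propagate_ancestors(closed, dag)[, 1:2], closed[, 1:2])
  # stopping below the root is available
  below <- propagate_ancestors(ann, dag, include_root = FALSE)
  expect_setequal(below$term_id, c("GO:C", "GO:P"))

  diamond <- ontology_dag(
    ids = c("GO:R", "GO:L", "GO:M", "GO:X"),
    names = c("r", "l", "m", "x"),
    parents = list("GO:R" = character(0), "GO:L" = "GO:R",
                   "GO:M" = "GO:R", "GO:X" = c("GO:L", "GO:M")))
  closed2 <- propagate_ancestors(data.frame(gene_id = "g", term_id = "GO:X"),
                                 diamond)
  expect_equal(sum(closed2$term_id == "GO:R"), 1L)

  expect_warning(
    propagate_ancestors(data.frame(gene_id = "g", term_id = "GO:ZZZ"), dag),
    "not in the ontology")
})

test_that("ontology construction rejects cycles and orphans", {
  expect_error(ontology_dag(c("a", "b"), c("a", "b"),
                            list(a = "b", b = "a")), "no root|cycle")
  expect_error(ontology_dag("a", "a", list(a = "zzz")), "not in ontology")
})

test_that("hypergeometric edge cases give exact textbook values", {
  universe <- paste0("u", 1:10)
  ann <- data.frame(gene_id = universe,
                    term_id = rep(c("GO:T", "GO:O"), each = 5))
  # study = exactly the five carriers of GO:T -> p = 1 / C(10, 5)
  res <- hypergeom_enrichment(universe[1:5], universe, ann,
                              all_results = TRUE)
  expect_equal(res$p_value[res$term_id == "GO:T"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # a study disjoint from the term's carriers: upper tail at k = 0 is 1
  expect_equal(res$p_value[res$term_id == "GO:O"], 1)
  expect_equal(res$k[res$term_id == "GO:O"], 0L)
})

test_that("enrichment p-values match exhaustive enumeration on tiny data", {
  set.seed(31)
  for (rep in 1:4) {
    universe <- paste0("u", 1:12)
    ann <- do.call(rbind, lapply(c("GO:T1", "GO:T2", "GO:T3"), function(t)
      data.frame(gene_id = sample(universe, sample(3:8, 1)), term_id = t)))
    # catch-all term: every universe gene annotated, so the annotated
    # universe equals the enumeration universe
    ann <- rbind(ann, data.frame(gene_id = universe, term_id = "GO:ALL"))
    study <- sample(universe, 5)
    res <- hypergeom_enrichment(study, universe, ann, all_results = TRUE)
    for (i in seq_len(nrow(res))) {
      term_genes <- ann$gene_id[ann$term_id == res$term_id[i]]
      expect_equal(res$p_value[i],
                   hyper_enum_p(universe, term_genes, 5, res$k[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment is invariant under gene relabeling", {
  set.seed(13)
  universe <- paste0("u", 1:30)
  ann <- data.frame(gene_id = sample(universe, 60, replace = TRUE),
                    term_id = sample(c("GO:A", "GO:B", "GO:C"), 60, TRUE))
  ann <- unique(ann)
  study <- sample(universe, 10)
  res1 <- hypergeom_enrichment(study, universe, ann, all_results = TRUE)
  relabel <- setNames(paste0("x", 1:30), universe)
  ann2 <- transform(ann, gene_id = relabel[gene_id])
  res2 <- hypergeom_enrichment(relabel[study], relabel[universe], ann2,
                               all_results = TRUE)
  expect_equal(res1$p_value, res2$p_value)
})

test_that("closure never decreases a term's annotation counts", {
  sim <- generate_tag_counts(200, seed = 41)
  gen <- generate_annotations(sim$truth, n_terms = 15, seed = 4)
  open_tab <- table(gen$annotations$term_id)
  closed <- propagate_ancestors(gen$annotations, gen$ontology)
  closed_tab <- table(closed$term_id)
  for (t in names(open_tab))
    expect_gte(closed_tab[[t]], open_tab[[t]])
})

test_that("study genes outside the universe are reported", {
  expect_error(
    hypergeom_enrichment(c("a", "zz"), c("a", "b"),
                         data.frame(gene_id = "a", term_id = "GO:1")),
    "absent from the universe.*zz")
})

test_that("enrichment maps connect terms at the inclusive Jaccard cutoff", {
  mk <- function(ids, genes, p) {
    data.frame(term_id = ids, term_name = ids, k = lengths(genes),
               K = lengths(genes), n = 10, N = 100, p_value = p,
               member_genes = I(genes))
  }
  up <- mk(c("GO:1", "GO:2"),
           list(c("a", "b", "c"), c("a", "b", "c")), c(1e-4, 2e-4))
  down <- mk(c("GO:3", "GO:4"),
             list(c("d", "e", "f", "g"), c("g", "x", "y", "z")),
             c(1e-3, 5e-3))
  map <- build_enrichment_map(up, down)
  expect_equal(nrow(map$nodes), 4L)
  w <- setNames(map$edges$jaccard, paste(map$edges$from, map$edges$to))
  # identical member sets -> weight exactly 1
  expect_equal(unname(w[["GO:1 GO:2"]]), 1)
  # |intersection| 1, |union| 7 -> below cutoff, no edge
  expect_false("GO:3 GO:4" %in% names(w))
  # boundary: |intersection| 1 of |union| 4 is exactly 0.25 -> edge present
  b <- build_enrichment_map(mk(c("GO:5", "GO:6"),
                               list(c("a", "b"), c("b", "c", "d")),
                               c(1e-3, 1e-3)), NULL)
  expect_equal(nrow(b$edges), 1L)
  expect_equal(b$edges$jaccard, 0.25)
})

test_that("map edges match brute-force pairwise Jaccard", {
  sim <- generate_tag_counts(300, seed = 51)
  gen <- generate_annotations(sim$truth, n_terms = 12,
                              genes_per_term = c(10, 40), seed = 6)
  ann <- propagate_ancestors(gen$annotations, gen$ontology)
  universe <- names(sim$truth$archetype)
  study <- names(sim$truth$archetype)[sim$truth$archetype %in% 1:3]
  res <- hypergeom_enrichment(study, universe, ann, gen$ontology,
                              all_results = TRUE)
  res <- res[res$K < res$N, ]
  map <- build_enrichment_map(res, NULL, jaccard_cutoff = 0.25)
  sets <- setNames(map$nodes$member_genes, map$nodes$term_id)
  expected <- 0L
  for (i in seq_len(length(sets) - 1)) {
    for (j in (i + 1):length(sets)) {
      ji <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      if (!is.nan(ji) && ji >= 0.25) expected <- expected + 1L
    }
  }
  expect_equal(nrow(map$edges), expected)
  expect_true(all(map$edges$jaccard >= 0.25 & map$edges$jaccard <= 1))
  expect_false(any(map$edges$from == map$edges$to))
})

test_that("duplicate terms within one phenotype are rejected", {
  dup <- data.frame(term_id = c("GO:1", "GO:1"), term_name = "t",
                    k = 1, K = 1, n = 2, N = 4, p_value = 1e-3,
                    member_genes = I(list("a", "a")))
  expect_error(build_enrichment_map(dup, NULL), "duplicate term")
})

test_that("map exports are well-formed", {
  up <- data.frame(term_id = c("GO:1", "GO:2"), term_name = c("one", "two"),
                   k = 2, K = 3, n = 5, N = 50, p_value = c(1e-4, 3e-3),
                   member_genes = I(list(c("a", "b"), c("b", "c"))))
  map <- build_enrichment_map(up, NULL, jaccard_cutoff = 0.2)
  dir <- withr::local_tempdir()
  tab <- file.path(dir, "enrichment.tsv")
  write_enrichment_table(map, tab)
  parsed <- read.delim(tab)
  expect_equal(names(parsed), c("go_id", "go_term", "p_value", "phenotype"))
  expect_equal(parsed$phenotype, c(1L, 1L))

  gmt <- file.path(dir, "sets.gmt")
  write_gmt(map, gmt)
  fields <- strsplit(readLines(gmt), "\t")
  expect_equal(vapply(fields, `[[`, "", 1), c("GO:1", "GO:2"))
  expect_equal(fields[[1]][-(1:2)], c("a", "b"))

  gml <- file.path(dir, "map.graphml")
  write_graphml(map, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})
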