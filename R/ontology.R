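#' Transfer GO annotations from homology hits
#'
#' Assigns to every query gene the union of the GO terms of all its homology
#' hits whose E-value passes the transfer cutoff (inclusive), the standard
#' way of annotating a poorly annotated genome from better-annotated
#' species. Genes without a qualifying hit are absent from the result.
#'
#' @param blast Path to a 12-column BLAST tabular file (qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore) or an
#'   equivalent data.frame.
#' @param protein_go Data.frame mapping subject proteins to GO terms
#'   (columns `protein_id`, `term_id`), or a path to such a two-column TSV.
#' @param e_cutoff E-value transfer threshold (default 1e-20, inclusive).
#' @return Annotation data.frame (`gene_id`, `term_id`), attribute
#'   `closed = FALSE`.
#' @export
transfer_annotations <- function(blast, protein_go, e_cutoff = 1e-20) {
  if (is.character(blast)) blast <- read_blast_table(blast)
  if (!is.data.frame(blast) || ncol(blast) < 12L)
    stopf("'blast' must be a 12-column tabular hit table")
  names(blast)[c(1L, 2L, 11L)] <- c("qseqid", "sseqid", "evalue")
  if (is.character(protein_go))
    protein_go <- read.delim(protein_go, header = TRUE,
                             stringsAsFactors = FALSE)
  names(protein_go)[1:2] <- c("protein_id", "term_id")
  check_scalar_number(e_cutoff, "e_cutoff", lower = 0)
  hits <- blast[blast$evalue <= e_cutoff, c("qseqid", "sseqid")]
  ann <- merge(hits, protein_go, by.x = "sseqid", by.y = "protein_id")
  ann <- unique(ann[, c("qseqid", "term_id")])
  names(ann) <- c("gene_id", "term_id")
  ann <- ann[order(ann$gene_id, ann$term_id), ]
  rownames(ann) <- NULL
  attr(ann, "closed") <- FALSE
  ann
}

#' Read a 12-column BLAST tabular file
#' @param path File path; E-values in scientific notation (e.g. `1e-180`)
#'   are parsed as numbers.
#' @return Data.frame with the 12 standard columns.
#' @export
read_blast_table <- function(path) {
  if (!file.exists(path)) stopf("BLAST table not found: %s", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 12L)
  if (length(bad))
    stopf("malformed BLAST row at line %d: expected 12 fields, found %d",
          bad[1L], lengths(cells)[bad[1L]])
  out <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(out) <- cols
  num <- c(3:10, 11:12)
  for (j in num) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (anyNA(v))
      stopf("malformed BLAST row at line %d: non-numeric '%s' in column %s",
            which(is.na(v))[1L], out[[j]][which(is.na(v))[1L]], cols[j])
    out[[j]] <- v
  }
  out
}

#' Close gene annotations under ontology ancestry
#'
#' Applies the GO true-path rule: a gene annotated to a term is implicitly
#' annotated to all of that term's ancestors, so every gene's term set is
#' replaced by its closure under `is_a`/`part_of` ancestry (root included).
#' Idempotent. Annotated terms missing from the DAG are kept but not
#' propagated, with a warning.
#'
#' @param annotations Data.frame (`gene_id`, `term_id`).
#' @param dag An [ontology_dag()].
#' @param include_root Propagate up to and including the root terms
#'   (default `TRUE`); set `FALSE` to stop below the root.
#' @return Annotation data.frame with attribute `closed = TRUE`.
#' @export
propagate_ancestors <- function(annotations, dag, include_root = TRUE) {
  stopifnot(is.data.frame(annotations), inherits(dag, "ontology_dag"))
  terms <- unique(annotations$term_id)
  missing <- setdiff(terms, dag$ids)
  if (length(missing))
    warning(sprintf("%d annotated term(s) not in the ontology, not propagated: %s",
                    length(missing), paste(head(missing, 3L), collapse = ", ")),
            call. = FALSE)
  anc <- lapply(stats::setNames(setdiff(terms, missing), setdiff(terms, missing)),
                term_ancestors, dag = dag, include_root = include_root)
  extra <- annotations[annotations$term_id %in% names(anc), ]
  n_anc <- lengths(anc[extra$term_id])
  closed <- rbind(
    annotations,
    data.frame(gene_id = rep(extra$gene_id, n_anc),
               term_id = unlist(anc[extra$term_id], use.names = FALSE)))
  closed <- unique(closed)
  closed <- closed[order(closed$gene_id, closed$term_id), ]
  rownames(closed) <- NULL
  attr(closed, "closed") <- TRUE
  closed
}

#' GO over-representation by the one-sided hypergeometric test
#'
#' For every term annotated in the universe, tests whether the study set
#' contains more genes of that term than expected under random sampling
#' without replacement: with `N` universe genes, `K` of them carrying the
#' term, and a study of size `n` containing `k` carriers, the upper-tail
#' p-value is
#' \deqn{p = \sum_{i=k}^{\min(n, K)} \binom{K}{i}\binom{N-K}{n-i} \Big/
#'   \binom{N}{n}.}
#' The universe is restricted to genes with at least one annotation (an
#' unannotated gene is uninformative for GO). No multiple-testing
#' correction is applied; the fixed raw cutoff is inclusive.
#'
#' @param study Character vector of study gene ids (subset of `universe`).
#' @param universe Character vector of universe gene ids.
#' @param annotations Annotation data.frame (`gene_id`, `term_id`),
#'   normally ancestor-closed via [propagate_ancestors()].
#' @param dag Optional [ontology_dag()] used to attach term names.
#' @param p_cutoff Significance threshold (default 0.01, inclusive).
#' @param all_results Return every tested term instead of only those with
#'   `p <= p_cutoff`.
#' @return Data.frame sorted by ascending p-value with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_value` and a list-column
#'   `member_genes` (study genes carrying the term).
#' @export
hypergeom_enrichment <- function(study, universe, annotations, dag = NULL,
                                 p_cutoff = 0.01, all_results = FALSE) {
  study <- unique(as.character(study))
  universe <- unique(as.character(universe))
  offenders <- setdiff(study, universe)
  if (length(offenders))
    stopf("study genes absent from the universe: %s%s",
          paste(head(offenders, 5L), collapse = ", "),
          if (length(offenders) > 5L)
            sprintf(" (and %d more)", length(offenders) - 5L) else "")
  check_scalar_number(p_cutoff, "p_cutoff", 0, 1)
  annotated <- unique(annotations$gene_id)
  universe <- intersect(universe, annotated)
  study <- intersect(study, universe)
  ann <- annotations[annotations$gene_id %in% universe, c("gene_id", "term_id")]
  by_term <- split(ann$gene_id, ann$term_id)
  N <- length(universe)
  n <- length(study)
  res <- lapply(names(by_term), function(tid) {
    carriers <- by_term[[tid]]
    members <- intersect(study, carriers)
    K <- length(carriers)
    k <- length(members)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N, p_value = p,
               member_genes = I(list(sort(members))))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = double(0),
                      member_genes = I(list()))
  out$term_name <- if (!is.null(dag)) {
    unname(ifelse(out$term_id %in% dag$ids, dag$names[out$term_id],
                  out$term_id))
  } else out$term_id
  out <- out[, c("term_id", "term_name", "k", "K", "n", "N", "p_value",
                 "member_genes")]
  if (!all_results) out <- out[out$p_value <= p_cutoff, ]
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Build an enrichment map from up- and down-regulated enrichment results
#'
#' Combines the enriched terms of the two phenotypes into a term-overlap
#' graph: one node per enriched term (phenotype 1 = up-regulated, 0 =
#' down-regulated; node size = number of study genes carrying the term),
#' and an undirected edge between two terms whenever the Jaccard
#' coefficient of their member-gene sets is at least `jaccard_cutoff`
#' (inclusive), weighted by that coefficient. A term enriched in both
#' phenotypes keeps one node carrying the more significant phenotype. The
#' companion writers export the inputs a Cytoscape-style enrichment-map
#' renderer expects.
#'
#' @param results_up,results_down [hypergeom_enrichment()] results for the
#'   up- and down-regulated study sets (either may be empty or `NULL`).
#' @param jaccard_cutoff Minimum member-set Jaccard coefficient for an edge
#'   (default 0.25).
#' @return An object of class `"enrichment_map"`: list with `nodes`
#'   (data.frame `term_id`, `term_name`, `p_value`, `phenotype`, `size`,
#'   `member_genes`), `edges` (data.frame `from`, `to`, `jaccard`) and
#'   `graph` (an undirected [igraph::graph] with those attributes).
#' @export
build_enrichment_map <- function(results_up, results_down,
                                 jaccard_cutoff = 0.25) {
  check_scalar_number(jaccard_cutoff, "jaccard_cutoff", 0, 1)
  tag <- function(res, phen) {
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    if (anyDuplicated(res$term_id))
      stopf("duplicate term within one phenotype: %s",
            res$term_id[duplicated(res$term_id)][1L])
    res$phenotype <- phen
    res
  }
  nodes <- rbind(tag(results_up, 1L), tag(results_down, 0L))
  if (is.null(nodes) || nrow(nodes) == 0L)
    stopf("no enriched terms to map")
  # a term enriched in both phenotypes keeps its more significant record
  nodes <- nodes[order(nodes$p_value), ]
  nodes <- nodes[!duplicated(nodes$term_id), ]
  nodes$size <- lengths(nodes$member_genes)
  nodes <- nodes[, c("term_id", "term_name", "p_value", "phenotype", "size",
                     "member_genes")]
  rownames(nodes) <- NULL
  nt <- nrow(nodes)
  from <- integer(0); to <- integer(0); w <- double(0)
  if (nt >= 2L) {
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        jc <- jaccard(nodes$member_genes[[i]], nodes$member_genes[[j]])
        if (jc >= jaccard_cutoff) {
          from <- c(from, i); to <- c(to, j); w <- c(w, jc)
        }
      }
    }
  }
  edges <- data.frame(from = nodes$term_id[from], to = nodes$term_id[to],
                      jaccard = w)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$term_id,
                          term_name = nodes$term_name,
                          p_value = nodes$p_value,
                          phenotype = nodes$phenotype,
                          size = nodes$size))
  if (nrow(edges)) igraph::E(g)$weight <- edges$jaccard
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %d terms (%d up, %d down), %d edges\n",
              nrow(x$nodes), sum(x$nodes$phenotype == 1L),
              sum(x$nodes$phenotype == 0L), nrow(x$edges)))
  invisible(x)
}

#' Export enrichment-map files
#'
#' `write_enrichment_table()` writes the four obligatory columns (GO
#' identifier, GO term, enrichment p-value, phenotype with 1 = up-regulated
#' and 0 = down-regulated). `write_gmt()` writes one gene set per line:
#' term id, description, then the member gene ids, tab-separated.
#' `write_graphml()` writes the term-overlap graph with node and edge
#' attributes in GraphML.
#'
#' @param map An [build_enrichment_map()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(map, path) {
  stopifnot(inherits(map, "enrichment_map"))
  tab <- map$nodes[, c("term_id", "term_name", "p_value", "phenotype")]
  names(tab) <- c("go_id", "go_term", "p_value", "phenotype")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
write_gmt <- function(map, path) {
  stopifnot(inherits(map, "enrichment_map"))
  lines <- vapply(seq_len(nrow(map$nodes)), function(i)
    paste(c(map$nodes$term_id[i], map$nodes$term_name[i],
            map$nodes$member_genes[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_enrichment_table
#' @export
write_graphml <- function(map, path) {
  stopifnot(inherits(map, "enrichment_map"))
  igraph::write_graph(map$graph, path, format = "graphml")
  invisible(path)
}
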