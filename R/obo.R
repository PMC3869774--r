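#' Ontology DAG container
#'
#' A minimal rooted directed acyclic graph over ontology terms, holding for
#' every term its name and its parents through `is_a` and `part_of`
#' relations (both treated as ancestry, the usual convention for the GO
#' true-path rule). Acyclicity and rootedness are validated on
#' construction.
#'
#' @param ids Character vector of term identifiers.
#' @param names Character vector of term names (same length).
#' @param parents Named list mapping each id to the character vector of its
#'   parent ids (empty for roots).
#' @return An object of class `"ontology_dag"`.
#' @export
ontology_dag <- function(ids, names, parents) {
  if (length(ids) != length(names)) stopf("one name per term id required")
  if (anyDuplicated(ids)) stopf("duplicate term ids")
  if (!setequal(names(parents), ids))
    stopf("'parents' must have exactly one entry per term id")
  parents <- parents[ids]
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown))
    stopf("parent term not in ontology: %s", unknown[1L])
  roots <- ids[lengths(parents) == 0L]
  if (length(roots) == 0L) stopf("ontology has no root term")
  # cycle check by iterative leaf stripping (Kahn)
  remaining <- stats::setNames(lengths(parents), ids)
  children <- split(rep(names(parents), lengths(parents)),
                    unlist(parents, use.names = FALSE))
  queue <- roots
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stopf("ontology graph contains a cycle")
  structure(list(ids = ids, names = stats::setNames(names, ids),
                 parents = parents, roots = roots),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, root%s %s\n", length(x$ids),
              if (length(x$roots) > 1L) "s" else "",
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' All ancestors of an ontology term
#' @param dag An [ontology_dag()].
#' @param term A term id present in the DAG.
#' @param include_root Keep root terms in the result (default `TRUE`).
#' @return Character vector of ancestor ids (term itself excluded).
#' @export
term_ancestors <- function(dag, term, include_root = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term %in% dag$ids) stopf("unknown term: %s", term)
  out <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  if (!include_root) out <- setdiff(out, dag$roots)
  out
}

#' Read and write OBO 1.2 ontology files
#'
#' A deliberately small OBO reader/writer covering what GO-style enrichment
#' needs: `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of` lines; obsolete terms are skipped. Both `is_a`
#' and `part_of` become parent edges.
#'
#' @param path Path of the `.obo` file.
#' @return `parse_obo()` returns an [ontology_dag()]; `write_obo()` returns
#'   `path` invisibly.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stopf("OBO file not found: %s", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stopf("no [Term] stanza found in %s", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      if (length(v)) trimws(sub(paste0("^", key, ":\\s*"), "", v)) else
        character(0)
    }
    if (length(get1("is_obsolete")) && get1("is_obsolete")[1L] == "true")
      next
    id <- get1("id")[1L]
    if (is.na(id)) next
    isa <- sub("\\s*!.*$", "", get1("is_a"))
    po <- get1("relationship")
    po <- sub("\\s*!.*$", "", po[startsWith(po, "part_of")])
    po <- trimws(sub("^part_of\\s+", "", po))
    ids <- c(ids, id)
    nms <- c(nms, if (length(get1("name"))) get1("name")[1L] else id)
    parents[[id]] <- unique(c(isa, po))
  }
  # drop parent references to terms absent from the file (e.g. pruned)
  parents <- lapply(parents, intersect, ids)
  ontology_dag(ids, nms, parents)
}

#' @rdname parse_obo
#' @param dag An [ontology_dag()].
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in dag$ids) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", dag$names[[id]]), con)
    for (p in dag$parents[[id]])
      writeLines(sprintf("is_a: %s ! %s", p, dag$names[[p]]), con)
    writeLines("", con)
  }
  invisible(path)
}
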