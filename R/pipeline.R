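#' Default pipeline configuration
#'
#' Nested key-value configuration for [run_pipeline()], serializable to
#' YAML. Thresholds default to the fixed raw cutoffs conventional for this
#' analysis: 25% maximum missing stages, p <= 1e-3 for a significant
#' stage-to-stage change, |r| >= 0.7 and endpoint p <= 1e-10 for a
#' continuous trend, GO enrichment p <= 0.01, E <= 1e-20 for annotation
#' transfer and Jaccard >= 0.25 for enrichment-map edges (all inclusive).
#'
#' @param counts,annotations,ontology,blast,protein_go,second_list Optional
#'   input file paths (see [run_pipeline()]).
#' @return A nested list of class `"pipeline_config"`.
#' @export
default_config <- function(counts = NULL, annotations = NULL, ontology = NULL,
                           blast = NULL, protein_go = NULL,
                           second_list = NULL) {
  structure(list(
    paths = list(counts = counts, annotations = annotations,
                 ontology = ontology, blast = blast, protein_go = protein_go,
                 second_list = second_list),
    thresholds = list(max_missing_fraction = 0.25, alpha_smooth = 1e-3,
                      r_threshold = 0.7, endpoint_p = 1e-10, go_p = 0.01,
                      e_cutoff = 1e-20, jaccard = 0.25),
    stats = list(method = "audic-claverie"),
    clustering = list(k_min = 2L, k_max = 12L, reps = 10L, m = 2,
                      seed = 1L),
    overlap = list(S = NULL, reps = 10000L, seed = 1L)),
    class = "pipeline_config")
}

#' Read, write and validate a pipeline configuration
#' @param path YAML file path.
#' @return `read_config()` returns a validated `"pipeline_config"`;
#'   `write_config()` returns `path` invisibly. Round-trips losslessly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in intersect(names(raw), names(cfg)))
    for (key in names(raw[[section]]))
      cfg[[section]][[key]] <- raw[[section]][[key]]
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A `"pipeline_config"` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  check_scalar_number(th$max_missing_fraction, "max_missing_fraction", 0, 1)
  check_scalar_number(th$alpha_smooth, "alpha_smooth", 0, 1)
  check_scalar_number(th$r_threshold, "r_threshold", 0, 1)
  check_scalar_number(th$endpoint_p, "endpoint_p", 0, 1)
  check_scalar_number(th$go_p, "go_p", 0, 1)
  check_scalar_number(th$e_cutoff, "e_cutoff", lower = 0)
  check_scalar_number(th$jaccard, "jaccard", 0, 1)
  cl <- config$clustering
  check_count(cl$k_min, "k_min", 2L)
  check_count(cl$k_max, "k_max", cl$k_min)
  check_count(cl$reps, "reps")
  if (cl$m <= 1) stopf("fuzzifier 'm' must be > 1")
  check_count(config$overlap$reps, "overlap reps")
  if (!config$stats$method %in% c("audic-claverie", "fisher-exact"))
    stopf("unknown pairwise test method: %s", config$stats$method)
  structure(config, class = "pipeline_config")
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full age-course analysis pipeline
#'
#' Composes the stages in their methodological order — tpm normalization,
#' missing-value filtering, pairwise stage statistics, significance
#' smoothing, standardization, fuzzy clustering with cluster-number
#' selection, trend classification, GO enrichment with enrichment-map
#' export, and the cross-study overlap null — and writes every intermediate
#' artifact, a threshold/seed log and a machine-readable stage summary into
#' `out_dir`. Enrichment runs only when annotation inputs are configured
#' (either a ready `annotations` table or a `blast` + `protein_go` pair,
#' plus an `ontology` OBO file); the overlap stage runs only when a second
#' gene list is configured. Rerunning with the same config and inputs
#' reproduces the summary byte for byte.
#'
#' @param config A `"pipeline_config"` (see [default_config()]); its
#'   `paths$counts` must point to a count TSV readable by [load_counts()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the stage results and `summary` (the
#'   per-stage counts written to `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  if (is.null(config$paths$counts))
    stopf("config paths$counts is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  log_lines <- c("sagetime pipeline run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("sagetime"))),
                 sprintf("config: %s",
                         yaml::as.yaml(unclass(config))))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  counts <- stage("load", load_counts(config$paths$counts))
  tpm <- stage("normalize", normalize_tpm(counts))
  write_matrix_tsv(tpm$values, file.path(out_dir, "tpm.tsv"))
  tpm <- stage("filter",
               filter_missing(tpm, th$max_missing_fraction))
  sig <- stage("stats",
               pairwise_stage_pvalues(counts, method = config$stats$method))
  write_matrix_tsv(sig$p, file.path(out_dir, "pairwise_pvalues.tsv"))
  smoothed <- stage("smooth", smooth_all(tpm, sig, alpha = th$alpha_smooth))
  write_matrix_tsv(kept_values(smoothed), file.path(out_dir, "smoothed.tsv"))
  write.table(data.frame(gene_id = names(smoothed$flags),
                         flag = unname(smoothed$flags)),
              file.path(out_dir, "gene_flags.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  std <- stage("standardize", standardize(smoothed))
  write_matrix_tsv(kept_values(std), file.path(out_dir, "standardized.tsv"))

  cl <- config$clustering
  sel <- stage("cluster",
               select_k(std, k_range = seq(cl$k_min, cl$k_max),
                        reps = cl$reps, m = cl$m, seed = cl$seed))
  write_matrix_tsv(sel$best$memberships,
                   file.path(out_dir, "memberships.tsv"))
  write_matrix_tsv(sel$best$centroids, file.path(out_dir, "centroids.tsv"),
                   id_col = "cluster")
  write.table(sel$table, file.path(out_dir, "xie_beni.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  trends <- stage("trends",
                  classify_trends(tpm, sig, r_threshold = th$r_threshold,
                                  p_threshold = th$endpoint_p))
  write.table(trends$calls, file.path(out_dir, "trend_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(trends$up, file.path(out_dir, "up_genes.txt"))
  write_gene_list(trends$down, file.path(out_dir, "down_genes.txt"))

  enrich <- NULL
  p <- config$paths
  if (!is.null(p$ontology) &&
      (!is.null(p$annotations) || (!is.null(p$blast) &&
                                   !is.null(p$protein_go)))) {
    enrich <- stage("enrich", {
      dag <- parse_obo(p$ontology)
      ann <- if (!is.null(p$annotations)) {
        read.delim(p$annotations, stringsAsFactors = FALSE)
      } else {
        transfer_annotations(p$blast, p$protein_go, e_cutoff = th$e_cutoff)
      }
      names(ann)[1:2] <- c("gene_id", "term_id")
      ann <- propagate_ancestors(ann, dag)
      universe <- kept_genes(tpm)
      up <- hypergeom_enrichment(intersect(trends$up, universe), universe,
                                 ann, dag, p_cutoff = th$go_p)
      down <- hypergeom_enrichment(intersect(trends$down, universe),
                                   universe, ann, dag, p_cutoff = th$go_p)
      map <- if (nrow(up) + nrow(down) > 0) {
        m <- build_enrichment_map(up, down, jaccard_cutoff = th$jaccard)
        write_enrichment_table(m, file.path(out_dir, "enrichment.tsv"))
        write_gmt(m, file.path(out_dir, "gene_sets.gmt"))
        write_graphml(m, file.path(out_dir, "enrichment_map.graphml"))
        m
      }
      list(up = up, down = down, map = map)
    })
  }

  overlap <- NULL
  if (!is.null(p$second_list)) {
    overlap <- stage("overlap", {
      second <- read_gene_list(p$second_list)
      inter <- intersect_gene_lists(trends$down, second)
      ov <- config$overlap
      S <- if (is.null(ov$S)) min(length(kept_genes(tpm)), length(second))
      else ov$S
      null <- simulate_overlap_null(
        N1 = length(kept_genes(tpm)), n1 = length(trends$down),
        N2 = max(length(second), S), n2 = length(second), S = S,
        reps = ov$reps, seed = ov$seed)
      z <- overlap_zscore(inter$count, null)
      writeLines(c(
        sprintf("observed overlap: %d", inter$count),
        sprintf("null mean: %.4f", null$mean),
        sprintf("null sd: %.4f", null$sd),
        sprintf("z: %.4f", z$z),
        sprintf("significant (z >= 3): %s", z$significant)),
        file.path(out_dir, "overlap_report.txt"))
      write.table(data.frame(overlap = null$draws),
                  file.path(out_dir, "overlap_null_draws.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(intersection = inter, null = null, z = z)
    })
  }

  summary <- list(
    n_genes = nrow(counts$counts),
    n_stages = length(counts$stage_days),
    kept_after_missing_filter = sum(tpm$flags == "kept"),
    cluster_profile_library = length(kept_genes(smoothed)),
    standardized = length(kept_genes(std)),
    best_k = sel$best_k,
    n_up = length(trends$up),
    n_down = length(trends$down),
    n_enriched_terms = if (is.null(enrich)) NA_integer_
    else nrow(enrich$map$nodes),
    overlap_observed = if (is.null(overlap)) NA_integer_
    else overlap$intersection$count,
    overlap_z = if (is.null(overlap)) NA_real_
    else round(overlap$z$z, 6))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(counts = counts, tpm = tpm, sig = sig, smoothed = smoothed,
                 standardized = std, clustering = sel, trends = trends,
                 enrichment = enrich, overlap = overlap, summary = summary))
}
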