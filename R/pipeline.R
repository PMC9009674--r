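#' Analysis run configuration
#'
#' Bundles the tunable parameters of the full pipeline with the published
#' defaults: rank grid 1..10, 10 balanced folds, 300 random starts per
#' fit, ECM tolerance 1e-5 with at most 2000 iterations, cosine matching
#' threshold 0.8, and the 10 mutations/Mb hypermutator cutoff over a
#' 3000 Mb genome.
#'
#' @param r_min,r_max Rank grid bounds.
#' @param K Number of balanced folds.
#' @param n_starts Random starts per (rank, fold).
#' @param tol ECM stopping tolerance.
#' @param max_iterations ECM iteration cap.
#' @param master_seed Master seed for all randomness.
#' @param threshold Cosine-similarity matching threshold.
#' @param genome_size_mb Genome size for the burden filter.
#' @param burden_threshold Hypermutator cutoff, mutations/Mb; `Inf`
#'   disables filtering.
#' @param n_workers Workers for the multistart loops.
#' @return A `run_config` list.
#' @export
run_config <- function(r_min = 1L, r_max = 10L, K = 10L, n_starts = 300L,
                       tol = 1e-5, max_iterations = 2000L, master_seed = 1L,
                       threshold = 0.8, genome_size_mb = 3000,
                       burden_threshold = 10, n_workers = 1L) {
  structure(list(r_min = as.integer(r_min), r_max = as.integer(r_max),
                 K = as.integer(K), n_starts = as.integer(n_starts),
                 tol = tol, max_iterations = as.integer(max_iterations),
                 master_seed = as.integer(master_seed),
                 threshold = threshold, genome_size_mb = genome_size_mb,
                 burden_threshold = burden_threshold,
                 n_workers = as.integer(n_workers)),
            class = "run_config")
}

#' Run the full signature-discovery pipeline
#'
#' Hypermutator filtering, cross-validated selection of the number of
#' signatures, fixed-rank extraction on the full matrix, optional catalog
#' annotation, and (if `output_dir` is given) tab-delimited reports: the
#' per-fold error table, the error curve, profiles, activities, the match
#' report and a JSON run summary capturing configuration and seeds, from
#' which any run is exactly reproducible.
#'
#' @param V Count matrix or path to one (see [read_count_matrix()]).
#' @param catalog Optional reference catalog matrix or path.
#' @param config A [run_config()].
#' @param output_dir Optional directory for on-disk reports.
#' @return List with `selection` (a `rank_selection`), `signatures` (a
#'   `signature_fit`), `matches` (tibble or `NULL`), `dropped`
#'   (hypermutator IDs) and `config`.
#' @export
run_pipeline <- function(V, catalog = NULL, config = run_config(),
                         output_dir = NULL) {
  if (is.character(V)) V <- read_count_matrix(V)
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  V <- validate_counts(V)
  dropped <- character(0)
  if (is.finite(config$burden_threshold)) {
    V <- filter_hypermutators(V, config$genome_size_mb,
                              config$burden_threshold)
    dropped <- attr(V, "dropped")
  }
  selection <- select_rank(V, r_min = config$r_min, r_max = config$r_max,
                           K = config$K, n_starts = config$n_starts,
                           master_seed = config$master_seed,
                           tol = config$tol,
                           max_iterations = config$max_iterations,
                           n_workers = config$n_workers)
  signatures <- extract_signatures(V, selection$selected_rank,
                                   n_starts = config$n_starts,
                                   master_seed = config$master_seed,
                                   tol = config$tol,
                                   max_iterations = config$max_iterations,
                                   n_workers = config$n_workers)
  matches <- if (!is.null(catalog)) {
    match_to_catalog(signatures$W, catalog, threshold = config$threshold)
  }
  result <- list(selection = selection, signatures = signatures,
                 matches = matches, dropped = dropped, config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(result, V, output_dir)
  result
}

write_pipeline_outputs <- function(result, V, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  readr::write_tsv(tidy(result$selection), out("rank_errors.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$selection$curve, out("error_curve.tsv"),
                   progress = FALSE)
  write_count_matrix(result$signatures$W, out("profiles.tsv"))
  write_count_matrix(result$signatures$H, out("activities.tsv"),
                     label_column = "Signature")
  if (!is.null(result$matches))
    readr::write_tsv(result$matches, out("matches.tsv"), progress = FALSE)
  summary <- list(
    package_version = as.character(utils::packageVersion("sigcv")),
    dims = list(P = nrow(V), N = ncol(V)),
    dropped_hypermutators = result$dropped,
    selected_rank = result$selection$selected_rank,
    config = unclass(result$config))
  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}
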