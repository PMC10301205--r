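#' Simulate a scenario cohort and write it to CSV
#'
#' Thin entry point behind the `simulate` CLI command: builds the named
#' scenario, simulates the cohort, writes the cohort CSV and prints a
#' compact incidence summary. Repeated calls with identical arguments
#' produce byte-identical files.
#'
#' @param scenario Scenario name, see [scenario_library()].
#' @param out Output CSV path.
#' @param seed Master seed.
#' @param n_per_group Individuals per group.
#' @param quiet Suppress the printed incidence summary.
#' @return The `cohort_study`, invisibly.
#' @export
cmd_simulate <- function(scenario, out, seed = 1, n_per_group = 30,
                         quiet = FALSE) {
  config <- get_scenario(scenario, seed = seed, n_per_group = n_per_group)
  study <- simulate_cohort(config)
  write_cohort(study, out)
  if (!quiet) {
    inc <- incidence_summary(study)
    last <- inc[inc$dpf == max(inc$dpf), ]
    cat("Wrote ", nrow(study), " rows to ", out, "\n", sep = "")
    cat("Incidence at ", max(inc$dpf), " dpf (count/denominator):\n",
        sep = "")
    wide <- stats::reshape(
      last[c("group", "endpoint", "count")],
      idvar = "group", timevar = "endpoint", direction = "wide"
    )
    names(wide) <- sub("^count\\.", "", names(wide))
    print(wide, row.names = FALSE)
  }
  invisible(study)
}

#' Run the full co-occurrence network analysis on a cohort CSV
#'
#' Pipeline behind the `analyze` CLI command: read and validate the cohort,
#' compute pairwise exact-test association matrices, assemble the dynamic
#' network at significance level `alpha`, and write the report bundle into
#' `out_dir`:
#' \itemize{
#'   \item `association_pvalues.csv` — long-format p-values;
#'   \item `networks/<group>_<dpf>dpf.csv` / `.graphml` — adjacency
#'     matrices and graphs;
#'   \item `centrality_trajectories.csv` — per-node degree (raw and
#'     normalized) and eigenvector centrality;
#'   \item `global_centrality.csv` — max degree and spectral radius per
#'     group and day;
#'   \item `critical_nodes.csv` — critical-node table;
#'   \item `importance_summary.json` — node-importance percentages;
#'   \item `manifest.json` — parameters, input hash, package version.
#' }
#' All filenames are deterministic and CSV/JSON content depends only on the
#' input and parameters, so re-runs can be diffed byte by byte.
#'
#' @param input Cohort CSV path.
#' @param out_dir Output directory (created if needed).
#' @param alpha Edge-presence significance level, see [build_adjacency()].
#' @param policy Post-mortality status policy, see [resolve_status()].
#' @param tol Tie tolerance for critical-node sets.
#' @param plots Also render p-value heatmaps (requires \pkg{pheatmap}).
#' @param catalog An [outcome_catalog()].
#' @return Invisible list with the main intermediate objects (`study`,
#'   `associations`, `network`, `critical_table`, `importance`) and the
#'   bundle `paths`.
#' @export
cmd_analyze <- function(input, out_dir, alpha = 0.05,
                        policy = c("carry_forward", "missing_after_death"),
                        tol = 1e-9, plots = FALSE,
                        catalog = outcome_catalog()) {
  policy <- match.arg(policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- read_cohort(input, catalog)
  assoc <- association_matrices(study, policy)

  paths <- list(
    association = file.path(out_dir, "association_pvalues.csv"),
    networks = file.path(out_dir, "networks"),
    trajectories = file.path(out_dir, "centrality_trajectories.csv"),
    global = file.path(out_dir, "global_centrality.csv"),
    critical = file.path(out_dir, "critical_nodes.csv"),
    importance = file.path(out_dir, "importance_summary.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  export_heatmap_table(assoc, paths$association,
                       plot_dir = if (plots)
                         file.path(out_dir, "plots") else NULL)
  net <- build_dynamic_network(assoc, alpha, catalog)
  export_network(net, paths$networks)

  utils::write.csv(centrality_trajectories(net, tol), paths$trajectories,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(global_centrality(net, tol), paths$global,
                   row.names = FALSE, quote = FALSE)

  tbl <- critical_node_table(net, tol)
  write_critical_node_table(tbl, paths$critical)
  imp <- summarize_importance(tbl, catalog)
  write_importance_json(imp, paths$importance)

  manifest <- list(
    package = "dynetox",
    version = as.character(utils::packageVersion("dynetox")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input = normalizePath(input),
    input_md5 = unname(tools::md5sum(input)),
    parameters = list(alpha = alpha, policy = policy, tol = tol),
    n_individuals = length(unique(study$individual_id)),
    groups = study_groups(study),
    timepoints = study_timepoints(study)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(study = study, associations = assoc, network = net,
                 critical_table = tbl, importance = imp, paths = paths))
}

write_importance_json <- function(imp, path) {
  jsonlite::write_json(list(
    unique_pct = as.list(imp$unique_pct),
    unique_pct_rounded = as.list(imp$unique_pct_rounded),
    with_ties_pct = as.list(imp$with_ties_pct),
    with_ties_pct_rounded = as.list(imp$with_ties_pct_rounded),
    n_unique_cells = imp$n_unique_cells,
    n_appearances = imp$n_appearances
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Summarize a critical-node table CSV
#'
#' Entry point behind the `summarize` CLI command: reads a critical-node
#' table (written by [cmd_analyze()] or hand-encoded from a publication)
#' and reports unique and with-ties node-importance percentages. An empty
#' table warns and returns an all-zero summary.
#'
#' @param table_path Critical-node table CSV.
#' @param out Optional JSON output path; when `NULL` the summary is
#'   printed.
#' @param catalog An [outcome_catalog()].
#' @return The `importance_summary`, invisibly.
#' @export
cmd_summarize <- function(table_path, out = NULL,
                          catalog = outcome_catalog()) {
  tbl <- read_critical_node_table(table_path)
  imp <- summarize_importance(tbl, catalog)
  if (is.null(out)) {
    print(imp)
  } else {
    write_importance_json(imp, out)
  }
  invisible(imp)
}
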