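# One-command orchestration: io -> nulls -> global topology -> communities
# -> hubs -> motifs -> homology, with deterministic sub-seeds derived from a
# master seed and a structured report bundle.

SUMMARY_SCHEMA_VERSION <- "1.0"

#' Analysis configuration
#'
#' All defaults match the reference analysis where stated: 1,000 rewired
#' nulls for global metrics and rich club, 100 for motifs and homology,
#' 1,000 optimizer runs per resolution over gamma in \[0.5, 2.2\].
#' Every stochastic stage draws its seed deterministically from `seed`.
#'
#' @param input path to a weights CSV (see [load_connectome()]), or a
#'   `connectome_graph` supplied directly to [run_pipeline()].
#' @param coords optional coordinates CSV path.
#' @param out_dir output directory for the report bundle.
#' @param n_nulls_global ensemble size for global metrics and rich club.
#' @param n_nulls_motifs ensemble size for the motif spectrum.
#' @param n_nulls_homology ensemble size for cavity statistics.
#' @param swaps_per_edge rewiring intensity.
#' @param gamma_grid resolution grid.
#' @param n_runs optimizer runs per resolution.
#' @param tau consensus threshold.
#' @param keep_geq rich-club filter convention flag.
#' @param max_dim maximal simplex dimension for homology.
#' @param mean_rule path-length summary rule.
#' @param seed master seed.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(input = NULL, coords = NULL, out_dir = "connectocore_out",
                            n_nulls_global = 1000, n_nulls_motifs = 100,
                            n_nulls_homology = 100, swaps_per_edge = 10,
                            gamma_grid = seq(0.5, 2.2, by = 0.1),
                            n_runs = 1000, tau = 0.4, keep_geq = FALSE,
                            max_dim = 3, mean_rule = "arithmetic",
                            seed = 42) {
  structure(list(input = input, coords = coords, out_dir = out_dir,
                 n_nulls_global = n_nulls_global,
                 n_nulls_motifs = n_nulls_motifs,
                 n_nulls_homology = n_nulls_homology,
                 swaps_per_edge = swaps_per_edge, gamma_grid = gamma_grid,
                 n_runs = n_runs, tau = tau, keep_geq = keep_geq,
                 max_dim = max_dim, mean_rule = mean_rule,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read/write an analysis configuration as JSON
#'
#' @param path JSON file path.
#' @return for `read_config`, an `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- paste0(...)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg), con)
  message(msg)
}

#' Run the full topological characterization pipeline
#'
#' Executes every stage on the input matrix and writes a report bundle:
#' `summary.json` (all headline scalars), per-stage CSVs (null
#' distributions, community labels, co-assignment and NMI matrices, per-node
#' hub table, rich-club curve, motif spectrum, persistence barcode), and
#' `pipeline.log`. The summary is byte-identical for identical config +
#' seed.
#'
#' @param config an [analysis_config()].
#' @param graph optionally a ready-made [connectome_graph()] (overrides
#'   `config$input`).
#' @return the summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, graph = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "pipeline.log"), "w")
  on.exit(close(logf))
  seeds <- derive_seeds(config$seed, 6)
  stage <- function(name, expr) {
    pipeline_log(logf, "stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  g <- stage("io", {
    if (!is.null(graph)) graph
    else load_connectome(config$input, config$coords)
  })
  ens_global <- stage("nulls", build_ensemble(g, config$n_nulls_global,
                                              config$swaps_per_edge,
                                              seed = seeds[1]))
  ens_motifs <- stage("nulls", build_ensemble(g, config$n_nulls_motifs,
                                              config$swaps_per_edge,
                                              seed = seeds[2]))
  ens_hom <- stage("nulls", build_ensemble(g, config$n_nulls_homology,
                                           config$swaps_per_edge,
                                           seed = seeds[3]))
  gm <- stage("global_topology", global_metrics(g, config$mean_rule))
  sw <- stage("global_topology", small_world(g, ens_global, config$mean_rule))
  sweep <- stage("communities",
                 resolution_sweep(g, config$gamma_grid, n_runs = config$n_runs,
                                  tau = config$tau, seed = seeds[4]))
  prof <- stage("hubs", participation_rank_profile(g, sweep))
  sr <- stage("hubs", strength_ratio(g))
  rc <- stage("hubs", rich_club(g, ens_global, keep_geq = config$keep_geq))
  ms <- stage("motifs", motif_significance(g, ens_motifs))
  cav <- stage("homology", cavity_significance(g, ens_hom,
                                               max_dim = config$max_dim))
  out <- config$out_dir
  stage("report", {
    s <- strengths(g)
    utils::write.csv(data.frame(label = g$labels, s_in = s$s_in,
                                s_out = s$s_out, k_in = s$k_in,
                                k_out = s$k_out,
                                ratio = sr$ratio,
                                rank_in = prof$rank_in,
                                rank_out = prof$rank_out),
                     file.path(out, "nodes.csv"), row.names = FALSE)
    labmat <- vapply(sweep$consensus, function(x) x$partition$labels,
                     integer(n_nodes(g)))
    colnames(labmat) <- paste0("gamma_", sweep$gamma_grid)
    utils::write.csv(cbind(data.frame(label = g$labels), labmat),
                     file.path(out, "communities.csv"), row.names = FALSE)
    utils::write.csv(sweep$nmi_matrix, file.path(out, "nmi_matrix.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(k = rc$k_levels, phi = rc$phi,
                                phi_norm = rc$phi_norm, p = rc$p_values),
                     file.path(out, "rich_club.csv"), row.names = FALSE)
    utils::write.csv(data.frame(motif = seq_along(ms$class_count),
                                count = ms$class_count, p = ms$p_two_tailed,
                                direction = ms$direction),
                     file.path(out, "motifs.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cav$diagram),
                     file.path(out, "barcode.csv"), row.names = FALSE)
    utils::write.csv(data.frame(clustering = sw$null_clustering,
                                path_length = sw$null_path_length),
                     file.path(out, "null_global.csv"), row.names = FALSE)
    dens <- density_connectome(g)
    summary <- list(
      schema_version = SUMMARY_SCHEMA_VERSION,
      seed = config$seed,
      n_nodes = n_nodes(g), n_edges = n_edges(g),
      density_directed = dens$directed,
      density_undirected = dens$undirected,
      reciprocity = gm$reciprocity,
      assortativity_degree = gm$assortativity_degree,
      assortativity_strength = gm$assortativity_strength,
      clustering_mean = gm$clustering_mean,
      char_path_length = gm$char_path_length,
      gamma_norm = sw$gamma_norm, lambda_norm = sw$lambda_norm,
      sigma = sw$sigma,
      selected_scales = sweep$scales,
      n_communities = stats::setNames(as.list(sweep$n_communities),
                                      paste0("gamma_", sweep$gamma_grid)),
      strength_ratio_correlation = sr$correlation,
      rich_club_regime = as.list(rc$regime),
      motif_counts = ms$class_count,
      motif_p = ms$p_two_tailed,
      motif_direction = ms$direction,
      cavities = cav$summary,
      top_cavities = lapply(cav$top_bars, function(x)
        if (is.null(x)) NULL else as.list(x)))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", always_decimal = FALSE)
    summary
  }) -> summary
  pipeline_log(logf, "done")
  invisible(summary)
}
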