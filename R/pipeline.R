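#' Pipeline configuration
#'
#' One object holding every stage's settings; the whole analysis is
#' regenerable from it plus its seed. Stage seeds are fanned out
#' deterministically from the single `seed` so stages can be rerun in
#' isolation.
#'
#' @param input `"synthetic"` or a path to an item CSV.
#' @param generator a [generator_config()] (used when `input` is
#'   `"synthetic"`); its seed is overridden by the fan-out from `seed`.
#' @param estimation an [estimation_settings()].
#' @param esa an [esa_settings()] plus the scenario list.
#' @param scenarios subset of `c("minimum", "median", "maximum")`.
#' @param stability list: `enabled`, `replicates`, `drop_proportions`.
#' @param seed master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "synthetic",
                            generator = generator_config(),
                            estimation = estimation_settings(),
                            esa = esa_settings(),
                            scenarios = c("minimum", "median", "maximum"),
                            stability = list(enabled = TRUE,
                                             replicates = 100,
                                             drop_proportions = seq(0.1, 0.75, by = 0.05)),
                            seed = 1) {
  structure(list(input = input, generator = generator,
                 estimation = estimation, esa = esa,
                 scenarios = scenarios, stability = stability,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and write a pipeline configuration as JSON
#'
#' A configuration file fully determines an analysis (together with its
#' embedded seed); writing then reading reproduces the configuration, so a
#' run can be archived and regenerated from the file alone.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- raw$generator
  pce <- if (is.null(gen$planted_cross_edges)) default_cross_edges()
         else as.data.frame(gen$planted_cross_edges)
  est <- raw$estimation
  pipeline_config(
    input = raw$input,
    generator = generator_config(
      n = gen$n, loading = gen$loading,
      strategy_intercorrelation = gen$strategy_intercorrelation,
      planted_cross_edges = pce,
      within_symptom_edge = gen$within_symptom_edge,
      seed = gen$seed),
    estimation = estimation_settings(
      ebic_gamma = est$ebic_gamma, n_lambda = est$n_lambda,
      lambda_min_ratio = est$lambda_min_ratio, cv_folds = est$cv_folds,
      cv_seed = est$cv_seed, edge_rule = est$edge_rule,
      cv_rule = est$cv_rule),
    esa = esa_settings(n_samples = raw$esa$n_samples,
                       burn_in = raw$esa$burn_in, thin = raw$esa$thin,
                       seed = raw$esa$seed),
    scenarios = raw$scenarios,
    stability = list(enabled = raw$stability$enabled,
                     replicates = raw$stability$replicates,
                     drop_proportions = raw$stability$drop_proportions),
    seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate item data; score the six strategy
#' subscales; exploratory graph analysis of the 38 RESS items (Pearson
#' correlations, EBIC-glasso, walktrap); mixed graphical model over the 22
#' strategy + symptom nodes; centralities and global properties;
#' case-dropping bootstrap stability (optional); baseline symptom activity;
#' ESA sweeps of every strategy under every requested scenario.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return A report bundle: list with `data`, `scores`, `ega`, `mgm`,
#'   `centrality`, `global_properties`, `stability`, `baseline`,
#'   `esa_profiles` (one per strategy x scenario), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # stage 1: data
  if (identical(config$input, "synthetic")) {
    gen <- config$generator
    gen$seed <- derive_seed(config$seed, 1L)
    say("[data] generating synthetic dataset (n = %d, seed = %d)",
        gen$n, gen$seed)
    data <- generate_dataset(gen)
  } else {
    say("[data] reading %s", config$input)
    data <- read_item_csv(config$input)
  }
  validate_item_response_matrix(data)

  # stage 2: subscale scores
  scores <- score_subscales(data)

  # stage 3: EGA on the RESS items
  say("[ega] estimating item network and walktrap communities")
  ega_res <- ega(data, settings = config$estimation)
  say("[ega] %d communities", ega_res$partition$n_communities)

  # stage 4: MGM over 22 nodes
  say("[mgm] nodewise cross-validated lasso over 22 nodes")
  est <- config$estimation
  est$cv_seed <- derive_seed(config$seed, 4L)
  node_tbl <- cbind(scores, as.data.frame(symptom_matrix(data)))
  mgm <- estimate_mgm(node_tbl, settings = est)

  # stage 5: metrics
  centrality <- centrality_table(mgm)
  gp <- global_properties(mgm)
  say("[metrics] %d edges (%d negative), density %.3f",
      gp$n_edges, gp$n_negative_edges, gp$density)

  # stage 6: stability (optional)
  boot <- NULL
  if (isTRUE(config$stability$enabled)) {
    say("[stability] case-dropping bootstrap (%d replicates/proportion)",
        config$stability$replicates)
    est_fun <- local({
      s <- est
      nodes <- mgm$nodes
      function(x) estimate_mgm(x, nodes = nodes, settings = s)
    })
    boot <- case_dropping_bootstrap(
      node_tbl, est_fun,
      statistics = c("strength", "edge_weights"),
      drop_proportions = config$stability$drop_proportions,
      replicates = config$stability$replicates,
      seed = derive_seed(config$seed, 6L))
    say("[stability] CS(strength) = %.2f, CS(edges) = %.2f",
        boot$cs[["strength"]], boot$cs[["edge_weights"]])
  }

  # stage 7: baseline symptom activity
  esa_set <- config$esa
  esa_set$seed <- derive_seed(config$seed, 7L)
  baseline <- baseline_esa(data, net = mgm, settings = esa_set)
  say("[esa] baseline ESA: observed %.3f, model-implied %.3f",
      baseline$observed, baseline$model_implied)

  # stage 8: ESA sweeps
  profiles <- list()
  for (scenario in config$scenarios) {
    for (strategy in strategy_names()) {
      key <- paste(strategy, scenario, sep = ".")
      profiles[[key]] <- esa_scenario_sweep(mgm, strategy, scenario,
                                            settings = esa_set,
                                            baseline = baseline$value)
    }
  }
  say("[esa] %d profiles computed", length(profiles))

  provenance <- list(
    seed = config$seed,
    scenarios = config$scenarios,
    n = data$n,
    package_version = as.character(utils::packageVersion("esanet")),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(data = data, scores = scores, ega = ega_res, mgm = mgm,
                 centrality = centrality, global_properties = gp,
                 stability = boot, baseline = baseline,
                 esa_profiles = profiles, config = config,
                 provenance = provenance),
            class = "report_bundle")
}

#' Serialize a report bundle to a directory
#'
#' Writes: the item data (`items.csv`), EGA and MGM edge lists and GraphML,
#' the community assignment, centralities, global properties, the stability
#' summary, all ESA profiles, and a JSON report with the headline numbers
#' and provenance. All floating-point CSV values carry 6 decimals so
#' identical configurations yield byte-identical files.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)

  add(write_item_csv(bundle$data, file.path(dir, "items.csv")))
  add(write_csv_fixed(network_edges(bundle$ega$network),
                      file.path(dir, "ega_edges.csv")))
  add(write_csv_fixed(network_edges(bundle$mgm),
                      file.path(dir, "mgm_edges.csv")))
  add(write_graphml(bundle$ega$network, file.path(dir, "ega_network.graphml")))
  add(write_graphml(bundle$mgm, file.path(dir, "mgm_network.graphml")))

  part <- data.frame(node_id = names(bundle$ega$partition$assignment),
                     community = as.integer(bundle$ega$partition$assignment),
                     stringsAsFactors = FALSE)
  add(write_csv_fixed(part, file.path(dir, "ega_communities.csv")))
  add(write_csv_fixed(bundle$centrality, file.path(dir, "centrality.csv")))
  if (!is.null(bundle$stability))
    add(write_csv_fixed(stability_summary(bundle$stability),
                        file.path(dir, "stability.csv")))
  add(write_csv_fixed(esa_profiles_table(bundle$esa_profiles),
                      file.path(dir, "esa_profiles.csv")))

  gp <- bundle$global_properties
  report <- list(
    global_properties = lapply(gp, function(v)
      if (is.numeric(v)) round(v, 6) else v),
    baseline_esa = list(observed = round(bundle$baseline$observed, 6),
                        model_implied = round(bundle$baseline$model_implied, 6)),
    n_communities = bundle$ega$partition$n_communities,
    cs_coefficients = if (!is.null(bundle$stability))
      as.list(round(bundle$stability$cs, 6)) else NULL,
    crossing_points = lapply(bundle$esa_profiles, function(p)
      if (is.na(p$crossing_point)) NULL else p$crossing_point),
    provenance = bundle$provenance[c("seed", "scenarios", "n",
                                     "package_version")])
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  add(json_path)
  invisible(paths)
}
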