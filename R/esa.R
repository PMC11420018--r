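#' Sampler settings for the expected-symptom-activity simulation
#'
#' @param n_samples retained Gibbs sweeps per conditioning point.
#' @param burn_in discarded initial sweeps.
#' @param thin keep every `thin`-th sweep.
#' @param seed integer seed.
#' @return An `esa_settings` list.
#' @export
esa_settings <- function(n_samples = 20000, burn_in = 2000, thin = 1,
                         seed = 1) {
  stopifnot(n_samples > 0, burn_in >= 0, thin >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "esa_settings")
}

#' Background strategy values of a conditioning scenario
#'
#' The three scenarios fix the five non-swept strategies at their minimum
#' (suppression/engagement/reappraisal 8, rumination 6, arousal control/
#' distraction 4), median (24 / 18 / 12), or maximum (40 / 30 / 20)
#' sum-scores.
#'
#' @param scenario `"minimum"`, `"median"`, or `"maximum"`.
#' @return Named numeric vector of sum-scores for the six strategies.
#' @export
scenario_background <- function(scenario = c("minimum", "median", "maximum")) {
  scenario <- match.arg(scenario)
  vals <- switch(scenario,
                 minimum = c(8, 6, 4),
                 median = c(24, 18, 12),
                 maximum = c(40, 30, 20))
  c(suppression = vals[1], engagement = vals[1], reappraisal = vals[1],
    rumination = vals[2], arousal_control = vals[3], distraction = vals[3])
}

# validate a clamp specification against the network's node ranges
check_clamp <- function(net, clamp) {
  stopifnot(is.numeric(clamp), !is.null(names(clamp)))
  nodes <- net$nodes
  for (id in names(clamp)) {
    i <- match(id, nodes$node_id)
    if (is.na(i)) stop("unknown node in clamp: ", id)
    if (nodes$kind[i] == "ordinal_symptom")
      stop("symptom nodes are never clamped: ", id)
    lo <- nodes$range_min[i]; hi <- nodes$range_max[i]
    if (!is.na(lo) && (clamp[[id]] < lo || clamp[[id]] > hi))
      stop("clamp value ", clamp[[id]], " for ", id,
           " outside its range [", lo, ", ", hi, "]")
  }
  invisible(clamp)
}

#' Gibbs samples of the network conditional on clamped strategies
#'
#' Single-site Gibbs sampling of the mixed graphical model using each
#' node's stored nodewise linear conditional: a Gaussian draw around the
#' regression mean, clipped to the 0-3 code range and rounded for ordinal
#' symptom nodes. Clamped strategy values are entered on the raw sum-score
#' scale and standardized internally with the training means and sds.
#'
#' @param net a `weighted_network` with nodewise `models` (from
#'   [estimate_mgm()] or [toy_mgm_network()]).
#' @param clamp named numeric vector: strategy node -> fixed sum-score.
#'   Empty for an unconditional run.
#' @param settings an [esa_settings()].
#' @return Matrix (`n_samples / thin` rows) of raw-scale node values,
#'   columns named by node; clamped columns are constant.
#' @export
gibbs_sample_conditional <- function(net, clamp = numeric(0),
                                     settings = esa_settings()) {
  stopifnot(inherits(net, "weighted_network"))
  m <- net$models
  if (is.null(m)) stop("network carries no nodewise models; fit with estimate_mgm()")
  if (length(clamp)) check_clamp(net, clamp)

  ids <- net$nodes$node_id
  p <- length(ids)
  clamped <- ids %in% names(clamp)
  clamp_raw <- numeric(p)
  clamp_raw[clamped] <- clamp[ids[clamped]]
  ordinal <- net$nodes$kind == "ordinal_symptom"
  init <- m$center  # start each free node at its training mean

  samples <- with_seed(settings$seed,
    gibbs_mgm_cpp(m$B, m$intercept, m$sigma, m$center, m$scale,
                  ordinal, net$nodes$range_min, net$nodes$range_max,
                  clamped, clamp_raw, init,
                  settings$n_samples, settings$burn_in, settings$thin))
  colnames(samples) <- ids
  samples
}

#' Expected symptom activity under a conditioning
#'
#' ESA is the sum, over the 16 symptom nodes, of their conditional sample
#' means on the original 0-3 code scale, with the named strategies clamped.
#'
#' @inheritParams gibbs_sample_conditional
#' @return A single number in \[0, sum of symptom maxima\] (48 for the full
#'   battery).
#' @export
expected_symptom_activity <- function(net, clamp = numeric(0),
                                      settings = esa_settings()) {
  samples <- gibbs_sample_conditional(net, clamp, settings)
  sym <- net$nodes$node_id[net$nodes$kind == "ordinal_symptom"]
  sum(colMeans(samples[, sym, drop = FALSE]))
}

#' Baseline symptom activity
#'
#' The observed baseline is the sum of the 16 symptom sample means in the
#' data (the primary definition). When a fitted network is supplied, the
#' model-implied baseline (an unclamped Gibbs run) is also computed, with
#' the discrepancy between the two reported as a diagnostic.
#'
#' @param data an `item_response_matrix` (or participants x symptoms
#'   matrix of 0-3 codes).
#' @param net optional fitted `weighted_network` with nodewise models.
#' @param settings an [esa_settings()] for the model-implied run.
#' @return List: `observed`, `model_implied` (or NA), `discrepancy`,
#'   `value` (= observed).
#' @export
baseline_esa <- function(data, net = NULL, settings = esa_settings()) {
  sym <- if (inherits(data, "item_response_matrix")) symptom_matrix(data)
         else as.matrix(data)
  observed <- sum(colMeans(sym))
  model_implied <- NA_real_
  if (!is.null(net)) {
    model_implied <- expected_symptom_activity(net, clamp = numeric(0),
                                               settings = settings)
  }
  list(value = observed, observed = observed,
       model_implied = model_implied,
       discrepancy = model_implied - observed)
}

#' ESA sweep of one strategy under a background scenario
#'
#' Clamps the chosen strategy at every integer sum-score in its range while
#' the other five strategies are held at the scenario's background values,
#' computing ESA at each grid point. The crossing point is the smallest
#' clamp value whose ESA strictly exceeds the baseline.
#'
#' @param net fitted `weighted_network` with nodewise models.
#' @param strategy one of the six strategy node ids.
#' @param scenario `"minimum"`, `"median"`, or `"maximum"`.
#' @param settings an [esa_settings()]; each grid point reuses the same
#'   seed so profiles are deterministic.
#' @param baseline baseline ESA value to compare against (e.g.
#'   `baseline_esa(data)$value`); optional.
#' @return An `esa_profile`: list with `strategy`, `scenario`, `grid`,
#'   `esa_values`, `baseline_esa`, `crossing_point`, `background`.
#' @export
esa_scenario_sweep <- function(net, strategy,
                               scenario = c("minimum", "median", "maximum"),
                               settings = esa_settings(), baseline = NULL) {
  scenario <- match.arg(scenario)
  i <- match(strategy, net$nodes$node_id)
  if (is.na(i) || net$nodes$kind[i] != "continuous_strategy")
    stop("unknown strategy node: ", strategy)
  grid <- seq(net$nodes$range_min[i], net$nodes$range_max[i])
  background <- scenario_background(scenario)
  background <- background[names(background) %in% net$nodes$node_id]
  background <- background[setdiff(names(background), strategy)]

  esa_values <- vapply(grid, function(v) {
    clamp <- c(setNames(v, strategy), background)
    expected_symptom_activity(net, clamp, settings)
  }, numeric(1))

  profile <- structure(list(strategy = strategy, scenario = scenario,
                            grid = grid, esa_values = esa_values,
                            baseline_esa = if (is.null(baseline)) NA_real_
                                           else baseline,
                            crossing_point = NA_integer_,
                            background = background),
                       class = "esa_profile")
  profile$crossing_point <- crossing_point(profile)
  profile
}

#' Smallest clamp value whose ESA exceeds baseline
#'
#' @param profile an `esa_profile` with a baseline attached.
#' @return The smallest grid value with ESA strictly above the baseline, or
#'   `NA` if the profile never exceeds it (or no baseline is attached).
#' @export
crossing_point <- function(profile) {
  stopifnot(inherits(profile, "esa_profile"))
  if (is.na(profile$baseline_esa)) return(NA_integer_)
  above <- profile$esa_values > profile$baseline_esa
  if (!any(above)) return(NA_integer_)
  as.integer(profile$grid[which(above)[1]])
}

#' @export
print.esa_profile <- function(x, ...) {
  cat("ESA profile: ", x$strategy, " (", x$scenario, " scenario), ",
      length(x$grid), " grid points [", min(x$grid), "-", max(x$grid),
      "]\n", sep = "")
  cat("  ESA range: ", format(min(x$esa_values), digits = 5), " - ",
      format(max(x$esa_values), digits = 5), sep = "")
  if (!is.na(x$baseline_esa))
    cat("; baseline ", format(x$baseline_esa, digits = 5),
        "; crossing at ", x$crossing_point, sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy data.frame of one or more ESA profiles
#'
#' @param profiles an `esa_profile` or list of them.
#' @return data.frame: strategy, scenario, sum_score, esa, baseline,
#'   crossing_point.
#' @export
esa_profiles_table <- function(profiles) {
  if (inherits(profiles, "esa_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(strategy = p$strategy, scenario = p$scenario,
               sum_score = p$grid, esa = p$esa_values,
               baseline = p$baseline_esa, crossing_point = p$crossing_point,
               stringsAsFactors = FALSE)
  }))
}

#' Construct a toy mixed-graphical-model network
#'
#' Builds a `weighted_network` whose nodewise conditionals are read
#' directly off a symmetric weight matrix (conditional mean of each node =
#' weighted sum of the others on the standardized scale), for simulation
#' experiments and fixtures where no data are fitted.
#'
#' @param weights symmetric p x p matrix, zero diagonal.
#' @param nodes node metadata (see [weighted_network()]).
#' @param center,scale training means / sds per node (defaults 0 / 1).
#' @param sigma residual sds per node on the standardized scale (default 1).
#' @param intercept standardized-scale intercepts (default 0).
#' @return A `weighted_network` with `models` attached.
#' @export
toy_mgm_network <- function(weights, nodes, center = NULL, scale = NULL,
                            sigma = NULL, intercept = NULL) {
  p <- nrow(weights)
  if (is.null(center)) center <- rep(0, p)
  if (is.null(scale)) scale <- rep(1, p)
  if (is.null(sigma)) sigma <- rep(1, p)
  if (is.null(intercept)) intercept <- rep(0, p)
  B <- as.matrix(weights)
  diag(B) <- 0
  models <- list(B = B, intercept = intercept, sigma = sigma,
                 center = setNames(center, nodes$node_id),
                 scale = setNames(scale, nodes$node_id))
  weighted_network(weights, nodes, estimator_tag = "mgm", models = models)
}
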