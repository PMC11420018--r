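#' Planted strategy-symptom cross associations
#'
#' The default set of 14 signed conditional associations between
#' emotion-regulation strategies and individual symptoms that the synthetic
#' generator plants in the latent precision matrix: positive links such as
#' rumination with uncontrollable worry and suppression with low self-esteem,
#' and negative links such as reappraisal with hopelessness, fatigue, low
#' self-esteem, uncontrollable worry, and irritability. Magnitudes are partial
#' correlations on the latent scale.
#'
#' @param magnitude partial-correlation magnitude for every planted edge.
#' @return data.frame with columns `strategy`, `symptom`, `sign`, `magnitude`.
#' @export
default_cross_edges <- function(magnitude = 0.2) {
  edges <- rbind(
    c("rumination",      "gad2", 1),   # uncontrollable worry
    c("suppression",     "phq6", 1),   # low self-esteem
    c("arousal_control", "phq4", 1),   # fatigue
    c("arousal_control", "gad5", 1),   # restlessness
    c("arousal_control", "gad3", 1),   # excessive worry
    c("reappraisal",     "phq2", -1),  # hopelessness
    c("reappraisal",     "phq4", -1),
    c("reappraisal",     "phq6", -1),
    c("reappraisal",     "gad2", -1),
    c("reappraisal",     "gad6", -1),  # irritability
    c("engagement",      "phq4", -1),
    c("distraction",     "phq6", -1),
    c("distraction",     "phq9", -1),  # suicidal ideation
    c("rumination",      "gad5", -1)
  )
  data.frame(strategy = edges[, 1], symptom = edges[, 2],
             sign = as.numeric(edges[, 3]), magnitude = magnitude,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic item-response generator
#'
#' @param n sample size (default 376, a community-sample scale study).
#' @param loading factor loading of each RESS item on its strategy's latent
#'   factor, in (0, 1).
#' @param strategy_intercorrelation pairwise latent correlation among the six
#'   strategy factors (all positive by default).
#' @param planted_cross_edges data.frame of signed strategy-symptom partial
#'   associations, as [default_cross_edges()].
#' @param within_symptom_edge baseline positive partial association among
#'   symptoms of the same instrument (latent scale). Must stay below
#'   1/(m - 1) for an m-item instrument block to keep the precision matrix
#'   positive definite (0.125 for the 9-item PHQ block).
#' @param seed integer seed; all generator randomness flows from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 376, loading = 0.7,
                             strategy_intercorrelation = 0.3,
                             planted_cross_edges = default_cross_edges(),
                             within_symptom_edge = 0.1,
                             seed = 1) {
  if (length(n) != 1 || n <= 0 || n != round(n))
    stop("`n` must be a positive integer")
  if (loading <= 0 || loading >= 1)
    stop("`loading` must lie strictly inside (0, 1)")
  if (!is.null(planted_cross_edges) && nrow(planted_cross_edges) > 0) {
    if (!all(planted_cross_edges$sign %in% c(-1, 1)))
      stop("planted edge `sign` values must be -1 or +1")
    if (any(planted_cross_edges$magnitude < 0))
      stop("planted edge magnitudes must be non-negative")
  }
  structure(list(n = as.integer(n), loading = loading,
                 strategy_intercorrelation = strategy_intercorrelation,
                 planted_cross_edges = planted_cross_edges,
                 within_symptom_edge = within_symptom_edge,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# 22 x 22 latent correlation matrix over 6 strategy factors + 16 symptom
# latents. Strategy block: equicorrelated at the configured marginal
# correlation (entered through its inverse so cross-edges can be planted in
# precision space). Symptom blocks and strategy-symptom cross edges are
# planted as partial correlations; if the assembled precision matrix is not
# positive definite its diagonal is inflated minimally.
latent_correlation <- function(config, items = default_item_meta()) {
  strategies <- strategy_names()
  syms <- symptom_ids(items)
  ids <- c(strategies, syms)
  p <- length(ids)
  K <- diag(p)
  rownames(K) <- colnames(K) <- ids

  rho <- config$strategy_intercorrelation
  Rs <- matrix(rho, 6, 6); diag(Rs) <- 1
  K[1:6, 1:6] <- solve(Rs)

  w <- config$within_symptom_edge
  for (inst in c("PHQ9", "GAD7")) {
    blk <- items$item_id[items$instrument == inst]
    K[blk, blk] <- -w * sqrt(diag(K)[blk] %o% diag(K)[blk]) *
      (1 - diag(length(blk))) + diag(diag(K)[blk])
  }

  pc <- config$planted_cross_edges
  if (!is.null(pc) && nrow(pc) > 0) {
    for (r in seq_len(nrow(pc))) {
      s <- pc$strategy[r]; y <- pc$symptom[r]
      if (!s %in% strategies) stop("unknown strategy in planted edge: ", s)
      if (!y %in% syms) stop("unknown symptom in planted edge: ", y)
      v <- -pc$sign[r] * pc$magnitude[r] * sqrt(K[s, s] * K[y, y])
      K[s, y] <- K[s, y] + v
      K[y, s] <- K[s, y]
    }
  }

  # if the planted structure is too strong to be a valid precision matrix,
  # shrink all off-diagonal entries proportionally (preserves the relative
  # planted structure, unlike additive diagonal inflation)
  min_eig <- function(M) min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (min_eig(K) < 1e-4) {
    D <- diag(diag(K))
    O <- K - D
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (min_eig(D + mid * O) >= 1e-4) lo <- mid else hi <- mid
    }
    warning("planted structure scaled by ", signif(lo, 3),
            " to keep the latent precision matrix positive definite")
    K <- D + lo * O
  }
  stats::cov2cor(solve(K))
}

#' Generate a synthetic RESS + PHQ-9 + GAD-7 item-response dataset
#'
#' Draws a latent multivariate Gaussian over 6 strategy factors and 16
#' symptom latents whose precision matrix encodes within-instrument positive
#' dependencies and the planted signed strategy-symptom links, then
#' discretizes: RESS items load on their strategy factor (plus unique noise)
#' and are thresholded to 1-5 Likert codes; symptom latents are thresholded
#' to right-skewed 0-3 codes with expected per-item mean 0.9, so the summed
#' 16-symptom baseline sits near 14.4 (community-sample severity).
#'
#' @param config a [generator_config()].
#' @return An `item_response_matrix`: list with `values` (n x 54 integer
#'   matrix, columns named by item id), `items` (metadata), `n`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  items <- default_item_meta()
  Sigma <- latent_correlation(config, items)
  n <- config$n
  lam <- config$loading

  with_seed(config$seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, ncol(Sigma)), Sigma = Sigma)
    colnames(Z) <- colnames(Sigma)

    values <- matrix(NA_integer_, n, nrow(items),
                     dimnames = list(NULL, items$item_id))
    likert_cuts <- c(-1.5, -0.5, 0.5, 1.5)
    sym_cuts <- qnorm(c(0.45, 0.75, 0.90))  # P(code) = .45/.30/.15/.10

    ress <- items[items$instrument == "RESS", ]
    for (r in seq_len(nrow(ress))) {
      f <- Z[, ress$subscale[r]]
      x <- lam * f + sqrt(1 - lam^2) * rnorm(n)
      values[, ress$item_id[r]] <- 1L + findInterval(x, likert_cuts)
    }
    for (id in symptom_ids(items)) {
      values[, id] <- findInterval(Z[, id], sym_cuts)
    }
    new_item_response_matrix(values, items)
  })
}

new_item_response_matrix <- function(values, items) {
  structure(list(values = values, items = items, n = nrow(values)),
            class = "item_response_matrix")
}

#' @export
print.item_response_matrix <- function(x, ...) {
  cat("Item response matrix:", x$n, "participants x", nrow(x$items), "items\n")
  tab <- table(x$items$instrument)
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

validate_item_response_matrix <- function(x) {
  stopifnot(inherits(x, "item_response_matrix"))
  if (anyNA(x$values)) {
    bad <- which(is.na(x$values), arr.ind = TRUE)[1, ]
    stop("missing cell at row ", bad[1], ", item ",
         colnames(x$values)[bad[2]], "; complete data required")
  }
  for (r in seq_len(nrow(x$items))) {
    id <- x$items$item_id[r]
    v <- x$values[, id]
    if (any(v < x$items$min_code[r] | v > x$items$max_code[r])) {
      i <- which(v < x$items$min_code[r] | v > x$items$max_code[r])[1]
      stop("out-of-range code ", v[i], " at row ", i, ", item ", id,
           " (legal range ", x$items$min_code[r], "-", x$items$max_code[r], ")")
    }
  }
  invisible(x)
}

#' Score the six RESS strategy subscales
#'
#' Each strategy score is the plain sum of its items' codes; ranges are 8-40
#' for suppression, engagement, and reappraisal, 6-30 for rumination, and
#' 4-20 for arousal control and distraction.
#'
#' @param data an `item_response_matrix` containing all 38 RESS items.
#' @return data.frame (participants x 6) of integer sum-scores, columns in
#'   canonical strategy order.
#' @export
score_subscales <- function(data) {
  stopifnot(inherits(data, "item_response_matrix"))
  ress <- data$items[data$items$instrument == "RESS", ]
  missing <- setdiff(ress$item_id, colnames(data$values))
  if (length(missing) > 0)
    stop("missing RESS item(s): ", paste(missing, collapse = ", "))
  out <- sapply(strategy_names(), function(s) {
    ids <- ress$item_id[ress$subscale == s]
    rowSums(data$values[, ids, drop = FALSE])
  })
  as.data.frame(out)
}

#' Symptom columns of an item-response matrix
#'
#' @param data an `item_response_matrix`.
#' @return Integer matrix (participants x 16) of PHQ-9 and GAD-7 codes.
#' @export
symptom_matrix <- function(data) {
  stopifnot(inherits(data, "item_response_matrix"))
  data$values[, symptom_ids(data$items), drop = FALSE]
}
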