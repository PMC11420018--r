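#' Construct a weighted network object
#'
#' Symmetric signed weighted adjacency over named nodes, the common currency
#' of the estimation, metrics, stability, and simulation stages.
#'
#' @param weights symmetric p x p numeric matrix with zero diagonal.
#' @param nodes data.frame with columns `node_id`, `kind`
#'   (`continuous_strategy` / `ordinal_symptom`), `group`
#'   (`ER` / `depression` / `anxiety`), `range_min`, `range_max`.
#' @param estimator_tag `"ebic_glasso"` or `"mgm"` (or `"manual"` for
#'   constructed fixtures).
#' @param models optional per-node conditional models (see
#'   [estimate_mgm()]), required by the Gibbs sampler.
#' @param ... further fields stored on the object (fit diagnostics).
#' @return A `weighted_network`.
#' @export
weighted_network <- function(weights, nodes, estimator_tag = "manual",
                             models = NULL, ...) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  stopifnot(ncol(weights) == p, nrow(nodes) == p)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  rownames(weights) <- colnames(weights) <- nodes$node_id
  structure(c(list(weights = weights, nodes = nodes,
                   estimator_tag = estimator_tag, models = models),
              list(...)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  p <- nrow(x$weights)
  ut <- x$weights[upper.tri(x$weights)]
  cat("Weighted network (", x$estimator_tag, "): ", p, " nodes, ",
      sum(ut != 0), " edges (", sum(ut < 0), " negative)\n", sep = "")
  invisible(x)
}

# default 22-node metadata: 6 continuous strategies + 16 ordinal symptoms
default_node_meta <- function(items = default_item_meta()) {
  rng <- strategy_ranges(items)
  strat <- data.frame(node_id = strategy_names(),
                      kind = "continuous_strategy", group = "ER",
                      range_min = sapply(strategy_names(), function(s) rng[[s]][1]),
                      range_max = sapply(strategy_names(), function(s) rng[[s]][2]),
                      stringsAsFactors = FALSE, row.names = NULL)
  sym <- items[items$instrument %in% c("PHQ9", "GAD7"), ]
  symdf <- data.frame(node_id = sym$item_id, kind = "ordinal_symptom",
                      group = ifelse(sym$instrument == "PHQ9",
                                     "depression", "anxiety"),
                      range_min = sym$min_code, range_max = sym$max_code,
                      stringsAsFactors = FALSE)
  rbind(strat, symdf)
}

#' Estimation settings for the network stages
#'
#' @param ebic_gamma hyperparameter gamma of the extended BIC (default 0.5,
#'   the exploratory-graph-analysis convention).
#' @param n_lambda number of penalties on the log-spaced graphical-lasso
#'   path.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   (the largest is the maximal absolute off-diagonal correlation).
#' @param cv_folds folds for the nodewise cross-validation in the mixed
#'   graphical model.
#' @param cv_seed seed fixing the fold assignment.
#' @param edge_rule `"AND"` (edge present only if both directed coefficients
#'   are nonzero with agreeing sign) or `"OR"` (mean of the nonzero ones).
#' @param cv_rule `"lambda.min"` (penalty minimizing cross-validated error,
#'   the mixed-graphical-model convention and the default) or `"lambda.1se"`
#'   (largest penalty within one standard error of the minimum; markedly
#'   sparser, near-certain to return an empty network on independent data,
#'   at a substantial cost in power for weak edges).
#' @return An `estimation_settings` list.
#' @export
estimation_settings <- function(ebic_gamma = 0.5, n_lambda = 100,
                                lambda_min_ratio = 0.01, cv_folds = 10,
                                cv_seed = 1, edge_rule = c("AND", "OR"),
                                cv_rule = c("lambda.min", "lambda.1se")) {
  stopifnot(ebic_gamma >= 0, cv_folds >= 2, n_lambda >= 1,
            lambda_min_ratio > 0, lambda_min_ratio <= 1)
  structure(list(ebic_gamma = ebic_gamma, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 edge_rule = match.arg(edge_rule),
                 cv_rule = match.arg(cv_rule)),
            class = "estimation_settings")
}

#' Correlation matrix of raw item codes or sum-scores
#'
#' @param data an `item_response_matrix`, matrix, or data.frame of numeric
#'   columns.
#' @param method `"pearson"` (default, raw-score convention) or
#'   `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- if (inherits(data, "item_response_matrix")) data$values else as.matrix(data)
  storage.mode(x) <- "double"
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cor(x, method = method)
}

#' Regularized partial-correlation network (graphical lasso + EBIC)
#'
#' Fits the graphical lasso along a descending penalty path and scores each
#' fit with the extended Bayesian information criterion
#' EBIC = -2 loglik + E log(n) + 4 gamma E log(p), where E counts nonzero
#' edges; the minimizing fit is returned as a partial-correlation network.
#'
#' @param corr p x p correlation matrix (repaired to the nearest positive
#'   definite matrix if needed, with a message).
#' @param n sample size behind `corr`.
#' @param settings an [estimation_settings()].
#' @param nodes optional node metadata; defaults to generic nodes named by
#'   `corr`'s column names.
#' @return A `weighted_network` (estimator tag `ebic_glasso`) whose weights
#'   are partial correlations; carries `lambda` (selected penalty), `ebic`
#'   (path of scores), and `lambda_path`.
#' @export
ebic_glasso <- function(corr, n, settings = estimation_settings(),
                        nodes = NULL) {
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (length(n) != 1 || n <= 0) stop("`n` must be a positive count")
  if (settings$n_lambda < 1) stop("empty lambda grid")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("correlation matrix not positive definite; applying nearest-PD repair")
    corr <- as.matrix(Matrix::nearPD(corr, corr = TRUE)$mat)
  }

  lmax <- max(abs(corr[upper.tri(corr)]))
  if (lmax <= 0) lmax <- 0.1
  lambdas <- exp(seq(log(lmax), log(lmax * settings$lambda_min_ratio),
                     length.out = settings$n_lambda))

  fit <- glasso_path_cpp(corr, lambdas)
  ebic <- vapply(fit$theta, function(Theta) {
    E <- sum(Theta[upper.tri(Theta)] != 0)
    ld <- determinant(Theta, logarithm = TRUE)$modulus
    loglik <- (n / 2) * (as.numeric(ld) - sum(Theta * corr))
    -2 * loglik + E * log(n) + 4 * settings$ebic_gamma * E * log(p)
  }, numeric(1))
  best <- which.min(ebic)
  Theta <- fit$theta[[best]]

  d <- sqrt(diag(Theta))
  pcor <- -Theta / (d %o% d)
  diag(pcor) <- 0
  pcor[Theta == 0] <- 0
  pcor <- pmin(pmax(pcor, -1), 1)

  if (is.null(nodes)) {
    ids <- colnames(corr)
    if (is.null(ids)) ids <- paste0("V", seq_len(p))
    nodes <- data.frame(node_id = ids, kind = "generic", group = "all",
                        range_min = NA, range_max = NA,
                        stringsAsFactors = FALSE)
  }
  weighted_network(pcor, nodes, estimator_tag = "ebic_glasso",
                   lambda = lambdas[best], ebic = ebic,
                   lambda_path = lambdas)
}

#' Walktrap community detection
#'
#' Runs the walktrap algorithm (short random walks; canonical 4 steps) on
#' the network, with negative edge weights entered by absolute value, and
#' returns the maximum-modularity partition of the merge dendrogram.
#' Isolated nodes form their own communities.
#'
#' @param net a `weighted_network`.
#' @param steps random-walk length.
#' @return A `community_partition`: list with `assignment` (named integer
#'   vector, communities numbered contiguously from 1), `n_communities`.
#' @export
walktrap_communities <- function(net, steps = 4) {
  stopifnot(inherits(net, "weighted_network"))
  p <- nrow(net$weights)
  if (p < 1) stop("empty network")
  g <- igraph::graph_from_adjacency_matrix(abs(net$weights),
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- if (igraph::ecount(g) == 0) {
    seq_len(p)
  } else {
    wt <- igraph::cluster_walktrap(g, steps = steps)
    igraph::membership(wt)
  }
  memb <- as.integer(factor(memb))  # contiguous 1..k
  names(memb) <- net$nodes$node_id
  structure(list(assignment = memb, n_communities = max(memb)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities over",
      length(x$assignment), "nodes\n")
  invisible(x)
}

#' Exploratory graph analysis of the RESS items
#'
#' Convenience wrapper chaining [correlation_matrix()] (Pearson on raw
#' scores), [ebic_glasso()], and [walktrap_communities()] on the 38 RESS
#' items; the detected communities play the role of factors, expected to
#' recover the six emotion-regulation strategies.
#'
#' @param data an `item_response_matrix`.
#' @param settings an [estimation_settings()].
#' @param method correlation type.
#' @return List with `network`, `partition`, `items` (the RESS metadata).
#' @export
ega <- function(data, settings = estimation_settings(),
                method = c("pearson", "spearman")) {
  stopifnot(inherits(data, "item_response_matrix"))
  ress <- data$items[data$items$instrument == "RESS", ]
  sub <- data$values[, ress$item_id, drop = FALSE]
  corr <- correlation_matrix(sub, method = match.arg(method))
  nodes <- data.frame(node_id = ress$item_id, kind = "ordinal_item",
                      group = ress$subscale, range_min = ress$min_code,
                      range_max = ress$max_code, stringsAsFactors = FALSE)
  net <- ebic_glasso(corr, n = data$n, settings = settings, nodes = nodes)
  part <- walktrap_communities(net)
  list(network = net, partition = part, items = ress)
}

#' Mixed graphical model by nodewise cross-validated lasso
#'
#' Regresses each of the 22 nodes (6 continuous strategy sum-scores, 16
#' ordinal symptoms entered as their 0-3 integer codes) on all others with
#' a lasso penalty on standardized variables; the penalty per node is chosen
#' by k-fold cross-validation with folds fixed by `cv_seed`. The two
#' directed coefficients of each pair are aggregated into one undirected
#' edge by the `AND` rule (mean if both nonzero with agreeing sign, zero if
#' either is zero) or `OR` rule (mean of nonzero); sign-conflicting nonzero
#' pairs are zeroed and counted in `sign_conflicts`. The fitted nodewise
#' conditionals (standardized-scale coefficients, intercepts, residual
#' scales, training means and sds) are stored for the Gibbs simulation.
#'
#' @param tbl participants x p data.frame or matrix (columns named by node).
#' @param nodes node metadata as in [weighted_network()]; defaults to the
#'   canonical 22-node layout when column names match it.
#' @param settings an [estimation_settings()].
#' @return A `weighted_network` with estimator tag `mgm`.
#' @export
estimate_mgm <- function(tbl, nodes = NULL, settings = estimation_settings()) {
  x <- as.matrix(tbl)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (n < 50) stop("need at least 50 rows to fit the mixed graphical model")
  if (is.null(colnames(x))) stop("columns must be named by node")

  if (is.null(nodes)) {
    nd <- default_node_meta()
    if (!setequal(colnames(x), nd$node_id))
      stop("supply `nodes` metadata for non-canonical node sets")
    nodes <- nd[match(colnames(x), nd$node_id), ]
  }
  stopifnot(all(nodes$node_id == colnames(x)))

  sds <- apply(x, 2, sd)
  if (any(sds == 0)) stop("constant column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  cx <- cor(x)
  dup <- which(abs(cx) > 0.999 & upper.tri(cx), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    stop("effectively duplicate columns: ",
         paste(colnames(x)[dup[1, 1]], colnames(x)[dup[1, 2]], sep = " ~ "))
  }

  centers <- colMeans(x)
  xs <- scale(x)

  foldid <- with_seed(settings$cv_seed,
                      sample(rep(seq_len(settings$cv_folds), length.out = n)))

  B <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  intercepts <- numeric(p)
  sigmas <- numeric(p)
  for (j in seq_len(p)) {
    fit <- glmnet::cv.glmnet(xs[, -j, drop = FALSE], xs[, j],
                             foldid = foldid, standardize = FALSE,
                             family = "gaussian")
    cf <- as.numeric(coef(fit, s = if (is.null(settings$cv_rule)) "lambda.min"
                                   else settings$cv_rule))
    intercepts[j] <- cf[1]
    B[j, -j] <- cf[-1]
    resid <- xs[, j] - cf[1] - xs[, -j, drop = FALSE] %*% cf[-1]
    sigmas[j] <- sqrt(mean(resid^2))
  }

  W <- matrix(0, p, p, dimnames = dimnames(B))
  conflicts <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- B[i, j]; b <- B[j, i]
      if (a != 0 && b != 0) {
        if (sign(a) == sign(b)) {
          W[i, j] <- W[j, i] <- mean(c(a, b))
        } else {
          conflicts <- conflicts + 1L
        }
      } else if (settings$edge_rule == "OR" && (a != 0 || b != 0)) {
        nz <- c(a, b)[c(a, b) != 0]
        W[i, j] <- W[j, i] <- mean(nz)
      }
    }
  }
  if (conflicts > 0)
    warning(conflicts, " sign-conflicting coefficient pair(s) set to zero")

  models <- list(B = B, intercept = intercepts, sigma = sigmas,
                 center = centers, scale = sds)
  weighted_network(W, nodes, estimator_tag = "mgm", models = models,
                   sign_conflicts = conflicts, foldid = foldid)
}
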