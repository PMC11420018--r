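#' Correlation-stability coefficient
#'
#' The CS-coefficient summarizes a case-dropping bootstrap: the largest
#' proportion of cases that can be dropped such that at least `prob` of the
#' subsample statistics still correlate at least `threshold` with the
#' full-sample statistic; 0 if no proportion qualifies.
#'
#' @param correlations named list: one numeric vector of replicate
#'   correlations per drop proportion (names are the proportions).
#' @param threshold correlation a replicate must reach (default 0.7).
#' @param prob required fraction of qualifying replicates (default 0.95).
#' @return The CS-coefficient (a drop proportion, or 0).
#' @export
cs_coefficient <- function(correlations, threshold = 0.7, prob = 0.95) {
  if (length(correlations) == 0) stop("no drop proportions evaluated")
  props <- as.numeric(names(correlations))
  stopifnot(!anyNA(props))
  ok <- vapply(correlations, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && mean(v >= threshold) >= prob
  }, logical(1))
  if (!any(ok)) 0 else max(props[ok])
}

#' Case-dropping bootstrap for statistic stability
#'
#' For each drop proportion q, repeatedly retains ceiling((1 - q) n) rows
#' without replacement, re-runs the estimator, and correlates the subsample
#' statistic vector with the full-sample one; the CS-coefficient is derived
#' from those correlations. Several statistics (e.g. node strength and
#' vectorized edge weights) can be tracked from the same refits.
#'
#' @param data matrix or data.frame of cases x variables passed to
#'   `estimator`.
#' @param estimator function `data -> weighted_network` (or, if
#'   `statistics = "custom"`, `data -> numeric vector`), deterministic given
#'   its input.
#' @param statistics character subset of `c("strength", "edge_weights")`,
#'   or `"custom"`.
#' @param drop_proportions grid of dropped-case proportions.
#' @param replicates subsamples per proportion.
#' @param seed integer seed for the subsample draws.
#' @param threshold,prob forwarded to [cs_coefficient()].
#' @return A `bootstrap_result`: per statistic, the list of replicate
#'   correlations by proportion and the CS-coefficient; `skipped` lists
#'   proportions whose subsamples were too small to fit.
#' @export
case_dropping_bootstrap <- function(data, estimator,
                                    statistics = c("strength", "edge_weights"),
                                    drop_proportions = seq(0.1, 0.75, by = 0.05),
                                    replicates = 500, seed = 1,
                                    threshold = 0.7, prob = 0.95) {
  x <- if (is.data.frame(data)) as.matrix(data) else data
  n <- nrow(x)
  custom <- identical(statistics, "custom")

  extract <- function(fit) {
    if (custom) return(list(custom = as.numeric(fit)))
    stopifnot(inherits(fit, "weighted_network"))
    out <- list()
    if ("strength" %in% statistics) out$strength <- unname(node_strength(fit))
    if ("edge_weights" %in% statistics)
      out$edge_weights <- fit$weights[upper.tri(fit$weights)]
    out
  }
  full <- extract(estimator(x))
  stats_names <- names(full)

  min_rows <- ncol(x) + 1
  cors <- setNames(lapply(stats_names, function(s) list()), stats_names)
  skipped <- numeric(0)

  with_seed(seed, {
    for (qi in seq_along(drop_proportions)) {
      q <- drop_proportions[qi]
      m <- ceiling((1 - q) * n)
      if (m < min_rows) {
        skipped <- c(skipped, q)
        next
      }
      reps <- matrix(NA_real_, replicates, length(stats_names),
                     dimnames = list(NULL, stats_names))
      for (r in seq_len(replicates)) {
        rows <- sample.int(n, m)
        sub <- tryCatch(extract(estimator(x[rows, , drop = FALSE])),
                        error = function(e) NULL)
        if (is.null(sub)) next
        for (s in stats_names) {
          a <- full[[s]]; b <- sub[[s]]
          reps[r, s] <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
        }
      }
      for (s in stats_names) cors[[s]][[format(q)]] <- reps[, s]
    }
  })

  cs <- vapply(stats_names, function(s)
    cs_coefficient(cors[[s]], threshold = threshold, prob = prob), numeric(1))

  structure(list(statistics = stats_names, correlations = cors,
                 cs = setNames(cs, stats_names),
                 drop_proportions = setdiff(drop_proportions, skipped),
                 skipped = skipped, replicates = replicates,
                 threshold = threshold, prob = prob, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Case-dropping bootstrap (", x$replicates, " replicates/proportion)\n",
      sep = "")
  for (s in x$statistics)
    cat("  CS-coefficient [", s, "]: ", format(x$cs[[s]]), "\n", sep = "")
  if (length(x$skipped))
    cat("  skipped proportions (subsample too small):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Stability summary for plotting/export
#'
#' @param boot a `bootstrap_result`.
#' @return Tidy data.frame: statistic, drop proportion, mean correlation and
#'   2.5%/97.5% quantiles across replicates.
#' @export
stability_summary <- function(boot) {
  stopifnot(inherits(boot, "bootstrap_result"))
  do.call(rbind, lapply(boot$statistics, function(s) {
    do.call(rbind, lapply(names(boot$correlations[[s]]), function(q) {
      v <- boot$correlations[[s]][[q]]
      data.frame(statistic = s, drop_proportion = as.numeric(q),
                 mean_correlation = mean(v, na.rm = TRUE),
                 q025 = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
                 q975 = unname(stats::quantile(v, 0.975, na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  }))
}
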