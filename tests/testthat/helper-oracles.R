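# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: metrics are brute-force loops over the
# adjacency matrix, and the conditional-simulation oracle enumerates the
# exact stationary distribution of the discretized Gibbs kernel.

# --- brute-force graph metrics on a weight matrix -------------------------

bf_strength <- function(w) unname(rowSums(abs(w)))

bf_bridge <- function(w, groups) {
  sapply(seq_len(nrow(w)), function(i)
    sum(abs(w[i, groups != groups[i]])))
}

bf_density <- function(w) {
  p <- nrow(w)
  sum(w[upper.tri(w)] != 0) / (p * (p - 1) / 2)
}

# Floyd-Warshall over the binarized graph; mean over connected unordered pairs
bf_avg_path_length <- function(w) {
  p <- nrow(w)
  d <- ifelse(w != 0, 1, Inf)
  diag(d) <- 0
  for (k in 1:p) for (i in 1:p) for (j in 1:p)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

# global transitivity: 3 * triangles / connected triples
bf_transitivity <- function(w) {
  a <- (w != 0) * 1
  diag(a) <- 0
  tri <- sum(diag(a %*% a %*% a)) / 6
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) NaN else 3 * tri / triples
}

# mean local clustering over nodes of degree >= 2
bf_clustering <- function(w) {
  a <- (w != 0) * 1
  diag(a) <- 0
  loc <- sapply(seq_len(nrow(a)), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    sum(a[nb, nb]) / (k * (k - 1))
  })
  if (all(is.na(loc))) NA_real_ else mean(loc, na.rm = TRUE)
}

# --- exact ESA oracle for small discrete networks -------------------------

# Exact stationary distribution of the systematic-scan Gibbs kernel over the
# product space of the free (ordinal) nodes' codes, with clamped nodes held
# fixed; returns the exact expected sum of the free nodes' codes.
enumerate_esa <- function(net, clamp = numeric(0)) {
  nodes <- net$nodes
  m <- net$models
  ids <- nodes$node_id
  free <- setdiff(ids, names(clamp))
  stopifnot(all(nodes$kind[match(free, ids)] == "ordinal_symptom"))
  levs <- lapply(free, function(id) {
    i <- match(id, ids)
    seq(nodes$range_min[i], nodes$range_max[i])
  })
  states <- as.matrix(expand.grid(levs))
  colnames(states) <- free
  ns <- nrow(states)
  state_key <- apply(states, 1, paste, collapse = ",")

  zclamp <- vapply(names(clamp), function(id)
    (clamp[[id]] - m$center[[id]]) / m$scale[[id]], numeric(1))

  site_probs <- function(id, x_std) {
    i <- match(id, ids)
    mu <- m$intercept[i] + sum(m$B[i, ] * x_std)
    mu_raw <- m$center[[id]] + m$scale[[id]] * mu
    s_raw <- m$scale[[id]] * m$sigma[i]
    lev <- seq(nodes$range_min[i], nodes$range_max[i])
    up <- c(lev[-length(lev)] + 0.5, Inf)
    lo <- c(-Inf, up[-length(up)])
    p <- pnorm(up, mu_raw, s_raw) - pnorm(lo, mu_raw, s_raw)
    p / sum(p)
  }
  std_state <- function(row) {
    x <- setNames(numeric(length(ids)), ids)
    if (length(zclamp)) x[names(zclamp)] <- zclamp
    x[free] <- (row - m$center[free]) / m$scale[free]
    x
  }

  P <- diag(ns)
  for (f in seq_along(free)) {
    Pf <- matrix(0, ns, ns)
    lev <- levs[[f]]
    for (s in seq_len(ns)) {
      pr <- site_probs(free[f], std_state(states[s, ]))
      for (li in seq_along(lev)) {
        new <- states[s, ]
        new[f] <- lev[li]
        Pf[s, match(paste(new, collapse = ","), state_key)] <- pr[li]
      }
    }
    P <- P %*% Pf
  }
  ev <- eigen(t(P))
  pi_ <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_ <- pi_ / sum(pi_)
  sum(pi_ * rowSums(states))
}

# --- small fixture builders ----------------------------------------------

# node metadata for toy networks: first `n_strat` continuous strategies,
# the rest ordinal 0-3 symptoms
toy_nodes <- function(n_strat, n_sym,
                      strat_min = 4, strat_max = 20) {
  data.frame(
    node_id = c(if (n_strat > 0) paste0("S", seq_len(n_strat)),
                if (n_sym > 0) paste0("y", seq_len(n_sym))),
    kind = c(rep("continuous_strategy", n_strat),
             rep("ordinal_symptom", n_sym)),
    group = c(rep("ER", n_strat), rep("depression", n_sym)),
    range_min = c(rep(strat_min, n_strat), rep(0, n_sym)),
    range_max = c(rep(strat_max, n_strat), rep(3, n_sym)),
    stringsAsFactors = FALSE)
}

# random sparse symmetric weight matrix for metric oracle checks
random_network <- function(p, prob = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, p, p)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < prob, round(runif(sum(ut), -1, 1), 2), 0)
  w[ut] <- vals
  w <- w + t(w)
  nodes <- data.frame(node_id = paste0("n", 1:p), kind = "generic",
                      group = rep(c("A", "B", "C"), length.out = p),
                      range_min = NA, range_max = NA,
                      stringsAsFactors = FALSE)
  weighted_network(w, nodes)
}
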