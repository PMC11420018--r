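test_that("correlation matrix behaves on worked cases and rejects constants", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  co <- correlation_matrix(x)
  expect_equal(co["a", "b"], 1.0)

  y <- cbind(u = rnorm(50), v = 0)
  y[, "v"] <- y[, "u"]
  expect_equal(correlation_matrix(y)["u", "v"], 1.0)

  z <- cbind(u = rnorm(50), flat = rep(2, 50))
  expect_error(correlation_matrix(z), "flat")

  set.seed(1)
  big <- matrix(rnorm(10000 * 4), ncol = 4,
                dimnames = list(NULL, paste0("x", 1:4)))
  cb <- correlation_matrix(big)
  expect_true(all(abs(cb[upper.tri(cb)]) < 0.05))
})

test_that("ebic_glasso recovers block structure and prunes independence", {
  # identity: nothing to shrink
  co <- diag(5)
  colnames(co) <- rownames(co) <- paste0("v", 1:5)
  net <- ebic_glasso(co, n = 300)
  expect_true(all(net$weights == 0))

  # 2-block: r12 = 0.8, node 3 independent; partial corr 1-2 equals the
  # marginal (analytic inverse of the 2x2 block)
  co3 <- diag(3)
  co3[1, 2] <- co3[2, 1] <- 0.8
  colnames(co3) <- rownames(co3) <- c("a", "b", "c")
  net3 <- ebic_glasso(co3, n = 500)
  expect_gt(net3$weights["a", "b"], 0.6)
  expect_equal(net3$weights["a", "c"], 0)
  expect_equal(net3$weights["b", "c"], 0)

  # weights are partial correlations: bounded, symmetric, zero diagonal
  expect_true(all(abs(net3$weights) <= 1))
  expect_equal(net3$weights, t(net3$weights))
  expect_true(all(diag(net3$weights) == 0))
})

test_that("ebic penalty trades likelihood against edges as designed", {
  # at fixed loglik the fit with fewer edges always wins, for any gamma
  ebic <- function(loglik, E, n, p, gamma)
    -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
  for (g in c(0, 0.25, 0.5, 1)) {
    expect_lt(ebic(-100, 5, 376, 22, g), ebic(-100, 7, 376, 22, g))
  }

  # on data, the selected edge set shrinks (never grows) as gamma increases
  d <- generate_dataset(generator_config(n = 150, seed = 5))
  co <- correlation_matrix(d$values[, 1:12])
  edge_set <- function(gamma) {
    w <- ebic_glasso(co, n = 150,
                     estimation_settings(ebic_gamma = gamma))$weights
    which(w[upper.tri(w)] != 0)
  }
  e0 <- edge_set(0); e05 <- edge_set(0.5); e1 <- edge_set(1)
  expect_true(all(e05 %in% e0))
  expect_true(all(e1 %in% e05))
})

test_that("walktrap finds blocks, isolates, and the generating subscales", {
  # two disconnected 4-cliques
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.5
  w[5:8, 5:8] <- 0.5
  diag(w) <- 0
  nodes <- data.frame(node_id = paste0("n", 1:8), kind = "generic",
                      group = "all", range_min = NA, range_max = NA)
  part <- walktrap_communities(weighted_network(w, nodes))
  expect_equal(part$n_communities, 2)
  expect_equal(length(unique(part$assignment[1:4])), 1)
  expect_equal(length(unique(part$assignment[5:8])), 1)

  # appended isolated node forms its own community
  w9 <- rbind(cbind(w, 0), 0)
  nodes9 <- rbind(nodes, data.frame(node_id = "iso", kind = "generic",
                                    group = "all", range_min = NA,
                                    range_max = NA))
  part9 <- walktrap_communities(weighted_network(w9, nodes9))
  expect_equal(part9$n_communities, 3)
  expect_false(part9$assignment["iso"] %in% part9$assignment[1:8])

  # full EGA chain on default synthetic data recovers the six subscales
  d <- generate_dataset(generator_config(seed = 1))
  e <- ega(d)
  expect_equal(e$partition$n_communities, 6)
  expect_equal(adjusted_rand_index(e$partition$assignment,
                                   e$items$subscale), 1)
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:4, c(2, 3, 4, 5)), 1)
})

test_that("mgm recovers a Gaussian chain and rejects degenerate input", {
  # A - B - C chain, partial correlation 0.5 on each edge: precision matrix
  # is the conditional-independence oracle
  K <- diag(3)
  K[1, 2] <- K[2, 1] <- -0.5
  K[2, 3] <- K[3, 2] <- -0.5
  Sigma <- solve(K)
  set.seed(7)
  x <- MASS::mvrnorm(2000, rep(0, 3), Sigma)
  colnames(x) <- c("A", "B", "C")
  nodes <- data.frame(node_id = c("A", "B", "C"), kind = "continuous_strategy",
                      group = "ER", range_min = NA, range_max = NA)
  net <- estimate_mgm(x, nodes = nodes)
  expect_true(net$weights["A", "B"] > 0.2)
  expect_true(net$weights["B", "C"] > 0.2)
  expect_lt(abs(net$weights["A", "C"]), 0.05)
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))

  # duplicated column is rejected up front
  xd <- cbind(x, D = x[, "C"])
  nodes4 <- rbind(nodes, data.frame(node_id = "D", kind = "continuous_strategy",
                                    group = "ER", range_min = NA, range_max = NA))
  expect_error(estimate_mgm(xd, nodes = nodes4), "duplicate")

  expect_error(estimate_mgm(x[1:20, ], nodes = nodes), "50")
})

test_that("mgm on independent columns is empty under the conservative CV rule", {
  nodes <- data.frame(node_id = c("A", "B", "C"),
                      kind = "continuous_strategy", group = "ER",
                      range_min = NA, range_max = NA)
  empty <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(2000 * 3), ncol = 3,
                dimnames = list(NULL, c("A", "B", "C")))
    net <- estimate_mgm(x, nodes = nodes,
                        settings = estimation_settings(cv_seed = s,
                                                       cv_rule = "lambda.1se"))
    all(net$weights == 0)
  }, logical(1))
  expect_gte(mean(empty), 0.95)

  # the default (minimum-CV-error) rule admits occasional tiny spurious
  # edges on null data; networks must still be empty in a clear majority
  empty_min <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(2000 * 3), ncol = 3,
                dimnames = list(NULL, c("A", "B", "C")))
    net <- estimate_mgm(x, nodes = nodes,
                        settings = estimation_settings(cv_seed = s))
    all(net$weights == 0)
  }, logical(1))
  expect_gte(mean(empty_min), 0.5)
})
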