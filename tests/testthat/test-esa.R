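# toy networks: strategies are continuous nodes (range 4-20, centered at 12,
# sd 4), symptoms ordinal 0-3 (centered near 1)

test_that("clamping an unconnected strategy leaves symptom activity unchanged", {
  nodes <- toy_nodes(1, 1)
  w <- matrix(0, 2, 2)
  net <- toy_mgm_network(w, nodes, center = c(12, 1), scale = c(4, 0.9),
                        sigma = c(1, 0.8))
  set <- esa_settings(n_samples = 30000, burn_in = 1000, seed = 3)
  e_lo <- expected_symptom_activity(net, c(S1 = 4), set)
  e_hi <- expected_symptom_activity(net, c(S1 = 20), set)
  exact <- enumerate_esa(net, c(S1 = 12))
  expect_lt(abs(e_lo - exact), 0.02)
  expect_lt(abs(e_hi - exact), 0.02)
})

test_that("a continuous conditional mean is reproduced by the sampler", {
  # 2-node all-continuous toy: mu_y = 0.4 x, clamp x (std scale) at 2
  nodes <- data.frame(node_id = c("x", "y"),
                      kind = "continuous_strategy", group = "ER",
                      range_min = c(-10, -10), range_max = c(10, 10))
  w <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  net <- toy_mgm_network(w, nodes)
  s <- gibbs_sample_conditional(net, c(x = 2),
                                esa_settings(n_samples = 40000, seed = 5))
  expect_lt(abs(mean(s[, "y"]) - 0.8), 0.02)
  expect_true(all(s[, "x"] == 2))
})

test_that("clamp effects travel only through connecting edges", {
  # chain S - yA - yB: the strategy reaches yB only via yA
  nodes <- toy_nodes(1, 2)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.35
  w[2, 3] <- w[3, 2] <- 0.3
  net <- toy_mgm_network(w, nodes, center = c(12, 1, 1),
                        scale = c(4, 0.9, 0.9), sigma = c(1, 0.8, 0.8))
  ex_lo <- enumerate_esa(net, c(S1 = 4))
  ex_hi <- enumerate_esa(net, c(S1 = 20))
  expect_gt(ex_hi, ex_lo)  # positive path: clamping high raises activity

  # zeroing the yA-yB edge removes the indirect effect on yB
  w0 <- w
  w0[2, 3] <- w0[3, 2] <- 0
  net0 <- toy_mgm_network(w0, nodes, center = c(12, 1, 1),
                         scale = c(4, 0.9, 0.9), sigma = c(1, 0.8, 0.8))
  yB_mean <- function(net, v) {
    s <- gibbs_sample_conditional(net, c(S1 = v),
                                  esa_settings(n_samples = 30000,
                                               burn_in = 1000, seed = 9))
    mean(s[, "y2"])
  }
  expect_lt(abs(yB_mean(net0, 4) - yB_mean(net0, 20)), 0.02)
  # and the sampler agrees with enumeration on the modified net
  expect_lt(abs(yB_mean(net0, 20) +
                  mean(gibbs_sample_conditional(net0, c(S1 = 20),
                    esa_settings(30000, 1000, seed = 9))[, "y1"]) -
                  enumerate_esa(net0, c(S1 = 20))), 0.03)
})

test_that("esa sums symptom means and respects its bounds", {
  # zero-noise, zero-coupling network pinned at code 1: ESA is exactly 16
  nodes <- toy_nodes(6, 16, strat_min = 4, strat_max = 40)
  w <- matrix(0, 22, 22)
  net <- toy_mgm_network(w, nodes, center = c(rep(12, 6), rep(1, 16)),
                        scale = rep(1, 22), sigma = rep(0, 22))
  esa <- expected_symptom_activity(net, c(S1 = 12),
                                   esa_settings(n_samples = 200, seed = 1))
  expect_equal(esa, 16)

  # ESA can never leave [0, 48] whatever the clamped configuration
  set.seed(4)
  wr <- matrix(0, 22, 22)
  wr[upper.tri(wr)] <- runif(231, -0.2, 0.3)
  wr <- wr + t(wr)
  netr <- toy_mgm_network(wr, nodes, center = c(rep(12, 6), rep(1, 16)),
                         scale = c(rep(4, 6), rep(0.9, 16)),
                         sigma = rep(0.8, 22))
  for (v in c(4, 40)) {
    e <- expected_symptom_activity(netr, c(S1 = v),
                                   esa_settings(n_samples = 2000,
                                                burn_in = 200, seed = 2))
    expect_gte(e, 0)
    expect_lte(e, 48)
  }
})

test_that("baseline esa reads the data and reports the model diagnostic", {
  items <- default_item_meta()
  v <- matrix(rep(items$min_code, each = 4), nrow = 4,
              dimnames = list(NULL, items$item_id))
  v[, items$item_id[items$instrument != "RESS"]] <- 1L
  d <- esanet:::new_item_response_matrix(v, items)
  b <- baseline_esa(d)
  expect_equal(b$value, 16)
  expect_true(is.na(b$model_implied))
})

test_that("scenario sweeps have the documented grids and flat-profile limit", {
  d <- generate_dataset(generator_config(n = 120, seed = 8))
  sc <- score_subscales(d)
  tbl <- cbind(sc, as.data.frame(symptom_matrix(d)))
  m <- estimate_mgm(tbl)
  set <- esa_settings(n_samples = 300, burn_in = 50, seed = 1)
  expect_equal(length(esa_scenario_sweep(m, "suppression", "minimum", set)$grid), 33)
  expect_equal(length(esa_scenario_sweep(m, "rumination", "minimum", set)$grid), 25)
  expect_equal(length(esa_scenario_sweep(m, "distraction", "minimum", set)$grid), 17)
  expect_error(esa_scenario_sweep(m, "phq1", "minimum", set), "strategy")

  # with no strategy-symptom edges the profile is flat at the
  # background-conditioned value
  nodes <- toy_nodes(6, 3, strat_min = 4, strat_max = 20)
  nodes$node_id[1:6] <- esanet:::strategy_names()
  w <- matrix(0, 9, 9)
  w[7, 8] <- w[8, 7] <- 0.2
  net <- toy_mgm_network(w, nodes, center = c(rep(12, 6), rep(1, 3)),
                        scale = c(rep(4, 6), rep(0.9, 3)),
                        sigma = c(rep(1, 6), rep(0.8, 3)))
  net$nodes$range_min[1:6] <- 4; net$nodes$range_max[1:6] <- 20
  prof <- esa_scenario_sweep(net, "distraction", "minimum",
                             esa_settings(n_samples = 5000, burn_in = 500,
                                          seed = 2))
  expect_lt(diff(range(prof$esa_values)), 0.05)
})

test_that("crossing point uses strict exceedance of the baseline", {
  mk <- function(esa, base) {
    structure(list(strategy = "rumination", scenario = "minimum",
                   grid = c(6, 7, 8), esa_values = esa,
                   baseline_esa = base, crossing_point = NA,
                   background = NULL), class = "esa_profile")
  }
  expect_equal(crossing_point(mk(c(14.0, 14.5, 15.0), 14.6)), 8)
  expect_true(is.na(crossing_point(mk(c(14.0, 14.1, 14.2), 14.6))))
  expect_equal(crossing_point(mk(c(15.0, 15.1, 15.2), 14.6)), 6)
  # equality does not cross
  expect_true(is.na(crossing_point(mk(c(14.6, 14.6, 14.6), 14.6))))
})

test_that("clamp validation enforces ranges and node kinds", {
  nodes <- toy_nodes(1, 1)
  net <- toy_mgm_network(matrix(0, 2, 2), nodes)
  expect_error(gibbs_sample_conditional(net, c(S1 = 99)), "range")
  expect_error(gibbs_sample_conditional(net, c(y1 = 1)), "never clamped")
  expect_error(gibbs_sample_conditional(net, c(zz = 1)), "unknown")
  expect_error(esa_settings(n_samples = 0), "n_samples")
})
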