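test_that("generators are pure functions of configuration and seed", {
  cfg <- simulation_config(seed = 104, n_compounds = 22)
  expect_identical(gen_compound_table(cfg), gen_compound_table(cfg))
  d <- taguchi_l27(7)
  cfg2 <- simulation_config(seed = 104,
                            planted_effects = list(A = c(-3, 0, 3)))
  expect_identical(gen_doe_response(d, cfg2), gen_doe_response(d, cfg2))
  expect_identical(gen_pathway_pair(cfg), gen_pathway_pair(cfg))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- stats::rnorm(1)
  set.seed(1); invisible(gen_compound_table(cfg)); after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate spreads collapse to the target and all-ones scores", {
  cfg <- simulation_config(seed = 2, n_compounds = 10,
                           binding_spread = 0, energy_spread = 0)
  tab <- gen_compound_table(cfg)
  expect_equal(tab$binding_free_energy, rep(-100, 10))
  expect_equal(tab$transition_energy, rep(6.5, 10))
  scores <- score_table(tab, policies = target_policy("order_statistic",
                                                      order_index = 5))
  expect_true(all(scores$score == 1))
})

test_that("synthetic compound tables score end-to-end over many seeds", {
  for (seed in 1:50) {
    tab <- gen_compound_table(simulation_config(seed = seed, n_compounds = 22))
    expect_true(all(tab$binding_free_energy < 0))
    expect_true(all(tab$transition_energy > 0))
    scores <- score_table(tab, policies = target_policy("order_statistic",
                                                        order_index = 11))
    expect_true(all(is.finite(scores$score) & scores$score > 0))
  }
})

test_that("noiseless responses recover the planted offsets exactly", {
  d <- taguchi_l27(7)
  planted <- list(A = c(-5, 1, 4), E = c(-10, 4, 6))
  cfg <- simulation_config(seed = 8, planted_effects = planted, noise_sd = 0)
  y <- gen_doe_response(d, cfg)
  eff <- level_means(d, y)
  expect_equal(eff$level_means["A", ] - eff$grand_mean, planted$A,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(eff$level_means["E", ] - eff$grand_mean, planted$E,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(eff$level_means["B", ] - eff$grand_mean, c(0, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(gen_doe_response(d, simulation_config(
    seed = 1, planted_effects = list(Z = c(-1, 0, 1)))), "unknown factor")
  expect_error(simulation_config(planted_effects = list(A = c(1, 2, 3))),
               "summing to 0")
})

test_that("a dominant planted effect is ranked first in >= 95% of seeds", {
  d <- taguchi_l27(7)
  hits <- 0L
  for (seed in 1:200) {
    cfg <- simulation_config(seed = seed, noise_sd = 1,
                             planted_effects = list(C = c(-5, 0, 5)))
    rk <- rank_factors(level_means(d, gen_doe_response(d, cfg)))
    hits <- hits + (rk$rank[rk$factor == "C"] == 1L)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("with no planted signal every factor wins rank one equally often", {
  d <- taguchi_l27(7)
  wins <- integer(7)
  for (seed in 1:2000) {
    cfg <- simulation_config(seed = seed, noise_sd = 1)
    rk <- rank_factors(level_means(d, gen_doe_response(d, cfg)))
    wins[rk$rank == 1L] <- wins[rk$rank == 1L] + 1L
  }
  expect_true(all(abs(wins / 2000 - 1 / 7) <= 0.05))
})

test_that("level-mean noise shrinks like sigma over three", {
  d <- taguchi_l27(7)
  dev <- vapply(1:300, function(seed) {
    cfg <- simulation_config(seed = seed, noise_sd = 1)
    level_means(d, gen_doe_response(d, cfg))$level_means["A", 1] -
      cfg$doe_grand_mean
  }, numeric(1))
  # 9 runs per level: SD of a level mean should be ~ 1/3
  expect_gt(stats::sd(dev), 1 / 3 - 0.08)
  expect_lt(stats::sd(dev), 1 / 3 + 0.08)
})

test_that("pathway pairs round-trip their planted reduction", {
  for (seed in c(1, 9, 27)) {
    pair <- gen_pathway_pair(simulation_config(seed = seed,
                                               pathway_steps = 4),
                             reduction_pct = 15.73)
    cmp <- pathway_compare(pair$reference, pair$modified)
    expect_equal(cmp$percent_reduction, pair$true_reduction_pct,
                 tolerance = 1e-9)
  }
  pair0 <- gen_pathway_pair(simulation_config(seed = 4), reduction_pct = 0)
  expect_equal(pathway_compare(pair0$reference,
                               pair0$modified)$percent_reduction, 0)
})
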