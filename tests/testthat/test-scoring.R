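test_that("target selection supports reference-compound and order-statistic modes", {
  tab <- opfr_compounds()
  mags <- abs(tab$binding_free_energy)

  by_ref <- select_target(tab$binding_free_energy,
                          target_policy("reference_compound",
                                        reference_id = "TCIPP"),
                          ids = tab$compound_id, use_magnitude = TRUE)
  expect_equal(by_ref, 144.537)

  # oracle: exhaustive ascending sort of the 22 magnitudes, take the 11th
  oracle <- sort(mags)[11]
  by_rank <- select_target(tab$binding_free_energy,
                           target_policy("order_statistic", order_index = 11),
                           use_magnitude = TRUE)
  expect_equal(by_rank, oracle)
  expect_equal(by_rank, 144.537) # TCIPP is the lower median of the 22

  # same dual rule on the photodegradation channel: TCIPP is the 12th of 22
  expect_equal(select_target(tab$transition_energy,
                             target_policy("order_statistic", order_index = 12)),
               7.2211)

  expect_equal(select_target(5, target_policy("order_statistic",
                                              order_index = 1)), 5)
  expect_error(select_target(numeric(0),
                             target_policy("order_statistic", order_index = 1)),
               "empty")
  expect_error(select_target(c(1, 2), target_policy("reference_compound",
                                                    reference_id = "X"),
                             ids = c("A", "B")),
               "unknown reference_id")
})

test_that("efficacy coefficients reproduce printed reference values", {
  expect_equal(round(efficacy_coefficient(123.731, 144.537, "ratio_ge1"), 3),
               1.168)
  expect_equal(round(efficacy_coefficient(41.842, 144.537, "ratio_ge1"), 3),
               3.454)
  expect_equal(round(efficacy_coefficient(4.3292, 7.2211, "ratio_le1"), 3),
               0.600)
  expect_equal(efficacy_coefficient(7.2211, 7.2211, "ratio_le1"), 1)
  expect_equal(efficacy_coefficient(7.2211, 7.2211, "ratio_ge1"), 1)
  expect_error(efficacy_coefficient(-1, 2, "ratio_le1"), "positive")
  expect_error(efficacy_coefficient(1, 0, "ratio_le1"), "positive")
})

test_that("coefficient orientations are reciprocal and scale invariant", {
  set.seed(42)
  for (i in 1:200) {
    x <- stats::runif(1, 1e-3, 1e3)
    target <- stats::runif(1, 1e-3, 1e3)
    le <- efficacy_coefficient(x, target, "ratio_le1")
    ge <- efficacy_coefficient(x, target, "ratio_ge1")
    expect_equal(le * ge, 1, tolerance = 1e-12)
    expect_lte(le, 1)
    expect_gte(ge, 1)
    k <- stats::runif(1, 1e-3, 1e3)
    expect_equal(efficacy_coefficient(k * x, k * target, "ratio_le1"), le,
                 tolerance = 1e-12)
  }
})

test_that("comprehensive score is the validated weighted sum", {
  expect_equal(comprehensive_score(c(1, 1), c(0.3, 0.7)), 1)
  r1 <- efficacy_coefficient(41.842, 144.537, "ratio_ge1")
  r2 <- efficacy_coefficient(7.2874, 7.2211, "ratio_le1")
  expect_equal(round(comprehensive_score(c(r1, r2), c(0.5, 0.5)), 2), 2.22)
  r1 <- efficacy_coefficient(9.191, 144.537, "ratio_ge1")
  r2 <- efficacy_coefficient(8.1795, 7.2211, "ratio_le1")
  expect_equal(round(comprehensive_score(c(r1, r2), c(0.5, 0.5)), 2), 8.30)
  expect_error(comprehensive_score(c(1, 2), c(0.5, 0.25, 0.25)), "weights")
  expect_error(comprehensive_score(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(comprehensive_score(c(1, 2), c(-0.2, 1.2)), "\\[0, 1\\]")
})

test_that("score is monotone non-decreasing in each coefficient", {
  set.seed(7)
  w <- c(0.5, 0.5)
  for (i in 1:100) {
    co <- stats::runif(2, 0.1, 10)
    bump <- co + c(stats::runif(1, 0, 5), 0)
    expect_gte(comprehensive_score(bump, w), comprehensive_score(co, w))
  }
})

test_that("score_table reproduces printed spot values under defaults", {
  scores <- score_table(opfr_compounds())
  expect_equal(attr(scores, "targets"),
               c(biodegradation = 144.537, photodegradation = 7.2211))
  row <- function(id) scores[scores$compound_id == id, ]
  expect_equal(round(row("TMP")$r_biodegradation, 3), 7.292)
  expect_equal(round(row("TEHP")$r_biodegradation, 3), 1.859)
  expect_equal(round(row("TEHP")$r_photodegradation, 3), 0.880)
})

test_that("a constant table scores all-ones", {
  tab <- data.frame(compound_id = c("A", "B", "C"),
                    binding_free_energy = -50,
                    transition_energy = 6)
  scores <- score_table(tab, policies = target_policy("order_statistic",
                                                      order_index = 1))
  expect_true(all(scores$r_biodegradation == 1))
  expect_true(all(scores$r_photodegradation == 1))
  expect_true(all(scores$score == 1))
})
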