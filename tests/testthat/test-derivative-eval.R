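test_that("intensity operations follow their sign conventions", {
  expect_equal(round(reduction_intensity(225.72, 209.57), 2), 7.15)
  expect_equal(reduction_intensity(3, 3), 0)
  expect_equal(round(change_rate(5.38, 5.15), 2), -4.28)
  # change rates of negative totals keep the sign of the raw change
  expect_equal(round(change_rate(-1023.57, -1536.08), 2), -50.07)
  expect_equal(increase_intensity(1, 2), 100)
  expect_equal(increase_intensity(2, 2), 0)
  # recomputation from 2 d.p. inputs lands near, not on, the printed 48.68
  expect_equal(round(increase_intensity(2.09, 3.11), 2), 48.80)
  expect_lt(abs(increase_intensity(2.09, 3.11) - 48.68), 0.2)
  expect_error(reduction_intensity(0, 1), "nonzero")
  expect_error(increase_intensity(0, 1), "nonzero")
  expect_error(change_rate(0, 1), "nonzero")
})

test_that("reduction and increase intensities are complementary", {
  set.seed(31)
  for (i in 1:100) {
    old <- stats::runif(1, 0.1, 100); new <- stats::runif(1, 0.1, 100)
    expect_equal(reduction_intensity(old, new) + new / old * 100, 100)
    expect_equal(reduction_intensity(old, new), -increase_intensity(old, new))
  }
})

test_that("effect ratio divides the two improvement percentages", {
  expect_equal(round(effect_ratio(55.48, 46.37), 2), 1.20)
  expect_equal(round(effect_ratio(42.43, 52.98), 2), 0.80)
  expect_equal(effect_ratio(37, 37), 1)
  expect_error(effect_ratio(10, 0), "nonzero")
})

tcpp_oh_row <- data.frame(
  derivative_id = "TCPP-OH",
  c_parent = 2.22, c_derivative = 1.40,
  b_parent = 1.62, b_derivative = 2.52,
  p_parent = 7.29, p_derivative = 3.91,
  flame_parent = 225.72, flame_derivative = 209.57,
  gap_parent = 5.38, gap_derivative = 5.15,
  min_frequency = 2.34)

test_that("the environment-friendly screen applies all six criteria", {
  v <- screen_environment_friendly(tcpp_oh_row)
  expect_true(v$pass)
  expect_true(all(unlist(v[c("score_reduced", "biodegradation_increased",
                             "photodegradation_reduced",
                             "flame_retardancy_enhanced", "structure_stable",
                             "insulation_maintained")])))

  # flame-retardancy loss alone sinks a derivative
  ch2oh <- tcpp_oh_row
  ch2oh$flame_derivative <- 256.70 # enhanced rate -13.73%
  v2 <- screen_environment_friendly(ch2oh)
  expect_false(v2$pass)
  expect_false(v2$flame_retardancy_enhanced)

  # identical parent and derivative: no score reduction
  same <- tcpp_oh_row
  same[c("c_derivative", "b_derivative", "p_derivative",
         "flame_derivative", "gap_derivative")] <-
    same[c("c_parent", "b_parent", "p_parent", "flame_parent", "gap_parent")]
  expect_false(screen_environment_friendly(same)$pass)

  expect_error(screen_environment_friendly(tcpp_oh_row[-which(
    names(tcpp_oh_row) == "min_frequency")]), "structure_stable")
})

test_that("worsening any single input never flips fail into pass", {
  worsen <- list(
    c_derivative = function(r) { r$c_derivative <- r$c_derivative + 1; r },
    b_derivative = function(r) { r$b_derivative <- r$b_derivative - 1; r },
    p_derivative = function(r) { r$p_derivative <- r$p_derivative + 1; r },
    flame_derivative = function(r) { r$flame_derivative <- r$flame_derivative + 50; r },
    gap_derivative = function(r) { r$gap_derivative <- r$gap_derivative - 1; r },
    min_frequency = function(r) { r$min_frequency <- -r$min_frequency; r })
  # from a passing row, each single worsening can only keep or lose the pass
  for (w in worsen) {
    expect_false(isFALSE(screen_environment_friendly(tcpp_oh_row)$pass) &&
                   isTRUE(screen_environment_friendly(w(tcpp_oh_row))$pass))
  }
  # from a failing row, further worsening never produces a pass
  failing <- tcpp_oh_row
  failing$flame_derivative <- 300
  for (w in worsen) {
    expect_false(screen_environment_friendly(w(failing))$pass)
  }
})

test_that("derivative evaluation splits the roster seven/seven", {
  report <- evaluate_derivatives(derivative_predictions(),
                                 derivative_properties())
  expect_equal(nrow(report), 14L)
  passers <- sort(report$derivative_id[report$pass])
  expect_equal(passers, sort(c("TCPP-OH", "TCPP-CONH2", "TCPP-CHO",
                               "TCPP-PO3H2", "TCEP-PO3H2", "TCEP-COOCH3",
                               "TCEP-SO3H")))
  failed <- report[!report$pass, ]
  expect_equal(nrow(failed), 7L)
  # every failure is a flame-retardancy failure, the other criteria hold
  expect_true(all(!failed$flame_retardancy_enhanced))
  expect_true(all(failed$score_reduced & failed$biodegradation_increased &
                    failed$photodegradation_reduced & failed$structure_stable &
                    failed$insulation_maintained))
})
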