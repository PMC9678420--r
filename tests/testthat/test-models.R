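test_that("two-component curve evaluates to its defining identities", {
  # each component is at half its own maximum at its half-frequency
  p <- two_component_params(1, 0.7, 0, 10, 1)
  expect_equal(eval_two_component(p, 0.7), 0.5)
  # hand arithmetic: 4/6 + 4/12 = 1
  p2 <- two_component_params(1, 2, 1, 8, 1)
  expect_equal(eval_two_component(p2, 4), 1.0)
  # zero at zero frequency for any parameters
  set.seed(1)
  for (i in 1:20) expect_identical(eval_two_component(random_two_component_truth(), 0), 0)
  expect_error(eval_two_component(p, -1), "frequencies")
})

test_that("two-component curve is nondecreasing and bounded by its asymptote", {
  set.seed(2)
  for (i in 1:50) {
    p <- random_two_component_truth()
    f <- sort(runif(2, 0, 60))
    y <- eval_two_component(p, f)
    expect_true(y[2] >= y[1])
    expect_true(all(y >= 0 & y <= derive_t_max(p)))
  }
})

test_that("two-component curve with zero Hf amplitude equals the one-component curve", {
  set.seed(3)
  for (i in 1:20) {
    one <- random_one_component_truth()
    two <- two_component_params(one[["y_max"]], one[["f_half"]], 0,
                                runif(1, 20, 100), one[["m"]])
    f <- runif(6, 0, 50)
    expect_equal(eval_two_component(two, f), eval_one_component(one, f))
  }
})

test_that("one-component curve hits half-maximum at f_half and saturates", {
  p <- one_component_params(140, 8, 2)
  expect_equal(eval_one_component(p, 8), 70)
  expect_identical(eval_one_component(p, 0), 0)
  expect_equal(eval_one_component(one_component_params(1, 4, 1), 12), 0.75)
  expect_error(eval_one_component(p, -0.1), "frequencies")
})

test_that("reduction curve interpolates between its plateaus with an exact midpoint", {
  p <- reduction_params(31.8, 0, 6.7, 2)
  expect_equal(eval_reduction_curve(p, 0), 31.8)
  expect_equal(eval_reduction_curve(p, 6.7), 15.9)
  # flat degenerate curve
  flat <- reduction_params(12.5, 12.5, 3, 1.7)
  expect_equal(eval_reduction_curve(flat, c(0, 1, 5, 100)), rep(12.5, 4))
  # midpoint identity holds for any exponent
  set.seed(4)
  for (i in 1:50) {
    pr <- random_reduction_truth()
    expect_equal(eval_reduction_curve(pr, pr[["k"]]),
                 (pr[["t_lf"]] + pr[["t_hf"]]) / 2)
  }
})

test_that("derived maximal response is the sum of component maxima and the curve limit", {
  expect_equal(derive_t_max(two_component_params(1.5, 2, 0.7, 15, 2)), 2.2)
  expect_equal(derive_t_max(two_component_params(0, 3, 0, 3, 1)), 0)
  set.seed(5)
  for (i in 1:30) {
    p <- random_two_component_truth()
    t_max <- derive_t_max(p)
    f_far <- 1e6 * max(p[["f_star_lf"]], p[["f_star_hf"]])
    expect_equal(eval_two_component(p, f_far), t_max, tolerance = 1e-3)
    expect_equal(t_max, p[["y_lf_max"]] + p[["y_hf_max"]])
  }
})

test_that("half-maximal frequency solver matches closed forms and the grid oracle", {
  # equal half-frequencies collapse to one component
  for (m in c(0.5, 1, 2)) {
    expect_equal(solve_f_half(two_component_params(1, 3, 1, 3, m)), 3,
                 tolerance = 1e-5)
  }
  # equal maxima, m = 1: closed form f^2 = f*_Lf * f*_Hf
  expect_equal(solve_f_half(two_component_params(1, 2, 1, 8, 1)), 4,
               tolerance = 1e-5)
  # single-component curve
  expect_equal(solve_f_half(two_component_params(1, 0.7, 0, 10, 1)), 0.7,
               tolerance = 1e-5)
  expect_error(solve_f_half(two_component_params(0, 1, 0, 5, 1)),
               "zero total amplitude")
  set.seed(6)
  for (i in 1:30) {
    p <- random_two_component_truth()
    expect_equal(solve_f_half(p), grid_f_half_oracle(p), tolerance = 1e-4)
  }
  # the solved frequency really is the half-maximum point
  set.seed(7)
  for (i in 1:10) {
    p <- random_two_component_truth()
    expect_equal(eval_two_component(p, solve_f_half(p, 1e-9)),
                 derive_t_max(p) / 2, tolerance = 1e-6)
  }
})

test_that("low-frequency component fraction behaves at its extremes", {
  expect_equal(component_fraction_lf(two_component_params(1, 0.7, 0, 10, 1), 2), 1)
  expect_equal(component_fraction_lf(two_component_params(0, 0.7, 1, 10, 1), 2), 0)
  expect_equal(component_fraction_lf(two_component_params(1, 2, 1, 8, 1), 4),
               (4 / 6) / 1.0, tolerance = 1e-12)
  expect_error(component_fraction_lf(two_component_params(1, 2, 1, 8, 1), 0),
               "undefined")
})

test_that("parameter constructors reject invalid values", {
  expect_error(two_component_params(-1, 2, 1, 8, 1), "amplitudes")
  expect_error(two_component_params(1, 0, 1, 8, 1), "half-frequencies")
  expect_error(two_component_params(1, 2, 1, 8, 0), "exponent")
  expect_error(one_component_params(1, -3, 1), "f_half")
  expect_error(reduction_params(10, 0, 0, 1), "k must be > 0")
  expect_error(one_component_params(NA, 1, 1), "finite")
})
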