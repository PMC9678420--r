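grid <- default_grid()

test_that("noiseless data are recovered to high precision for all three models", {
  truth2 <- two_component_params(1.5, 2.0, 0.7, 15.0, 2.0)
  fit2 <- fit_two_component(grid, eval_two_component(truth2, grid))
  expect_lt(max(abs(coef(fit2) - unclass(truth2)) / unclass(truth2)), 1e-4)

  truth1 <- one_component_params(140, 8, 2)
  fit1 <- fit_one_component(grid, eval_one_component(truth1, grid))
  expect_lt(max(abs(coef(fit1) - unclass(truth1)) / unclass(truth1)), 1e-4)

  truthr <- reduction_params(31.8, 0, 6.7, 2)
  fitr <- fit_reduction_curve(grid, eval_reduction_curve(truthr, grid))
  expect_lt(abs(coef(fitr)[["t_lf"]] - 31.8) / 31.8, 1e-4)
  expect_lt(abs(coef(fitr)[["k"]] - 6.7) / 6.7, 1e-4)
  expect_lt(fitr$sse, 1e-8)

  set.seed(8)
  for (i in 1:10) {
    p <- random_two_component_truth()
    fit <- fit_two_component(grid, eval_two_component(p, grid))
    expect_lt(max(abs(coef(fit) - unclass(p)) / unclass(p)), 1e-4)
  }
})

test_that("random monotone-decreasing reduction profiles refit with near-zero SSE", {
  set.seed(9)
  for (i in 1:10) {
    p <- random_reduction_truth()
    # force a decreasing profile (t_lf above t_hf)
    if (p[["t_hf"]] > p[["t_lf"]])
      p <- reduction_params(p[["t_hf"]], p[["t_lf"]], p[["k"]], p[["m"]])
    fit <- fit_reduction_curve(grid, eval_reduction_curve(p, grid))
    expect_lt(fit$sse, 1e-8)
  }
})

test_that("fit result internals are consistent", {
  set.seed(10)
  y <- eval_two_component(two_component_params(1.5, 2, 0.7, 15, 2), grid) *
    (1 + 0.1 * rnorm(length(grid)))
  fit <- fit_two_component(grid, y)
  expect_s3_class(fit, "frfit")
  expect_length(residuals(fit), fit$n_points)
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_gt(fit$n_points, fit$n_params)
  expect_true(fit$converged)
  expect_lte(coef(fit)[["f_star_lf"]], coef(fit)[["f_star_hf"]])
  expect_equal(deviance(fit), fit$sse)
})

test_that("the formula interface and prediction methods work", {
  d <- data.frame(freq = grid,
                  tension = eval_two_component(
                    two_component_params(1.5, 2, 0.7, 15, 2), grid))
  fit <- frfit(tension ~ freq, d, model = "two_component")
  expect_equal(unname(derive_t_max(fit$params)), 2.2, tolerance = 1e-6)
  expect_equal(predict(fit, 4), eval_two_component(fit$params, 4))
  expect_equal(predict(fit, data.frame(frequency_hz = c(1, 20))),
               eval_two_component(fit$params, c(1, 20)))
  s <- summary(fit)
  expect_equal(s$derived$t_max, 2.2, tolerance = 1e-6)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(8L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("the nested SSE ordering holds even on one-component truth data", {
  set.seed(11)
  for (i in 1:10) {
    truth <- random_one_component_truth()
    y <- eval_one_component(truth, grid) * (1 + 0.05 * rnorm(length(grid)))
    f1 <- fit_one_component(grid, y)
    f2 <- fit_two_component(grid, y)
    expect_lte(f2$sse, f1$sse + 1e-10)
    expect_equal(derive_t_max(f2$params), coef(f1)[["y_max"]],
                 tolerance = 0.05)
  }
})

test_that("insufficient or invalid data are rejected and all-zero data flagged", {
  expect_error(fit_two_component(c(1, 2, 4, 8), c(1, 2, 3, 4)),
               "insufficient data")
  expect_error(fit_one_component(c(1, 2, 4), c(1, 2, 3)), "insufficient data")
  expect_error(fit_reduction_curve(c(1, 2, 4, 8), rep(1, 4)),
               "insufficient data")
  expect_error(fit_one_component(grid, c(1, NaN, rep(1, 6))), "finite")
  expect_error(fit_two_component(c(-1, grid[-1]), rep(1, 8)),
               "strictly positive")

  z <- fit_two_component(grid, rep(0, 8))
  expect_true(z$degenerate)
  expect_equal(derive_t_max(z$params), 0)
  z1 <- fit_one_component(grid, rep(0, 8))
  expect_true(z1$degenerate)
  expect_equal(unname(coef(z1)[["y_max"]]), 0)
  # flat zero reductions fit to near-zero plateaus
  zr <- fit_reduction_curve(grid, rep(0, 8))
  expect_lt(abs(coef(zr)[["t_lf"]]), 1e-6)
  expect_lt(abs(coef(zr)[["t_hf"]]), 1e-6)
})

test_that("refitting identical data is bit-reproducible", {
  set.seed(12)
  y <- eval_two_component(two_component_params(1.5, 2, 0.7, 15, 2), grid) *
    (1 + 0.1 * rnorm(length(grid)))
  f1 <- fit_two_component(grid, y)
  f2 <- fit_two_component(grid, y)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sse, f2$sse)
})

test_that("the extra-sum-of-squares F test matches its formula and edge cases", {
  set.seed(13)
  y <- eval_one_component(one_component_params(100, 8, 2), grid) *
    (1 + 0.05 * rnorm(length(grid)))
  f1 <- fit_one_component(grid, y)
  f2 <- fit_two_component(grid, y)
  cm <- compare_models(f1, f2)
  n <- length(grid)
  f_hand <- ((f1$sse - f2$sse) / 2) / (f2$sse / (n - 5))
  expect_equal(cm$f_statistic, f_hand, tolerance = 1e-12)
  expect_equal(cm$p_value, pf(f_hand, 2, n - 5, lower.tail = FALSE))
  expect_identical(cm$df_numerator, 2L)
  expect_identical(cm$df_denominator, n - 5L)

  # identical SSEs give F = 0, p = 1, one-component preferred
  cm0 <- compare_models(f1, structure(
    modifyList(unclass(f2), list(sse = f1$sse)), class = "frfit"))
  expect_equal(cm0$f_statistic, 0)
  expect_equal(cm0$p_value, 1)
  expect_identical(cm0$preferred, "one_component")

  # noiseless well-separated two-component truth: overwhelming preference
  ysep <- eval_two_component(two_component_params(1, 0.3, 1, 18, 4), grid)
  cms <- compare_models(fit_one_component(grid, ysep),
                        fit_two_component(grid, ysep))
  expect_lt(cms$p_value, 1e-10)
  expect_identical(cms$preferred, "two_component")

  # incompatible fits are rejected
  f_short <- fit_one_component(grid[-1], eval_one_component(
    one_component_params(100, 8, 2), grid[-1]))
  expect_error(compare_models(f_short, f2), "incompatible")
})
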