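# Nonlinear least-squares estimation of the frequency-response models.
#
# All three curve families are fitted with bounded multi-start least squares:
# a deterministic grid of data-driven starting values, each refined by the
# Levenberg-Marquardt algorithm (minpack.lm::nls.lm), keeping the solution
# with the smallest sum of squared residuals. The two-component search is
# additionally seeded at the one-component optimum with a zero high-frequency
# amplitude, which guarantees the nested SSE ordering
# sse(two-component) <= sse(one-component).

#' Control parameters for frequency-response fitting
#'
#' @param n_starts Maximum number of multi-start initialisations per fit.
#' @param f_bounds Lower/upper bounds for half-frequencies (Hz).
#' @param m_bounds Lower/upper bounds for the exponent m.
#' @param amp_factor Amplitude upper bound as a multiple of the largest
#'   absolute observed value.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances (relative
#'   reduction in SSE and relative parameter change).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param sse_tie Relative SSE band within which multi-start solutions are
#'   treated as ties, resolved in favour of the least-extrapolating
#'   parameter set.
#' @return A list of class `"frfit_control"`.
#' @export
frfit_control <- function(n_starts = 20, f_bounds = c(0.05, 400),
                          m_bounds = c(0.2, 10), amp_factor = 10,
                          ftol = 1e-13, ptol = 1e-13, maxiter = 500,
                          sse_tie = 0.001) {
  stopifnot(n_starts >= 1, length(f_bounds) == 2, f_bounds[1] > 0,
            diff(f_bounds) > 0, length(m_bounds) == 2, m_bounds[1] > 0,
            diff(m_bounds) > 0, amp_factor > 0, maxiter >= 1, sse_tie >= 0)
  structure(list(n_starts = as.integer(n_starts), f_bounds = f_bounds,
                 m_bounds = m_bounds, amp_factor = amp_factor,
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 sse_tie = sse_tie),
            class = "frfit_control")
}

.model_info <- function(model) {
  switch(model,
    two_component = list(
      n_params = 5L, min_freqs = 6L,
      fields = c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf", "m"),
      eval = eval_two_component, constructor = two_component_params),
    one_component = list(
      n_params = 3L, min_freqs = 4L,
      fields = c("y_max", "f_half", "m"),
      eval = eval_one_component, constructor = one_component_params),
    reduction = list(
      n_params = 4L, min_freqs = 5L,
      fields = c("t_lf", "t_hf", "k", "m"),
      eval = eval_reduction_curve, constructor = reduction_params),
    stop("unknown model: ", model))
}

.fit_bounds <- function(model, f, y, control) {
  amp_hi <- control$amp_factor * max(abs(y), 1e-12)
  # A component half-saturating beyond half the largest tested frequency has
  # no characterised plateau within the design, leaving its amplitude free
  # to run along a flat ridge; the half-frequency search is therefore capped
  # at max(f)/2 (or the configured bound, if tighter).
  fb <- c(control$f_bounds[1], min(control$f_bounds[2], max(f) / 2))
  mb <- control$m_bounds
  switch(model,
    two_component = list(
      lower = c(0, fb[1], 0, fb[1], mb[1]),
      upper = c(amp_hi, fb[2], amp_hi, fb[2], mb[2])),
    one_component = list(
      lower = c(0, fb[1], mb[1]),
      upper = c(amp_hi, fb[2], mb[2])),
    reduction = {
      # the low-frequency plateau t_lf is observed only through points at
      # f >= min(f); a transition already half-complete below 2*min(f)
      # would leave t_lf as pure extrapolation, so k is kept above that
      k_lo <- max(fb[1], min(2 * min(f), fb[2] / 2))
      list(
        lower = c(-amp_hi - 10, -amp_hi - 10, k_lo, mb[1]),
        upper = c(amp_hi + 10, amp_hi + 10, fb[2], mb[2]))
    })
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic, data-driven multi-start grid. Amplitude guesses come from
# the largest observed value, half-frequency guesses from the 25th/75th
# frequency percentiles, and the exponent from a coarse grid.
.fit_starts <- function(model, f, y, control) {
  q <- stats::quantile(f, c(0.25, 0.5, 0.75), names = FALSE)
  ymax <- max(abs(y))
  ms <- c(0.5, 1, 2, 4)
  starts <- list()
  if (model == "two_component") {
    splits <- list(c(0.5, 0.5), c(0.7, 0.3), c(0.3, 0.7), c(0.9, 0.1))
    for (m in ms) for (s in splits)
      starts[[length(starts) + 1L]] <-
        c(s[1] * ymax, q[1], s[2] * ymax, q[3], m)
    # a low-frequency component may half-saturate below the tested range
    for (m in c(1, 2, 4))
      starts[[length(starts) + 1L]] <-
        c(0.5 * ymax, min(f) / 4, 0.5 * ymax, q[3], m)
  } else if (model == "one_component") {
    for (m in ms) for (fh in c(q[1], q[3])) for (a in c(1, 1.3))
      starts[[length(starts) + 1L]] <- c(a * ymax, fh, m)
  } else {
    o <- order(f)
    t_lo <- mean(y[o][seq_len(min(2L, length(y)))])
    t_hi <- mean(y[o][seq(max(1L, length(y) - 1L), length(y))])
    for (m in ms) for (th in c(t_hi, 0)) for (k in c(q[1], q[3]))
      starts[[length(starts) + 1L]] <- c(t_lo, th, k, m)
  }
  starts
}

.lm_refine <- function(start, f, y, info, bounds, control) {
  resid_fn <- function(theta) info$eval(theta, f) - y
  fit <- try(minpack.lm::nls.lm(
    par = .clamp(start, bounds$lower, bounds$upper),
    lower = bounds$lower, upper = bounds$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = control$ftol, ptol = control$ptol, maxiter = control$maxiter)),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  list(par = fit$par, sse = sum(fit$fvec^2),
       converged = fit$info %in% c(1L, 2L, 3L, 4L))
}

.frfit_build <- function(model, f, y, par, sse, converged, n_starts_used,
                         degenerate, control, call) {
  info <- .model_info(model)
  names(par) <- info$fields
  params <- do.call(info$constructor, as.list(unname(par)))
  fitted <- info$eval(params, f)
  structure(list(
    model = model, coefficients = par, params = params,
    data = list(f = f, y = y), fitted = fitted, residuals = y - fitted,
    sse = sum((y - fitted)^2), n_points = length(y),
    n_params = info$n_params, converged = converged,
    degenerate = degenerate, n_starts_used = n_starts_used,
    control = control, call = call), class = "frfit")
}

#' Fit a frequency-response curve model
#'
#' Estimates one of the three curve families by bounded multi-start
#' Levenberg-Marquardt least squares and returns a fitted-model object.
#'
#' `frfit` is generic: the formula method takes `response ~ frequency` with
#' a data frame, the default method takes frequency and response vectors.
#' Components of a two-component fit are relabelled after fitting so that
#' the low-frequency component has the smaller half-frequency.
#'
#' If every response value is exactly zero (a completely blocked
#' preparation) the amplitude parameters cannot be estimated; the fit is
#' returned with zero amplitudes and `degenerate = TRUE` instead of failing.
#'
#' @param x A formula `response ~ frequency`, or a numeric vector of
#'   stimulation frequencies (Hz, strictly positive).
#' @param ... Passed between methods.
#' @return An object of class `"frfit"` with components `model`,
#'   `coefficients`, `params`, `fitted`, `residuals`, `sse`, `n_points`,
#'   `n_params`, `converged`, `degenerate` and `n_starts_used`. Standard
#'   methods (`print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `deviance`, `plot`, `simulate`) are available.
#' @examples
#' truth <- two_component_params(1.5, 2, 0.7, 15, 2)
#' f <- c(1, 2, 4, 8, 12, 16, 20, 40)
#' fit <- frfit(f, eval_two_component(truth, f), model = "two_component")
#' coef(fit)
#' summary(fit)
#' @export
frfit <- function(x, ...) UseMethod("frfit")

#' @rdname frfit
#' @param data A data frame containing the formula variables.
#' @param model One of `"two_component"`, `"one_component"`, `"reduction"`.
#' @param control A [frfit_control()] list.
#' @export
frfit.formula <- function(x, data,
                          model = c("two_component", "one_component",
                                    "reduction"),
                          control = frfit_control(), ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L)
    stop("formula must have the form response ~ frequency")
  out <- frfit.default(mf[[2L]], mf[[1L]], model = model, control = control)
  out$call <- match.call()
  out
}

#' @rdname frfit
#' @param y Numeric vector of responses (same length as `x`).
#' @export
frfit.default <- function(x, y,
                          model = c("two_component", "one_component",
                                    "reduction"),
                          control = frfit_control(), ...) {
  model <- match.arg(model)
  info <- .model_info(model)
  call <- match.call()
  f <- as.numeric(x)
  y <- as.numeric(y)
  if (length(f) != length(y)) stop("frequency and response lengths differ")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be finite and strictly positive")
  if (any(!is.finite(y)))
    stop("response values must be finite (no NA/NaN)")
  n_distinct <- length(unique(f))
  if (n_distinct < info$min_freqs || length(y) <= info$n_params)
    stop("insufficient data: ", model, " fit needs at least ",
         info$min_freqs, " distinct frequencies and more points than its ",
         info$n_params, " parameters")

  if (model != "reduction" && all(y == 0)) {
    par <- switch(model,
      two_component = c(0, stats::median(f), 0, stats::median(f), 1),
      one_component = c(0, stats::median(f), 1))
    return(.frfit_build(model, f, y, par, 0, TRUE, 0L, TRUE, control, call))
  }

  bounds <- .fit_bounds(model, f, y, control)
  starts <- .fit_starts(model, f, y, control)
  one_sse <- NULL
  if (model == "two_component") {
    # seed at the nested one-component optimum (zero Hf amplitude) so the
    # two-component SSE can never exceed the one-component SSE
    one <- frfit.default(f, y, model = "one_component", control = control)
    one_sse <- one$sse
    c1 <- coef(one)
    seed <- c(c1[["y_max"]], c1[["f_half"]], 0,
              min(max(4 * c1[["f_half"]], stats::quantile(f, 0.75, names = FALSE)),
                  bounds$upper[4]),
              c1[["m"]])
    starts <- c(list(seed), starts)
  }
  starts <- starts[seq_len(min(length(starts), control$n_starts))]

  sols <- list()
  for (s in starts) {
    res <- .lm_refine(s, f, y, info, bounds, control)
    if (!is.null(res)) sols[[length(sols) + 1L]] <- res
  }
  if (!length(sols)) stop("all optimisation starts failed for ", model, " fit")
  sses <- vapply(sols, `[[`, numeric(1), "sse")
  # Multi-start solutions whose SSE differs by less than the tie tolerance
  # are statistically indistinguishable on noisy data; among them, prefer
  # the least-extrapolating solution (smallest total amplitude) rather than
  # the raw SSE winner, which on a flat amplitude/half-frequency ridge is
  # often a wildly extrapolated parameter set.
  tied <- which(sses <= min(sses) * (1 + control$sse_tie) + 1e-300)
  amp <- vapply(sols[tied], function(sol) switch(model,
    two_component = sol$par[1] + sol$par[3],
    one_component = sol$par[1],
    reduction = abs(sol$par[1] - sol$par[2])), numeric(1))
  best <- sols[[tied[which.min(amp)]]]
  # never let the tie-break undo the nested-SSE guarantee
  if (!is.null(one_sse) && best$sse > one_sse)
    best <- sols[[which.min(sses)]]

  par <- best$par
  if (model == "two_component" && par[2] > par[4])
    par <- c(par[3], par[4], par[1], par[2], par[5])

  .frfit_build(model, f, y, par, best$sse, best$converged,
               length(starts), FALSE, control, call)
}

#' Fit the two-component frequency-response curve
#'
#' Convenience wrapper around [frfit()] for tension or ATP release data.
#'
#' @param freqs Stimulation frequencies (Hz, > 0), at least 6 distinct.
#' @param values Responses at `freqs`.
#' @param options A [frfit_control()] list.
#' @return An `"frfit"` object.
#' @export
fit_two_component <- function(freqs, values, options = frfit_control()) {
  frfit.default(freqs, values, model = "two_component", control = options)
}

#' Fit the one-component frequency-response curve
#'
#' @param freqs Stimulation frequencies (Hz, > 0), at least 4 distinct.
#' @param values Responses at `freqs`.
#' @param options A [frfit_control()] list.
#' @return An `"frfit"` object.
#' @export
fit_one_component <- function(freqs, values, options = frfit_control()) {
  frfit.default(freqs, values, model = "one_component", control = options)
}

#' Fit the percentage-reduction curve
#'
#' @param freqs Stimulation frequencies (Hz, > 0), at least 5 distinct.
#' @param reductions Percent reductions at `freqs` (negative values encode
#'   enhancement and are allowed).
#' @param options A [frfit_control()] list.
#' @return An `"frfit"` object.
#' @export
fit_reduction_curve <- function(freqs, reductions, options = frfit_control()) {
  frfit.default(freqs, reductions, model = "reduction", control = options)
}

#' Compare nested one- and two-component fits
#'
#' Extra-sum-of-squares F test for whether the two-component curve fits
#' significantly better than the nested one-component curve on the same
#' data:
#' \deqn{F = \frac{(SSE_1 - SSE_2) / (p_2 - p_1)}{SSE_2 / (n - p_2)}}
#' with `p` from the F distribution.
#'
#' @param one_fit One-component `"frfit"` object.
#' @param two_fit Two-component `"frfit"` object on the same data.
#' @param alpha Significance level used to label the preferred model.
#' @return A list of class `"frfit_anova"` with `f_statistic`,
#'   `df_numerator`, `df_denominator`, `p_value` and `preferred`
#'   (`"one_component"` or `"two_component"`).
#' @export
compare_models <- function(one_fit, two_fit, alpha = 0.05) {
  stopifnot(inherits(one_fit, "frfit"), inherits(two_fit, "frfit"))
  if (one_fit$n_points != two_fit$n_points)
    stop("incompatible fits: different numbers of data points")
  if (two_fit$n_params <= one_fit$n_params)
    stop("two_fit must have more parameters than one_fit")
  sse1 <- one_fit$sse
  sse2 <- two_fit$sse
  if (sse2 > sse1 * (1 + 1e-8) + 1e-12)
    warning("two-component SSE exceeds one-component SSE; ",
            "treating the improvement as zero")
  n <- two_fit$n_points
  df1 <- two_fit$n_params - one_fit$n_params
  df2 <- n - two_fit$n_params
  if (df2 <= 0) stop("no residual degrees of freedom for the F test")
  if (sse2 <= 0) {
    fstat <- Inf
    p <- 0
  } else {
    fstat <- max(0, (sse1 - sse2) / df1 / (sse2 / df2))
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  structure(list(f_statistic = fstat, df_numerator = df1,
                 df_denominator = df2, p_value = p, alpha = alpha,
                 preferred = if (p < alpha) "two_component" else "one_component"),
            class = "frfit_anova")
}

#' @export
print.frfit_anova <- function(x, ...) {
  cat("Extra-sum-of-squares F test (one- vs two-component)\n")
  cat(sprintf("  F = %.4g on %d and %d df, p = %.4g\n", x$f_statistic,
              x$df_numerator, x$df_denominator, x$p_value))
  cat("  preferred model:", x$preferred, "\n")
  invisible(x)
}

# ---- frfit methods ---------------------------------------------------------

#' @export
print.frfit <- function(x, digits = 4, ...) {
  label <- switch(x$model,
    two_component = "Two-component frequency-response fit",
    one_component = "One-component frequency-response fit",
    reduction = "Percentage-reduction curve fit")
  cat(label, "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("SSE %.6g on %d points (%d parameters)%s\n", x$sse,
              x$n_points, x$n_params,
              if (x$degenerate) " [degenerate: all-zero data]" else ""))
  invisible(x)
}

#' @export
coef.frfit <- function(object, ...) object$coefficients

#' @export
deviance.frfit <- function(object, ...) object$sse

#' @export
residuals.frfit <- function(object, ...) object$residuals

#' @export
fitted.frfit <- function(object, ...) object$fitted

#' Predict from a fitted frequency-response model
#'
#' @param object An `"frfit"` object.
#' @param newdata Numeric vector of frequencies, or a data frame with a
#'   `frequency_hz` (or single numeric) column. Defaults to the fitted
#'   frequencies.
#' @param ... Unused.
#' @export
predict.frfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  f <- if (is.data.frame(newdata)) {
    col <- intersect(c("frequency_hz", "f", "frequency"), names(newdata))
    if (length(col)) newdata[[col[1]]] else newdata[[1L]]
  } else as.numeric(newdata)
  .model_info(object$model)$eval(object$params, f)
}

#' Simulate responses from a fitted frequency-response model
#'
#' Draws Gaussian responses around the fitted curve with standard deviation
#' equal to the residual standard error.
#'
#' @param object An `"frfit"` object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses at the
#'   fitted frequencies.
#' @export
simulate.frfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(1L, object$n_points - object$n_params))
  out <- replicate(nsim, object$fitted + stats::rnorm(object$n_points, 0, sigma))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
summary.frfit <- function(object, ...) {
  derived <- switch(object$model,
    two_component = if (derive_t_max(object$params) > 0)
      derived_summary(object$params) else list(t_max = 0, f_half_overall = NA_real_),
    one_component = list(y_max = unname(coef(object)[["y_max"]]),
                         f_half = unname(coef(object)[["f_half"]])),
    reduction = list(midpoint = (coef(object)[["t_lf"]] + coef(object)[["t_hf"]]) / 2,
                     k = unname(coef(object)[["k"]])))
  structure(list(fit = object, derived = derived,
                 sigma = sqrt(object$sse /
                                max(1L, object$n_points - object$n_params))),
            class = "summary.frfit")
}

#' @export
print.summary.frfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("Residual standard error:", signif(x$sigma, digits), "\n")
  cat("Derived quantities:\n")
  for (nm in names(x$derived))
    cat(sprintf("  %s = %s\n", nm, signif(x$derived[[nm]], digits)))
  invisible(x)
}

#' Plot a fitted frequency-response curve
#'
#' @param x An `"frfit"` object.
#' @param n_curve Number of points used to draw the fitted curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.frfit <- function(x, n_curve = 200, ...) {
  f <- x$data$f
  grid <- exp(seq(log(min(f)), log(max(f)), length.out = n_curve))
  graphics::plot(f, x$data$y, xlab = "Stimulation frequency (Hz)",
                 ylab = if (x$model == "reduction") "Reduction (%)" else "Response",
                 ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}
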