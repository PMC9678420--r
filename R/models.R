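# Curve models for nerve-mediated frequency-response data.
#
# Three curve families are used throughout the package:
#   * a two-component Hill-type sum describing tension or ATP release as a
#     low-frequency (purinergic) plus a high-frequency (cholinergic)
#     saturating component sharing one exponent m;
#   * a one-component Hill-type curve for ACh release;
#   * a sigmoidal interpolating curve for intervention-induced percentage
#     reductions as a function of stimulation frequency.

#' Two-component frequency-response parameters
#'
#' Parameter container for the two-component curve
#' \deqn{Y(f) = Y_{Lf,max} \frac{f^m}{f^{*m}_{Lf} + f^m} +
#'       Y_{Hf,max} \frac{f^m}{f^{*m}_{Hf} + f^m}}
#' used for nerve-mediated tension and ATP release. Each component rises
#' from 0 at \eqn{f = 0} to its own maximum, reaching half of that maximum
#' at its half-frequency \eqn{f^*}. The exponent `m` is shared between the
#' two components. By convention the low-frequency component is the one
#' with the smaller half-frequency (`f_star_lf <= f_star_hf`); fitting
#' relabels components to enforce this.
#'
#' @param y_lf_max Maximal response of the low-frequency component
#'   (e.g. mN per mg, or fmol per uL per mg); must be >= 0.
#' @param f_star_lf Half-frequency of the low-frequency component (Hz), > 0.
#' @param y_hf_max Maximal response of the high-frequency component, >= 0.
#' @param f_star_hf Half-frequency of the high-frequency component (Hz), > 0.
#' @param m Dimensionless exponent shared by both components, > 0.
#' @return A named numeric vector of class `"two_component_params"`.
#' @seealso [eval_two_component()], [derive_t_max()], [solve_f_half()]
#' @examples
#' p <- two_component_params(1.5, 2, 0.7, 15, 2)
#' eval_two_component(p, c(1, 4, 20))
#' @export
two_component_params <- function(y_lf_max, f_star_lf, y_hf_max, f_star_hf, m) {
  p <- c(y_lf_max = as.numeric(y_lf_max), f_star_lf = as.numeric(f_star_lf),
         y_hf_max = as.numeric(y_hf_max), f_star_hf = as.numeric(f_star_hf),
         m = as.numeric(m))
  if (any(!is.finite(p)))
    stop("two-component parameters must be finite numbers")
  if (p[["y_lf_max"]] < 0 || p[["y_hf_max"]] < 0)
    stop("component amplitudes must be >= 0")
  if (p[["f_star_lf"]] <= 0 || p[["f_star_hf"]] <= 0)
    stop("half-frequencies must be > 0")
  if (p[["m"]] <= 0) stop("exponent m must be > 0")
  structure(p, class = "two_component_params")
}

#' One-component frequency-response parameters
#'
#' Parameter container for the single Hill-type curve
#' \deqn{Y(f) = Y_{max} \frac{f^m}{f_{1/2}^m + f^m}}
#' used for ACh release, which rises from 0 to `y_max` and is exactly
#' `y_max / 2` at `f = f_half`.
#'
#' @param y_max Maximal response, >= 0.
#' @param f_half Frequency at half-maximal response (Hz), > 0.
#' @param m Dimensionless exponent, > 0.
#' @return A named numeric vector of class `"one_component_params"`.
#' @export
one_component_params <- function(y_max, f_half, m) {
  p <- c(y_max = as.numeric(y_max), f_half = as.numeric(f_half),
         m = as.numeric(m))
  if (any(!is.finite(p))) stop("one-component parameters must be finite")
  if (p[["y_max"]] < 0) stop("y_max must be >= 0")
  if (p[["f_half"]] <= 0) stop("f_half must be > 0")
  if (p[["m"]] <= 0) stop("exponent m must be > 0")
  structure(p, class = "one_component_params")
}

#' Percentage-reduction curve parameters
#'
#' Parameter container for the frequency-dependent percentage reduction of a
#' response by an intervention,
#' \deqn{T(f) = T_{Lf} - (T_{Lf} - T_{Hf}) \frac{f^m}{k^m + f^m},}
#' which interpolates from the low-frequency reduction `t_lf` at \eqn{f = 0}
#' to the high-frequency reduction `t_hf` as \eqn{f \to \infty}, and equals
#' their midpoint exactly at `f = k` for any exponent.
#'
#' Reductions are on the 0-100 percent scale; negative values encode
#' enhancement and are allowed for both plateaus.
#'
#' @param t_lf Reduction plateau at low frequency (percent).
#' @param t_hf Reduction plateau at high frequency (percent).
#' @param k Half-transition frequency (Hz), > 0.
#' @param m Dimensionless exponent, > 0.
#' @return A named numeric vector of class `"reduction_params"`.
#' @export
reduction_params <- function(t_lf, t_hf, k, m) {
  p <- c(t_lf = as.numeric(t_lf), t_hf = as.numeric(t_hf),
         k = as.numeric(k), m = as.numeric(m))
  if (any(!is.finite(p))) stop("reduction parameters must be finite")
  if (p[["k"]] <= 0) stop("half-transition frequency k must be > 0")
  if (p[["m"]] <= 0) stop("exponent m must be > 0")
  structure(p, class = "reduction_params")
}

.check_freq <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)))
    stop("frequencies must be finite numbers")
  if (any(f < 0)) stop("frequencies must be >= 0")
  as.numeric(f)
}

.as_params <- function(params, constructor, fields) {
  if (is.list(params)) params <- unlist(params)
  if (!is.numeric(params) || length(params) != length(fields))
    stop("expected ", length(fields), " parameters (", paste(fields, collapse = ", "), ")")
  if (!is.null(names(params)) && all(fields %in% names(params)))
    params <- params[fields]
  do.call(constructor, as.list(unname(params)))
}

#' Evaluate the two-component frequency-response curve
#'
#' @param params A [two_component_params()] object (or a numeric vector in
#'   the order y_lf_max, f_star_lf, y_hf_max, f_star_hf, m).
#' @param f Stimulation frequencies in Hz, >= 0.
#' @return Numeric vector of responses; 0 at `f = 0`, increasing towards
#'   `y_lf_max + y_hf_max`.
#' @export
eval_two_component <- function(params, f) {
  p <- .as_params(params, two_component_params,
                  c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf", "m"))
  f <- .check_freq(f)
  fm <- f^p[["m"]]
  p[["y_lf_max"]] * fm / (p[["f_star_lf"]]^p[["m"]] + fm) +
    p[["y_hf_max"]] * fm / (p[["f_star_hf"]]^p[["m"]] + fm)
}

#' Evaluate the one-component frequency-response curve
#'
#' @param params A [one_component_params()] object (or numeric vector
#'   y_max, f_half, m).
#' @param f Stimulation frequencies in Hz, >= 0.
#' @return Numeric vector of responses bounded by `y_max`.
#' @export
eval_one_component <- function(params, f) {
  p <- .as_params(params, one_component_params, c("y_max", "f_half", "m"))
  f <- .check_freq(f)
  fm <- f^p[["m"]]
  p[["y_max"]] * fm / (p[["f_half"]]^p[["m"]] + fm)
}

#' Evaluate the percentage-reduction curve
#'
#' @param params A [reduction_params()] object (or numeric vector t_lf,
#'   t_hf, k, m).
#' @param f Stimulation frequencies in Hz, >= 0.
#' @return Numeric vector of percent reductions; equals `t_lf` at `f = 0`
#'   and tends to `t_hf` as `f` grows.
#' @export
eval_reduction_curve <- function(params, f) {
  p <- .as_params(params, reduction_params, c("t_lf", "t_hf", "k", "m"))
  f <- .check_freq(f)
  fm <- f^p[["m"]]
  p[["t_lf"]] - (p[["t_lf"]] - p[["t_hf"]]) * fm / (p[["k"]]^p[["m"]] + fm)
}

#' Maximal response of a two-component curve
#'
#' The estimated maximal response (T_max for tension) is the sum of the two
#' component amplitudes, i.e. the limit of the curve as frequency grows.
#'
#' @inheritParams eval_two_component
#' @return `y_lf_max + y_hf_max`.
#' @export
derive_t_max <- function(params) {
  p <- .as_params(params, two_component_params,
                  c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf", "m"))
  unname(p[["y_lf_max"]] + p[["y_hf_max"]])
}

#' Frequency at half-maximal response of a two-component curve
#'
#' Solves for the frequency f_1/2 at which the two-component curve reaches
#' half of its maximal response (half of [derive_t_max()]). The curve is
#' strictly increasing so the root is unique; it is located by bracketed
#' bisection on \[1e-3, 1e4\] Hz.
#'
#' @inheritParams eval_two_component
#' @param tolerance Relative frequency tolerance of the bisection.
#' @return Frequency in Hz.
#' @export
solve_f_half <- function(params, tolerance = 1e-6) {
  p <- .as_params(params, two_component_params,
                  c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf", "m"))
  total <- derive_t_max(p)
  if (total <= 0)
    stop("half-maximal frequency is undefined for zero total amplitude")
  target <- total / 2
  lo <- 1e-3
  hi <- 1e4
  g <- function(f) eval_two_component(p, f) - target
  if (g(lo) > 0) return(lo)
  if (g(hi) < 0) return(hi)
  while ((hi - lo) / ((hi + lo) / 2) > tolerance) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Low-frequency component share of the total response
#'
#' Fraction of the two-component response contributed by the low-frequency
#' (purinergic) component at a given frequency. Used to reason about which
#' transmitter dominates a response at a given stimulation frequency.
#'
#' @inheritParams eval_two_component
#' @return Fraction in \[0, 1\].
#' @export
component_fraction_lf <- function(params, f) {
  p <- .as_params(params, two_component_params,
                  c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf", "m"))
  f <- .check_freq(f)
  total <- eval_two_component(p, f)
  if (any(total <= 0))
    stop("component fraction is undefined where the total response is zero")
  fm <- f^p[["m"]]
  lf <- p[["y_lf_max"]] * fm / (p[["f_star_lf"]]^p[["m"]] + fm)
  lf / total
}

#' Derived summary of a two-component fit
#'
#' @inheritParams eval_two_component
#' @param tolerance Passed to [solve_f_half()].
#' @return List with `t_max` (sum of component maxima) and `f_half_overall`
#'   (frequency at half-maximal response).
#' @export
derived_summary <- function(params, tolerance = 1e-6) {
  list(t_max = derive_t_max(params),
       f_half_overall = solve_f_half(params, tolerance))
}
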