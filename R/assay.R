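# Assay calibration and release arithmetic.
#
# ATP is assayed by luciferin-luciferase bioluminescence, calibrated daily
# against ATP standards; luminescence is linear in concentration on a
# log10-log10 plot over a wide range, with an explicit detection limit.
# ACh is quantified as the difference between total choline (sample treated
# with acetylcholinesterase) and free background choline, calibrated with a
# linear choline standard curve. Nerve-mediated release is the during-EFS
# minus pre-EFS concentration, normalised to preparation wet weight.

#' Build an assay calibration model from standards
#'
#' Fits the calibration line in the stated space: `"loglog"` regresses
#' log10(signal) on log10(concentration) (bioluminescent ATP assay);
#' `"linear"` regresses signal on concentration (fluorometric choline
#' assay). The fitted model stores the standards' concentration range and a
#' detection limit below which inverted concentrations are floored.
#'
#' @param standards Either a data frame with columns `concentration` and
#'   `signal`, or a numeric vector of standard concentrations.
#' @param signal Numeric vector of measured signals (if `standards` is a
#'   vector).
#' @param kind `"loglog"` or `"linear"`.
#' @param detection_limit Concentration below which results are floored and
#'   flagged. Defaults to the smallest standard concentration for
#'   `"loglog"` and to 0 for `"linear"`.
#' @return An object of class `"calibration"` with `kind`, `slope`,
#'   `intercept`, `valid_range` and `detection_limit`.
#' @examples
#' cal <- build_calibration(c(1e-13, 1e-10, 1e-7, 1e-6),
#'                          c(2, 95, 3.1e4, 1.7e5), kind = "loglog")
#' signal_to_concentration(cal, predict(cal, 1e-10))
#' @export
build_calibration <- function(standards, signal = NULL,
                              kind = c("loglog", "linear"),
                              detection_limit = NULL) {
  kind <- match.arg(kind)
  if (is.data.frame(standards)) {
    if (!all(c("concentration", "signal") %in% names(standards)))
      stop("standards data frame needs columns 'concentration' and 'signal'")
    conc <- standards$concentration
    signal <- standards$signal
  } else {
    conc <- as.numeric(standards)
  }
  if (length(conc) != length(signal))
    stop("concentration and signal lengths differ")
  keep <- is.finite(conc) & is.finite(signal)
  conc <- conc[keep]
  signal <- signal[keep]
  if (length(unique(conc)) < 2L)
    stop("singular calibration: need at least 2 distinct standard concentrations")
  if (kind == "loglog") {
    if (any(conc <= 0) || any(signal <= 0))
      stop("log-log calibration requires positive concentrations and signals")
    fit <- stats::lm(log10(signal) ~ log10(conc))
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope <= 0)
      stop("log-log calibration slope must be positive ",
           "(signal must increase with concentration)")
  } else {
    fit <- stats::lm(signal ~ conc)
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope == 0)
      stop("singular calibration: zero slope")
  }
  if (is.null(detection_limit))
    detection_limit <- if (kind == "loglog") min(conc) else 0
  structure(list(kind = kind, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 valid_range = range(conc),
                 detection_limit = detection_limit,
                 n_standards = length(conc)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("%s assay calibration (%d standards)\n",
              if (x$kind == "loglog") "log-log" else "linear", x$n_standards))
  cat(sprintf("  slope %.4g, intercept %.4g\n", x$slope, x$intercept))
  cat(sprintf("  valid range [%.3g, %.3g], detection limit %.3g\n",
              x$valid_range[1], x$valid_range[2], x$detection_limit))
  invisible(x)
}

#' Predict assay signal from concentration
#'
#' Forward evaluation of a calibration line (the inverse of
#' [signal_to_concentration()]).
#'
#' @param object A `"calibration"` object.
#' @param concentration Concentrations in the standards' units.
#' @param ... Unused.
#' @export
predict.calibration <- function(object, concentration, ...) {
  if (object$kind == "loglog") {
    if (any(concentration <= 0))
      stop("log-log calibration requires positive concentrations")
    10^(object$intercept + object$slope * log10(concentration))
  } else {
    object$intercept + object$slope * concentration
  }
}

#' Convert assay signal to concentration
#'
#' Inverts the calibration line. Concentrations implied below the
#' detection limit are returned as the detection limit with
#' `below_detection` set; concentrations outside the calibrated standard
#' range are flagged `out_of_range` (but still returned).
#'
#' @param model A `"calibration"` object.
#' @param signal Measured signals.
#' @return Data frame with columns `concentration`, `below_detection`,
#'   `out_of_range`.
#' @export
signal_to_concentration <- function(model, signal) {
  stopifnot(inherits(model, "calibration"))
  signal <- as.numeric(signal)
  if (model$kind == "loglog") {
    if (any(signal <= 0))
      stop("log-log calibration cannot invert non-positive signals")
    conc <- 10^((log10(signal) - model$intercept) / model$slope)
  } else {
    conc <- (signal - model$intercept) / model$slope
  }
  out_of_range <- conc < model$valid_range[1] | conc > model$valid_range[2]
  below <- conc < model$detection_limit
  conc[below] <- model$detection_limit
  data.frame(concentration = conc, below_detection = below,
             out_of_range = out_of_range)
}

#' ACh concentration from the choline difference
#'
#' The acetylcholinesterase-treated aliquot measures total choline, the
#' untreated aliquot free background choline; their difference estimates
#' the ACh present. Negative differences (assay noise) are retained, not
#' clamped, so that averaging across preparations stays unbiased; they are
#' marked in the `"negative"` attribute.
#'
#' @param total Total choline concentration(s) (with AChE).
#' @param free Free choline concentration(s) (without AChE).
#' @return Numeric vector `total - free` with a logical attribute
#'   `"negative"` flagging noise-driven negative estimates.
#' @export
ach_from_choline <- function(total, free) {
  if (any(total < 0, na.rm = TRUE) || any(free < 0, na.rm = TRUE))
    stop("choline concentrations must be >= 0")
  out <- total - free
  attr(out, "negative") <- out < 0
  out
}

#' Weight-normalised nerve-mediated net release
#'
#' Nerve-mediated release is the during-EFS concentration minus the
#' pre-EFS concentration, divided by preparation wet weight. The sign is
#' preserved: negative net release (during < pre) is flagged, not clamped.
#'
#' @param pre Pre-EFS concentration(s).
#' @param during During-EFS concentration(s).
#' @param weight Preparation wet weight(s) in mg, > 0.
#' @return Numeric vector `(during - pre) / weight` with a logical
#'   attribute `"negative"`.
#' @export
net_release <- function(pre, during, weight) {
  if (any(weight <= 0)) stop("preparation weight must be > 0")
  out <- (during - pre) / weight
  attr(out, "negative") <- out < 0
  out
}

#' Percentage reduction of a response by an intervention
#'
#' `100 * (1 - intervention / control)`. In cohort analyses this is
#' computed per preparation and then averaged across preparations (the
#' mean of per-preparation ratios, not the ratio of means).
#'
#' @param control Response(s) under the reference condition; must be
#'   non-zero.
#' @param intervention Response(s) under the intervention.
#' @return Percent reduction (negative = enhancement).
#' @export
percent_reduction <- function(control, intervention) {
  if (any(control == 0))
    stop("percent reduction is undefined for a zero control response")
  100 * (1 - intervention / control)
}
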