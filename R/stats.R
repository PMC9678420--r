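# Paired statistical machinery applied to fitted parameters and reductions.

#' Student's paired t test
#'
#' Two-sided paired t test on within-pair differences, reported with the
#' mean and SD of the differences.
#'
#' @param x,y Paired measurement vectors of equal length (n >= 2).
#' @return List of class `"paired_t"` with `statistic`, `df`, `p_value`,
#'   `mean_difference`, `sd_difference`, `n`.
#' @examples
#' paired_t(c(2, 4, 6, 9), c(1, 2, 3, 4))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("pairing error: x and y must have equal lengths")
  if (length(x) < 2) stop("paired t test needs at least 2 pairs")
  d <- x - y
  if (any(!is.finite(d))) stop("paired values must be finite")
  if (stats::sd(d) == 0)
    stop("degenerate paired t test: zero variance of differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = mean(d),
                 sd_difference = stats::sd(d),
                 n = length(d)),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  mean difference %.4g (SD %.4g, n = %d)\n",
              x$mean_difference, x$sd_difference, x$n))
  invisible(x)
}

#' Repeated-measures one-way ANOVA with Holm post hoc tests
#'
#' Within-subject one-way ANOVA (condition effect tested against the
#' subject-by-condition residual, via `aov` with a subject error stratum),
#' followed by Holm-adjusted paired t tests of every condition against a
#' designated reference condition.
#'
#' @param values Matrix or data frame of measurements, rows =
#'   preparations, columns = conditions; must be complete (no missing
#'   cells).
#' @param reference Column (name or index) of the reference condition for
#'   the post hoc comparisons.
#' @return List of class `"rm_anova"` with `f_statistic`, `df_between`,
#'   `df_error`, `p_value` and `posthoc` (data frame of pairwise raw and
#'   Holm-adjusted p values versus the reference).
#' @export
rm_anova_oneway <- function(values, reference = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (any(!is.finite(values)))
    stop("incomplete design: missing cells in the preparations x conditions table")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 preparations and 2 conditions")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cond", seq_len(ncol(values)))
  ref <- if (is.character(reference)) match(reference, colnames(values))
         else as.integer(reference)
  if (is.na(ref) || ref < 1 || ref > ncol(values))
    stop("unknown reference condition")

  long <- data.frame(
    value = as.vector(values),
    prep = factor(rep(seq_len(nrow(values)), times = ncol(values))),
    condition = factor(rep(colnames(values), each = nrow(values)),
                       levels = colnames(values)))
  fit <- stats::aov(value ~ condition + Error(prep), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_b <- tab["condition", "Df"]
  df_e <- tab["Residuals", "Df"]
  if (ss_cond <= .Machine$double.eps * max(1, sum(values^2))) {
    fstat <- 0
    p <- 1
  } else if (ss_err <= .Machine$double.eps * max(1, sum(values^2))) {
    fstat <- Inf
    p <- 0
  } else {
    fstat <- (ss_cond / df_b) / (ss_err / df_e)
    p <- stats::pf(fstat, df_b, df_e, lower.tail = FALSE)
  }

  others <- setdiff(seq_len(ncol(values)), ref)
  raw <- vapply(others, function(j) {
    tryCatch(paired_t(values[, j], values[, ref])$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  posthoc <- data.frame(
    condition = colnames(values)[others],
    reference = colnames(values)[ref],
    p_raw = raw,
    p_holm = stats::p.adjust(raw, method = "holm"))

  structure(list(f_statistic = fstat, df_between = df_b, df_error = df_e,
                 p_value = p, posthoc = posthoc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_error, x$f_statistic, x$p_value))
  cat("Holm-adjusted paired post hoc tests vs", x$posthoc$reference[1], ":\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with non-zero
#'   variance.
#' @return List with `r`, `p_value`, `n`, `df`, `statistic` (the t
#'   transform of r).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (length(x) < 3) stop("Pearson correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       df = unname(ct$parameter), statistic = unname(ct$statistic))
}

#' Sample size for a paired design
#'
#' Smallest number of preparations giving the requested power for a
#' two-sided paired t test, for a within-pair difference of `delta` with
#' standard deviation `sd` (noncentral-t power calculation via
#' [stats::power.t.test()]). The floor is n = 2, the smallest analysable
#' paired design.
#'
#' @param sd Standard deviation of the within-pair differences.
#' @param delta Smallest effect (mean difference) to detect.
#' @param alpha Two-sided significance level.
#' @param power Required power.
#' @return Integer sample size.
#' @examples
#' required_n(sd = 1, delta = 1)  # 10
#' @export
required_n <- function(sd, delta, alpha = 0.05, power = 0.80) {
  stopifnot(sd > 0, delta > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  p2 <- stats::power.t.test(n = 2, delta = delta, sd = sd,
                            sig.level = alpha, type = "paired")$power
  if (p2 >= power) return(2L)
  res <- stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                             power = power, type = "paired")
  max(2L, as.integer(ceiling(res$n)))
}
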