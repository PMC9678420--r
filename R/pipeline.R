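# Cohort analysis pipeline: per-preparation fits, derived parameters,
# paired comparisons and summary tables.
#
# Reporting conventions follow the source study design: intervention
# effects on tension and ATP release are summarised as the per-preparation
# percentage reduction averaged over 1 and 2 Hz (where the purinergic
# component dominates), ACh effects are reported at 20 Hz (where
# cholinergic release peaks), and each condition is compared against the
# immediately preceding condition in the chain.

`%||%` <- function(a, b) if (is.null(a)) b else a

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", what, ": ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Default pipeline configuration
#'
#' @param alpha Significance level for paired comparisons.
#' @param low_freqs Frequencies (Hz) averaged for the low-frequency
#'   tension/ATP reduction summaries.
#' @param ach_freq Frequency (Hz) at which ACh effects are reported.
#' @param conditions Optional explicit condition ordering (first =
#'   reference, each condition compared to the one preceding it).
#' @param fit_options A [frfit_control()] list.
#' @param seed Optional seed recorded in run records (the analysis itself
#'   is deterministic).
#' @return Named list of configuration values.
#' @export
cohort_config <- function(alpha = 0.05, low_freqs = c(1, 2), ach_freq = 20,
                          conditions = NULL, fit_options = frfit_control(),
                          seed = NULL) {
  list(alpha = alpha, low_freqs = low_freqs, ach_freq = ach_freq,
       conditions = conditions, fit_options = fit_options, seed = seed)
}

# wide pre/during table of net weight-normalised release per
# prep x condition x frequency for one analyte concentration table
.net_one <- function(conc, analyte_label) {
  pre <- conc[conc$phase == "pre_efs", ]
  dur <- conc[conc$phase == "during_efs", ]
  key <- c("prep_id", "condition", "frequency_hz", "weight_mg")
  m <- merge(pre[, c(key, "value")], dur[, c(key, "value")],
             by = key, suffixes = c("_pre", "_during"))
  if (nrow(m) != nrow(pre) || nrow(m) != nrow(dur))
    stop("unpaired pre/during-EFS records for ", analyte_label)
  net <- net_release(m$value_pre, m$value_during, m$weight_mg)
  data.frame(prep_id = m$prep_id, condition = m$condition,
             frequency_hz = m$frequency_hz, analyte = analyte_label,
             net = as.numeric(net), weight_mg = m$weight_mg)
}

#' Net weight-normalised release from a release record table
#'
#' Computes nerve-mediated net release (during-EFS minus pre-EFS,
#' divided by weight) per preparation, condition and frequency. ATP uses
#' the calibrated ATP concentrations directly; ACh is first formed as the
#' total-minus-free choline difference within each phase.
#'
#' @param release Data frame with columns `prep_id`, `condition`,
#'   `analyte` (`ATP`, `ACh_total_choline`, `ACh_free_choline`),
#'   `frequency_hz`, `phase` (`pre_efs`/`during_efs`), `value`,
#'   `weight_mg`.
#' @return Data frame with columns `prep_id`, `condition`,
#'   `frequency_hz`, `analyte` (`ATP`/`ACh`), `net`, `weight_mg`.
#' @export
net_release_table <- function(release) {
  .require_cols(release, c("prep_id", "condition", "analyte", "frequency_hz",
                           "phase", "value", "weight_mg"), "release table")
  out <- list()
  if (any(release$analyte == "ATP"))
    out$atp <- .net_one(release[release$analyte == "ATP", ], "ATP")
  if (all(c("ACh_total_choline", "ACh_free_choline") %in% release$analyte)) {
    key <- c("prep_id", "condition", "frequency_hz", "phase", "weight_mg")
    tot <- release[release$analyte == "ACh_total_choline", c(key, "value")]
    fre <- release[release$analyte == "ACh_free_choline", c(key, "value")]
    m <- merge(tot, fre, by = key, suffixes = c("_total", "_free"))
    m$value <- as.numeric(ach_from_choline(m$value_total, m$value_free))
    out$ach <- .net_one(m[, c(key, "value")], "ACh")
  }
  if (!length(out)) stop("release table contains no recognised analytes")
  do.call(rbind, out)
}

.fit_row <- function(fit, prep, cond, response) {
  cf <- coef(fit)
  row <- data.frame(prep_id = prep, condition = cond, response = response,
                    model = fit$model,
                    y_lf_max = NA_real_, f_star_lf = NA_real_,
                    y_hf_max = NA_real_, f_star_hf = NA_real_,
                    y_max = NA_real_, f_half = NA_real_, m = cf[["m"]],
                    sse = fit$sse, n_points = fit$n_points,
                    converged = fit$converged, degenerate = fit$degenerate,
                    t_max = NA_real_, f_half_overall = NA_real_)
  if (fit$model == "two_component") {
    row[c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf")] <-
      as.list(cf[c("y_lf_max", "f_star_lf", "y_hf_max", "f_star_hf")])
    row$t_max <- derive_t_max(fit$params)
    row$f_half_overall <- if (row$t_max > 0) solve_f_half(fit$params) else NA_real_
  } else if (fit$model == "one_component") {
    row[c("y_max", "f_half")] <- as.list(cf[c("y_max", "f_half")])
  }
  row
}

.safe_paired_p <- function(x, y) {
  tryCatch(paired_t(x, y)$p_value, error = function(e) NA_real_)
}

# per-preparation value averaged over selected frequencies
.avg_at <- function(df, value_col, freqs) {
  sub <- df[df$frequency_hz %in% freqs, ]
  if (!nrow(sub))
    return(data.frame(prep_id = character(0), value = numeric(0)))
  agg <- stats::aggregate(sub[[value_col]],
                          by = list(prep_id = sub$prep_id), FUN = mean)
  names(agg)[2] <- "value"
  agg
}

#' Analyse a paired control/intervention cohort
#'
#' Runs the full analysis for one cohort: fits the two-component curve to
#' each preparation's weight-normalised tension (and ATP net release) under
#' each condition, the one-component curve to ACh net release, derives
#' T_max and f_1/2, computes per-preparation percentage reductions (tension
#' and ATP averaged over the low-frequency points, ACh at the reporting
#' frequency), aggregates means and SDs, and runs paired comparisons of
#' each condition against the immediately preceding one. With three or
#' more chained conditions the chain p values are Holm-adjusted and a
#' repeated-measures one-way ANOVA over the chain is included.
#'
#' @param tension Data frame with columns `prep_id`, `condition`,
#'   `frequency_hz`, `tension_mN`, `weight_mg`.
#' @param release Optional release record table (see
#'   [net_release_table()]); without it the release summaries are marked
#'   not recorded.
#' @param config A [cohort_config()] list.
#' @return Object of class `"cohort_analysis"`: a list with `fits`
#'   (per-preparation parameter table), `table2` (T_max / f_1/2 summary),
#'   `table3` (percentage-reduction summary; `ach_recorded = FALSE` marks
#'   conditions without ACh data), `profile` (across-preparation mean
#'   reduction by frequency), `correlation` (Pearson r of tension vs ATP
#'   reductions across interventions, when at least 3 are present),
#'   `anova`, `net`, `conditions` and `config`. A `p_value` of `NA` in the
#'   summary tables marks a degenerate comparison (zero variance of
#'   paired differences).
#' @export
analyze_cohort <- function(tension, release = NULL, config = cohort_config()) {
  .require_cols(tension, c("prep_id", "condition", "frequency_hz",
                           "tension_mN", "weight_mg"), "tension table")
  conditions <- config$conditions %||% unique(tension$condition)
  if (!all(tension$condition %in% conditions))
    stop("tension table contains conditions not listed in the configuration")
  preps <- unique(tension$prep_id)
  alpha <- config$alpha %||% 0.05
  low_freqs <- config$low_freqs %||% c(1, 2)
  ach_freq <- config$ach_freq %||% 20
  opts <- config$fit_options %||% frfit_control()

  tension$norm <- tension$tension_mN / tension$weight_mg

  net <- if (!is.null(release)) net_release_table(release) else NULL
  atp <- if (!is.null(net)) net[net$analyte == "ATP", ] else NULL
  ach <- if (!is.null(net) && any(net$analyte == "ACh"))
    net[net$analyte == "ACh", ] else NULL

  # ---- per-preparation fits ----
  fits <- list()
  per_prep <- list()  # derived values for paired tests
  for (cond in conditions) {
    for (prep in preps) {
      tsub <- tension[tension$condition == cond & tension$prep_id == prep, ]
      if (!nrow(tsub))
        stop("unpaired preparation: ", prep, " has no tension data under ",
             cond)
      fit <- fit_two_component(tsub$frequency_hz, tsub$norm, opts)
      fits[[length(fits) + 1L]] <- .fit_row(fit, prep, cond, "tension")
      if (!is.null(atp)) {
        asub <- atp[atp$condition == cond & atp$prep_id == prep, ]
        if (nrow(asub)) {
          afit <- fit_two_component(asub$frequency_hz, asub$net, opts)
          fits[[length(fits) + 1L]] <- .fit_row(afit, prep, cond, "atp")
        }
      }
      if (!is.null(ach)) {
        csub <- ach[ach$condition == cond & ach$prep_id == prep, ]
        if (nrow(csub)) {
          cfit <- fit_one_component(csub$frequency_hz, csub$net, opts)
          row <- .fit_row(cfit, prep, cond, "ach")
          sigma <- sqrt(cfit$sse / max(1L, cfit$n_points - cfit$n_params))
          row$ach_quantifiable <- row$y_max > 2 * sigma
          fits[[length(fits) + 1L]] <- row
        }
      }
    }
  }
  for (i in seq_along(fits))
    if (is.null(fits[[i]]$ach_quantifiable)) fits[[i]]$ach_quantifiable <- NA
  fits <- do.call(rbind, fits)

  # ---- derived-parameter summary: T_max and f_1/2 per condition ----
  t2 <- list()
  tension_fits <- fits[fits$response == "tension", ]
  for (j in seq_along(conditions)) {
    cond <- conditions[j]
    sub <- tension_fits[tension_fits$condition == cond, ]
    sub <- sub[match(preps, sub$prep_id), ]
    row <- data.frame(condition = cond, n = nrow(sub),
                      t_max_mean = mean(sub$t_max), t_max_sd = stats::sd(sub$t_max),
                      t_max_p = NA_real_,
                      f_half_mean = mean(sub$f_half_overall),
                      f_half_sd = stats::sd(sub$f_half_overall),
                      f_half_p = NA_real_,
                      reference = NA_character_)
    if (j > 1) {
      ref <- tension_fits[tension_fits$condition == conditions[j - 1], ]
      ref <- ref[match(preps, ref$prep_id), ]
      row$t_max_p <- .safe_paired_p(sub$t_max, ref$t_max)
      row$f_half_p <- .safe_paired_p(sub$f_half_overall, ref$f_half_overall)
      row$reference <- conditions[j - 1]
    }
    t2[[j]] <- row
  }
  table2 <- do.call(rbind, t2)
  if (length(conditions) > 2) {
    table2$t_max_p[-1] <- stats::p.adjust(table2$t_max_p[-1], method = "holm")
    table2$f_half_p[-1] <- stats::p.adjust(table2$f_half_p[-1], method = "holm")
  }

  anova <- NULL
  if (length(conditions) > 2) {
    tmat <- sapply(conditions, function(cond) {
      s <- tension_fits[tension_fits$condition == cond, ]
      s$t_max[match(preps, s$prep_id)]
    })
    fmat <- sapply(conditions, function(cond) {
      s <- tension_fits[tension_fits$condition == cond, ]
      s$f_half_overall[match(preps, s$prep_id)]
    })
    anova <- list(t_max = rm_anova_oneway(tmat),
                  f_half = rm_anova_oneway(fmat))
  }

  # ---- reduction summary: tension/ATP at low frequency, ACh at 20 Hz ----
  redn_block <- function(df, value_col, freqs, cond, ref_cond) {
    if (is.null(df)) return(NULL)
    cc <- .avg_at(df[df$condition == ref_cond, ], value_col, freqs)
    ii <- .avg_at(df[df$condition == cond, ], value_col, freqs)
    m <- merge(cc, ii, by = "prep_id", suffixes = c("_ref", "_int"))
    if (!nrow(m)) return(NULL)
    list(redn = percent_reduction(m$value_ref, m$value_int),
         p = .safe_paired_p(m$value_ref, m$value_int), n = nrow(m))
  }
  t3 <- list()
  profile <- list()
  for (j in seq_along(conditions)[-1]) {
    cond <- conditions[j]
    ref_cond <- conditions[j - 1]
    tb <- redn_block(tension, "norm", low_freqs, cond, ref_cond)
    ab <- redn_block(atp, "net", low_freqs, cond, ref_cond)
    cb <- redn_block(ach, "net", ach_freq, cond, ref_cond)
    t3[[length(t3) + 1L]] <- data.frame(
      condition = cond, reference = ref_cond, n = tb$n,
      tension_redn_mean = mean(tb$redn), tension_redn_sd = stats::sd(tb$redn),
      tension_p = tb$p,
      atp_redn_mean = if (!is.null(ab)) mean(ab$redn) else NA_real_,
      atp_redn_sd = if (!is.null(ab)) stats::sd(ab$redn) else NA_real_,
      atp_p = if (!is.null(ab)) ab$p else NA_real_,
      ach_redn_mean = if (!is.null(cb)) mean(cb$redn) else NA_real_,
      ach_redn_sd = if (!is.null(cb)) stats::sd(cb$redn) else NA_real_,
      ach_p = if (!is.null(cb)) cb$p else NA_real_,
      ach_recorded = !is.null(cb))

    # mean reduction by frequency (feeds the reduction-curve profile fit)
    for (resp in c("tension", "atp")) {
      df <- if (resp == "tension") tension else atp
      vc <- if (resp == "tension") "norm" else "net"
      if (is.null(df)) next
      for (f in sort(unique(df$frequency_hz))) {
        b <- redn_block(df, vc, f, cond, ref_cond)
        if (is.null(b)) next
        profile[[length(profile) + 1L]] <- data.frame(
          response = resp, condition = cond, frequency_hz = f,
          mean_reduction = mean(b$redn), sd_reduction = stats::sd(b$redn),
          n = b$n)
      }
    }
  }
  table3 <- if (length(t3)) do.call(rbind, t3) else NULL
  profile <- if (length(profile)) do.call(rbind, profile) else NULL

  correlation <- NULL
  if (!is.null(table3) && sum(!is.na(table3$atp_redn_mean)) >= 3)
    correlation <- correlate_reductions(table3)

  structure(list(fits = fits, table2 = table2, table3 = table3,
                 profile = profile, correlation = correlation, anova = anova,
                 net = net, conditions = conditions,
                 config = config, alpha = alpha),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, digits = 3, ...) {
  cat("Cohort analysis:", length(unique(x$fits$prep_id)), "preparations,",
      "conditions:", paste(x$conditions, collapse = " -> "), "\n\n")
  cat("Force-frequency parameters (T_max, f_1/2):\n")
  print(format(x$table2, digits = digits), row.names = FALSE)
  if (!is.null(x$table3)) {
    cat("\nPercentage reductions (tension/ATP at low frequency, ACh at",
        paste0(x$config$ach_freq %||% 20, " Hz):\n"))
    print(format(x$table3, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$correlation))
    cat(sprintf("\nTension vs ATP reduction correlation: r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p_value, x$correlation$n))
  invisible(x)
}

#' Correlate tension and ATP reductions across interventions
#'
#' Pearson correlation of the mean low-frequency tension reduction against
#' the mean ATP-release reduction across intervention summary rows (e.g.
#' `table3` rows pooled from several cohort analyses).
#'
#' @param table3 Data frame with columns `tension_redn_mean` and
#'   `atp_redn_mean`.
#' @return See [pearson()].
#' @export
correlate_reductions <- function(table3) {
  .require_cols(table3, c("tension_redn_mean", "atp_redn_mean"),
                "reduction summary")
  keep <- !is.na(table3$tension_redn_mean) & !is.na(table3$atp_redn_mean)
  pearson(table3$tension_redn_mean[keep], table3$atp_redn_mean[keep])
}

#' Fit the percentage-reduction curve to a cohort reduction profile
#'
#' Fits the sigmoidal reduction curve to across-preparation mean
#' percentage reductions as a function of stimulation frequency.
#'
#' @param x A `"cohort_analysis"` object (its `profile` component is
#'   used), a data frame with columns `frequency_hz` and `mean_reduction`,
#'   or a numeric vector of frequencies.
#' @param reductions Percent reductions (when `x` is a frequency vector).
#' @param response `"tension"` or `"atp"` (when `x` is a cohort analysis).
#' @param condition Condition to profile (default: first intervention).
#' @param options A [frfit_control()] list.
#' @return An `"frfit"` object for the reduction model.
#' @export
fit_reduction_profile <- function(x, reductions = NULL, response = "tension",
                                  condition = NULL,
                                  options = frfit_control()) {
  if (inherits(x, "cohort_analysis")) {
    if (is.null(x$profile)) stop("cohort analysis has no reduction profile")
    prof <- x$profile[x$profile$response == response, ]
    condition <- condition %||% prof$condition[1]
    prof <- prof[prof$condition == condition, ]
    f <- prof$frequency_hz
    r <- prof$mean_reduction
  } else if (is.data.frame(x)) {
    .require_cols(x, c("frequency_hz", "mean_reduction"), "reduction profile")
    f <- x$frequency_hz
    r <- x$mean_reduction
  } else {
    f <- as.numeric(x)
    r <- as.numeric(reductions)
  }
  if (length(unique(f)) < 5)
    stop("insufficient data: reduction profile needs mean reductions at ",
         "5 or more distinct frequencies")
  fit_reduction_curve(f, r, options)
}
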