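# Synthetic paired cohorts.
#
# The generator emulates the paired in vitro study design: per-animal
# detrusor preparations measured under a control condition and again under
# an intervention, with tension and transmitter release recorded at each
# stimulation frequency. Population curve parameters are anchored to the
# published cohort summaries for mouse detrusor (control T_max ~ 2.2
# mN/mg with f_1/2 ~ 5.1 Hz shifting to ~7.5 Hz when the purinergic
# component is scaled to 70%; ATP release ~ 73.6 fmol/uL/mg at 8 Hz; ACh
# release ~ 140 fmol/uL/mg at 20 Hz with negligible release below 4 Hz).
# Interventions act multiplicatively on component amplitudes only.

#' Default stimulation-frequency grid
#'
#' Eight frequencies spanning the 1-40 Hz stimulation range, dense enough
#' for stable five-parameter two-component fits.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
default_grid <- function() c(1, 2, 4, 8, 12, 16, 20, 40)

#' Population truth underlying the synthetic cohorts
#'
#' Population-mean curve parameters and assay baselines from which
#' per-preparation truths are drawn. Tension and ATP follow two-component
#' curves, ACh a one-component curve; concentrations are in fmol/uL and
#' weights in mg.
#'
#' @return List with `tension`, `atp`, `ach` parameter objects,
#'   `weight_mean`/`weight_cv` (mg), and assay baselines `atp_baseline`
#'   and `choline_baseline` (fmol/uL).
#' @export
population_truth <- function() {
  list(
    tension = two_component_params(0.969, 0.7, 1.231, 13.75, 2),
    atp = two_component_params(62, 0.7, 54.5, 15, 2),
    ach = one_component_params(157.5, 10, 3),
    weight_mean = 5, weight_cv = 0.15,
    atp_baseline = 10, choline_baseline = 100)
}

#' Define an intervention preset
#'
#' Multiplicative intervention effects for [draw_cohort()]: scales applied
#' to the low-/high-frequency tension components, both ATP components and
#' the ACh amplitude (1 = no effect, 0 = abolished), plus the cohort's
#' measurement-noise CV and between-preparation parameter CV.
#'
#' @param name Condition label used in the simulated tables.
#' @param tension_lf_scale,tension_hf_scale Scales on the low-/high-
#'   frequency tension component amplitudes.
#' @param atp_scale Scale applied uniformly to both ATP components.
#' @param ach_scale Scale on the ACh amplitude.
#' @param noise_cv Coefficient of variation of proportional measurement
#'   noise.
#' @param between_prep_cv Coefficient of variation of the log-normal
#'   per-preparation parameter draws.
#' @return An `"intervention_preset"` object.
#' @export
intervention_preset <- function(name, tension_lf_scale, tension_hf_scale,
                                atp_scale, ach_scale, noise_cv = 0.10,
                                between_prep_cv = 0.25) {
  if (any(c(tension_lf_scale, tension_hf_scale, atp_scale, ach_scale) < 0))
    stop("intervention scales must be >= 0")
  stopifnot(is.character(name), length(name) == 1, noise_cv >= 0,
            between_prep_cv >= 0)
  structure(list(name = name, tension_lf_scale = tension_lf_scale,
                 tension_hf_scale = tension_hf_scale, atp_scale = atp_scale,
                 ach_scale = ach_scale, noise_cv = noise_cv,
                 between_prep_cv = between_prep_cv),
            class = "intervention_preset")
}

#' Intervention presets for synthetic cohorts
#'
#' Named multiplicative-effect presets anchored to the published cohort
#' reductions: each intervention scales the low-frequency (purinergic)
#' tension component and both ATP-release components, leaving ACh
#' untouched, except `ttx` which abolishes all nerve-mediated responses.
#' Scales of 1 encode "no effect". `noise_cv` is the coefficient of
#' variation of the proportional measurement noise and `between_prep_cv`
#' that of the log-normal per-preparation parameter draws.
#'
#' @return Named list of `"intervention_preset"` objects: `control`,
#'   `adenosine`, `cpa`, `neca`, `dpcpx`, `dpcpx_adenosine`, `camps_rp`,
#'   `forskolin`, `ttx`.
#' @export
default_presets <- function() {
  list(
    control         = intervention_preset("control",         1,     1, 1,     1),
    adenosine       = intervention_preset("adenosine",       0.70,  1, 0.659, 1),
    cpa             = intervention_preset("cpa",             0.493, 1, 0.559, 1),
    neca            = intervention_preset("neca",            0.308, 1, 0.482, 1),
    dpcpx           = intervention_preset("dpcpx",           1,     1, 1,     1),
    dpcpx_adenosine = intervention_preset("dpcpx_adenosine", 1,     1, 1,     1),
    camps_rp        = intervention_preset("camps_rp",        0.536, 1, 0.645, 1),
    forskolin       = intervention_preset("forskolin",       0.384, 1, 1,     1),
    ttx             = intervention_preset("ttx",             0,     0, 0,     0))
}

# mean-preserving log-normal multiplier(s)
.lognorm_factor <- function(k, cv) {
  if (cv <= 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.prep_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483647)
}

.scale_two_component <- function(p, lf_scale, hf_scale) {
  two_component_params(p[["y_lf_max"]] * lf_scale, p[["f_star_lf"]],
                       p[["y_hf_max"]] * hf_scale, p[["f_star_hf"]],
                       p[["m"]])
}

#' Draw a paired synthetic control/intervention cohort
#'
#' For each preparation, truth parameters are drawn log-normally around the
#' population means (coefficient of variation `between_prep_cv`), the
#' intervention scales the appropriate component amplitudes, and
#' measurements at each grid frequency receive additive Gaussian noise with
#' standard deviation `noise_cv` times the measured quantity. Release
#' records carry pre-EFS and during-EFS concentrations (the during-EFS
#' concentration is the pre-EFS baseline plus the weight-scaled true
#' release); when an intervention abolishes release entirely the during-EFS
#' sample is the pre-EFS sample, so net release is exactly zero.
#'
#' Each preparation uses its own seed derived from the global `seed`, so
#' cohorts of different sizes share their first preparations and the
#' output is bit-reproducible for a fixed seed.
#'
#' @param preset A preset name (see [default_presets()]) or an
#'   `"intervention_preset"` object.
#' @param n Number of preparations (>= 2).
#' @param grid Stimulation frequencies in Hz.
#' @param seed Integer seed.
#' @param truth Population truth, see [population_truth()].
#' @return List with `tension` (columns `prep_id`, `condition`,
#'   `frequency_hz`, `tension_mN`, `weight_mg`), `release` (columns
#'   `prep_id`, `condition`, `analyte`, `frequency_hz`, `phase`, `value`,
#'   `weight_mg`), and `truth` (per-preparation parameter draws).
#' @examples
#' coh <- draw_cohort("adenosine", n = 3, seed = 1)
#' head(coh$tension)
#' @export
draw_cohort <- function(preset, n, grid = default_grid(), seed = 1,
                        truth = population_truth()) {
  if (is.character(preset)) {
    presets <- default_presets()
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    preset <- presets[[preset]]
  }
  stopifnot(inherits(preset, "intervention_preset"))
  if (!is.numeric(n) || n < 2) stop("cohort design needs n >= 2 preparations")
  n <- as.integer(n)
  grid <- .check_freq(grid)
  if (any(grid <= 0)) stop("grid frequencies must be > 0")

  cond2 <- if (identical(preset$name, "control")) "control_repeat" else preset$name
  conditions <- c("control", cond2)
  cv <- preset$noise_cv
  bcv <- preset$between_prep_cv

  tension_rows <- list()
  release_rows <- list()
  truths <- list()

  for (i in seq_len(n)) {
    set.seed(.prep_seed(seed, i))
    prep <- sprintf("prep%02d", i)
    weight <- truth$weight_mean * .lognorm_factor(1, truth$weight_cv)

    tp <- unclass(truth$tension) * .lognorm_factor(5, bcv)
    ap <- unclass(truth$atp) * .lognorm_factor(5, bcv)
    cp <- unclass(truth$ach) * .lognorm_factor(3, bcv)
    tension_ctrl <- do.call(two_component_params, as.list(unname(tp)))
    atp_ctrl <- do.call(two_component_params, as.list(unname(ap)))
    ach_ctrl <- do.call(one_component_params, as.list(unname(cp)))

    params <- list(
      control = list(tension = tension_ctrl, atp = atp_ctrl, ach = ach_ctrl))
    params[[cond2]] <- list(
      tension = .scale_two_component(tension_ctrl, preset$tension_lf_scale,
                                     preset$tension_hf_scale),
      atp = .scale_two_component(atp_ctrl, preset$atp_scale, preset$atp_scale),
      ach = one_component_params(ach_ctrl[["y_max"]] * preset$ach_scale,
                                 ach_ctrl[["f_half"]], ach_ctrl[["m"]]))

    truths[[prep]] <- c(list(prep_id = prep, weight = weight), params)

    noisy <- function(x) x * (1 + cv * stats::rnorm(length(x)))

    for (cond in conditions) {
      pc <- params[[cond]]
      tension_true <- eval_two_component(pc$tension, grid) * weight
      tension_rows[[length(tension_rows) + 1L]] <- data.frame(
        prep_id = prep, condition = cond, frequency_hz = grid,
        tension_mN = noisy(tension_true), weight_mg = weight)

      # ATP: pre-EFS baseline vs during-EFS baseline + release
      atp_inc <- eval_two_component(pc$atp, grid) * weight
      atp_pre <- noisy(rep(truth$atp_baseline, length(grid)))
      atp_dur <- noisy(truth$atp_baseline + atp_inc)
      atp_dur[atp_inc == 0] <- atp_pre[atp_inc == 0]

      # ACh via the choline difference: AChE-treated (total) vs untreated
      ach_inc <- eval_one_component(pc$ach, grid) * weight
      chol_total_pre <- noisy(rep(truth$choline_baseline, length(grid)))
      chol_free_pre <- noisy(rep(truth$choline_baseline, length(grid)))
      chol_total_dur <- noisy(truth$choline_baseline + ach_inc)
      chol_free_dur <- noisy(rep(truth$choline_baseline, length(grid)))
      zero <- ach_inc == 0
      chol_total_dur[zero] <- chol_total_pre[zero]
      chol_free_dur[zero] <- chol_free_pre[zero]

      rel <- function(analyte, phase, value) data.frame(
        prep_id = prep, condition = cond, analyte = analyte,
        frequency_hz = grid, phase = phase, value = value,
        weight_mg = weight)
      release_rows[[length(release_rows) + 1L]] <- rbind(
        rel("ATP", "pre_efs", atp_pre),
        rel("ATP", "during_efs", atp_dur),
        rel("ACh_total_choline", "pre_efs", chol_total_pre),
        rel("ACh_total_choline", "during_efs", chol_total_dur),
        rel("ACh_free_choline", "pre_efs", chol_free_pre),
        rel("ACh_free_choline", "during_efs", chol_free_dur))
    }
  }

  list(tension = do.call(rbind, tension_rows),
       release = do.call(rbind, release_rows),
       truth = truths,
       preset = preset, grid = grid, seed = seed,
       conditions = conditions)
}
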