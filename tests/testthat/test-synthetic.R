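test_that("noiseless dispersion-free cohorts reproduce the generating curves exactly", {
  pres <- noiseless_preset("adenosine_like", lf = 0.7)
  coh <- draw_cohort(pres, n = 3, seed = 1)
  pop <- population_truth()
  for (prep in unique(coh$tension$prep_id)) {
    tc <- coh$tension[coh$tension$prep_id == prep &
                        coh$tension$condition == "control", ]
    expect_equal(tc$tension_mN,
                 eval_two_component(pop$tension, tc$frequency_hz) * tc$weight_mg,
                 tolerance = 1e-10)
    ti <- coh$tension[coh$tension$prep_id == prep &
                        coh$tension$condition == "adenosine_like", ]
    scaled <- two_component_params(0.7 * pop$tension[["y_lf_max"]],
                                   pop$tension[["f_star_lf"]],
                                   pop$tension[["y_hf_max"]],
                                   pop$tension[["f_star_hf"]],
                                   pop$tension[["m"]])
    expect_equal(ti$tension_mN,
                 eval_two_component(scaled, ti$frequency_hz) * ti$weight_mg,
                 tolerance = 1e-10)
  }
  net <- net_release_table(coh$release)
  atp <- net[net$analyte == "ATP" & net$condition == "control", ]
  expect_equal(atp$net, eval_two_component(pop$atp, atp$frequency_hz),
               tolerance = 1e-10)
  ach <- net[net$analyte == "ACh" & net$condition == "control", ]
  expect_equal(ach$net, eval_one_component(pop$ach, ach$frequency_hz),
               tolerance = 1e-10)
})

test_that("low-frequency tension reduction in the deterministic limit equals the preset scale", {
  coh <- draw_cohort(noiseless_preset("probe", lf = 0.6), n = 2, seed = 1)
  pop <- population_truth()
  tension <- coh$tension
  tension$norm <- tension$tension_mN / tension$weight_mg
  # at f far below the Hf half-frequency the reduction approaches
  # 100 * (1 - lf_scale), attenuated only by the tiny Hf contribution
  f1 <- 1
  ctrl <- tension$norm[tension$condition == "control" & tension$frequency_hz == f1]
  intv <- tension$norm[tension$condition == "probe" & tension$frequency_hz == f1]
  frac <- component_fraction_lf(pop$tension, f1)
  expect_equal(percent_reduction(ctrl, intv), rep(40 * frac, 2),
               tolerance = 1e-8)
})

test_that("cohorts are bit-reproducible and nest across sizes for a fixed seed", {
  a <- draw_cohort("adenosine", n = 4, seed = 7)
  b <- draw_cohort("adenosine", n = 4, seed = 7)
  expect_identical(a$tension, b$tension)
  expect_identical(a$release, b$release)
  big <- draw_cohort("adenosine", n = 6, seed = 7)
  expect_identical(a$tension,
                   big$tension[big$tension$prep_id %in% a$tension$prep_id, ])
  different <- draw_cohort("adenosine", n = 4, seed = 8)
  expect_false(identical(a$tension$tension_mN, different$tension$tension_mN))
})

test_that("complete nerve blockade yields exactly zero tension and net release", {
  coh <- draw_cohort("ttx", n = 3, seed = 2)
  blocked <- coh$tension[coh$tension$condition == "ttx", ]
  expect_identical(unique(blocked$tension_mN), 0)
  net <- net_release_table(coh$release)
  expect_identical(unique(net$net[net$condition == "ttx"]), 0)
})

test_that("preset effect directions encode the cohort summaries they emulate", {
  pres <- default_presets()
  expect_identical(pres$adenosine$ach_scale, 1)       # no effect on ACh
  expect_identical(pres$adenosine$tension_hf_scale, 1)
  expect_lt(pres$adenosine$tension_lf_scale, 1)
  expect_lt(pres$adenosine$atp_scale, 1)
  # receptor antagonism abolishes the adenosine effect
  expect_identical(pres$dpcpx_adenosine$tension_lf_scale, 1)
  expect_identical(pres$dpcpx_adenosine$atp_scale, 1)
  # agonist potency ordering: neca > cpa > adenosine
  expect_lt(pres$neca$tension_lf_scale, pres$cpa$tension_lf_scale)
  expect_lt(pres$cpa$tension_lf_scale, pres$adenosine$tension_lf_scale)
  expect_error(draw_cohort("no_such_preset", n = 3), "unknown preset")
  expect_error(draw_cohort("control", n = 1), "n >= 2")
})

test_that("a noiseless control cohort reproduces the anchored derived parameters", {
  coh <- draw_cohort(noiseless_preset("none"), n = 2, seed = 1)
  t1 <- coh$tension[coh$tension$prep_id == "prep01" &
                      coh$tension$condition == "control", ]
  fit <- fit_two_component(t1$frequency_hz, t1$tension_mN / t1$weight_mg)
  expect_equal(derive_t_max(fit$params), 2.2, tolerance = 0.01)
  expect_equal(solve_f_half(fit$params), 5.1, tolerance = 0.01)
  # ACh negligible at low frequency: < 5% of its maximum at 2 Hz
  pop <- population_truth()
  expect_lt(eval_one_component(pop$ach, 2) / pop$ach[["y_max"]], 0.05)
  expect_equal(eval_one_component(pop$ach, 20), 140, tolerance = 1e-10)
})

test_that("between-preparation dispersion matches the emulated cohort spread", {
  # across-preparation SD of fitted T_max within a factor 2 of the
  # emulated 0.66 mN/mg at default dispersions
  coh <- draw_cohort("control", n = 12, seed = 3)
  tension <- coh$tension[coh$tension$condition == "control", ]
  t_max <- vapply(unique(tension$prep_id), function(p) {
    sub <- tension[tension$prep_id == p, ]
    derive_t_max(fit_two_component(sub$frequency_hz,
                                   sub$tension_mN / sub$weight_mg)$params)
  }, numeric(1))
  expect_gt(sd(t_max), 0.66 / 2)
  expect_lt(sd(t_max), 0.66 * 2)
})

test_that("no systematic ACh effect is injected under the adenosine preset", {
  coh <- draw_cohort("adenosine", n = 12, seed = 4)
  net <- net_release_table(coh$release)
  ach20 <- net[net$analyte == "ACh" & net$frequency_hz == 20, ]
  d <- ach20$net[ach20$condition == "adenosine"] -
    ach20$net[ach20$condition == "control"]
  pop <- population_truth()
  expect_lt(abs(mean(d)), 0.10 * pop$ach[["y_max"]] / sqrt(12))
})

test_that("nerve-mediated ACh release is negligible below 4 Hz", {
  coh <- draw_cohort("control", n = 12, seed = 3)
  net <- net_release_table(coh$release)
  ach <- net[net$analyte == "ACh" & net$condition == "control", ]
  low <- mean(ach$net[ach$frequency_hz <= 2])
  at20 <- mean(ach$net[ach$frequency_hz == 20])
  expect_lt(abs(low), 0.03 * at20)
})
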