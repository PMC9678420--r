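# Shared fixtures: random but identifiable truth parameter draws used by
# the recovery and property tests. Truths are kept inside the region the
# default 1-40 Hz design can identify (half-frequencies below half the
# largest tested frequency, non-degenerate amplitudes).

random_two_component_truth <- function() {
  tr <- c(runif(1, 0.5, 2), runif(1, 0.3, 3), runif(1, 0.3, 2),
          runif(1, 6, 18), runif(1, 1, 3))
  if (tr[4] < 3 * tr[2]) tr[4] <- 3 * tr[2] + 3
  do.call(two_component_params, as.list(tr))
}

random_one_component_truth <- function() {
  one_component_params(runif(1, 50, 200), runif(1, 2, 15), runif(1, 1, 4))
}

random_reduction_truth <- function() {
  reduction_params(runif(1, 10, 70), runif(1, -10, 10), runif(1, 2, 15),
                   runif(1, 1, 3))
}

# dense-grid inversion oracle for the half-maximal frequency, independent
# of the package's bisection solver
grid_f_half_oracle <- function(params, n_grid = 1e6) {
  f <- exp(seq(log(1e-3), log(1e4), length.out = n_grid))
  target <- derive_t_max(params) / 2
  y <- eval_two_component(params, f)
  i <- which(y >= target)[1]
  # linear interpolation between the bracketing grid points
  f[i - 1] + (f[i] - f[i - 1]) * (target - y[i - 1]) / (y[i] - y[i - 1])
}

noiseless_preset <- function(name = "probe", lf = 1, hf = 1, atp = 1, ach = 1) {
  intervention_preset(name, lf, hf, atp, ach,
                      noise_cv = 0, between_prep_cv = 0)
}
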