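# Hand-built miniature cohorts used across test files.

mini_cohort <- function() {
  cohort(
    visits = data.frame(
      subject_id = rep(c("a", "b", "c"), each = 2),
      time_m = rep(c(0, 3), 3),
      sbp = c(120, 118, 140, 142, 131, 128),
      dbp = c(80, 79, 90, 91, 85, 84)),
    baseline = data.frame(subject_id = c("a", "b", "c"),
                          dm = c("no", "yes", "no")),
    outcomes = data.frame(subject_id = c("a", "b", "c"),
                          followup_m = c(10, 20, 30),
                          event = c(1, 0, 1)))
}

# small spec with a fixed basis and tiny MCMC, for structural joint tests
mini_spec <- function(association = "current_value", total = 0, burn = 0,
                      chains = 1, n_intervals = 1, seed = 1, ...) {
  joint_model_spec(
    association = association, basis = time_basis(c(0, 120), c(40, 80)),
    n_intervals = n_intervals,
    mcmc = mcmc_settings(chains = chains, total_iterations = total,
                         burn_in = burn, thin = 1, seed = seed,
                         quadrature_points = 15), ...)
}
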