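# Shared fixtures: a reduced-size generator configuration used by the
# simulation-based tests.  It keeps the study conditions (quarterly visits,
# 120-month horizon, ~14% cumulative event fraction, exponential loss to
# follow-up, Table-style trajectory and hazard coefficients) while trimming
# the covariate set so that test-scale MCMC runs stay affordable.

recovery_config <- function(seed, n_subjects = 150,
                            association = "value_and_slope",
                            alpha = c(sbp_value = log(6.25),
                                      sbp_slope = log(3.75),
                                      dbp_value = log(4.32),
                                      dbp_slope = log(5.64)),
                            gamma = c(age_group_65plus = log(4.64),
                                      dm_yes = log(3.08),
                                      proteinuria_positive = log(2.85)),
                            heights = 4.7e-5) {
  generator_config(
    n_subjects = n_subjects, seed = seed,
    beta = list(sbp = c("(Intercept)" = 11.99, time1 = -0.13, time2 = -1.41,
                        time3 = -0.37, dm_yes = 0.17),
                dbp = c("(Intercept)" = 9.19, time1 = -0.14, time2 = -0.95,
                        time3 = -0.37, dm_yes = 0.45)),
    gamma = gamma, alpha = alpha, association = association,
    baseline_hazard = list(cutpoints = numeric(0), heights = heights))
}

recovery_spec <- function(g, association = g$association,
                          chains = 2, total = 4000, burn = 1000, thin = 2,
                          seed = 1000 + g$seed, n_intervals = 5,
                          qp = 5) {
  joint_model_spec(
    association = association, basis = g$basis, centers = g$centers,
    long_covariates = "dm",
    surv_covariates = c("age_group", "dm", "proteinuria"),
    n_intervals = n_intervals,
    mcmc = mcmc_settings(chains = chains, total_iterations = total,
                         burn_in = burn, thin = thin, seed = seed,
                         quadrature_points = qp))
}

sim_eligible <- function(g) {
  sim <- simulate_cohort(g)
  complete_case_filter(apply_eligibility(sim$cohort)$cohort)$cohort
}

table4_alpha_truth <- c(log(6.25), log(3.75), log(4.32), log(5.64))
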