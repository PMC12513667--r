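test_that("trajectory functionals obey their closed forms", {
  tb <- time_basis(c(0, 120), c(40, 80))
  # zero parameters: all modes vanish
  for (m in c("value", "slope", "area"))
    expect_equal(eta_eval(c(0, 10, 50), 0, c(0, 0, 0), tb, m), rep(0, 3))
  # linear-in-time trajectory below the first interior knot:
  # eta = a + (c1/S) t, quarterly slope = 3 c1/S, area closed form
  a <- 2; c1 <- 6; S <- 120
  t <- c(5, 17.3, 39)
  expect_equal(eta_eval(t, a, c(c1, 0, 0), tb), a + c1 / S * t)
  expect_equal(eta_eval(t, a, c(c1, 0, 0), tb, "slope"),
               rep(3 * c1 / S, 3))
  expect_equal(eta_eval(t, a, c(c1, 0, 0), tb, "area", center = 0.5),
               a * t + c1 / S * t^2 / 2 - 0.5 * t)
  # general parameters: area matches adaptive quadrature
  th <- c(-0.6, -1.3, 0.4)
  got <- eta_eval(17.3, 1.2, th, tb, "area", center = 0.8)
  want <- integrate(function(s) eta_eval(s, 1.2, th, tb) - 0.8, 0, 17.3,
                    rel.tol = 1e-12)$value
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("the survival log-likelihood matches closed forms", {
  coh <- mini_cohort()
  spec <- mini_spec()
  des <- jm_design(coh, spec)
  q <- des$long$sbp$q
  params <- list(beta = list(sbp = c(12, 0, 0, 0), dbp = c(8.5, 0, 0, 0)),
                 b = list(sbp = matrix(0, 3, q), dbp = matrix(0, 3, q)),
                 sigma2 = c(sbp = 0.25, dbp = 0.25), gamma = numeric(0),
                 alpha = c(sbp_value = 0, dbp_value = 0), lambda = 0.02)
  # alpha = 0, single interval: exponential closed form
  for (i in 1:3) {
    ll <- subject_loglik(des, i, params)
    expect_equal(unname(ll["survival"]),
                 des$delta[i] * log(0.02) - 0.02 * des$Tm[i],
                 tolerance = 1e-10)
  }
  # constant trajectory under the value association:
  # Lambda = lambda * exp(alpha (eta - c)) * T
  params$alpha <- c(sbp_value = 0.7, dbp_value = -0.3)
  e <- 0.7 * (12 - des$centers[["sbp"]]) - 0.3 * (8.5 - des$centers[["dbp"]])
  ll3 <- subject_loglik(des, 3, params)
  expect_equal(unname(ll3["survival"]),
               (log(0.02) + e) - 0.02 * exp(e) * 30, tolerance = 1e-8)
})

test_that("with zero association the joint log-likelihood factorizes into
           the mixed-model and piecewise-exponential parts", {
  g <- generator_config(n_subjects = 25, seed = 19)
  coh <- apply_eligibility(simulate_cohort(g)$cohort)$cohort
  spec <- mini_spec(association = "value_and_slope", n_intervals = 3,
                    surv_covariates = "dm")
  des <- jm_design(coh, spec)
  n <- des$n; q <- des$long$sbp$q
  set.seed(2)
  params <- list(beta = list(sbp = c(11.9, -0.2, -1.2, -0.3),
                             dbp = c(9.1, -0.1, -0.9, -0.4)),
                 b = list(sbp = matrix(rnorm(n * q, 0, 0.2), n, q),
                          dbp = matrix(rnorm(n * q, 0, 0.2), n, q)),
                 sigma2 = c(sbp = 0.4, dbp = 0.3),
                 gamma = 0.8,
                 alpha = c(sbp_value = 0, sbp_slope = 0,
                           dbp_value = 0, dbp_slope = 0),
                 lambda = rep(c(0.001, 0.003, 0.002), length.out = des$J))
  bounds <- c(0, des$cutpoints, Inf)
  for (i in c(1, 5, n)) {
    ll <- subject_loglik(des, i, params)
    # longitudinal part: Gaussian density at eta given b
    ll_long <- 0
    for (k in c("sbp", "dbp")) {
      dk <- des$long[[k]]
      r <- which(dk$subj == i)
      mu <- drop(dk$X[r, , drop = FALSE] %*% params$beta[[k]]) +
        drop(dk$Z[r, , drop = FALSE] %*% params$b[[k]][i, ])
      ll_long <- ll_long + sum(dnorm(dk$y[r], mu,
                                     sqrt(params$sigma2[[k]]), log = TRUE))
    }
    expect_equal(unname(ll["longitudinal"]), ll_long, tolerance = 1e-10)
    # survival part: hand piecewise-exponential with proportional shift
    w <- des$W[i, ] * params$gamma
    Ti <- des$Tm[i]
    expo <- sum(params$lambda *
                  pmax(pmin(Ti, bounds[-1]) - bounds[-length(bounds)], 0))
    hand <- des$delta[i] * (log(params$lambda[des$int_T[i]]) + sum(w)) -
      exp(sum(w)) * expo
    expect_equal(unname(ll["survival"]), hand, tolerance = 1e-8)
  }
})

test_that("doubling the quadrature order leaves cumulative hazards
           essentially unchanged", {
  g <- generator_config(n_subjects = 200, seed = 23)
  coh <- apply_eligibility(simulate_cohort(g)$cohort)$cohort
  ll_at <- function(qp) {
    spec <- joint_model_spec(association = "value_and_slope",
                             basis = g$basis, centers = g$centers,
                             n_intervals = 12,
                             mcmc = mcmc_settings(chains = 1,
                                                  total_iterations = 0,
                                                  burn_in = 0,
                                                  quadrature_points = qp))
    des <- jm_design(coh, spec)
    n <- des$n; q <- des$long$sbp$q
    params <- list(beta = list(sbp = c(11.9, -0.2, -1.2, -0.3),
                               dbp = c(9.1, -0.1, -0.9, -0.4)),
                   b = list(sbp = matrix(0.1, n, q),
                            dbp = matrix(-0.1, n, q)),
                   sigma2 = c(sbp = 0.4, dbp = 0.3), gamma = numeric(0),
                   alpha = c(sbp_value = 0.5, sbp_slope = 0.3,
                             dbp_value = 0.4, dbp_slope = 0.2),
                   lambda = rep(c(0.001, 0.003, 0.002),
                                length.out = des$J))
    vapply(seq_len(n), function(i)
      subject_loglik(des, i, params)[["survival"]], numeric(1))
  }
  expect_lt(max(abs(ll_at(15) - ll_at(30))), 1e-6)
})

test_that("a zero-iteration run yields empty draws and the sampler is
           deterministic given the seed", {
  g <- generator_config(n_subjects = 30, seed = 27)
  coh <- complete_case_filter(apply_eligibility(
    simulate_cohort(g)$cohort)$cohort)$cohort
  f0 <- fit_joint(coh, mini_spec(total = 0, burn = 0, n_intervals = 2))
  expect_equal(f0$n_keep, 0)
  expect_equal(nrow(f0$chains[[1]]$draws), 0)
  sp <- mini_spec(total = 60, burn = 20, n_intervals = 2, seed = 77,
                  surv_covariates = "dm")
  f1 <- fit_joint(coh, sp)
  f2 <- fit_joint(coh, sp)
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_equal(f1$n_keep, 40)
})

test_that("posterior summaries transform hazard-scale parameters and a
           degenerate chain is handled", {
  g <- generator_config(n_subjects = 30, seed = 29)
  coh <- complete_case_filter(apply_eligibility(
    simulate_cohort(g)$cohort)$cohort)$cohort
  fit <- fit_joint(coh, mini_spec(total = 120, burn = 40, n_intervals = 2,
                                  chains = 2, surv_covariates = "dm"))
  s <- summary(fit)
  arow <- s[s$parameter == "alpha.sbp_value", ]
  pooled <- as.vector(vapply(fit$chains,
                             function(ch) ch$draws[, "alpha.sbp_value"],
                             numeric(fit$n_keep)))
  expect_equal(arow$ahr, exp(mean(pooled)))
  expect_equal(arow$ahr_lower, exp(unname(quantile(pooled, 0.025))))
  expect_true(all(s$lower <= s$upper))
  # transform check: gamma draws frozen at log 4.64 give AHR 4.64
  fitc <- fit
  for (ch in seq_along(fitc$chains))
    fitc$chains[[ch]]$draws[, "gamma.dm_yes"] <- log(4.64)
  sc <- summary(fitc)
  expect_equal(sc$ahr[sc$parameter == "gamma.dm_yes"], 4.64)
  expect_error(summary(suppressWarnings(
    fit_joint(coh, mini_spec(total = 1, burn = 0, n_intervals = 2)))),
    "two retained draws")
})

test_that("the conjugate residual-variance update tracks its closed-form
           posterior mean in a noise-dominated fit", {
  # trajectories with negligible random effects: sigma^2 posterior should
  # match the inverse-gamma closed form computed from OLS residuals
  beta <- c(12, -0.4, -1, -0.3)
  tb <- time_basis(c(0, 120), c(40, 80))
  set.seed(55)
  n_subj <- 40; tt <- seq(0, 114, by = 6)
  B <- cbind(1, basis_eval(tb, tt))
  visits <- do.call(rbind, lapply(seq_len(n_subj), function(i)
    data.frame(subject_id = sprintf("s%02d", i), time_m = tt,
               sbp = 10 * drop(B %*% beta + rnorm(length(tt), 0, 0.6)),
               dbp = 10 * drop(B %*% (beta - 3) + rnorm(length(tt), 0, 0.5)))))
  coh <- cohort(visits,
                data.frame(subject_id = sprintf("s%02d", 1:n_subj)),
                data.frame(subject_id = sprintf("s%02d", 1:n_subj),
                           followup_m = 121, event = 0))
  fit <- fit_joint(coh, mini_spec(total = 600, burn = 200, n_intervals = 1,
                                  seed = 5))
  s2_draws <- fit$chains[[1]]$draws[, "sigma_sbp"]^2
  res <- resid(lm(visits$sbp / 10 ~ basis_eval(tb, visits$time_m)))
  N <- length(res)
  post_mean <- (0.005 + sum(res^2) / 2) / (1 + N / 2 - 1)
  expect_lt(abs(mean(s2_draws) - post_mean) / post_mean, 0.05)
})
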