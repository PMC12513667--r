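test_that("scheduled visit grids are correct", {
  expect_equal(schedule_visits(7, 3), c(0, 3, 6))
  expect_equal(schedule_visits(3, 3), 0)
  expect_length(schedule_visits(120, 3), 40)
  expect_error(schedule_visits(10, 0), "positive")
})

test_that("the noise-free limit reproduces the latent trajectory exactly", {
  g <- generator_config(n_subjects = 12, seed = 2,
                        sigma_eps = c(sbp = 0, dbp = 0),
                        re_sd = list(sbp = rep(1e-12, 4),
                                     dbp = rep(1e-12, 4)),
                        alpha = c(sbp_value = 0, sbp_slope = 0,
                                  dbp_value = 0, dbp_slope = 0),
                        gamma = c(dm_yes = 0),
                        missing_rate = 0)
  sim <- simulate_cohort(g)
  v <- sim$cohort$visits
  for (id in unique(v$subject_id)) {
    p <- sim$truth$eta_pars[[match(id, sim$cohort$outcomes$subject_id)]]
    rows <- v$subject_id == id
    eta <- eta_eval(v$time_m[rows], p$sbp$a, p$sbp$theta, g$basis)
    expect_equal(v$sbp[rows], 10 * eta, tolerance = 1e-8)
  }
})

test_that("an empty configuration yields an empty cohort and truth", {
  sim <- simulate_cohort(generator_config(n_subjects = 0))
  expect_equal(nrow(sim$cohort$outcomes), 0)
  expect_length(sim$truth$event_time, 0)
})

test_that("event-time inversion matches the constant-hazard closed form", {
  bh <- list(cutpoints = numeric(0), heights = 0.05)
  pars <- list(sbp = list(a = 0, theta = c(0, 0, 0)))
  tb <- time_basis(c(0, 120), c(40, 80))
  for (u in c(0.9, 0.5, 0.13)) {
    t_star <- simulate_event_time(u, bh, 0, c(sbp_value = 0),
                                  "current_value", pars,
                                  c(sbp = 0), tb, horizon = 500)
    expect_equal(t_star, -log(u) / 0.05, tolerance = 1e-8)
  }
  # u near 1 gives an event time near 0
  expect_lt(simulate_event_time(1 - 1e-9, bh, 0, c(sbp_value = 0),
                                "current_value", pars, c(sbp = 0), tb,
                                horizon = 500), 1e-6)
  # insufficient cumulative hazard returns Inf
  expect_identical(simulate_event_time(0.99999, list(cutpoints = numeric(0),
                                                     heights = 1e-12),
                                       0, c(sbp_value = 0), "current_value",
                                       pars, c(sbp = 0), tb, horizon = 10),
                   Inf)
})

test_that("value-association event times agree with dense-grid inversion", {
  tb <- time_basis(c(0, 120), c(40, 80))
  bh <- list(cutpoints = c(30, 60), heights = c(0.01, 0.02, 0.03))
  pars <- list(sbp = list(a = 11.5, theta = c(-0.6, -1.2, -0.4)))
  alpha <- c(sbp_value = 0.8)
  grid <- seq(0, 120, by = 0.001)
  lh <- log(bh$heights)[findInterval(grid, bh$cutpoints) + 1] + 0.3 +
    alpha * (eta_eval(grid, 11.5, c(-0.6, -1.2, -0.4), tb) - 11.2)
  H <- cumsum(c(0, diff(grid) * (exp(lh[-1]) + exp(lh[-length(lh)])) / 2))
  set.seed(4)
  u_all <- runif(4, 0.1, 0.9)
  t_star <- vapply(u_all, function(u)
    simulate_event_time(u, bh, 0.3, alpha, "current_value", pars,
                        c(sbp = 11.2), tb, horizon = 120), numeric(1))
  expect_true(any(is.finite(t_star)))
  for (j in which(is.finite(t_star))) {
    t_grid <- grid[which(H >= -log(u_all[j]))[1]]
    expect_lt(abs(t_star[j] - t_grid), 0.01)
  }
})

test_that("with zero association the 12-month event fraction matches the
           exponential closed form", {
  tb <- time_basis(c(0, 120), c(40, 80))
  bh <- list(cutpoints = numeric(0), heights = 0.01)
  pars <- list(sbp = list(a = 12, theta = c(-0.5, -1, -0.3)))
  set.seed(99)
  u <- runif(5000)
  tt <- vapply(u, function(ui)
    simulate_event_time(ui, bh, 0, c(sbp_value = 0), "current_value",
                        pars, c(sbp = 11.2), tb, horizon = 200), numeric(1))
  p_hat <- mean(tt <= 12)
  p0 <- 1 - exp(-0.12)
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 5000))
})

test_that("raising the baseline hazard weakly decreases mean follow-up", {
  fu <- sapply(c(5e-6, 5e-5), function(lam) {
    g <- generator_config(n_subjects = 400, seed = 31,
                          baseline_hazard = list(cutpoints = numeric(0),
                                                 heights = lam))
    mean(simulate_cohort(g)$cohort$outcomes$followup_m)
  })
  expect_lte(fu[2], fu[1])
})

test_that("with zero association the event process is independent of the
           random effects", {
  g <- generator_config(n_subjects = 1200, seed = 13,
                        alpha = c(sbp_value = 0, sbp_slope = 0,
                                  dbp_value = 0, dbp_slope = 0),
                        baseline_hazard = list(cutpoints = numeric(0),
                                               heights = 1.5e-3))
  sim <- simulate_cohort(g)
  r <- cor(sim$truth$b[, "sbp_b0"], sim$cohort$outcomes$event)
  expect_lt(abs(r), 3 / sqrt(1200))
})

test_that("observed-value variance matches basis' D basis + sigma^2", {
  g <- generator_config(n_subjects = 4000, seed = 17, missing_rate = 0,
                        alpha = c(sbp_value = 0, sbp_slope = 0,
                                  dbp_value = 0, dbp_slope = 0),
                        gamma = c(dm_yes = 0),
                        beta = list(sbp = c("(Intercept)" = 11.99,
                                            time1 = -0.13, time2 = -1.41,
                                            time3 = -0.37),
                                    dbp = c("(Intercept)" = 9.19,
                                            time1 = -0.14, time2 = -0.95,
                                            time3 = -0.37)),
                        censoring_rate = 0)
  sim <- simulate_cohort(g)
  v <- sim$cohort$visits
  for (tt in c(0, 24)) {
    y <- v$sbp[v$time_m == tt] / 10
    z <- c(1, basis_eval(g$basis, tt))
    v_theory <- drop(t(z) %*% g$D[1:4, 1:4] %*% z) + g$sigma_eps["sbp"]^2
    # sampling error of a variance estimate: ~ v * sqrt(2/(n-1)) * 3
    expect_lt(abs(var(y) - v_theory),
              3 * v_theory * sqrt(2 / (length(y) - 1)))
  }
})
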