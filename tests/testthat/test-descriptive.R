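test_that("incidence arithmetic reproduces the reported cohort quantities", {
  r <- incidence_density(n_events = 58, person_years = 2322.83)
  expect_equal(round(r$rate_per_100py, 1), 2.5)
  expect_equal(round(100 * 58 / 408, 2), 14.22)
  # exact Poisson CI from chi-square quantiles, checked by hand evaluation
  expect_equal(r$ci95[1], 100 * qchisq(0.025, 2 * 58) / 2 / 2322.83)
  expect_equal(r$ci95[2], 100 * qchisq(0.975, 2 * 59) / 2 / 2322.83)
})

test_that("incidence edge cases behave", {
  o <- data.frame(subject_id = letters[1:10], followup_m = rep(12, 10),
                  event = c(1, rep(0, 9)))
  r <- incidence_density(o)
  expect_equal(r$person_years, 10)
  expect_equal(r$rate_per_100py, 10)
  r0 <- incidence_density(n_events = 0, person_years = 50)
  expect_equal(r0$rate_per_100py, 0)
  expect_equal(r0$ci95[1], 0)
  expect_error(incidence_density(o[0, ]), "empty")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  o <- data.frame(subject_id = c("a", "b", "c"),
                  followup_m = c(2, 4, 6), event = c(1, 0, 1))
  k <- km_estimate(o)
  expect_equal(km_at(k, 2), 2 / 3)
  expect_equal(km_at(k, 5), 2 / 3)
  expect_equal(km_at(k, 6), 0)
  expect_equal(km_at(k, 0), 1)
  # all censored: survival identically one
  o2 <- o; o2$event <- 0
  expect_true(all(km_estimate(o2)$survival == 1))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(8)
  o <- data.frame(subject_id = as.character(1:40),
                  followup_m = round(rexp(40, 0.02), 1) + 0.1,
                  event = 1)
  k <- km_estimate(o)
  for (tt in c(10, 30, 80))
    expect_equal(km_at(k, tt), mean(o$followup_m > tt))
})

test_that("KM at scale agrees with the exponential closed form", {
  set.seed(12)
  o <- data.frame(subject_id = as.character(1:10000),
                  followup_m = rexp(10000, 0.02), event = 1)
  s24 <- km_at(km_estimate(o), 24)
  p <- exp(-0.48)
  expect_lt(abs(s24 - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("log-rank test respects symmetry and matches hand tabulation", {
  o <- data.frame(subject_id = as.character(1:6),
                  followup_m = c(1, 1, 3, 5, 7, 9),
                  event = c(1, 1, 1, 0, 1, 0))
  gr <- c("x", "y", "x", "y", "x", "y")
  lr <- logrank_test(o, gr)
  # hand risk-set tabulation of observed-minus-expected for group x
  ev_t <- c(1, 3, 7)
  O <- E <- V <- 0
  for (tt in ev_t) {
    at_risk <- o$followup_m >= tt
    d <- sum(o$event == 1 & o$followup_m == tt)
    n <- sum(at_risk); n1 <- sum(at_risk & gr == "x")
    d1 <- sum(o$event == 1 & o$followup_m == tt & gr == "x")
    O <- O + d1; E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
  }
  expect_equal(lr$chi2, (O - E)^2 / V, tolerance = 1e-10)
  # identical event histories in both groups
  o2 <- data.frame(subject_id = as.character(1:6),
                   followup_m = rep(c(2, 5, 8), 2),
                   event = rep(c(1, 0, 1), 2))
  expect_lt(logrank_test(o2, rep(c("x", "y"), each = 3))$chi2, 1e-10)
  # label permutation invariance
  expect_equal(logrank_test(o, gr)$chi2,
               logrank_test(o, c("y", "x", "y", "x", "y", "x"))$chi2,
               tolerance = 1e-12)
  expect_error(logrank_test(o, rep("x", 6)), "two groups")
})

test_that("Cox fit matches brute-force partial-likelihood maximization", {
  o <- data.frame(subject_id = letters[1:8],
                  followup_m = c(2, 3, 5, 7, 11, 13, 17, 19),
                  event = c(1, 0, 1, 1, 0, 1, 1, 0))
  x <- c(1, 1, 0, 1, 0, 0, 1, 0)
  f <- cox_fit(o, matrix(x, dimnames = list(NULL, "x")))
  # no ties: the hand-written partial likelihood is unambiguous
  pl <- function(b) {
    s <- 0
    for (i in which(o$event == 1)) {
      rs <- o$followup_m >= o$followup_m[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }
  b_opt <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(f$coef), b_opt, tolerance = 1e-6)
  expect_equal(unname(f$hr), exp(b_opt), tolerance = 1e-6)
  expect_equal(sum(f$martingale), 0, tolerance = 1e-6)
})

test_that("Cox coefficient is near zero for a symmetric covariate and the
           score vanishes at the optimum", {
  o <- data.frame(subject_id = as.character(1:8),
                  followup_m = rep(c(2, 4, 6, 8), 2),
                  event = rep(c(1, 1, 0, 1), 2))
  x <- rep(c(0, 1), each = 4)
  f <- cox_fit(o, matrix(x, dimnames = list(NULL, "x")))
  expect_lt(abs(f$coef), 1e-8)
  # numerical score at the optimum (Efron-tied partial likelihood via the
  # fitted model's own loglik surface)
  eps <- 1e-5
  ll <- function(b) survival::coxph(survival::Surv(followup_m, event) ~ x,
                                    data = cbind(o, x = x), ties = "efron",
                                    init = b,
                                    control = survival::coxph.control(iter.max = 0))$loglik[2]
  expect_lt(abs((ll(f$coef + eps) - ll(f$coef - eps)) / (2 * eps)), 1e-6)
})

test_that("Cox fit recovers a known log hazard ratio at scale", {
  set.seed(20)
  n <- 2000
  x <- rbinom(n, 1, 0.25)
  tt <- rexp(n, 0.01 * exp(log(4.64) * x))
  cens <- runif(n, 0, 150)
  o <- data.frame(subject_id = as.character(1:n),
                  followup_m = pmin(tt, cens),
                  event = as.integer(tt <= cens))
  f <- cox_fit(o, matrix(x, dimnames = list(NULL, "age65")))
  expect_lt(abs(f$coef - log(4.64)), 3 * f$se)
})

test_that("degenerate Cox inputs are rejected", {
  o <- data.frame(subject_id = letters[1:4], followup_m = 1:4,
                  event = c(1, 0, 1, 0))
  expect_error(cox_fit(o, matrix(1, 4, 1)), "constant")
  expect_error(cox_fit(o[o$event == 0, ], matrix(c(0, 1), 2, 1)), "no events")
  # perfect separation: events all in one group, early
  o2 <- data.frame(subject_id = letters[1:6], followup_m = c(1, 2, 3, 9, 9, 9),
                   event = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(o2, matrix(c(1, 1, 1, 0, 0, 0), 6, 1)),
               "monotone|converge")
})

test_that("Schoenfeld diagnostics detect a time-varying effect", {
  set.seed(33)
  rej <- replicate(40, {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    # effect flips sign at the median time: simulate piecewise
    t1 <- rexp(n, 0.02 * exp(1.2 * x))
    tt <- ifelse(t1 <= 30, t1, 30 + rexp(n, 0.02 * exp(-1.2 * x)))
    o <- data.frame(subject_id = as.character(1:n),
                    followup_m = pmin(tt, 100),
                    event = as.integer(tt <= 100))
    d <- ph_diagnostics(cox_fit(o, matrix(x, dimnames = list(NULL, "x"))))
    d$schoenfeld$p[d$schoenfeld$covariate == "GLOBAL"] < 0.05
  })
  expect_gte(mean(rej), 0.5)
})

test_that("bivariable screen flags strong predictors and respects the
           threshold", {
  set.seed(40)
  n <- 600
  x1 <- rbinom(n, 1, 0.3); x2 <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.01 * exp(1.5 * x1))
  o <- data.frame(subject_id = as.character(1:n),
                  followup_m = pmin(tt, 120),
                  event = as.integer(tt <= 120))
  sc <- bivariable_screen(o, cbind(strong = x1, noise = x2))
  expect_true(sc$include[sc$covariate == "strong"])
  expect_equal(sc$include, sc$p <= 0.25)
})
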