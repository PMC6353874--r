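# Gompertz proportional-hazards likelihood, fitting, and span summaries.

test_that("negative log-likelihood matches hand arithmetic", {
  p <- gompertz_params(0.01, 0.1)
  # zero follow-up contributes nothing
  r0 <- data.frame(t1 = 0, t2 = 0, td = NA, delta = 0L)
  expect_equal(gompertz_neg_loglik(p, r0), 0)
  # one event at age 50: 0.1 (e^5 - 1) - (log 0.01 + 5)
  r1 <- data.frame(t1 = 0, t2 = 60, td = 50, delta = 1L)
  expect_equal(gompertz_neg_loglik(p, r1),
               0.1 * expm1(5) - (log(0.01) + 5), tolerance = 1e-12)
  expect_equal(round(gompertz_neg_loglik(p, r1), 4), 14.3465)
  # gamma -> 0 limit reduces to the exponential model's h0 * t2
  tiny <- gompertz_params(0.1, 1e-9)
  rc <- data.frame(t1 = 0, t2 = 10, td = NA, delta = 0L)
  expect_equal(gompertz_neg_loglik(tiny, rc), 1.0, tolerance = 1e-6)
  expect_error(gompertz_params(0, 0.1), "strictly positive")
})

test_that("cumulative hazard agrees with quadrature of the hazard", {
  p <- gompertz_params(0.01, 0.1)
  expect_equal(cumulative_hazard(p, 0), 0)
  expect_equal(cumulative_hazard(p, 50), 14.74132, tolerance = 1e-6)
  for (t in c(5, 30, 80)) {
    quad <- stats::integrate(function(u) 0.01 * exp(0.1 * u + 0.3),
                             0, t, rel.tol = 1e-10)$value
    expect_equal(cumulative_hazard(p, t, eta = 0.3), quad,
                 tolerance = 1e-8)
  }
  # numerically stable deep into the exponential growth regime
  expect_true(is.finite(cumulative_hazard(gompertz_params(1e-5, 0.25),
                                          80)))
})

test_that("likelihood is invariant to record permutation", {
  recs <- make_records(200, 1e-4, 0.1, seed = 2)
  p <- gompertz_params(2e-4, 0.09)
  expect_equal(gompertz_neg_loglik(p, recs),
               gompertz_neg_loglik(p, recs[sample(nrow(recs)), ]))
})

test_that("ML fit recovers generating parameters and satisfies the score equation", {
  n <- 2e4
  set.seed(31)
  sex <- stats::rbinom(n, 1, 0.5)
  recs <- make_records(n, 1e-4, 0.098, eta = 0.26 * sex, seed = 31)
  X <- cbind(sex = sex)
  fit <- coxgomp_fit(recs, X)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$gamma - 0.098), 0.01)
  expect_lt(abs(fit$params$beta[["sex"]] - 0.26), 0.06)
  # baseline score equation: fitted cumulative hazards sum to N_d
  eta_hat <- drop(X %*% fit$params$beta)
  H <- cumulative_hazard(fit$params,
                         ifelse(recs$delta == 1L, recs$td, recs$t2),
                         eta_hat)
  expect_lt(abs(sum(H) - fit$n_events) / fit$n_events, 1e-6)
})

test_that("ML fit matches the independent Gompertz oracle", {
  skip_if_not_installed("flexsurv")
  recs <- make_records(5000, 1e-4, 0.098, seed = 37)
  set.seed(37)
  x <- stats::rnorm(nrow(recs))
  recs2 <- make_records(5000, 1e-4, 0.098, eta = 0.2 * x, seed = 41)
  time <- ifelse(recs2$delta == 1L, recs2$td, recs2$t2)
  orc <- flexsurv::flexsurvreg(
    survival::Surv(time, recs2$delta) ~ x,
    data = data.frame(time = time, x = x), dist = "gompertz")
  fit <- coxgomp_fit(recs2, cbind(x = x))
  oc <- orc$res[, "est"]
  expect_equal(fit$params$gamma, unname(oc["shape"]), tolerance = 1e-4)
  expect_equal(fit$params$h0, unname(oc["rate"]), tolerance = 1e-3)
  expect_equal(unname(fit$params$beta[["x"]]), unname(oc["x"]),
               tolerance = 1e-3)
  expect_equal(fit$neg_loglik, -orc$loglik, tolerance = 1e-6)
  # standard errors agree with the oracle's observed-information SEs
  ose <- orc$res[, "se"]
  expect_equal(unname(fit$se[["x"]]), unname(ose["x"]), tolerance = 1e-2)
})

test_that("duplicating every record halves variance, not the estimates", {
  recs <- make_records(3000, 1e-4, 0.098, seed = 43)
  f1 <- coxgomp_fit(recs)
  f2 <- coxgomp_fit(rbind(recs, recs))
  expect_equal(f2$params$gamma, f1$params$gamma, tolerance = 1e-5)
  expect_equal(f2$params$h0, f1$params$h0, tolerance = 1e-4)
  expect_equal(f2$se[["gamma"]], f1$se[["gamma"]] / sqrt(2),
               tolerance = 1e-3)
})

test_that("exponential data drives the fitted shape towards zero", {
  set.seed(47)
  n <- 5000
  age <- stats::rexp(n, rate = 0.02)
  t2 <- stats::runif(n, 20, 60)
  delta <- as.integer(age <= t2)
  recs <- data.frame(t1 = 0, t2 = t2, td = ifelse(delta == 1, age, NA),
                     delta = delta)
  # the optimum sits on the gamma -> 0 boundary, so the optimizer may
  # legitimately report unclean convergence there
  fit <- suppressWarnings(coxgomp_fit(recs))
  # recovered shape is indistinguishable from zero at its own SE scale
  expect_lt(fit$params$gamma, 3 * fit$se[["gamma"]] + 1e-3)
  expect_lt(abs(fit$params$h0 - 0.02), 0.003)
})

test_that("left truncation conditions on survival to enrollment", {
  recs <- make_records(200, 1e-3, 0.08, seed = 53)
  p <- gompertz_params(1e-3, 0.08)
  full <- gompertz_neg_loglik(p, recs)
  trunc <- gompertz_neg_loglik(p, recs, left_truncated = TRUE)
  H1 <- cumulative_hazard(p, recs$t1)
  expect_equal(full - trunc, sum(H1), tolerance = 1e-8)
})

test_that("fit refuses degenerate inputs", {
  cens <- data.frame(t1 = 0, t2 = c(10, 20), td = NA, delta = 0L)
  expect_error(coxgomp_fit(cens), "at least one event")
  recs <- make_records(100, 1e-3, 0.08, seed = 59)
  X <- cbind(a = rep(1, 100), b = rep(2, 100))  # collinear
  expect_error(coxgomp_fit(recs, X), "rank")
})

test_that("mean span matches the asymptotic formula and quadrature", {
  p <- gompertz_params(1e-5, 0.1)
  expect_equal(mean_span(p), (log(1e4) - 0.5772156649) / 0.1,
               tolerance = 1e-8)
  expect_equal(round(mean_span(p), 2), 86.33)
  # against numerical integration of the survival function
  S <- function(t) exp(-1e-5 / 0.1 * expm1(0.1 * t))
  quad <- stats::integrate(S, 0, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(mean_span(p) - quad), 0.5)
  # scaling both parameters by c divides the span by c
  p2 <- gompertz_params(2e-5, 0.2)
  expect_equal(mean_span(p2), mean_span(p) / 2, tolerance = 1e-10)
  expect_warning(mean_span(gompertz_params(0.05, 0.1)), "inaccurate")
})

test_that("span shift is the log-HR difference over the shape", {
  expect_equal(span_shift(0, 0.1), 0)
  expect_equal(round(span_shift(0.26, 0.098), 2), 2.65)
  # algebraic identity with the mean-span formula
  p <- gompertz_params(1e-5, 0.098)
  expect_equal(mean_span(p) - mean_span(p, eta = 0.26),
               span_shift(0.26, 0.098), tolerance = 1e-10)
})

test_that("doubling time inverts the shape", {
  expect_equal(round(doubling_time(0.098), 2), 7.07)
  expect_equal(doubling_time(log(2)), 1.0)
  expect_equal(doubling_time(log(2) / 8), 8.0)
  expect_error(doubling_time(0), "strictly positive")
})
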