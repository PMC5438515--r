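# Independent oracle: Breslow log partial likelihood written directly from
# its definition (risk-set sums by brute force), for tiny fixtures.
brute_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tk in sort(unique(time[event == 1]))) {
    ev <- which(time == tk & event == 1)
    risk <- which(time >= tk)
    ll <- ll + sum(x[ev] * beta) -
      length(ev) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

test_that("the Cox score at beta = 0 matches the hand-worked 4-subject example", {
  machine <- survscan:::cox_machine(
    time = c(1, 2, 3, 4), event = rep(1, 4),
    X = matrix(c(1, 0, 1, 0), ncol = 1L)
  )
  expect_equal(machine(0)$score, 2 / 3)
})

test_that("Cox estimates maximise the partial likelihood (grid-search oracle)", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1, x = c(1, 0, 1, 0))
  fit <- fit_cox(d, terms = "x")
  opt <- optimize(function(b) brute_partial_loglik(b, d$time, d$event, d$x),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-9)
  expect_equal(fit$loglik_null, brute_partial_loglik(0, d$time, d$event, d$x))
})

test_that("Cox fits agree with the reference implementation with and without ties", {
  skip_if_not_installed("survival")
  for (case in list(list(seed = 21, ties = FALSE), list(seed = 22, ties = TRUE))) {
    d <- rand_surv_data(n = 250L, p = 2L, ties = case$ties, seed = case$seed)
    fit <- fit_cox(d, terms = c("x1", "x2"))
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d,
                           ties = "breslow")
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$std_errors), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(fit$loglik, ref$loglik[[2L]], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[[1L]], tolerance = 1e-8)
  }
})

test_that("fits refuse data with no events", {
  d <- tibble::tibble(time = 1:4, event = 0, x = c(1, 0, 1, 0))
  expect_error(fit_cox(d, terms = "x"), "no events",
               class = "survscan_data_error")
  expect_error(fit_weibull(d, terms = "x"), "no events",
               class = "survscan_data_error")
})

test_that("the exponential sub-model recovers the closed-form rate", {
  d <- tibble::tibble(time = c(1, 2, 3), event = 1)
  fit <- fit_weibull(d, terms = character(), fix_shape = 1)
  expect_equal(fit$intercept, log(3 / 6), tolerance = 1e-9)
  expect_equal(fit$shape, 1)
})

test_that("Weibull fits match the AFT reference through beta_AFT = -beta_PH/gamma", {
  skip_if_not_installed("survival")
  d <- rand_surv_data(n = 400L, p = 2L, seed = 31)
  fit <- fit_weibull(d, terms = c("x1", "x2"))
  ref <- survival::survreg(survival::Surv(time, event) ~ x1 + x2, data = d,
                           dist = "weibull")
  gam <- 1 / ref$scale
  expect_true(fit$converged)
  expect_equal(fit$shape, gam, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(-coef(ref)[-1L] * gam),
               tolerance = 1e-6)
  expect_equal(fit$intercept, unname(-coef(ref)[[1L]] * gam), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[[2L]], tolerance = 1e-8)
})

test_that("Weibull parameter recovery is within sampling error at n = 2000", {
  sc <- sim_scenario(n_subjects = 2000L, n_snps = 1L, causal_maf = 0.3,
                     beta_snp = 0.4, beta_treatment = -0.3,
                     baseline_shape = 1.4, baseline_scale = 4,
                     censor_fraction = 0.2, seed = 77L)
  geno <- simulate_genotypes(sc)
  trt <- simulate_treatment(sc$n_subjects, seed = 77L)
  dos <- attr(geno, "hard_calls")[, 1L]
  surv <- simulate_survival(dos, trt, sc)
  d <- tibble::tibble(time = surv$time, event = surv$event,
                      snp = dos, trt = as.numeric(trt))
  fit <- fit_weibull(d, terms = c("snp", "trt"))
  alpha_true <- -sc$baseline_shape * log(sc$baseline_scale)
  expect_lt(abs(fit$coefficients[["snp"]] - 0.4) / fit$std_errors[["snp"]], 3)
  expect_lt(abs(fit$coefficients[["trt"]] + 0.3) / fit$std_errors[["trt"]], 3)
  expect_lt(abs(fit$log_shape - log(1.4)) / fit$se_log_shape, 3)
  expect_lt(abs(fit$intercept - alpha_true) / fit$se_intercept, 3)
})

test_that("Wald tests follow the normal quantile identities", {
  fake <- structure(
    list(family = "cox", terms = "x",
         coefficients = c(x = qnorm(0.975) * 0.2),
         std_errors = c(x = 0.2), vcov = matrix(0.04),
         loglik = -10, loglik_null = -12, n = 10L, n_events = 8L,
         converged = TRUE, iterations = 3L),
    class = "survscan_fit"
  )
  w <- wald_test(fake, "x")
  expect_equal(w$p_value, 0.05, tolerance = 1e-6)
  expect_true(w$ci_low <= exp(fake$coefficients) &&
                exp(fake$coefficients) <= w$ci_high)

  fake$coefficients <- c(x = 0)
  w0 <- wald_test(fake, "x")
  expect_equal(w0$p_value, 1)
  expect_true(w0$ci_low <= 1 && 1 <= w0$ci_high)
})

test_that("the Weibull score vanishes at the unrestricted MLE", {
  d <- rand_surv_data(n = 200L, p = 2L, seed = 41)
  fit <- fit_weibull(d, terms = c("x1", "x2"))
  derivs <- survscan:::weibull_machine(d$time, d$event,
                                       as.matrix(d[c("x1", "x2")]))
  at_mle <- derivs(c(fit$intercept, fit$log_shape, fit$coefficients))
  quad <- drop(crossprod(at_mle$score, solve(at_mle$info, at_mle$score)))
  expect_lt(quad, 1e-10)
})

test_that("df = 1 score tests report z with z^2 equal to the statistic", {
  d <- rand_surv_data(n = 150L, p = 2L, seed = 42)
  st <- score_test(d, terms = c("x1", "x2"), tested = "x1")
  expect_equal(st$z^2, st$statistic, tolerance = 1e-12)
  expect_gte(st$statistic, 0)
  expect_true(st$p_value >= 0 && st$p_value <= 1)
})

test_that("likelihood-ratio tests follow the chi-squared identities", {
  fake <- structure(
    list(family = "cox", terms = "x", coefficients = c(x = 0.1),
         std_errors = c(x = 0.1), loglik = -20, loglik_null = -20,
         n = 10L, n_events = 8L, converged = TRUE, iterations = 2L),
    class = "survscan_fit"
  )
  l0 <- lr_test(fake)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)

  fake$loglik <- -20 + 3.841459 / 2
  l1 <- lr_test(fake)
  expect_equal(l1$p_value, 0.05, tolerance = 1e-5)
})

test_that("full-model log likelihood dominates the null on random fits", {
  for (seed in 51:54) {
    d <- rand_surv_data(n = 120L, p = 2L, ties = seed %% 2 == 0, seed = seed)
    fc <- fit_cox(d, terms = c("x1", "x2"))
    fw <- fit_weibull(d, terms = c("x1", "x2"))
    expect_gte(fc$loglik, fc$loglik_null - 1e-6)
    expect_gte(fw$loglik, fw$loglik_null - 1e-6)
    expect_gte(lr_test(fc)$statistic, 0)
    expect_gte(lr_test(fw)$statistic, 0)
  }
})

test_that("rescaling time leaves Cox estimates unchanged and maps Weibull exactly", {
  d <- rand_surv_data(n = 200L, p = 2L, seed = 61)
  d3 <- dplyr::mutate(d, time = 3 * time)
  fc <- fit_cox(d, terms = c("x1", "x2"))
  fc3 <- fit_cox(d3, terms = c("x1", "x2"))
  expect_equal(fc$coefficients, fc3$coefficients, tolerance = 1e-9)

  fw <- fit_weibull(d, terms = c("x1", "x2"))
  fw3 <- fit_weibull(d3, terms = c("x1", "x2"))
  expect_equal(fw$coefficients, fw3$coefficients, tolerance = 1e-6)
  expect_equal(fw$shape, fw3$shape, tolerance = 1e-6)
  expect_equal(fw3$intercept, fw$intercept - fw$shape * log(3), tolerance = 1e-5)
})

test_that("zero survival times are shifted for Weibull with a warning", {
  d <- tibble::tibble(time = c(0, 1, 2, 3), event = 1, x = c(1, 0, 1, 0))
  # the full fit and its internal null refit each warn once
  w <- capture_warnings(fit <- fit_weibull(d, terms = "x"))
  expect_match(w, "zero survival time", all = TRUE)
  expect_true(length(w) >= 1L)
  expect_true(fit$converged)
  expect_silent(fit_cox(d, terms = "x"))
})

test_that("tidy() and glance() summarise fits in broom form", {
  d <- rand_surv_data(n = 150L, p = 2L, seed = 71)
  fw <- fit_weibull(d, terms = c("x1", "x2"))
  td <- tidy(fw)
  expect_equal(td$term,
               c("(Intercept)", "log(shape)", "x1", "x2"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fw)
  expect_equal(gl$nobs, 150L)
  expect_true(gl$converged)

  fc <- fit_cox(d, terms = c("x1", "x2"))
  tdc <- tidy(fc)
  expect_equal(nrow(tdc), 2L)
  expect_true(all(tdc$conf.low < tdc$estimate & tdc$estimate < tdc$conf.high))
})
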