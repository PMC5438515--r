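#' Wald test of a single fitted coefficient
#'
#' Two-sided normal test `z = beta / SE`. For Cox fits a 95% confidence
#' interval on the hazard-ratio scale, `exp(beta +/- z_0.975 SE)`, is
#' attached (confidence intervals are reported for Cox only).
#'
#' @param fit A `survscan_fit` object.
#' @param term Coefficient name, or one of `"(Intercept)"` / `"log(shape)"`
#'   for Weibull fits.
#' @return A one-row tibble: `term`, `estimate`, `std_error`, `statistic`
#'   (z), `p_value`, `ci_low`, `ci_high` (NA unless Cox), `kind = "wald"`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "survscan_fit"))
  if (term %in% names(fit$coefficients)) {
    est <- fit$coefficients[[term]]
    se <- fit$std_errors[[term]]
  } else if (fit$family == "weibull" && term == "(Intercept)") {
    est <- fit$intercept
    se <- fit$se_intercept
  } else if (fit$family == "weibull" && term == "log(shape)") {
    est <- fit$log_shape
    se <- fit$se_log_shape
  } else {
    stop_usage(paste0("unknown coefficient: ", term))
  }
  if (!fit$converged || is.na(se) || se <= 0) {
    return(tibble::tibble(
      term = term, estimate = NA_real_, std_error = NA_real_,
      statistic = NA_real_, p_value = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, kind = "wald"
    ))
  }
  z <- est / se
  crit <- qnorm(0.975)
  is_cox <- fit$family == "cox"
  tibble::tibble(
    term = term, estimate = est, std_error = se,
    statistic = z, p_value = 2 * pnorm(-abs(z)),
    ci_low = if (is_cox) exp(est - crit * se) else NA_real_,
    ci_high = if (is_cox) exp(est + crit * se) else NA_real_,
    kind = "wald"
  )
}

#' Rao score test of Weibull regression coefficients
#'
#' Fits the restricted model with the tested coefficients held at zero (all
#' other terms, the intercept and the shape are nuisance parameters at their
#' restricted maximum-likelihood estimates), then evaluates the full-model
#' score vector and observed information at that point. The statistic is the
#' quadratic form `U' I^-1 U` over the tested block — equivalently the score
#' against the efficient (Schur-complement) information — and is referred to
#' a chi-squared distribution with one degree of freedom per tested column.
#' For a single tested column a signed `z = sign(U) sqrt(statistic)` is also
#' returned for per-coefficient reporting.
#'
#' @param data Tibble with `time`, `event` and all design columns.
#' @param terms All design columns of the full model, in order.
#' @param tested Subset of `terms` whose coefficients are tested against 0.
#' @param fix_shape Optional fixed shape (see [fit_weibull()]).
#' @param control See [fit_control()].
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `z` (NA when
#'   `df > 1`), `kind = "score"`.
#' @export
score_test <- function(data, terms, tested, fix_shape = NULL,
                       control = fit_control()) {
  if (!all(tested %in% terms)) {
    stop_usage("tested columns must be a subset of the model terms")
  }
  na_out <- tibble::tibble(statistic = NA_real_, df = length(tested),
                           p_value = NA_real_, z = NA_real_, kind = "score")
  nuisance <- setdiff(terms, tested)
  null_fit <- tryCatch(
    fit_weibull(data, terms = nuisance, fix_shape = fix_shape,
                control = control),
    error = function(e) NULL
  )
  if (is.null(null_fit) || !null_fit$converged) return(na_out)

  time <- shift_zero_times(data$time)
  X <- as.matrix(data[terms])
  storage.mode(X) <- "double"
  free_shape <- is.null(fix_shape)
  derivs <- weibull_machine(time, data$event, X,
                            if (free_shape) NULL else log(fix_shape))
  k <- if (free_shape) 2L else 1L
  theta0 <- c(null_fit$intercept,
              if (free_shape) null_fit$log_shape,
              rep(0, length(terms)))
  names(theta0) <- c("(Intercept)", if (free_shape) "log(shape)", terms)
  theta0[nuisance] <- null_fit$coefficients[nuisance]
  d <- derivs(theta0)
  u <- d$score
  # the score is zero at the restricted MLE for every nuisance coordinate
  # (up to convergence error); zero it exactly so df is exact
  tested_idx <- k + match(tested, terms)
  u[-tested_idx] <- 0
  quad <- tryCatch(drop(crossprod(u, solve(d$info, u))),
                   error = function(e) NA_real_)
  if (!is.finite(quad) || quad < 0) return(na_out)
  df <- length(tested)
  tibble::tibble(
    statistic = quad, df = df,
    p_value = pchisq(quad, df = df, lower.tail = FALSE),
    z = if (df == 1L) unname(sign(u[tested_idx])) * sqrt(quad) else NA_real_,
    kind = "score"
  )
}

#' Likelihood-ratio test of the overall model
#'
#' `statistic = 2 (loglik_full - loglik_null)`, clamped at zero, referred to
#' a chi-squared distribution with one degree of freedom per regression
#' coefficient (the Weibull intercept and shape appear in both the null and
#' full models and contribute no degrees of freedom).
#'
#' @param fit A converged `survscan_fit`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `kind = "lrt"`.
#' @export
lr_test <- function(fit) {
  stopifnot(inherits(fit, "survscan_fit"))
  df <- length(fit$coefficients)
  if (df == 0L || !fit$converged) {
    return(tibble::tibble(statistic = NA_real_, df = df, p_value = NA_real_,
                          kind = "lrt"))
  }
  stat <- max(0, 2 * (fit$loglik - fit$loglik_null))
  tibble::tibble(
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE),
    kind = "lrt"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted survival model
#'
#' One row per parameter with estimate, standard error, Wald z statistic and
#' two-sided p-value; Cox rows carry 95% hazard-ratio confidence bounds, and
#' Weibull fits include their intercept and log-shape rows.
#'
#' @param x A `survscan_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy survscan_fit
#' @export
tidy.survscan_fit <- function(x, ...) {
  terms <- if (x$family == "weibull") {
    c("(Intercept)", if (!x$shape_fixed) "log(shape)", names(x$coefficients))
  } else {
    names(x$coefficients)
  }
  rows <- purrr::map_dfr(terms, function(tm) wald_test(x, tm))
  tibble::tibble(
    term = rows$term, estimate = rows$estimate, std.error = rows$std_error,
    statistic = rows$statistic, p.value = rows$p_value,
    conf.low = log_or_na(rows$ci_low), conf.high = log_or_na(rows$ci_high)
  )
}

log_or_na <- function(x) ifelse(is.na(x), NA_real_, log(x))

#' Model-level summary of a fitted survival model
#'
#' @param x A `survscan_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log likelihoods, overall LRT, sample and event
#'   counts, convergence diagnostics.
#' @method glance survscan_fit
#' @export
glance.survscan_fit <- function(x, ...) {
  lrt <- lr_test(x)
  tibble::tibble(
    family = x$family,
    logLik = x$loglik,
    logLik_null = x$loglik_null,
    statistic = lrt$statistic,
    df = lrt$df,
    p.value = lrt$p_value,
    nobs = x$n,
    nevent = x$n_events,
    converged = x$converged,
    iterations = x$iterations
  )
}
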