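# Weibull proportional-hazards log likelihood, score and observed
# information, parameterised as theta = (alpha, log_shape, beta) for
# unconstrained Newton-Raphson. Hazard: h(t|x) = gamma t^(gamma-1)
# exp(alpha + x'beta), so
#   ll = sum d_i (log gamma + (gamma-1) log t_i + alpha + x_i'beta)
#        - sum t_i^gamma exp(alpha + x_i'beta).
# When fix_log_shape is non-NULL the shape is held fixed and dropped from
# theta (exponential sub-model at fix_log_shape = 0).
weibull_machine <- function(time, event, X, fix_log_shape = NULL) {
  d <- as.numeric(event == 1)
  lt <- log(time)
  p <- ncol(X)
  free_shape <- is.null(fix_log_shape)

  function(theta) {
    alpha <- theta[[1L]]
    phi <- if (free_shape) theta[[2L]] else fix_log_shape
    beta <- theta[-seq_len(if (free_shape) 2L else 1L)]
    gam <- exp(phi)
    eta <- alpha + if (p > 0L) drop(X %*% beta) else 0
    mu <- exp(gam * lt + eta) # t^gamma * exp(eta), cumulative hazard
    glt <- gam * lt
    loglik <- sum(d * (phi + (gam - 1) * lt + eta)) - sum(mu)

    u_alpha <- sum(d - mu)
    u_phi <- sum(d * (1 + glt)) - sum(mu * glt)
    u_beta <- if (p > 0L) drop(crossprod(X, d - mu)) else numeric(0)

    i_aa <- sum(mu)
    i_ap <- sum(mu * glt)
    i_pp <- -sum(d * glt) + sum(mu * glt * (1 + glt))
    if (p > 0L) {
      i_ab <- drop(crossprod(X, mu))
      i_pb <- drop(crossprod(X, mu * glt))
      i_bb <- crossprod(X, mu * X)
    }
    if (free_shape) {
      score <- c(u_alpha, u_phi, u_beta)
      info <- matrix(0, p + 2L, p + 2L)
      info[1L, 1L] <- i_aa
      info[1L, 2L] <- info[2L, 1L] <- i_ap
      info[2L, 2L] <- i_pp
      if (p > 0L) {
        info[1L, 3:(p + 2L)] <- info[3:(p + 2L), 1L] <- i_ab
        info[2L, 3:(p + 2L)] <- info[3:(p + 2L), 2L] <- i_pb
        info[3:(p + 2L), 3:(p + 2L)] <- i_bb
      }
    } else {
      score <- c(u_alpha, u_beta)
      info <- matrix(0, p + 1L, p + 1L)
      info[1L, 1L] <- i_aa
      if (p > 0L) {
        info[1L, 2:(p + 1L)] <- info[2:(p + 1L), 1L] <- i_ab
        info[2:(p + 1L), 2:(p + 1L)] <- i_bb
      }
    }
    list(loglik = loglik, score = score, info = info)
  }
}

# Zero event times make log(t) undefined in the Weibull likelihood; shift
# them to half the smallest positive time with a warning.
shift_zero_times <- function(time) {
  zero <- time <= 0
  if (any(zero)) {
    pos <- time[time > 0]
    if (length(pos) == 0L) stop_data("all survival times are zero")
    warn(sprintf(
      "%d zero survival time(s) shifted to half the smallest positive time for Weibull fitting",
      sum(zero)
    ))
    time[zero] <- min(pos) / 2
  }
  time
}

#' Fit a parametric Weibull proportional-hazards regression model
#'
#' Maximises the Weibull log likelihood with hazard
#' `h(t|x) = gamma t^(gamma-1) exp(alpha + x'beta)` by Newton-Raphson in the
#' unconstrained parameterisation `(alpha, log gamma, beta)`. Regression
#' coefficients are therefore log hazard ratios, directly comparable to Cox
#' estimates. The null log likelihood (for the overall likelihood-ratio
#' test) comes from refitting with intercept and shape only.
#'
#' @param data A tibble/data frame containing `time`, `event` and the design
#'   columns.
#' @param terms Design column names in order (default: everything but
#'   `time`/`event`). May be empty for the intercept+shape null model.
#' @param fix_shape Optional fixed shape value `gamma`; `fix_shape = 1`
#'   fits the exponential sub-model.
#' @param control See [fit_control()].
#' @return A `survscan_fit` object with additional elements `intercept`,
#'   `log_shape`, `shape` and their standard errors, and the full
#'   variance-covariance matrix over `(alpha, log gamma, beta)`.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = 1)
#' fit_weibull(d, terms = character(), fix_shape = 1)$intercept # log(3/6)
#' @export
fit_weibull <- function(data, terms = NULL, fix_shape = NULL,
                        control = fit_control()) {
  if (is.null(terms)) terms <- setdiff(names(data), c("time", "event"))
  time <- shift_zero_times(data$time)
  event <- data$event
  n_events <- sum(event == 1)
  if (n_events == 0L) stop_data("no events in the data; model cannot be fitted")
  X <- if (length(terms) > 0L) {
    m <- as.matrix(data[terms]); storage.mode(m) <- "double"; m
  } else {
    matrix(numeric(0), nrow = length(time), ncol = 0L)
  }
  free_shape <- is.null(fix_shape)
  fix_phi <- if (free_shape) NULL else log(fix_shape)
  derivs <- weibull_machine(time, event, X, fix_phi)
  # exponential-model starting value: rate = events / total time
  alpha0 <- log(n_events / sum(time))
  theta0 <- c(alpha0, if (free_shape) 0, rep(0, length(terms)))
  nr <- newton_raphson(derivs, theta0, control)

  loglik_null <- if (length(terms) > 0L) {
    null_fit <- fit_weibull(data[c("time", "event")], terms = character(),
                            fix_shape = fix_shape, control = control)
    null_fit$loglik
  } else {
    nr$loglik
  }

  k <- if (free_shape) 2L else 1L
  beta_idx <- if (length(terms) > 0L) (k + 1L):(k + length(terms)) else integer(0)
  se_all <- sqrt(diag(nr$vcov))
  phi_hat <- if (free_shape) nr$theta[[2L]] else fix_phi
  structure(
    list(
      family = "weibull",
      terms = terms,
      coefficients = setNames(nr$theta[beta_idx], terms),
      std_errors = setNames(se_all[beta_idx], terms),
      intercept = nr$theta[[1L]],
      se_intercept = se_all[[1L]],
      log_shape = phi_hat,
      se_log_shape = if (free_shape) se_all[[2L]] else NA_real_,
      shape = exp(phi_hat),
      shape_fixed = !free_shape,
      vcov = nr$vcov,
      param_names = c("(Intercept)", if (free_shape) "log(shape)", terms),
      loglik = nr$loglik,
      loglik_null = loglik_null,
      n = length(time),
      n_events = n_events,
      converged = nr$converged,
      iterations = nr$iterations
    ),
    class = "survscan_fit"
  )
}
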