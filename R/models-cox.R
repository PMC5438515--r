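#' Newton-Raphson control parameters
#'
#' Convergence is declared when the relative change in the objective falls
#' below `tol_loglik` or the maximum absolute score falls below `tol_score`;
#' a step that decreases the objective is halved up to `max_halvings` times.
#'
#' @param max_iter Maximum Newton iterations.
#' @param tol_loglik Relative objective-change tolerance.
#' @param tol_score Max-absolute-score tolerance.
#' @param max_halvings Maximum step halvings per iteration.
#' @return A list of control parameters.
#' @export
fit_control <- function(max_iter = 30L, tol_loglik = 1e-10,
                        tol_score = 1e-8, max_halvings = 10L) {
  list(max_iter = max_iter, tol_loglik = tol_loglik,
       tol_score = tol_score, max_halvings = max_halvings)
}

# Breslow-ties log partial likelihood, score and information for the Cox
# model, fully vectorised: subjects are sorted by descending time so risk-set
# sums are cumulative sums, evaluated at the last index of each tie block.
cox_machine <- function(time, event, X) {
  o <- order(time, decreasing = TRUE)
  t_s <- time[o]
  e_s <- event[o] == 1
  X_s <- X[o, , drop = FALSE]
  p <- ncol(X)
  n <- length(t_s)
  # last index of each distinct-time block (sorted desc => block end holds
  # the cumulative sum over all subjects with time >= that value)
  block_end <- which(c(t_s[-n] != t_s[-1L], TRUE))
  block_id <- rep(seq_along(block_end), diff(c(0L, block_end)))
  # distinct times with >= 1 event, their death counts and covariate sums
  ev_blocks <- sort(unique(block_id[e_s]))
  d_k <- vapply(ev_blocks, function(b) sum(e_s & block_id == b), numeric(1))
  s_k <- t(vapply(ev_blocks, function(b) {
    colSums(X_s[e_s & block_id == b, , drop = FALSE])
  }, numeric(p)))
  if (p == 1L) s_k <- matrix(s_k, ncol = 1L)
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)

  function(beta) {
    eta <- drop(X_s %*% beta)
    w <- exp(eta)
    S0 <- cumsum(w)[block_end][ev_blocks]
    wX <- w * X_s
    S1 <- apply(wX, 2L, cumsum)[block_end, , drop = FALSE][ev_blocks, , drop = FALSE]
    # S2: cumulative sums of w * x_i * x_j for each pair
    S2 <- apply(wX[, pair_i, drop = FALSE] * X_s[, pair_j, drop = FALSE],
                2L, cumsum)[block_end, , drop = FALSE][ev_blocks, , drop = FALSE]
    loglik <- sum(eta[e_s]) - sum(d_k * log(S0))
    M <- S1 / S0
    U <- colSums(s_k) - colSums(d_k * M)
    info <- matrix(colSums(d_k * S2 / S0), p, p) - crossprod(sqrt(d_k) * M)
    list(loglik = loglik, score = U, info = info)
  }
}

# Generic damped Newton-Raphson maximiser over a derivs(theta) closure
# returning list(loglik, score, info). Returns theta, loglik, vcov, status.
newton_raphson <- function(derivs, theta0, control) {
  theta <- theta0
  d <- derivs(theta)
  if (!is.finite(d$loglik)) {
    stop_data("log-likelihood not finite at the starting values")
  }
  converged <- FALSE
  singular <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step) || anyNA(step) || any(!is.finite(step))) {
      singular <- TRUE
      break
    }
    new_theta <- theta + step
    new_d <- derivs(new_theta)
    halvings <- 0L
    while ((!is.finite(new_d$loglik) || new_d$loglik < d$loglik) &&
           halvings < control$max_halvings) {
      step <- step / 2
      halvings <- halvings + 1L
      new_theta <- theta + step
      new_d <- derivs(new_theta)
    }
    if (!is.finite(new_d$loglik) || new_d$loglik < d$loglik) {
      # no further improvement: converged if the objective has flattened to
      # within tolerance (float resolution), else rely on the score
      rel <- abs(new_d$loglik - d$loglik) / (abs(d$loglik) + 1)
      converged <- (is.finite(new_d$loglik) && rel < control$tol_loglik) ||
        max(abs(d$score)) < control$tol_score
      break
    }
    rel <- abs(new_d$loglik - d$loglik) / (abs(d$loglik) + 1)
    theta <- new_theta
    d <- new_d
    if (rel < control$tol_loglik || max(abs(d$score)) < control$tol_score) {
      converged <- TRUE
      break
    }
  }
  vcov <- tryCatch(solve(d$info), error = function(e) NULL)
  if (is.null(vcov) || anyNA(vcov) ||
      any(!is.finite(vcov)) || any(diag(vcov) <= 0)) {
    singular <- TRUE
    vcov <- matrix(NA_real_, length(theta), length(theta))
  }
  list(theta = theta, loglik = d$loglik, score = d$score, info = d$info,
       vcov = vcov, converged = converged && !singular,
       singular = singular, iterations = iter)
}

#' Fit a Cox proportional hazards model
#'
#' Maximises the Breslow-ties log partial likelihood by Newton-Raphson with
#' step halving. Standard errors come from the inverse observed information;
#' the null log partial likelihood is the partial likelihood at `beta = 0`.
#'
#' @param data A tibble/data frame containing `time`, `event` and the design
#'   columns.
#' @param terms Character vector naming the design columns, in order
#'   (default: every column other than `time` and `event`).
#' @param control See [fit_control()].
#' @return A `survscan_fit` object: coefficients, standard errors, the
#'   variance-covariance matrix, full/null log likelihoods, event counts and
#'   convergence diagnostics. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1, x = c(1, 0, 1, 0))
#' fit <- fit_cox(d)
#' tidy(fit)
#' @export
fit_cox <- function(data, terms = NULL, control = fit_control()) {
  if (is.null(terms)) terms <- setdiff(names(data), c("time", "event"))
  if (length(terms) == 0L) stop_usage("fit_cox needs at least one design column")
  time <- data$time
  event <- data$event
  n_events <- sum(event == 1)
  if (n_events == 0L) stop_data("no events in the data; model cannot be fitted")
  X <- as.matrix(data[terms])
  storage.mode(X) <- "double"
  derivs <- cox_machine(time, event, X)
  loglik_null <- derivs(rep(0, length(terms)))$loglik
  nr <- newton_raphson(derivs, rep(0, length(terms)), control)
  se <- sqrt(diag(nr$vcov))
  structure(
    list(
      family = "cox",
      terms = terms,
      coefficients = setNames(nr$theta, terms),
      std_errors = setNames(se, terms),
      vcov = nr$vcov,
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

#' @export
print.survscan_fit <- function(x, ...) {
  cat(sprintf(
    "<survscan_fit> %s model: n = %d, events = %d, %s in %d iteration(s)\n",
    x$family, x$n, x$n_events,
    if (x$converged) "converged" else "DID NOT CONVERGE", x$iterations
  ))
  print(tidy(x))
  invisible(x)
}
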