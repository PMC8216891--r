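## State-space separation of observation and process error in log-abundance
## series: a local level with drift (stochastic exponential growth),
##   x_t = x_{t-1} + u + w_t,  w_t ~ N(0, q)
##   y_t = x_t + v_t,          v_t ~ N(0, r)
## fitted by maximum likelihood via the prediction-error decomposition of
## the likelihood conditional on the first observation (diffuse
## initialization: under a flat prior the initial state given y_1 is
## N(y_1, r)).  A full likelihood with the initial state as a free
## parameter is unbounded as r -> 0 (the first observation's density
## diverges once x_1 can sit exactly on y_1), so the conditional form is
## the well-posed ML problem at these series lengths.  A density-dependent
## (Gompertz) process x_t = a + b x_{t-1} + w_t is available behind a flag.

.SS_MIN_LOG_SD <- log(1e-6)

## Kalman forward pass, conditioning on y_1.  Returns the log-likelihood
## (terms t = 2..T) and the filtered / predicted moments needed by the RTS
## smoother.  `b` is the state transition multiplier (1 for the drift
## model), `u` the state intercept.
.kalman_forward <- function(y, u, b, q, r) {
  n <- length(y)
  mf <- Pf <- mp <- Pp <- numeric(n)
  ll <- 0
  m <- y[1]
  P <- r
  mp[1] <- mf[1] <- m
  Pp[1] <- Pf[1] <- P
  for (t in seq_len(n)[-1]) {
    m <- u + b * m
    P <- b^2 * P + q
    mp[t] <- m
    Pp[t] <- P
    S <- P + r
    ll <- ll + stats::dnorm(y[t], m, sqrt(S), log = TRUE)
    K <- P / S
    m <- m + K * (y[t] - m)
    P <- (1 - K) * P
    mf[t] <- m
    Pf[t] <- P
  }
  list(loglik = ll, mf = mf, Pf = Pf, mp = mp, Pp = Pp)
}

## Rauch-Tung-Striebel backward pass on the forward output.
.rts_backward <- function(kf, b) {
  n <- length(kf$mf)
  ms <- kf$mf
  Ps <- kf$Pf
  if (n > 1) {
    for (t in (n - 1):1) {
      if (kf$Pp[t + 1] > 1e-300) {
        C <- kf$Pf[t] * b / kf$Pp[t + 1]
        ms[t] <- kf$mf[t] + C * (ms[t + 1] - kf$mp[t + 1])
        Ps[t] <- kf$Pf[t] + C^2 * (Ps[t + 1] - kf$Pp[t + 1])
      }
    }
  }
  list(mean = ms, var = pmax(Ps, 0))
}

#' Fit a state-space model to a positive abundance series
#'
#' Maximum-likelihood estimation of (process sd, observation sd, drift)
#' for the log-scale local-level-with-drift model, via bounded
#' quasi-Newton optimization from a grid of deterministic starting points
#' that spread the observed variability across process and observation
#' error.  The likelihood is the prediction-error decomposition
#' conditional on the first observation (diffuse initialization: the
#' initial state given \eqn{y_1} is \eqn{N(\log y_1, r)}), which keeps
#' the ML problem bounded.  Standard deviations are log-parameterized (so
#' constrained positive); boundary estimates at the numerical floor
#' (1e-6) are legal and indicate a negligible variance component.
#'
#' @param y Positive yearly abundance series, length >= 4.  Zeros are
#'   rejected unless a positive \code{offset} is supplied, in which case the
#'   model is fitted to \code{log(y + offset)}.
#' @param gompertz Logical; fit the density-dependent variant
#'   \eqn{x_t = a + b x_{t-1} + w_t} instead of the random walk with drift.
#' @param offset Non-negative constant added before taking logs.
#' @param n_starts Number of deterministic multi-start points (>= 5
#'   recommended; fewer are rejected).
#' @return A \code{state_space_fit} with elements \code{process_sd},
#'   \code{observation_sd}, \code{drift} (or \code{a}, \code{b} for the
#'   Gompertz variant), \code{initial_state} (smoothed initial
#'   log-state), \code{log_likelihood},
#'   \code{smoothed_states} and \code{smoothed_sd} (log scale), plus the
#'   input series.
#' @seealso [smooth_series()] for natural-scale smoothed abundances.
#' @export
fit_state_space <- function(y, gompertz = FALSE, offset = 0, n_starts = 5) {
  if (length(y) < 4) stop("series must have length >= 4")
  if (offset < 0) stop("offset must be non-negative")
  if (any(y + offset <= 0))
    stop("series contains non-positive values; supply a positive offset")
  if (n_starts < 5) stop("n_starts must be at least 5")
  x <- log(y + offset)
  n <- length(x)
  d <- diff(x)
  s2 <- max(stats::var(d), 1e-8)
  u0 <- mean(d)

  negll <- function(theta) {
    q <- exp(2 * theta[["lq"]])
    r <- exp(2 * theta[["lr"]])
    if (gompertz) {
      kf <- .kalman_forward(x, theta[["a"]], theta[["b"]], q, r)
    } else {
      kf <- .kalman_forward(x, theta[["u"]], 1, q, r)
    }
    -kf$loglik
  }

  fracs <- c(0.9, 0.5, 0.1, 0.99, 0.01, 0.75, 0.25)
  fracs <- fracs[seq_len(min(n_starts, length(fracs)))]
  starts <- lapply(fracs, function(f) {
    th <- c(lq = 0.5 * log(s2 * f), lr = 0.5 * log(s2 * (1 - f) / 2))
    if (gompertz) c(a = 0.5 * mean(x), b = 0.5, th) else c(u = u0, th)
  })
  lower <- c(lq = .SS_MIN_LOG_SD, lr = .SS_MIN_LOG_SD)
  upper <- c(lq = 10, lr = 10)
  if (gompertz) {
    lower <- c(a = -Inf, b = -2, lower)
    upper <- c(a = Inf, b = 2, upper)
  } else {
    lower <- c(u = -Inf, lower)
    upper <- c(u = Inf, upper)
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, negll, method = "L-BFGS-B",
                   lower = lower[names(th0)], upper = upper[names(th0)],
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("state-space optimizer failed to converge from any starting point")

  th <- best$par
  q <- exp(2 * th[["lq"]])
  r <- exp(2 * th[["lr"]])
  b <- if (gompertz) th[["b"]] else 1
  u <- if (gompertz) th[["a"]] else th[["u"]]
  kf <- .kalman_forward(x, u, b, q, r)
  sm <- .rts_backward(kf, b)
  structure(
    list(process_sd = sqrt(q), observation_sd = sqrt(r),
         drift = if (gompertz) NA_real_ else u,
         a = if (gompertz) u else NA_real_,
         b = if (gompertz) b else 1,
         gompertz = gompertz,
         initial_state = sm$mean[1],
         log_likelihood = kf$loglik,
         smoothed_states = sm$mean,
         smoothed_sd = sqrt(sm$var),
         series = y, offset = offset,
         convergence = best$convergence),
    class = "state_space_fit")
}

#' @export
print.state_space_fit <- function(x, ...) {
  cat("State-space fit (", if (x$gompertz) "Gompertz" else "local level + drift",
      "), T = ", length(x$series), "\n", sep = "")
  cat(sprintf("  process sd = %.4g, observation sd = %.4g",
              x$process_sd, x$observation_sd))
  if (!x$gompertz) cat(sprintf(", drift = %.4g", x$drift))
  cat(sprintf(", logLik = %.3f\n", x$log_likelihood))
  invisible(x)
}

#' Smoothed abundance series on the natural scale
#'
#' Runs the forward Kalman filter and backward RTS smoother at the fitted
#' parameters and back-transforms the smoothed posterior means with
#' \code{exp()}.
#'
#' @param fit A \code{state_space_fit}.
#' @param y The series the fit was produced from (checked).
#' @return Data frame with columns \code{raw}, \code{smoothed} (natural
#'   scale) and \code{smoothed_sd} (log scale).
#' @export
smooth_series <- function(fit, y = fit$series) {
  stopifnot(inherits(fit, "state_space_fit"))
  if (length(y) != length(fit$series))
    stop("series length does not match the fitted series")
  if (any(abs(y - fit$series) > 1e-8))
    stop("series does not match the one the model was fitted to")
  data.frame(raw = y,
             smoothed = exp(fit$smoothed_states) - fit$offset,
             smoothed_sd = fit$smoothed_sd)
}
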