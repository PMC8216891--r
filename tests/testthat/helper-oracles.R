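# Independent oracles and small generators shared across test files.

# Log-density of a multivariate normal via Cholesky (no package dependency).
ldmvnorm <- function(y, mu, S) {
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Brute-force Gaussian conditioning oracle for the local-level-with-drift
# state-space model, conditional on the first observation (the model's
# initial state given y_1 is N(y_1, r); states accumulate drift u and
# process variance q; observations t >= 2 add noise variance r).
# Returns the conditional log-likelihood of y[2:T] and the posterior
# mean/variance of every state given the full series.
ss_conditioning_oracle <- function(y, u, q, r) {
  T <- length(y)
  idx <- 2:T
  mu_x <- y[1] + u * (0:(T - 1))
  Cxx <- outer(1:T, 1:T, function(s, t) r + q * (pmin(s, t) - 1))
  Cyy <- Cxx[idx, idx, drop = FALSE] + r * diag(T - 1)
  Cxy <- Cxx[, idx, drop = FALSE]
  mu_y <- mu_x[idx]
  w <- solve(Cyy, y[idx] - mu_y)
  list(loglik = ldmvnorm(y[idx], mu_y, Cyy),
       mean = as.numeric(mu_x + Cxy %*% w),
       var = pmax(diag(Cxx - Cxy %*% solve(Cyy, t(Cxy))), 0))
}

# Random regression design in the package's design-table layout.
random_design <- function(n, seed, response = "Fs") {
  set.seed(seed)
  cols <- c("ar", "P_winter", "P_spring_summer", "N_chamois", "N_deer")
  d <- as.data.frame(sapply(cols, function(j)
    as.numeric(standardize(rnorm(n)))))
  d$response <- rnorm(n)
  d$year <- seq_len(n)
  attr(d, "response_name") <- response
  d
}

# Design whose response follows a known linear model in the named columns.
linear_design <- function(n, seed, beta, sigma, intercept = 0.5,
                          response = "Fs") {
  d <- random_design(n, seed, response)
  xb <- if (length(beta))
    as.matrix(d[, names(beta), drop = FALSE]) %*% beta else 0
  d$response <- as.numeric(intercept + xb + rnorm(n, 0, sigma))
  d
}

# Small well-formed raw count table (wide dialect) for IO tests.
toy_count_table <- function() {
  data.frame(year = 2001:2003,
             kid = c(40, 35, 30), yearling = c(20, 22, 18),
             adult_female = c(100, 95, 90), adult_male = c(60, 58, 55),
             unknown_1plus = c(10, 0, 4), unknown_2plus = c(8, 6, 6))
}
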