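## Three-variable recursive path models: deer abundance (X) -> vital-rate
## mediator (M) -> population growth (Y), with no direct X -> Y edge, so the
## implied model has 1 degree of freedom (6 second moments, 5 free
## parameters).  Maximum-likelihood fitting of the two structural equations
## coincides with the two OLS regressions; the chi-square discrepancy tests
## the vanishing partial correlation of X and Y given M.

#' Fit one mediation path model
#'
#' Variables are z-scored, the standardized paths \eqn{a} (X to M) and
#' \eqn{b} (M to Y) are estimated by least squares, and the implied
#' covariance \eqn{\Sigma(\theta)} is compared with the sample covariance
#' via the ML discrepancy \eqn{F = \ln|\Sigma| + tr(S\Sigma^{-1}) - \ln|S|
#' - 3}.  The chi-square statistic is \eqn{(n-1) F} (Wishart convention;
#' \eqn{n F} behind \code{chisq_scale = "n"}), with
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df (n-1))}} and the usual
#' close-fit p-value (noncentrality 0.05^2 df (n-1)).  The indirect effect
#' is \eqn{ab} with delta-method standard error
#' \eqn{\sqrt{a^2 SE_b^2 + b^2 SE_a^2}} and normal 95\% limits; a seeded
#' bootstrap percentile interval is available as an alternative.
#'
#' @param data Data frame of aligned triplets (e.g. from
#'   [build_path_data()]).
#' @param mediator Column name of the mediator (\code{"Br"}, \code{"Ks"},
#'   \code{"Fs"} or \code{"Ms"}).
#' @param exposure,outcome Column names of the exogenous driver and the
#'   outcome (defaults \code{"N_deer"}, \code{"Y"}).
#' @param direct Add the direct X to Y edge (saturates the model: df = 0,
#'   chi-square 0).
#' @param chisq_scale \code{"n-1"} (Wishart, default) or \code{"n"}.
#' @param boot_ci Number of bootstrap resamples for a percentile indirect
#'   CI (0 = delta method only).
#' @param seed Seed for the bootstrap.
#' @return A \code{path_fit}: standardized paths \code{a}, \code{b} (with
#'   SEs), \code{indirect} (estimate, se, lcl, ucl), \code{chisq},
#'   \code{df}, \code{p_value}, \code{rmsea}, \code{rmsea_p}, \code{aic},
#'   \code{n}.
#' @export
fit_path_model <- function(data, mediator,
                           exposure = "N_deer", outcome = "Y",
                           direct = FALSE,
                           chisq_scale = c("n-1", "n"),
                           boot_ci = 0, seed = 1) {
  chisq_scale <- match.arg(chisq_scale)
  cols <- c(exposure, mediator, outcome)
  if (!all(cols %in% names(data)))
    stop("data must have columns ", paste(cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols]
  n <- nrow(d)
  if (n < 4) stop("need at least 4 complete triplets")
  if (n < 10)
    warning("only ", n, " complete triplets; at least 10 data points per ",
            "variable are conventionally required in causal analysis")
  z <- as.data.frame(lapply(d, function(x) as.numeric(standardize(x))))
  names(z) <- c("X", "M", "Y")
  S <- stats::cov(as.matrix(z))
  if (abs(det(S)) < 1e-12) stop("singular sample covariance")

  fa <- stats::lm(M ~ X, data = z)
  a <- stats::coef(fa)[["X"]]
  se_a <- summary(fa)$coefficients["X", 2]
  if (direct) {
    fb <- stats::lm(Y ~ M + X, data = z)
  } else {
    fb <- stats::lm(Y ~ M, data = z)
  }
  b <- stats::coef(fb)[["M"]]
  se_b <- summary(fb)$coefficients["M", 2]

  ## implied covariance from the path coefficients and ML residual
  ## variances (moments on the same n-1 divisor as S)
  phi <- S[1, 1]
  psi1 <- S[2, 2] - a^2 * phi
  Sigma <- matrix(0, 3, 3, dimnames = dimnames(S))
  Sigma[1, 1] <- phi
  Sigma[1, 2] <- Sigma[2, 1] <- a * phi
  Sigma[2, 2] <- a^2 * phi + psi1
  if (direct) {
    cfb <- stats::coef(fb)
    bx <- cfb[["X"]]
    psi2 <- S[3, 3] - 2 * b * S[2, 3] - 2 * bx * S[1, 3] +
      2 * b * bx * S[1, 2] + b^2 * S[2, 2] + bx^2 * S[1, 1]
    Sigma[1, 3] <- Sigma[3, 1] <- b * Sigma[1, 2] + bx * phi
    Sigma[2, 3] <- Sigma[3, 2] <- b * Sigma[2, 2] + bx * Sigma[1, 2]
    Sigma[3, 3] <- b * Sigma[2, 3] + bx * Sigma[1, 3] + psi2
    df <- 0L
    q <- 6L
  } else {
    psi2 <- S[3, 3] - b^2 * S[2, 2]
    Sigma[1, 3] <- Sigma[3, 1] <- a * b * phi
    Sigma[2, 3] <- Sigma[3, 2] <- b * Sigma[2, 2]
    Sigma[3, 3] <- b^2 * Sigma[2, 2] + psi2
    df <- 1L
    q <- 5L
  }

  Fml <- as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sigma))) -
      determinant(S, logarithm = TRUE)$modulus - 3)
  Fml <- max(Fml, 0)
  scale_n <- if (chisq_scale == "n-1") n - 1 else n
  chisq <- scale_n * Fml
  p_value <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else 0
  rmsea_p <- if (df > 0)
    stats::pchisq(chisq, df, ncp = 0.05^2 * df * (n - 1),
                  lower.tail = FALSE) else NA_real_

  Sml <- S * (n - 1) / n
  ll <- -n / 2 * (3 * log(2 * pi) +
                    as.numeric(determinant(Sigma, TRUE)$modulus) +
                    sum(diag(Sml %*% solve(Sigma))))
  aic <- -2 * ll + 2 * q

  ind <- a * b
  se_ind <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  ci <- c(ind - 1.96 * se_ind, ind + 1.96 * se_ind)
  boot <- NULL
  if (boot_ci > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(boot_ci), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      zz <- z[idx, ]
      if (stats::sd(zz$X) == 0 || stats::sd(zz$M) == 0) return(NA_real_)
      (stats::cov(zz$X, zz$M) / stats::var(zz$X)) *
        (stats::cov(zz$M, zz$Y) / stats::var(zz$M))
    }, numeric(1))
    boot <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
  }

  structure(
    list(mediator = mediator, exposure = exposure, outcome = outcome,
         a = a, se_a = se_a, b = b, se_b = se_b,
         indirect = ind, se_indirect = se_ind,
         indirect_lcl = ci[1], indirect_ucl = ci[2],
         indirect_boot_ci = boot,
         chisq = chisq, df = df, p_value = p_value,
         rmsea = rmsea, rmsea_p = rmsea_p,
         log_likelihood = ll, aic = aic, n = n,
         chisq_scale = chisq_scale),
    class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Path model: ", x$exposure, " -> ", x$mediator, " -> ", x$outcome,
      "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  indirect = %.3f [%.3f, %.3f]\n",
              x$indirect, x$indirect_lcl, x$indirect_ucl))
  cat(sprintf("  chisq(%d) = %.3f, p = %.3f, RMSEA = %.3f, AIC = %.1f\n",
              x$df, x$chisq, x$p_value, x$rmsea, x$aic))
  invisible(x)
}

#' Rank competing path models and flag acceptable fits
#'
#' Sorts by AIC and flags each model as accepted when its chi-square
#' p-value exceeds \code{alpha} and its RMSEA does not exceed
#' \code{rmsea_max} (conventional close-fit cut-off 0.06 by default; a
#' looser threshold can be supplied).
#'
#' @param fits List of \code{path_fit} objects on the same sample.
#' @param rmsea_max RMSEA acceptance threshold (default 0.06).
#' @param alpha Chi-square p-value threshold (default 0.05).
#' @return Data frame sorted by AIC: \code{mediator}, \code{chisq},
#'   \code{df}, \code{p_value}, \code{rmsea}, \code{rmsea_p}, \code{aic},
#'   \code{indirect}, \code{indirect_lcl}, \code{indirect_ucl},
#'   \code{accepted}.
#' @export
compare_path_models <- function(fits, rmsea_max = 0.06, alpha = 0.05) {
  if (length(fits) < 2) stop("need at least 2 path fits to compare")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1)
    stop("path fits use different sample sizes: ",
         paste(unique(ns), collapse = ", "))
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(mediator = f$mediator, chisq = f$chisq, df = f$df,
               p_value = f$p_value, rmsea = f$rmsea, rmsea_p = f$rmsea_p,
               aic = f$aic, indirect = f$indirect,
               indirect_lcl = f$indirect_lcl,
               indirect_ucl = f$indirect_ucl,
               accepted = !is.na(f$p_value) && f$p_value > alpha &&
                 f$rmsea <= rmsea_max)
  }))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  out
}
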