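## Candidate-set OLS fitting, AICc ranking, Akaike-weight averaging and the
## diagnostic battery (VIF, Durbin-Watson, bootstrap optimism-corrected
## RMSE, robust refit).

.design_predictors <- c("P_winter", "P_spring_summer", "N_chamois", "N_deer")

#' Specify one candidate regression model
#'
#' A model is the 1-year autoregressive term (always present) plus up to
#' three main covariates and at most one interaction pair; an interaction
#' requires both of its mains.  These complexity limits guard parameter
#' estimation at the short time-series lengths the package targets; pass
#' \code{validate = FALSE} only for diagnostic "global" models.
#'
#' @param name Model label (e.g. \code{"m.13.ks"}).
#' @param terms Character vector over \code{"ar"}, \code{"P_winter"},
#'   \code{"P_spring_summer"}, \code{"N_chamois"}, \code{"N_deer"} and at
#'   most one \code{"A:B"} interaction.
#' @param response Response name the spec belongs to.
#' @param validate Enforce the complexity rule (default \code{TRUE}).
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(name, terms, response = NA_character_,
                       validate = TRUE) {
  terms <- unique(as.character(terms))
  if (!"ar" %in% terms) terms <- c("ar", terms)
  is_int <- grepl(":", terms, fixed = TRUE)
  mains <- setdiff(terms[!is_int], "ar")
  ints <- terms[is_int]
  if (!all(mains %in% .design_predictors))
    stop("unknown term(s): ", paste(setdiff(mains, .design_predictors),
                                    collapse = ", "))
  for (int in ints) {
    parts <- strsplit(int, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% .design_predictors))
      stop("malformed interaction term: ", int)
    if (validate && !all(parts %in% mains))
      stop("interaction ", int, " requires both main effects in the model")
  }
  if (validate) {
    if (length(mains) > 3)
      stop("model ", name, " has ", length(mains),
           " main covariates; at most 3 are allowed")
    if (length(ints) > 1)
      stop("model ", name, " has ", length(ints),
           " interactions; at most 1 is allowed")
  }
  structure(list(name = name, terms = c("ar", mains, ints),
                 response = response),
            class = "model_spec")
}

.default_structures <- list(
  m.1  = c("P_winter", "N_chamois", "P_winter:N_chamois", "N_deer"),
  m.2  = c("P_spring_summer", "N_chamois", "P_spring_summer:N_chamois"),
  m.3  = c("P_winter", "P_spring_summer"),
  m.4  = c("P_spring_summer", "N_deer", "P_spring_summer:N_deer",
           "N_chamois"),
  m.5  = c("P_winter", "N_deer", "P_winter:N_deer"),
  m.6  = c("P_spring_summer", "N_deer", "P_spring_summer:N_deer"),
  m.7  = c("P_winter", "N_deer", "N_chamois"),
  m.8  = c("P_spring_summer", "N_deer", "N_chamois"),
  m.9  = c("P_winter", "N_deer"),
  m.10 = c("P_spring_summer", "N_deer"),
  m.11 = c("N_deer", "N_chamois"),
  m.12 = c("N_deer"),
  m.13 = c("P_winter", "N_chamois", "P_winter:N_chamois"),
  m.14 = c("P_spring_summer", "N_chamois"),
  m.15 = c("P_winter", "N_chamois"),
  m.16 = character(0),
  m.17 = c("P_winter"),
  m.18 = c("P_spring_summer"),
  m.19 = c("N_chamois")
)

## Structures m.2, m.3, m.10, m.14 and m.16 are reconstructed fill-ins
## (simple additive/interactive complements of the published 14); they are
## fully overridable through the `structures` argument.

#' Build the default 19-model candidate set for a response
#'
#' Nineteen autoregressive linear models spanning contrasting biological
#' hypotheses: climate-only, density-only, competitor-only, additive and
#' single-interaction combinations.  Lag shifting is handled by the design
#' table, so the same structures serve every response.
#'
#' @param response Response name (\code{"Br"}, \code{"Ks"}, \code{"Fs"},
#'   \code{"Ms"}); used to suffix model names (e.g. \code{m.13.ks}).
#' @param structures Optional named list of character term vectors
#'   overriding the defaults; each entry is validated against the
#'   complexity rule.
#' @return List of [model_spec()] objects.
#' @export
build_model_set <- function(response = c("Br", "Ks", "Fs", "Ms"),
                            structures = NULL) {
  response <- match.arg(response)
  if (is.null(structures)) structures <- .default_structures
  suffix <- tolower(response)
  specs <- lapply(names(structures), function(nm) {
    model_spec(paste0(nm, ".", suffix), structures[[nm]],
               response = response)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  specs
}

## Interaction columns get syntactic internal names ("A.x.B") so that
## formula interfaces accept them; `labels` maps internal -> display names.
.model_frame <- function(design, spec) {
  resp <- design$response
  X <- data.frame(row.names = seq_len(nrow(design)))
  labels <- c("(Intercept)" = "(Intercept)")
  for (term in spec$terms) {
    safe <- gsub(":", ".x.", term, fixed = TRUE)
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      X[[safe]] <- design[[parts[1]]] * design[[parts[2]]]
    } else {
      X[[safe]] <- design[[term]]
    }
    labels[safe] <- term
  }
  list(y = resp, X = X, labels = labels)
}

.relabel_terms <- function(terms, labels) {
  terms <- sub("^`|`$", "", terms)
  out <- unname(labels[terms])
  ifelse(is.na(out), terms, out)
}

#' Fit one candidate model by ordinary least squares
#'
#' Exact least-squares fit with a Gaussian maximum-likelihood
#' log-likelihood (so AICc values are internally consistent across the
#' candidate set), coefficient table with t-based 95\% confidence limits,
#' adjusted R-squared, per-term variance inflation factors (interaction
#' columns treated as predictors in their own right) and the Durbin-Watson
#' statistic of the time-ordered residuals.
#'
#' @param design Design table from [build_design()].
#' @param spec A [model_spec()].
#' @return A \code{vr_fit} object.  \code{k} counts intercept, slopes and
#'   the residual variance; \code{aicc} is \code{NA} when the
#'   small-sample correction is undefined (\code{n - k - 1 <= 0}), which
#'   can happen for diagnostic global models on very short series.
#' @export
fit_ols <- function(design, spec) {
  mf <- .model_frame(design, spec)
  dat <- cbind(data.frame(.y = mf$y), mf$X)
  names(dat) <- c(".y", names(mf$X))
  qx <- qr(cbind(1, as.matrix(mf$X)))
  if (qx$rank < ncol(mf$X) + 1) {
    Xm <- cbind(`(Intercept)` = 1, as.matrix(mf$X))
    drop_idx <- setdiff(seq_len(ncol(Xm)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient design for model ", spec$name, ": column(s) ",
         paste(colnames(Xm)[drop_idx], collapse = ", "),
         " are collinear with the rest")
  }
  fit <- stats::lm(.y ~ ., data = dat)
  n <- nrow(dat)
  p <- length(stats::coef(fit))
  k <- p + 1
  ll <- as.numeric(stats::logLik(fit))
  sm <- summary(fit)
  est <- sm$coefficients
  tcrit <- stats::qt(0.975, df = n - p)
  coefs <- data.frame(term = .relabel_terms(rownames(est), mf$labels),
                      estimate = est[, 1], se = est[, 2],
                      t = est[, 3],
                      lcl = est[, 1] - tcrit * est[, 2],
                      ucl = est[, 1] + tcrit * est[, 2],
                      row.names = NULL)
  v <- if (ncol(mf$X) >= 2) {
    vv <- vif(mf$X)
    stats::setNames(vv, .relabel_terms(names(vv), mf$labels))
  } else NULL
  structure(
    list(spec = spec, lm = fit, coefficients = coefs,
         residuals = stats::residuals(fit),
         adj_r2 = sm$adj.r.squared, log_likelihood = ll,
         n = n, k = k,
         aicc = if (n - k - 1 > 0) aicc(ll, k = k, n = n) else NA_real_,
         vif = v,
         durbin_watson = .dw_statistic(stats::residuals(fit))),
    class = "vr_fit")
}

#' @export
print.vr_fit <- function(x, ...) {
  cat("Model", x$spec$name, "(n =", x$n, ", AICc =",
      sprintf("%.2f", x$aicc), ", adj R2 =",
      sprintf("%.3f", x$adj_r2), ")\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}, with \eqn{k} counting every
#' fitted parameter including the residual variance.  Requires
#' \eqn{n - k - 1 > 0}.
#'
#' @param object A \code{vr_fit}, an \code{lm}, or a numeric
#'   log-likelihood (then supply \code{k} and \code{n}).
#' @param k,n Parameter count and sample size (numeric method only).
#' @param ... Unused.
#' @return AICc value.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.numeric <- function(object, k, n, ...) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n - k - 1 > 0 (n = ", n, ", k = ", k, ")")
  -2 * object + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aicc.lm <- function(object, ...) {
  k <- length(stats::coef(object)) + 1
  aicc(as.numeric(stats::logLik(object)), k = k,
       n = stats::nobs(object))
}

#' @rdname aicc
#' @export
aicc.vr_fit <- function(object, ...) object$aicc

#' Rank candidate fits and compute Akaike weights
#'
#' @param fits List of \code{vr_fit} objects on identical data (same
#'   response and row count).
#' @return Data frame sorted by AICc: \code{model}, \code{aicc},
#'   \code{delta}, \code{weight} (\eqn{w_i = e^{-\Delta_i/2}/\sum_j
#'   e^{-\Delta_j/2}}), \code{adj_r2}.
#' @export
rank_and_weight <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  resp <- unique(vapply(fits, function(f) f$spec$response, character(1)))
  if (length(resp) > 1)
    stop("fits mix responses: ", paste(resp, collapse = ", "))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1)
    stop("fits were made on different sample sizes")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  if (anyNA(a))
    stop("AICc is undefined for model(s) ",
         paste(vapply(fits[is.na(a)], function(f) f$spec$name,
                      character(1)), collapse = ", "))
  delta <- a - min(a)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = vapply(fits, function(f) f$spec$name,
                                   character(1)),
                    aicc = a, delta = delta, weight = w,
                    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
                    row.names = NULL)
  out[order(out$delta), ]
}

#' Average coefficients across well-supported models
#'
#' Renormalizes Akaike weights over the models with \eqn{\Delta AICc}
#' below \code{delta_max} and averages each term's coefficient.  The
#' default full (shrinkage) averaging lets a term absent from a model
#' contribute an estimate of 0 with variance 0; conditional averaging
#' renormalizes over the models actually containing the term.
#' Unconditional standard errors follow the multimodel-inference
#' convention \eqn{\bar{SE} = \sum_i w_i \sqrt{SE_i^2 + (\beta_i -
#' \bar\beta)^2}}, with normal 95\% limits \eqn{\bar\beta \pm 1.96
#' \bar{SE}}.
#'
#' @param fits List of \code{vr_fit} objects.
#' @param delta_max AICc-difference cut-off for the averaged subset
#'   (default 4).
#' @param method \code{"full"} (default) or \code{"conditional"}.
#' @return Data frame \code{term}, \code{estimate}, \code{se}, \code{lcl},
#'   \code{ucl}; attributes \code{"models"} (subset labels) and
#'   \code{"weights"}.
#' @export
average_models <- function(fits, delta_max = 4,
                           method = c("full", "conditional")) {
  method <- match.arg(method)
  rk <- rank_and_weight(fits)
  keep <- rk$model[rk$delta < delta_max]
  if (!length(keep)) stop("no models with delta AICc < ", delta_max)
  sel <- fits[vapply(fits, function(f) f$spec$name %in% keep, logical(1))]
  w <- vapply(sel, function(f) exp(-(f$aicc - min(rk$aicc)) / 2), numeric(1))
  w <- w / sum(w)
  terms <- unique(unlist(lapply(sel, function(f) f$coefficients$term)))
  rows <- lapply(terms, function(tm) {
    est <- se <- numeric(length(sel))
    has <- logical(length(sel))
    for (i in seq_along(sel)) {
      co <- sel[[i]]$coefficients
      j <- match(tm, co$term)
      has[i] <- !is.na(j)
      if (has[i]) {
        est[i] <- co$estimate[j]
        se[i] <- co$se[j]
      }
    }
    if (method == "full") {
      wt <- w
    } else {
      wt <- ifelse(has, w, 0)
      wt <- wt / sum(wt)
    }
    b <- sum(wt * est)
    s <- sum(wt * sqrt(se^2 + (est - b)^2))
    data.frame(term = tm, estimate = b, se = s,
               lcl = b - 1.96 * s, ucl = b + 1.96 * s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- keep
  attr(out, "weights") <- stats::setNames(w, vapply(sel, function(f)
    f$spec$name, character(1)))
  attr(out, "method") <- method
  out
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R_j^2)} from regressing each explanatory column on
#' the others (intercept included).  Interaction columns are screened as
#' predictors in their own right.  Perfect collinearity yields \code{Inf},
#' not an error.
#'
#' @param X Data frame or matrix of explanatory columns (no intercept), or
#'   a \code{vr_fit}.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  if (inherits(X, "vr_fit")) {
    if (is.null(X$vif)) stop("fit has fewer than 2 explanatory columns")
    return(X$vif)
  }
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 explanatory columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

.dw_statistic <- function(e) {
  sum(diff(e)^2) / sum(e^2)
}

#' Durbin-Watson test with a permutation p-value
#'
#' The classical first-order autocorrelation statistic
#' \eqn{DW = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2} (about 2 under
#' independence), with a two-sided p-value obtained by permuting the
#' residual order (the exact small-sample null is impractical; the
#' statistic itself is the standard one).
#'
#' @param residuals Time-ordered residuals, length >= 3, not all zero.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
durbin_watson <- function(residuals, n_perm = 10000, seed = 1) {
  e <- as.numeric(residuals)
  if (length(e) < 3) stop("need at least 3 residuals")
  if (all(e == 0)) stop("Durbin-Watson undefined for all-zero residuals")
  obs <- .dw_statistic(e)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    .dw_statistic(sample(e)), numeric(1))
  p_lo <- (sum(perm <= obs) + 1) / (n_perm + 1)
  p_hi <- (sum(perm >= obs) + 1) / (n_perm + 1)
  list(statistic = obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

#' Bootstrap optimism-corrected RMSE
#'
#' Internal-validation estimate of prediction error: the apparent RMSE of
#' the model on the full data, plus the mean bootstrap optimism (RMSE of
#' each bootstrap-refitted model on the original data minus its RMSE on
#' its own bootstrap sample).  Rank-deficient resamples are redrawn (at
#' most 10 retries each).
#'
#' @param design Design table from [build_design()].
#' @param spec A [model_spec()].
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @return List with \code{apparent}, \code{optimism} and \code{corrected}
#'   RMSE.
#' @export
bootstrap_rmse <- function(design, spec, B = 200, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  if (nrow(design) < 8) stop("need at least 8 rows for the bootstrap")
  mf <- .model_frame(design, spec)
  X <- cbind(1, as.matrix(mf$X))
  y <- mf$y
  n <- length(y)
  beta <- qr.solve(X, y)
  rmse <- function(yy, pred) sqrt(mean((yy - pred)^2))
  apparent <- rmse(y, X %*% beta)
  set.seed(seed)
  optimism <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:11) {
      if (try == 11)
        stop("bootstrap resample remained rank-deficient after 10 retries")
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank == ncol(X)) break
    }
    bb <- qr.solve(Xb, y[idx])
    optimism[b] <- rmse(y, X %*% bb) - rmse(y[idx], Xb %*% bb)
  }
  list(apparent = apparent, optimism = mean(optimism),
       corrected = apparent + mean(optimism))
}

#' Robust (Huber M-estimation) refit of a candidate model
#'
#' Iteratively reweighted least squares with the Huber psi function
#' (tuning constant 1.345 on the MAD residual scale), convergence tolerance
#' 1e-8, at most 200 iterations.  Used to check whether an OLS slope
#' survives downweighting of outlying years.
#'
#' @param design Design table from [build_design()].
#' @param spec A [model_spec()].
#' @return List with \code{coefficients} (term, estimate, se),
#'   \code{weights} (final IRLS weights) and the underlying
#'   \code{MASS::rlm} fit.
#' @export
robust_fit <- function(design, spec) {
  mf <- .model_frame(design, spec)
  dat <- cbind(data.frame(.y = mf$y), mf$X)
  names(dat) <- c(".y", names(mf$X))
  fit <- MASS::rlm(.y ~ ., data = dat, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 200, acc = 1e-8)
  if (!fit$converged)
    stop("robust IRLS did not converge within 200 iterations")
  sm <- summary(fit)$coefficients
  terms <- .relabel_terms(rownames(sm), mf$labels)
  list(coefficients = data.frame(term = terms, estimate = sm[, 1],
                                 se = sm[, 2], row.names = NULL),
       weights = fit$w, rlm = fit)
}
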