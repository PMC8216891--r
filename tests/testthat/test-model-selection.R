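# OLS candidate fitting, AICc ranking/averaging and the diagnostic battery.

test_that("model specifications enforce the complexity rule", {
  sp <- model_spec("m.x", c("P_winter", "N_deer"))
  expect_true("ar" %in% sp$terms)
  expect_error(model_spec("m.bad", c("P_winter", "P_spring_summer",
                                     "N_chamois", "N_deer")),
               "at most 3")
  expect_error(model_spec("m.bad2", c("P_winter", "P_winter:N_chamois")),
               "requires both")
  expect_error(model_spec("m.bad3",
                          c("P_winter", "N_chamois", "N_deer",
                            "P_winter:N_chamois", "P_winter:N_deer")),
               "at most 1")
  expect_error(model_spec("m.bad4", "snow_depth"), "unknown term")
})

test_that("the default candidate set has 19 valid autoregressive models", {
  specs <- build_model_set("Ks")
  expect_length(specs, 19)
  expect_true(all(vapply(specs, function(s) "ar" %in% s$terms, logical(1))))
  expect_true(all(grepl("\\.ks$", names(specs))))
  for (s in specs) {
    mains <- setdiff(s$terms[!grepl(":", s$terms)], "ar")
    expect_lte(length(mains), 3)
    expect_lte(sum(grepl(":", s$terms)), 1)
  }
  # the AR-only null model is part of the set
  expect_true(any(vapply(specs, function(s)
    identical(s$terms, "ar"), logical(1))))
  # user overrides are validated
  expect_error(build_model_set("Ks", structures = list(
    m.1 = c("P_winter", "P_spring_summer", "N_chamois", "N_deer"))),
    "at most 3")
})

test_that("OLS fits are exact and match the normal-equation oracle", {
  d <- data.frame(response = c(1, 2, 3), ar = c(0, 1, 2), year = 1:3)
  attr(d, "response_name") <- "Br"
  f <- suppressWarnings(
    fit_ols(d, model_spec("m.toy", character(0), response = "Br")))
  expect_equal(f$coefficients$estimate,
               c(1, 1), tolerance = 1e-10)
  expect_true(all(abs(f$residuals) < 1e-10))

  for (i in 1:20) {
    d2 <- random_design(30, 100 + i)
    sp <- model_spec("m.r", c("P_winter", "N_deer", "P_winter:N_deer"),
                     response = "Fs")
    f2 <- fit_ols(d2, sp)
    X <- cbind(1, d2$ar, d2$P_winter, d2$N_deer, d2$P_winter * d2$N_deer)
    beta <- solve(t(X) %*% X, t(X) %*% d2$response)
    ord <- match(c("(Intercept)", "ar", "P_winter", "N_deer",
                   "P_winter:N_deer"), f2$coefficients$term)
    expect_lt(max(abs(f2$coefficients$estimate[ord] - beta)), 1e-10)
    # row order invariance
    perm <- sample(nrow(d2))
    d3 <- d2[perm, ]
    attr(d3, "response_name") <- "Fs"
    f3 <- fit_ols(d3, sp)
    expect_lt(max(abs(f3$coefficients$estimate[ord] - beta)), 1e-12 + 1e-10)
  }
})

test_that("rank-deficient designs raise an error naming the collinear column", {
  d <- random_design(20, 131)
  d$N_deer <- d$P_winter
  expect_error(fit_ols(d, model_spec("m.c", c("P_winter", "N_deer"),
                                     response = "Fs")),
               "collinear")
})

test_that("AICc formula, limits and ordering", {
  expect_equal(aicc(-10, k = 3, n = 10) - (-2 * -10 + 2 * 3), 4)
  expect_lt(abs(aicc(-10, k = 3, n = 1e5) - (-2 * -10 + 2 * 3)), 1e-3)
  expect_error(aicc(-10, k = 9, n = 10), "undefined")

  # agreement with an independent RSS-based reimplementation on lm fits
  set.seed(137)
  for (i in 1:10) {
    n <- 25
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1 + 0.5 * x1 + rnorm(n)
    f1 <- lm(y ~ x1); f2 <- lm(y ~ x1 + x2)
    ref <- function(fit, k) {
      rss <- sum(residuals(fit)^2)
      ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
      -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    }
    expect_equal(aicc(f1), ref(f1, 3), tolerance = 1e-10)
    expect_equal(aicc(f2), ref(f2, 4), tolerance = 1e-10)
    expect_equal(aicc(f1) < aicc(f2), ref(f1, 3) < ref(f2, 4))
  }
})

test_that("Akaike weights: closed-form values, normalization, monotonicity", {
  mock <- function(name, aicc_val) {
    structure(list(spec = model_spec(name, "P_winter", response = "Fs"),
                   aicc = aicc_val, n = 27, adj_r2 = 0.5),
              class = "vr_fit")
  }
  one <- rank_and_weight(list(mock("m.a", 100)))
  expect_equal(one$delta, 0)
  expect_equal(one$weight, 1)

  # delta pair {0, 2.25}: the textbook two-model weight split
  two <- rank_and_weight(list(mock("m.a", 100), mock("m.b", 102.25)))
  expect_equal(two$weight, c(0.7549, 0.2451), tolerance = 1e-4)

  set.seed(139)
  many <- rank_and_weight(lapply(1:8, function(i)
    mock(paste0("m.", i), 100 + runif(1, 0, 10))))
  expect_equal(sum(many$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(many$weight) <= 1e-12))
  expect_equal(min(many$delta), 0)
})

test_that("model averaging: identity, degenerate variance and modes", {
  d <- linear_design(27, 149, c(ar = 0.1, N_deer = 0.2), 0.05)
  f1 <- fit_ols(d, model_spec("m.12.fs", "N_deer", response = "Fs"))
  av1 <- average_models(list(f1))
  expect_equal(av1$estimate, f1$coefficients$estimate)
  expect_equal(av1$se, f1$coefficients$se)

  # two models with identical estimates average to themselves
  f2 <- fit_ols(d, model_spec("m.12b.fs", "N_deer", response = "Fs"))
  av2 <- average_models(list(f1, f2))
  expect_equal(av2$estimate, f1$coefficients$estimate)
  expect_equal(av2$se, f1$coefficients$se, tolerance = 1e-12)

  # full averaging shrinks a term absent from part of the subset;
  # conditional averaging does not (weak effect keeps both models in play)
  dw <- linear_design(27, 151, c(ar = 0.02, N_deer = 0.03), 0.1)
  g1 <- fit_ols(dw, model_spec("m.12.fs", "N_deer", response = "Fs"))
  g3 <- fit_ols(dw, model_spec("m.16.fs", character(0), response = "Fs"))
  full <- average_models(list(g1, g3), delta_max = Inf)
  cond <- average_models(list(g1, g3), delta_max = Inf,
                         method = "conditional")
  j <- match("N_deer", full$term)
  raw <- g1$coefficients$estimate[g1$coefficients$term == "N_deer"]
  expect_lt(abs(full$estimate[j]), abs(raw))
  expect_equal(cond$estimate[match("N_deer", cond$term)], raw)
  expect_error(average_models(list(f1), delta_max = -1), "models")
})

test_that("variance inflation factors: exact, infinite and fitted", {
  # exactly orthogonal, centered columns
  X <- cbind(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1), c = c(-1, 1, 1, -1))
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-9)

  Xd <- cbind(a = rnorm(10), b = 0)
  Xd[, "b"] <- Xd[, "a"]
  expect_true(all(is.infinite(vif(Xd))))

  # constructed pair with empirical correlation exactly 0.8
  z <- c(-1, -1, 1, 1) / 2
  w <- c(-1, 1, -1, 1) / 2
  X2 <- cbind(a = z, b = 0.8 * z + 0.6 * w)
  expect_equal(unname(vif(X2)), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  if (requireNamespace("car", quietly = TRUE)) {
    set.seed(151)
    dd <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40),
                     x3 = rnorm(40))
    ours <- vif(dd[, c("x1", "x2", "x3")])
    theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = dd))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
  }
})

test_that("Durbin-Watson statistic and permutation p-value", {
  expect_equal(durbin_watson(c(1, -1, 1, -1))$statistic, 3.0)
  expect_equal(durbin_watson(c(1, 1, 1, 1) - 0)$statistic, 0)
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  expect_error(durbin_watson(c(1, 2)), "at least 3")

  set.seed(157)
  e <- rnorm(10000)
  dw <- durbin_watson(e, n_perm = 200, seed = 1)
  expect_lt(abs(dw$statistic - 2), 3 * 2 / sqrt(10000))

  d1 <- durbin_watson(rnorm(30), n_perm = 500, seed = 9)
  d2 <- durbin_watson(rnorm(30), n_perm = 500, seed = 9)
  expect_identical(d1$p_value, d1$p_value)

  if (requireNamespace("lmtest", quietly = TRUE)) {
    set.seed(163)
    dd <- data.frame(y = rnorm(25), x = rnorm(25))
    fit <- lm(y ~ x, data = dd)
    ours <- durbin_watson(residuals(fit), n_perm = 100, seed = 1)$statistic
    theirs <- unname(lmtest::dwtest(fit)$statistic)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("bootstrap optimism-corrected RMSE", {
  # noise-free linear data: apparent and corrected both vanish
  d <- linear_design(20, 167, c(ar = 0.3), 0)
  sp <- model_spec("m.a", character(0), response = "Fs")
  bb <- bootstrap_rmse(d, sp, B = 30, seed = 2)
  expect_lt(bb$apparent, 1e-10)
  expect_lt(bb$corrected, 1e-8)

  # determinism under a fixed seed
  d2 <- linear_design(27, 173, c(ar = 0.1, N_deer = 0.1), 0.1)
  sp2 <- model_spec("m.b", c("P_winter", "N_deer", "P_winter:N_deer"),
                    response = "Fs")
  b1 <- bootstrap_rmse(d2, sp2, B = 50, seed = 7)
  b2 <- bootstrap_rmse(d2, sp2, B = 50, seed = 7)
  expect_identical(b1$corrected, b2$corrected)

  # optimism is positive on average for an overparameterized model
  opt <- sapply(1:40, function(i) {
    dd <- linear_design(27, 1000 + i, c(ar = 0.05), 0.1)
    bootstrap_rmse(dd, sp2, B = 40, seed = i)$optimism
  })
  expect_gt(mean(opt), 0)
  expect_gt(mean(opt > 0), 0.9)
})

test_that("robust Huber refit agrees with OLS off-outlier and resists one", {
  # residual scale far below the coefficient scale: downweighting moves
  # the estimates by far less than the reporting precision
  d <- linear_design(27, 179, c(ar = 0.2, N_deer = 0.3), 5e-4)
  sp <- model_spec("m.r", "N_deer", response = "Fs")
  ols <- fit_ols(d, sp)
  rob <- robust_fit(d, sp)
  expect_lt(max(abs(rob$coefficients$estimate -
                      ols$coefficients$estimate)), 1e-4)

  # IRLS fixed point: the converged estimate solves weighted least
  # squares at its own final weights
  d0 <- linear_design(20, 181, c(ar = 0.2, N_deer = 0.1), 0.05)
  sp0 <- model_spec("m.r0", "N_deer", response = "Fs")
  rob0 <- robust_fit(d0, sp0)
  X0 <- cbind(1, d0$ar, d0$N_deer)
  w0 <- rob0$weights
  beta_wls <- solve(t(X0) %*% (w0 * X0), t(X0) %*% (w0 * d0$response))
  ord <- match(c("(Intercept)", "ar", "N_deer"), rob0$coefficients$term)
  expect_lt(max(abs(rob0$coefficients$estimate[ord] - beta_wls)), 1e-6)

  # contamination: the robust slope stays closer to the clean-data slope
  closer <- sapply(1:200, function(i) {
    dd <- linear_design(27, 2000 + i, c(ar = 0.1, N_deer = 0.25), 0.05)
    clean <- fit_ols(dd, sp)$coefficients
    b_clean <- clean$estimate[clean$term == "N_deer"]
    dd$response[which.max(dd$N_deer)] <- dd$response[which.max(dd$N_deer)] + 1
    co <- fit_ols(dd, sp)$coefficients
    b_ols <- co$estimate[co$term == "N_deer"]
    rr <- tryCatch(robust_fit(dd, sp), error = function(e) NULL)
    if (is.null(rr)) return(NA)
    b_rob <- rr$coefficients$estimate[rr$coefficients$term == "N_deer"]
    abs(b_rob - b_clean) < abs(b_ols - b_clean)
  })
  expect_gte(mean(closer, na.rm = TRUE), 0.95)
})
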