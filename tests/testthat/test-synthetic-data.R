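# The generative model: climate, competitor trajectory, age-structured
# population and the observation process.

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(years = 3), "years")
  expect_error(sim_config(detection_prob = 0), "detection_prob")
  expect_error(sim_config(unknown_2plus_rate = 1), "unknown_2plus_rate")
  expect_error(sim_config(deer_params = list(n0 = 100, growth = -1.5,
                                             capacity = 500, sd = 0)),
               "growth")
  expect_error(sim_config(climate_params = list(
    winter = list(mean = -5, sd = 1, family = "lognormal"),
    spring_summer = list(mean = 300, sd = 50, family = "gamma"))),
    "mean must be positive")
  rc <- default_rate_coefficients()
  rc$Br$baseline <- 1.2
  expect_error(sim_config(rate_coefficients = rc), "strictly in")
})

test_that("climate simulation: degenerate, distributional and seeded cases", {
  cfg0 <- sim_config(climate_params = list(
    winter = list(mean = 250, sd = 0, family = "lognormal"),
    spring_summer = list(mean = 330, sd = 0, family = "gamma")), seed = 5)
  cl0 <- simulate_climate(cfg0)
  expect_equal(cl0$P_winter, rep(250, cfg0$years))
  expect_equal(cl0$P_spring_summer, rep(330, cfg0$years))

  # law-of-large-numbers check against the configured mean, both families
  for (fam in c("lognormal", "gamma")) {
    cfg <- sim_config(years = 10000,
                      climate_params = list(
                        winter = list(mean = 250, sd = 80, family = fam),
                        spring_summer = list(mean = 330, sd = 90,
                                             family = fam)),
                      seed = 11)
    cl <- simulate_climate(cfg)
    expect_true(all(cl$P_winter > 0) && all(cl$P_spring_summer > 0))
    mcse <- sd(cl$P_winter) / sqrt(nrow(cl))
    expect_lt(abs(mean(cl$P_winter) - 250), 3 * mcse)
  }

  cfg <- sim_config(seed = 21)
  expect_identical(simulate_climate(cfg), simulate_climate(cfg))
})

test_that("deer trajectory: fixed point, logistic limit and noise mean", {
  cfg <- sim_config(deer_params = list(n0 = 500, growth = 0, capacity = 2000,
                                       sd = 0))
  expect_equal(simulate_deer(cfg), rep(500, cfg$years))

  cfg2 <- sim_config(years = 60, deer_params = list(n0 = 20, growth = 0.3,
                                                    capacity = 1000, sd = 0))
  d2 <- simulate_deer(cfg2)
  expect_false(is.unsorted(d2))
  expect_lt(abs(d2[60] - 1000) / 1000, 0.01)

  # Monte-Carlo mean of the noisy trajectory tracks the noise-free one
  base <- sim_config(deer_params = list(n0 = 150, growth = 0.25,
                                        capacity = 2000, sd = 0))
  noise_free <- simulate_deer(base)
  # small-noise regime so the logistic concavity (Jensen) bias stays well
  # inside the Monte-Carlo budget
  reps <- sapply(1:200, function(i)
    simulate_deer(sim_config(deer_params = list(n0 = 150, growth = 0.25,
                                                capacity = 2000, sd = 5),
                             seed = 700 + i)))
  mcse <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - noise_free) <= 3 * mcse + 1e-9))
})

test_that("deterministic projection matches the analytic matrix recursion", {
  rc <- list(Br = list(baseline = 0.5, slopes = numeric(0)),
             Ks = list(baseline = 0.4, slopes = numeric(0)),
             Fs = list(baseline = 0.8, slopes = numeric(0)),
             Ms = list(baseline = 0.8, slopes = numeric(0)))
  cfg <- sim_config(years = 12,
                    initial_counts = c(kid = 500, yearling = 300,
                                       adult_female = 1000, adult_male = 700),
                    rate_coefficients = rc, demographic_noise = FALSE,
                    yearling_split = "deterministic", seed = 1)
  tr <- simulate_population(cfg)
  k <- 500; y <- 300; f <- 1000; m <- 700
  for (t in 2:12) {
    y2 <- 0.4 * k
    f2 <- 0.8 * (f + y / 2)
    m2 <- 0.8 * (m + y / 2)
    k2 <- 0.5 * f2
    expect_equal(tr$yearling[t], y2, tolerance = 1e-9)
    expect_equal(tr$adult_female[t], f2, tolerance = 1e-9)
    expect_equal(tr$adult_male[t], m2, tolerance = 1e-9)
    expect_equal(tr$kid[t], k2, tolerance = 1e-9)
    k <- k2; y <- y2; f <- f2; m <- m2
  }
  # conservation limit: survival 1, births ~0, empty juvenile classes
  rc1 <- list(Br = list(baseline = 1e-12, slopes = numeric(0)),
              Ks = list(baseline = 1 - 1e-12, slopes = numeric(0)),
              Fs = list(baseline = 1 - 1e-12, slopes = numeric(0)),
              Ms = list(baseline = 1 - 1e-12, slopes = numeric(0)))
  cfg1 <- sim_config(years = 8,
                     initial_counts = c(kid = 0, yearling = 0,
                                        adult_female = 100, adult_male = 80),
                     rate_coefficients = rc1, demographic_noise = FALSE,
                     yearling_split = "deterministic", seed = 1)
  tr1 <- simulate_population(cfg1)
  expect_equal(tr1$adult_female, rep(100, 8), tolerance = 1e-6)
  expect_equal(tr1$adult_male, rep(80, 8), tolerance = 1e-6)
  expect_true(all(tr1$kid < 1e-6))
})

test_that("long-run realized rates recover the configured baselines", {
  # baselines at the conventional mean-rate values of chamois censuses
  rc <- list(Br = list(baseline = 0.56, slopes = numeric(0)),
             Ks = list(baseline = 0.38, slopes = numeric(0)),
             Fs = list(baseline = 0.74, slopes = numeric(0)),
             Ms = list(baseline = 0.74, slopes = numeric(0)))
  ratios <- list(Br = c(), Ks = c(), Fs = c(), Ms = c())
  for (i in 1:50) {
    cfg <- sim_config(years = 11,
                      initial_counts = c(kid = 1000, yearling = 600,
                                         adult_female = 1400,
                                         adult_male = 1000),
                      rate_coefficients = rc, seed = 3000 + i)
    tr <- simulate_population(cfg)
    nn <- nrow(tr)
    ratios$Br <- c(ratios$Br, (tr$kid / tr$adult_female)[-1])
    ratios$Ks <- c(ratios$Ks, (tr$yearling[-1] / tr$kid[-nn]))
    ratios$Fs <- c(ratios$Fs, tr$adult_female[-1] /
                     (tr$adult_female[-nn] + tr$yearling[-nn] / 2))
    ratios$Ms <- c(ratios$Ms, tr$adult_male[-1] /
                     (tr$adult_male[-nn] + tr$yearling[-nn] / 2))
  }
  target <- c(Br = 0.56, Ks = 0.38, Fs = 0.74, Ms = 0.74)
  for (nm in names(target)) {
    mcse <- sd(ratios[[nm]]) / sqrt(length(ratios[[nm]]))
    expect_lt(abs(mean(ratios[[nm]]) - target[[nm]]), 3 * mcse)
  }
})

test_that("observation model: identity, thinning and misclassification rates", {
  cfg <- sim_config(detection_prob = 1, unknown_1plus_rate = 0,
                    unknown_2plus_rate = 0, seed = 3)
  tr <- simulate_population(cfg)
  ob <- observe_counts(tr, cfg)
  expect_equal(ob$kid, tr$kid)
  expect_equal(ob$adult_female, tr$adult_female)
  expect_true(all(ob$unknown_1plus == 0) && all(ob$unknown_2plus == 0))

  # binomial thinning at detection 0.8 on a large class
  cfg2 <- sim_config(years = 4,
                     initial_counts = c(kid = 0, yearling = 0,
                                        adult_female = 12500,
                                        adult_male = 12500),
                     rate_coefficients = list(
                       Br = list(baseline = 1e-6, slopes = numeric(0)),
                       Ks = list(baseline = 0.5, slopes = numeric(0)),
                       Fs = list(baseline = 1 - 1e-6, slopes = numeric(0)),
                       Ms = list(baseline = 1 - 1e-6, slopes = numeric(0))),
                     demographic_noise = FALSE, detection_prob = 0.8,
                     unknown_1plus_rate = 0, unknown_2plus_rate = 0,
                     seed = 13)
  ob2 <- observe_counts(simulate_population(cfg2), cfg2)
  frac <- ob2$adult_female[1] / 12500
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / 12500))

  # per-animal unknown rates recovered on the eligible pools
  cfg3 <- sim_config(years = 6,
                     initial_counts = c(kid = 4000, yearling = 2500,
                                        adult_female = 7000,
                                        adult_male = 5000),
                     seed = 17)
  tr3 <- simulate_population(cfg3)
  ob3 <- observe_counts(tr3, cfg3)
  det1 <- sum(ob3$yearling + ob3$adult_female + ob3$adult_male +
                ob3$unknown_1plus + ob3$unknown_2plus)
  f1 <- sum(ob3$unknown_1plus) / det1
  pool2 <- sum(ob3$adult_female + ob3$adult_male + ob3$unknown_2plus)
  f2 <- sum(ob3$unknown_2plus) / pool2
  expect_lt(abs(f1 - 0.075), 3 * sqrt(0.075 * 0.925 / det1))
  expect_lt(abs(f2 - 0.146), 3 * sqrt(0.146 * 0.854 / pool2))
})

test_that("count conservation and seeded determinism of the full dataset", {
  cfg <- sim_config(seed = 29)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$observed, sim2$observed)
  expect_identical(sim1$deer_observed, sim2$deer_observed)
  expect_identical(sim1$truth, sim2$truth)

  # detected totals = classified + unknown, every year (conservation is
  # structural: the unknown classes are carved out of detected animals)
  ob <- sim1$observed
  tr <- sim1$truth
  expect_true(all(ob$kid <= tr$kid))
  expect_true(all(ob$yearling + ob$adult_female + ob$adult_male +
                    ob$unknown_1plus + ob$unknown_2plus <=
                    tr$yearling + tr$adult_female + tr$adult_male))
  expect_true(all(ob$unknown_1plus >= 0 & ob$unknown_2plus >= 0))
})

test_that("own-abundance standardization tracks the realized trajectory", {
  # without density feedback the two passes coincide, so the reference
  # moments equal the realized ones exactly
  rc <- list(Br = list(baseline = 0.5, slopes = c(P_winter = 0.05)),
             Ks = list(baseline = 0.5, slopes = c(P_winter = -0.05)),
             Fs = list(baseline = 0.87, slopes = c(N_deer = -0.04)),
             Ms = list(baseline = 0.85, slopes = numeric(0)))
  cfg0 <- sim_config(rate_coefficients = rc, seed = 31)
  tr0 <- simulate_population(cfg0)
  ref0 <- attr(tr0, "chamois_ref")
  tot0 <- tr0$kid + tr0$yearling + tr0$adult_female + tr0$adult_male
  expect_equal(ref0$mean, mean(tot0), tolerance = 1e-9)
  expect_equal(ref0$sd, sd(tot0), tolerance = 1e-9)

  # with feedback the second pass drifts a little from the first; the
  # anchor must still sit near the realized scale (pilot-derived bound)
  cfg <- sim_config(seed = 31)
  tr <- simulate_population(cfg)
  ref <- attr(tr, "chamois_ref")
  tot <- tr$kid + tr$yearling + tr$adult_female + tr$adult_male
  expect_lt(abs(ref$mean - mean(tot)) / mean(tot), 0.35)
})

test_that("population crash is flagged, not raised", {
  rc <- list(Br = list(baseline = 0.05, slopes = numeric(0)),
             Ks = list(baseline = 0.05, slopes = numeric(0)),
             Fs = list(baseline = 0.05, slopes = numeric(0)),
             Ms = list(baseline = 0.05, slopes = numeric(0)))
  cfg <- sim_config(years = 15,
                    initial_counts = c(kid = 5, yearling = 5,
                                       adult_female = 10, adult_male = 5),
                    rate_coefficients = rc, seed = 37)
  tr <- simulate_population(cfg)
  expect_true(attr(tr, "extinct"))
})
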