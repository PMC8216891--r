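## Synthetic population and observation model.
##
## All public simulator functions draw from seed substreams derived from the
## master seed (climate +1, deer +2, population +3, chamois observation +4,
## deer observation +5), so each stage is reproducible both standalone and
## inside simulate_dataset().

.zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

.draw_positive <- function(n, mean, sd, family) {
  if (sd == 0) return(rep(mean, n))
  if (family == "lognormal") {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  } else {
    stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
  }
}

#' Simulate seasonal precipitation series
#'
#' Draws the two seasonal aggregates used by the analysis -- summed winter
#' (January--March) and spring--summer (April--July) precipitation in mm --
#' directly from the configured positive-valued distributions, one
#' independent draw per year.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns \code{year}, \code{P_winter},
#'   \code{P_spring_summer} (mm), one row per simulated year.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  w <- config$climate_params$winter
  s <- config$climate_params$spring_summer
  data.frame(
    year = config$start_year + seq_len(config$years) - 1L,
    P_winter = .draw_positive(config$years, w$mean, w$sd, w$family),
    P_spring_summer = .draw_positive(config$years, s$mean, s$sd, s$family))
}

#' Simulate the red deer abundance trajectory
#'
#' Discrete logistic growth with additive Gaussian process noise, truncated
#' at zero: \eqn{N_{t+1} = \max(0, N_t + r N_t (1 - N_t/K) + \epsilon_t)}.
#' With positive growth, no noise and a small founder population the series
#' rises monotonically toward the carrying capacity, emulating a competitor
#' recolonizing the study area.
#'
#' @param config A [sim_config()] object.
#' @return Numeric vector of yearly deer abundances (length
#'   \code{config$years}).
#' @export
simulate_deer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  p <- config$deer_params
  n <- numeric(config$years)
  n[1] <- p$n0
  if (config$years > 1) {
    eps <- if (p$sd > 0) stats::rnorm(config$years - 1, 0, p$sd) else
      numeric(config$years - 1)
    for (t in 2:config$years) {
      n[t] <- max(0, n[t - 1] + p$growth * n[t - 1] *
                    (1 - n[t - 1] / p$capacity) + eps[t - 1])
    }
  }
  n
}

## Linear predictor for one vital rate in year t, on the logit scale.
## z is a named list of covariate z-score series; lags is a named integer
## vector of year indices at which each covariate is read.
.rate_value <- function(entry, z, idx) {
  eta <- stats::qlogis(entry$baseline)
  scale <- entry$baseline * (1 - entry$baseline)
  sl <- entry$slopes
  if (length(sl)) {
    for (nm in names(sl)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      val <- prod(vapply(parts, function(p) z[[p]][idx[[p]]], numeric(1)))
      eta <- eta + sl[[nm]] / scale * val
    }
  }
  stats::plogis(eta)
}

.binom_step <- function(size, prob, noise) {
  if (noise) stats::rbinom(length(size), round(size), prob) else size * prob
}

## One forward pass of the population given fixed covariate z-scores for
## deer and climate and a reference (mean, sd) for own abundance.
.simulate_pop_pass <- function(config, climate, deer, ref) {
  set.seed(config$seed + 3L)
  yrs <- config$years
  noise <- config$demographic_noise
  zPw <- .zscore_or_zero(climate$P_winter)
  zPss <- .zscore_or_zero(climate$P_spring_summer)
  zdeer <- .zscore_or_zero(deer)
  rc <- config$rate_coefficients

  kid <- yearling <- af <- am <- total <- numeric(yrs)
  Br <- Ks <- Fs <- Ms <- rep(NA_real_, yrs)
  kid[1] <- config$initial_counts[["kid"]]
  yearling[1] <- config$initial_counts[["yearling"]]
  af[1] <- config$initial_counts[["adult_female"]]
  am[1] <- config$initial_counts[["adult_male"]]
  total[1] <- kid[1] + yearling[1] + af[1] + am[1]
  zN <- function(t) (total[t] - ref$mean) / ref$sd
  z <- list(P_winter = zPw, P_spring_summer = zPss, N_deer = zdeer)
  extinct <- FALSE

  ## birth-rate covariate indices for year t (lag-1 terms clamped at year 1)
  br_idx <- function(t) {
    tm1 <- max(t - 1L, 1L)
    list(P_winter = t, P_spring_summer = tm1, N_deer = tm1, N_chamois = tm1)
  }
  sv_idx <- function(t) {
    tm1 <- max(t - 1L, 1L)
    list(P_winter = t + 1L, P_spring_summer = t, N_deer = tm1, N_chamois = t)
  }
  rate_at <- function(entry, idx) {
    zz <- c(z, list(N_chamois = vapply(seq_len(yrs), zN, numeric(1))))
    .rate_value(entry, zz, idx)
  }

  Br[1] <- rate_at(rc$Br, br_idx(1L))
  if (yrs > 1) {
    for (t in seq_len(yrs - 1L)) {
      idx <- sv_idx(t)
      Ks[t] <- rate_at(rc$Ks, idx)
      Fs[t] <- rate_at(rc$Fs, idx)
      Ms[t] <- rate_at(rc$Ms, idx)
      yearling[t + 1] <- .binom_step(kid[t], Ks[t], noise)
      if (config$yearling_split == "binomial" && noise) {
        yf <- stats::rbinom(1, round(yearling[t]), 0.5)
      } else {
        yf <- yearling[t] / 2
      }
      ym <- yearling[t] - yf
      af[t + 1] <- .binom_step(af[t], Fs[t], noise) +
        .binom_step(yf, Fs[t], noise)
      am[t + 1] <- .binom_step(am[t], Ms[t], noise) +
        .binom_step(ym, Ms[t], noise)
      total[t + 1] <- yearling[t + 1] + af[t + 1] + am[t + 1]
      Br[t + 1] <- rate_at(rc$Br, br_idx(t + 1L))
      kid[t + 1] <- .binom_step(af[t + 1], Br[t + 1], noise)
      total[t + 1] <- total[t + 1] + kid[t + 1]
      if (total[t + 1] <= 0) {
        extinct <- TRUE
        break
      }
    }
  }
  out <- data.frame(
    year = config$start_year + seq_len(yrs) - 1L,
    kid = kid, yearling = yearling, adult_female = af, adult_male = am,
    Br = Br, Ks = Ks, Fs = Fs, Ms = Ms,
    N_deer = deer,
    P_winter = climate$P_winter, P_spring_summer = climate$P_spring_summer)
  attr(out, "extinct") <- extinct
  attr(out, "chamois_ref") <- ref
  class(out) <- c("true_trajectory", "data.frame")
  out
}

#' Simulate the true chamois population trajectory
#'
#' Projects an age/sex-structured population (kid, yearling, adult female,
#' adult male) forward with yearly binomial survival and binomial births.
#' Each year's vital rates are inverse-logit transforms of linear predictors
#' in standardized covariates (own abundance, deer abundance, seasonal
#' precipitation and their configured interactions), with the same lag
#' structure the downstream regressions assume.  Surviving yearlings are
#' recruited into the two adult classes under a balanced sex ratio.
#'
#' Own-abundance standardization uses the realized trajectory's own mean and
#' standard deviation via a two-pass scheme: a provisional pass fixes the
#' scale, then the population is re-simulated under the identical random
#' substream with the realized moments.  Supplying \code{config$chamois_ref}
#' disables the second pass.  Population extinction before the horizon is
#' flagged in the \code{"extinct"} attribute rather than raised as an error.
#'
#' @param config A [sim_config()] object.
#' @param climate Optional climate table from [simulate_climate()];
#'   generated from \code{config} when \code{NULL}.
#' @param deer Optional deer abundance vector from [simulate_deer()].
#' @return A \code{true_trajectory} data frame: per-year class abundances,
#'   realized vital rates (\code{Br}, \code{Ks}, \code{Fs}, \code{Ms};
#'   survival rates \code{NA} in the final year), and covariate values.
#' @export
simulate_population <- function(config, climate = NULL, deer = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(climate)) climate <- simulate_climate(config)
  if (is.null(deer)) deer <- simulate_deer(config)
  if (nrow(climate) != config$years || length(deer) != config$years)
    stop("climate and deer series must cover config$years years")
  n0 <- sum(config$initial_counts)
  if (!is.null(config$chamois_ref)) {
    return(.simulate_pop_pass(config, climate, deer, config$chamois_ref))
  }
  ref <- list(mean = n0, sd = 0.1 * n0)
  pass1 <- .simulate_pop_pass(config, climate, deer, ref)
  tot <- pass1$kid + pass1$yearling + pass1$adult_female + pass1$adult_male
  s <- stats::sd(tot)
  ref2 <- list(mean = mean(tot), sd = if (is.finite(s) && s > 1e-8) s else ref$sd)
  .simulate_pop_pass(config, climate, deer, ref2)
}

#' Apply the observation model to a true trajectory
#'
#' Each animal is detected independently with \code{detection_prob}; each
#' detected animal of age >= 1 is then recorded as "unknown 1+" with
#' probability \code{unknown_1plus_rate}, and each detected adult (age >= 2)
#' not already misclassified is recorded as "unknown 2+" with probability
#' \code{unknown_2plus_rate}.  An animal is misclassified at most once, so
#' the two unknown classes are disjoint and detected totals are conserved:
#' detected = classified + unknown, every year.
#'
#' @param truth A \code{true_trajectory} from [simulate_population()].
#' @param config The [sim_config()] used to generate it.
#' @return Data frame with per-year observed counts: \code{kid},
#'   \code{yearling}, \code{adult_female}, \code{adult_male},
#'   \code{unknown_1plus}, \code{unknown_2plus}.
#' @export
observe_counts <- function(truth, config) {
  stopifnot(inherits(truth, "true_trajectory"), inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  p <- config$detection_prob
  p1 <- config$unknown_1plus_rate
  p2 <- config$unknown_2plus_rate
  n <- nrow(truth)
  identity_case <- (p == 1 && p1 == 0 && p2 == 0)
  det <- function(x) {
    if (identity_case) x else stats::rbinom(n, round(x), p)
  }
  dk <- det(truth$kid)
  dy <- det(truth$yearling)
  df_ <- det(truth$adult_female)
  dm <- det(truth$adult_male)
  thin <- function(x, q) {
    if (q == 0) rep(0, n) else stats::rbinom(n, round(x), q)
  }
  u1y <- thin(dy, p1); u1f <- thin(df_, p1); u1m <- thin(dm, p1)
  u2f <- thin(df_ - u1f, p2); u2m <- thin(dm - u1m, p2)
  data.frame(
    year = truth$year,
    kid = dk,
    yearling = dy - u1y,
    adult_female = df_ - u1f - u2f,
    adult_male = dm - u1m - u2m,
    unknown_1plus = u1y + u1f + u1m,
    unknown_2plus = u2f + u2m)
}

#' Simulate a complete synthetic census dataset
#'
#' Runs the full generative chain -- climate, deer trajectory, chamois
#' population, chamois observation, deer observation (binomial thinning with
#' \code{deer_detection_prob}) -- under the configuration's seed.
#'
#' @param config A [sim_config()] object.
#' @return A \code{chamois_sim} list: \code{truth} (true trajectory),
#'   \code{observed} (observed chamois count table), \code{deer_true},
#'   \code{deer_observed} (data frame \code{year}, \code{count}),
#'   \code{climate} (seasonal table) and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  climate <- simulate_climate(config)
  deer <- simulate_deer(config)
  truth <- simulate_population(config, climate, deer)
  observed <- observe_counts(truth, config)
  set.seed(config$seed + 5L)
  deer_obs <- if (config$deer_detection_prob == 1) round(deer) else
    stats::rbinom(config$years, round(deer), config$deer_detection_prob)
  structure(
    list(truth = truth, observed = observed, deer_true = deer,
         deer_observed = data.frame(year = truth$year, count = deer_obs),
         climate = climate, config = config),
    class = "chamois_sim")
}

#' @export
print.chamois_sim <- function(x, ...) {
  cat("Synthetic chamois census dataset:", x$config$years, "years",
      if (attr(x$truth, "extinct")) "(population went extinct)" else "", "\n")
  cat("  final true total:",
      round(sum(x$truth[nrow(x$truth),
                        c("kid", "yearling", "adult_female", "adult_male")])),
      "| final deer:", round(x$deer_true[length(x$deer_true)]), "\n")
  invisible(x)
}

#' Write a simulated dataset as the three analysis input CSVs
#'
#' Produces \code{counts.csv} (wide per-class observed counts including the
#' unknown classes), \code{deer.csv} (\code{year,count}, observed) and
#' \code{climate.csv} (\code{year,month,precip_mm}).  Seasonal totals are
#' disaggregated uniformly across their months (winter over 1--3,
#' spring--summer over 4--7; months 8--12 carry a neutral filler that no
#' analysis window reads), so re-aggregation recovers the simulated seasonal
#' sums exactly.
#'
#' @param sim A \code{chamois_sim} from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the three files.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "chamois_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_path <- file.path(dir, "counts.csv")
  deer_path <- file.path(dir, "deer.csv")
  climate_path <- file.path(dir, "climate.csv")
  utils::write.csv(sim$observed, counts_path, row.names = FALSE)
  utils::write.csv(sim$deer_observed, deer_path, row.names = FALSE)
  cl <- sim$climate
  monthly <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    data.frame(
      year = cl$year[i], month = 1:12,
      precip_mm = c(rep(cl$P_winter[i] / 3, 3),
                    rep(cl$P_spring_summer[i] / 4, 4),
                    rep((cl$P_winter[i] + cl$P_spring_summer[i]) / 14, 5)))
  }))
  utils::write.csv(monthly, climate_path, row.names = FALSE)
  invisible(c(counts = counts_path, deer = deer_path, climate = climate_path))
}
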