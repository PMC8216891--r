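## Ratio-based vital rates, climate aggregation and lag-aligned design tables.

#' Compute ratio-based vital rates from class abundances
#'
#' Given yearly (ideally state-space filtered) abundances of kids,
#' yearlings, adult females and adult males, computes:
#' \describe{
#'   \item{Br}{kids per adult female in the same year,
#'     \eqn{kid_t / adultF_t}; confounds fecundity with early kid survival.}
#'   \item{Ks}{kid survival t to t+1, \eqn{yearling_{t+1} / kid_t}.}
#'   \item{Fs}{female (1+) survival,
#'     \eqn{adultF_{t+1} / (adultF_t + yearling_t / 2)}; half the yearlings
#'     are allocated to each sex (balanced sex ratio assumption).}
#'   \item{Ms}{male (1+) survival, analogous with adult males.}
#'   \item{Y}{log growth rate of the kid-excluded population,
#'     \eqn{\ln(N_{t+1}/N_t)} with
#'     \eqn{N = yearling + adultF + adultM}.}
#' }
#' Rates indexed t to t+1 are stored in row t; the final year carries only
#' \code{Br}.  Zero denominators yield \code{NA} with a warning, never an
#' error; survival ratios above 1 (a legitimate consequence of count noise)
#' are retained and flagged in the \code{"above_one"} attribute.
#'
#' @param counts Data frame with columns \code{year}, \code{kid},
#'   \code{yearling}, \code{adult_female}, \code{adult_male}.
#' @return The input years with columns \code{Br}, \code{Ks}, \code{Fs},
#'   \code{Ms}, \code{Y}.
#' @export
compute_vital_rates <- function(counts) {
  need <- c("year", "kid", "yearling", "adult_female", "adult_male")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  n <- nrow(counts)
  k <- counts$kid; yl <- counts$yearling
  f <- counts$adult_female; m <- counts$adult_male
  ratio <- function(num, den, what) {
    bad <- den <= 0
    if (any(bad, na.rm = TRUE))
      warning("zero denominator for ", what, " in year(s) ",
              paste(counts$year[which(bad)], collapse = ", "),
              "; returning NA")
    ifelse(bad, NA_real_, num / den)
  }
  lead1 <- function(x) c(x[-1], NA_real_)
  out <- data.frame(year = counts$year)
  out$Br <- ratio(k, f, "Br")
  out$Ks <- ratio(lead1(yl), k, "Ks")
  out$Fs <- ratio(lead1(f), f + yl / 2, "Fs")
  out$Ms <- ratio(lead1(m), m + yl / 2, "Ms")
  nk <- yl + f + m
  out$Y <- ifelse(nk > 0 & lead1(nk) > 0, log(lead1(nk) / nk), NA_real_)
  out$Ks[n] <- out$Fs[n] <- out$Ms[n] <- out$Y[n] <- NA_real_
  attr(out, "above_one") <-
    which(out$Ks > 1 | out$Fs > 1 | out$Ms > 1)
  out
}

#' Aggregate monthly precipitation into the two seasonal covariates
#'
#' \code{P_winter} is the January--March sum and \code{P_spring_summer} the
#' April--July sum, in mm.  A missing month inside the aggregation window is
#' an error naming the (year, month).
#'
#' @param climate Data frame \code{year}, \code{month}, \code{precip_mm}.
#' @return Data frame \code{year}, \code{P_winter}, \code{P_spring_summer}.
#' @export
aggregate_climate <- function(climate) {
  need <- c("year", "month", "precip_mm")
  if (!all(need %in% names(climate)))
    stop("climate must have columns ", paste(need, collapse = ", "))
  years <- sort(unique(climate$year))
  for (yr in years) {
    have <- climate$month[climate$year == yr]
    miss <- setdiff(1:7, have)
    if (length(miss))
      stop("missing climate month ", miss[1], " in year ", yr)
  }
  agg <- function(months) {
    sub <- climate[climate$month %in% months, ]
    tapply(sub$precip_mm, factor(sub$year, levels = years), sum)
  }
  data.frame(year = years,
             P_winter = as.numeric(agg(1:3)),
             P_spring_summer = as.numeric(agg(4:7)))
}

#' Standardize a series to zero mean and unit standard deviation
#'
#' Centering and scaling use the sample mean and (n-1)-denominator standard
#' deviation over the supplied window.  The center and scale are stored as
#' attributes so the transform is invertible.
#'
#' @param x Numeric series of length >= 2 with positive sd.
#' @return Z-scored numeric vector with attributes \code{center},
#'   \code{scale}.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need at least 2 values to standardize")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant series")
  structure((x - mean(x)) / s, center = mean(x), scale = s)
}

.lag1 <- function(x) c(NA_real_, x[-length(x)])

#' Build the lag-aligned regression design table for one response
#'
#' Assembles, for the chosen vital rate, the complete-case rows of
#' (response, 1-year autoregressive term, z-scored covariates) under the
#' lag conventions of the analysis:
#' \itemize{
#'   \item Birth rate at year t: AR term \eqn{Br_{t-1}}; covariates
#'     \eqn{P_{ss,t-1}}, \eqn{Ncham_{t-1}}, \eqn{Ndeer_{t-1}},
#'     \eqn{P_{w,t}}.
#'   \item Survival rates over t to t+1: AR term is the same rate over
#'     t-1 to t; covariates \eqn{P_{w,t+1}}, \eqn{P_{ss,t}},
#'     \eqn{Ncham_t}, \eqn{Ndeer_{t-1}}.
#' }
#' All predictors (including the AR term) are standardized over the
#' complete-case window; the response is left on its natural scale, so
#' model intercepts are interpretable as mean rates.  Interaction columns,
#' created downstream, are elementwise products of z-scores.
#'
#' @param response One of \code{"Br"}, \code{"Ks"}, \code{"Fs"},
#'   \code{"Ms"}.
#' @param rates Vital-rate table from [compute_vital_rates()].
#' @param covariates Data frame with columns \code{year}, \code{P_winter},
#'   \code{P_spring_summer}, \code{N_chamois}, \code{N_deer} (natural
#'   scale; standardization happens here).
#' @return Data frame with columns \code{year}, \code{response}, \code{ar},
#'   \code{P_winter}, \code{P_spring_summer}, \code{N_chamois},
#'   \code{N_deer}; attribute \code{"response_name"}.
#' @export
build_design <- function(response = c("Br", "Ks", "Fs", "Ms"),
                         rates, covariates) {
  response <- match.arg(response)
  need <- c("year", "P_winter", "P_spring_summer", "N_chamois", "N_deer")
  if (!all(need %in% names(covariates)))
    stop("covariates must have columns ", paste(need, collapse = ", "))
  if (!all(rates$year %in% covariates$year))
    stop("covariates must cover the rate years ",
         min(rates$year), "-", max(rates$year))
  cv <- covariates[match(rates$year, covariates$year), ]
  y <- rates[[response]]
  if (response == "Br") {
    d <- data.frame(
      year = rates$year,
      response = y,
      ar = .lag1(y),
      P_winter = cv$P_winter,
      P_spring_summer = .lag1(cv$P_spring_summer),
      N_chamois = .lag1(cv$N_chamois),
      N_deer = .lag1(cv$N_deer))
  } else {
    d <- data.frame(
      year = rates$year,
      response = y,
      ar = .lag1(y),
      P_winter = c(cv$P_winter[-1], NA_real_),
      P_spring_summer = cv$P_spring_summer,
      N_chamois = cv$N_chamois,
      N_deer = .lag1(cv$N_deer))
  }
  cc <- stats::complete.cases(d)
  if (sum(cc) < 8)
    stop("only ", sum(cc), " complete cases for response ", response,
         "; at least 8 years of aligned data are required")
  d <- d[cc, , drop = FALSE]
  for (nm in c("ar", "P_winter", "P_spring_summer", "N_chamois", "N_deer"))
    d[[nm]] <- as.numeric(standardize(d[[nm]]))
  rownames(d) <- NULL
  attr(d, "response_name") <- response
  d
}

#' Build the aligned triplet table for the path analysis
#'
#' Aligns deer abundance at t-1 (the exogenous driver), each vital rate
#' (birth rate at t; survival rates over t to t+1) and the log growth rate
#' over t to t+1 on a common complete-case window.  Values are left on
#' their natural scales; path fitting standardizes internally.
#'
#' @param rates Vital-rate table from [compute_vital_rates()].
#' @param covariates As in [build_design()].
#' @return Data frame \code{year}, \code{N_deer} (lag-1), \code{Br},
#'   \code{Ks}, \code{Fs}, \code{Ms}, \code{Y}.
#' @export
build_path_data <- function(rates, covariates) {
  cv <- covariates[match(rates$year, covariates$year), ]
  d <- data.frame(year = rates$year,
                  N_deer = .lag1(cv$N_deer),
                  Br = rates$Br, Ks = rates$Ks, Fs = rates$Fs,
                  Ms = rates$Ms, Y = rates$Y)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  rownames(d) <- NULL
  d
}
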