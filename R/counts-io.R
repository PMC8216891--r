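## Reading, validation and preprocessing of the tabular inputs.

.count_classes <- c("kid", "yearling", "adult_female", "adult_male",
                    "unknown_1plus", "unknown_2plus")

.check_years <- function(year, what) {
  if (anyDuplicated(year))
    stop(what, ": duplicate year(s) ",
         paste(unique(year[duplicated(year)]), collapse = ", "))
  if (is.unsorted(year, strictly = TRUE))
    stop(what, ": years must be strictly increasing")
  gaps <- diff(year) != 1
  if (any(gaps))
    stop(what, ": gap in years after ", paste(year[which(gaps)], collapse = ", "))
  invisible(year)
}

#' Read an annual sex/age-classified count table
#'
#' Accepts either the wide dialect (columns \code{year} plus one column per
#' class) or the long dialect (\code{year,class,count}).  Classes are
#' \code{kid}, \code{yearling}, \code{adult_female}, \code{adult_male},
#' \code{unknown_1plus}, \code{unknown_2plus}; unknown columns absent from a
#' wide file default to zero.  Validation rejects negative counts (naming
#' the offending row), duplicate (year, class) cells, and gappy or unsorted
#' year sequences.
#'
#' @param path CSV file path (comma-separated, UTF-8, header row).
#' @return Wide data frame with columns \code{year} and the six classes.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"year" %in% names(raw)) stop("count file must have a 'year' column")
  if (all(c("class", "count") %in% names(raw))) {
    bad <- which(!raw$class %in% .count_classes)
    if (length(bad))
      stop("unknown class in row ", bad[1], ": '", raw$class[bad[1]], "'")
    neg <- which(raw$count < 0)
    if (length(neg))
      stop("negative count in row ", neg[1], " (year ", raw$year[neg[1]], ")")
    key <- paste(raw$year, raw$class)
    if (anyDuplicated(key))
      stop("duplicate (year, class) in row ", which(duplicated(key))[1])
    years <- sort(unique(raw$year))
    wide <- data.frame(year = years)
    for (cl in .count_classes) {
      m <- raw[raw$class == cl, ]
      wide[[cl]] <- m$count[match(years, m$year)]
      wide[[cl]][is.na(wide[[cl]])] <- 0
    }
  } else {
    present <- intersect(.count_classes, names(raw))
    if (!all(c("kid", "yearling", "adult_female", "adult_male") %in% present))
      stop("wide count file must have columns kid, yearling, adult_female, ",
           "adult_male (missing: ",
           paste(setdiff(c("kid", "yearling", "adult_female", "adult_male"),
                         present), collapse = ", "), ")")
    wide <- raw[, c("year", present)]
    for (cl in setdiff(.count_classes, present)) wide[[cl]] <- 0
    wide <- wide[, c("year", .count_classes)]
    for (cl in .count_classes) {
      neg <- which(wide[[cl]] < 0)
      if (length(neg))
        stop("negative count in row ", neg[1], ", column '", cl, "'")
    }
  }
  .check_years(wide$year, "count table")
  wide
}

#' Read the annual competitor (red deer) abundance series
#'
#' @param path CSV with columns \code{year,count}.
#' @return Data frame \code{year}, \code{count}.
#' @export
read_deer_table <- function(path) {
  if (!file.exists(path)) stop("deer file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "count") %in% names(x)))
    stop("deer file must have columns year, count")
  neg <- which(x$count < 0)
  if (length(neg)) stop("negative deer count in row ", neg[1])
  .check_years(x$year, "deer table")
  x[, c("year", "count")]
}

#' Read the monthly precipitation table
#'
#' @param path CSV with columns \code{year,month,precip_mm}.
#' @return Data frame \code{year}, \code{month}, \code{precip_mm}.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) stop("climate file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "month", "precip_mm") %in% names(x)))
    stop("climate file must have columns year, month, precip_mm")
  if (any(!x$month %in% 1:12)) stop("climate months must lie in 1..12")
  neg <- which(x$precip_mm < 0)
  if (length(neg)) stop("negative precipitation in row ", neg[1])
  key <- paste(x$year, x$month)
  if (anyDuplicated(key))
    stop("duplicate (year, month) in row ", which(duplicated(key))[1])
  x[, c("year", "month", "precip_mm")]
}

#' Read the three analysis inputs at once
#'
#' @param counts,deer,climate File paths for the count, deer and climate
#'   CSVs (dialects as in the single-table readers).
#' @param quiet Suppress the descriptive summary message.
#' @return List with elements \code{counts}, \code{deer}, \code{climate}.
#' @export
read_tables <- function(counts, deer, climate, quiet = FALSE) {
  out <- list(counts = read_count_table(counts),
              deer = read_deer_table(deer),
              climate = read_climate_table(climate))
  if (!quiet) {
    yr <- range(out$counts$year)
    tot <- rowSums(out$counts[, .count_classes])
    message("counts: ", yr[1], "-", yr[2], ", yearly totals ",
            round(min(tot)), "-", round(max(tot)),
            "; deer: ", nrow(out$deer), " years; climate: ",
            nrow(out$climate), " month-rows")
  }
  out
}

#' Reassign partially classified animals to sex/age classes
#'
#' Two-stage proportional allocation mirroring the census bookkeeping:
#' "unknown 1+" animals are first split across yearling, adult female and
#' adult male in proportion to that year's known counts; "unknown 2+"
#' animals are then split across the two (updated) adult classes.
#' Fractional animals are retained so that yearly totals are conserved
#' exactly.  A year with unknown animals but an empty eligible pool is an
#' error (no silent dropping).
#'
#' @param raw Wide count table as returned by [read_count_table()].
#' @return Data frame with columns \code{year}, \code{kid}, \code{yearling},
#'   \code{adult_female}, \code{adult_male} (non-negative reals).
#' @export
reassign_unknowns <- function(raw) {
  need <- c("year", .count_classes)
  if (!all(need %in% names(raw)))
    stop("input must have columns ", paste(need, collapse = ", "))
  out <- raw[, c("year", "kid", "yearling", "adult_female", "adult_male")]
  for (i in seq_len(nrow(raw))) {
    u1 <- raw$unknown_1plus[i]
    u2 <- raw$unknown_2plus[i]
    pool1 <- raw$yearling[i] + raw$adult_female[i] + raw$adult_male[i]
    if (u1 > 0) {
      if (pool1 <= 0)
        stop("year ", raw$year[i],
             ": unknown 1+ animals but no classified 1+ animals to set ratios")
      out$yearling[i] <- out$yearling[i] + u1 * raw$yearling[i] / pool1
      out$adult_female[i] <- out$adult_female[i] + u1 * raw$adult_female[i] / pool1
      out$adult_male[i] <- out$adult_male[i] + u1 * raw$adult_male[i] / pool1
    }
    if (u2 > 0) {
      pool2 <- out$adult_female[i] + out$adult_male[i]
      if (pool2 <= 0)
        stop("year ", raw$year[i],
             ": unknown 2+ animals but no classified adults to set ratios")
      out$adult_female[i] <- out$adult_female[i] + u2 * out$adult_female[i] / pool2
      out$adult_male[i] <- out$adult_male[i] + u2 * out$adult_male[i] / pool2
    }
  }
  out
}

#' Adjust counts for a known undercount
#'
#' A census that misses a fraction \code{coefficient} of the animals obeys
#' \code{raw = (1 - coefficient) * truth}, so every count is divided by
#' \code{1 - coefficient}.  The scaling is uniform, leaving all between-class
#' ratios -- and hence every ratio-based vital rate -- unchanged.
#'
#' @param x A numeric vector, or a data frame whose non-\code{year} numeric
#'   columns are counts.
#' @param coefficient Undercount fraction in [0, 1); 0.20 is conventional
#'   for chamois block counts and 0.35 for deer spotlight counts.
#' @return Object of the same shape with adjusted counts.
#' @export
adjust_counts <- function(x, coefficient) {
  if (!is.numeric(coefficient) || coefficient < 0 || coefficient >= 1)
    stop("coefficient must lie in [0, 1)")
  f <- 1 / (1 - coefficient)
  if (is.data.frame(x)) {
    for (nm in setdiff(names(x), "year"))
      if (is.numeric(x[[nm]])) x[[nm]] <- x[[nm]] * f
    x
  } else {
    x * f
  }
}
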