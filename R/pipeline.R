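## End-to-end orchestration: simulate or read -> preprocess -> filter ->
## rates -> select -> path, with per-stage outputs, a JSON run manifest and
## seeded determinism.

#' Pipeline configuration
#'
#' @param counts,deer,climate Input CSV paths (ignored when \code{simulate}
#'   is supplied).
#' @param simulate Optional [sim_config()]; when present the inputs are
#'   generated in memory instead of read from disk.
#' @param chamois_adjust,deer_adjust Undercount coefficients (defaults 0.20
#'   and 0.35, the conventional block-count and spotlight-count values).
#' @param filter Apply state-space filtering to the class and deer series
#'   (default \code{TRUE}).
#' @param gompertz Use the density-dependent state-space variant.
#' @param exclude_kids Exclude kids from the chamois abundance covariate.
#' @param structures Optional model-set override for [build_model_set()].
#' @param delta_max,averaging Passed to [average_models()].
#' @param bootstrap_B Bootstrap resamples for the optimism-corrected RMSE
#'   of each candidate model (0 skips the bootstrap).
#' @param rmsea_max,chisq_scale Passed to the path-analysis stage.
#' @param seed Master seed for every stochastic step (bootstrap,
#'   permutation tests).
#' @param outdir Optional output directory; when set, stage CSVs, a JSON
#'   run manifest and a log are written there.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(counts = NULL, deer = NULL, climate = NULL,
                            simulate = NULL,
                            chamois_adjust = 0.20, deer_adjust = 0.35,
                            filter = TRUE, gompertz = FALSE,
                            exclude_kids = FALSE,
                            structures = NULL,
                            delta_max = 4,
                            averaging = c("full", "conditional"),
                            bootstrap_B = 200,
                            rmsea_max = 0.06,
                            chisq_scale = c("n-1", "n"),
                            seed = 1L, outdir = NULL) {
  averaging <- match.arg(averaging)
  chisq_scale <- match.arg(chisq_scale)
  for (cc in c(chamois_adjust, deer_adjust))
    if (!is.numeric(cc) || cc < 0 || cc >= 1)
      stop("adjustment coefficients must lie in [0, 1)")
  if (is.null(simulate) &&
      (is.null(counts) || is.null(deer) || is.null(climate)))
    stop("supply either input paths (counts, deer, climate) or a ",
         "simulate = sim_config(...)")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("simulate must be a sim_config object")
  if (delta_max <= 0) stop("delta_max must be positive")
  structure(
    list(counts = counts, deer = deer, climate = climate,
         simulate = simulate,
         chamois_adjust = chamois_adjust, deer_adjust = deer_adjust,
         filter = filter, gompertz = gompertz,
         exclude_kids = exclude_kids, structures = structures,
         delta_max = delta_max, averaging = averaging,
         bootstrap_B = bootstrap_B, rmsea_max = rmsea_max,
         chisq_scale = chisq_scale, seed = as.integer(seed),
         outdir = outdir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' File keys mirror the arguments of [pipeline_config()]; a
#' \code{simulate:} section holds [sim_config()] arguments.
#'
#' @param path Configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    if (!is.null(sim_args$initial_counts))
      sim_args$initial_counts <- unlist(sim_args$initial_counts)
    raw$simulate <- do.call(sim_config, sim_args)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

.global_structures <- list(
  Br = c("P_winter", "P_spring_summer", "N_chamois", "N_deer",
         "P_spring_summer:N_chamois", "P_spring_summer:N_deer"),
  surv = c("P_winter", "P_spring_summer", "N_chamois", "N_deer",
           "P_winter:N_chamois", "P_winter:N_deer"))

.filter_series <- function(x, gompertz) {
  fit <- fit_state_space(x, gompertz = gompertz)
  list(fit = fit, smoothed = smooth_series(fit)$smoothed)
}

#' Run the full demographic analysis pipeline
#'
#' Executes, in dependency order: input acquisition (simulation or CSV
#' reading), unknown-class reassignment and undercount adjustment,
#' state-space filtering of each class series and the deer series,
#' vital-rate and covariate construction, candidate-set fitting with AICc
#' ranking, Akaike-weight averaging and diagnostics (global-model VIF and
#' Durbin-Watson, per-model optimism-corrected RMSE, robust refit of the
#' top model), and the four mediation path models.  With
#' \code{config$outdir} set, every stage's table is written as CSV along
#' with a JSON manifest (configuration, seed, versions) sufficient to
#' reproduce the run.
#'
#' @param config A [pipeline_config()] or the path of a YAML/JSON
#'   configuration file.
#' @param stages Subset of
#'   \code{c("preprocess", "filter", "rates", "select", "path")} to run
#'   (contiguous from the start; later stages require earlier ones).
#' @return A \code{chamois_pipeline} list with elements \code{inputs},
#'   \code{classified}, \code{adjusted}, \code{filtered}, \code{rates},
#'   \code{covariates}, \code{selection} (per response: ranking table,
#'   averaged estimates, diagnostics), and \code{path} (fits and
#'   comparison table).
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "filter", "rates",
                                    "select", "path")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  result <- list(config = config)

  if (!is.null(config$simulate)) {
    note("stage simulate: generating synthetic dataset (seed ",
         config$simulate$seed, ")")
    sim <- simulate_dataset(config$simulate)
    counts <- sim$observed
    deer <- sim$deer_observed
    climate_seasonal <- sim$climate
    result$simulation <- sim
  } else {
    note("stage read: loading input tables")
    tabs <- read_tables(config$counts, config$deer, config$climate,
                        quiet = TRUE)
    counts <- tabs$counts
    deer <- tabs$deer
    climate_seasonal <- aggregate_climate(tabs$climate)
  }
  result$inputs <- list(counts = counts, deer = deer,
                        climate = climate_seasonal)
  if (!"preprocess" %in% stages) return(.finish_pipeline(result, log))

  note("stage preprocess: reassigning unknowns, adjusting undercounts (",
       config$chamois_adjust, " / ", config$deer_adjust, ")")
  classified <- reassign_unknowns(counts)
  adjusted <- adjust_counts(classified, config$chamois_adjust)
  deer_adj <- data.frame(year = deer$year,
                         count = adjust_counts(deer$count,
                                               config$deer_adjust))
  result$classified <- classified
  result$adjusted <- adjusted
  result$deer_adjusted <- deer_adj
  if (!"filter" %in% stages) return(.finish_pipeline(result, log))

  filtered <- adjusted
  deer_f <- deer_adj
  fits <- NULL
  if (config$filter) {
    note("stage filter: state-space filtering class and deer series")
    cls <- c("kid", "yearling", "adult_female", "adult_male")
    fits <- lapply(cls, function(cl) .filter_series(adjusted[[cl]],
                                                    config$gompertz))
    names(fits) <- cls
    for (cl in cls) filtered[[cl]] <- fits[[cl]]$smoothed
    dfit <- .filter_series(deer_adj$count, config$gompertz)
    fits$deer <- dfit
    deer_f$count <- dfit$smoothed
  } else {
    note("stage filter: skipped (config$filter = FALSE)")
  }
  result$filtered <- filtered
  result$deer_filtered <- deer_f
  result$state_space <- fits
  if (!"rates" %in% stages) return(.finish_pipeline(result, log))

  note("stage rates: vital rates and covariates")
  rates <- compute_vital_rates(filtered)
  ncham <- filtered$yearling + filtered$adult_female + filtered$adult_male
  if (!config$exclude_kids) ncham <- ncham + filtered$kid
  covariates <- data.frame(
    year = filtered$year,
    P_winter = climate_seasonal$P_winter[match(filtered$year,
                                               climate_seasonal$year)],
    P_spring_summer = climate_seasonal$P_spring_summer[
      match(filtered$year, climate_seasonal$year)],
    N_chamois = ncham,
    N_deer = deer_f$count[match(filtered$year, deer_f$year)])
  result$rates <- rates
  result$covariates <- covariates
  if (!"select" %in% stages) return(.finish_pipeline(result, log))

  note("stage select: 19-model candidate sets, AICc averaging, diagnostics")
  selection <- list()
  for (resp in c("Br", "Ks", "Fs", "Ms")) {
    design <- build_design(resp, rates, covariates)
    specs <- build_model_set(resp, structures = config$structures)
    fits_r <- lapply(specs, function(sp) fit_ols(design, sp))
    ranking <- rank_and_weight(fits_r)
    if (config$bootstrap_B > 0) {
      ranking$rmse <- vapply(ranking$model, function(nm) {
        bootstrap_rmse(design, specs[[nm]], B = config$bootstrap_B,
                       seed = config$seed)$corrected
      }, numeric(1))
    }
    averaged <- average_models(fits_r, delta_max = config$delta_max,
                               method = config$averaging)
    glob_terms <- if (resp == "Br") .global_structures$Br else
      .global_structures$surv
    glob <- fit_ols(design, model_spec(paste0("global.", tolower(resp)),
                                       glob_terms, response = resp,
                                       validate = FALSE))
    dw <- durbin_watson(glob$residuals, seed = config$seed)
    top_spec <- specs[[ranking$model[1]]]
    robust <- tryCatch(robust_fit(design, top_spec), error = function(e) {
      note("robust refit of ", top_spec$name, " failed: ",
           conditionMessage(e))
      NULL
    })
    selection[[resp]] <- list(design = design, fits = fits_r,
                              ranking = ranking, averaged = averaged,
                              global = glob,
                              diagnostics = list(vif = glob$vif, dw = dw),
                              robust = robust)
  }
  result$selection <- selection
  if (!"path" %in% stages) return(.finish_pipeline(result, log))

  note("stage path: four mediation models")
  path_data <- build_path_data(rates, covariates)
  path_fits <- lapply(c("Br", "Ks", "Fs", "Ms"), function(m)
    fit_path_model(path_data, m, chisq_scale = config$chisq_scale))
  names(path_fits) <- c("Br", "Ks", "Fs", "Ms")
  result$path <- list(data = path_data, fits = path_fits,
                      comparison = compare_path_models(
                        path_fits, rmsea_max = config$rmsea_max))
  .finish_pipeline(result, log)
}

.finish_pipeline <- function(result, log) {
  result$log <- log
  class(result) <- "chamois_pipeline"
  outdir <- result$config$outdir
  if (!is.null(outdir)) .write_pipeline_outputs(result, outdir)
  result
}

.write_pipeline_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x))
      utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  wr(result$inputs$counts, "counts_raw")
  wr(result$classified, "counts_classified")
  wr(result$adjusted, "counts_adjusted")
  wr(result$filtered, "counts_filtered")
  wr(result$rates, "vital_rates")
  wr(result$covariates, "covariates")
  if (!is.null(result$selection)) {
    for (resp in names(result$selection)) {
      wr(result$selection[[resp]]$ranking,
         paste0("selection_", tolower(resp)))
      wr(result$selection[[resp]]$averaged,
         paste0("averaged_", tolower(resp)))
    }
  }
  if (!is.null(result$path)) wr(result$path$comparison, "path_comparison")
  cfg <- result$config
  manifest <- list(
    package = "chamoisdem",
    package_version = as.character(utils::packageVersion("chamoisdem")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "structures")],
    timestamp_free = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, null = "null")
  writeLines(result$log, file.path(outdir, "run.log"))
  invisible(outdir)
}

#' @export
print.chamois_pipeline <- function(x, ...) {
  cat("chamois demographic analysis pipeline\n")
  for (l in x$log) cat(" -", l, "\n")
  if (!is.null(x$selection)) {
    cat("top models: ",
        paste(vapply(x$selection, function(s) s$ranking$model[1],
                     character(1)), collapse = ", "), "\n")
  }
  if (!is.null(x$path)) {
    best <- x$path$comparison$mediator[1]
    cat("best path mediator by AIC:", best, "\n")
  }
  invisible(x)
}
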