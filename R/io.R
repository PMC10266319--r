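#' Read and write the two CSV trial formats
#'
#' Long daily-state format: columns `patient_id,day,state` with state
#' strings exactly `home|hospital|life_support|dead`.  Per-patient format:
#' `patient_id,arm,outcome,died` plus optional covariate columns.
#'
#' @param path File path.
#' @return `read_daily_csv`: a validated daily-state tibble.
#' @export
read_daily_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_daily(tibble::as_tibble(d))
}

#' @rdname read_daily_csv
#' @param spec An [outcome_spec] used to validate the per-patient table.
#' @param arm_levels Optional arm ordering (first = control).
#' @return `read_trial_csv`: a validated `dawols_trial` tibble.
#' @export
read_trial_csv <- function(path, spec, arm_levels = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$died <- as.logical(d$died)
  trial_table(tibble::as_tibble(d), spec, arm_levels = arm_levels)
}

#' @rdname read_daily_csv
#' @param data Table to write.
#' @export
write_trial_csv <- function(data, path) {
  cols <- setdiff(names(data), "raw_days")
  utils::write.csv(as.data.frame(data)[, c(cols, intersect("raw_days",
                                                           names(data)))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_daily_csv
#' @export
write_daily_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, c("patient_id", "day", "state")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load an outcome specification from a YAML or JSON config
#'
#' Recognised keys: `max_days`, `death_handling`, `scale`, `free_states`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [outcome_spec].
#' @export
read_outcome_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  outcome_spec(cfg$max_days,
               cfg$death_handling %||% "penalize_zero",
               cfg$scale %||% "days",
               unlist(cfg$free_states) %||% c("home", "hospital"))
}

#' Load arm scenarios from a YAML config
#'
#' The file maps arm names (first = control) to [arm_scenario] fields.
#'
#' @param path Path to a YAML file.
#' @return Named list of [arm_scenario] objects.
#' @export
read_scenarios <- function(path) {
  ## identity handlers keep scenario keys like `n` from parsing as booleans
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) x, "bool#no" = function(x) x))
  lapply(cfg, function(s) do.call(arm_scenario, s))
}

#' Serialise a fit to JSON
#'
#' Writes the family, point estimates and per-parameter draw summaries
#' (median, 95% percentile interval) plus engine metadata; optionally the
#' full draws matrix as CSV next to it.
#'
#' @param fit A `dawols_fit`.
#' @param path Output JSON path.
#' @param draws_csv Optional path for the full draws matrix.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, draws_csv = NULL) {
  summ <- apply(fit$draws, 2, summarize_draws)
  obj <- list(
    family = fit$family,
    point = as.list(fit$point),
    draw_summaries = apply(summ, 2, as.list),
    value_map = fit$value_map,
    metadata = fit$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(draws_csv))
    utils::write.csv(as.data.frame(fit$draws), draws_csv, row.names = FALSE)
  invisible(path)
}

#' Fit all four families and assemble the comparison report
#'
#' The package's one-call workflow: takes a days-scale trial table with
#' deaths coded 0, derives the ordinal (-1) recoding for the cumulative
#' model, fits the linear, hurdle negative-binomial, zero-one-inflated
#' beta and cumulative logistic families, and returns the fits together
#' with the fitness/estimand report and the cumulative odds ratio.
#'
#' @param data A `dawols_trial` on the days scale with deaths coded 0.
#' @param spec The matching [outcome_spec] (`death_handling`
#'   `"penalize_zero"`).
#' @param draws Uncertainty draws per fit.
#' @param seed Integer seed.
#' @param terms Predictors (default treatment arm only).
#' @return A list with `fits` (named list), `report` (tibble from
#'   [fitness_report]) and `cumulative_or` (tibble).
#' @export
compare_models <- function(data, spec, draws = 1000, seed = 1L,
                           terms = "arm") {
  .assert(spec$death_handling == "penalize_zero" && spec$scale == "days",
          "compare_models expects a days-scale table with deaths coded 0")
  arms <- levels(data$arm)
  spec_prop <- outcome_spec(spec$max_days, "penalize_zero", "proportion",
                            spec$free_states)
  spec_ord <- outcome_spec(spec$max_days, "penalize_minus_one", "ordinal",
                           spec$free_states)
  data_ord <- data
  data_ord$outcome <- apply_death_handling(data$raw_days %||%
                                             pmax(data$outcome, 0),
                                           data$died, spec_ord)
  ## deaths must sit in the worst category even under "actual"-style raw
  data_ord$outcome[data_ord$died] <- -1L
  data_ord <- trial_table(as.data.frame(data_ord), spec_ord,
                          arm_levels = arms)
  fits <- list(
    linear = fit_model(model_spec("linear", terms), data, spec,
                       draws = draws, seed = seed),
    hurdle_nb = fit_model(model_spec("hurdle_nb", terms), data, spec,
                          draws = draws, seed = seed),
    zoib = fit_model(model_spec("zoib", terms), data, spec_prop,
                     draws = draws, seed = seed),
    cumlogit = fit_model(model_spec("cumlogit", terms), data_ord, spec_ord,
                         draws = draws, seed = seed))
  list(fits = fits,
       report = fitness_report(fits, data),
       cumulative_or = cumulative_odds_ratio(fits$cumlogit))
}
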