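#' Validate a daily-state table
#'
#' Checks the structural invariants of a long daily-state table: one row per
#' patient-day, days contiguous from 1, states drawn from [dawols_states],
#' and death absorbing (once dead, dead on every later day).
#'
#' @param daily A data frame with columns `patient_id`, `day`, `state`.
#' @return The table, invisibly, with `day` as integer.  Errors name the
#'   offending patient and day.
#' @export
validate_daily <- function(daily) {
  .assert(all(c("patient_id", "day", "state") %in% names(daily)),
          "daily table needs columns patient_id, day, state")
  bad <- setdiff(unique(daily$state), dawols_states)
  .assert(length(bad) == 0, "unknown state(s): %s", paste(bad, collapse = ", "))
  daily$day <- as.integer(daily$day)
  ord <- order(daily$patient_id, daily$day)
  daily <- daily[ord, , drop = FALSE]
  for (rows in split(seq_len(nrow(daily)), daily$patient_id)) {
    pid <- daily$patient_id[rows[1]]
    d <- daily$day[rows]
    if (!identical(d, seq_len(length(d)))) {
      miss <- setdiff(seq_len(max(d)), d)
      stop("patient ", pid, ": days must be contiguous from 1; ",
           if (length(miss)) paste0("missing day ", miss[1])
           else "duplicated or non-positive days", call. = FALSE)
    }
    s <- daily$state[rows]
    dead <- which(s == "dead")
    if (length(dead) && any(s[seq(dead[1], length(s))] != "dead"))
      stop("patient ", pid, ": death must be absorbing (non-dead state ",
           "after day ", dead[1], ")", call. = FALSE)
  }
  invisible(daily)
}

#' Construct outcomes from a daily-state table
#'
#' Collapses per-day states into the per-patient outcome: the number of days
#' within the follow-up window spent alive in one of the "free" states
#' (by default home or hospital without life support), with death handled
#' according to the outcome specification.  Days after discharge and days
#' between repeat life-support episodes count, so occurrent events are
#' incorporated naturally.  The day of death, and any day on life support,
#' never counts as a free day.
#'
#' @param daily A daily-state table (see [validate_daily]); every patient must
#'   have at least `spec$max_days` days of follow-up.
#' @param spec An [outcome_spec].
#' @return A [tibble::tibble] with columns `patient_id`, `raw_days` (free days
#'   before death handling), `died` (death within the window) and `outcome`.
#' @examples
#' daily <- data.frame(
#'   patient_id = "p1", day = 1:28,
#'   state = c(rep("life_support", 5), rep("hospital", 5), rep("home", 18)))
#' build_outcome_from_daily(daily, outcome_spec(28, "penalize_zero", "days"))
#' @export
build_outcome_from_daily <- function(daily, spec) {
  stopifnot(inherits(spec, "dawols_outcome_spec"))
  daily <- validate_daily(daily)
  win <- daily[daily$day <= spec$max_days, , drop = FALSE]
  n_days <- tapply(win$day, win$patient_id, length)
  short <- names(n_days)[n_days < spec$max_days]
  .assert(length(short) == 0,
          "patient %s has fewer than max_days = %d days of follow-up",
          short[1], spec$max_days)
  free <- tapply(win$state %in% spec$free_states, win$patient_id, sum)
  died <- tapply(win$state == "dead", win$patient_id, any)
  pid <- names(free)
  raw <- as.integer(free[pid])
  dd <- as.logical(died[pid])
  tibble::tibble(patient_id = pid, raw_days = raw, died = dd,
                 outcome = apply_death_handling(raw, dd, spec))
}

#' Apply a death-handling rule to raw free-day counts
#'
#' @param raw_count Integer vector of free days in `[0, max_days]`.
#' @param died Logical vector; death within the follow-up window.
#' @param spec An [outcome_spec]; its `death_handling` decides the result:
#'   non-survivors get 0 (`penalize_zero`), -1 (`penalize_minus_one`, ordinal
#'   scale only) or keep their raw count (`actual`).  Survivors are never
#'   altered.
#' @return Integer outcome vector.
#' @export
apply_death_handling <- function(raw_count, died, spec) {
  stopifnot(inherits(spec, "dawols_outcome_spec"))
  .assert(all(raw_count >= 0 & raw_count <= spec$max_days),
          "raw counts must lie in [0, max_days]")
  .assert(length(raw_count) == length(died), "length mismatch")
  out <- as.integer(raw_count)
  out[died] <- switch(spec$death_handling,
                      penalize_zero = 0L,
                      penalize_minus_one = -1L,
                      actual = out[died])
  out
}

#' Rescale day counts to proportions of the follow-up window
#'
#' Boundary membership (exactly 0 or exactly 1) is decided on the integer
#' inputs, never by floating-point comparison of the ratio.
#'
#' @param outcome_days Integer day counts in `[0, max_days]`; the -1 death
#'   code is rejected (recode deaths to 0 first).
#' @param max_days Positive integer follow-up length.
#' @return Numeric proportions in `[0, 1]`.
#' @export
to_proportion <- function(outcome_days, max_days) {
  .assert(.is_count(max_days), "`max_days` must be a positive integer")
  if (any(outcome_days == -1))
    stop("outcome contains the -1 death code; beta-type models need deaths ",
         "assigned 0 days (death_handling \"penalize_zero\") before ",
         "rescaling to proportions", call. = FALSE)
  .assert(all(outcome_days >= 0 & outcome_days <= max_days &
                outcome_days == round(outcome_days)),
          "outcome days must be integers in [0, max_days]")
  p <- as.numeric(outcome_days) / max_days
  p[outcome_days == 0] <- 0
  p[outcome_days == max_days] <- 1
  p
}

#' Map outcomes to ordered categories
#'
#' Builds the category system used by the cumulative (proportional-odds)
#' logistic model: the distinct observed values, sorted ascending, with -1
#' (the death category) first when present.
#'
#' @param outcomes Integer vector of values in `{-1} U [0, max_days]`.
#' @return A list with `index` (1-based category per observation) and
#'   `values` (the ascending index-to-value map).
#' @export
to_ordinal_categories <- function(outcomes) {
  .assert(all(outcomes == round(outcomes) & outcomes >= -1),
          "ordinal outcomes must be integers >= -1")
  values <- sort(unique(as.integer(outcomes)))
  if (length(values) < 3)
    stop("fewer than 3 distinct outcome values; an ordinal model is ",
         "degenerate here - use a logistic model instead", call. = FALSE)
  list(index = match(as.integer(outcomes), values), values = values)
}

#' Assemble and validate a per-patient trial table
#'
#' @param data A data frame with columns `patient_id`, `arm`, `outcome`,
#'   `died`, plus optional covariate columns.  `arm` is coerced to a factor;
#'   its first level is the control group.
#' @param spec An [outcome_spec] used to check the outcome range and death
#'   coding.
#' @param arm_levels Optional explicit arm ordering (first = control).
#' @return A `tibble` of class `dawols_trial`, validated.
#' @export
trial_table <- function(data, spec, arm_levels = NULL) {
  stopifnot(inherits(spec, "dawols_outcome_spec"))
  .assert(all(c("patient_id", "arm", "outcome", "died") %in% names(data)),
          "trial table needs columns patient_id, arm, outcome, died")
  data <- tibble::as_tibble(data)
  data$arm <- if (is.null(arm_levels)) {
    if (is.factor(data$arm)) data$arm else factor(data$arm)
  } else factor(data$arm, levels = arm_levels)
  .assert(!anyNA(data$arm) && !anyNA(data$outcome),
          "missing values in arm/outcome are not supported")
  .assert(nlevels(data$arm) >= 2 && all(table(data$arm) > 0),
          "at least 2 non-empty arms are required")
  .assert(all(data$outcome <= spec$max_days),
          "outcomes above max_days found")
  .assert(all(data$outcome >= -1), "outcomes below -1 found")
  if (any(data$outcome == -1)) {
    .assert(spec$death_handling == "penalize_minus_one",
            "-1 outcomes require death_handling \"penalize_minus_one\"")
    .assert(all(data$died[data$outcome == -1]),
            "-1 outcomes found for survivors")
  }
  if (spec$death_handling == "penalize_zero")
    .assert(all(data$outcome[data$died] == 0),
            "under penalize_zero all non-survivors must have outcome 0")
  class(data) <- c("dawols_trial", class(data))
  attr(data, "outcome_spec") <- spec
  data
}
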