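#' Describe one arm of a synthetic trial
#'
#' A generative scenario for one treatment arm, shaped like the published
#' distributions of 28-day DAWOLS in severe respiratory failure: a heavy
#' point mass at the minimum (deaths), a secondary point mass at the maximum
#' (patients never on life support within follow-up) and a skewed interior.
#' A patient is simulated as: death with probability `p_death` (0 free days;
#' simulated non-survivors spend their pre-death days on life support); else
#' the maximum value with probability `p_max`; else an interior free-day
#' count drawn from a negative-binomial distribution with mean
#' `interior_mean` and dispersion `interior_dispersion` truncated to
#' `1..max_days - 1`.
#'
#' @param n Number of patients in the arm.
#' @param p_death Probability of death within follow-up.
#' @param p_max Probability, among survivors, of the maximum value.
#' @param interior_mean Mean of the untruncated negative-binomial free-day
#'   distribution for the remaining survivors (days; in `(0, max_days)`).
#' @param interior_dispersion Negative-binomial dispersion (`size`); smaller
#'   values give more overdispersion.
#' @param death_day_rate Rate of the geometric death-day distribution
#'   (truncated to the follow-up window); affects only the daily-state
#'   expansion, never the outcome value.
#' @param covariate_effect Additive shift of `interior_mean` (days) for
#'   patients with the optional binary prognostic covariate set to 1.
#' @return An object of class `dawols_arm_scenario`.
#' @export
arm_scenario <- function(n, p_death, p_max, interior_mean,
                         interior_dispersion, death_day_rate = 0.15,
                         covariate_effect = 0) {
  .assert(.is_count(n), "`n` must be a positive integer")
  .assert(p_death >= 0 && p_death <= 1 && p_max >= 0 && p_max <= 1,
          "probabilities must lie in [0, 1]")
  .assert(interior_mean > 0, "`interior_mean` must be positive")
  .assert(interior_dispersion > 0, "`interior_dispersion` must be positive")
  .assert(death_day_rate > 0 && death_day_rate < 1,
          "`death_day_rate` must lie in (0, 1)")
  structure(list(n = as.integer(n), p_death = p_death, p_max = p_max,
                 interior_mean = interior_mean,
                 interior_dispersion = interior_dispersion,
                 death_day_rate = death_day_rate,
                 covariate_effect = covariate_effect),
            class = "dawols_arm_scenario")
}

#' Default two-arm scenarios
#'
#' The study conditions used throughout the package's tests and examples: a
#' two-arm trial whose outcome distribution emulates published 28-day DAWOLS
#' data from a large ICU corticosteroid trial -- 28-day mortality around
#' 32% (control) and 27% (intervention), a substantial secondary peak at
#' the maximum (survivors never on life support within follow-up), and a
#' left-skewed interior.  The implied true group means under death = 0 are
#' about 14.8 (control) and 16.3 (intervention) days.
#'
#' @param n_per_arm Patients per arm (the emulated trial analysed 971 in
#'   total).
#' @return Named list of [arm_scenario] objects; the first is the control.
#' @export
default_scenarios <- function(n_per_arm = 486) {
  list(
    control = arm_scenario(n_per_arm, p_death = 0.32, p_max = 0.40,
                           interior_mean = 23, interior_dispersion = 6),
    intervention = arm_scenario(n_per_arm, p_death = 0.27, p_max = 0.44,
                                interior_mean = 24, interior_dispersion = 6)
  )
}

## interior pmf over free days 1..max_days-1 (NB truncated to that range)
.interior_pmf <- function(s, max_days, mean_shift = 0) {
  k <- seq_len(max_days - 1L)
  m <- min(max(s$interior_mean + mean_shift, 0.25), max_days - 0.25)
  w <- stats::dnbinom(k, size = s$interior_dispersion, mu = m)
  if (sum(w) <= 0) w <- rep(1, length(k))
  w / sum(w)
}

.death_day_pmf <- function(s, max_days) {
  d <- seq_len(max_days)
  w <- stats::dgeom(d - 1L, prob = s$death_day_rate)
  w / sum(w)
}

#' Exact expected outcome under a scenario
#'
#' Closed-form mixture mean
#' `p_death * v_death + (1 - p_death) * (p_max * max_days + (1 - p_max) * E[interior])`,
#' with the interior expectation computed by exact summation over
#' `1..max_days - 1` and `v_death` the death value implied by the outcome
#' specification (0 under `penalize_zero`, -1 under `penalize_minus_one`, and
#' 0 under `actual` since simulated non-survivors accrue no free days).
#'
#' @param s An [arm_scenario].
#' @param spec An [outcome_spec].
#' @return The expected outcome value (days scale).
#' @export
scenario_true_mean <- function(s, spec) {
  stopifnot(inherits(s, "dawols_arm_scenario"),
            inherits(spec, "dawols_outcome_spec"))
  v_death <- switch(spec$death_handling,
                    penalize_zero = 0, penalize_minus_one = -1, actual = 0)
  pmf <- .interior_pmf(s, spec$max_days)
  e_int <- sum(seq_len(spec$max_days - 1L) * pmf)
  s$p_death * v_death +
    (1 - s$p_death) * (s$p_max * spec$max_days + (1 - s$p_max) * e_int)
}

#' Simulate a multi-arm trial with inflated count outcomes
#'
#' Draws per-patient outcomes arm by arm under [arm_scenario] mixtures.  Each
#' arm uses its own child random stream derived from the root seed and the
#' arm label, so adding an arm never perturbs the draws of existing arms; the
#' same seed always yields an identical table.
#'
#' @param scenarios Named list of [arm_scenario]s; the first name is the
#'   control arm.
#' @param spec An [outcome_spec].
#' @param seed Integer root seed.
#' @param daily If `TRUE`, also expand each patient into a consistent
#'   daily-state trajectory (death day from the geometric death-day
#'   distribution; pre-death and pre-recovery life-support days placed as a
#'   single leading block, then hospital, then home), attached as
#'   `attr(, "daily")`.
#' @param covariate Optional list `list(name =, prevalence =)` adding a
#'   binary prognostic covariate that shifts the interior mean by each
#'   scenario's `covariate_effect`.
#' @return A `dawols_trial` table (see [trial_table]).
#' @export
simulate_trial <- function(scenarios, spec, seed, daily = FALSE,
                           covariate = NULL) {
  stopifnot(inherits(spec, "dawols_outcome_spec"))
  .assert(length(scenarios) >= 2 && !is.null(names(scenarios)),
          "at least two named arm scenarios are required")
  arms <- names(scenarios)
  res <- vector("list", length(arms))
  daily_res <- if (daily) vector("list", length(arms))
  for (i in seq_along(arms)) {
    a <- arms[i]
    s <- scenarios[[a]]
    stopifnot(inherits(s, "dawols_arm_scenario"))
    set.seed(.arm_child_seed(seed, a))
    n <- s$n
    cov_val <- if (!is.null(covariate))
      stats::rbinom(n, 1L, covariate$prevalence) else NULL
    died <- stats::runif(n) < s$p_death
    at_max <- !died & (stats::runif(n) < s$p_max)
    raw <- integer(n)
    raw[at_max] <- spec$max_days
    interior <- which(!died & !at_max)
    if (length(interior)) {
      if (is.null(cov_val) || s$covariate_effect == 0) {
        pmf <- .interior_pmf(s, spec$max_days)
        raw[interior] <- sample(seq_len(spec$max_days - 1L), length(interior),
                                replace = TRUE, prob = pmf)
      } else {
        for (cv in c(0L, 1L)) {
          idx <- interior[cov_val[interior] == cv]
          if (!length(idx)) next
          pmf <- .interior_pmf(s, spec$max_days, cv * s$covariate_effect)
          raw[idx] <- sample(seq_len(spec$max_days - 1L), length(idx),
                             replace = TRUE, prob = pmf)
        }
      }
    }
    death_day <- rep(NA_integer_, n)
    if (any(died))
      death_day[died] <- sample(seq_len(spec$max_days), sum(died),
                                replace = TRUE,
                                prob = .death_day_pmf(s, spec$max_days))
    pid <- sprintf("%s-%04d", a, seq_len(n))
    tab <- tibble::tibble(
      patient_id = pid, arm = a,
      raw_days = raw, died = died,
      outcome = apply_death_handling(raw, died, spec)
    )
    if (!is.null(cov_val)) tab[[covariate$name]] <- cov_val
    res[[i]] <- tab
    if (daily)
      daily_res[[i]] <- .expand_daily(pid, raw, died, death_day, spec)
  }
  out <- do.call(rbind, res)
  out <- trial_table(out, spec, arm_levels = arms)
  if (daily) attr(out, "daily") <- do.call(rbind, daily_res)
  out
}

## One trajectory per patient: non-survivors are on life support until the
## day of death; survivors spend max_days - free days on life support as a
## single leading block, then split the free days between hospital and home.
.expand_daily <- function(pid, raw, died, death_day, spec) {
  md <- spec$max_days
  n <- length(pid)
  states <- matrix("home", nrow = n, ncol = md)
  for (i in seq_len(n)) {
    if (died[i]) {
      d <- death_day[i]
      if (d > 1) states[i, seq_len(d - 1L)] <- "life_support"
      states[i, d:md] <- "dead"
    } else {
      supp <- md - raw[i]
      if (supp > 0) states[i, seq_len(supp)] <- "life_support"
      if (raw[i] > 0) {
        hosp <- ceiling(raw[i] / 2)
        if (hosp > 0) states[i, supp + seq_len(hosp)] <- "hospital"
      }
    }
  }
  tibble::tibble(
    patient_id = rep(pid, each = md),
    day = rep(seq_len(md), times = n),
    state = as.vector(t(states))
  )
}

#' Simulate an ordinal trial under exact proportional odds
#'
#' Draws a two-arm ordinal outcome from a cumulative logistic model, so the
#' proportional-odds assumption holds by construction.  Used to exercise the
#' cumulative model under its own assumption (the mixture generator of
#' [simulate_trial] does not satisfy proportional odds in general).
#'
#' @param n_per_arm Patients per arm.
#' @param values Ascending integer value map (categories); `-1` may be the
#'   first value to act as the death category.
#' @param control_probs Category probabilities in the control arm.
#' @param log_or Log cumulative odds ratio of the intervention (positive
#'   favours higher categories).
#' @param spec An [outcome_spec] with `scale = "ordinal"`.
#' @param seed Integer seed.
#' @param arms Arm labels (control first).
#' @return A `dawols_trial` table.
#' @export
simulate_po_trial <- function(n_per_arm, values, control_probs, log_or,
                              spec, seed,
                              arms = c("control", "intervention")) {
  .assert(length(values) == length(control_probs) && length(values) >= 3,
          "values and control_probs must match with length >= 3")
  .assert(abs(sum(control_probs) - 1) < 1e-8, "control_probs must sum to 1")
  values <- as.integer(values)
  .assert(!is.unsorted(values, strictly = TRUE), "values must be ascending")
  K <- length(values)
  theta <- stats::qlogis(cumsum(control_probs)[-K])
  probs <- list(control_probs,
                diff(c(0, stats::plogis(theta - log_or), 1)))
  res <- vector("list", 2L)
  for (i in 1:2) {
    set.seed(.arm_child_seed(seed, arms[i]))
    y <- values[sample.int(K, n_per_arm, replace = TRUE, prob = probs[[i]])]
    res[[i]] <- tibble::tibble(
      patient_id = sprintf("%s-%04d", arms[i], seq_len(n_per_arm)),
      arm = arms[i], raw_days = pmax(y, 0L), died = y == -1L, outcome = y)
  }
  trial_table(do.call(rbind, res), spec, arm_levels = arms)
}
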