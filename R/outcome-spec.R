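#' Daily patient states
#'
#' The four mutually exclusive states a patient can occupy on any day after
#' randomisation: at home, in hospital without life support, in hospital on
#' life support (mechanical ventilation, vasopressors/inotropes or renal
#' replacement therapy), or dead.  Death is absorbing.
#'
#' @format Character vector of length 4.
#' @export
dawols_states <- c("home", "hospital", "life_support", "dead")

#' Define how a days-alive-type outcome is operationalised
#'
#' An outcome specification fixes the three decisions needed before a
#' days-alive-without-life-support (DAWOLS) or days-alive-out-of-hospital
#' (DAOH) outcome can be constructed and modelled: the follow-up truncation,
#' the handling of death, and the analysis scale.
#'
#' @param max_days Positive integer; length of the follow-up window in days
#'   (the outcome is truncated at this value, e.g. 28).
#' @param death_handling One of `"penalize_zero"` (non-survivors are assigned
#'   0 days, the worst possible count), `"penalize_minus_one"` (non-survivors
#'   are assigned -1, an ordinal category worse than all real values; only
#'   valid with `scale = "ordinal"`), or `"actual"` (the observed number of
#'   free days is kept regardless of vital status).
#' @param scale Analysis scale: `"days"` (counts 0..`max_days`),
#'   `"proportion"` (counts rescaled to `k / max_days`), or `"ordinal"`
#'   (each distinct value its own ordered category).
#' @param free_states Character subset of [dawols_states] (excluding
#'   `"dead"`) that counts as a "free" day.  The default
#'   `c("home", "hospital")` yields DAWOLS; use `"home"` for DAOH.  The same
#'   machinery serves both definitions.
#'
#' @return An object of class `dawols_outcome_spec`.
#' @examples
#' outcome_spec(28, "penalize_zero", "days")
#' outcome_spec(28, "penalize_minus_one", "ordinal")
#' outcome_spec(90, "actual", "days", free_states = "home") # DAOH
#' @export
outcome_spec <- function(max_days,
                         death_handling = c("penalize_zero",
                                            "penalize_minus_one", "actual"),
                         scale = c("days", "proportion", "ordinal"),
                         free_states = c("home", "hospital")) {
  death_handling <- match.arg(death_handling)
  scale <- match.arg(scale)
  .assert(.is_count(max_days), "`max_days` must be a positive integer")
  .assert(length(free_states) >= 1 &&
            all(free_states %in% setdiff(dawols_states, "dead")),
          "`free_states` must be a non-empty subset of %s",
          paste(setdiff(dawols_states, "dead"), collapse = "/"))
  if (death_handling == "penalize_minus_one" && scale != "ordinal")
    stop("death_handling \"penalize_minus_one\" is only valid with ",
         "scale \"ordinal\"; use \"penalize_zero\" on the days or ",
         "proportion scale", call. = FALSE)
  structure(
    list(max_days = as.integer(max_days), death_handling = death_handling,
         scale = scale, free_states = free_states),
    class = "dawols_outcome_spec"
  )
}

#' @export
print.dawols_outcome_spec <- function(x, ...) {
  cat("<outcome spec> ", x$max_days, "-day follow-up, deaths: ",
      x$death_handling, ", scale: ", x$scale,
      ", free states: {", paste(x$free_states, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}
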