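## shared fixtures, all built in code

spec_days <- outcome_spec(28, "penalize_zero", "days")
spec_prop <- outcome_spec(28, "penalize_zero", "proportion")
spec_ord <- outcome_spec(28, "penalize_minus_one", "ordinal")
spec_actual <- outcome_spec(28, "actual", "days")

## one patient's daily rows from a state vector
daily_from_states <- function(states, pid = "p1") {
  data.frame(patient_id = pid, day = seq_along(states), state = states,
             stringsAsFactors = FALSE)
}

## recode a deaths-as-zero days table to the ordinal -1 coding
to_ordinal_table <- function(tt) {
  d <- as.data.frame(tt)
  d$outcome <- ifelse(d$died, -1L, d$outcome)
  trial_table(d, spec_ord, arm_levels = levels(tt$arm))
}

## small two-arm trial used across tests
small_trial <- function(n = 150, seed = 101) {
  simulate_trial(default_scenarios(n), spec_days, seed = seed)
}
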