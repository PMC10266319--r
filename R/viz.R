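## Figures for raw outcome data and daily states.  Every figure has a
## tidy-table twin: the plot functions are pure functions of those tables,
## so tests assert on the tables and the figures are for eyes.  Group
## colours default to control = red, intervention = blue; deterministic
## layout throughout (fixed orderings, no jitter).

.arm_colours <- function(arms) {
  base <- c("#C0392B", "#2E6FBA", "#7D9C43", "#8E5DA8", "#C98A27")
  stats::setNames(base[(seq_along(arms) - 1L) %% length(base) + 1L], arms)
}

#' Per-arm outcome distribution summaries
#'
#' The printed block accompanying distribution panels: median, IQR and the
#' percentages of patients at the minimum value, strictly between minimum
#' and maximum, and at the maximum value.
#'
#' @param data A `dawols_trial` table.
#' @param spec The [outcome_spec] of `data` (defaults to the attached one).
#' @return A tibble with one row per arm.
#' @export
distribution_summary <- function(data, spec = attr(data, "outcome_spec")) {
  stopifnot(inherits(spec, "dawols_outcome_spec"))
  min_val <- min(data$outcome)
  rows <- lapply(levels(factor(data$arm)), function(a) {
    y <- data$outcome[data$arm == a]
    q <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      arm = a, n = length(y), median = q[2], q25 = q[1], q75 = q[3],
      pct_min = 100 * mean(y == min_val),
      pct_between = 100 * mean(y > min_val & y < spec$max_days),
      pct_max = 100 * mean(y == spec$max_days))
  })
  do.call(rbind, rows)
}

#' Histogram panels of the outcome distribution
#'
#' One histogram per arm (and per death-handling variant when several
#' tables are supplied), annotated by the [distribution_summary] block.
#'
#' @param ... One or more `dawols_trial` tables, named by variant (e.g.
#'   `actual =`, `death_as_zero =`, `death_as_minus_one =`).
#' @return A list with `plot` (ggplot) and `summary` (tibble over arms and
#'   variants).
#' @export
plot_distribution_panels <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    names(tabs) <- paste0("variant", seq_along(tabs))
  long <- do.call(rbind, lapply(names(tabs), function(v)
    tibble::tibble(variant = v, arm = as.character(tabs[[v]]$arm),
                   outcome = tabs[[v]]$outcome)))
  summ <- do.call(rbind, lapply(names(tabs), function(v) {
    s <- distribution_summary(tabs[[v]])
    s$variant <- v
    s
  }))
  arms <- sort(unique(long$arm))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$outcome,
                                          fill = .data$arm)) +
    ggplot2::geom_histogram(binwidth = 1, position = "identity",
                            alpha = 0.6, boundary = -0.5) +
    ggplot2::facet_grid(arm ~ variant) +
    ggplot2::scale_fill_manual(values = .arm_colours(arms)) +
    ggplot2::labs(x = "days", y = "patients") +
    ggplot2::theme_minimal()
  list(plot = p, summary = summ)
}

#' Cumulative percentage of patients by outcome value
#'
#' Per arm, the percentage of patients with an outcome less than or equal
#' to each observed value (a step curve over the sorted distinct values,
#' -1 included when present; the last point is always 100).
#'
#' @param data A `dawols_trial` table.
#' @return A tibble `arm, value, cum_pct`.
#' @export
cumulative_pct_table <- function(data) {
  values <- sort(unique(as.integer(data$outcome)))
  rows <- lapply(levels(factor(data$arm)), function(a) {
    y <- data$outcome[data$arm == a]
    tibble::tibble(arm = a, value = values,
                   cum_pct = 100 * vapply(values,
                                          function(v) mean(y <= v), 0))
  })
  do.call(rbind, rows)
}

#' @rdname cumulative_pct_table
#' @return `plot_cumulative_pct` returns a list with `plot` and `table`.
#' @export
plot_cumulative_pct <- function(data) {
  tab <- cumulative_pct_table(data)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$value, y = .data$cum_pct,
                                         colour = .data$arm)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = .arm_colours(unique(tab$arm))) +
    ggplot2::labs(x = "days", y = "cumulative % of patients") +
    ggplot2::theme_minimal()
  list(plot = p, table = tab)
}

#' Value "heat map" of the outcome distribution
#'
#' One horizontal stacked bar per arm: segment widths are the proportions
#' of patients with each value (deaths coded 0 days), segments ordered by
#' ascending value and coloured on a red-to-blue gradient -- an overturned
#' stacked bar plot showing the full distributions.
#'
#' @param data A `dawols_trial` table on the days scale with deaths coded
#'   0 (no -1 values).
#' @return `value_heatmap_table`: a tibble `arm, value, prop`.
#' @export
value_heatmap_table <- function(data) {
  .assert(all(data$outcome >= 0),
          "heat map needs deaths coded 0 days (no -1 values)")
  rows <- lapply(levels(factor(data$arm)), function(a) {
    y <- data$outcome[data$arm == a]
    values <- sort(unique(as.integer(y)))
    tibble::tibble(arm = a, value = values,
                   prop = vapply(values, function(v) mean(y == v), 0))
  })
  do.call(rbind, rows)
}

#' @rdname value_heatmap_table
#' @return `plot_value_heatmap` returns a list with `plot` and `table`.
#' @export
plot_value_heatmap <- function(data) {
  tab <- value_heatmap_table(data)
  tab$value_f <- factor(tab$value, levels = sort(unique(tab$value)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$prop, y = .data$arm,
                                         fill = .data$value_f)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                      width = 0.7) +
    ggplot2::scale_fill_manual(
      values = stats::setNames(
        grDevices::colorRampPalette(c("#C0392B", "#2E6FBA"))(
          nlevels(tab$value_f)), levels(tab$value_f)),
      name = "days") +
    ggplot2::labs(x = "proportion of patients", y = NULL) +
    ggplot2::theme_minimal()
  list(plot = p, table = tab[, c("arm", "value", "prop")])
}

#' Daily state occupancy per arm
#'
#' The proportion of each arm's patients in each state (home / hospital /
#' life support / dead) on every day after randomisation.  Proportions sum
#' to 1 each arm-day and the dead proportion is non-decreasing in day.
#'
#' @param daily A daily-state table (see [validate_daily]).
#' @param arms A lookup of arms: either a `dawols_trial` table or a data
#'   frame with `patient_id` and `arm`.
#' @return A tibble of class `dawols_state_occupancy`:
#'   `arm, day, state, prop`.
#' @export
state_occupancy <- function(daily, arms) {
  daily <- validate_daily(daily)
  lk <- stats::setNames(as.character(arms$arm), arms$patient_id)
  arm <- lk[as.character(daily$patient_id)]
  .assert(!anyNA(arm), "daily table contains patients missing from `arms`")
  out <- lapply(sort(unique(arm)), function(a) {
    sub <- daily[arm == a, ]
    n <- length(unique(sub$patient_id))
    tab <- table(factor(sub$state, levels = dawols_states), sub$day) / n
    tibble::tibble(
      arm = a,
      day = rep(as.integer(colnames(tab)), each = nrow(tab)),
      state = rep(rownames(tab), times = ncol(tab)),
      prop = as.vector(tab))
  })
  out <- do.call(rbind, out)
  sums <- tapply(out$prop, paste(out$arm, out$day), sum)
  .assert(all(abs(sums - 1) < 1e-12), "state proportions must sum to 1")
  dead <- out[out$state == "dead", ]
  for (a in unique(dead$arm))
    .assert(!is.unsorted(dead$prop[dead$arm == a]),
            "dead proportion must be non-decreasing in day")
  class(out) <- c("dawols_state_occupancy", class(out))
  out
}

#' @rdname state_occupancy
#' @param so A `dawols_state_occupancy` table.
#' @return `plot_state_occupancy` returns a stacked-area ggplot per arm.
#' @export
plot_state_occupancy <- function(so) {
  stopifnot(inherits(so, "dawols_state_occupancy"))
  so$state <- factor(so$state, levels = c("dead", "life_support",
                                          "hospital", "home"))
  ggplot2::ggplot(so, ggplot2::aes(x = .data$day, y = .data$prop,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::scale_fill_manual(values = c(
      dead = "#2C2C2C", life_support = "#C0392B",
      hospital = "#E8A33D", home = "#2E6FBA")) +
    ggplot2::labs(x = "day after randomisation",
                  y = "proportion of patients") +
    ggplot2::theme_minimal()
}
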