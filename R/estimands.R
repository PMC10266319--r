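#' Summarise draws by median and 95% percentile interval
#'
#' The single summary rule used throughout the package: the median and the
#' 2.5th / 97.5th percentiles of the draws, using R's default
#' linear-interpolation quantile definition (type 7).
#'
#' @param draws Numeric vector of at least one draw.
#' @return Named numeric vector `c(median, lower95, upper95)`.
#' @examples
#' summarize_draws(1:100) # 50.5, 3.475, 98.525
#' @export
summarize_draws <- function(draws) {
  .assert(length(draws) >= 1, "at least one draw is required")
  q <- stats::quantile(draws, c(0.5, 0.025, 0.975), type = 7, names = FALSE)
  c(median = q[1], lower95 = q[2], upper95 = q[3])
}

#' Truncate predictions to the valid outcome space
#'
#' Clamps predicted values to `[0, max_days]` -- or to `[-1, max_days]` for
#' the cumulative model's `minus_one_as_is` variant, where the death
#' category keeps its -1 value.  Truncation is applied at the patient level,
#' before any averaging.
#'
#' @param values Numeric predictions (days scale).
#' @param spec An [outcome_spec].
#' @param variant `"minus_one_as_zero"` (death category remapped to 0 before
#'   weighting) or `"minus_one_as_is"`.
#' @return Clamped values.
#' @export
truncate_to_valid <- function(values, spec,
                              variant = c("minus_one_as_zero",
                                          "minus_one_as_is")) {
  variant <- match.arg(variant)
  lo <- if (variant == "minus_one_as_is") -1 else 0
  clamp(values, lo, spec$max_days)
}

## expected outcome (days scale) per draw for one covariate row.
## Returns a vector over the rows of `Dr` (a draws-or-point matrix).
.expected_days_row <- function(fit, Dr, xrow, variant) {
  idx <- fit$par_index
  md <- fit$outcome_spec$max_days
  switch(fit$family,
    linear = drop(Dr[, idx$mean, drop = FALSE] %*% xrow$mean),
    hurdle_nb = {
      pi0 <- stats::plogis(drop(Dr[, idx$zero, drop = FALSE] %*% xrow$zero))
      mu <- exp(drop(Dr[, idx$count, drop = FALSE] %*% xrow$count))
      (1 - pi0) * truncated_nb_mean(mu, Dr[, idx$phi])
    },
    zoib = {
      alpha <- stats::plogis(drop(Dr[, idx$boundary, drop = FALSE] %*%
                                    xrow$boundary))
      gamma <- stats::plogis(drop(Dr[, idx$one, drop = FALSE] %*% xrow$one))
      mu_b <- stats::plogis(drop(Dr[, idx$mu, drop = FALSE] %*% xrow$mu))
      zoib_mean_proportion(alpha, gamma, mu_b) * md
    },
    cumlogit = {
      eta <- if (length(idx$location))
        drop(Dr[, idx$location, drop = FALSE] %*% xrow$location) else 0
      Th <- Dr[, idx$theta, drop = FALSE]
      FF <- stats::plogis(Th - eta)
      P <- cbind(FF, 1) - cbind(0, FF)
      v <- fit$value_map
      if (variant == "minus_one_as_zero") v <- pmax(v, 0L)
      drop(P %*% v)
    })
}

#' Expected mean outcome per treatment group
#'
#' Computes, for every draw and the point estimate, the expected mean
#' outcome (days scale) in each arm by combining all sub-models: the linear
#' prediction; `(1 - pi) *` the zero-truncated negative-binomial mean for
#' the hurdle model; the zero-one-inflated beta mean multiplied by
#' `max_days`; and the category probabilities multiplied by each category's
#' value and summed for the cumulative model.  When covariates are present,
#' predictions are marginally standardised: every patient in `newdata` is
#' predicted under each arm and the patient-level predictions are averaged
#' (pass a single-row `newdata` for conditional-at-covariate-values means).
#' Patient-level predictions are truncated to the valid outcome space
#' before averaging (see [truncate_to_valid]).
#'
#' @param fit A `dawols_fit`.
#' @param newdata Data to standardise over; defaults to the analysis set.
#' @param variant Death-category handling for cumulative fits (see
#'   [truncate_to_valid]).
#' @param truncate Apply truncation (default `TRUE`).
#' @return A `dawols_group_means` object: `draws` (`D x arms` matrix),
#'   `point`, arm names and flags.
#' @export
expected_mean <- function(fit, newdata = fit$data,
                          variant = c("minus_one_as_zero",
                                      "minus_one_as_is"),
                          truncate = TRUE) {
  stopifnot(inherits(fit, "dawols_fit"))
  variant <- match.arg(variant)
  need <- unique(unlist(c(fit$mspec$terms, fit$mspec$sub_terms)))
  miss <- setdiff(need, c(names(newdata)))
  .assert(length(miss) == 0, "newdata lacks model term column(s): %s",
          paste(miss, collapse = ", "))
  arms <- levels(fit$data$arm)
  Dr <- rbind(fit$draws, fit$point)  # last row = point estimate
  lo <- if (fit$family == "cumlogit" && variant == "minus_one_as_is") -1 else 0
  gm <- matrix(NA_real_, nrow = nrow(Dr), ncol = length(arms),
               dimnames = list(NULL, arms))
  for (a in arms) {
    nd <- as.data.frame(newdata)
    nd$arm <- factor(a, levels = arms)
    Xl <- .build_design(fit$mspec, nd)
    comb <- do.call(cbind, Xl)
    grp <- .row_groups(comb)
    w <- tabulate(grp$id, nbins = max(grp$id))
    w <- w / sum(w)
    acc <- 0
    for (u in seq_along(w)) {
      i <- which(grp$id == u)[1]
      xrow <- lapply(Xl, function(X) X[i, ])
      ev <- .expected_days_row(fit, Dr, xrow, variant)
      if (truncate) ev <- clamp(ev, lo, fit$outcome_spec$max_days)
      acc <- acc + w[u] * ev
    }
    gm[, a] <- acc
  }
  structure(list(draws = gm[-nrow(gm), , drop = FALSE],
                 point = gm[nrow(gm), ], arms = arms, variant = variant,
                 truncated = truncate,
                 max_days = fit$outcome_spec$max_days),
            class = "dawols_group_means")
}

#' @export
print.dawols_group_means <- function(x, ...) {
  s <- t(apply(x$draws, 2, summarize_draws))
  print(round(cbind(point = x$point, s), 3))
  invisible(x)
}

.contrast_pairs <- function(gm, contrast) {
  if (!is.null(contrast)) {
    .assert(length(contrast) == 2 && all(contrast %in% gm$arms),
            "contrast must name two arms present in the fit")
    return(list(contrast))  # c(intervention, control)
  }
  lapply(gm$arms[-1], function(a) c(a, gm$arms[1]))
}

.effect_tibble <- function(estimand, pairs, draw_list, point) {
  rows <- lapply(seq_along(pairs), function(i) {
    s <- summarize_draws(draw_list[[i]])
    tibble::tibble(estimand = estimand,
                   contrast = paste(pairs[[i]][1], "vs", pairs[[i]][2]),
                   point = point[i], median = s[["median"]],
                   lower95 = s[["lower95"]], upper95 = s[["upper95"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- draw_list
  out
}

#' Mean difference between arms
#'
#' Per-draw difference in expected mean outcome (intervention minus
#' control), summarised by [summarize_draws].  By default one estimate per
#' non-control arm against the first (control) arm.
#'
#' @param gm A `dawols_group_means` from [expected_mean].
#' @param contrast Optional `c(intervention, control)` arm pair.
#' @return A tibble with one row per contrast (`median`, `lower95`,
#'   `upper95`, plus the point estimate); per-draw values in
#'   `attr(, "draws")`.
#' @export
mean_difference <- function(gm, contrast = NULL) {
  stopifnot(inherits(gm, "dawols_group_means"))
  pairs <- .contrast_pairs(gm, contrast)
  dl <- lapply(pairs, function(p) gm$draws[, p[1]] - gm$draws[, p[2]])
  pt <- vapply(pairs, function(p) gm$point[p[1]] - gm$point[p[2]], 0)
  .effect_tibble("mean_difference", pairs, dl, pt)
}

#' Ratio of means between arms
#'
#' Per-draw ratio of expected mean outcomes (intervention / control).
#' Draws with a non-positive control mean are excluded with a warning; more
#' than 1% such draws is an error (the ratio is not a usable estimand
#' there).
#'
#' @inheritParams mean_difference
#' @return A tibble as in [mean_difference].
#' @export
ratio_of_means <- function(gm, contrast = NULL) {
  stopifnot(inherits(gm, "dawols_group_means"))
  pairs <- .contrast_pairs(gm, contrast)
  dl <- lapply(pairs, function(p) {
    ctrl <- gm$draws[, p[2]]
    bad <- ctrl <= 0
    if (any(bad)) {
      if (mean(bad) > 0.01)
        stop("more than 1% of control-mean draws are non-positive; ",
             "ratio of means is not estimable", call. = FALSE)
      warning(sum(bad), " draw(s) with non-positive control mean excluded ",
              "from the ratio of means", call. = FALSE)
    }
    gm$draws[!bad, p[1]] / ctrl[!bad]
  })
  pt <- vapply(pairs, function(p) gm$point[p[1]] / gm$point[p[2]], 0)
  .effect_tibble("ratio_of_means", pairs, dl, pt)
}

#' Cumulative odds ratio from a cumulative logistic fit
#'
#' `exp` of the arm coefficient, per draw: the odds ratio of being in a
#' higher (better) outcome category for the intervention versus the control
#' arm, constant across all cutpoints under proportional odds.
#'
#' @param fit A `dawols_fit` with `family == "cumlogit"`.
#' @param contrast Optional `c(intervention, control)`; the control must be
#'   the reference (first) arm.
#' @return A tibble as in [mean_difference].
#' @export
cumulative_odds_ratio <- function(fit, contrast = NULL) {
  stopifnot(inherits(fit, "dawols_fit"))
  .assert(fit$family == "cumlogit",
          "cumulative odds ratios require a cumlogit fit")
  arms <- levels(fit$data$arm)
  pairs <- if (is.null(contrast)) lapply(arms[-1], function(a) c(a, arms[1]))
           else list(contrast)
  dl <- list(); pt <- numeric(0)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    .assert(p[2] == arms[1],
            "the control of the contrast must be the reference arm")
    cn <- paste0("b_arm", p[1])
    .assert(cn %in% colnames(fit$draws),
            "no arm coefficient \"%s\" in this fit", cn)
    dl[[i]] <- exp(fit$draws[, cn])
    pt[i] <- exp(fit$point[[cn]])
  }
  .effect_tibble("cumulative_or", pairs, dl, pt)
}
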