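## Model-fitness battery: in-sample prediction errors over draws,
## predicted-vs-observed group-mean gaps, predictive checks and the
## proportional-odds diagnostic.
##
## Predictions entering RMSE/MAE are patient-level *expected* means (clamped
## to the valid space, days scale), not predictive draws: near-identical
## RMSEs across families of very different structure are only possible with
## expected-value predictions.  Evaluation is in-sample by design; pass a
## `holdout` table to evaluate elsewhere.

## observed outcome on the days scale with deaths coded 0
.observed_days <- function(data) pmax(as.numeric(data$outcome), 0)

## D x n matrix of clamped expected predictions (plus point as last row)
.prediction_matrix <- function(fit, data, variant) {
  arms <- levels(fit$data$arm)
  Dr <- rbind(fit$draws, fit$point)
  lo <- if (fit$family == "cumlogit" && variant == "minus_one_as_is") -1 else 0
  Xl <- .build_design(fit$mspec, as.data.frame(data))
  comb <- do.call(cbind, Xl)
  grp <- .row_groups(comb)
  EV <- matrix(NA_real_, nrow = nrow(Dr), ncol = nrow(grp$Xu))
  for (u in seq_len(nrow(grp$Xu))) {
    i <- which(grp$id == u)[1]
    xrow <- lapply(Xl, function(X) X[i, ])
    EV[, u] <- clamp(.expected_days_row(fit, Dr, xrow, variant),
                     lo, fit$outcome_spec$max_days)
  }
  EV[, grp$id, drop = FALSE]
}

#' Per-draw root-mean-squared error of model predictions
#'
#' For each draw, predictions are the patient-level expected mean outcomes
#' (clamped, days scale) and the error is against the observed outcomes
#' with deaths coded 0 days.
#'
#' @param fit A `dawols_fit`.
#' @param data Evaluation data; defaults to the data the model was fit to
#'   (in-sample, the primary use).
#' @param variant Death-category handling for cumulative fits.
#' @return Numeric vector of length `D` (one RMSE per draw); the point
#'   estimate's RMSE is in `attr(, "point")`.
#' @export
rmse_draws <- function(fit, data = fit$data,
                       variant = c("minus_one_as_zero", "minus_one_as_is")) {
  variant <- match.arg(variant)
  P <- .prediction_matrix(fit, data, variant)
  y <- .observed_days(data)
  E <- P - matrix(y, nrow = nrow(P), ncol = length(y), byrow = TRUE)
  v <- sqrt(rowMeans(E^2))
  out <- v[-length(v)]
  attr(out, "point") <- v[length(v)]
  out
}

#' Per-draw median absolute error of model predictions
#'
#' Median over patients of the absolute prediction error, per draw (the
#' same median rule as [summarize_draws] is applied when summarising the
#' draw vector).
#'
#' @inheritParams rmse_draws
#' @return Numeric vector of length `D`; point-estimate MAE in
#'   `attr(, "point")`.
#' @export
mae_draws <- function(fit, data = fit$data,
                      variant = c("minus_one_as_zero", "minus_one_as_is")) {
  variant <- match.arg(variant)
  P <- .prediction_matrix(fit, data, variant)
  y <- .observed_days(data)
  v <- apply(abs(P - matrix(y, nrow = nrow(P), ncol = length(y),
                            byrow = TRUE)), 1, stats::median)
  out <- v[-length(v)]
  attr(out, "point") <- v[length(v)]
  out
}

#' Per-draw predicted-minus-observed group mean
#'
#' @inheritParams rmse_draws
#' @param arm Arm label.
#' @return Numeric vector of length `D` of (predicted arm mean) - (observed
#'   arm mean); point-estimate gap in `attr(, "point")`.
#' @export
mean_gap_draws <- function(fit, data = fit$data, arm,
                           variant = c("minus_one_as_zero",
                                       "minus_one_as_is")) {
  variant <- match.arg(variant)
  .assert(arm %in% data$arm, "arm \"%s\" not present in data", arm)
  P <- .prediction_matrix(fit, data, variant)
  sel <- data$arm == arm
  v <- rowMeans(P[, sel, drop = FALSE]) - mean(.observed_days(data)[sel])
  out <- v[-length(v)]
  attr(out, "point") <- v[length(v)]
  out
}

#' Model-fitness report
#'
#' Assembles, for each fitted model, the RMSE, MAE and per-arm
#' predicted-vs-observed mean gaps, each as median and 95% percentile
#' interval over draws -- plus group means, mean differences and ratios of
#' means, mirroring a standard model-comparison table.  Cumulative fits are
#' reported twice, once per death-category variant.
#'
#' @param fits Named list of `dawols_fit` objects.
#' @param data Common evaluation data (defaults to the first fit's data).
#' @return A tibble with one row per model (x variant).
#' @export
fitness_report <- function(fits, data = fits[[1]]$data) {
  rows <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    variants <- if (fit$family == "cumlogit")
      c("minus_one_as_zero", "minus_one_as_is") else "minus_one_as_zero"
    for (va in variants) {
      gm <- expected_mean(fit, newdata = data, variant = va)
      md <- mean_difference(gm)
      rm_ <- ratio_of_means(gm)
      lab <- if (fit$family == "cumlogit")
        paste0(nm, if (va == "minus_one_as_zero") " (death as 0)"
               else " (death as -1)") else nm
      fmt <- function(x) {
        s <- summarize_draws(x)
        sprintf("%.2f (%.2f to %.2f)", s[1], s[2], s[3])
      }
      arms <- levels(fit$data$arm)
      gaps <- vapply(arms, function(a)
        fmt(mean_gap_draws(fit, data, a, variant = va)), "")
      means <- vapply(arms, function(a) fmt(gm$draws[, a]), "")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = lab,
        rmse = fmt(rmse_draws(fit, data, variant = va)),
        mae = fmt(mae_draws(fit, data, variant = va)),
        !!!stats::setNames(as.list(gaps), paste0("mean_gap_", arms)),
        !!!stats::setNames(as.list(means), paste0("mean_", arms)),
        mean_difference = fmt(attr(md, "draws")[[1]]),
        ratio_of_means = fmt(attr(rm_, "draws")[[1]]))
    }
  }
  do.call(rbind, rows)
}

## histogram over an integer grid, as proportions
.hist_prop <- function(y, grid) {
  tabulate(match(clamp(round(y), grid[1], grid[length(grid)]), grid),
           nbins = length(grid)) / length(y)
}

.tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

#' Predictive check against the observed outcome distribution
#'
#' Samples `n_rep` replicated datasets from the fitted model and compares
#' their per-arm outcome histograms with the observed histogram
#' (discretised to whole days over the valid grid).  Returns plottable
#' overlays plus numeric summaries enabling automated assertions: per-arm
#' replicate means, proportions at the minimum and maximum value, and
#' total-variation (TV) discrepancies.  Calibration: each replicate is also
#' compared against every other replicate, giving a null band for the
#' observed-vs-replicate TV distance; an observed statistic inside that
#' band is what a well-fitting model produces.
#'
#' @param fit A `dawols_fit`.
#' @param data Data whose distribution is checked (defaults to the analysis
#'   set).
#' @param n_rep Number of replicated datasets (default 100).
#' @param seed Integer seed; `n_rep = 1` with a fixed seed is reproducible.
#' @return A list of class `dawols_ppc` with per-arm components
#'   (`obs_hist`, `rep_hist`, `rep_means`, `prop_min`, `prop_max`,
#'   `tv_obs`), the pooled `tv_stat` (median observed-vs-replicate TV),
#'   `tv_null` (pseudo-observed-vs-replicate medians) and `tv_band` (its
#'   central 95% interval), plus a tidy `table`
#'   (arm, replicate, value, count, prop).
#' @export
predictive_check <- function(fit, data = fit$data, n_rep = 100, seed = 1L) {
  pp <- sample_predictive(fit, newdata = data, n_rep = n_rep, seed = seed)
  ## null calibration set: datasets simulated at the point estimate, so a
  ## pseudo-observation has the same structure as the data (sampling
  ## variation only, no parameter draw) -- scoring replicates against each
  ## other instead would inflate the null distances
  fit_pt <- fit
  fit_pt$draws <- rbind(fit$point)
  pq <- sample_predictive(fit_pt, newdata = data, n_rep = n_rep,
                          seed = .arm_child_seed(seed, "ppc-null"))
  md <- fit$outcome_spec$max_days
  lo <- if (fit$family == "cumlogit" && any(fit$value_map < 0)) -1L else 0L
  grid <- seq.int(lo, md)
  arms <- levels(data$arm)
  per_arm <- list()
  tv_obs_all <- matrix(NA_real_, n_rep, length(arms))
  cross_sum <- matrix(0, n_rep, n_rep)  # replicate r x pseudo-observation q
  tabs <- list()
  for (j in seq_along(arms)) {
    sel <- data$arm == arms[j]
    yobs <- data$outcome[sel]
    if (lo == 0L) yobs <- pmax(yobs, 0)
    obs <- .hist_prop(yobs, grid)
    H <- t(apply(pp$clamped[, sel, drop = FALSE], 1, .hist_prop, grid = grid))
    Hq <- t(apply(pq$clamped[, sel, drop = FALSE], 1, .hist_prop,
                  grid = grid))
    tv_obs <- apply(H, 1, .tv_dist, q = obs)
    ## cross distances: replicate r vs pseudo-observation q
    cross_sum <- cross_sum + vapply(seq_len(n_rep), function(qi)
      colSums(abs(t(H) - Hq[qi, ])) / 2, numeric(n_rep))
    per_arm[[arms[j]]] <- list(
      grid = grid, obs_hist = obs, rep_hist = H,
      rep_means = rowMeans(pp$clamped[, sel, drop = FALSE]),
      prop_min = H[, 1], prop_max = H[, length(grid)],
      obs_prop_min = obs[1], obs_prop_max = obs[length(grid)],
      tv_obs = tv_obs)
    tv_obs_all[, j] <- tv_obs
    n_arm <- sum(sel)
    tabs[[j]] <- tibble::tibble(
      arm = arms[j],
      replicate = rep(seq_len(n_rep), each = length(grid)),
      value = rep(grid, times = n_rep),
      count = as.integer(round(as.vector(t(H)) * n_arm)),
      prop = as.vector(t(H)))
  }
  ## pooled statistic: average over arms, median over replicates; the null
  ## treats each point-estimate pseudo-observation the same way
  tv_stat <- stats::median(rowMeans(tv_obs_all))
  tv_null <- apply(cross_sum / length(arms), 2, stats::median)
  structure(list(arms = per_arm, tv_stat = tv_stat, tv_null = tv_null,
                 tv_band = if (n_rep > 1)
                   unname(stats::quantile(tv_null, c(0.025, 0.975),
                                          type = 7)) else c(NA_real_, NA_real_),
                 table = do.call(rbind, tabs), n_rep = n_rep),
            class = "dawols_ppc")
}

#' @export
print.dawols_ppc <- function(x, ...) {
  cat("<predictive check> ", x$n_rep, " replicates; observed-vs-replicate ",
      "TV ", round(x$tv_stat, 3), ", calibration band [",
      round(x$tv_band[1], 3), ", ", round(x$tv_band[2], 3), "]\n", sep = "")
  invisible(x)
}

#' Empirical check of the proportional-odds assumption
#'
#' For each cutpoint `k` of the ordinal outcome, computes the empirical
#' cumulative log odds ratio
#' `log odds(Y <= k | control) - log odds(Y <= k | intervention)`
#' with the Haldane-Anscombe 0.5 correction for empty cells.  Under
#' proportional odds the profile is constant (equal to the model's log
#' cumulative OR); trends or sign changes indicate violation, e.g. a
#' mortality effect opposite to the survivor-days effect.
#'
#' @param data A `dawols_trial` table with an ordinal-compatible outcome.
#' @param arms Pair of arm labels `c(control, intervention)`; defaults to
#'   the first two declared arms.
#' @return A tibble of class `dawols_po_check`: `cutpoint_value` (highest
#'   value included in `Y <= k`) and `log_cum_or`.
#' @export
proportional_odds_check <- function(data, arms = NULL) {
  .assert("arm" %in% names(data) && "outcome" %in% names(data),
          "data must be a trial table with arm and outcome")
  if (is.null(arms)) arms <- levels(factor(data$arm))[1:2]
  .assert(length(arms) == 2 && !anyNA(arms) && all(arms %in% data$arm),
          "two arms present in the data are required")
  oc <- to_ordinal_categories(data$outcome[data$arm %in% arms])
  K <- length(oc$values)
  sub <- data[data$arm %in% arms, ]
  kidx <- match(as.integer(sub$outcome), oc$values)
  out <- lapply(seq_len(K - 1L), function(k) {
    a <- sum(kidx <= k & sub$arm == arms[1]) + 0.5
    b <- sum(kidx > k & sub$arm == arms[1]) + 0.5
    cc <- sum(kidx <= k & sub$arm == arms[2]) + 0.5
    d <- sum(kidx > k & sub$arm == arms[2]) + 0.5
    tibble::tibble(cutpoint = k, cutpoint_value = oc$values[k],
                   log_cum_or = log(a / b) - log(cc / d))
  })
  out <- do.call(rbind, out)
  class(out) <- c("dawols_po_check", class(out))
  out
}
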