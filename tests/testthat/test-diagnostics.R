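test_that("RMSE and MAE reproduce hand arithmetic and a brute-force loop", {
  ## constructed fit predicting 14 for everyone, data at 0 and 28
  d <- data.frame(patient_id = as.character(1:4),
                  arm = factor(rep(c("c", "i"), 2)),
                  outcome = c(0L, 28L, 0L, 28L), died = c(TRUE, FALSE,
                                                          TRUE, FALSE))
  tt <- trial_table(d, spec_days)
  f <- fit_model(model_spec("linear", terms = NULL), tt, spec_days,
                 draws = 2, seed = 1)
  f$point[["b_(Intercept)"]] <- 14
  f$draws[, "b_(Intercept)"] <- 14
  r <- rmse_draws(f, tt)
  m <- mae_draws(f, tt)
  expect_equal(as.vector(r), rep(14, 2))
  expect_equal(as.vector(m), rep(14, 2))
  expect_equal(attr(r, "point"), 14)

  ## brute-force oracle on a real fit
  tt2 <- small_trial(120, seed = 3)
  f2 <- fit_model(model_spec("hurdle_nb"), tt2, spec_days, draws = 8,
                  seed = 1)
  r2 <- rmse_draws(f2, tt2)
  m2 <- mae_draws(f2, tt2)
  P <- dawols:::.prediction_matrix(f2, tt2, "minus_one_as_zero")
  y <- pmax(tt2$outcome, 0)
  for (dr in seq_len(8)) {
    errs <- numeric(nrow(tt2))
    for (i in seq_len(nrow(tt2))) errs[i] <- P[dr, i] - y[i]
    expect_equal(r2[dr], sqrt(mean(errs^2)), tolerance = 1e-12)
    expect_equal(m2[dr], median(abs(errs)), tolerance = 1e-12)
  }
})

test_that("perfect predictions give zero error", {
  d <- data.frame(patient_id = as.character(1:4),
                  arm = factor(rep(c("c", "i"), each = 2)),
                  outcome = rep(c(10L, 20L), each = 2), died = FALSE)
  tt <- trial_table(d, spec_days)
  f <- fit_model(model_spec("linear"), tt, spec_days, draws = 1, seed = 1)
  expect_equal(attr(rmse_draws(f, tt), "point"), 0, tolerance = 1e-8)
  expect_equal(attr(mae_draws(f, tt), "point"), 0, tolerance = 1e-8)
})

test_that("group mean gaps are zero at the saturated linear MLE and track
          constant shifts", {
  tt <- small_trial(150, seed = 7)
  f <- fit_model(model_spec("linear"), tt, spec_days, draws = 5, seed = 1)
  expect_equal(attr(mean_gap_draws(f, tt, "control"), "point"), 0,
               tolerance = 1e-8)
  expect_equal(attr(mean_gap_draws(f, tt, "intervention"), "point"), 0,
               tolerance = 1e-8)
  f$point[["b_(Intercept)"]] <- f$point[["b_(Intercept)"]] + 2
  f$draws[, "b_(Intercept)"] <- f$draws[, "b_(Intercept)"] + 2
  expect_equal(attr(mean_gap_draws(f, tt, "control"), "point"), 2,
               tolerance = 1e-6)
})

test_that("RMSE draws are invariant to patient ordering", {
  tt <- small_trial(100, seed = 9)
  f <- fit_model(model_spec("hurdle_nb"), tt, spec_days, draws = 5,
                 seed = 1)
  perm <- sample(nrow(tt))
  tt_perm <- trial_table(as.data.frame(tt)[perm, ], spec_days,
                         arm_levels = levels(tt$arm))
  expect_equal(unname(rmse_draws(f, tt)), unname(rmse_draws(f, tt_perm)),
               tolerance = 1e-12)
})

test_that("deaths kept at -1 cannot beat the death-as-zero recode on
          zero-coded data", {
  tt <- to_ordinal_table(small_trial(250, seed = 15))
  f <- fit_model(model_spec("cumlogit"), tt, spec_ord, draws = 20, seed = 1)
  r_zero <- median(rmse_draws(f, tt, variant = "minus_one_as_zero"))
  r_as_is <- median(rmse_draws(f, tt, variant = "minus_one_as_is"))
  expect_gte(r_as_is, r_zero)
})

test_that("predictive checks are reproducible and well calibrated on data
          from the fitted model itself", {
  tt <- small_trial(200, seed = 23)
  f <- fit_model(model_spec("hurdle_nb"), tt, spec_days, draws = 40,
                 seed = 1)
  p1 <- predictive_check(f, n_rep = 1, seed = 4)
  p2 <- predictive_check(f, n_rep = 1, seed = 4)
  expect_identical(p1$arms$control$rep_hist, p2$arms$control$rep_hist)

  ## data simulated from the fitted model should sit inside the band
  pc <- predictive_check(f, n_rep = 60, seed = 5)
  expect_true(is.finite(pc$tv_stat))
  expect_true(all(abs(rowSums(pc$arms$control$rep_hist) - 1) < 1e-12))
  ## replicate means bracket the fitted group mean
  gm <- expected_mean(f)
  rng <- range(pc$arms$control$rep_means)
  expect_gt(gm$point[["control"]], rng[1])
  expect_lt(gm$point[["control"]], rng[2])
})

test_that("a linear fit to strongly zero-inflated data fails the
          zero-proportion predictive check", {
  s <- arm_scenario(400, p_death = 0.45, p_max = 0.25, interior_mean = 22,
                    interior_dispersion = 8)
  tt <- simulate_trial(list(control = s, intervention = s), spec_days,
                       seed = 33)
  f <- fit_model(model_spec("linear"), tt, spec_days, draws = 40, seed = 1)
  pc <- predictive_check(f, n_rep = 60, seed = 6)
  obs0 <- pc$arms$control$obs_prop_min
  expect_gt(obs0, max(pc$arms$control$prop_min))  # outside the envelope
})

test_that("proportional-odds profile is flat under PO and crosses zero
          under an opposing mortality/survivor effect", {
  ## identical arms: profile near zero everywhere
  s <- arm_scenario(3000, 0.3, 0.3, 20, 5)
  tt <- simulate_trial(list(a = s, b = s), spec_days, seed = 41)
  po0 <- proportional_odds_check(tt)
  expect_true(all(abs(po0$log_cum_or) < 0.5))

  ## PO-consistent data: profile scatters around the true log OR
  vals <- c(-1L, 0L, 7L, 14L, 21L, 28L)
  probs <- c(0.3, 0.1, 0.15, 0.15, 0.1, 0.2)
  tt_po <- simulate_po_trial(3000, vals, probs, log(1.5), spec_ord,
                             seed = 43)
  po1 <- proportional_odds_check(tt_po)
  expect_true(all(abs(po1$log_cum_or - log(1.5)) < 0.35))
  expect_lt(abs(mean(po1$log_cum_or) - log(1.5)), 0.1)

  ## constructed violation: intervention has more deaths but far better
  ## survivor outcomes -> sign change across cutpoints
  sc <- list(control = arm_scenario(2000, 0.15, 0.05, 10, 6),
             intervention = arm_scenario(2000, 0.35, 0.40, 20, 6))
  tt_v <- to_ordinal_table(simulate_trial(sc, spec_days, seed = 47))
  po2 <- proportional_odds_check(tt_v)
  expect_lt(min(po2$log_cum_or), 0)
  expect_gt(max(po2$log_cum_or), 0)
  expect_error(proportional_odds_check(tt_v[tt_v$arm == "control", ]),
               "two arms")
})

test_that("the fitness report has one row per model and variant", {
  tt <- small_trial(120, seed = 51)
  fits <- list(
    linear = fit_model(model_spec("linear"), tt, spec_days, draws = 8,
                       seed = 1),
    cumlogit = fit_model(model_spec("cumlogit"), to_ordinal_table(tt),
                         spec_ord, draws = 8, seed = 1))
  rep_ <- fitness_report(fits, tt)
  expect_equal(nrow(rep_), 3)  # linear + two cumlogit variants
  expect_true(all(c("rmse", "mae", "mean_difference", "ratio_of_means")
                  %in% names(rep_)))
})
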