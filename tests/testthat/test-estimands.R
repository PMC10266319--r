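test_that("draw summaries use the linear-interpolation quantile rule", {
  expect_equal(unname(summarize_draws(1:100)), c(50.5, 3.475, 97.525))
  expect_equal(unname(summarize_draws(rep(7, 10))), c(7, 7, 7))
  expect_equal(unname(summarize_draws(3.2)), c(3.2, 3.2, 3.2))
  expect_error(summarize_draws(numeric(0)), "at least one")
})

test_that("truncation clamps to the valid space and handles the death
          category variants", {
  expect_equal(truncate_to_valid(-0.3, spec_days), 0)
  expect_equal(truncate_to_valid(28.9, spec_days), 28)
  expect_equal(truncate_to_valid(-0.5, spec_ord, "minus_one_as_is"), -0.5)
  ## two-point category distributions: 0.5 on -1 and 0.5 on 28
  expect_equal(sum(c(0.5, 0.5) * c(0, 28)), 14)    # death remapped to 0
  expect_equal(sum(c(0.5, 0.5) * c(-1, 28)), 13.5) # death kept as -1
  x <- c(-3, 5, 40)
  expect_identical(truncate_to_valid(truncate_to_valid(x, spec_days),
                                     spec_days),
                   truncate_to_valid(x, spec_days))  # idempotent
})

test_that("cumlogit group means honour the death-category variant", {
  tt <- to_ordinal_table(small_trial(150, seed = 61))
  f <- fit_model(model_spec("cumlogit"), tt, spec_ord, draws = 10, seed = 1)
  gz <- expected_mean(f, variant = "minus_one_as_zero")
  gi <- expected_mean(f, variant = "minus_one_as_is")
  ## keeping -1 for deaths can only lower the expected mean
  expect_true(all(gz$point > gi$point))
  p_death_ctrl <- sum(dawols:::.expected_days_row(
    f, rbind(f$point), lapply(f$design, function(X) X[1, ]),
    "minus_one_as_zero") - dawols:::.expected_days_row(
      f, rbind(f$point), lapply(f$design, function(X) X[1, ]),
      "minus_one_as_is"))
  expect_gt(p_death_ctrl, 0)  # gap equals P(death category) exactly
})

test_that("mean difference and ratio of means enumerate paired draws", {
  gm <- structure(list(
    draws = cbind(control = c(10, 12, 14), intervention = c(12, 14, 16)),
    point = c(control = 12, intervention = 14),
    arms = c("control", "intervention"), variant = "minus_one_as_zero",
    truncated = TRUE, max_days = 28), class = "dawols_group_means")
  md <- mean_difference(gm)
  expect_equal(md$median, 2)
  rm_ <- ratio_of_means(gm)
  expect_equal(rm_$median, median(c(12 / 10, 14 / 12, 16 / 14)),
               tolerance = 1e-12)
  expect_equal(rm_$median, 14 / 12, tolerance = 1e-4)
  ## identical arms give MD 0 and RoM 1
  gm$draws[, 2] <- gm$draws[, 1]
  expect_equal(mean_difference(gm)$median, 0)
  expect_equal(ratio_of_means(gm)$median, 1)
})

test_that("per-draw coherence: the ratio exceeds one exactly when the
          difference is positive", {
  tt <- small_trial(200, seed = 71)
  f <- fit_model(model_spec("hurdle_nb"), tt, spec_days, draws = 50,
                 seed = 1)
  gm <- expected_mean(f)
  md <- attr(mean_difference(gm), "draws")[[1]]
  rm_ <- attr(ratio_of_means(gm), "draws")[[1]]
  expect_true(all(gm$draws[, "control"] > 0))
  expect_identical(rm_ > 1, md > 0)
})

test_that("a three-arm trial yields one estimate per non-control arm", {
  sc <- default_scenarios(80)
  sc$high <- arm_scenario(80, 0.2, 0.45, 24, 6)
  tt <- simulate_trial(sc, spec_days, seed = 81)
  f <- fit_model(model_spec("linear"), tt, spec_days, draws = 20, seed = 1)
  gm <- expected_mean(f)
  md <- mean_difference(gm)
  expect_equal(nrow(md), 2)
  expect_setequal(md$contrast, c("intervention vs control",
                                 "high vs control"))
  ## linear with a saturated arm factor: group means equal sample means
  expect_equal(as.numeric(gm$point),
               as.numeric(tapply(tt$outcome, tt$arm, mean)[gm$arms]),
               tolerance = 1e-8)
})

test_that("expected means agree with closed forms and predictive draws", {
  tt <- small_trial(200, seed = 91)
  f <- fit_model(model_spec("hurdle_nb", terms = NULL), tt, spec_days,
                 draws = 3, seed = 1)
  ## overwrite with known parameters: pi = 0.4, mu = 10, phi = 2
  f$point[["zero_(Intercept)"]] <- qlogis(0.4)
  f$point[["count_(Intercept)"]] <- log(10)
  f$point[["phi"]] <- 2
  for (j in colnames(f$draws)) f$draws[, j] <- f$point[[j]]
  gm <- expected_mean(f, truncate = FALSE)
  closed <- 0.6 * truncated_nb_mean(10, 2)
  expect_equal(unname(gm$point), rep(closed, 2), tolerance = 1e-10)
  ## Monte-Carlo predictive oracle
  pp <- sample_predictive(f, n_rep = 200, seed = 5)
  mc <- mean(pp$raw)
  se <- sd(pp$raw) / sqrt(length(pp$raw))
  expect_lt(abs(mc - closed), 3 * se)
})

test_that("cumulative odds ratio is exp of the arm coefficient", {
  tt <- to_ordinal_table(small_trial(150, seed = 101))
  f <- fit_model(model_spec("cumlogit"), tt, spec_ord, draws = 10, seed = 1)
  or <- cumulative_odds_ratio(f)
  expect_equal(or$point, exp(f$point[["b_armintervention"]]),
               tolerance = 1e-12)
  f0 <- f
  f0$draws[, "b_armintervention"] <- 0
  f0$point[["b_armintervention"]] <- 0
  expect_equal(cumulative_odds_ratio(f0)$median, 1)
  f2 <- f
  f2$draws[, "b_armintervention"] <- log(2)
  expect_equal(cumulative_odds_ratio(f2)$median, 2, tolerance = 1e-12)
  fl <- fit_model(model_spec("linear"), small_trial(60), spec_days,
                  draws = 2, seed = 1)
  expect_error(cumulative_odds_ratio(fl), "cumlogit")
})

test_that("marginal standardisation averages patient-level predictions
          over the pooled covariate distribution", {
  s <- arm_scenario(400, 0.25, 0.2, 18, 4, covariate_effect = -6)
  tt <- simulate_trial(list(control = s, intervention = s), spec_days,
                       seed = 13, covariate = list(name = "frail",
                                                   prevalence = 0.4))
  f <- fit_model(model_spec("linear", terms = c("arm", "frail")), tt,
                 spec_days, draws = 5, seed = 1)
  gm <- expected_mean(f)
  ## manual standardisation at the point estimate
  b <- f$point
  pool_frail <- mean(tt$frail)
  manual <- b[["b_(Intercept)"]] + b[["b_frail"]] * pool_frail
  expect_equal(unname(gm$point[["control"]]), unname(manual),
               tolerance = 1e-8)
  ## conditional mode via single-row newdata
  nd <- data.frame(arm = factor("control",
                                levels = levels(tt$arm)), frail = 1)
  gmc <- expected_mean(f, newdata = nd)
  expect_equal(unname(gmc$point[["control"]]),
               unname(b[["b_(Intercept)"]] + b[["b_frail"]]),
               tolerance = 1e-8)
})

test_that("each family's estimated group means are consistent with the
          generator's exact means at large n", {
  sc <- default_scenarios(5000)
  truth <- vapply(sc, scenario_true_mean, 0, spec = spec_days)
  tt <- simulate_trial(sc, spec_days, seed = 4242)
  tto <- to_ordinal_table(tt)
  for (family in c("linear", "hurdle_nb", "zoib", "cumlogit")) {
    sp <- switch(family, linear = spec_days, hurdle_nb = spec_days,
                 zoib = spec_prop, cumlogit = spec_ord)
    dd <- if (family == "cumlogit") tto else tt
    f <- fit_model(model_spec(family), dd, sp, draws = 5, seed = 1)
    gm <- expected_mean(f, newdata = tt)
    expect_lt(max(abs(gm$point - truth)), 0.5,
              label = paste(family, "group-mean deviation (days)"))
  }
})
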