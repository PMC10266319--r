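test_that("zero-truncated NB mean matches brute-force pmf summation", {
  for (mu in c(0.5, 2, 5, 20)) {
    for (phi in c(0.5, 2, 10)) {
      y <- 1:5000
      brute <- sum(y * dnbinom(y, size = phi, mu = mu)) /
        (1 - dnbinom(0, size = phi, mu = mu))
      expect_equal(truncated_nb_mean(mu, phi), brute, tolerance = 1e-9)
    }
  }
  ## Poisson limit and the mu -> 0 floor
  expect_equal(truncated_nb_mean(5, 1e8), 5 / (1 - exp(-5)),
               tolerance = 1e-6)
  expect_gt(truncated_nb_mean(0.01, 1), 1)
  expect_error(truncated_nb_mean(-1, 2), "positive")
})

test_that("zoib mean combines the three parts correctly", {
  expect_equal(zoib_mean_proportion(1, 1, 0.7), 1)
  expect_equal(zoib_mean_proportion(0, 0.5, 0.4), 0.4)
  ## Monte-Carlo oracle for the generative three-part draw
  set.seed(99)
  n <- 2e5
  alpha <- 0.5; gamma <- 0.3; mu_b <- 0.6; phi_b <- 4
  bnd <- runif(n) < alpha
  y <- ifelse(bnd, as.numeric(runif(n) < gamma),
              rbeta(n, mu_b * phi_b, (1 - mu_b) * phi_b))
  expect_lt(abs(zoib_mean_proportion(alpha, gamma, mu_b) - mean(y)),
            3 * sd(y) / sqrt(n))
  expect_error(zoib_mean_proportion(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("cumulative-logit category probabilities telescope to one", {
  p <- cumlogit_category_probs(c(-1, 1), 0)
  expect_equal(p, c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1)),
               tolerance = 1e-12)
  expect_equal(unname(cumlogit_category_probs(0, 0)), c(0.5, 0.5))
  set.seed(4)
  for (i in 1:20) {
    th <- sort(rnorm(sample(2:15, 1), sd = 2))
    if (any(diff(th) == 0)) next
    P <- cumlogit_category_probs(th, rnorm(3))
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
  }
  expect_error(cumlogit_category_probs(c(1, 0), 0), "increasing")
})

test_that("hurdle log-likelihood: a zero contributes only the zero part", {
  d <- data.frame(patient_id = c("a", "b"), arm = factor(c("x", "y")),
                  outcome = c(0L, 3L), died = c(TRUE, FALSE))
  tt <- trial_table(d, spec_days)
  ms <- model_spec("hurdle_nb", terms = NULL)
  base <- list(zero = c("(Intercept)" = qlogis(0.3)),
               count = c("(Intercept)" = log(5)), phi = 2)
  ll_both <- loglik(ms, base, tt, spec_days)
  for (mu in c(1, 5, 50)) {
    pr <- base; pr$count <- c("(Intercept)" = log(mu))
    d_pos <- ll_both - loglik(ms, pr, tt, spec_days)
    ## changing the count part never changes the zero observation's term
    only_pos <- (dnbinom(3, size = 2, mu = 5, log = TRUE) -
                   log(1 - dnbinom(0, size = 2, mu = 5))) -
      (dnbinom(3, size = 2, mu = mu, log = TRUE) -
         log(1 - dnbinom(0, size = 2, mu = mu)))
    expect_equal(d_pos, only_pos, tolerance = 1e-10)
  }
  ## and the zero's contribution is exactly log(pi)
  pr1 <- base
  ll_pi <- loglik(ms, pr1, tt, spec_days)
  pr2 <- base; pr2$zero <- c("(Intercept)" = qlogis(0.6))
  expect_equal(loglik(ms, pr2, tt, spec_days) - ll_pi,
               log(0.6) + log(0.4) - log(0.3) - log(0.7),
               tolerance = 1e-10)
})

test_that("zoib log-likelihood matches an independent textbook density", {
  ## data covering both boundaries and the interior
  d <- data.frame(patient_id = as.character(1:6),
                  arm = factor(rep(c("c", "i"), 3)),
                  outcome = c(0L, 28L, 7L, 14L, 21L, 0L),
                  died = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  tt <- trial_table(d, spec_prop)
  ms <- model_spec("zoib", terms = "arm")
  X <- model.matrix(~arm, tt)
  set.seed(5)
  for (r in 1:10) {
    pr <- list(boundary = rnorm(2), one = rnorm(2), mu = rnorm(2) / 2,
               phi_b = runif(1, 1, 10))
    ## independent evaluation written from the density definition
    ref <- 0
    for (i in seq_len(nrow(tt))) {
      p <- tt$outcome[i] / 28
      al <- 1 / (1 + exp(-sum(X[i, ] * pr$boundary)))
      ga <- 1 / (1 + exp(-sum(X[i, ] * pr$one)))
      mb <- 1 / (1 + exp(-sum(X[i, ] * pr$mu)))
      ref <- ref + if (p == 0) log(al * (1 - ga))
      else if (p == 1) log(al * ga)
      else log((1 - al) * p^(mb * pr$phi_b - 1) *
                 (1 - p)^((1 - mb) * pr$phi_b - 1) /
                 beta(mb * pr$phi_b, (1 - mb) * pr$phi_b))
    }
    expect_equal(loglik(ms, pr, tt, spec_prop), ref, tolerance = 1e-10)
  }
})

test_that("cumlogit with two categories reduces to logistic regression", {
  set.seed(2)
  n <- 400
  z <- rbinom(n, 1, plogis(-0.3 + 0.5 * rep(0:1, each = n / 2)))
  X <- cbind(armb = rep(0:1, each = n / 2))
  ours <- dawols:::.fit_cumlogit_core(X, z + 1L, 2L)
  ref <- glm(z ~ X, family = binomial(),
             control = glm.control(epsilon = 1e-12))
  ## P(Y <= 1) = F(theta - x beta) = 1 - P(z = 1), so theta = -c0, beta = c1
  expect_equal(unname(ours$par[["theta_1"]]), unname(-coef(ref)[1]),
               tolerance = 1e-6)
  expect_equal(unname(ours$par[["b_armb"]]), unname(coef(ref)[2]),
               tolerance = 1e-6)
})

test_that("cumlogit matches an independent proportional-odds fitter", {
  skip_if_not_installed("MASS")
  tt <- to_ordinal_table(small_trial(250, seed = 11))
  f <- fit_model(model_spec("cumlogit"), tt, spec_ord, draws = 1, seed = 1)
  ref <- MASS::polr(factor(outcome, levels = sort(unique(outcome))) ~ arm,
                    data = tt)
  expect_equal(unname(f$point[["b_armintervention"]]),
               unname(coef(ref)[[1]]), tolerance = 1e-3)
  expect_equal(unname(f$point[grep("^theta", names(f$point))]),
               unname(ref$zeta), tolerance = 1e-3)
})

test_that("intercept-only sub-models reproduce empirical fractions", {
  tt <- small_trial(300, seed = 21)
  fh <- fit_model(model_spec("hurdle_nb", terms = NULL), tt, spec_days,
                  draws = 1, seed = 1)
  expect_equal(plogis(fh$point[["zero_(Intercept)"]]),
               mean(tt$outcome == 0), tolerance = 1e-6)
  fz <- fit_model(model_spec("zoib", terms = NULL), tt, spec_prop,
                  draws = 1, seed = 1)
  expect_equal(plogis(fz$point[["bound_(Intercept)"]]),
               mean(tt$outcome %in% c(0L, 28L)), tolerance = 1e-6)
  expect_equal(plogis(fz$point[["one_(Intercept)"]]),
               mean(tt$outcome[tt$outcome %in% c(0L, 28L)] == 28L),
               tolerance = 1e-6)
})

test_that("the fitted point is a local maximum of the likelihood", {
  tt <- small_trial(200, seed = 31)
  fits <- list(
    fit_model(model_spec("linear"), tt, spec_days, draws = 1, seed = 1),
    fit_model(model_spec("hurdle_nb"), tt, spec_days, draws = 1, seed = 1),
    fit_model(model_spec("zoib"), tt, spec_prop, draws = 1, seed = 1))
  set.seed(7)
  for (f in fits) {
    ll0 <- loglik(f)
    for (r in 1:100) {
      pr <- dawols:::.params_of(f)
      pr <- lapply(pr, function(v)
        if (is.numeric(v)) v * exp(rnorm(length(v), 0, 0.02)) +
          rnorm(length(v), 0, 0.02) else v)
      if (f$family == "hurdle_nb") pr$phi <- abs(pr$phi)
      if (f$family == "zoib") pr$phi_b <- abs(pr$phi_b)
      expect_lte(loglik(f$mspec, pr, tt, f$outcome_spec), ll0 + 1e-8)
    }
  }
})

test_that("hurdle predictive pmf sums to one", {
  pi0 <- 0.35; mu <- 12; phi <- 3
  y <- 1:1e4
  total <- pi0 + (1 - pi0) * sum(dnbinom(y, size = phi, mu = mu)) /
    (1 - dnbinom(0, size = phi, mu = mu))
  expect_gte(total, 1 - 1e-8)
})

test_that("predictive sampling respects degeneracy, seeds, and the linear
          family's unbounded support", {
  tt <- small_trial(100, seed = 41)
  fh <- fit_model(model_spec("hurdle_nb", terms = NULL), tt, spec_days,
                  draws = 5, seed = 1)
  ## force a degenerate zero part: pi = 1
  fh$point[["zero_(Intercept)"]] <- 50
  fh$draws[, "zero_(Intercept)"] <- 50
  pp <- sample_predictive(fh, n_rep = 10, seed = 2)
  expect_true(all(pp$raw == 0))

  fl <- fit_model(model_spec("linear"), tt, spec_days, draws = 5, seed = 1)
  fl$point[["sigma"]] <- 25
  fl$draws[, "sigma"] <- 25
  pp1 <- sample_predictive(fl, n_rep = 20, seed = 3)
  pp2 <- sample_predictive(fl, n_rep = 20, seed = 3)
  expect_identical(pp1$raw, pp2$raw)
  expect_gt(mean(pp1$raw < 0 | pp1$raw > 28), 0)    # out-of-space mass
  expect_true(all(pp1$clamped >= 0 & pp1$clamped <= 28))
})

test_that("an arm without zeros triggers the penalised separation fallback", {
  d <- data.frame(patient_id = as.character(1:200),
                  arm = factor(rep(c("c", "i"), each = 100)),
                  outcome = c(pmax(rpois(100, 10), 0),
                              pmax(rpois(100, 12), 1)),
                  died = FALSE)
  d$outcome[1:30] <- 0L
  d$died[1:30] <- TRUE
  tt <- trial_table(d, spec_days)
  expect_warning(
    f <- fit_model(model_spec("hurdle_nb"), tt, spec_days, draws = 1,
                   seed = 1),
    "separation")
  expect_true(f$metadata$separation)
  expect_true(all(is.finite(f$point)))
  expect_lt(abs(f$point[["zero_armi"]]), 15)
})

test_that("family-scale compatibility is enforced", {
  tt <- small_trial(60)
  expect_error(fit_model(model_spec("zoib"), tt, spec_days, draws = 1),
               "incompatible")
  expect_error(fit_model(model_spec("cumlogit"), tt, spec_days, draws = 1),
               "incompatible")
  expect_error(fit_model(model_spec("hurdle_nb"), tt, spec_ord, draws = 1),
               "incompatible")
})

test_that("the sampler engine contract accepts a pluggable backend", {
  tt <- small_trial(80, seed = 51)
  dummy <- function(log_post, init, draws, seed) {
    set.seed(seed)
    ## crude contract check: jitter around the mode, reject non-finite
    out <- matrix(rep(init, each = draws), nrow = draws)
    stopifnot(is.finite(log_post(init)))
    out
  }
  f <- fit_model(model_spec("linear"), tt, spec_days, draws = 50, seed = 1,
                 engine = "sampler", sampler = dummy)
  expect_equal(nrow(f$draws), 50)
  expect_equal(unname(f$draws[1, ]), unname(f$point))
})
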