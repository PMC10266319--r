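#' Sample replicated outcomes from a fitted model
#'
#' Draws `n_rep` replicated outcome vectors from the fitted model's
#' generative form, each under a parameter draw sampled from the fit's
#' draws matrix (the predictive-distribution analogue of posterior
#' predictive sampling).  Hurdle replicates draw the zero indicator then a
#' zero-truncated negative binomial; zero-one-inflated beta replicates draw
#' the two boundary indicators then a beta variate; cumulative replicates
#' draw a category from the value map; linear replicates are Gaussian and
#' can fall outside the valid value space in both directions.
#'
#' @param fit A `dawols_fit`.
#' @param newdata Covariate rows to predict for; defaults to the analysis
#'   set.
#' @param n_rep Number of replicated datasets.
#' @param seed Integer seed.
#' @return A list of class `dawols_predictive`: `raw` and `clamped`
#'   (`n_rep x n` matrices on the days scale; `clamped` truncated to the
#'   valid space), `draw_index` (which parameter draw generated each
#'   replicate), and the `arm` of each column.
#' @export
sample_predictive <- function(fit, newdata = fit$data, n_rep = 100,
                              seed = 1L) {
  stopifnot(inherits(fit, "dawols_fit"))
  .assert(.is_count(n_rep), "`n_rep` must be a positive integer")
  Xl <- .build_design(fit$mspec, as.data.frame(newdata))
  n <- nrow(Xl[[1]])
  md <- fit$outcome_spec$max_days
  set.seed(.arm_child_seed(seed, "predictive"))
  di <- sample.int(nrow(fit$draws), n_rep, replace = TRUE)
  raw <- matrix(NA_real_, nrow = n_rep, ncol = n)
  for (r in seq_len(n_rep)) {
    y <- .simulate_family(fit$family, fit$draws[di[r], ], fit$par_index,
                          Xl, fit$value_map, fit$outcome_spec)
    if (fit$family == "zoib") y <- y * md
    raw[r, ] <- y
  }
  lo <- if (fit$family == "cumlogit" && any(fit$value_map < 0)) -1 else 0
  structure(list(raw = raw, clamped = clamp(raw, lo, md),
                 draw_index = di, arm = newdata$arm,
                 family = fit$family, max_days = md),
            class = "dawols_predictive")
}
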