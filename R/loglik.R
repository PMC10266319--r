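#' Log-likelihood of a model family on trial data
#'
#' Evaluates the exact log-likelihood of each family at given parameter
#' values, summed over patients.  This is the definitional, per-observation
#' evaluation; the fitting routines maximise numerically equivalent
#' sufficient-statistic objectives.
#'
#' Parameter lists by family (coefficient vectors are aligned with the
#' design matrix implied by `mspec` and `data`):
#' \describe{
#'   \item{linear}{`list(beta =, sigma =)`; Gaussian density.}
#'   \item{hurdle_nb}{`list(zero =, count =, phi =)`; zeros contribute
#'     `log(pi)`, positives `log(1 - pi) + log NB(y; mu, phi) -
#'     log(1 - NB(0; mu, phi))` (zero-truncated count part).}
#'   \item{zoib}{`list(boundary =, one =, mu =, phi_b =)`; boundary
#'     observations contribute `log(alpha) + log(gamma)` (y = 1) or
#'     `log(alpha) + log(1 - gamma)` (y = 0); interior observations
#'     `log(1 - alpha) + log Beta(y; mu_b phi_b, (1 - mu_b) phi_b)`.}
#'   \item{cumlogit}{`list(theta =, beta =, values =)`;
#'     `log(F(theta_k - eta) - F(theta_{k-1} - eta))` with `F` the logistic
#'     CDF.}
#' }
#'
#' @param mspec A [model_spec] (or a fitted `dawols_fit`, in which case the
#'   remaining arguments default to the fit's own parameters and data).
#' @param params Named parameter list (see Details).
#' @param data A `dawols_trial` table.
#' @param spec The [outcome_spec] of `data`.
#' @return Scalar log-likelihood.
#' @export
loglik <- function(mspec, params = NULL, data = NULL, spec = NULL) {
  if (inherits(mspec, "dawols_fit")) {
    fit <- mspec
    return(loglik(fit$mspec, params %||% .params_of(fit),
                  data %||% fit$data, spec %||% fit$outcome_spec))
  }
  stopifnot(inherits(mspec, "dawols_model_spec"),
            inherits(spec, "dawols_outcome_spec"))
  .check_family_scale(mspec$family, spec)
  Xl <- .build_design(mspec, data)
  y <- data$outcome
  ll <- switch(mspec$family,
    linear = {
      mu <- drop(Xl$mean %*% params$beta)
      .assert(params$sigma > 0, "sigma must be positive")
      sum(stats::dnorm(y, mu, params$sigma, log = TRUE))
    },
    hurdle_nb = {
      .assert(all(y >= 0 & y == round(y)),
              "hurdle_nb supports integer outcomes >= 0 only")
      .assert(params$phi > 0, "phi must be positive")
      pi0 <- stats::plogis(drop(Xl$zero %*% params$zero))
      mu <- exp(drop(Xl$count %*% params$count))
      z <- y == 0
      sum(log(pi0[z])) +
        sum(log1p(-pi0[!z]) +
              stats::dnbinom(y[!z], size = params$phi, mu = mu[!z],
                             log = TRUE) -
              .log1mexp(.nb_log_p0(mu[!z], params$phi)))
    },
    zoib = {
      p <- to_proportion(y, spec$max_days)
      .assert(params$phi_b > 0, "phi_b must be positive")
      alpha <- stats::plogis(drop(Xl$boundary %*% params$boundary))
      gamma <- stats::plogis(drop(Xl$one %*% params$one))
      mu_b <- stats::plogis(drop(Xl$mu %*% params$mu))
      b0 <- p == 0; b1 <- p == 1; int <- !b0 & !b1
      a <- mu_b * params$phi_b; b <- (1 - mu_b) * params$phi_b
      sum(log(alpha[b0]) + log1p(-gamma[b0])) +
        sum(log(alpha[b1]) + log(gamma[b1])) +
        sum(log1p(-alpha[int]) +
              stats::dbeta(p[int], a[int], b[int], log = TRUE))
    },
    cumlogit = {
      k <- match(as.integer(y), params$values)
      .assert(!anyNA(k), "outcome values outside the model's value map")
      eta <- if (ncol(Xl$location))
        drop(Xl$location %*% params$beta) else rep(0, length(y))
      P <- cumlogit_category_probs(params$theta, eta)
      if (is.null(dim(P))) P <- matrix(P, nrow = length(y), ncol = length(P),
                                       byrow = TRUE)
      sum(log(P[cbind(seq_along(k), k)]))
    })
  if (!is.finite(ll))
    stop("non-finite log-likelihood at the supplied parameters ",
         "(numerical guard)", call. = FALSE)
  ll
}

## point parameters of a fit as the loglik() parameter list
.params_of <- function(fit) {
  v <- fit$point
  idx <- fit$par_index
  switch(fit$family,
    linear = list(beta = v[idx$mean], sigma = v[idx$sigma]),
    hurdle_nb = list(zero = v[idx$zero], count = v[idx$count],
                     phi = v[idx$phi]),
    zoib = list(boundary = v[idx$boundary], one = v[idx$one],
                mu = v[idx$mu], phi_b = v[idx$phi_b]),
    cumlogit = list(theta = v[idx$theta], beta = v[idx$location],
                    values = fit$value_map))
}
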