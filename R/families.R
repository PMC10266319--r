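## Distributional building blocks shared by the model families.  The
## negative binomial uses the mean--dispersion parameterisation
## (mu, phi) with Var = mu + mu^2 / phi (phi = `size` in stats::dnbinom);
## the beta uses mean--precision (mu_b, phi_b) with shape1 = mu_b * phi_b.

## log P(Y = 0) for NB(mu, phi)
.nb_log_p0 <- function(mu, phi) phi * (log(phi) - log(mu + phi))

#' Mean of the zero-truncated negative binomial
#'
#' The conditional mean `E[Y | Y >= 1] = mu / (1 - p0)` with
#' `p0 = (phi / (mu + phi))^phi`, used by the count part of the hurdle model.
#' Computed on the log scale so that `1 - p0` stays accurate when `p0` is
#' close to 1 (tiny `mu`); the truncated mean always exceeds `mu` and tends
#' to 1 as `mu` tends to 0.
#'
#' @param mu,phi Negative-binomial mean and dispersion; both positive
#'   (vectorised, recycled).
#' @return Numeric vector of conditional means.
#' @examples
#' truncated_nb_mean(5, 2)
#' @export
truncated_nb_mean <- function(mu, phi) {
  .assert(all(mu > 0) && all(phi > 0), "`mu` and `phi` must be positive")
  mu / -expm1(.nb_log_p0(mu, phi))
}

## zero-truncated NB sampler by quantile inversion (exact, vectorised)
.rztnbinom <- function(n, mu, phi) {
  p0 <- exp(.nb_log_p0(mu, phi))
  u <- stats::runif(n)
  stats::qnbinom(p0 + u * (1 - p0), size = phi, mu = mu)
}

#' Expected proportion under the zero-one-inflated beta model
#'
#' Combines the three sub-models: `alpha` (probability of a boundary value,
#' 0 or 1), `gamma` (probability of 1 given a boundary value) and `mu_b`
#' (mean of the interior beta):
#' `E[Y] = alpha * gamma + (1 - alpha) * mu_b`.
#'
#' @param alpha,gamma,mu_b Probabilities / means in `[0, 1]` (vectorised).
#' @return Expected proportion in `[0, 1]`.
#' @export
zoib_mean_proportion <- function(alpha, gamma, mu_b) {
  .assert(all(alpha >= 0 & alpha <= 1) && all(gamma >= 0 & gamma <= 1) &&
            all(mu_b >= 0 & mu_b <= 1),
          "all arguments must lie in [0, 1]")
  alpha * gamma + (1 - alpha) * mu_b
}

#' Category probabilities of the cumulative logistic model
#'
#' With strictly increasing cutpoints `theta_1 < ... < theta_{K-1}` and
#' linear predictor `eta = x'beta`, the probability of category `k` is
#' `F(theta_k - eta) - F(theta_{k-1} - eta)` where `F` is the logistic CDF
#' (with `theta_0 = -Inf`, `theta_K = +Inf`).  Positive `eta` shifts mass to
#' higher (better) categories.
#'
#' @param theta Numeric cutpoint vector, strictly increasing.
#' @param eta Linear predictor(s); scalar or vector.
#' @return If `eta` is scalar, a probability vector of length `K`; else a
#'   `length(eta) x K` matrix.  Rows sum to 1.
#' @examples
#' cumlogit_category_probs(c(-1, 1), 0)
#' @export
cumlogit_category_probs <- function(theta, eta = 0) {
  .assert(length(theta) >= 1 && !is.unsorted(theta, strictly = TRUE),
          "`theta` must be strictly increasing")
  FF <- stats::plogis(outer(eta, theta, function(e, t) t - e))
  P <- cbind(FF, 1) - cbind(0, FF)
  if (length(eta) == 1L) drop(P) else P
}
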