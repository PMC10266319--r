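#' Fit a model family to trial data
#'
#' Maximum-likelihood point estimates with parameter-uncertainty draws.
#' The default engine refits the model to `draws` parametric-bootstrap
#' replicates simulated from the point estimate, producing a draws matrix
#' with the same downstream contract as posterior samples (all estimands and
#' diagnostics are computed per draw and summarised by median and 2.5/97.5
#' percentiles).  A pluggable sampler interface is provided for users who
#' want genuine posterior draws.
#'
#' Multi-part likelihoods factorise, so each part is maximised separately:
#' logistic parts by iteratively reweighted least squares, the Gaussian part
#' in closed form, and the zero-truncated negative-binomial, beta and
#' cumulative-logit parts by quasi-Newton optimisation of
#' sufficient-statistic objectives (positivity and cutpoint-ordering
#' constraints handled on the log / log-difference scale; bootstrap refits
#' warm-start at the parent estimate).  If a logistic sub-model separates
#' (an arm with 0% or 100% zeros or boundary values), a penalised fit with
#' weakly-informative Gaussian shrinkage (sd 10 on the intercept, 2.5 on
#' slopes) is used instead and a warning is raised.
#'
#' @param mspec A [model_spec].
#' @param data A `dawols_trial` table (see [trial_table]); the outcome column
#'   holds integer days (or -1 death codes); the scale conversions implied by
#'   the family (proportion, ordinal categories) are applied internally.
#' @param spec The [outcome_spec] of `data`.
#' @param draws Number of uncertainty draws `D` (default 1000).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param engine `"bootstrap"` (default) or `"sampler"`.
#' @param sampler For `engine = "sampler"`: a function
#'   `function(log_post, init, draws, seed)` returning a `draws x p` matrix
#'   of parameter vectors on the flat scale (e.g. an MCMC backend with its
#'   own chains/warmup/convergence gating).  No backend is shipped.
#' @param validate Validate family/scale compatibility and outcome support
#'   (disable only for simulation studies feeding raw family draws).
#' @return An object of class `dawols_fit`: point estimates (`point`, a
#'   named flat vector), a `draws x p` matrix (`draws`), the value map for
#'   ordinal fits, and engine metadata (seed, convergence flags, bootstrap
#'   non-convergence and separation counts).
#' @export
fit_model <- function(mspec, data, spec, draws = 1000, seed = 1L,
                      engine = c("bootstrap", "sampler"), sampler = NULL,
                      validate = TRUE) {
  stopifnot(inherits(mspec, "dawols_model_spec"),
            inherits(spec, "dawols_outcome_spec"))
  engine <- match.arg(engine)
  .assert(.is_count(draws), "`draws` must be a positive integer")
  if (validate) .check_family_scale(mspec$family, spec)
  Xl <- .cache_groups(.build_design(mspec, data))
  y <- data$outcome
  ## validate = FALSE treats the outcome as already on the family's native
  ## scale (used by simulation studies feeding raw family draws)
  prep <- .prepare_y(mspec$family, y, spec, validate, native = !validate)

  pt <- .fit_core(mspec$family, Xl, prep, spec, start = NULL)
  if (pt$separation)
    warning("complete separation in a logistic sub-model (an arm with 0% ",
            "or 100% zeros/boundary values); penalised fit with ",
            "weakly-informative shrinkage used", call. = FALSE)
  if (!pt$converged)
    warning("point estimation did not converge; see $metadata", call. = FALSE)

  n_bad <- 0L; n_sep <- 0L
  if (engine == "bootstrap") {
    set.seed(.arm_child_seed(seed, "bootstrap"))
    D <- matrix(NA_real_, nrow = draws, ncol = length(pt$par),
                dimnames = list(NULL, names(pt$par)))
    for (d in seq_len(draws)) {
      ystar <- .simulate_family(mspec$family, pt$par, pt$index, Xl,
                                prep$value_map, spec)
      pstar <- .prepare_y(mspec$family, ystar, spec, validate = FALSE,
                          value_map = prep$value_map, native = TRUE)
      r <- .fit_core(mspec$family, Xl, pstar, spec, start = pt$par,
                     tol = 1e-9)
      if (!r$converged) {  # one retry from cold start
        r2 <- .fit_core(mspec$family, Xl, pstar, spec, start = NULL,
                        tol = 1e-9)
        if (r2$converged) r <- r2
      }
      if (!r$converged) n_bad <- n_bad + 1L
      if (r$separation) n_sep <- n_sep + 1L
      D[d, ] <- r$par
    }
  } else {
    .assert(is.function(sampler),
            "engine \"sampler\" requires a sampler function")
    D <- sampler(function(par) .flat_loglik(mspec$family, par, pt$index, Xl,
                                            prep, spec),
                 pt$par, draws, seed)
    .assert(is.matrix(D) && ncol(D) == length(pt$par),
            "sampler must return a draws x p matrix")
    colnames(D) <- names(pt$par)
  }

  structure(list(
    family = mspec$family, mspec = mspec, outcome_spec = spec, data = data,
    design = Xl, point = pt$par, par_index = pt$index, draws = D,
    value_map = prep$value_map,
    metadata = list(D = nrow(D), seed = seed, engine = engine,
                    converged = pt$converged, separation = pt$separation,
                    n_boot_nonconverged = n_bad, n_boot_separated = n_sep)
  ), class = "dawols_fit")
}

## family-specific view of the outcome vector; `native = TRUE` marks vectors
## already on the family's own scale (bootstrap replicates)
.prepare_y <- function(family, y, spec, validate = TRUE, value_map = NULL,
                       native = FALSE) {
  out <- list(y = y, value_map = value_map)
  if (family == "hurdle_nb") {
    if (validate) .assert(all(y >= 0 & y == round(y)),
                          "hurdle_nb needs integer outcomes >= 0")
    out$y <- as.numeric(y)
  } else if (family == "zoib") {
    out$y <- if (native) y else to_proportion(y, spec$max_days)
  } else if (family == "cumlogit") {
    if (is.null(value_map)) {
      oc <- to_ordinal_categories(y)
      out$value_map <- oc$values
      out$k <- oc$index
    } else {
      out$k <- findInterval(as.integer(y), value_map)
      out$k[out$k < 1L] <- 1L
    }
  }
  out
}

## ---- point estimation -----------------------------------------------------

.fit_core <- function(family, Xl, prep, spec, start = NULL,
                      tol = 3e-15) {
  switch(family,
    linear = .fit_linear(Xl$mean, prep$y),
    hurdle_nb = .fit_hurdle(Xl, prep$y, start, tol),
    zoib = .fit_zoib(Xl, prep$y, start, tol),
    cumlogit = .fit_cumlogit_core(Xl$location, prep$k,
                                  length(prep$value_map), start, tol))
}

.fit_linear <- function(X, y) {
  qx <- qr(X)
  beta <- qr.coef(qx, y)
  beta[is.na(beta)] <- 0
  sigma <- sqrt(mean((y - drop(X %*% beta))^2))  # ML scale estimate
  par <- c(stats::setNames(beta, paste0("b_", colnames(X))),
           sigma = max(sigma, 1e-8))
  list(par = par,
       index = list(mean = seq_len(ncol(X)), sigma = ncol(X) + 1L),
       converged = TRUE, separation = FALSE)
}

## unique-row group ids for a design matrix; the result can be attached to
## the matrix (attr "dawols_groups") so repeated fits on the same design
## (bootstrap refits) skip the key computation
.row_groups <- function(X) {
  g <- attr(X, "dawols_groups")
  if (!is.null(g)) return(g)
  if (ncol(X) == 0) return(list(id = rep(1L, nrow(X)), Xu = X[1, , drop = FALSE]))
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  uk <- unique(key)
  list(id = match(key, uk), Xu = X[match(uk, key), , drop = FALSE])
}

.cache_groups <- function(Xl) {
  for (p in names(Xl)) attr(Xl[[p]], "dawols_groups") <- .row_groups(Xl[[p]])
  Xl
}

## group-wise sum of x by id, over a fixed number of groups A (absent
## groups give 0 -- sub-model subsets can empty a cell)
.group_sum <- function(x, id, A) {
  out <- numeric(A)
  rs <- rowsum(x, id)
  out[as.integer(rownames(rs))] <- rs
  out
}

.fit_logistic <- function(X, z, start = NULL, grp = NULL) {
  if (length(z) == 0)  # sub-model has no observations: fully shrunk fit
    return(list(coef = stats::setNames(rep(0, ncol(X)), colnames(X)),
                separation = TRUE, converged = TRUE))
  if (is.null(grp)) grp <- .row_groups(X)
  A <- nrow(grp$Xu)
  grouped <- A < length(z)
  ## successes / trials per unique covariate cell (IRLS on the collapsed
  ## data is exact for the binomial likelihood and much faster)
  succ <- .group_sum(z, grp$id, A)
  tot <- tabulate(grp$id, nbins = A)
  obs <- tot > 0
  ## pre-flag separation only for genuinely grouped (factor-type) designs;
  ## with near-unique rows (continuous covariates) rely on the post-checks
  sep <- grouped && 4L * A <= length(z) &&
    any(succ[obs] == 0 | succ[obs] == tot[obs])
  conv <- TRUE
  if (!sep) {
    yy <- ifelse(obs, succ / pmax(tot, 1L), 0)
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(grp$Xu, yy, weights = tot,
                                      family = stats::binomial(),
                                      start = start)),
      error = function(e)
        suppressWarnings(stats::glm.fit(grp$Xu, yy, weights = tot,
                                        family = stats::binomial())))
    co <- f$coefficients
    conv <- f$converged
    if (any(!is.finite(co)) || any(abs(co) > 15)) sep <- TRUE
  }
  if (sep) {
    ss <- ifelse(colnames(X) == "(Intercept)", 10, 2.5)
    nll <- function(b) {
      eta <- drop(grp$Xu %*% b)
      -sum(succ * eta - tot * log1p(exp(pmin(eta, 30)))) +
        sum(b^2 / (2 * ss^2))
    }
    o <- stats::optim(start %||% rep(0, ncol(X)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    co <- o$par
    conv <- o$convergence == 0
  }
  list(coef = stats::setNames(co, colnames(X)), separation = sep,
       converged = conv)
}

.fit_ztnb <- function(X, y, start = NULL, grp = NULL, tol = 3e-15) {
  if (length(y) == 0)
    return(list(coef = stats::setNames(rep(0, ncol(X)), colnames(X)),
                phi = 1, converged = FALSE))
  if (is.null(grp)) grp <- .row_groups(X)
  key <- (grp$id - 1) * (max(y) + 1) + y
  uk <- unique(key)
  pos <- match(uk, key)
  cnt <- tabulate(match(key, uk))
  yk <- y[pos]; gk <- grp$id[pos]
  Xu <- grp$Xu
  p <- ncol(X)
  nll <- function(th) {
    phi <- exp(th[p + 1L])
    mu <- exp(drop(Xu %*% th[seq_len(p)]))[gk]
    if (any(!is.finite(mu)) || !is.finite(phi) || phi > 1e8 || phi < 1e-8)
      return(1e12)
    ll <- sum(cnt * (suppressWarnings(
      stats::dnbinom(yk, size = phi, mu = mu, log = TRUE)) -
        .log1mexp(.nb_log_p0(mu, phi))))
    if (!is.finite(ll)) 1e12 else -ll
  }
  gr <- function(th) {
    phi <- exp(th[p + 1L])
    mu <- exp(drop(Xu %*% th[seq_len(p)]))[gk]
    if (any(!is.finite(mu)) || !is.finite(phi) || phi > 1e8 || phi < 1e-8)
      return(rep(0, p + 1L))
    mp <- mu + phi
    p0 <- exp(.nb_log_p0(mu, phi))
    om <- -expm1(.nb_log_p0(mu, phi))          # 1 - p0
    dmu <- yk / mu - (yk + phi) / mp - p0 * phi / (mp * om)
    dphi <- digamma(yk + phi) - digamma(phi) + log(phi / mp) +
      (mu - yk) / mp + p0 * (log(phi / mp) + mu / mp) / om
    w <- cnt * dmu * mu                        # d/dbeta via log link
    gb <- -drop(crossprod(Xu[gk, , drop = FALSE], w))
    c(gb, -sum(cnt * dphi) * phi)
  }
  if (is.null(start)) {
    m <- sum(cnt * yk) / sum(cnt)
    v <- sum(cnt * (yk - m)^2) / max(sum(cnt) - 1, 1)
    phi0 <- if (v > m) clamp(m^2 / (v - m), 0.05, 1e3) else 100
    start <- c(log(max(m, 1.01)), rep(0, p - 1L), log(phi0))
  }
  o <- stats::optim(start, nll, gr, method = "BFGS",
                    control = list(maxit = 500, reltol = tol))
  list(coef = stats::setNames(o$par[seq_len(p)], colnames(X)),
       phi = exp(o$par[p + 1L]), converged = o$convergence == 0)
}

.fit_hurdle <- function(Xl, y, start = NULL, tol = 3e-15) {
  z <- as.numeric(y == 0)
  pz <- ncol(Xl$zero); pc <- ncol(Xl$count)
  s_zero <- if (!is.null(start)) start[seq_len(pz)]
  s_cnt <- if (!is.null(start)) c(start[pz + seq_len(pc)],
                                  log(start[pz + pc + 1L]))
  gz <- .row_groups(Xl$zero)
  gc_ <- .row_groups(Xl$count)
  lz <- .fit_logistic(Xl$zero, z, s_zero, gz)
  pos <- y > 0
  lc <- .fit_ztnb(Xl$count, y[pos], s_cnt,
                  grp = list(id = gc_$id[pos], Xu = gc_$Xu), tol = tol)
  par <- c(stats::setNames(lz$coef, paste0("zero_", colnames(Xl$zero))),
           stats::setNames(lc$coef, paste0("count_", colnames(Xl$count))),
           phi = lc$phi)
  list(par = par,
       index = list(zero = seq_len(pz), count = pz + seq_len(pc),
                    phi = pz + pc + 1L),
       converged = lz$converged && lc$converged, separation = lz$separation)
}

.fit_betareg <- function(X, y, start = NULL, grp = NULL, tol = 3e-15) {
  if (length(y) == 0)
    return(list(coef = stats::setNames(rep(0, ncol(X)), colnames(X)),
                phi = 1, converged = FALSE))
  if (is.null(grp)) grp <- .row_groups(X)
  A <- nrow(grp$Xu)
  ng <- tabulate(grp$id, nbins = A)
  S1 <- .group_sum(log(y), grp$id, A)
  S2 <- .group_sum(log1p(-y), grp$id, A)
  Xu <- grp$Xu
  p <- ncol(X)
  nll <- function(th) {
    phi <- exp(th[p + 1L])
    mu <- stats::plogis(drop(Xu %*% th[seq_len(p)]))
    a <- mu * phi; b <- (1 - mu) * phi
    if (phi > 1e8 || any(a <= 0) || any(b <= 0)) return(1e12)
    ll <- sum((a - 1) * S1 + (b - 1) * S2 - ng * lbeta(a, b))
    if (!is.finite(ll)) 1e12 else -ll
  }
  gr <- function(th) {
    phi <- exp(th[p + 1L])
    mu <- stats::plogis(drop(Xu %*% th[seq_len(p)]))
    a <- mu * phi; b <- (1 - mu) * phi
    if (phi > 1e8 || any(a <= 0) || any(b <= 0)) return(rep(0, p + 1L))
    dab <- digamma(a + b)
    dla <- S1 - ng * (digamma(a) - dab)
    dlb <- S2 - ng * (digamma(b) - dab)
    w <- (dla - dlb) * phi * mu * (1 - mu)     # d/dbeta via logit link
    gb <- -drop(crossprod(Xu, w))
    c(gb, -sum(dla * a + dlb * b))             # d/dlog(phi)
  }
  if (is.null(start)) {
    m <- clamp(mean(y), 0.02, 0.98)
    v <- max(stats::var(y), 1e-6)
    phi0 <- clamp(m * (1 - m) / v - 1, 0.5, 500)
    start <- c(stats::qlogis(m), rep(0, p - 1L), log(phi0))
  }
  o <- stats::optim(start, nll, gr, method = "BFGS",
                    control = list(maxit = 500, reltol = tol))
  list(coef = stats::setNames(o$par[seq_len(p)], colnames(X)),
       phi = exp(o$par[p + 1L]), converged = o$convergence == 0)
}

.fit_zoib <- function(Xl, y, start = NULL, tol = 3e-15) {
  bnd <- y == 0 | y == 1
  pb <- ncol(Xl$boundary); po <- ncol(Xl$one); pm <- ncol(Xl$mu)
  s_b <- if (!is.null(start)) start[seq_len(pb)]
  s_o <- if (!is.null(start)) start[pb + seq_len(po)]
  s_m <- if (!is.null(start)) c(start[pb + po + seq_len(pm)],
                                log(start[pb + po + pm + 1L]))
  gb <- .row_groups(Xl$boundary)
  go <- .row_groups(Xl$one)
  gm <- .row_groups(Xl$mu)
  lb <- .fit_logistic(Xl$boundary, as.numeric(bnd), s_b, gb)
  lo <- .fit_logistic(Xl$one, as.numeric(y[bnd] == 1), s_o,
                      grp = list(id = go$id[bnd], Xu = go$Xu))
  int <- !bnd
  lm_ <- .fit_betareg(Xl$mu, clamp(y[int], 1e-12, 1 - 1e-12), s_m,
                      grp = list(id = gm$id[int], Xu = gm$Xu), tol = tol)
  par <- c(stats::setNames(lb$coef, paste0("bound_", colnames(Xl$boundary))),
           stats::setNames(lo$coef, paste0("one_", colnames(Xl$one))),
           stats::setNames(lm_$coef, paste0("betamu_", colnames(Xl$mu))),
           phi_b = lm_$phi)
  list(par = par,
       index = list(boundary = seq_len(pb), one = pb + seq_len(po),
                    mu = pb + po + seq_len(pm), phi_b = pb + po + pm + 1L),
       converged = lb$converged && lo$converged && lm_$converged,
       separation = lb$separation || lo$separation)
}

.fit_cumlogit_core <- function(X, kidx, K, start = NULL, tol = 3e-15) {
  grp <- .row_groups(X)
  A <- nrow(grp$Xu)
  N <- matrix(tabulate((grp$id - 1L) * K + kidx, nbins = A * K),
              nrow = A, ncol = K, byrow = TRUE)
  Xu <- grp$Xu
  p <- ncol(X)
  lam <- 1e-8  # tiny ridge: numerical guard for categories emptied in refits
  theta_of <- function(par) {
    if (K == 2L) par[1L] else cumsum(c(par[1L], exp(par[2:(K - 1L)])))
  }
  last <- new.env(parent = emptyenv())  # share work between nll and gr calls
  cells <- function(par) {
    if (!is.null(last$par) && identical(par, last$par)) return(last$cc)
    th <- theta_of(par)
    eta <- if (p) drop(Xu %*% par[K - 1L + seq_len(p)]) else numeric(A)
    Tm <- matrix(th, nrow = A, ncol = K - 1L, byrow = TRUE) - eta
    FF <- 1 / (1 + exp(-Tm))            # logistic CDF
    f <- FF * (1 - FF)
    P <- pmax(cbind(FF, 1) - cbind(0, FF), 1e-300)
    last$par <- par
    last$cc <- list(f = f, P = P)
    last$cc
  }
  nll <- function(par) {
    cc <- cells(par)
    v <- -sum(N * log(cc$P)) + lam * sum(par^2)
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(par) {
    cc <- cells(par)
    R <- N / cc$P
    Gth <- -colSums(cc$f * (R[, 1:(K - 1L), drop = FALSE] -
                              R[, 2:K, drop = FALSE]))
    cs <- rev(cumsum(rev(Gth)))
    gt <- c(cs[1L],
            if (K > 2L) exp(par[2:(K - 1L)]) * cs[2:(K - 1L)])
    gb <- if (p) {
      s <- rowSums((cbind(cc$f, 0) - cbind(0, cc$f)) * R)
      drop(crossprod(Xu, s))
    } else numeric(0)
    c(gt, gb) + 2 * lam * par
  }
  if (is.null(start_t <- start)) {
    cf <- cumsum(colSums(N))[-K] / sum(N)
    th0 <- stats::qlogis(clamp(cf, 1e-5, 1 - 1e-5)) +
      seq_len(K - 1L) * 1e-6
    par0 <- c(th0[1L], if (K > 2L) log(pmax(diff(th0), 1e-8)),
              rep(0, p))
  } else {
    th <- start[seq_len(K - 1L)]
    par0 <- c(th[1L], if (K > 2L) log(pmax(diff(th), 1e-8)),
              start[K - 1L + seq_len(p)])
  }
  o <- stats::optim(par0, nll, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = tol))
  th <- theta_of(o$par)
  par <- c(stats::setNames(th, paste0("theta_", seq_len(K - 1L))),
           if (p) stats::setNames(o$par[K - 1L + seq_len(p)],
                                  paste0("b_", colnames(X))))
  list(par = par,
       index = list(theta = seq_len(K - 1L), location = K - 1L + seq_len(p)),
       converged = o$convergence == 0, separation = FALSE)
}

## ---- generative sampling (shared by bootstrap, predictive draws) ----------

## per-observation linear predictor, computed on unique design rows
.lp <- function(X, beta) {
  grp <- .row_groups(X)
  drop(grp$Xu %*% beta)[grp$id]
}

## simulate one outcome vector (native family scale) from flat parameters
.simulate_family <- function(family, par, idx, Xl, value_map, spec) {
  switch(family,
    linear = {
      mu <- .lp(Xl$mean, par[idx$mean])
      stats::rnorm(length(mu), mu, par[idx$sigma])
    },
    hurdle_nb = {
      pi0 <- stats::plogis(.lp(Xl$zero, par[idx$zero]))
      mu <- exp(.lp(Xl$count, par[idx$count]))
      n <- length(pi0)
      y <- numeric(n)
      pos <- stats::runif(n) >= pi0
      if (any(pos))
        y[pos] <- .rztnbinom(sum(pos), mu[pos], par[idx$phi])
      y
    },
    zoib = {
      alpha <- stats::plogis(.lp(Xl$boundary, par[idx$boundary]))
      gamma <- stats::plogis(.lp(Xl$one, par[idx$one]))
      mu_b <- stats::plogis(.lp(Xl$mu, par[idx$mu]))
      n <- length(alpha)
      y <- numeric(n)
      bnd <- stats::runif(n) < alpha
      y[bnd] <- as.numeric(stats::runif(sum(bnd)) < gamma[bnd])
      int <- !bnd
      if (any(int)) {
        phi <- par[idx$phi_b]
        y[int] <- clamp(stats::rbeta(sum(int), mu_b[int] * phi,
                                     (1 - mu_b[int]) * phi),
                        1e-12, 1 - 1e-12)
      }
      y
    },
    cumlogit = {
      theta <- par[idx$theta]
      grp <- .row_groups(Xl$location)
      eta_u <- if (length(idx$location))
        drop(grp$Xu %*% par[idx$location]) else numeric(max(grp$id))
      K <- length(value_map)
      ## cumulative probabilities per unique row, then inverse-CDF draw
      cum_u <- cbind(stats::plogis(matrix(theta, nrow = length(eta_u),
                                          ncol = K - 1L, byrow = TRUE) -
                                     eta_u), 1)
      cum <- cum_u[grp$id, , drop = FALSE]
      u <- stats::runif(length(grp$id))
      k <- rowSums(u > cum) + 1L
      value_map[k]
    })
}

## loglik over the flat parameter vector (sampler-interface objective)
.flat_loglik <- function(family, par, idx, Xl, prep, spec) {
  params <- switch(family,
    linear = list(beta = par[idx$mean], sigma = par[idx$sigma]),
    hurdle_nb = list(zero = par[idx$zero], count = par[idx$count],
                     phi = par[idx$phi]),
    zoib = list(boundary = par[idx$boundary], one = par[idx$one],
                mu = par[idx$mu], phi_b = par[idx$phi_b]),
    cumlogit = list(theta = par[idx$theta], beta = par[idx$location],
                    values = prep$value_map))
  tryCatch(.loglik_from_design(family, params, Xl, prep, spec),
           error = function(e) -Inf)
}

## same likelihood as loglik(), evaluated on prebuilt designs
.loglik_from_design <- function(family, params, Xl, prep, spec) {
  y <- prep$y
  switch(family,
    linear = sum(stats::dnorm(y, drop(Xl$mean %*% params$beta),
                              params$sigma, log = TRUE)),
    hurdle_nb = {
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
      alpha <- stats::plogis(drop(Xl$boundary %*% params$boundary))
      gamma <- stats::plogis(drop(Xl$one %*% params$one))
      mu_b <- stats::plogis(drop(Xl$mu %*% params$mu))
      b0 <- y == 0; b1 <- y == 1; int <- !b0 & !b1
      a <- mu_b * params$phi_b; b <- (1 - mu_b) * params$phi_b
      sum(log(alpha[b0]) + log1p(-gamma[b0])) +
        sum(log(alpha[b1]) + log(gamma[b1])) +
        sum(log1p(-alpha[int]) +
              stats::dbeta(y[int], a[int], b[int], log = TRUE))
    },
    cumlogit = {
      eta <- if (length(params$beta))
        drop(Xl$location %*% params$beta) else rep(0, length(prep$k))
      FF <- stats::plogis(outer(-eta, params$theta, `+`))
      P <- cbind(FF, 1) - cbind(0, FF)
      sum(log(pmax(P[cbind(seq_along(prep$k), prep$k)], 1e-300)))
    })
}

#' @export
print.dawols_fit <- function(x, ...) {
  cat("<dawols fit> family:", x$family, "  D =", x$metadata$D, "draws (",
      x$metadata$engine, ")\n", sep = " ")
  est <- t(apply(x$draws, 2, stats::quantile, c(0.5, 0.025, 0.975),
                 type = 7))
  tab <- cbind(estimate = x$point, median = est[, 1],
               lower95 = est[, 2], upper95 = est[, 3])
  print(round(tab, 4))
  if (!x$metadata$converged) cat("warning: point fit not converged\n")
  invisible(x)
}
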