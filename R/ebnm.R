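# Empirical Bayes normal means (EBNM) solvers.
#
# Each solver takes observations x with known standard deviations s, where
# x_i ~ N(theta_i, s_i^2) and the theta_i are i.i.d. from a family-specific
# prior.  The prior hyperparameters are estimated by maximizing the marginal
# likelihood; the solver then reports the posterior first and second moments
# of each theta_i, the posterior probability that theta_i is nonzero, and the
# maximized log marginal likelihood.  These are the atomic subproblems of the
# EBMF engine in ebmf.R.

new_ebnm_res <- function(prior, post_mean, post_mean2, zeta, loglik,
                         converged = TRUE, extra = list()) {
  post_mean2 <- pmax(post_mean2, post_mean^2)
  res <- c(list(prior = prior,
                post_mean = post_mean,
                post_mean2 = post_mean2,
                post_sd = sqrt(pmax(post_mean2 - post_mean^2, 0)),
                zeta = zeta,
                loglik = loglik,
                converged = converged),
           extra)
  class(res) <- "ebnm_res"
  res
}

# Log-likelihood of the pure spike (all theta = 0) prior; the degenerate
# member of every prior family considered here.
spike_only_loglik <- function(x, s) sum(dnorm(x, 0, s, log = TRUE))

spike_only_res <- function(x, s, prior) {
  n <- length(x)
  new_ebnm_res(prior,
               post_mean = numeric(n), post_mean2 = numeric(n),
               zeta = numeric(n), loglik = spike_only_loglik(x, s))
}

## ---------------------------------------------------------------------------
## Generalized binary prior: (1 - pi) delta_0 + pi N+(mu, (omega mu)^2)
## ---------------------------------------------------------------------------

# Per-observation log density of the slab component of the GB prior
# convolved with N(0, s^2) noise: N(x; mu, sigma^2 + s^2) * Phi(mu_t/sg_t) /
# Phi(mu/sigma), where (mu_t, sg_t) are the moments of the untruncated
# normal posterior.
gb_log_slab <- function(x, s, mu, sigma) {
  if (mu <= 0 || sigma <= 0) {
    # slab collapses to a point mass at max(mu, 0)
    return(dnorm(x, max(mu, 0), s, log = TRUE))
  }
  s2 <- s^2
  sig2 <- sigma^2
  mu_t <- (s2 * mu + sig2 * x) / (s2 + sig2)
  sg_t <- sqrt(sig2 * s2 / (s2 + sig2))
  dnorm(x, mu, sqrt(sig2 + s2), log = TRUE) +
    pnorm(mu_t / sg_t, log.p = TRUE) -
    pnorm(mu / sigma, log.p = TRUE)
}

#' Marginal log-likelihood under the generalized binary prior
#'
#' Computes the log marginal likelihood of observations `x` with standard
#' deviations `s` under the generalized binary (GB) prior
#' \eqn{(1-\pi)\delta_0 + \pi N_+(\mu, \sigma^2)} with \eqn{\sigma = \omega\mu},
#' where \eqn{N_+} denotes a normal distribution left-truncated at zero.  The
#' closed form uses the truncation correction
#' \eqn{\Phi(\tilde\mu_i/\tilde\sigma_i)/\Phi(\mu/\sigma)} and is evaluated in
#' log space.
#'
#' @param x Numeric vector of observations.
#' @param s Numeric vector (or scalar) of known standard deviations.
#' @param pi Slab weight in \[0, 1\].
#' @param mu Slab mode (nonnegative).
#' @param omega Fixed ratio \eqn{\sigma/\mu} (positive); default 0.02.
#' @return Scalar log marginal likelihood.
#' @export
gb_marginal_loglik <- function(x, s, pi, mu, omega = 0.02) {
  s <- check_nm_problem(x, s)
  stopifnot(pi >= 0, pi <= 1, mu >= 0, omega > 0)
  log_spike <- dnorm(x, 0, s, log = TRUE)
  if (pi == 0) return(sum(log_spike))
  log_slab <- gb_log_slab(x, s, mu, omega * mu)
  if (pi == 1) return(sum(log_slab))
  sum(logspace_add(log(1 - pi) + log_spike, log(pi) + log_slab))
}

# E-step: posterior probability that each observation comes from the slab.
gb_zeta <- function(x, s, pi, mu, omega) {
  if (pi <= 0) return(numeric(length(x)))
  if (pi >= 1) return(rep(1, length(x)))
  log_spike <- log(1 - pi) + dnorm(x, 0, s, log = TRUE)
  log_slab <- log(pi) + gb_log_slab(x, s, mu, omega * mu)
  1 / (1 + exp(log_spike - log_slab))
}

# M-step objective in mu (weighted slab log-likelihood); the Phi(1/omega)
# normalizer is constant in mu and omitted.
gb_mu_objective <- function(mu, x, s, zeta, omega) {
  sigma <- omega * mu
  s2 <- s^2
  sig2 <- sigma^2
  mu_t <- (s2 * mu + sig2 * x) / (s2 + sig2)
  sg_t <- sqrt(sig2 * s2 / (s2 + sig2))
  sum(zeta * (dnorm(x, mu, sqrt(sig2 + s2), log = TRUE) +
                pnorm(mu_t / sg_t, log.p = TRUE)))
}

# One EM run for the GB prior from a given start; monotone in the marginal
# log-likelihood.
gb_em <- function(x, s, pi, mu, omega, max_iter, em_tol) {
  upper <- 2 * max(abs(x))
  ll <- gb_marginal_loglik(x, s, pi, mu, omega)
  trace <- ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    zeta <- gb_zeta(x, s, pi, mu, omega)
    pi_new <- mean(zeta)
    if (sum(zeta) > 0) {
      opt <- optimize(gb_mu_objective, c(1e-8, upper), x = x, s = s,
                      zeta = zeta, omega = omega, maximum = TRUE,
                      tol = 1e-8)
      # optimize() can miss the current point on flat objectives; never step
      # downhill in the M-step.
      if (opt$objective >= gb_mu_objective(mu, x, s, zeta, omega)) {
        mu <- opt$maximum
      }
    }
    pi <- pi_new
    ll_new <- gb_marginal_loglik(x, s, pi, mu, omega)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= em_tol * (abs(ll) + 1e-8)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(pi = pi, mu = mu, ll = ll, trace = trace, converged = converged)
}

#' Solve the EBNM problem with a generalized binary prior by EM
#'
#' Alternates an E-step (posterior slab probabilities by Bayes rule) with an
#' M-step (closed-form update of the slab weight; bounded one-dimensional
#' maximization of the slab mode) until the marginal log-likelihood is stable.
#' The ratio \eqn{\omega = \sigma/\mu} is held fixed.  If the expectation-
#' maximization solution does not beat the pure-spike prior, the spike-only
#' solution is returned (the spike is a member of the family's closure).
#'
#' @param x Numeric vector of observations.
#' @param s Numeric vector (or scalar) of known standard deviations.
#' @param omega Fixed slab coefficient of variation; default 0.02.
#' @param em_tol Relative tolerance on the marginal log-likelihood; default 1e-6.
#' @param max_iter Maximum EM iterations; default 500.
#' @param init Optional list with starting values `pi` and `mu` (used for warm
#'   starts inside the matrix-factorization engine).
#' @return An object of class `ebnm_res`: fitted prior (`pi`, `mu`, `omega`),
#'   posterior moments `post_mean`, `post_mean2`, `post_sd`, slab
#'   probabilities `zeta`, maximized marginal `loglik`, convergence flag, the
#'   per-observation truncated-normal posterior parameters `trunc_params`, and
#'   the EM `loglik_trace`.
#' @export
ebnm_gb <- function(x, s, omega = 0.02, em_tol = 1e-6, max_iter = 500,
                    init = NULL) {
  s <- check_nm_problem(x, s)
  stopifnot(omega > 0)
  xmax <- max(abs(x))
  prior0 <- list(family = "generalized_binary", pi = 0, mu = 0, omega = omega)
  if (xmax == 0 || max(x) <= 0) return(spike_only_res(x, s, prior0))

  # Candidate starts.  The slab lives on the positive axis, so the slab-mode
  # guesses come from the positive part of x only (large negative residual
  # observations are common inside the factorization engine and would
  # otherwise inflate the starting mode); multiple starts guard against the
  # EM latching onto a high tail of the slab.
  pos <- x[x > 0]
  if (!is.null(init) && init$mu > 0) {
    # warm start from the previous solve of the same subproblem, with one
    # bulk-scale fallback
    starts <- list(list(pi = min(max(init$pi, 1e-4), 1 - 1e-4),
                        mu = init$mu),
                   list(pi = 0.3, mu = mean(pos)))
  } else {
    starts <- list(
      list(pi = 0.5, mu = mean(pos[pos >= quantile(pos, 0.9)])),
      list(pi = 0.3, mu = mean(pos)),
      list(pi = min(0.9, max(0.1, mean(x > 2 * s))),
           mu = as.numeric(quantile(pos, 0.75))))
  }

  best <- NULL
  for (st in starts) {
    run <- gb_em(x, s, st$pi, max(st$mu, 1e-8), omega,
                 max_iter = 25, em_tol = em_tol)
    if (is.null(best) || run$ll > best$ll) best <- run
  }
  run <- gb_em(x, s, best$pi, best$mu, omega,
               max_iter = max_iter, em_tol = em_tol)
  pi <- run$pi
  mu <- run$mu
  ll <- run$ll
  converged <- run$converged
  trace <- c(best$trace, run$trace)

  if (spike_only_loglik(x, s) >= ll) {
    res <- spike_only_res(x, s, prior0)
    res$loglik_trace <- trace
    return(res)
  }

  sigma <- omega * mu
  s2 <- s^2
  sig2 <- sigma^2
  mu_t <- (s2 * mu + sig2 * x) / (s2 + sig2)
  sg_t <- sqrt(sig2 * s2 / (s2 + sig2))
  zeta <- gb_zeta(x, s, pi, mu, omega)
  mom <- tnorm_pos_moments(mu_t, sg_t)
  new_ebnm_res(list(family = "generalized_binary", pi = pi, mu = mu,
                    omega = omega),
               post_mean = zeta * mom$m1,
               post_mean2 = zeta * mom$m2,
               zeta = zeta, loglik = ll, converged = converged,
               extra = list(trunc_params = list(mu_t = mu_t, sg_t = sg_t),
                            loglik_trace = trace))
}

## ---------------------------------------------------------------------------
## Point-Laplace prior: (1 - pi) delta_0 + pi Laplace(rate lambda)
## ---------------------------------------------------------------------------

# Log density of the two exponential tails of a Laplace(lambda) prior
# convolved with N(0, s^2); returned separately for the positive and
# negative parts (each with weight 1/2 already included in the caller).
laplace_conv_parts <- function(x, s, lambda) {
  a <- lambda^2 * s^2 / 2
  pos <- a - lambda * x + pnorm((x - lambda * s^2) / s, log.p = TRUE)
  neg <- a + lambda * x + pnorm(-(x + lambda * s^2) / s, log.p = TRUE)
  list(pos = pos, neg = neg)
}

pl_log_slab <- function(x, s, lambda) {
  parts <- laplace_conv_parts(x, s, lambda)
  log(lambda / 2) + logspace_add(parts$pos, parts$neg)
}

pl_loglik <- function(x, s, pi, lambda) {
  log_spike <- dnorm(x, 0, s, log = TRUE)
  if (pi <= 0) return(sum(log_spike))
  log_slab <- pl_log_slab(x, s, lambda)
  if (pi >= 1) return(sum(log_slab))
  sum(logspace_add(log(1 - pi) + log_spike, log(pi) + log_slab))
}

# Maximize a 2-parameter spike-slab marginal over (logit pi, log lambda).
# A warm start (from the previous solve of the same subproblem inside the
# factorization engine) restricts the search to a single polish run.
optimize_spike_slab <- function(x, s, loglik_fun, lambda0, opt_tol,
                                warm = NULL) {
  obj <- function(par) {
    pi <- plogis(par[1])
    lambda <- exp(par[2])
    -loglik_fun(x, s, pi, lambda)
  }
  if (!is.null(warm) && isTRUE(warm$pi > 0)) {
    starts <- list(c(qlogis(min(max(warm$pi, 1e-4), 1 - 1e-4)),
                     log(warm$lambda)))
  } else {
    starts <- list(c(0, log(lambda0)),
                   c(qlogis(0.1), log(lambda0 * 4)),
                   c(qlogis(0.9), log(lambda0 / 4)))
  }
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      optim(start, obj, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = opt_tol)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  list(pi = plogis(best$par[1]), lambda = exp(best$par[2]),
       loglik = -best$value, converged = best$convergence == 0)
}

# Scale guess for the slab rate from the excess variance of x.
slab_rate_init <- function(x, s) {
  excess <- mean(x^2) - mean(s^2)
  1 / sqrt(max(excess, 0.01 * mean(s^2)))
}

#' Solve the EBNM problem with a point-Laplace prior
#'
#' Maximizes the marginal likelihood of the spike + Laplace(\eqn{\lambda})
#' mixture over the spike weight and the Laplace rate, using the closed-form
#' Gaussian-Laplace convolution, then reports exact posterior moments (the
#' posterior on each mean is a mixture of a point mass at zero and two
#' oppositely-truncated normals).
#'
#' @inheritParams ebnm_gb
#' @param opt_tol Relative convergence tolerance of the optimizer.
#' @return An object of class `ebnm_res` with prior fields `pi` and `lambda`.
#' @export
ebnm_point_laplace <- function(x, s, opt_tol = 1e-9, init = NULL) {
  s <- check_nm_problem(x, s)
  prior0 <- list(family = "point_laplace", pi = 0, lambda = 1)
  if (max(abs(x)) == 0) return(spike_only_res(x, s, prior0))
  lambda0 <- if (is.null(init)) slab_rate_init(x, s) else init$lambda
  opt <- optimize_spike_slab(x, s, pl_loglik, lambda0, opt_tol, warm = init)
  if (spike_only_loglik(x, s) >= opt$loglik) {
    return(spike_only_res(x, s, prior0))
  }
  post <- pl_posterior(x, s, opt$pi, opt$lambda)
  new_ebnm_res(list(family = "point_laplace", pi = opt$pi,
                    lambda = opt$lambda),
               post_mean = post$mean, post_mean2 = post$mean2,
               zeta = post$zeta, loglik = opt$loglik,
               converged = opt$converged)
}

# Posterior moments under a fixed point-Laplace prior.
pl_posterior <- function(x, s, pi, lambda) {
  n <- length(x)
  if (pi <= 0) return(list(mean = numeric(n), mean2 = numeric(n),
                           zeta = numeric(n)))
  parts <- laplace_conv_parts(x, s, lambda)
  log_wp <- log(pi) + log(lambda / 2) + parts$pos
  log_wn <- log(pi) + log(lambda / 2) + parts$neg
  log_w0 <- if (pi >= 1) rep(-Inf, n) else log(1 - pi) + dnorm(x, 0, s, log = TRUE)
  m <- pmax(log_wp, pmax(log_wn, log_w0))
  wp <- exp(log_wp - m); wn <- exp(log_wn - m); w0 <- exp(log_w0 - m)
  tot <- wp + wn + w0
  wp <- wp / tot; wn <- wn / tot
  mp <- tnorm_pos_moments(x - lambda * s^2, s)
  mn <- tnorm_neg_moments(x + lambda * s^2, s)
  list(mean = wp * mp$m1 + wn * mn$m1,
       mean2 = wp * mp$m2 + wn * mn$m2,
       zeta = wp + wn)
}

## ---------------------------------------------------------------------------
## Point-exponential prior: (1 - pi) delta_0 + pi Exp(rate lambda) on (0, Inf)
## ---------------------------------------------------------------------------

pe_log_slab <- function(x, s, lambda) {
  log(lambda) + lambda^2 * s^2 / 2 - lambda * x +
    pnorm((x - lambda * s^2) / s, log.p = TRUE)
}

pe_loglik <- function(x, s, pi, lambda) {
  log_spike <- dnorm(x, 0, s, log = TRUE)
  if (pi <= 0) return(sum(log_spike))
  log_slab <- pe_log_slab(x, s, lambda)
  if (pi >= 1) return(sum(log_slab))
  sum(logspace_add(log(1 - pi) + log_spike, log(pi) + log_slab))
}

pe_posterior <- function(x, s, pi, lambda) {
  n <- length(x)
  if (pi <= 0) return(list(mean = numeric(n), mean2 = numeric(n),
                           zeta = numeric(n)))
  log_w1 <- log(pi) + pe_log_slab(x, s, lambda)
  log_w0 <- if (pi >= 1) rep(-Inf, n) else log(1 - pi) + dnorm(x, 0, s, log = TRUE)
  zeta <- 1 / (1 + exp(log_w0 - log_w1))
  mom <- tnorm_pos_moments(x - lambda * s^2, s)
  list(mean = zeta * mom$m1, mean2 = zeta * mom$m2, zeta = zeta)
}

#' Solve the EBNM problem with a point-exponential prior
#'
#' As [ebnm_point_laplace()] but with a nonnegative exponential slab, so the
#' posterior means are constrained to be nonnegative.
#'
#' @inheritParams ebnm_point_laplace
#' @return An object of class `ebnm_res` with prior fields `pi` and `lambda`.
#' @export
ebnm_point_exponential <- function(x, s, opt_tol = 1e-9, init = NULL) {
  s <- check_nm_problem(x, s)
  prior0 <- list(family = "point_exponential", pi = 0, lambda = 1)
  if (max(x) <= 0) return(spike_only_res(x, s, prior0))
  lambda0 <- if (is.null(init)) slab_rate_init(x, s) else init$lambda
  opt <- optimize_spike_slab(x, s, pe_loglik, lambda0, opt_tol, warm = init)
  if (spike_only_loglik(x, s) >= opt$loglik) {
    return(spike_only_res(x, s, prior0))
  }
  post <- pe_posterior(x, s, opt$pi, opt$lambda)
  new_ebnm_res(list(family = "point_exponential", pi = opt$pi,
                    lambda = opt$lambda),
               post_mean = post$mean, post_mean2 = post$mean2,
               zeta = post$zeta, loglik = opt$loglik,
               converged = opt$converged)
}

## ---------------------------------------------------------------------------
## Normal prior: theta ~ N(0, tau^2) (conjugate special case, used by the
## factorization engine's tests and available as a prior family)
## ---------------------------------------------------------------------------

#' Solve the EBNM problem with a zero-mean normal prior
#'
#' The prior variance is estimated by maximizing the marginal likelihood
#' (a one-dimensional bounded search); the posterior is the conjugate ridge
#' shrinkage \eqn{E[\theta_i|x_i] = x_i \tau^2/(\tau^2 + s_i^2)}.
#'
#' @inheritParams ebnm_gb
#' @param tau2 Optional fixed prior variance; when supplied no estimation is
#'   performed.
#' @return An object of class `ebnm_res` with prior field `tau2`.
#' @export
ebnm_normal <- function(x, s, tau2 = NULL, init = NULL) {
  s <- check_nm_problem(x, s)
  ll_fun <- function(t2) sum(dnorm(x, 0, sqrt(t2 + s^2), log = TRUE))
  if (is.null(tau2)) {
    upper <- max(mean(x^2), max(s^2))
    opt <- optimize(ll_fun, c(0, 4 * upper + 1e-12), maximum = TRUE,
                    tol = 1e-12)
    tau2 <- opt$maximum
    if (ll_fun(0) >= opt$objective) tau2 <- 0
  }
  w <- tau2 / (tau2 + s^2)
  pm <- w * x
  pv <- w * s^2
  new_ebnm_res(list(family = "normal", tau2 = tau2),
               post_mean = pm, post_mean2 = pm^2 + pv,
               zeta = as.numeric(rep(tau2 > 0, length(x))),
               loglik = ll_fun(tau2))
}

## ---------------------------------------------------------------------------
## Adaptive shrinkage: zero-anchored scale mixture of normals
## ---------------------------------------------------------------------------

#' Adaptive shrinkage of effect estimates by a normal scale mixture
#'
#' Fits, by expectation-maximization over mixture weights, a prior
#' \eqn{g = \sum_m w_m N(0, \tau_m^2)} on a fixed multiplicative grid of
#' standard deviations (including a point mass at zero) to effect estimates
#' `betahat` with standard errors `sehat`, then reports posterior means,
#' posterior standard deviations, and local false sign rates
#' \eqn{lfsr = \min\{P(\beta \le 0), P(\beta \ge 0)\}}.
#'
#' @param betahat Numeric vector of effect estimates.
#' @param sehat Numeric vector of positive standard errors.
#' @param grid_mult Multiplicative spacing of the SD grid; default `sqrt(2)`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return An object of class `ash_res` with elements `post_mean`, `post_sd`,
#'   `lfsr`, the grid `mix_sd`, fitted `mix_weight`, and `loglik`.
#' @export
adaptive_shrinkage <- function(betahat, sehat, grid_mult = sqrt(2),
                               max_iter = 1000, tol = 1e-9) {
  sehat <- check_nm_problem(betahat, sehat)
  n <- length(betahat)
  lo <- min(sehat) / 10
  hi <- max(2 * max(abs(betahat)), lo * grid_mult)
  sd_grid <- lo * grid_mult^(0:ceiling(log(hi / lo) / log(grid_mult)))
  sd_grid <- c(0, sd_grid)
  M <- length(sd_grid)

  # n x M log-likelihood matrix of each observation under each component
  tot_sd <- sqrt(outer(sehat^2, sd_grid^2, `+`))
  log_lik <- dnorm(betahat, 0, tot_sd, log = TRUE)

  w <- rep(1 / M, M)
  ll <- -Inf
  for (iter in seq_len(max_iter)) {
    lw <- sweep(log_lik, 2, log(w), `+`)
    m <- apply(lw, 1, max)
    p <- exp(lw - m)
    rs <- rowSums(p)
    ll_new <- sum(m + log(rs))
    resp <- p / rs
    w <- colMeans(resp)
    if (is.finite(ll) && abs(ll_new - ll) <= tol * (abs(ll) + 1e-8)) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  # component-wise conjugate posteriors
  shrink <- sweep(outer(rep(1, n), sd_grid^2), 1, sehat^2,
                  function(t2, s2) t2 / (t2 + s2))
  pm <- shrink * betahat
  pv <- shrink * sehat^2
  post_mean <- rowSums(resp * pm)
  post_m2 <- rowSums(resp * (pm^2 + pv))
  post_sd <- sqrt(pmax(post_m2 - post_mean^2, 0))

  p_zero <- resp[, 1]
  psd <- sqrt(pv[, -1, drop = FALSE])
  p_neg <- rowSums(resp[, -1, drop = FALSE] *
                     pnorm(0, pm[, -1, drop = FALSE], psd))
  p_pos <- pmax(1 - p_zero - p_neg, 0)
  lfsr <- pmin(pmin(p_neg, p_pos) + p_zero, 1)

  structure(list(post_mean = post_mean, post_sd = post_sd, lfsr = lfsr,
                 mix_sd = sd_grid, mix_weight = w, loglik = ll),
            class = "ash_res")
}
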