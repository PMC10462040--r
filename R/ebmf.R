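# Empirical Bayes matrix factorization (EBMF) engine.
#
# Fits A = sum_k l_k f_k^T + E by mean-field variational inference, where
# every loading and factor vector carries a prior from one of the EBNM
# families in ebnm.R, fitted by empirical Bayes.  Each coordinate update
# reduces to an EBNM problem; factors are added greedily (best rank-1
# approximation of the residual) and then refined by cyclic backfitting,
# with automatic selection of the number of components by pruning factors
# whose fitted prior collapses to a point mass at zero.
#
# Supported noise models: a single residual variance ("constant") or one
# variance per column ("by_column").  For symmetric covariance-type targets
# a scalar offset epsilon on the diagonal can be estimated by an outer loop.

#' Specify a prior family for one side of an EBMF fit
#'
#' @param family One of `"point_laplace"`, `"generalized_binary"`,
#'   `"point_exponential"`, `"normal"`.
#' @param omega Coefficient of variation of the generalized-binary slab.
#' @param tau2 Fixed variance for the normal family (`NULL`: estimated).
#' @return A list consumed by [ebmf_fit()] and [ebmf_rank1_update()].
#' @export
prior_spec <- function(family = c("point_laplace", "generalized_binary",
                                  "point_exponential", "normal"),
                       omega = 0.02, tau2 = NULL) {
  family <- match.arg(family)
  list(family = family, omega = omega, tau2 = tau2)
}

# Dispatch an EBNM solve for a prior specification, with warm starting.
solve_ebnm <- function(x, s, spec, warm = NULL) {
  switch(spec$family,
         generalized_binary = ebnm_gb(x, s, omega = spec$omega, init = warm),
         point_laplace = ebnm_point_laplace(x, s, init = warm),
         point_exponential = ebnm_point_exponential(x, s, init = warm),
         normal = ebnm_normal(x, s, tau2 = spec$tau2),
         stop("unknown prior family: ", spec$family))
}

# Empty model container.  EL/EF hold posterior first moments, EL2/EF2 second
# moments; KL terms are stored per factor and side.
new_ebmf_model <- function(n, p, var_type) {
  structure(list(EL = matrix(0, n, 0), EL2 = matrix(0, n, 0),
                 EF = matrix(0, p, 0), EF2 = matrix(0, p, 0),
                 kl_l = numeric(0), kl_f = numeric(0),
                 priors_l = list(), priors_f = list(),
                 tau = NULL, var_type = var_type,
                 fixed_loadings = FALSE,
                 elbo_trace = numeric(0), K = 0L),
            class = "ebmf_fit")
}

model_fitted_values <- function(model) {
  if (model$K == 0L) return(0)
  model$EL %*% t(model$EF)
}

# Expected residual sum of squares per column (length p): the Gaussian
# quadratic form under the variational posterior.
ebmf_erss <- function(A, model) {
  R <- A - model_fitted_values(model)
  err <- colSums(R^2)
  if (model$K > 0L) {
    err <- err + colSums(model$EL2 %*% t(model$EF2) -
                           (model$EL^2) %*% t(model$EF^2))
  }
  pmax(err, .Machine$double.eps)
}

update_tau <- function(A, model) {
  n <- nrow(A)
  erss <- ebmf_erss(A, model)
  if (model$var_type == "by_column") {
    model$tau <- n / erss
  } else {
    model$tau <- length(A) / sum(erss)
  }
  model
}

tau_vec <- function(model, p) {
  if (model$var_type == "by_column") model$tau else rep(model$tau, p)
}

#' Evidence lower bound of an EBMF model
#'
#' The expected Gaussian log-likelihood of the residuals under the
#' variational posteriors, minus the Kullback-Leibler divergence of each
#' factor's posterior from its fitted prior.
#'
#' @param A Target matrix.
#' @param model An `ebmf_fit` object.
#' @return Scalar ELBO.
#' @export
ebmf_elbo <- function(A, model) {
  n <- nrow(A)
  p <- ncol(A)
  tau <- tau_vec(model, p)
  erss <- ebmf_erss(A, model)
  eloglik <- sum(n / 2 * (log(tau) - log(2 * pi)) - tau / 2 * erss)
  eloglik - sum(model$kl_l) - sum(model$kl_f)
}

# E_q[log p(x | theta)] for a normal-means subproblem; combined with the
# EBNM marginal log-likelihood this yields the exact KL term of the factor.
nm_expected_loglik <- function(x, s, post_mean, post_mean2) {
  sum(-0.5 * log(2 * pi * s^2) -
        (x^2 - 2 * x * post_mean + post_mean2) / (2 * s^2))
}

#' Single-factor coordinate update
#'
#' Updates one side (loadings or factors) of factor `k` by forming the
#' induced normal-means problem from the residualized target and solving it
#' with the side's prior family.  Precision weights come from the current
#' residual-variance estimates.
#'
#' @param A Target matrix.
#' @param model An `ebmf_fit` object.
#' @param k Factor index.
#' @param side `"l"` (update loadings, length `nrow(A)`) or `"f"`.
#' @param spec Prior specification from [prior_spec()].
#' @return The updated model.
#' @export
ebmf_rank1_update <- function(A, model, k, side = c("l", "f"), spec) {
  side <- match.arg(side)
  n <- nrow(A)
  p <- ncol(A)
  w <- tau_vec(model, p)
  if (side == "l") {
    if (model$fixed_loadings) return(model)
    v <- model$EF[, k]
    v2 <- model$EF2[, k]
    d <- sum(v2 * w)
    if (d <= 0) return(model)
    wv <- v * w
    b <- drop(A %*% wv)
    if (model$K > 1L) {
      others <- setdiff(seq_len(model$K), k)
      b <- b - drop(model$EL[, others, drop = FALSE] %*%
                      (t(model$EF[, others, drop = FALSE]) %*% wv))
    }
    x <- b / d
    s <- rep(1 / sqrt(d), n)
    warm <- model$priors_l[[k]]
    res <- solve_ebnm(x, s, spec, warm)
    model$EL[, k] <- res$post_mean
    model$EL2[, k] <- res$post_mean2
    model$priors_l[[k]] <- res$prior
    model$kl_l[k] <- nm_expected_loglik(x, s, res$post_mean, res$post_mean2) -
      res$loglik
  } else {
    u <- model$EL[, k]
    u2 <- model$EL2[, k]
    # per-column precisions multiply the row weights elementwise
    d <- sum(u2) * w
    if (all(d <= 0)) return(model)
    b <- drop(crossprod(A, u))
    if (model$K > 1L) {
      others <- setdiff(seq_len(model$K), k)
      b <- b - drop(model$EF[, others, drop = FALSE] %*%
                      (t(model$EL[, others, drop = FALSE]) %*% u))
    }
    x <- b / sum(u2)
    s <- 1 / sqrt(d)
    warm <- model$priors_f[[k]]
    res <- solve_ebnm(x, s, spec, warm)
    model$EF[, k] <- res$post_mean
    model$EF2[, k] <- res$post_mean2
    model$priors_f[[k]] <- res$prior
    model$kl_f[k] <- nm_expected_loglik(x, s, res$post_mean, res$post_mean2) -
      res$loglik
  }
  model
}

# Is a fitted prior a point mass at zero?
prior_is_null <- function(prior) {
  if (is.null(prior)) return(FALSE)
  switch(prior$family,
         generalized_binary = prior$pi <= 1e-3 || prior$mu <= 1e-6,
         point_laplace = prior$pi <= 1e-3,
         point_exponential = prior$pi <= 1e-3,
         normal = prior$tau2 <= 0,
         FALSE)
}

drop_factors <- function(model, idx) {
  keep <- setdiff(seq_len(model$K), idx)
  model$EL <- model$EL[, keep, drop = FALSE]
  model$EL2 <- model$EL2[, keep, drop = FALSE]
  model$EF <- model$EF[, keep, drop = FALSE]
  model$EF2 <- model$EF2[, keep, drop = FALSE]
  model$kl_l <- model$kl_l[keep]
  model$kl_f <- model$kl_f[keep]
  model$priors_l <- model$priors_l[keep]
  model$priors_f <- model$priors_f[keep]
  model$K <- length(keep)
  model
}

#' Prune null factors from an EBMF model
#'
#' Removes factors whose fitted prior on either side is a point mass at zero,
#' whose posterior means vanish on either side, or whose removal does not
#' decrease the ELBO (each candidate removal is evaluated with the residual
#' variance re-optimized); the returned model has its residual variance
#' re-optimized.
#'
#' @inheritParams ebmf_elbo
#' @param scope `"all"` (default) or `"last"`: which factors to examine.
#'   The greedy stage checks only the factor it just added; the final
#'   nullcheck examines every factor.
#' @return The pruned (and re-variance-optimized) model.
#' @export
ebmf_nullcheck <- function(A, model, scope = c("all", "last")) {
  scope <- match.arg(scope)
  if (model$K == 0L) return(model)
  idx <- if (scope == "last") model$K else seq_len(model$K)
  null_k <- vapply(idx, function(k) {
    (!model$fixed_loadings &&
       (prior_is_null(model$priors_l[[k]]) || all(model$EL[, k] == 0))) ||
      prior_is_null(model$priors_f[[k]]) || all(model$EF[, k] == 0)
  }, logical(1))
  if (any(null_k)) {
    model <- drop_factors(model, idx[null_k])
  }
  model <- update_tau(A, model)
  # ELBO-based removal: a factor must pay for its KL cost.  Scan from the
  # last factor down so index shifts from drops cannot skip a factor.
  elbo_cur <- ebmf_elbo(A, model)
  idx <- if (scope == "last") model$K else rev(seq_len(model$K))
  for (k in idx) {
    if (k > model$K || k < 1L) next
    cand <- update_tau(A, drop_factors(model, k))
    elbo_cand <- ebmf_elbo(A, cand)
    if (elbo_cand >= elbo_cur) {
      model <- cand
      elbo_cur <- elbo_cand
    }
  }
  model
}

# Deterministic best rank-1 approximation of M by power iteration, started
# from the column with the largest norm.
power_rank1 <- function(M, iters = 30) {
  cn <- colSums(M^2)
  if (max(cn) == 0) {
    return(list(u = rep(0, nrow(M)), v = rep(0, ncol(M))))
  }
  v <- drop(crossprod(M, M[, which.max(cn)]))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    u <- drop(M %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    v <- drop(crossprod(M, u))
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  d <- drop(crossprod(u, M %*% v))
  # orient so the largest-magnitude loading entry is positive
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    v <- -v
  }
  sc <- sqrt(abs(d))
  list(u = u * sc, v = v * sc)
}

add_factor <- function(model, l_init, f_init) {
  model$EL <- cbind(model$EL, l_init)
  model$EL2 <- cbind(model$EL2, l_init^2)
  model$EF <- cbind(model$EF, f_init)
  model$EF2 <- cbind(model$EF2, f_init^2)
  model$kl_l <- c(model$kl_l, 0)
  model$kl_f <- c(model$kl_f, 0)
  model$priors_l <- c(model$priors_l, list(NULL))
  model$priors_f <- c(model$priors_f, list(NULL))
  model$K <- model$K + 1L
  model
}

# Refine one factor by alternating coordinate updates.
refine_factor <- function(A, model, k, prior_l, prior_f, iters = 50,
                          rel_tol = 1e-4) {
  for (i in seq_len(iters)) {
    old <- model$EL[, k]
    model <- ebmf_rank1_update(A, model, k, "f", prior_f)
    model <- ebmf_rank1_update(A, model, k, "l", prior_l)
    newv <- model$EL[, k]
    denom <- sqrt(sum(old^2))
    if (denom == 0 || sqrt(sum((newv - old)^2)) <= rel_tol * denom) break
  }
  model
}

#' Fit an empirical Bayes matrix factorization
#'
#' Greedy-plus-backfit EBMF.  Factors are added one at a time (each
#' initialized from the best rank-1 approximation of the current residual and
#' refined by alternating updates); adding stops when a new factor is pruned
#' to zero or `Kmax` is reached.  All factors are then backfitted cyclically
#' until the ELBO improvement per sweep falls below `tol`.  Supports a
#' fixed-loadings mode (loadings held at supplied values; only factors,
#' priors and residual variances are updated), explicit initialization of
#' both sides (skipping the greedy stage), and estimation of a diagonal
#' offset for symmetric covariance-type targets via an outer loop.
#'
#' @param A Numeric target matrix.
#' @param prior_l,prior_f Prior specifications from [prior_spec()] for the
#'   loadings and factors.
#' @param Kmax Maximum number of factors (>= 1).
#' @param var_type `"constant"` (one residual variance) or `"by_column"`.
#' @param fixed_loadings Optional matrix of loadings to hold fixed; implies
#'   `init_f` is estimated and no greedy stage.
#' @param init_l,init_f Optional initialization matrices; when both are given
#'   the greedy stage is skipped and the factors are backfitted.
#' @param diag_offset If `TRUE`, `A` is treated as a symmetric covariance-type
#'   target and a nonnegative scalar subtracted from its diagonal is
#'   estimated by alternating fit / moment-update rounds.
#' @param tol Backfit tolerance on the ELBO per sweep; default
#'   `1e-6 * length(A)`.
#' @param max_sweeps Cap on backfit sweeps; default 500.
#' @param backfit Run the backfit stage (default `TRUE`).
#' @param verbose Print per-sweep ELBO.
#' @return An object of class `ebmf_fit` with posterior moment matrices
#'   `EL`, `EL2`, `EF`, `EF2`, fitted priors, residual precisions `tau`,
#'   `elbo_trace` (one value per backfit sweep), factor count `K`, and, when
#'   `diag_offset` is used, the fitted offset `epsilon`.
#' @export
ebmf_fit <- function(A, prior_l, prior_f, Kmax,
                     var_type = c("constant", "by_column"),
                     fixed_loadings = NULL, init_l = NULL, init_f = NULL,
                     diag_offset = FALSE, eps_init = NULL, tol = NULL,
                     max_sweeps = 500, backfit = TRUE, verbose = FALSE) {
  var_type <- match.arg(var_type)
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!all(is.finite(A))) stop("target matrix has non-finite entries")
  if (Kmax < 1) stop("Kmax must be at least 1")
  if (is.null(tol)) tol <- 1e-6 * length(A)

  if (!diag_offset) {
    return(ebmf_fit_inner(A, prior_l, prior_f, Kmax, var_type,
                          fixed_loadings, init_l, init_f, tol, max_sweeps,
                          backfit, verbose))
  }

  # Outer loop for the diagonal offset of a symmetric target: fit on
  # A - eps*I, then move eps to the mean diagonal residual.
  if (nrow(A) != ncol(A)) stop("diag_offset requires a square target")
  n <- nrow(A)
  eps <- if (is.null(eps_init)) {
    max(0, mean(diag(A)) - mean(A[row(A) != col(A)]))
  } else {
    eps_init
  }
  model <- NULL
  for (round in seq_len(6)) {
    A_off <- A
    diag(A_off) <- diag(A) - eps
    if (is.null(model)) {
      model <- ebmf_fit_inner(A_off, prior_l, prior_f, Kmax, var_type,
                              fixed_loadings, init_l, init_f, tol,
                              max_sweeps, backfit, verbose)
    } else {
      # warm start: re-backfit the previous model against the new target
      model <- ebmf_backfit(A_off, model, prior_l, prior_f, tol,
                            min(max_sweeps, 100), verbose)
      model <- ebmf_nullcheck(A_off, model)
    }
    fitted_diag <- if (model$K > 0L)
      rowSums(model$EL * model$EF) else rep(0, n)
    eps_new <- max(0, mean(diag(A) - fitted_diag))
    if (abs(eps_new - eps) <= 1e-3 * max(eps, .Machine$double.eps)) {
      eps <- eps_new
      break
    }
    eps <- eps_new
  }
  model$epsilon <- eps
  model
}

ebmf_fit_inner <- function(A, prior_l, prior_f, Kmax, var_type,
                           fixed_loadings, init_l, init_f, tol, max_sweeps,
                           backfit, verbose) {
  n <- nrow(A)
  p <- ncol(A)
  model <- new_ebmf_model(n, p, var_type)

  if (!is.null(fixed_loadings)) {
    L <- as.matrix(fixed_loadings)
    if (nrow(L) != n) stop("fixed loadings have wrong number of rows")
    if (ncol(L) > Kmax) stop("more fixed loadings than Kmax")
    F0 <- if (is.null(init_f)) matrix(0, p, ncol(L)) else as.matrix(init_f)
    for (k in seq_len(ncol(L))) model <- add_factor(model, L[, k], F0[, k])
    model$fixed_loadings <- TRUE
    model$kl_l[] <- 0
    model <- update_tau(A, model)
    model <- ebmf_backfit(A, model, prior_l, prior_f, tol, max_sweeps,
                          verbose)
    return(model)
  }

  if (!is.null(init_l) && !is.null(init_f)) {
    Li <- as.matrix(init_l)
    Fi <- as.matrix(init_f)
    for (k in seq_len(ncol(Li))) model <- add_factor(model, Li[, k], Fi[, k])
    model <- update_tau(A, model)
    model <- ebmf_backfit(A, model, prior_l, prior_f, tol, max_sweeps,
                          verbose)
    return(ebmf_nullcheck(A, model))
  }

  # Greedy stage
  model <- update_tau(A, model)
  for (k_new in seq_len(Kmax)) {
    R <- A - model_fitted_values(model)
    sv <- power_rank1(R)
    model <- add_factor(model, sv$u, sv$v)
    model <- update_tau(A, model)
    model <- refine_factor(A, model, model$K, prior_l, prior_f)
    model <- update_tau(A, model)
    K_before <- model$K
    # during the greedy stage only the newly added factor is examined
    model <- ebmf_nullcheck(A, model, scope = "last")
    if (model$K < K_before) break
  }

  if (backfit) {
    model <- ebmf_backfit(A, model, prior_l, prior_f, tol, max_sweeps,
                          verbose)
    model <- ebmf_nullcheck(A, model)
  }
  model
}

# One cyclic pass over all factors followed by a residual-variance update.
ebmf_sweep <- function(A, model, prior_l, prior_f) {
  for (k in seq_len(model$K)) {
    model <- ebmf_rank1_update(A, model, k, "f", prior_f)
    if (!model$fixed_loadings) {
      model <- ebmf_rank1_update(A, model, k, "l", prior_l)
    }
  }
  update_tau(A, model)
}

# Extrapolate the posterior-mean matrices along the direction of the last
# accepted sweep, preserving the posterior variances; nonnegative families
# are kept on their support by clamping.
extrapolate_state <- function(model, prev, beta) {
  prop <- model
  prop$EL <- model$EL + beta * (model$EL - prev$EL)
  prop$EF <- model$EF + beta * (model$EF - prev$EF)
  prop$EL[sign(prop$EL) != sign(model$EL)] <- 0
  prop$EF[sign(prop$EF) != sign(model$EF)] <- 0
  prop$EL2 <- prop$EL^2 + pmax(model$EL2 - model$EL^2, 0)
  prop$EF2 <- prop$EF^2 + pmax(model$EF2 - model$EF^2, 0)
  prop
}

# Cyclic backfitting of all factors until the ELBO stabilizes.  Sweeps are
# accelerated by momentum extrapolation: a proposal state extrapolated along
# the last step is swept once and accepted only if it improves the ELBO, so
# the recorded trace remains nondecreasing; on rejection the plain
# coordinate-ascent sweep is taken and the momentum is reduced.
ebmf_backfit <- function(A, model, prior_l, prior_f, tol, max_sweeps,
                         verbose = FALSE) {
  if (model$K == 0L) return(model)
  elbo_old <- ebmf_elbo(A, model)
  prev <- NULL
  beta <- 0.5
  for (sweep in seq_len(max_sweeps)) {
    state <- list(EL = model$EL, EF = model$EF)
    accepted <- FALSE
    if (!is.null(prev) && beta > 0.05 && nrow(prev$EL) == nrow(model$EL) &&
        ncol(prev$EL) == ncol(model$EL)) {
      prop <- extrapolate_state(model, prev, beta)
      cand <- ebmf_sweep(A, prop, prior_l, prior_f)
      elbo_cand <- ebmf_elbo(A, cand)
      if (elbo_cand >= elbo_old) {
        model <- cand
        elbo <- elbo_cand
        beta <- min(0.95, beta * 1.1)
        accepted <- TRUE
      } else {
        beta <- beta * 0.5
      }
    }
    if (!accepted) {
      model <- ebmf_sweep(A, model, prior_l, prior_f)
      elbo <- ebmf_elbo(A, model)
    }
    model$elbo_trace <- c(model$elbo_trace, elbo)
    if (verbose) message(sprintf("sweep %d: elbo %.6f", sweep, elbo))
    prev <- state
    if (abs(elbo - elbo_old) <= tol) break
    elbo_old <- elbo
  }
  model
}
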