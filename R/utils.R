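# Internal numerical helpers shared by the EBNM solvers and the EBMF engine.

# Row-wise log(exp(a) + exp(b)) without overflow.
logspace_add <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0) = -Inf
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log Mills-type hazard: log phi(z) - log Phi(-z), stable for large |z|.
log_hazard_upper <- function(z) {
  dnorm(z, log = TRUE) - pnorm(z, lower.tail = FALSE, log.p = TRUE)
}

#' First two moments of a normal distribution truncated to the positive axis
#'
#' For X ~ N(mean, sd^2) conditioned on X > 0, returns E\[X\] and E\[X^2\],
#' computed in log space so that means far below zero (where the truncated
#' distribution collapses onto the boundary) do not produce NaN.
#'
#' @param mean Vector of untruncated means.
#' @param sd Vector of untruncated standard deviations (positive).
#' @return List with elements `m1` and `m2`.
#' @keywords internal
#' @noRd
tnorm_pos_moments <- function(mean, sd) {
  alpha <- -mean / sd
  # h = phi(alpha) / (1 - Phi(alpha)), the hazard of the lower tail cut
  h <- exp(log_hazard_upper(alpha))
  # For alpha -> +Inf, h ~ alpha + 1/alpha; guard against h < alpha which
  # would give negative E[X].
  big <- alpha > 30
  if (any(big)) h[big] <- alpha[big] + 1 / alpha[big]
  m1 <- mean + sd * h
  # E[X^2] = m^2 + 2 m s h + s^2 (1 + alpha h); with s*alpha = -m this
  # simplifies to m^2 + s^2 + m s h.
  m2 <- mean^2 + sd^2 + mean * sd * h
  if (any(big)) {
    # deep in the truncated tail X is approximately Exp(alpha/s)
    m2[big] <- 2 * m1[big]^2
  }
  # numerical floor: E[X^2] >= E[X]^2
  m2 <- pmax(m2, m1^2)
  list(m1 = m1, m2 = m2)
}

# Moments of N(mean, sd^2) truncated to the negative axis, by symmetry.
tnorm_neg_moments <- function(mean, sd) {
  mom <- tnorm_pos_moments(-mean, sd)
  list(m1 = -mom$m1, m2 = mom$m2)
}

# Validate an (x, s) normal-means problem.
check_nm_problem <- function(x, s) {
  if (length(x) == 0L) stop("empty normal-means problem")
  if (length(s) == 1L) s <- rep(s, length(x))
  if (length(s) != length(x)) stop("x and s must have equal length")
  if (!all(is.finite(x))) stop("non-finite observations x")
  if (!all(is.finite(s)) || any(s <= 0)) stop("standard deviations s must be positive and finite")
  s
}
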