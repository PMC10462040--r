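# Empirical Bayes normal-means solvers: closed forms against quadrature
# oracles, EM behavior, and shrinkage properties.

test_that("GB marginal log-likelihood matches its spike/slab limits", {
  set.seed(1)
  x <- rnorm(20, 1, 2)
  s <- runif(20, 0.3, 1.5)
  expect_equal(gb_marginal_loglik(x, s, pi = 0, mu = 3),
               sum(dnorm(x, 0, s, log = TRUE)))
  # pi = 1 with omega -> 0: binary slab at mu
  expect_equal(gb_marginal_loglik(x, s, pi = 1, mu = 3, omega = 1e-12),
               sum(dnorm(x, 3, s, log = TRUE)), tolerance = 1e-6)
  # mu = 0 degenerate slab equals the spike for any pi
  expect_equal(gb_marginal_loglik(x, s, pi = 0.4, mu = 0),
               sum(dnorm(x, 0, s, log = TRUE)))
})

test_that("GB marginal log-likelihood matches adaptive quadrature", {
  set.seed(42)
  for (r in 1:100) {
    n <- 5
    x <- runif(n, -3, 8)
    s <- runif(n, 0.2, 1.5)
    pi <- runif(1, 0.05, 0.95)
    mu <- runif(1, 0.5, 5)
    omega <- runif(1, 0.02, 0.5)
    ll <- gb_marginal_loglik(x, s, pi, mu, omega)
    ll_quad <- gb_marginal_quadrature(x, s, pi, mu, omega)
    expect_equal(ll, ll_quad, tolerance = 1e-8)
  }
})

test_that("GB EM recovers the grid-search maximizer on bimodal data", {
  set.seed(7)
  n <- 400
  s <- 0.1
  omega <- 0.02
  x <- c(rnorm(n / 2, 0, s),
         rnorm(n / 2, 5, sqrt(s^2 + (omega * 5)^2)))
  fit <- ebnm_gb(x, s, omega = omega)

  pi_grid <- seq(0.005, 0.995, length.out = 200)
  mu_grid <- seq(0.05, 10, length.out = 200)
  best <- c(-Inf, NA, NA)
  for (m in mu_grid) {
    lls <- vapply(pi_grid, function(p) gb_marginal_loglik(x, s, p, m, omega),
                  numeric(1))
    j <- which.max(lls)
    if (lls[j] > best[1]) best <- c(lls[j], pi_grid[j], m)
  }
  pi_step <- diff(pi_grid[1:2])
  mu_step <- diff(mu_grid[1:2])
  expect_lt(abs(fit$prior$pi - best[2]), 2 * pi_step)
  expect_lt(abs(fit$prior$mu - best[3]), 2 * mu_step)
  expect_gte(fit$loglik, best[1] - 1e-6)
})

test_that("GB EM marginal log-likelihood is nondecreasing and beats the spike", {
  set.seed(8)
  for (r in 1:5) {
    n <- 100
    theta <- ifelse(runif(n) < 0.4, 2.5, 0)
    s <- runif(n, 0.2, 0.8)
    x <- rnorm(n, theta, s)
    fit <- ebnm_gb(x, s)
    expect_true(all(diff(fit$loglik_trace) > -1e-9))
    expect_gte(fit$loglik, gbcd:::spike_only_loglik(x, s))
  }
})

test_that("GB solver handles all-null data and concentrates for small omega", {
  x <- rep(0, 50)
  fit <- ebnm_gb(x, 1)
  expect_equal(fit$post_mean, rep(0, 50))
  expect_equal(fit$loglik, sum(dnorm(0, 0, rep(1, 50), log = TRUE)))

  # well-separated data, omega -> 0: posterior support approaches {0, mu}
  set.seed(9)
  x <- c(rnorm(100, 0, 0.05), rnorm(100, 3, 0.05))
  for (omega in c(0.1, 0.01, 0.001)) {
    fit <- ebnm_gb(x, 0.05, omega = omega)
    dev <- pmin(abs(fit$post_mean), abs(fit$post_mean - fit$prior$mu))
    if (omega == 0.001) expect_lt(max(dev), 0.01)
  }
})

test_that("point-Laplace posterior matches the quadrature oracle", {
  set.seed(10)
  for (r in 1:20) {
    x <- runif(1, -4, 4)
    s <- runif(1, 0.3, 1.5)
    pi <- runif(1, 0.2, 0.9)
    lambda <- runif(1, 0.5, 3)
    post <- gbcd:::pl_posterior(x, s, pi, lambda)
    w <- 12 * max(s, 1 / lambda)
    oracle <- slab_posterior_quadrature(
      x, s, pi, function(th) lambda / 2 * exp(-lambda * abs(th)),
      min(x, 0) - w, max(x, 0) + w)
    expect_equal(post$mean, oracle, tolerance = 1e-6)
  }
})

test_that("point-Laplace solver is sign-symmetric and sharp in the noiseless limit", {
  set.seed(11)
  x <- rnorm(200, 0, 2) * rbinom(200, 1, 0.5)
  fit_pos <- ebnm_point_laplace(x, 1)
  fit_neg <- ebnm_point_laplace(-x, 1)
  expect_equal(fit_pos$post_mean, -fit_neg$post_mean, tolerance = 1e-4)

  fit_sharp <- ebnm_point_laplace(x, 1e-4)
  expect_equal(fit_sharp$post_mean, x, tolerance = 1e-2)
  expect_gte(fit_pos$loglik, gbcd:::spike_only_loglik(x, rep(1, 200)))
})

test_that("point-exponential posterior matches quadrature and respects support", {
  set.seed(12)
  for (r in 1:20) {
    x <- runif(1, -2, 5)
    s <- runif(1, 0.3, 1.5)
    pi <- runif(1, 0.2, 0.9)
    lambda <- runif(1, 0.5, 3)
    post <- gbcd:::pe_posterior(x, s, pi, lambda)
    w <- 12 * max(s, 1 / lambda)
    oracle <- slab_posterior_quadrature(
      x, s, pi, function(th) lambda * exp(-lambda * th) * (th > 0),
      0, max(x, 0) + w)
    expect_equal(post$mean, oracle, tolerance = 1e-6)
  }

  # strongly negative data: nonnegativity forces posterior means to zero
  fit <- ebnm_point_exponential(rnorm(50, -6, 0.1), 0.1)
  expect_lt(max(abs(fit$post_mean)), 1e-3)

  # strongly positive data: slight shrinkage, all slab probabilities ~ 1
  set.seed(13)
  x <- runif(10, 5, 8)
  fit <- ebnm_point_exponential(x, 0.1)
  expect_true(all(fit$zeta > 0.99))
  expect_true(all(fit$post_mean > x - 0.1) && all(fit$post_mean < x + 0.01))
})

test_that("posterior second moments dominate squared means in every solver", {
  set.seed(14)
  x <- rnorm(100, 1, 1.5)
  s <- runif(100, 0.2, 1)
  for (fit in list(ebnm_gb(x, s), ebnm_point_laplace(x, s),
                   ebnm_point_exponential(x, s), ebnm_normal(x, s))) {
    expect_true(all(fit$post_mean2 >= fit$post_mean^2 - 1e-12))
    expect_true(all(fit$zeta >= 0 & fit$zeta <= 1))
    expect_true(is.finite(fit$loglik))
    expect_gte(fit$loglik, gbcd:::spike_only_loglik(x, s) - 1e-9)
  }
})

test_that("adaptive shrinkage handles null data and the noiseless limit", {
  a0 <- adaptive_shrinkage(rep(0, 100), rep(1, 100))
  expect_equal(a0$post_mean, rep(0, 100))
  expect_true(all(a0$lfsr >= 0.5))

  set.seed(15)
  b <- rnorm(50, 0, 2)
  a1 <- adaptive_shrinkage(b, rep(1e-6, 50))
  expect_equal(a1$post_mean, b, tolerance = 1e-4)
})

test_that("adaptive shrinkage improves the RMSE of mixture-distributed effects", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 2000
    b <- ifelse(runif(n) < 0.7, rnorm(n, 0, 0.1), rnorm(n, 0, 2))
    se <- rep(0.5, n)
    bhat <- rnorm(n, b, se)
    a <- adaptive_shrinkage(bhat, se)
    expect_lt(sqrt(mean((a$post_mean - b)^2)), sqrt(mean((bhat - b)^2)))
    expect_true(all(a$lfsr >= 0 & a$lfsr <= 1))
  }
})
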