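# GBCD pipeline: transform, covariance decomposition on constructed data,
# signature estimation, and LFC statistics.

test_that("log-pc transform preserves zeros, is monotone, and matches direct evaluation", {
  set.seed(1)
  X <- matrix(rpois(200, 3), 20, 10)
  X[1, ] <- c(0, 1, 2, 5, 0, 3, 1, 0, 2, 4)
  lp <- log_pc_transform(X, c = 0.1)
  expect_true(all(lp$Y >= 0))
  expect_equal(lp$Y == 0, X == 0)
  expect_equal(lp$size_factors, rowSums(X))
  # a cell at the median size factor with count 1: y = log(11)
  Xc <- matrix(c(0:10, rep(1, 11)), 11, 2)
  Xc <- rbind(Xc, Xc, Xc)  # all cells share size factor 12? no: rows differ
  X2 <- matrix(1, 5, 11)
  X2[3, 1] <- 1  # all size factors equal -> s_i = s_med
  lp2 <- log_pc_transform(X2, c = 0.1)
  expect_equal(lp2$Y[3, 1], log(11), tolerance = 1e-12)
  # monotone in the count at fixed size factor
  y_row <- log1p((lp$median_size_factor / 0.1) * ((0:10) / 100))
  expect_true(all(diff(y_row) > 0))
  # zero-count cells are rejected by name
  X3 <- X
  X3[4, ] <- 0
  expect_error(log_pc_transform(X3), "4")
  # tpm mode is on the log2 scale and also preserves zeros
  lp_tpm <- log_pc_transform(X, mode = "tpm")
  expect_equal(lp_tpm$log_base, "log2")
  expect_equal(lp_tpm$Y == 0, X == 0)
})

test_that("covariance decomposition recovers two disjoint cell blocks", {
  dat <- two_block_dataset()
  cf <- fit_covariance(dat$Y, Kmax = 6)
  rec <- gep_recovery(dat$L, cf$L)
  expect_true(all(rec > 0.95))
  expect_true(all(cf$L >= 0))
  expect_true(all(apply(cf$L, 2, max) == 1))
  expect_true(all(cf$mirror_corr[cf$kept] > 0.8))
  expect_gte(cf$epsilon, 0)
})

test_that("covariance decomposition is equivariant to row permutation", {
  dat <- two_block_dataset(n_per_block = 40, n_genes = 150, n_de = 20,
                           seed = 21)
  cf1 <- fit_covariance(dat$Y, Kmax = 5)
  perm <- sample(nrow(dat$Y))
  cf2 <- fit_covariance(dat$Y[perm, ], Kmax = 5)
  expect_equal(ncol(cf1$L), ncol(cf2$L))
  # estimated memberships agree up to the row permutation (columns may come
  # out in any order)
  agree <- gep_recovery(cf1$L[perm, , drop = FALSE], cf2$L)
  expect_true(all(agree > 0.999))
})

test_that("signature estimation recovers exact signatures under true memberships", {
  set.seed(3)
  n <- 150; J <- 300
  L <- cbind(rbinom(n, 1, 0.4), rbinom(n, 1, 0.3))
  F_true <- matrix(0, J, 2)
  F_true[1:40, 1] <- rnorm(40, 1.5, 0.3)
  F_true[41:80, 2] <- rnorm(40, -1, 0.3)
  Y <- L %*% t(F_true) + 1  # constant baseline absorbed by the intercept
  cov_fit <- structure(list(L = `colnames<-`(L, c("GEP1", "GEP2"))),
                       class = "cov_fit")
  sf <- estimate_signatures(Y, cov_fit)
  expect_equal(colnames(sf$F), c("baseline", "GEP1", "GEP2"))
  for (k in 1:2) {
    expect_gt(cor(sf$F[, k + 1], F_true[, k]), 0.999)
  }
})

test_that("signature estimation shrinks constant genes and is sign-equivariant", {
  set.seed(4)
  n <- 120; J <- 80
  L <- cbind(rbinom(n, 1, 0.5))
  F_true <- matrix(rnorm(J, 0, 1), J, 1)
  F_true[1:10] <- 0
  Y <- L %*% t(F_true) + matrix(rnorm(n * J, 0, 0.05), n, J)
  Y[, 5] <- 2  # constant gene
  cov_fit <- structure(list(L = `colnames<-`(L, "GEP1")), class = "cov_fit")
  sf <- estimate_signatures(Y, cov_fit)
  expect_lt(abs(sf$F[5, "GEP1"]), 1e-3)
  # flipping the deviations of one gene flips its signature entry
  Y2 <- Y
  j <- 20
  Y2[, j] <- mean(Y[, j]) - (Y[, j] - mean(Y[, j]))
  sf2 <- estimate_signatures(Y2, cov_fit)
  expect_equal(sf2$F[j, "GEP1"], -sf$F[j, "GEP1"], tolerance = 0.05)
})

test_that("rank-deficient memberships are rejected with the collinear components named", {
  set.seed(5)
  L <- cbind(GEP1 = rbinom(50, 1, 0.5))
  L <- cbind(L, GEP2 = L[, 1])
  cov_fit <- structure(list(L = L), class = "cov_fit")
  Y <- matrix(rnorm(50 * 30), 50, 30)
  expect_error(estimate_signatures(Y, cov_fit), "collinear")
  expect_error(lfc_statistics(Y, cov_fit), "collinear")
})

test_that("LFC statistics match the least-squares oracle and shrinkage helps", {
  set.seed(6)
  n <- 500; J <- 400
  L <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.3))
  B <- matrix(0, J, 2)
  B[1:60, 1] <- rnorm(60, 0.8, 0.2)
  B[61:120, 2] <- rnorm(60, 0.8, 0.2)
  Y <- 1.5 + L %*% t(B) + matrix(rnorm(n * J, 0, 0.1), n, J)
  cov_fit <- structure(list(L = `colnames<-`(L, c("GEP1", "GEP2"))),
                       class = "cov_fit")
  st <- lfc_statistics(Y, cov_fit)

  # normal-equations oracle, gene by gene
  X <- cbind(1, L)
  XtXinv <- solve(crossprod(X))
  for (j in c(1, 30, 200)) {
    beta <- drop(XtXinv %*% crossprod(X, Y[, j]))
    expect_equal(unname(st$fhat[j, ]), beta[2:3], tolerance = 1e-10)
    resid <- Y[, j] - X %*% beta
    s2 <- sum(resid^2) / (n - 3)
    expect_equal(unname(st$se[j, ]),
                 sqrt(diag(XtXinv)[2:3] * s2), tolerance = 1e-10)
  }
  # shrinkage cannot hurt overall accuracy
  expect_lte(sqrt(mean((st$post_mean - B)^2)),
             sqrt(mean((st$fhat - B)^2)) + 1e-8)
  # z-scores are posterior mean over posterior sd wherever defined
  idx <- st$post_sd > 0
  expect_equal(st$z[idx], (st$post_mean / st$post_sd)[idx])
  expect_true(all(st$lfsr >= 0 & st$lfsr <= 1))
})

test_that("LFC statistics on constant expression are all null", {
  n <- 80
  L <- cbind(GEP1 = rbinom(n, 1, 0.5))
  Y <- matrix(3, n, 20)
  cov_fit <- structure(list(L = L), class = "cov_fit")
  st <- lfc_statistics(Y, cov_fit)
  expect_true(all(abs(st$fhat) < 1e-12))
  # no spurious signal: z negligible, sign uncertainty maximal
  expect_lt(max(abs(st$z)), 0.01)
  expect_true(all(st$lfsr >= 0.5))
})

test_that("the pipeline runs end to end deterministically on a small simulated dataset", {
  cfg <- sim_gep_config(n_patients = 2, cells_per_patient = 60,
                        n_genes = 300, n_continuous_cells = 20,
                        de_genes_range = c(10, 25), seed = 5)
  truth <- suppressWarnings(sim_gep_membership(cfg, 31))
  truth <- sim_gep_signatures(cfg, truth, 32)
  counts <- sim_gep_counts(truth, rng_seed = 33)
  fit1 <- run_gbcd(counts$X, Kmax = 8, L_true = truth$L_true)
  expect_s3_class(fit1, "gbcd_fit")
  expect_true(all(c("transform", "cov_fit", "sig_fit", "lfc", "recovery")
                  %in% names(fit1)))
  expect_equal(nrow(fit1$sig_fit$F), 300)
  # deterministic: an identical rerun gives bitwise-identical memberships
  fit2 <- run_gbcd(counts$X, Kmax = 8, L_true = truth$L_true)
  expect_identical(fit1$cov_fit$L, fit2$cov_fit$L)
  # errors are tagged with the failing stage
  expect_error(run_gbcd(counts$X * 0, Kmax = 8), "transform")
})

test_that("count matrices round-trip through MatrixMarket and fits serialize", {
  set.seed(7)
  X <- matrix(rpois(600, 1), 30, 20)
  d <- tempfile()
  write_counts_mtx(X, d)
  X2 <- read_counts_mtx(d)
  expect_equal(unname(X2), X, ignore_attr = TRUE)
  expect_equal(dim(X2), dim(X))
})
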