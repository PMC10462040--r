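# Shared fixtures for the test suite.  All data are generated in code under
# fixed seeds; sizes are kept small so the full suite runs quickly.

# Reduced multi-patient simulation: 8 patients x 100 cells, 2,000 genes,
# GEP structure (8 patient + 2 subtype + 1 continuous).  The DE-gene range
# keeps the full design's lower bound (75 genes per GEP) but caps the upper
# bound so that 11 disjoint DE sets remain feasible within 2,000 genes.
reduced_sim_config <- function(seed = 1) {
  sim_gep_config(n_patients = 8, cells_per_patient = 100, n_genes = 2000,
                 n_continuous_cells = 150, de_genes_range = c(75, 180),
                 seed = seed)
}

reduced_sim_dataset <- function(seed = 1) {
  cfg <- reduced_sim_config(seed)
  truth <- sim_gep_membership(cfg, seed + 100L)
  truth <- sim_gep_signatures(cfg, truth, seed + 200L)
  counts <- sim_gep_counts(truth, rng_seed = seed + 300L)
  list(config = cfg, truth = truth, counts = counts)
}

# Small two-block expression matrix with known block memberships: two
# disjoint groups of cells over-express disjoint gene sets on top of a
# gene-specific baseline.
two_block_dataset <- function(n_per_block = 100, n_genes = 500,
                              n_de = 40, noise_sd = 0.3, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_block
  block <- rep(c(1, 2), each = n_per_block)
  L <- cbind(as.numeric(block == 1), as.numeric(block == 2))
  F_true <- matrix(0, n_genes, 2)
  F_true[seq_len(n_de), 1] <- runif(n_de, 1, 2)
  F_true[n_de + seq_len(n_de), 2] <- runif(n_de, 1, 2)
  baseline <- matrix(rep(runif(n_genes, 0.5, 2), each = n), n, n_genes)
  Y <- baseline + L %*% t(F_true) +
    matrix(rnorm(n * n_genes, 0, noise_sd), n, n_genes)
  list(Y = Y, L = L, F_true = F_true)
}

# Quadrature oracle for the GB-prior marginal likelihood of one observation:
# integrates the truncated-normal slab numerically over a window wide enough
# to cover both the prior and the likelihood mass.
gb_marginal_quadrature <- function(x, s, pi, mu, omega) {
  sigma <- omega * mu
  sum(vapply(seq_along(x), function(i) {
    w <- 12 * max(sigma, s[i])
    lo <- max(0, min(mu, x[i]) - w)
    hi <- max(mu, x[i]) + w
    slab <- integrate(function(th)
      dnorm(x[i], th, s[i]) * dnorm(th, mu, sigma) / pnorm(mu / sigma),
      lo, hi, rel.tol = 1e-13, abs.tol = 0)$value
    log((1 - pi) * dnorm(x[i], 0, s[i]) + pi * slab)
  }, numeric(1)))
}

# Quadrature oracle for posterior means under fixed spike-slab priors.
slab_posterior_quadrature <- function(x, s, pi, slab_density, lower, upper) {
  Z_slab <- integrate(function(th) dnorm(x, th, s) * slab_density(th),
                      lower, upper, rel.tol = 1e-12, abs.tol = 0)$value
  M_slab <- integrate(function(th) th * dnorm(x, th, s) * slab_density(th),
                      lower, upper, rel.tol = 1e-12, abs.tol = 0)$value
  Z <- (1 - pi) * dnorm(x, 0, s) + pi * Z_slab
  pi * M_slab / Z
}
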