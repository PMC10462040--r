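# Simulation of multi-patient scRNA-seq counts with known GEP structure.
#
# The generator first draws a "null" count matrix X_null with Poisson counts
# whose rates are the product of a per-cell size factor and a gene-specific
# baseline (relative expression alpha), then imposes differential-expression
# structure by binomial thinning: counts are binomially subsampled with
# gene/cell-specific keep probabilities so that the thinned counts have
# expectation proportional to exp(log(alpha_tilde_j) + [L F^T]_ij).
# Thinning can only reduce counts, and the implied new baseline alpha_tilde
# is recorded.

#' Configuration of the multi-patient GEP simulation
#'
#' The defaults describe a population of 8 patients with 400 cells each
#' (N = 3,200 cells) measured on 10,000 genes, structured by K = 11 gene
#' expression programs: one binary patient-specific GEP per patient, two
#' binary subtype GEPs (patients 1-4 and 5-8), and one continuous GEP
#' expressed in 600 randomly chosen cells with membership values drawn from
#' Unif(0.4, 2).  Each GEP up-regulates a disjoint set of genes (count drawn
#' uniformly from `de_genes_range`) with fold changes averaging
#' `fold_change_mean` within `fold_change_range`.
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Cells per patient.
#' @param n_genes Number of genes.
#' @param n_continuous_cells Cells expressing the continuous GEP.
#' @param continuous_membership_range Range (low, high) of nonzero continuous
#'   memberships.
#' @param de_genes_range Integer range (min, max) of differentially expressed
#'   genes per GEP.
#' @param fold_change_mean Average fold change of DE genes.
#' @param fold_change_range Range (low, high) of fold changes.
#' @param n_replicates Number of replicate datasets in a batch.
#' @param seed Master seed.
#' @return A list of class `gep_sim_config`.
#' @export
sim_gep_config <- function(n_patients = 8, cells_per_patient = 400,
                           n_genes = 10000, n_continuous_cells = 600,
                           continuous_membership_range = c(0.4, 2),
                           de_genes_range = c(75, 500),
                           fold_change_mean = 3,
                           fold_change_range = c(1.5, 11),
                           n_replicates = 20, seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes),
              n_continuous_cells = as.integer(n_continuous_cells),
              continuous_membership_range = continuous_membership_range,
              de_genes_range = as.integer(de_genes_range),
              fold_change_mean = fold_change_mean,
              fold_change_range = fold_change_range,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "gep_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1 || cells_per_patient < 1 || n_genes < 1)
      stop("invalid simulation config: counts must be positive")
    if (n_continuous_cells > n_patients * cells_per_patient)
      stop("invalid simulation config: n_continuous_cells exceeds the total number of cells")
    if (n_continuous_cells < 0)
      stop("invalid simulation config: negative n_continuous_cells")
    if (de_genes_range[1] > de_genes_range[2] || de_genes_range[1] < 1)
      stop("invalid simulation config: bad de_genes_range")
    if (fold_change_range[1] <= 0 ||
        fold_change_range[1] > fold_change_mean ||
        fold_change_mean > fold_change_range[2])
      stop("invalid simulation config: need 0 < fc_low <= fc_mean <= fc_high")
    if (continuous_membership_range[1] <= 0 ||
        continuous_membership_range[1] > continuous_membership_range[2])
      stop("invalid simulation config: bad continuous_membership_range")
  })
  invisible(cfg)
}

#' Ground-truth GEP memberships
#'
#' Builds the cells-by-K membership matrix: binary block-diagonal
#' patient-specific columns, two binary subtype columns covering the first
#' and second halves of the patients, and one continuous column whose
#' nonzero entries (in `n_continuous_cells` cells chosen independently of
#' patient identity) are drawn uniformly from the configured range.
#' Duplicate columns arising from degenerate configurations (e.g. a single
#' patient, where a subtype column equals the patient column) are dropped
#' with a warning.
#'
#' @param config A [sim_gep_config()] object.
#' @param rng_seed Seed for this draw.
#' @return A list of class `gep_truth` with elements `L_true` (cells x K),
#'   `gep_labels` (per-column: patient / subtype / continuous), `patient`
#'   (per-cell patient labels), and `K`.
#' @export
sim_gep_membership <- function(config, rng_seed = config$seed) {
  validate_sim_config(config)
  set.seed(rng_seed)
  n_pat <- config$n_patients
  n_cells <- n_pat * config$cells_per_patient
  patient <- rep(seq_len(n_pat), each = config$cells_per_patient)

  L_pat <- matrix(0, n_cells, n_pat)
  L_pat[cbind(seq_len(n_cells), patient)] <- 1
  colnames(L_pat) <- paste0("P", seq_len(n_pat))

  half <- ceiling(n_pat / 2)
  L_sub <- cbind(S1 = as.numeric(patient <= half),
                 S2 = as.numeric(patient > half))

  cont <- numeric(n_cells)
  if (config$n_continuous_cells > 0) {
    idx <- sample.int(n_cells, config$n_continuous_cells)
    cont[idx] <- runif(config$n_continuous_cells,
                       config$continuous_membership_range[1],
                       config$continuous_membership_range[2])
  }

  L <- cbind(L_pat, L_sub, C1 = cont)
  labels <- c(rep("patient", n_pat), rep("subtype", 2), "continuous")

  # drop duplicate or empty columns from degenerate configurations
  keep <- rep(TRUE, ncol(L))
  for (k in seq_len(ncol(L))) {
    if (!keep[k]) next
    if (all(L[, k] == 0)) {
      keep[k] <- FALSE
      next
    }
    for (k2 in seq_len(k - 1L)) {
      if (keep[k2] && all(L[, k] == L[, k2])) {
        keep[k] <- FALSE
        break
      }
    }
  }
  if (!all(keep)) {
    warning("degenerate configuration: dropping ",
            sum(!keep), " duplicate or empty GEP column(s)")
    L <- L[, keep, drop = FALSE]
    labels <- labels[keep]
  }

  structure(list(L_true = L, gep_labels = labels, patient = patient,
                 K = ncol(L)),
            class = "gep_truth")
}

# Solve for the location parameter of a shifted, upper-truncated log-normal
# fold-change distribution FC = low + T, T ~ LN(m, sdlog) truncated at
# (high - low), such that E[FC] = target mean.
fc_lognormal_location <- function(fc_mean, fc_range, sdlog = 0.8) {
  low <- fc_range[1]
  u <- fc_range[2] - low
  target <- fc_mean - low
  if (u <= 0 || target <= 0) return(NULL)  # point mass handled by caller
  trunc_mean <- function(m) {
    exp(m + sdlog^2 / 2) *
      pnorm((log(u) - m - sdlog^2) / sdlog) / pnorm((log(u) - m) / sdlog) -
      target
  }
  uniroot(trunc_mean, c(log(target) - 8, log(u) + 8), tol = 1e-12)$root
}

# Draw n fold changes with mean fc_mean on [low, high].
draw_fold_changes <- function(n, fc_mean, fc_range, sdlog = 0.8) {
  low <- fc_range[1]
  u <- fc_range[2] - low
  if (u <= 1e-12) return(rep(low, n))
  m <- fc_lognormal_location(fc_mean, fc_range, sdlog)
  # inverse-CDF sampling from the truncated log-normal
  pu <- plnorm(u, m, sdlog)
  low + qlnorm(runif(n) * pu, m, sdlog)
}

#' Ground-truth GEP signatures
#'
#' For each GEP draws a differential-expression gene count uniformly from
#' `de_genes_range`, assigns disjoint gene sets across GEPs, and draws
#' per-gene fold changes from a shifted truncated log-normal calibrated so
#' the mean fold change equals `fold_change_mean` on `fold_change_range`.
#' Signature entries are natural-log fold changes (nonnegative; zero for
#' non-DE genes).
#'
#' @param config A [sim_gep_config()] object.
#' @param truth A `gep_truth` from [sim_gep_membership()].
#' @param rng_seed Seed for this draw.
#' @return The input `truth` augmented with `F_true` (genes x K) and
#'   `de_gene_sets` (list of disjoint gene index vectors).
#' @export
sim_gep_signatures <- function(config, truth, rng_seed = config$seed + 1L) {
  validate_sim_config(config)
  set.seed(rng_seed)
  K <- truth$K
  J <- config$n_genes
  if (K * config$de_genes_range[2] > J)
    stop("invalid simulation config: disjoint DE sets infeasible (K * max DE genes > n_genes)")
  n_de <- sample(seq(config$de_genes_range[1], config$de_genes_range[2]),
                 K, replace = TRUE)
  pool <- sample.int(J, sum(n_de))
  splits <- rep(seq_len(K), n_de)
  de_sets <- split(pool, splits)
  names(de_sets) <- colnames(truth$L_true)
  F_true <- matrix(0, J, K, dimnames = list(NULL, colnames(truth$L_true)))
  for (k in seq_len(K)) {
    fc <- draw_fold_changes(n_de[k], config$fold_change_mean,
                            config$fold_change_range)
    F_true[de_sets[[k]], k] <- log(fc)
  }
  truth$F_true <- F_true
  truth$de_gene_sets <- de_sets
  truth
}

#' Simulate UMI counts with the configured GEP structure
#'
#' Draws the null counts \eqn{x^{null}_{ij} \sim Pois(s_i \theta_{ij})} with
#' \eqn{\Theta = 1_N \alpha^T} (gene baselines alpha from a gamma model of
#' relative expression, size factors s_i log-normal), then binomially thins
#' them with keep probabilities \eqn{p_{ij} = \exp([LF^T]_{ij} - M_j)},
#' \eqn{M_j = \max_i [LF^T]_{ij}}, so that thinned counts have expectation
#' proportional to \eqn{\exp(\log\tilde\alpha_j + [LF^T]_{ij})} with the
#' re-normalized baseline \eqn{\tilde\alpha_j = \alpha_j e^{-M_j}}.
#'
#' @param truth A `gep_truth` with `L_true` and `F_true`.
#' @param baseline Optional list overriding baseline parameters:
#'   `alpha_shape` (gamma shape of relative expression, default 0.6),
#'   `lib_size` (expected library size, default 1e4), `size_factor_sdlog`
#'   (log-normal SD of size factors, default 0.5), `size_factor_exponent`
#'   (power applied to s_i in the Poisson rate, default 1).
#' @param rng_seed Seed for this draw.
#' @return A list of class `gep_counts` with integer matrix `X` (cells x
#'   genes), the unthinned `X_null`, `alpha`, `alpha_tilde`, `size_factors`,
#'   and per-cell `patient` labels.
#' @export
sim_gep_counts <- function(truth, baseline = list(), rng_seed = 1) {
  stopifnot(inherits(truth, "gep_truth"), !is.null(truth$F_true))
  set.seed(rng_seed)
  base <- utils::modifyList(list(alpha_shape = 0.6, lib_size = 1e4,
                                 size_factor_sdlog = 0.5,
                                 size_factor_exponent = 1),
                            baseline)
  n <- nrow(truth$L_true)
  J <- nrow(truth$F_true)

  alpha <- rgamma(J, shape = base$alpha_shape, rate = 1)
  alpha <- pmax(alpha, 1e-12)
  alpha <- alpha / sum(alpha)
  sf <- rlnorm(n, 0, base$size_factor_sdlog)
  rate_cell <- sf^base$size_factor_exponent * base$lib_size

  X <- matrix(rpois(n * J, outer(rate_cell, alpha)), n, J)
  X_null <- X

  # binomial thinning, restricted to the DE genes of each GEP (keep
  # probability is 1 elsewhere)
  M <- numeric(J)
  for (k in seq_len(truth$K)) {
    genes <- truth$de_gene_sets[[k]]
    if (length(genes) == 0) next
    lf <- outer(truth$L_true[, k], truth$F_true[genes, k])  # n x |genes|
    Mk <- apply(lf, 2, max)
    M[genes] <- Mk
    keep_p <- exp(sweep(lf, 2, Mk, `-`))
    block <- X[, genes, drop = FALSE]
    thinned <- rbinom(length(block), size = as.integer(block), prob = keep_p)
    X[, genes] <- matrix(thinned, nrow = n)
  }
  alpha_tilde <- alpha * exp(-M)

  structure(list(X = X, X_null = X_null, alpha = alpha,
                 alpha_tilde = alpha_tilde, size_factors = sf,
                 patient = truth$patient),
            class = "gep_counts")
}

#' Best-correlation recovery of true GEP memberships
#'
#' For each column of the true membership matrix, the highest Pearson
#' correlation with any column of the estimated membership matrix.  Constant
#' estimated columns contribute correlation 0 by convention; constant true
#' columns are an error.
#'
#' @param L_true Cells x K_true membership matrix (non-constant columns).
#' @param L_est Cells x K_est estimated membership matrix (>= 1 column).
#' @return Named numeric vector of length K_true.
#' @export
gep_recovery <- function(L_true, L_est) {
  L_true <- as.matrix(L_true)
  L_est <- as.matrix(L_est)
  if (nrow(L_true) != nrow(L_est))
    stop("membership matrices must have the same number of rows")
  if (ncol(L_est) < 1) stop("L_est must have at least one column")
  sd_true <- apply(L_true, 2, sd)
  if (any(sd_true == 0))
    stop("true membership matrix has a constant column")
  sd_est <- apply(L_est, 2, sd)
  scores <- vapply(seq_len(ncol(L_true)), function(k) {
    cors <- vapply(seq_len(ncol(L_est)), function(j) {
      if (sd_est[j] == 0) 0 else cor(L_true[, k], L_est[, j])
    }, numeric(1))
    max(cors)
  }, numeric(1))
  names(scores) <- colnames(L_true)
  scores
}
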