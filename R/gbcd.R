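# The GBCD pipeline: transform counts to log-pc expression, decompose the
# cell-by-cell Gram matrix YY^T under generalized-binary priors to estimate
# GEP memberships, estimate GEP signatures by semi-nonnegative EBMF with the
# memberships fixed, and quantify per-gene uncertainty of the log-fold
# changes by gene-wise regression plus adaptive shrinkage.

#' Log pseudo-count transform of a count matrix
#'
#' UMI mode: with size factors \eqn{s_i} (row sums) and their median
#' \eqn{\tilde s}, computes \eqn{y_{ij} = \log(c + \tilde s/s_i \, x_{ij}) -
#' \log c} (natural log), which is nonnegative and preserves zeros exactly.
#' TPM mode: \eqn{y_{ij} = \log_2(1 + TPM_{ij}/10)}, the equivalent transform
#' with pseudo-count \eqn{c = \tilde s/10^5} on a log2 scale.
#'
#' @param X Cells x genes matrix of nonnegative counts (dense or sparse).
#' @param c Pseudo-count (positive); default 0.1.
#' @param mode `"umi"` or `"tpm"`.
#' @return A list of class `log_pc_matrix` with the transformed matrix `Y`,
#'   `size_factors`, `median_size_factor`, `pseudo_count`, and `log_base`
#'   (`"natural"` or `"log2"`).
#' @export
log_pc_transform <- function(X, c = 0.1, mode = c("umi", "tpm")) {
  mode <- match.arg(mode)
  if (c <= 0) stop("pseudo-count c must be positive")
  X <- as.matrix(X)
  if (any(X < 0)) stop("counts must be nonnegative")
  s <- rowSums(X)
  zero_cells <- which(s == 0)
  if (length(zero_cells) > 0) {
    stop("cell(s) with zero total count: ",
         paste(head(zero_cells, 5), collapse = ", "))
  }
  s_med <- median(s)
  if (mode == "umi") {
    Y <- log1p((s_med / c) * (X / s))
    log_base <- "natural"
    pseudo <- c
  } else {
    tpm <- 1e6 * X / s
    Y <- log2(1 + tpm / 10)
    log_base <- "log2"
    pseudo <- s_med / 1e5
  }
  structure(list(Y = Y, size_factors = s, median_size_factor = s_med,
                 pseudo_count = pseudo, log_base = log_base),
            class = "log_pc_matrix")
}

as_log_pc <- function(Y) {
  if (inherits(Y, "log_pc_matrix")) return(Y)
  structure(list(Y = as.matrix(Y), size_factors = NULL,
                 median_size_factor = NULL, pseudo_count = NULL,
                 log_base = "natural"),
            class = "log_pc_matrix")
}

# Split a signed matrix into concatenated nonnegative positive/negative
# parts, dropping all-zero columns.
split_nonneg <- function(M) {
  out <- cbind(pmax(M, 0), pmax(-M, 0))
  keep <- colSums(out) > 0
  out[, keep, drop = FALSE]
}

#' Fit the generalized binary covariance decomposition
#'
#' Decomposes the cell-by-cell Gram matrix \eqn{YY^T \approx L\tilde L^T +
#' \epsilon I + E}.  The fit is initialized by an EBMF fit with point-Laplace
#' priors on both sides; each side's posterior mean is then split into
#' concatenated positive and negative parts (doubling the candidate
#' components), and the decomposition is refitted with generalized-binary
#' priors (fixed coefficient of variation `omega`) on both \eqn{L} and
#' \eqn{\tilde L}, with the diagonal offset \eqn{\epsilon} re-estimated in an
#' outer loop.  Components whose two sides have Pearson correlation at or
#' below `corr_threshold` are dropped; the exported membership columns are
#' rescaled to maximum 1 with the scale recorded.
#'
#' @param Y A `log_pc_matrix` (or plain matrix of transformed expression).
#' @param Kmax Upper bound on the number of components in the initial fit
#'   (>= 2, to leave room for the baseline component).
#' @param omega Generalized-binary coefficient of variation; default 0.02.
#' @param corr_threshold Mirror-correlation filter; default 0.8.
#' @param center Center columns of `Y` before forming the Gram matrix
#'   (default `FALSE`).
#' @param prior Membership prior family for the refit: `"generalized_binary"`
#'   (default) or `"point_exponential"` (the generic-sparsity variant).
#' @param verbose Print fitting progress.
#' @return A list of class `cov_fit`: membership matrix `L` (kept components,
#'   columns scaled to max 1), the relaxed mirror `L_tilde`, `mirror_corr`
#'   and `kept` for all fitted components, diagonal offset `epsilon`,
#'   per-component GB priors `gb_priors`, column scalings `scaling`, and the
#'   underlying engine fit.
#' @export
fit_covariance <- function(Y, Kmax, omega = 0.02, corr_threshold = 0.8,
                           center = FALSE, prior = c("generalized_binary",
                                                     "point_exponential"),
                           verbose = FALSE) {
  prior <- match.arg(prior)
  lp <- as_log_pc(Y)
  Ymat <- lp$Y
  if (Kmax < 2) stop("Kmax must be at least 2")
  if (nrow(Ymat) < 2) stop("need at least 2 cells")
  if (center) Ymat <- scale(Ymat, center = TRUE, scale = FALSE)
  G <- tcrossprod(Ymat)

  pl <- prior_spec("point_laplace")
  init_fit <- ebmf_fit(G, pl, pl, Kmax = Kmax, diag_offset = TRUE,
                       verbose = verbose)
  if (init_fit$K == 0L)
    stop("initialization found no components; increase Kmax")

  L0 <- split_nonneg(init_fit$EL)
  Lt0 <- split_nonneg(init_fit$EF)
  # sides must have matching column counts for initialization
  K0 <- max(ncol(L0), ncol(Lt0))
  pad <- function(M, K) {
    if (ncol(M) < K) cbind(M, matrix(0, nrow(M), K - ncol(M))) else M
  }
  # avoid all-zero initial columns on either side: use the mirror side's
  # split where a side is missing a column
  L0 <- pad(L0, K0); Lt0 <- pad(Lt0, K0)
  zero_l <- colSums(L0) == 0
  zero_t <- colSums(Lt0) == 0
  L0[, zero_l] <- Lt0[, zero_l]
  Lt0[, zero_t] <- L0[, zero_t]

  memb_prior <- prior_spec(prior, omega = omega)
  fit <- ebmf_fit(G, memb_prior, memb_prior, Kmax = ncol(L0),
                  init_l = L0, init_f = Lt0, diag_offset = TRUE,
                  eps_init = init_fit$epsilon, verbose = verbose)
  if (fit$K == 0L)
    stop("all components pruned; increase Kmax")

  L <- fit$EL
  Lt <- fit$EF
  mirror <- vapply(seq_len(fit$K), function(k) {
    if (sd(L[, k]) == 0 || sd(Lt[, k]) == 0) return(0)
    cor(L[, k], Lt[, k])
  }, numeric(1))
  kept <- mirror > corr_threshold
  if (!any(kept))
    stop("all components filtered by the mirror-correlation threshold; ",
         "increase Kmax")

  Lk <- L[, kept, drop = FALSE]
  scaling <- apply(Lk, 2, max)
  Lk <- sweep(Lk, 2, scaling, `/`)
  colnames(Lk) <- paste0("GEP", seq_len(ncol(Lk)))

  structure(list(L = Lk, L_tilde = Lt[, kept, drop = FALSE],
                 mirror_corr = mirror, kept = kept,
                 epsilon = fit$epsilon,
                 gb_priors = fit$priors_l,
                 scaling = scaling,
                 engine_fit = fit),
            class = "cov_fit")
}

# Membership design matrix used for signature estimation and the gene-wise
# regressions: kept (rescaled) components plus an all-ones baseline column.
membership_design <- function(cov_fit) {
  L <- cov_fit$L
  X <- cbind(baseline = 1, L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("membership matrix is rank deficient; collinear components: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Unconstrained empirical Bayes semi-nonnegative matrix factorization
#'
#' Fits \eqn{Y = LF^T + \tilde E} directly (no orthogonality via the Gram
#' matrix, which is the key difference from [fit_covariance()]), with a
#' nonnegative prior on the memberships \eqn{L} (point-exponential by
#' default, or generalized binary) and point-Laplace priors on the
#' signatures, per-gene residual variances.  Initialized from a
#' point-Laplace fit on both sides whose memberships are split into positive
#' and negative parts.  Serves as the comparison factorization whose
#' subtype-GEP recovery the covariance decomposition is expected to beat on
#' simulated multi-patient data.
#'
#' @param Y A `log_pc_matrix` or matrix of transformed expression.
#' @param Kmax Upper bound on the number of components of the initial fit.
#' @param prior Membership prior: `"point_exponential"` (default) or
#'   `"generalized_binary"`.
#' @param omega GB coefficient of variation (used only for the GB prior).
#' @param verbose Print fitting progress.
#' @return A list of class `snmf_fit` with membership matrix `L` (columns
#'   rescaled to max 1), signatures `F`, and the engine fit.
#' @export
fit_ebsnmf <- function(Y, Kmax, prior = c("point_exponential",
                                          "generalized_binary"),
                       omega = 0.02, verbose = FALSE) {
  prior <- match.arg(prior)
  lp <- as_log_pc(Y)
  Ymat <- lp$Y
  pl <- prior_spec("point_laplace")
  init_fit <- ebmf_fit(Ymat, pl, pl, Kmax = Kmax, var_type = "by_column",
                       verbose = verbose)
  if (init_fit$K == 0L) stop("initialization found no components")
  L0 <- cbind(pmax(init_fit$EL, 0), pmax(-init_fit$EL, 0))
  F0 <- cbind(init_fit$EF, -init_fit$EF)
  keep0 <- colSums(L0) > 0
  L0 <- L0[, keep0, drop = FALSE]
  F0 <- F0[, keep0, drop = FALSE]
  memb_prior <- prior_spec(prior, omega = omega)
  fit <- ebmf_fit(Ymat, memb_prior, pl, Kmax = ncol(L0),
                  init_l = L0, init_f = F0, var_type = "by_column",
                  verbose = verbose)
  if (fit$K == 0L) stop("all components pruned")
  L <- fit$EL
  scaling <- apply(L, 2, max)
  scaling[scaling == 0] <- 1
  L <- sweep(L, 2, scaling, `/`)
  colnames(L) <- paste0("GEP", seq_len(ncol(L)))
  structure(list(L = L, F = fit$EF, scaling = scaling, engine_fit = fit),
            class = "snmf_fit")
}

#' Estimate GEP signatures by semi-nonnegative EBMF with fixed memberships
#'
#' Fits \eqn{Y = LF^T + \tilde E} with \eqn{L} held at the kept, rescaled
#' membership estimates (plus an all-ones baseline column absorbing
#' gene-specific mean expression), point-Laplace priors on each signature
#' column, and per-gene residual variances.  \eqn{F} is initialized from the
#' least-squares solve \eqn{(L^TL)^{-1}L^TY}; no orthogonality is enforced.
#'
#' @param Y A `log_pc_matrix` or matrix of transformed expression.
#' @param cov_fit A `cov_fit` from [fit_covariance()].
#' @return A list of class `sig_fit` with signature matrix `F` (genes x
#'   kept components; the baseline column is retained under name
#'   `"baseline"`), point-Laplace priors `pl_priors`, per-gene residual
#'   variances `resid_var_genes`, and the engine fit.
#' @export
estimate_signatures <- function(Y, cov_fit) {
  lp <- as_log_pc(Y)
  Ymat <- lp$Y
  L <- membership_design(cov_fit)
  if (nrow(Ymat) != nrow(L))
    stop("Y and membership matrix have different numbers of cells")
  F_init <- t(solve(crossprod(L), crossprod(L, Ymat)))
  pl <- prior_spec("point_laplace")
  fit <- ebmf_fit(Ymat, pl, pl, Kmax = ncol(L), fixed_loadings = L,
                  init_f = F_init, var_type = "by_column")
  Fhat <- fit$EF
  colnames(Fhat) <- colnames(L)
  structure(list(F = Fhat, pl_priors = fit$priors_f,
                 resid_var_genes = 1 / fit$tau,
                 log_base = lp$log_base,
                 engine_fit = fit),
            class = "sig_fit")
}

#' Log-fold-change statistics with uncertainty
#'
#' For each gene, fits an ordinary least-squares regression of its log-pc
#' expression on the membership matrix (baseline column included), extracts
#' coefficient estimates and standard errors, then applies adaptive
#' shrinkage separately per GEP across genes.  Reports shrunken posterior
#' means and SDs, posterior z-scores (posterior mean / posterior SD) and
#' local false sign rates.
#'
#' @param Y A `log_pc_matrix` or matrix of transformed expression.
#' @param cov_fit A `cov_fit` from [fit_covariance()].
#' @return A list of class `lfc_stats` with genes x GEP matrices `fhat`,
#'   `se`, `post_mean`, `post_sd`, `z`, `lfsr` (baseline column excluded)
#'   and the transform's `log_base`.
#' @export
lfc_statistics <- function(Y, cov_fit) {
  lp <- as_log_pc(Y)
  Ymat <- lp$Y
  X <- membership_design(cov_fit)
  n <- nrow(Ymat)
  K <- ncol(X)
  if (n <= K + 1) stop("not enough cells for residual degrees of freedom")

  qrX <- qr(X)
  coefs <- qr.coef(qrX, Ymat)              # K x J
  resid <- qr.resid(qrX, Ymat)
  df <- n - K
  sigma2 <- colSums(resid^2) / df          # per-gene residual variance
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))
  se <- sqrt(outer(XtXinv_diag, sigma2))   # K x J

  keep <- which(colnames(X) != "baseline")
  gep_names <- colnames(X)[keep]
  J <- ncol(Ymat)
  fhat <- t(coefs[keep, , drop = FALSE])
  sehat <- t(se[keep, , drop = FALSE])
  colnames(fhat) <- colnames(sehat) <- gep_names

  post_mean <- post_sd <- zmat <- lfsr <- matrix(
    0, J, length(keep), dimnames = list(NULL, gep_names))
  for (k in seq_along(keep)) {
    a <- adaptive_shrinkage(fhat[, k], pmax(sehat[, k], 1e-12))
    post_mean[, k] <- a$post_mean
    post_sd[, k] <- a$post_sd
    zmat[, k] <- ifelse(a$post_sd > 0, a$post_mean / a$post_sd, 0)
    lfsr[, k] <- a$lfsr
  }

  structure(list(fhat = fhat, se = sehat, post_mean = post_mean,
                 post_sd = post_sd, z = zmat, lfsr = lfsr,
                 log_base = lp$log_base),
            class = "lfc_stats")
}

#' Run the full GBCD pipeline on a count matrix
#'
#' Transform, covariance decomposition, signature estimation, and LFC
#' uncertainty quantification, with all stages deterministic given the
#' inputs.
#'
#' @param X Cells x genes count matrix.
#' @param Kmax Component bound for [fit_covariance()].
#' @param pseudo_count Pseudo-count of the transform.
#' @param mode Transform mode (`"umi"` or `"tpm"`).
#' @param omega,corr_threshold,center,prior Passed to [fit_covariance()].
#' @param L_true Optional true membership matrix; when given, a
#'   best-correlation recovery report is included.
#' @param verbose Print stage progress.
#' @return A list of class `gbcd_fit` with elements `transform`, `cov_fit`,
#'   `sig_fit`, `lfc`, and optionally `recovery`.
#' @export
run_gbcd <- function(X, Kmax, pseudo_count = 0.1, mode = "umi",
                     omega = 0.02, corr_threshold = 0.8, center = FALSE,
                     prior = "generalized_binary", L_true = NULL,
                     verbose = FALSE) {
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  lp <- stage("transform", log_pc_transform(X, c = pseudo_count, mode = mode))
  cov_fit <- stage("fit_covariance",
                   fit_covariance(lp, Kmax = Kmax, omega = omega,
                                  corr_threshold = corr_threshold,
                                  center = center, prior = prior,
                                  verbose = verbose))
  sig_fit <- stage("estimate_signatures", estimate_signatures(lp, cov_fit))
  lfc <- stage("lfc_statistics", lfc_statistics(lp, cov_fit))
  out <- list(transform = lp, cov_fit = cov_fit, sig_fit = sig_fit,
              lfc = lfc)
  if (!is.null(L_true)) {
    out$recovery <- stage("recovery", gep_recovery(L_true, cov_fit$L))
  }
  structure(out, class = "gbcd_fit")
}
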