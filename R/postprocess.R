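# Post-hoc annotation of fitted GEPs: driving genes, gene-set enrichment,
# concordance with external signatures, and a chromosome-position structure
# statistic that flags copy-number-driven components.

#' Driving genes of each GEP
#'
#' A gene drives a GEP when its shrunken log-fold-change estimate is at least
#' `log(fc_min)` (inclusive, in the fit's log base) and it ranks within the
#' top `top_fraction` of genes by that estimate.
#'
#' @param stats An `lfc_stats` object (or a genes x GEP matrix of LFC
#'   estimates on the natural-log scale).
#' @param fc_min Minimum fold change (> 1); default 1.5.
#' @param top_fraction Rank cutoff as a fraction of genes; default 0.02.
#' @param gene_names Optional gene identifiers.
#' @return A list of class `driving_gene_report`: per GEP a data frame of
#'   driving genes sorted by decreasing LFC (with z and lfsr columns when
#'   available), plus the thresholds used.
#' @export
driving_genes <- function(stats, fc_min = 1.5, top_fraction = 0.02,
                          gene_names = NULL) {
  stopifnot(fc_min > 1, top_fraction > 0, top_fraction < 1)
  if (inherits(stats, "lfc_stats")) {
    lfc <- stats$post_mean
    zmat <- stats$z
    lfsr <- stats$lfsr
    base <- stats$log_base
  } else {
    lfc <- as.matrix(stats)
    zmat <- lfsr <- NULL
    base <- "natural"
  }
  J <- nrow(lfc)
  if (is.null(gene_names)) gene_names <- rownames(lfc)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(J))
  thresh <- if (base == "log2") log2(fc_min) else log(fc_min)
  n_top <- ceiling(top_fraction * J)

  per_gep <- lapply(seq_len(ncol(lfc)), function(k) {
    v <- lfc[, k]
    ord <- order(v, decreasing = TRUE)
    sel <- ord[seq_len(n_top)]
    sel <- sel[v[sel] >= thresh]
    out <- data.frame(gene = gene_names[sel], lfc = v[sel],
                      stringsAsFactors = FALSE)
    if (!is.null(zmat)) {
      out$z <- zmat[sel, k]
      out$lfsr <- lfsr[sel, k]
    }
    out
  })
  names(per_gep) <- colnames(lfc)
  structure(list(gep = per_gep, fc_min = fc_min,
                 top_fraction = top_fraction, log_base = base),
            class = "driving_gene_report")
}

#' Gene-set enrichment of a gene list by Fisher's exact test
#'
#' One-sided (over-representation) Fisher's exact test of the overlap
#' between `gene_list` and each gene set, within `universe`, with Bonferroni
#' correction over the number of tested sets.
#'
#' @param gene_list Character vector of genes (subset of `universe`).
#' @param universe Character vector of all candidate genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); each set is intersected with the universe.
#' @param alpha Significance threshold on the adjusted p-value; default 0.05.
#' @return A list of class `enrichment_result`: data frame `table` (set,
#'   overlap, set size, list size, universe size, p, p_adjusted, significant)
#'   sorted by p, and `significant` (subset with adjusted p < alpha).
#' @export
fisher_enrichment <- function(gene_list, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("gene_list contains genes outside the universe")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    k <- length(intersect(gene_list, set))
    # one-sided hypergeometric upper tail: P(overlap >= k)
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- pmin(1, tab$p * nrow(tab))
  tab$significant <- tab$p_adjusted < alpha
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 significant = tab[tab$significant, , drop = FALSE],
                 alpha = alpha),
            class = "enrichment_result")
}

#' Concordance of a GEP signature with an external gene signature
#'
#' Compares the signature values `f_k` of the external signature's genes
#' against an expression-matched control set: genes are grouped into
#' `n_bins` equal-count bins of average expression, and for each signature
#' gene `multiplier` control genes are drawn from its bin.  A one-sided
#' Wilcoxon rank-sum test (by default: signature values greater than
#' control) yields the concordance score \eqn{-\log_{10}(p)}.
#'
#' @param f_k Named-or-indexed numeric vector of signature values for all
#'   genes.
#' @param signature_genes Indices (or names matching `names(f_k)`) of the
#'   external signature's genes.
#' @param mean_expr Per-gene average expression (same length/order as
#'   `f_k`).
#' @param n_bins Number of expression bins; default 50.
#' @param multiplier Control genes drawn per signature gene; default 100.
#' @param rng_seed Seed for control sampling.
#' @param alternative `"greater"` (default; large scores mean concordance)
#'   or `"less"`.
#' @return A list of class `concordance_result` with `neglog10_p`, the raw
#'   `p`, and the control-set indices.
#' @export
signature_concordance <- function(f_k, signature_genes, mean_expr,
                                  n_bins = 50, multiplier = 100,
                                  rng_seed = 1,
                                  alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  J <- length(f_k)
  stopifnot(length(mean_expr) == J)
  if (is.character(signature_genes)) {
    signature_genes <- match(signature_genes, names(f_k))
    if (anyNA(signature_genes))
      stop("some signature genes are absent from the gene universe")
  }
  set.seed(rng_seed)
  # equal-count bins of average expression
  bin <- ceiling(rank(mean_expr, ties.method = "first") / (J / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  bin_members <- split(seq_len(J), bin)

  controls <- integer(0)
  warned <- FALSE
  for (g in signature_genes) {
    members <- setdiff(bin_members[[as.character(bin[g])]], signature_genes)
    if (length(members) == 0) members <- bin_members[[as.character(bin[g])]]
    if (length(members) >= multiplier) {
      controls <- c(controls,
                    members[sample.int(length(members), multiplier)])
    } else {
      if (!warned) {
        warning("expression bin with fewer than `multiplier` genes; ",
                "sampling controls with replacement")
        warned <- TRUE
      }
      controls <- c(controls,
                    members[sample.int(length(members), multiplier,
                                       replace = TRUE)])
    }
  }
  wt <- suppressWarnings(
    wilcox.test(f_k[signature_genes], f_k[controls],
                alternative = alternative, exact = FALSE, correct = TRUE))
  structure(list(neglog10_p = -log10(max(wt$p.value, .Machine$double.xmin)),
                 p = wt$p.value, controls = controls,
                 n_bins = n_bins, multiplier = multiplier),
            class = "concordance_result")
}

#' Chromosome-position structure of a GEP signature
#'
#' For each autosome fits a penalized cubic spline (smoothness by
#' generalized cross-validation) of the signature values on genomic
#' position, against the constant-only null.  Deviances are aggregated over
#' chromosomes and reported as the fraction of deviance explained,
#' \eqn{\rho = 1 - \sum_l D_{model,l} / \sum_l D_{null,l}}; the raw deviance
#' ratio is also stored.  Large \eqn{\rho} flags signatures that vary
#' systematically along the genome (e.g. copy-number-driven patient
#' effects).
#'
#' @param f_k Numeric vector of signature values for all genes.
#' @param gene_coords Data frame with columns `chrom` (autosome labels,
#'   `"1"`-`"22"`, optionally prefixed `"chr"`) and `pos` (numeric position),
#'   one row per gene; e.g. from [read_gene_coords()].
#' @param min_genes Minimum genes per chromosome; smaller chromosomes are
#'   excluded with a warning.  Default 10.
#' @return A list of class `spatial_structure_result` with `rho`
#'   (deviance-explained form), `rho_raw` (the model/null deviance ratio),
#'   and per-chromosome deviances.
#' @export
spatial_rho <- function(f_k, gene_coords, min_genes = 10) {
  stopifnot(nrow(gene_coords) == length(f_k))
  chrom <- sub("^chr", "", as.character(gene_coords$chrom))
  autosomes <- as.character(1:22)
  model_dev <- null_dev <- setNames(rep(NA_real_, 22), autosomes)
  for (cl in autosomes) {
    idx <- which(chrom == cl)
    if (length(idx) == 0) next
    if (length(idx) < min_genes) {
      warning("chromosome ", cl, " has fewer than ", min_genes,
              " genes; excluded")
      next
    }
    y <- f_k[idx]
    pos <- gene_coords$pos[idx]
    kdim <- max(3, min(50, floor(length(idx) / 4)))
    fit <- mgcv::gam(y ~ s(pos, k = kdim, bs = "cr"), method = "GCV.Cp")
    model_dev[cl] <- deviance(fit)
    null_dev[cl] <- sum((y - mean(y))^2)
  }
  ok <- !is.na(model_dev)
  if (!any(ok)) stop("no chromosome with enough genes")
  tot_null <- sum(null_dev[ok])
  tot_model <- sum(model_dev[ok])
  ratio <- if (tot_null <= 0) 1 else tot_model / tot_null
  structure(list(rho = max(0, 1 - ratio), rho_raw = ratio,
                 model_dev = model_dev, null_dev = null_dev),
            class = "spatial_structure_result")
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member gene symbols
#' (case-sensitive).  Parsed with `fgsea::gmtPathways` when available.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Read gene coordinates from a BED-like TSV
#'
#' Four columns (no header): chrom, start, end, gene; 0-based half-open
#' intervals.  The gene position is taken as the interval midpoint by
#' default.
#'
#' @param path Path to the TSV/BED file.
#' @param position `"midpoint"` (default), `"start"`, or `"end"`.
#' @return Data frame with columns `chrom`, `pos`, `gene`.
#' @export
read_gene_coords <- function(path, position = c("midpoint", "start", "end")) {
  position <- match.arg(position)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "gene"),
                    stringsAsFactors = FALSE)
  pos <- switch(position,
                midpoint = (tab$start + tab$end) / 2,
                start = tab$start,
                end = tab$end)
  data.frame(chrom = tab$chrom, pos = pos, gene = tab$gene,
             stringsAsFactors = FALSE)
}
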