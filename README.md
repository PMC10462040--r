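# gbcd — generalized binary covariance decomposition

Multi-patient single-cell RNA-seq data from tumors are dominated by
patient-specific expression differences: pooled cells cluster by patient,
and standard factorizations (NMF and friends) return one component per
patient while silently absorbing the *shared* gene expression programs
(GEPs) — molecular subtypes, stress responses, cell-cycle activity — into
those patient components.  This package is for analysts who want to
decompose a pooled cells × genes expression matrix into patient-specific,
dataset-specific **and** shared programs without using patient labels.

## The model

Expression is decomposed as `Y ≈ L Fᵀ`, with nonnegative memberships
`L` (cells × K) and signatures `F` (genes × K, approximately log-fold
changes).  Two soft structural assumptions make shared programs
recoverable:

* **Generalized binary memberships** — each entry of `L` has a prior
  `(1 − π_k) δ₀ + π_k N₊(μ_k, (ω μ_k)²)` with small fixed `ω` (default
  0.02): memberships are pushed toward {0, μ_k} (crisp patient/subtype
  structure) while still allowing graded values for continuous programs.
* **Orthogonal signatures** — programs up-regulate essentially disjoint
  gene sets, so `Y Yᵀ ≈ L D Lᵀ` with `D = FᵀF` diagonal.  Memberships are
  therefore estimated from the cell-by-cell Gram matrix
  `Y Yᵀ = L L̃ᵀ + ε I + E` by empirical Bayes matrix factorization
  (point-Laplace initialization, positive/negative split, generalized-
  binary refit; components kept when `corr(l_k, l̃_k) > 0.8`).  Signatures
  are then estimated by a semi-nonnegative EBMF fit of `Y` with `L` held
  fixed, and per-gene uncertainty (posterior z-scores, local false sign
  rates) comes from gene-wise regression plus adaptive shrinkage.

The package also contains the building blocks as reusable pieces: the
empirical-Bayes normal-means solvers (`ebnm_gb`, `ebnm_point_laplace`,
`ebnm_point_exponential`, `adaptive_shrinkage`), a greedy + backfitting
EBMF engine with automatic selection of the number of components
(`ebmf_fit`), a multi-patient scRNA-seq count simulator with known GEP
structure (`sim_gep_*`, binomial thinning of Poisson counts), and
annotation statistics (driving genes, Fisher gene-set enrichment,
expression-matched Wilcoxon concordance, and a chromosome-position
deviance statistic `spatial_rho` that flags copy-number-driven
components).

## Worked example

Simulate a small two-patient dataset with a shared continuous program,
then run the full pipeline:

```r
library(gbcd)
set.seed(1)
cfg <- sim_gep_config(n_patients = 2, cells_per_patient = 100,
                      n_genes = 500, n_continuous_cells = 40,
                      de_genes_range = c(20, 40))
truth  <- sim_gep_membership(cfg, rng_seed = 1)   # warns: subtype columns
truth  <- sim_gep_signatures(cfg, truth, rng_seed = 2)  # collapse (2 patients)
counts <- sim_gep_counts(truth, rng_seed = 3)
dim(counts$X)
#> [1] 200 500

fit <- run_gbcd(counts$X, Kmax = 8, L_true = truth$L_true)
round(fit$recovery, 3)
#>    P1    P2    C1
#> 1.000 0.999 0.888
```

`fit$recovery` is the best Pearson correlation between each true
membership column and any estimated component: both patient programs are
recovered essentially exactly and the continuous program at 0.89.  The
fitted diagonal offset (`fit$cov_fit$epsilon`, here ≈ 260) absorbs the
per-cell noise norm that inflates the Gram-matrix diagonal.  Driving
genes of any component come with shrunken log-fold changes, posterior
z-scores, and local false sign rates:

```r
head(driving_genes(fit$lfc)$gep[[2]], 3)
#>      gene      lfc         z      lfsr
#> 1 gene141 9.318975 1.1408947 0.1780146
#> 2 gene328 6.734998 0.7999899 0.2745080
#> 3 gene112 5.073326 0.8026238 0.2600640
```

(`lfc` is on the natural-log scale of the log-pc transform; sparse genes
can show large values because a pseudo-count transform exaggerates fold
changes of genes that are off in most cells.)

On the package's reduced validation design — 8 patients × 100 cells,
2,000 genes, 8 patient programs + 2 subtype programs + 1 continuous
program — `fit_covariance(Y, Kmax = 16)` recovers all patient and subtype
memberships with best correlation ≥ 0.95 and the continuous program at
≈ 0.92, and its worst subtype recovery exceeds that of the unconstrained
semi-NMF variant (`fit_ebsnmf`);
`tests/testthat/test-acceptance.R` runs this comparison.

## Command line

```sh
Rscript inst/cli/gbcd.R simulate --out sims/ --replicates 20 --seed 1
Rscript inst/cli/gbcd.R fit --counts sims/replicate01 --kmax 20 --out run/
Rscript inst/cli/gbcd.R annotate --fit run/ --gmt hallmark.gmt --coords genes.bed --out ann/
```

Counts travel as MatrixMarket + barcode/feature TSVs; fits are serialized
as RDS plus TSV exports.

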