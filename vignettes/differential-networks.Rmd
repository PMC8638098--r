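---
title: "Estimating differential gene regulatory networks with a prior-weighted D-trace loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating differential gene regulatory networks with a prior-weighted D-trace loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdtrace)
```

## The model

Gene regulatory relationships change between biological conditions —
molecular subtypes of a tumor, treatment arms, developmental stages. Rather
than estimating a network per condition and subtracting, this package
estimates the *difference* directly. Expression in the two conditions is
modeled as zero-mean multivariate Gaussian,

$$X \sim N(0, \Sigma_X), \qquad Y \sim N(0, \Sigma_Y),$$

and the differential network is the difference of precision matrices,
$\Delta = \Theta_Y - \Theta_X = \Sigma_Y^{-1} - \Sigma_X^{-1}$. A nonzero
off-diagonal $\Delta_{ij}$ means the conditional dependence between genes
$i$ and $j$ differs between conditions — a changed regulatory relationship.

$\Delta$ is estimated by minimizing the D-trace loss

$$L_D(\Delta) = \tfrac14\left(\langle\hat\Sigma_X\Delta, \Delta\hat\Sigma_Y\rangle
 + \langle\hat\Sigma_Y\Delta, \Delta\hat\Sigma_X\rangle\right)
 - \langle\Delta, \hat\Sigma_X - \hat\Sigma_Y\rangle,$$

a convex quadratic whose unpenalized minimizer is exactly
$\hat\Sigma_Y^{-1} - \hat\Sigma_X^{-1}$, plus a weighted lasso penalty
$\lambda \sum_{ij} W_{ij} |\Delta_{ij}|$ that encodes sparsity and prior
knowledge: pairs of genes linked in a static regulatory database (a
TRRUST-style edge list) receive the reduced weight $W_{ij} = w < 1$
(default $w = 0.1$), all other pairs weight 1. Prior-supported edges are
thereby cheaper for the estimator to include, without being forced in.

The inner product is $\langle A, B\rangle = \mathrm{tr}(AB^T)$; for the
symmetric matrices involved this coincides with $\mathrm{tr}(AB)$.

## Optimization

The penalized problem is solved by FISTA (accelerated proximal gradient
descent). The gradient of the smooth part is
$\nabla L_D = \tfrac12(\hat\Sigma_X\Delta\hat\Sigma_Y +
\hat\Sigma_Y\Delta\hat\Sigma_X) - (\hat\Sigma_X - \hat\Sigma_Y)$, and the
proximal map of the penalty is weighted elementwise soft-thresholding,
which produces exact zeros and keeps iterates sparse from the all-zero
start. Specific choices:

* **Step size.** Fixed at $1/L$ with
  $L = \|\hat\Sigma_X\|_2\,\|\hat\Sigma_Y\|_2$, an upper bound on the
  gradient's Lipschitz constant (the Hessian is the symmetrized Kronecker
  product of the two covariances), so every proximal step is a descent step
  on the majorizer.
* **Momentum and restart.** Nesterov momentum
  $t_{k+1} = (1 + \sqrt{1 + 4t_k^2})/2$ with a function-value restart:
  whenever the accelerated step would increase the objective, momentum is
  dropped and a plain proximal step is taken. The objective sequence is
  therefore non-increasing (asserted in tests).
* **Symmetry.** The gradient-step input is averaged with its transpose each
  iteration; since $W$ is symmetric the prox preserves symmetry, so the
  estimate is exactly symmetric throughout.
* **Convergence.** Relative objective change below `tol` (default `1e-6`),
  capped at `max_iter = 5000`; hitting the cap returns
  `converged = FALSE` with a warning, never silently.
* **Support.** Edges are the exactly-nonzero off-diagonals of the prox
  output; a `1e-8` tolerance is applied only after the final
  symmetrization averaging, which can leave one-ulp residues at penalty
  boundaries. No magnitude re-thresholding happens downstream.
* **Diagonal.** The penalty covers the full matrix, diagonal included, by
  default. This keeps the clean boundary property that the solution is
  identically zero exactly when
  $\lambda \ge \lambda_{\max} = \max_{ij} |\hat\Sigma_X -
  \hat\Sigma_Y|_{ij} / W_{ij}$ (the gradient at zero is
  $-(\hat\Sigma_X - \hat\Sigma_Y)$, so zero is optimal iff it is covered by
  the penalty's subgradient — an argument that needs every entry
  penalized). Since edges are read off-diagonally anyway, penalizing the
  diagonal costs nothing for edge recovery; `penalize_diagonal = FALSE`
  restores the off-diagonal-only variant. `lambda_max()` nudges its value
  up by ulps when floating-point rounding would leave the argmax entry
  marginally uncovered, so the boundary is sharp in floating point too.

## Choosing the penalty: StARS

$\lambda$ is selected by stability selection (StARS): fit the network on
$S = 20$ paired subsamples (drawn without replacement, independently per
condition, size $b = \lfloor 10\sqrt{n}\rfloor$ capped at $n-1$) over a
grid of 20 log-spaced values from $\lambda_{\max}$ down to
$0.01\,\lambda_{\max}$; measure each pair's selection frequency $\xi_{ij}$,
edge instability $2\xi_{ij}(1-\xi_{ij})$, and total instability as the
mean over off-diagonal pairs; monotonize the curve from the most-penalized
end by running maximum; select the smallest $\lambda$ (densest graph)
whose monotonized instability is at most $\beta = 0.005$. Degenerate
cases: if every $\lambda$ is stable the smallest grid value is returned;
if none is, the largest, with a warning. Fits are warm-started along the
grid, and subsample fits that fail to converge are excluded (selection
proceeds while at least half remain, otherwise it aborts).

$\beta = 0.005$ is a deliberately strict stability demand. Two
consequences worth knowing: under a null where both conditions share one
network, the selected graph is (correctly) empty or nearly so; and on
pathway-sized gene sets (say 15 genes, ~100 pairs) a single flickering
edge already produces instability near $\beta$, so the selected model can
collapse to empty — on small sets, inspect the instability curve and
consider the network at a matched externally chosen $\lambda$ (the
`analysis/05` script shows both).

## The differential-expression stage

The pipeline's first track selects genes before the network stage using a
deliberately simple negative-binomial Wald test (counts
$K_{ij} \sim NB(\mu_{ij}, \alpha_i)$ with variance
$\mu + \alpha\mu^2$): median-of-ratios size factors (rescaled to geometric
mean 1, with a library-size fallback when no gene is everywhere-positive),
per-gene method-of-moments dispersion
$\hat\alpha = (s^2 - \bar\mu)/\bar\mu^2$ pooled within groups and floored
at $10^{-8}$ (the Poisson limit), fold change
$\log_2((\bar q_2 + \tfrac12)/(\bar q_1 + \tfrac12))$ with a 0.5
pseudocount to bound it on sparse genes, a delta-method standard error and
two-sided normal p-value, then Benjamini–Hochberg adjustment. This is a
transparent stand-in for a full DESeq2-style analysis: there is no
dispersion shrinkage, no outlier refitting, no independent filtering, so
results on real data will differ from DESeq2's. On the bundled synthetic
conditions it is calibrated (null $p<0.05$ rate ≈ 0.05) and fully powered
on $|\mathrm{lfc}| = 3$ genes at 40 samples per group.

Selection uses `p_adjust < 0.01` and `|log2FC| > 2` (both strict). The
absolute value is a choice: both up- and down-regulated genes matter for
the network, and a `two_sided = FALSE` switch restores the one-sided
filter. The "top 100" list for the network stage ranks by `p_adjust`, ties
broken by larger `|log2FC|` then gene identifier — the ranking key is
another genuinely open choice; adjusted p-value was picked because it is
the selection statistic.

Counts entering the network stage are transformed as
`log2(normalized count + 1)` by default, since the network model assumes
(approximate) Gaussianity; `transform = "none"` honors data already on a
suitable scale.

## Enrichment

Over-representation of a gene list against GMT gene sets uses the
hypergeometric upper tail
$\sum_{i=m}^{\min(M,n)} \binom{M}{i}\binom{N-M}{n-i}/\binom{N}{n}$,
computed in log space via `lchoose` and clamped to $[0,1]$, with BH
adjustment across tested sets. The universe $N$ defaults to the genes
surviving the expression filter — the defensible analogue of a database
universe when the analysis is self-contained — and is the caller's to
set. List genes outside the universe are dropped (with a message) before
$n$ is counted; set members outside the universe do not count toward $M$.

## What the synthetic data emulate — and what they do not

The generators produce exactly the structures the estimator assumes:

* `make_precision_pair()` plants ±`magnitude` entries on random disjoint
  off-diagonal pairs (shared edges in both precision matrices,
  differential edges in one), then conditions *both* matrices with the same
  diagonal shift $c = |\lambda_{\min}| + 0.1$, so the off-diagonal truth
  $\Delta$ is known exactly and untouched by the conditioning.
* `sample_expression()` draws exact zero-mean Gaussians via the Cholesky
  factor of the precision.
* `make_nb_counts()` draws NB counts at the stated mean/dispersion with a
  Poisson branch below the $10^{-8}$ dispersion floor.
* `make_prior_network()` covers a controllable fraction of the true
  differential edges plus noise pairs, written in a four-column
  TRRUST-style dialect so the same reader handles real TRRUST files.

Real RNA-seq is harsher in ways the generators deliberately omit: no
library-size heterogeneity, batch effects, latent confounders, outlier
samples, or count-to-Gaussian mismatch in the network stage (the Gaussian
track samples Gaussians directly). Passing tests therefore demonstrate
correctness of the estimator and pipeline under their own model, not
robustness to violations of it.

## Study conditions used by the tests and acceptance script

These sizes are the package's reference conditions; they were fixed once,
up front.

| Quantity | Setting |
|---|---|
| Support recovery | $p=40$, 20 shared + 10 differential edges of magnitude 0.4, $n=400$/condition, StARS $\beta=0.005$, $S=20$; median F1 over 10 replicates |
| Prior benefit | $p=30$, full-coverage prior at $w=0.1$ vs all-ones weights at matched $\lambda = 0.5\lambda_{\max}$ |
| Null stability | identical precisions, $p=20$, $n=200$/condition |
| DE calibration/power | 2000 genes, 40 samples/group, `base_mean` 100, dispersion 0.1, planted $\mathrm{lfc}=3$ |

The NB settings (mean 100, dispersion 0.1, 40 per group) are typical of a
moderately deep bulk RNA-seq comparison of tumor subtypes; 20 shared edges
at $p = 40$ keeps the background network sparse while making the
conditioning shift (and hence the signal-to-diagonal ratio) realistic
rather than trivially easy.

## Known limitations

* The Wald test's normal approximation is anticonservative for very small
  groups (< ~10 samples per group); the calibration checks run at 40.
* StARS instability is resolution-limited on small gene sets (see above).
* The estimator assumes both covariance estimates are PSD and reasonably
  scaled; astronomically scaled inputs abort with a diagnostic rather than
  iterate into overflow.
* Directionality of prior edges is discarded — the estimated $\Delta$ is
  symmetric, so direction cannot be represented.

## A worked example

The reference support-recovery conditions, end to end (this is the same
computation `analysis/03_differential_network.R` performs on files):

```{r example}
sc <- make_precision_pair(p = 40, n_common_edges = 20, n_diff_edges = 10,
                          magnitude = 0.4, seed = 20260929)
X <- sample_expression(sc$theta_X, n = 400, seed = 20260930)
Y <- sample_expression(sc$theta_Y, n = 400, seed = 20260931)
prior <- make_prior_network(sc, coverage = 1, noise_edges = 5, seed = 20260932)
W <- build_weight_matrix(prior, sc$gene_ids, w = 0.1)

res <- stars_select(X, Y, W, beta = 0.005, S = 20, seed = 7)
res
hub_genes(res$network, k = 10)
```

With these seeds StARS selects $\lambda = 0.465$ and a 14-edge network
containing all 10 planted differential edges.
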