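---
title: "Two-step mixed-model association scans: model, engines and design choices"
author: "lmmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mixed-model association scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmmscan)
```

## The model

`lmmscan` tests SNP-trait associations under the linear mixed model for
a structured sample of `n` individuals:

$$ y = X_L \beta_L + x_{snp}\,\gamma + g + e, \qquad
   g \sim N(0,\ \sigma^2 h^2 \Phi), \quad
   e \sim N(0,\ \sigma^2 (1 - h^2) I), $$

where $\Phi$ is the kinship matrix of pairwise relationship
coefficients, $\sigma^2$ the total trait variance and $h^2 \in [0, 1)$
the narrow-sense heritability. Marginally $y \sim N(X\beta, M)$ with

$$ M = \sigma^2\,(h^2 \Phi + (1 - h^2) I), $$

and each SNP test is the generalized least-squares (GLS) problem
$b = (X'M^{-1}X)^{-1} X'M^{-1} y$ for $X = [X_L \mid x_{snp}]$. Over
`m` SNPs and `t` traits this is an $m \times t$ grid of correlated GLS
problems: along the trait axis $M$ and $y$ change while $X_L$ does not;
along the SNP axis only the one design column changes. Everything in
this package is an exploitation of that structure. The output is the
$m \times t \times p$ cube of effects, standard errors and Wald
statistics, held in a `GwasResult` (a `SummarizedExperiment` with SNPs
as rows, traits as columns and one `beta.*`/`se.*` assay pair per
coefficient).

### The two-step approximation

Fitting $(\sigma^2, h^2)$ jointly with every SNP is unaffordable and
unnecessary at scan scale. Step one estimates the variance components
per trait under the covariates-only model and step two holds $M$ fixed
for all of that trait's SNP tests. Consequences worth knowing:

* The reported coefficient covariance is $(X'M^{-1}X)^{-1}$ with $M$
  already carrying the step-one $\hat\sigma^2$ — no post-hoc residual
  rescaling. `glsSolve(..., rescale = TRUE)` exposes the alternative
  convention (multiply by the whitened residual mean square with
  denominator $n - p$) for users who want it; the default matches the
  two-step logic, and the difference is $O(p/n)$.
* Step one uses profiled *maximum likelihood*. ML is marginally
  downward-biased in $\hat h^2$ relative to REML at small $n$, but is
  the simpler and faster criterion and the bias is negligible at the
  sample sizes the scan targets; `estimateH2(..., reml = TRUE)`
  switches to the restricted likelihood (with the
  $\log|X'WX|$ correction) when an unbiased variance convention
  matters.
* Inference is a two-sided Wald test on the SNP coefficient referred
  to $\chi^2_1$; it falls straight out of the GLS solve, and its
  calibration under the two-step approximation is verified by
  simulation in the test suite (type-I error $0.05 \pm 0.01$ and
  genomic-control $\lambda \in [0.95, 1.05]$ over a 10,000-cell null
  grid at $n = 300$).

### Step one on the kinship spectrum

With the one-time eigendecomposition $\Phi = V \Lambda V'$
(`eigenKinship`), rotating $y$ and $X_L$ by $V'$ makes the covariance
diagonal with entries $\sigma^2 w_i$, $w_i = h^2 \lambda_i + 1 - h^2$.
At a candidate $h^2$, `profileLoglik` fits the covariates by weighted
least squares, profiles $\hat\sigma^2 = \sum r_i^2 / w_i / n$, and
evaluates the profiled log-likelihood in $O(pn)$ — so after the shared
$O(n^3)$ factorization a trait costs only $O(vn)$, with $v$ the number
of likelihood evaluations. `estimateH2` maximizes over a 21-point grid
on $[0, 1 - 10^{-6}]$ followed by golden-section refinement to
tolerance $10^{-6}$; $v \le 60$ always. Numerical decisions:

* the upper search bound $1 - 10^{-6}$ keeps every $w_i$ positive even
  for zero eigenvalues;
* a flat likelihood (identity kinship makes all $w_i \equiv 1$)
  resolves to the *smallest* $h^2$ within $10^{-9}$ of the maximum, so
  unidentifiable traits report $h^2 = 0$ rather than an arbitrary
  interior point;
* kinship eigenvalues below zero are clipped to zero; they only warn
  when they fall below $-10^{-8}\lambda_{max}$, since empirical
  genomic kinships are routinely near-PSD.

## The two scan engines

**Cholesky whitening** (`runCholGwas`) is the single-trait engine.
Per trait, $M = LL'$ is factored once and the model is whitened by
forward substitution ($L^{-1}$ is never formed; no matrix in this
package is ever explicitly inverted). The covariate cross-products
$X_L'M^{-1}X_L$ and $X_L'M^{-1}y$ are cached as a Cholesky factor, so
each SNP needs only the $2p - 1$ cross-products involving its own
column plus an $O(p^2)$ bordered solve: $O(n^2)$ per SNP for the
whitening, $O(np)$ for the update, never $O(np^2)$.

**Eigen rotation** (`runEigGwas`) is the multi-trait engine. Because
$M$ shares eigenvectors with $\Phi$ and its eigenvalues are
shifted-and-scaled kinship eigenvalues (`shiftedEigenvalues`), a single
rotation of covariates, genotype columns and trait columns converts
every grid cell into a weighted least-squares solve with per-sample
weights $1/(\sigma_j^2 w_{ij})$. Each column is rotated exactly once
(the instrumentation counts rotations, and the test suite asserts the
counts equal `m` and `t`); per-trait weights are recomputed from the
shared eigenvalues in $O(n)$ rather than cached for all traits, which
keeps the resident working set within the memory bound below.

Both engines flag degenerate cells — a SNP collinear with the
covariates, e.g. monomorphic with an intercept present, detected by a
bordered-Cholesky pivot below $10^{-10}$ relative — as `NaN` records
and continue; a genome scan must not abort on a monomorphic marker.
Both are verified cell-for-cell against a brute-force GLS oracle that
*does* use explicit inverses, over 200 random instances, to $10^{-8}$
relative in effects and standard errors; the two engines also agree
with each other bit-for-bit in the `t = 1` overlap up to that same
tolerance.

### Determinism and blocking

Genotypes stream through `blockIterator` in consecutive column blocks
(default 256 columns). Whitening and rotation are applied column by
column rather than as blocked matrix-matrix products, deliberately:
identical floating-point operation order makes scan output
*bit-identical* for every block size (tested at 1, 7 and 64). The cost
is some BLAS-3 throughput; the benefit is that blocking is purely a
memory knob, never a numerical one.

### The memory contract

The engines' design working set is the $n^2$ factor (Cholesky factor or
eigenvectors) plus the $p$ fixed-effect columns plus `k` resident SNP
and trait columns: `memoryBudget(n, p, k)` $= n^2 + (k + p)n$ entries,
minimum `k = 2`. Built-in instrumentation (`instrReset`,
`instrPeakEntries`) tracks what the algorithms keep live and the tests
assert the peak stays under the budget for a file-backed scan. The
binary `MMG1` matrix layout is the streaming format (per-row seeks, one
block resident, truncation detected with the failing byte offset); TSV
input is a convenience that is read whole before slicing.

## The cost model and engine selection

`predictCosts` models multiply-add totals with the *same per-phase
counting convention the instrumented engines use* — triangular solve
$n(n+1)/2$ per column, rotation $n^2$ per column, OLS update
$(p+1)n + p^2$ per SNP, WLS cell $(p+2)n + p^2$, Cholesky $n^3/3$,
eigendecomposition $(10/3)n^3$ (an order of magnitude above the
Cholesky count, reflecting the practical cost ratio of the two
factorizations). The constants were fixed once from the
implementation's counted operations on a reference instance; because
model and instrumentation share formulas, selector decisions and
measured counts agree exactly on instances small enough to run both.

Both engine models are affine in `t` with the Cholesky slope two
orders of magnitude steeper at genome scale, so the selector has a
single monotone crossover; at $n = 1000$, $m = 10^6$, $p = 3$ it picks
the Cholesky engine up to two traits and the eigen engine from three
(the dominant terms reproduce the asymptotic regimes $O(mpn^2)$
single-trait, $O(tmn)$ for $t > n$, $O(mn^2)$ for $n > t$). The exact
crossover depends on these constants; the robust statement, asserted
in the tests, is that it is a single small number of traits
($t^* \le 10$), not its precise value.

## The synthetic-data generator

`simulateDataset` draws the study conditions used throughout the
validation suite:

* **Kinship**: block-diagonal full-sib families (within-family
  coefficient 0.5, diagonal 1), default family size 5. This is an
  exact, interpretable ground truth — the expected phenotypic
  correlation of a sib pair is $h^2/2$, which the tests check — and is
  positive definite by construction. `genomicKinship` builds a
  standardized-dosage GRM ($ZZ'/m$) when a pedigree matrix is not
  wanted.
* **Genotypes**: independent sites, dosage $\sim$ Binomial(2, f) with
  $f \sim U(0.05, 0.5)$ per SNP. Relatedness enters through $\Phi$
  only; the two-step model makes no use of linkage disequilibrium, so
  none is simulated.
* **Phenotypes**: $y = X_L\beta_L + \sum_c x_c \gamma_c + g + e$ with
  the polygenic part drawn through the Cholesky factor of $\Phi$.
  Defaults: $h^2 = 0.5$, $\sigma^2 = 1$, null covariate effects, no
  causal SNPs.
* **Seeding**: every component (genotypes, covariates, each trait)
  draws from its own stream derived from the master seed, so enlarging
  the trait panel never perturbs genotypes or existing traits.
* **Ratio traits**: `ratioTraits` reproduces the metabolomics
  convention of scanning all ordered pairwise concentration ratios —
  `k` base measurements become $k^2$ traits (328 give 107,584), which
  is what makes the multi-trait regime and its Bonferroni burden
  realistic (`bonferroniThreshold(5e-8, 107144)`
  $\approx 4.7\times10^{-13}$). `meanImpute` provides the simplest completion of sparse
  missingness, since both engines require complete data.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: linkage disequilibrium and its
effect on the effective number of tests, allele-frequency ascertainment,
genotyping and imputation error, non-Gaussian trait distributions,
shared environment within families (the generator's within-family
correlation is purely polygenic), and missingness that is informative
rather than ignorable.

## Validation problem sizes

The package's own checks run at deliberately modest sizes chosen to
make the statistical assertions sharp: 200 random instances with
$n \le 100$, $p \le 5$, $t \le 8$ for the three-way engine/oracle
equivalence; 50 replicates at $n = 500$ (family size 5) for recovery of
$h^2 = 0.5$ within $\pm 0.05$; a $500 \times 20$ null grid at $n = 300$
(10,000 cells) for type-I error and $\lambda$; and a 1000-SNP
file-backed scan at $n = 200$, block 64, for the memory contract. The
acceptance script (`scripts/acceptance.R`) recomputes all of these from
scratch under a caller-supplied seed.

## Known limitations

* One random effect only: no multi-component variance models, no
  SNP-by-SNP re-estimation of $h^2$ (that is the two-step
  approximation, by design), no low-rank kinship truncation.
* Univariate trait models per grid cell: the multi-trait engine shares
  computation across traits but does not fit joint multivariate
  models, and no likelihood-ratio or score tests are offered.
* Complete-data requirement in the scan engines; imputation is the
  user's explicit step (`meanImpute` for the simple case), which is
  adequate for low missingness and inappropriate for assays with
  heavy, structured missingness.
* The streaming layer bounds resident memory and never re-reads a
  block, but performs synchronous I/O; it does not overlap disk
  transfers with computation.
* Genomic coordinates are not modeled; SNPs are opaque identifiers,
  which is all the method needs.
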