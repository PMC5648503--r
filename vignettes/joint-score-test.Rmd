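---
title: "Multi-tissue eQTL mapping with DNA methylation: model, tests, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tissue eQTL mapping with DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlscore)
```

## The problem

Expression quantitative trait loci (eQTL) are genetic variants associated
with transcript abundance. When the same subjects are profiled in several
tissues, a variant can shift expression uniformly across tissues, act in a
tissue-specific way, or act only through an epigenetic intermediate such as
promoter CpG methylation — which is itself tissue-specific. `meqtlscore`
maps eQTL across tissues while modeling methylation, by jointly testing
four effects of a SNP on a transcript in the presence of a promoter CpG:

* an additive shift common to all tissues (fixed effect $\beta$),
* a genotype-by-methylation interaction (fixed effect $\phi$),
* a genotype-by-tissue interaction (variance component $\gamma$),
* a genotype-by-methylation-by-tissue interaction (variance component $\delta$).

## The model

For subject $i$ ($i = 1,\dots,n$) and tissue $j$ ($j = 1,\dots,t$), with
genotype $g_i \in \{0,1,2\}$ (minor-allele count) and methylation $m_{ij}$,
expression is modeled as

$$
y_{ij} = \alpha_j + \beta g_i + \lambda m_{ij} + \phi\, m_{ij} g_i
       + a_i + b_{ij} g_i + c_{ij} m_{ij} g_i + d_{ij} m_{ij} + \xi_{ij},
$$

with $a_i \sim N(0,\tau)$ a subject intercept, $b_{ij} \sim N(0,\gamma)$,
$c_{ij} \sim N(0,\delta)$ and $d_{ij} \sim N(0,\theta)$ independent
tissue-indexed random effects, and $\xi_{ij} \sim N(0,\epsilon)$ residual
noise. $\alpha_j$, $\lambda$, $\tau$, $\theta$, $\epsilon$ are nuisance
parameters. The null hypothesis of no genetic effect on this transcript is

$$H_0:\ \beta = \phi = \gamma = \delta = 0 .$$

Under $H_0$ the model reduces to $Y = J\alpha + M\lambda + Au + Dx + \xi$
and the covariance of each subject's $t$-vector is
$\Sigma_i = \epsilon I_t + \tau \mathbf{1}\mathbf{1}' + \theta\,
\mathrm{diag}(m_i^2)$, block diagonal over subjects. `fit_null()` estimates
$(\tau, \theta, \epsilon)$ by REML, profiling $(\alpha, \lambda)$ out by
GLS at each iterate; all linear algebra uses the closed-form
Sherman–Morrison inverse of the $t \times t$ blocks, so the $nt \times nt$
covariance is never formed.

### Efficient scores and the joint statistic

With $\hat Y$ the GLS residuals and $\hat\Sigma$ the fitted null
covariance, the four scores are

$$
U_\beta = \hat Y' \hat\Sigma^{-1} (G - \bar G), \qquad
U_\phi = \hat Y' \hat\Sigma^{-1} (MG - \overline{MG}),
$$
$$
U_\gamma = \tfrac12\, \hat Y' \hat\Sigma^{-1} B B' \hat\Sigma^{-1} \hat Y,
\qquad
U_\delta = \tfrac12\, \hat Y' \hat\Sigma^{-1} C C' \hat\Sigma^{-1} \hat Y,
$$

where $G$ and $MG$ are the expanded (grand-mean-centered) genotype and
genotype-by-methylation vectors and $B$, $C$ are the $nt \times t$ stacked
genotype and methylation-by-genotype designs. The joint statistic is the
weighted combination

$$
U_\zeta = a_\beta U_\beta^2 + a_\phi U_\phi^2 + a_\gamma U_\gamma
        + a_\delta U_\delta ,
$$

a single quadratic form $\hat Y' \hat\Sigma^{-1} K \hat\Sigma^{-1} \hat Y$
with a low-rank kernel $K$ (rank at most $2t + 2$). Its null mean and
variance are $E = \mathrm{tr}(P_0 K)$ and
$\mathrm{Var} = 2\,\mathrm{tr}(P_0 K P_0 K)$, where
$P_0 = \hat\Sigma^{-1} - \hat\Sigma^{-1} X (X'\hat\Sigma^{-1}X)^{-1}
X'\hat\Sigma^{-1}$ projects off the estimated fixed effects; both traces
are computed through the $(2t+2)\times(2t+2)$ Gram matrix of the kernel
columns, at cost $O(n t^2 \cdot \mathrm{rank})$. Computing the variance on
the combined kernel automatically accounts for all cross-component
covariances. The p-value uses the Satterthwaite approximation
$U_\zeta \sim \kappa \chi^2_\nu$ with $\kappa = \mathrm{Var}/(2E)$ and
$\nu = 2E^2/\mathrm{Var}$; for a rank-one kernel this is exact.

**Weights.** The combination weights are only identified up to a
convention (free minimization of the variance gives zero weights), so each
component is standardized to unit null standard deviation:
$a_\beta = 1/\mathrm{SD}_0(U_\beta^2)$, …, $a_\delta =
1/\mathrm{SD}_0(U_\delta)$, each computed with the same projected-trace
machinery applied to the component's own kernel. This is a documented
convention, chosen for symmetry; one consequence we observed is that in
pure genotype-by-tissue settings the four-component joint test can edge
out the two-component genotype + G$\times$T test, because the
G$\times$M$\times$T kernel overlaps the G$\times$T kernel and absorbs part
of the signal rather than pure noise.

**Degenerate cases.** A monomorphic SNP zeroes the centered additive
contrast; the statistic is flagged degenerate and reported with p = 1.
The same applies when the kernel's null variance collapses
(Var $< 10^{-12} E^2$).

**Per-pair estimation reuse.** The nuisance parameters depend only on the
(transcript, CpG) pair, so one null fit serves every cis-SNP of that pair;
`joint_score_test()` accepts a precomputed fit and `scan_triplets()`
exploits this.

## Comparators

* `tbt_eqtl()`: per-tissue OLS of expression on genotype, two-sided t-test
  on the slope; summary is the minimum p over tissues, judged at the
  Bonferroni level $0.05/t$.
* `tbtm_eqtl()`: per-tissue OLS with methylation covariate and
  genotype-by-methylation interaction; the test is the 2-df F-test of
  $(\beta, \phi) = 0$. The joint 2-df choice (rather than $\beta$ or
  $\phi$ alone) is required for the comparator to detect both additive
  and interaction signals, which is how it behaves in the reference
  power tables.
* `jaguar_style_test()`: the multi-tissue genotype + genotype-by-tissue
  score test without methylation terms (null $Y = J\alpha + Au + \xi$),
  using the identical Satterthwaite machinery on
  $a_\beta U_\beta^2 + a_\gamma U_\gamma$.

## What the simulator emulates

`sim_params()` + `sim_dataset()` generate one locus and one gene:
genotypes i.i.d. Binomial(2, MAF) (Hardy–Weinberg), methylation rows
i.i.d. $N_t(0, \Sigma_m)$ with a compound-symmetric default
($\sigma^2 = 1$, $\rho = 0.5$), and expression from the model above. The
tissue-indexed random effects are drawn independently per subject; this is
what makes the reported mid-range powers possible at all — if the
tissue effects were shared across subjects they would be estimable at
$n = 500$ and every tissue-interaction test would saturate at power 1.
A consequence worth knowing: the interaction score kernels are rank-$t$
with $O(n)$ eigenvalues, so the signal-to-null-SD ratio of
$U_\gamma$/$U_\delta$ is governed by the variance share (PVE), not by
$n$ — power against these alternatives plateaus in $n$.

Variance shares are specified as percentages:
$\mathrm{PVE}_\gamma = \gamma/(\theta+\tau+\epsilon+\gamma+\delta)$ and
analogously $\mathrm{PVE}_\delta$; `pve_to_variances()` solves the
implied 2$\times$2 linear system.

What the simulator does **not** emulate: linkage disequilibrium between
SNPs, bounded beta-distributed methylation values, batch structure, or
realistic genomic coordinates. Passing tests on this generator show the
statistical machinery is correct and calibrated for Gaussian
methylation/expression; they do not certify behavior on raw array data,
which needs the usual upstream normalization.

### Study-harness conventions

`run_power_study()` reproduces type-I error and power grids at the
reference conditions ($n = 500$, $t = 5$, MAF 0.3, 1000 replicates for
type-I error, nominal 0.05, Bonferroni $0.05/t$ for tissue-by-tissue
methods). Its nuisance convention is $\tau = \epsilon = 1$,
$\theta = \lambda = 0$: methylation influences expression only through
the effects under test. We chose this (over the symmetric
$\tau = \theta = \epsilon = 1$) because per-subject methylation noise at
$\theta = 1$ makes the TBTm F-test's null rejection rate climb to ~0.16
via genotype-correlated heteroscedasticity, which is incompatible with a
calibrated TBTm null (~0.04) in the reference tables; with $\theta = 0$
every method is calibrated. Fixed effects default to 0.3 when a grid row
switches them on. Replicate $r$ uses seed `base_seed + r - 1` in every
cell, so cells and methods are comparable with paired Monte Carlo error.

Absolute powers in pure-interaction cells depend, in addition, on the
methylation scale $\mathrm{Var}(m)$ (the $\delta$-heteroscedasticity seen
by every test is $\delta\, m^2 g^2$ while the PVE pins only
$\delta/(\tau+\theta+\epsilon)$); with the unit default our
$\mathrm{PVE}_\delta = 10$ powers are ~0.14 (joint) and ~0.12 (TBTm),
well below the reference values near 0.42, and we deliberately do not
tune the methylation scale to match them. Orderings between methods are
reproduced.

## Multiple testing and the genome scan

`qvalues()` implements Storey-style q-values:
$q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)$,
with $\hat\pi_0$ from the smoothed estimator
($\hat\pi_0(\lambda) = \Pr(p > \lambda)/(1-\lambda)$ on
$\lambda = 0.05, \dots, 0.95$, cubic smoothing spline, evaluated at
$\lambda = 0.95$), falling back to $\pi_0 = 1$ — exactly
Benjamini–Hochberg — when the estimate leaves $(0, 1]$ or fewer than 100
p-values are available.

`pair_cis()` forms candidate (transcript, CpG, SNP) triplets: SNPs within
100 kb of the transcript's TSS (inclusive boundary, "did not exceed"),
CpGs strictly within 1.5 kb (exclusive boundary, "less than"); both
windows are symmetric around the TSS and matching is within-chromosome
with 1-based coordinates. `scan_triplets()` fits one null model per
(transcript, CpG) pair, tests each cis-SNP, pools p-values scan-wide into
q-values (significance at $q \le$ FDR), and for joint-test scans reports
driver flags — which components are marginally significant at 0.05 within
each significant triplet (the marginal-at-0.05 rule is our interpretive
choice for attributing drivers). Tissue-by-tissue scans instead compute
per-tissue q-values, take the minimum across tissues, and declare
significance at $q \le \mathrm{FDR}/t$.

## Numerical choices

* REML optimizes log-variances with `nlminb`, floor $10^{-8}$ (boundary
  estimates allowed), relative tolerance $10^{-8}$, at most 200
  iterations; non-convergence is flagged on the returned object rather
  than raised.
* Starting values are moment-based fractions (0.3/0.1/0.6) of the
  centered per-tissue residual variance.
* `null_fit_se()` inverts a numerically differentiated observed
  information; SEs are available on the natural or log-variance scale.
* Degenerate designs (constant methylation, monomorphic SNPs,
  rank-deficient per-tissue regressions) are rejected or reported with
  p = 1 plus a flag/warning as documented on each function.
* Complete cases are required throughout; imputation is out of scope.

## Problem sizes used in the packaged checks

The test suite runs the reference grid at its published sizes where the
quantity is a calibration (1000 replicates for type-I error) and at 500
replicates for power orderings; dense-matrix oracle comparisons use
$n \le 8$, parameter-recovery checks use $n = 2000$, $t = 5$ over 100
seeded fits, and the example genome scans use 50–100 triplets at
$n = 150$–300. These sizes were chosen so that every check is
reproducible on a single CPU in minutes while keeping Monte Carlo error
well below the margins being asserted.

## Known limitations

* The combination-weight convention is a stand-in for an unpublished
  optimality rule; alternative weights change power trade-offs between
  components (see above).
* Power against pure tissue-interaction alternatives plateaus in $n$
  under the per-subject generative model (bounded per-locus information);
  additive and G$\times$M signals are detected at the usual
  $\sqrt{n}$ rate.
* The null model carries no extra covariates (age, batch, surrogate
  variables); adjust upstream.
* Exact mixture-of-chi-square tails (characteristic-function inversion)
  are not implemented; the Satterthwaite approximation is the method's
  specification, and its accuracy is verified by the calibration tests.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
vc <- pve_to_variances(10, 0, tau = 1, theta = 0, eps = 1)
p <- sim_params(n_subjects = 500, n_tissues = 5, maf = 0.3,
                gamma = vc["gamma"], theta = 0)
dat <- sim_dataset(p, seed = 1)

fit <- fit_null(dat$y, dat$m)
res <- combine_and_test(fit, efficient_scores(fit, dat$g))
res$p_value

# comparators on the same data
tbt_eqtl(dat$y, dat$g)$min_p
tbtm_eqtl(dat$y, dat$g, dat$m)$min_p
jaguar_style_test(fit_null(dat$y, m = NULL), dat$g)$p_value
```
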