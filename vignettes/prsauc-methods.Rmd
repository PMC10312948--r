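---
title: "Predicting PRS AUC from training summary statistics: model and methods"
author: "prsauc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PRS AUC from training summary statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsauc)
```

## The problem

Polygenic risk scores (PRS) for a binary disease combine per-SNP allele
dosages $g_{i,m} \in \{0,1,2\}$ with weights $\omega_m$ estimated by a PRS
method from a case-control GWAS: $\mathrm{PRS}_i = \sum_m \omega_m g_{i,m}$.
Most PRS methods expose hyperparameters — a p-value threshold for
pruning/clumping + thresholding (P+T, C+T), a risk-SNP proportion for
spike-and-slab methods — that are conventionally tuned on an external
individual-level validation cohort. Such cohorts are often unavailable:
large consortia release only meta-analysed summary statistics, and holding
out part of the training data wastes it.

`prsauc` predicts the out-of-sample AUC of each candidate weight vector
*from the training summary statistics alone*, so that the hyperparameter
with the best predicted AUC can be selected without any validation
genotypes.

## The AUC model

With case/control reference-allele frequencies $f_{1,m}, f_{0,m}$, genotype
variances $s_{j,m}^2 = 2 f_{j,m}(1-f_{j,m})$ and LD correlations
$R_{m_1 m_2}$, the PRS is asymptotically normal within each group and

$$\mathrm{AUC} = \Phi(\Delta), \qquad
\Delta = \frac{2 \sum_m \omega_m \delta_m}{\sqrt{\tau_0^2 + \tau_1^2}},
\qquad
\tau_j^2 = \sum_m \omega_m^2 s_{j,m}^2
  + 2\!\!\sum_{m_1<m_2}\!\! \omega_{m_1}\omega_{m_2} R_{m_1 m_2}
    s_{j,m_1} s_{j,m_2},$$

where $\delta_m = f_{1,m} - f_{0,m}$ is the case-control allele-frequency
difference. The denominators use observed frequencies and a reference-panel
LD estimate; they do not involve the unknown effects. The difficulty is
$\delta_m$: plugging in the *observed* differences
$\hat\delta_m = z_m s_m$ (with $z_m$ the allele-frequency-difference test
z-score and $s_m = \sqrt{s_{1,m}^2/4n_1 + s_{0,m}^2/4n_0}$ its standard
error) rewards exactly those SNPs whose effects were overestimated by
chance — the predicted AUC is inflated and the selected hyperparameter can
be wrong. `plugin_auc()` computes this unadjusted estimate as the baseline.

## Empirical-Bayes shrinkage

The standardized effects are modeled with a point-normal prior
$\beta_m/s_m \sim (1-\pi)\,\delta_0 + \pi\, N(0, \sigma^2)$, with
$\delta = S R S^{-1} \beta$ and $z \mid \delta \sim N(S^{-1}\delta, R)$.
Two regimes:

**Independent pre-selected SNPs** (e.g. after LD pruning, $R = I$).
The z-score marginal is a two-component normal mixture;
`em_fit()` maximizes its likelihood over $(\pi, \sigma^2)$ by EM
(E-step: posterior risk probabilities $h_m$; M-step:
$\pi = \bar h$, $\sigma^2 = \sum h_m z_m^2 / \sum h_m - 1$, floored at
zero). The posterior is then closed-form,
$$\delta_m \mid z_m \sim (1 - h_m)\,\delta_0 +
  h_m\, N(\lambda z_m s_m,\ \lambda s_m^2), \qquad
  \lambda = \frac{1}{1 + 1/\sigma^2},$$
and `predict_auc_independent()` converts Monte-Carlo draws of $\delta$
into draws of $\Phi(\Delta)$.

**SNPs linked by LD.** The $2^M$ mixture combinations make the marginal
likelihood intractable, so `same_gibbs()` uses a State-Augmentation for
Marginal Estimation (SAME) Gibbs sampler: $D$ artificial replicates of the
latent $(\beta, \gamma)$ are sampled jointly with $(\pi, \sigma^2)$ from a
posterior proportional to $\prod_{d=1}^D P(z, \beta^{(d)}, \gamma^{(d)}
\mid \pi, \sigma^2)$; because this marginalizes to $P(z \mid \pi,
\sigma^2)^D$, growing $D$ by one per outer iteration makes the sampled
$(\pi, \sigma^2)$ concentrate on their maximum-likelihood values. Per SNP
visit the update uses the residualized mean $\mu_m = \lambda(z_m -
\sum_{m' \neq m} R_{m m'} \beta_{m'} / s_{m'})$, slab draw $N(\mu_m,
\lambda)$ on the standardized scale, and spike-vs-slab odds $r_m =
\pi \sqrt{\lambda}/\sigma\, e^{\mu_m^2 / 2\lambda}$, $h_m = r_m / (1 - \pi
+ r_m)$; indicators $\gamma_m$ are drawn from the odds with the effect
marginalized, and the effect is redrawn conditional on the new indicator,
which keeps the state consistent ($\beta_m = 0$ wherever $\gamma_m = 0$)
and reduces exactly to the independent-SNP closed form when $M = 1$ — the
test suite enforces this equivalence, as well as agreement with exhaustive
enumeration of the $\gamma$ posterior on 2-3 SNP problems. All
likelihood-ratio arithmetic is done in the log domain, so z-scores up to
$|z| = 50$ cause no overflow.

After $(\pi, \sigma^2)$ converge they are frozen at the running mean of the
last window, and additional sweeps of the final replicate collect
$\delta = S R S^{-1}\beta$ and one AUC draw per candidate weight set. The
fit depends only on $(z, s, R)$, so one sampler run serves an entire
hyperparameter grid.

## LD: blocks, Ledoit-Wolf, banding

Long-range LD is negligible, so the genome is cut into approximately
independent blocks (LDetect-style 3-column BED partitions; the simulator
defines its own blocks). Cross-block correlation is treated as zero, which
makes blocks conditionally independent in the sampler and lets quadratic
forms cost $O(\sum_b p_b^2)$. Within a block, `estimate_ld()` mean-imputes
missing dosages, standardizes each SNP, and applies the Ledoit-Wolf
closed-form shrinkage toward the scaled identity, renormalized to unit
diagonal (the AUC formula needs correlations; Ledoit-Wolf natively targets
covariance). With a 1000-sample reference panel and weak LD the optimal
shrinkage intensity is substantial (often $\alpha \approx 0.5$); this is
the estimator's honest risk-minimizing answer, and the implementation is
verified to agree with the standard closed form. An optional LD radius
(`band_radius`) zeroes correlations beyond a fixed SNP-index distance;
blocks whose Cholesky fails get a small diagonal jitter ($10^{-6}$,
escalated at most 1000-fold before reporting the block as indefinite).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `em_fit`: `init_pi`, `init_sigma_sq` | 0.1, 1 | EM start; the mixture likelihood is well behaved, so defaults rarely matter |
| `em_fit`: `tol`, `max_iter` | 1e-6, 10000 | convergence on both parameter changes |
| `n_draws` (independent path) | 1000 | Monte-Carlo AUC draws; point estimate is the posterior mean of $\Phi(\Delta)$ |
| `same_schedule`: `d_max` | 100 | replicate cap; `D` grows by 1 per outer iteration |
| `same_schedule`: `window`, `tol` | 10, 1e-3 | running-mean convergence of $(\pi, \sigma^2)$ |
| `same_schedule`: `n_auc_draws` | 500 | post-convergence sweeps collecting AUC |
| `same_schedule`: `jitter` | 1e-6 | diagonal regularization of non-PD blocks |
| `band_radius` | none | LD radius in SNP-index units (the benchmark AR(1) runs use 5) |
| `ldpred_like_weights`: `h2_style_scale` | 0.5 | heritability-style constant; slab variance $c\,n/(M\pi)$ |

The posterior-mean point estimate and the draw count are deliberate
choices (the posterior summary is not prescribed by the model); the 95%
interval is the 2.5/97.5% quantile of the AUC draws.

## What the simulator emulates — and what it does not

`simulate_replicate()` reproduces two generative settings used for
validation: (i) independent SNPs with population frequencies
$U(0.05, 0.95)$, $\pi = 0.05$, $\sigma^2 = 0.001\,n$, prevalence 1%, and
(ii) AR(1)-correlated SNPs with adjacent genotype correlation $\rho = 0.2$
and $\sigma^2 = 0.0005\,n$. Standardized effects scale with $n$ because
$s_m \propto 1/\sqrt{n}$. Training z-scores are drawn directly from the
summary-level model $z \sim N(S^{-1}\delta, R)$ — exactly the model the
predictor assumes — while testing cohorts and reference panels are always
individual-level: binomial dosages, or paired first-order
correlated-Bernoulli haplotype chains with conditional success probability
$p(x_{m+1}{=}1 \mid x_m) = f_{m+1} + \rho\sqrt{\tfrac{f_{m+1}(1-f_{m+1})}
{f_m(1-f_m)}}(x_m - f_m)$, which gives exact adjacent correlation $\rho$
(infeasible conditional probabilities are clipped and counted; clipping
beyond 1% of SNPs is an error). Case frequencies $f_1 = f_0 + \delta$ are
clipped into $(0.01, 0.99)$, and $s$ is recomputed once from the realized
frequencies — the remaining discrepancy is second order.

Passing tests under this simulator show that the estimator inverts its own
generative model well; they do not exercise real-data complications:
realistic LD (block sizes, long-range LD, allele-frequency-dependent LD),
population stratification, imputation error, or — most importantly —
meta-analysis summary statistics whose per-SNP sample sizes are smaller
than the reported totals. The latter biases $s_m$ downward and hence the
predicted AUC downward; the ranking across hyperparameters is much more
robust, which is why `prs_tune()` warns rather than fails when per-SNP
sample sizes are constant.

## Evaluation metrics and benchmark scale

`evaluate_metrics()` scores a tuning run by $\rho_{AUC}$, the Pearson
correlation between predicted and testing AUC across the grid (reported as
NaN with a warning when either vector is constant — a nearly flat AUC
profile makes the correlation uninformative), and $rd_{AUC} =
|AUC_{test}(\hat\theta) - \max_\theta AUC_{test}|/\max_\theta AUC_{test}$,
the relative shortfall of the selected hyperparameter.

The packaged benchmarks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run both designs at $M = 10{,}000$ SNPs and
training sizes $n \in \{4000, 6000, 8000, 10000\}$ with 1000+1000 testing
individuals, using 12-40 replicates per sample size rather than the
original 50/20; the Monte-Carlo tolerances in the tests are widened
accordingly ($\pm 0.01$ on the independent-design correlation,
$\pm 0.03$ on the AR(1) one). The dominant noise source at this scale is
the testing cohort itself: a 2000-individual Mann-Whitney AUC has a
standard error near 0.011, comparable to the spread of the AUC curve
across hyperparameters at $n = 4000$, which caps the attainable
per-replicate correlation well below 1 regardless of prediction quality.
At a reduced SNP count (e.g. $M = 2000$) the curve spread shrinks further
and the correlation benchmark is noise-limited, which is why the shipped
benchmarks keep the full SNP count and reduce replicates instead.

## Design choices in corner cases

* **All-zero weight sets** (a threshold below every p-value) are assigned
  AUC exactly 0.5 on every path rather than an error: a constant score
  discriminates nothing.
* **Degenerate EM**: $\sigma^2$ is floored at machine epsilon so the
  shrinkage factor $\lambda$ stays defined; with all-null z-scores the fit
  collapses to the null and every posterior draw of $\delta$ is zero.
* **SAME with no active SNPs** in an iteration leaves $\sigma^2$
  unchanged (the conjugate Gamma update has zero rate).
* **Zero-variance SNPs** in a reference panel keep their row in the block
  (identity row/column, with a warning) so SNP alignment is never broken.
* **Harmonization** aligns weights, frequencies and panel dosages into
  the summary-statistics allele frame: swapped alleles negate $\omega$
  and flip dosages $g \to 2-g$; strand flips are resolved by
  complementing; strand-ambiguous A/T and C/G SNPs are dropped by default.
  The operation is a projection — applying it twice equals applying it
  once.
* **SNPs outside every partition interval** are assigned to the nearest
  block with a warning rather than dropped, so a weight vector never
  silently loses support.
* **Duplicated SNP ids** keep the first occurrence with a warning.

## Reproducibility

Every stochastic routine accepts an integer `seed` (or inherits the
session RNG state when `seed = NULL`); the replicated experiments and the
command-line runs consume a single seeded stream, so repeated runs with
the same seed are bit-identical. C++ samplers draw through R's RNG, so
`set.seed()` governs them too.

## Known limitations

* Quantitative traits (predictive $r^2$) are out of scope; the AUC model
  is inherently case-control.
* The point-normal prior has a single slab; multi-component mixtures
  (sBayesR-style architectures) are not modeled.
* The bundled P+T / C+T / spike-and-slab weight generators are minimal
  stand-ins so the tuning loop can run end to end; they do not reproduce
  the numerics of published PRS software.
* Per-SNP effective sample sizes are supported as columns but default to
  study-wide totals; with heterogeneous meta-analysis coverage the
  predicted AUC level (not ranking) is biased downward.
* LDetect partitions are consumed, never computed.
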