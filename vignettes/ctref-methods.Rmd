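---
title: "Individual-specific reference panels from longitudinal bulk data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific reference panels from longitudinal bulk data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctref)
```

## The problem

Bulk transcriptomes are mixtures: the expression of gene $g$ in a sample is a
proportion-weighted sum of the expression of the cell types composing that
sample. Signature-based deconvolution classically assumes one fixed
reference panel (gene $\times$ cell type) for a whole cohort, yet pure-cell
experiments show large between-subject heterogeneity in cell-type-specific
expression. When each subject is measured repeatedly — longitudinal cohort
designs — that repetition carries exactly the information needed to separate
*subject-level* reference expression from sample-level noise.

`ctref` models, for one gene at a time, the expression $y_{jt}$ of subject
$j$ at time point $t$ as

$$E(y_{jt}) = \sum_{k=1}^{K}\left(m_k + \beta_k z_j + u_{jk}\right)\theta_{jtk}$$

where $\theta_{jtk}$ are known (or externally estimated) cell-type
proportions, $z_j$ is the binary group flag, $m_k$ is the control-group mean
reference of cell type $k$, $\beta_k$ the case-group offset, and
$u_{jk}\sim N(0,\sigma_k^2)$ is subject $j$'s deviation from its group mean
in cell type $k$ — shared by all of subject $j$'s samples. Stacking samples
gives the linear mixed model

$$y = X\beta + Au + \varepsilon,\qquad u\sim N(0,\Sigma_u),\quad
\varepsilon\sim N(0,\sigma_0^2 I),$$

with $X$ the fixed-effect design (baseline and group blocks of proportion
columns), $A$ the random-effect design (one column per subject $\times$ cell
type, carrying that subject's proportions), and
$\Sigma_u = \mathrm{diag}(\sigma_1^2 I_J,\dots,\sigma_K^2 I_J)$.

A temporal extension adds per-cell-type covariate slopes and
group-by-covariate interactions (`model = "slope"` in `ct_design()`): a
nonzero interaction $\gamma_k$ means the cases' reference expression in cell
type $k$ *changes over time* differently from controls. Change rates are
assumed linear in the covariate; nonlinear trends are out of scope.

Because the likelihood is Gaussian, the same machinery applies to normalized
or rescaled expression and to other roughly Gaussian omics measurements
(e.g. methylation beta values).

## Estimation

Parameters $(\beta, \sigma_0^2, \sigma_1^2,\dots,\sigma_K^2)$ are estimated
by maximum likelihood via EM, treating $u$ as missing data. The E-step is
the exact Gaussian conditional of $u$ given $y$:
$\mu_p = \Sigma_u A' V^{-1}(y - X\beta)$ and
$\Sigma_p = \Sigma_u - \Sigma_u A' V^{-1} A \Sigma_u$ with
$V = A\Sigma_u A' + \sigma_0^2 I$. The M-step is closed-form:
$\beta \leftarrow (X'X)^{-1}X'(y - A\mu_p)$,
$\sigma_0^2 \leftarrow E[s's\,|\,y]/N$ with $s = Au + X\beta - y$, and
$\sigma_k^2 \leftarrow E[u_k'u_k\,|\,y]/J$. The residual part of
$E[s's\,|\,y]$ is evaluated at the updated $\beta$ — the joint maximizer of
the expected complete-data log-likelihood — so each iteration is a true EM
step and the marginal log-likelihood never decreases. No non-negativity
constraint is imposed during estimation; only the *reported* panels are
truncated at zero.

Three implementation choices matter in practice:

* **Subject-block algebra.** $V$ is block-diagonal by subject (each column
  of $A$ touches one subject's rows), so likelihood, E-step and posterior
  moments decompose into $J$ problems of size $T_j \times T_j$. The compiled
  core (`src/em.cpp`) exploits this; a pure-R reference engine
  (`engine = "R"`) implements the identical algorithm and the two are
  cross-checked in the tests, as is the dense-matrix construction of $V$.
* **Acceleration.** The plain EM map crawls along flat variance-component
  directions (hundreds to thousands of iterations on realistic data —
  and a prematurely stopped fit silently biases downstream likelihood-ratio
  statistics). The driver therefore wraps the EM map in squared
  extrapolation (SQUAREM-type): extrapolated steps are accepted *only* when
  their log-likelihood is at least that of the plain two-step move, so the
  recorded trace is non-decreasing by construction and the fixed points are
  those of the plain map. `ctlmm_control(accelerate = FALSE)` restores the
  plain iteration.
* **Floors and flags.** All variance components are floored at `1e-8`
  (configurable) to keep $V$ invertible; a fit whose variance sits at the
  floor at convergence carries a `boundary` flag. Convergence is declared
  when the relative log-likelihood change drops below `tol` (default
  `1e-6`, default cap 200 iterations). For likelihood-ratio testing we
  recommend (and the acceptance analyses use) `tol = 1e-7`–`1e-8` with a
  higher cap, since the test statistic is a *difference* of maximized
  log-likelihoods.

Initialization is ordinary least squares for $\beta$; half the OLS residual
variance goes to $\sigma_0^2$ and the other half is split evenly across the
$K$ random-effect variances. Each gene is fitted independently from its own
start; fits share one design factorization.

## Recovery and testing

The individual reference panel entry for subject $j$, cell type $k$ is
$\max(0,\ \hat m_k + \hat\beta_k z_j + \hat u_{jk})$ with $\hat u = \mu_p$
(`subject_panel()`); under the slope model it is reported at the centered
covariate value. `group_panel()` gives the fixed two-row (control/case)
baseline used as a comparator. Recovery error against a known truth is
summarized by NMSE — squared error normalized by the truth's centered sum of
squares, so "predict the grand mean" scores exactly 1 — computed per gene
and summarized by the median across genes.

Cell-type-specific differential expression is tested by likelihood-ratio:
the full and the reduced model (tested column(s) removed from $X$) are both
fitted by EM and $\Lambda = 2(L_{\text{full}} - L_{\text{reduced}})$ is
referred to $\chi^2_d$, $d$ = number of constrained coefficients. Available
hypotheses: per-cell-type group offset (`mean`), all offsets jointly
(`joint`, $d = K$), covariate-adjusted offset (`adjusted_mean`) and
differential slope (`slope`). Reduced fits warm-start from the full-model
estimates; negative statistics from residual numerical error are clipped at
zero (a clip beyond `1e-4` raises a flag instead). Non-convergent fits
yield a missing p-value, never a fabricated one. Benjamini–Hochberg
correction is applied within each cell type across genes — each cell type
is its own testing family, matching per-cell-type reporting; boundary
variance estimates do not alter the $\chi^2$ reference but are flagged.

Design choices on genuinely open points:

* Covariates in the slope model are mean-centered before design
  construction (conditioning; intercepts then refer to the average
  covariate value); each covariate receives both a slope and an interaction
  block.
* The screen reuses one full-model fit per gene across the $K$
  per-cell-type tests; each hypothesis gets its own exact reduced fit.
* Proportion rows are silently renormalized when their sum is within `1e-6`
  of 1, and rejected otherwise; identically-zero cell-type columns are an
  error rather than a silent drop.

## The generative simulator

`simulate_dataset()` reproduces the study conditions under which the method
is evaluated; every intermediate quantity is retained as ground truth.

1. **Composition.** Subject-level mean compositions
   $\bar\theta_j \sim \mathrm{Dir}(\xi_Z\,\bar\theta^{(0)}_Z)$ per group,
   then per-time-point compositions
   $\bar\theta_{jt}\sim\mathrm{Dir}(\xi_p\,\bar\theta_j)$. Group means come
   from Dirichlet parameters $\bar\alpha_C = (8.85, 6.49, 5.98, 5.28, 4.22,
   3.85)$ and $\bar\alpha_D = (1.90, 2.25, 2.10, 5.72, 7.33, 15.37)$ for
   the default $K = 6$.
2. **Gene-level parameters.** Per gene and subject, log-scale mean vectors
   $M\sim \mathrm{MVN}(\bar\mu_m, \Sigma_m)$ and overdispersions
   $\Phi\sim\mathrm{MVN}(\bar\mu_\phi,\Sigma_\phi)$, exponentiating $M$
   before the Gamma step. Case subjects of a DE-flagged gene have
   $\bar\mu_m$ shifted by the log fold change $\Delta$ in the flagged cell
   type (study grid $\Delta\in\{0, 0.5, 0.75, 1.0, 1.25, 1.5\}$).
3. **References.** $\lambda \sim \Gamma(\mathrm{shape}=e^{-\Phi},\
   \mathrm{scale}=M e^{\Phi})$, i.e. mean $M$ and variance $M^2 e^{\Phi}$ —
   the parameterization under which $M$ is the mean expression.
4. **Mixing and observation.** $\bar\lambda_{gjt} = \lambda_{gj}'\,
   \bar\theta_{jt}$ and $Y_{gjt}\sim\mathrm{Pois}(\bar\lambda_{gjt})$.
5. **Slope scenario.** Reference means shift additively over time,
   $\tilde M_{t} = M + \Delta_t$ with $\Delta_1 = 0$ and $\Delta_t$ fixed
   by group; references are redrawn per time point. The control-group shift
   is the trend shared by everyone; case subjects follow the case shift in
   a gene's DE-flagged cell types only, giving a per-cell-type differential
   change rate. Shifts act on the natural (count) scale, matching the
   linearity of the slope model.

Defaults are the study conditions: $T = 3$ time points, balanced groups,
10% of genes DE per designated cell type with disjoint DE sets across the
first four of six cell types (two cell types carry none). Where the study
conditions leave constants unstated we fixed, once: $\bar\mu_m$ evenly
spaced on $[2, 8]$ (log scale), $\Sigma_m$ compound-symmetric with sd 0.5
and correlation 0.5 (expression is strongly associated across cell types),
$\bar\mu_\phi = -1$ with sd 0.25 and correlation 0.5, $\xi_Z = 30$,
$\xi_p = 100$ (within-subject composition varies less than between-subject).
These imply biological coefficients of variation around 0.6 — realistic for
sorted-cell RNA-seq — and all are overridable in `sim_config()`.

`perturb_proportions()` is a *synthetic surrogate* for an external
signature-based deconvolution step: Gaussian noise is added to the true
reference panels, 200 marker genes are chosen by cross-cell-type
coefficient of variation, and each sample's composition is re-estimated by
nonnegative least squares on its subject's noisy marker panel, then
renormalized. The noise level of the external pipeline being emulated is
unknown; it is exposed as `noise_sd` (default 0.1 of the panel scale).

Reproducibility: the whole pipeline is deterministic in the seed, and genes
use derived RNG substreams so that (for a fixed DE design) growing `G` does
not perturb earlier genes.

### What the simulator does and does not capture

It reproduces the two-level composition variability, correlated
cell-type-specific means and overdispersions, Gamma biological plus Poisson
technical noise, and group-wise temporal trends. It does *not* emulate
library-size variation, batch effects, zero inflation, gene–gene
correlation beyond the shared composition, or proportion-estimation bias
beyond the NNLS surrogate. Passing tests therefore demonstrate correctness
of the algorithms and the claimed statistical behavior *under this
generative family*, not performance on any particular real cohort.

## Calibration and power, known limitations

The mixed model is Gaussian and homoscedastic while the simulated data are
Gamma–Poisson with roughly multiplicative (lognormal-like) between-subject
effects and composition-dependent noise scales. On data simulated from the
Gaussian model itself the mean-test p-values are exactly calibrated (type I
error at $\alpha = 0.05$ indistinguishable from 0.05 in our checks). On the
Gamma–Poisson simulator with the default configuration, cell types that are
rare in one group (around 5–6% of the mixture) show clear liberality in
both the mean and the slope test (empirical type I error roughly 0.10–0.17
at $\alpha = 0.05$), while abundant cell types stay near nominal; p-values
are approximately, not exactly, uniform under the null. This mirrors the
known behavior of Gaussian working models on overdispersed counts and
should be kept in mind when interpreting discoveries in rare cell types.

Power has the same geometry. A cell type's group effect is identified
through its proportion columns, so at ~5% abundance and modest expression
the effect is statistically almost invisible at 25 subjects per group:
sensitivity of the screen at the default configuration is low at small log
fold changes and grows steeply with both the effect size and the cell
type's abundance, and false discoveries concentrate in the rare,
miscalibrated cell types. Per-cell-type *slopes* are harder still — the
interaction columns `c·θ_k` are nearly collinear across cell types when
compositions are stable over time, and the slope scenario redraws the
biological reference at every time point, adding within-subject noise on
the order of 0.6 times the reference mean. The automated slope-power
experiment therefore uses the most abundant cell type and temporal shifts
that are large relative to the reference scale (on the order of the
reference mean per time unit); at smaller shifts the test has essentially
no power at these sample sizes, which is itself a finding about the
method's operating range. Sample-size comparisons of ranking quality (AUC)
are likewise made at the largest simulated effect size, where the ranking
is informative.

## Problem sizes used by the automated analyses

The test suite and the acceptance script run at desk scale, chosen to keep
the full run in the tens of minutes on one core: null-calibration screens
use 800–1000 genes at 25 subjects per group; power/FDR/AUC sweeps use
300–400 genes per log-fold-change with the four DE-carrying cell types
tested; panel-NMSE comparisons use 50–60 genes at 25–100 subjects per
group; EM-versus-optimizer checks use 12–20 random small instances;
parameter-recovery checks use 10 replicates at 50 and 200 subjects per
group. Expected behaviors (monotone trends, orderings, calibration bands)
are asserted at these sizes with their natural Monte-Carlo uncertainty;
binomial interval checks adapt their width to the n actually run.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(G = 200, J_per_group = 25), seed = 1)
design <- ct_design(sim$meta, sim$proportions)

# one gene: fit, inspect, recover the panel
fit <- ctlmm(sim$counts[1, ], design,
             ctlmm_control(tol = 1e-8, max_iter = 1000))
summary(fit)
panel <- subject_panel(fit)
nmse(panel$panel, sim$truth$lambda[1, , ])

# screen all genes for cell-type-specific DE in the group mean
res <- csde(sim$counts, design, kind = "mean",
            control = ctlmm_control(tol = 1e-7, max_iter = 800))
head(rank_genes(res[res$cell_type == "ct1", ]))
```

## Limitations and non-goals

Proportions are treated as known inputs; re-estimating them jointly with
the panels is out of scope, as are nonlinear time trends,
cell-type-specific residual variances, non-negativity-constrained or
restricted EM, REML, Wald/score tests, and any re-implementation of
external deconvolution or DE tools (external results can be compared via
the exported metric functions). The $\chi^2$ reference is used as-is at
variance boundaries, with a diagnostic flag.
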