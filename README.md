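# ctref

Individual-specific, cell-type-specific expression reference panels from
repeatedly measured bulk transcriptomes — and cell-type-specific
differential expression (csDE) testing in group mean and in temporal slope.

## The problem

Bulk RNA-seq measures a mixture over cell types, so the expression of gene
*g* in a sample is a proportion-weighted sum of cell-type-level expression.
Classical deconvolution assumes one fixed gene × cell-type reference panel
for the whole cohort, but pure-cell data show substantial between-subject
heterogeneity in those references. In longitudinal designs each subject is
measured several times, and that repetition identifies subject-level
references. `ctref` is for analysts of repeated-measure bulk cohorts (or
other admixed, roughly Gaussian omics such as methylation) who have
cell-type proportions per sample — known or externally estimated — and want
per-subject reference panels plus csDE tests.

## The model

For one gene, with subjects *j* (groups `z_j ∈ {0,1}`), time points *t* and
cell types *k* with proportions `θ_jtk`:

    E(y_jt) = Σ_k ( m_k + β_k z_j + u_jk ) θ_jtk ,   u_jk ~ N(0, σ_k²)

i.e. a linear mixed model `y = Xβ + Au + ε`, `ε ~ N(0, σ0² I)`, where `m_k`
is the control-group reference of cell type *k*, `β_k` the case offset, and
`u_jk` subject *j*'s deviation shared by all of its samples. A slope variant
adds per-cell-type covariate slopes and group × covariate interactions
`γ_k`, so differential *change rates* per cell type can be tested. Fitting
is maximum likelihood via an accelerated EM algorithm (closed-form E and M
steps exploiting the subject-block structure of the marginal covariance;
compiled core with a pure-R reference engine). csDE hypotheses
(`H0: β_k = 0`, all `β = 0` jointly, or `γ_k = 0`) are tested by
likelihood-ratio against `χ²`, with Benjamini–Hochberg correction per cell
type across genes. Recovered panels are `max(0, m̂_k + β̂_k z_j + û_jk)`.

The package also ships the full generative simulator used to exercise every
claim — two-level Dirichlet compositions, correlated log-normal gene
parameters, Gamma biological plus Poisson technical noise, log-fold-change
and group-wise temporal shifts, and a surrogate noisy-panel NNLS proportion
estimator — plus evaluation metrics (NMSE, TDR, ROC/AUC, sensitivity/FDR,
KS uniformity). See the methods vignette (`vignettes/ctref-methods.Rmd`)
for assumptions, parameter choices and limitations.

## Worked example

```r
library(ctref)

sim    <- simulate_dataset(sim_config(G = 200, J_per_group = 25), seed = 1)
design <- ct_design(sim$meta, sim$proportions)

fit <- ctlmm(sim$counts[1, ], design, ctlmm_control(tol = 1e-8, max_iter = 1000))
summary(fit)
#> Cell-type mixed-effect model (mean model), fit by EM
#>   log-likelihood: -995.2  iterations: 110 (converged)
#> ...
#> Per-cell-type effects:
#>      baseline     group   sigma_k_sq
#> ct1  -92.0927 -884.8034 4.506080e+01
#> ...
#> ct6 3599.4825  829.7708 2.029900e+07

panel <- subject_panel(fit)          # 50 subjects x 6 cell types, >= 0
nmse(panel$panel, sim$truth$lambda[1, , ])
#> [1] 0.0369913
```

The summary shows, per cell type, the estimated control-group reference
expression (`baseline`), the case-group offset (`group`) and the
between-subject variance (`sigma_k_sq`); the recovered panel for this gene
deviates from the simulated truth by an NMSE of 0.037 (0 = perfect, 1 =
no better than predicting the truth's mean). Screening genes for csDE:

```r
res <- csde(sim$counts[1:20, ], design, kind = "mean",
            control = ctlmm_control(tol = 1e-7, max_iter = 800))
head(rank_genes(res[res$cell_type == "ct4", ]), 3)
#>     gene_id cell_type test statistic df           p          q reject
#> 112  g00019       ct4 mean  8.573770  1 0.003410402 0.03411151   TRUE
#> 94   g00016       ct4 mean  8.573371  1 0.003411151 0.03411151   TRUE
#> 28   g00005       ct4 mean  5.697897  1 0.016985250 0.10211611  FALSE
```

Each row is one gene × cell type: the LRT statistic, its χ² p-value, the
BH q-value within that cell type's family, and the rejection flag at
FDR 0.1. A thin command-line front end (`exec/ctref`) wraps
`simulate`, `fit`, `test`, `recover` and `evaluate` for shell pipelines.

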