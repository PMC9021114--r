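# ggmeta

Maximum likelihood estimation of Gaussian graphical models (GGMs) —
networks whose edges are partial correlations — from one or several
sample correlation matrices, with fixed-effects and random-effects
meta-analytic aggregation across datasets.

The package is aimed at researchers who have summary statistics (a
correlation matrix and a sample size per study, the typical situation in
psychometric and epidemiological network analysis) and want classical
inference: estimates, standard errors, Wald-based edge pruning, fit
indices, and principled pooling over studies.

## The model

A GGM on `p` standardized variables is parameterized by a hollow
symmetric matrix **Ω** of partial correlations with implied correlation
matrix

**P** = **Δ** (**I** − **Ω**)⁻¹ **Δ**,

where **Δ** scales **P** to a unit diagonal. For a single study with
sample correlation matrix **R** and sample size *n*, estimation
minimizes the standardized-Gaussian discrepancy
*F* = trace(**RK**) − ln|**K**|, **K** = **P**⁻¹, using analytic
chain-rule derivatives; standard errors come from the Fisher
information, 𝓥 = 𝓘⁻¹/*n*.

Across *k* studies:

- **Fixed effects** — one common network. Either two-stage (pool the
  correlations by ML, then fit the network to them by WLS with the
  Fisher information as weight matrix) or one multi-dataset likelihood
  with equality constraints; the saturated fits agree exactly. Per-edge
  equality constraints and an exploratory **partial pruning** search
  (modification indices + BIC) locate edges that differ across
  datasets.
- **Random effects** — study correlation vectors are modeled as
  **r**ᵢ ~ N(**μ**(**Ω**), **V**ᵢ + **TT**′): sampling covariance
  **V**ᵢ (estimated first from saturated correlation fits) plus a
  Cholesky-parameterized heterogeneity covariance whose diagonal square
  roots are the per-correlation random-effect SDs.

A simulation harness generates sparse small-world truth networks,
injects correlated heterogeneity, samples finite-size studies, and
scores recovery (sensitivity, specificity, edge-weight correlation,
random-effect-SD bias).

## Worked example

```r
library(ggmeta)
set.seed(7)

net <- generate_true_network(8)        # 16 of 28 possible edges
studies <- simulate_studies(net, k = 8, n_range = c(250, 1000))

fit <- fixed_effects_ggm(studies, method = "two_stage", alpha = 0.05)
fit
#> Two-stage fixed-effects GGM fit: 16 free parameter(s), 1 group(s), n = 4935
#>   F = 0.003399, max|gradient| = 1.74e-07, converged: TRUE
#>   chi2 = 16.776 on df = 12, RMSEA = 0.0090

evaluate_network(net, omega_matrix(fit))
#>   sensitivity specificity correlation re_bias
#> 1           1           1   0.9963707      NA
```

After pruning at α = 0.05 the fitted network here keeps exactly the 16
true edges (sensitivity and specificity both 1), its weights correlate
0.996 with the truth, and the retained model fits well (RMSEA ≈ 0.009).
`edge_table(fit)` lists each edge with its estimate, SE, z and p value;
`prune()`, `modification_indices()`, `partial_prune()`,
`fit_random_effects()` and `run_study()` cover the constrained,
multi-dataset, random-effects and simulation workflows. A thin CLI
(`exec/ggmeta`) exposes `fit`, `fixed`, `random`, `partialprune` and
`simulate` subcommands over YAML manifests.

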