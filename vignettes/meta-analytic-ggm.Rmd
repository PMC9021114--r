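---
title: "Estimating Gaussian graphical models from one or many correlation matrices"
author: "ggmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Gaussian graphical models from one or many correlation matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmeta)
```

## The model

A Gaussian graphical model (GGM) represents a set of `p` standardized
variables as a network: nodes are variables, and an edge between nodes
`i` and `j` carries the partial correlation between them given all other
variables. The package parameterizes the GGM by a hollow symmetric matrix
`Omega` of partial correlations with implied correlation matrix

    P = Delta (I - Omega)^{-1} Delta,

where `Delta` is the diagonal scaling that gives `P` a unit diagonal.
`Omega` and `P` are smooth mutual transforms (`ggm_to_corr()`,
`corr_to_ggm()`); a zero in `Omega` is an absent edge, which is what
makes constrained (sparse) network estimation meaningful.

All estimation is maximum likelihood on a fit function proportional to
-2/n times the log-likelihood. For one standardized dataset with sample
correlation matrix `R` the fit function is `F = trace(R K) - ln|K|`,
`K = P^{-1}`: sample correlations are sufficient, so raw data are never
needed. Every model in the package is expressed through a three-stage
chain: free parameters (what the optimizer moves) map to model
parameters (all potential edges, per group) through a sparse 0/1
"manual Jacobian" that encodes fixed-to-zero and equality constraints;
model parameters map to distribution parameters (correlations, or means
and covariances) through an analytic model Jacobian; and the
distribution supplies its own Jacobian and expected Hessian. Gradients
come from the chain rule, and the Fisher information — hence standard
errors, Wald tests, and the parameter covariance `V = I^{-1}/n` — from
the same chain evaluated once at the optimum. All matrix-calculus
plumbing (duplication, elimination, commutation, and diagonal-selection
matrices; `structural_matrices()`) follows the column-stacked
convention, and every analytic derivative in the package is checked
against central finite differences in the test suite.

## Aggregating datasets

**Fixed effects.** When several datasets are assumed to share one
population correlation structure, the joint fit function is the
sample-size weighted sum of per-dataset fit functions. Two equivalent
routes estimate the common network: `two_stage_fixed()` first pools the
correlations by ML (with their Fisher information) and then fits the
network to the pooled correlations by weighted least squares with the
Fisher information as weight matrix; `multidataset_ggm()` fits all
datasets in one likelihood with edges constrained equal across groups.
For the saturated network the two give identical estimates and standard
errors (asserted to 1e-6 in the tests). The multi-dataset route
additionally supports per-edge choices — pooled, unique per dataset, or
excluded — which is what `partial_prune()` searches over.

**Significance pruning.** `prune()` removes, in one simultaneous pass,
every edge whose Wald test exceeds the chosen alpha, and refits.
Single-pass simultaneous removal is the default because it makes the
false-inclusion rate interpretable: on homogeneous data the expected
specificity is exactly `1 - alpha`, which the simulation harness
reproduces (mean specificity ~0.95 at alpha = 0.05). A recursive mode
is available behind a flag.

**Partial pruning.** To explore which edges genuinely differ across
datasets: (1) prune each dataset separately; (2) fit a pooled model
containing the union of the retained edges, all equal across datasets;
(3) repeatedly free the edge with the largest modification index summed
across datasets, keeping the change only if BIC improves; (4) prune the
final model at alpha = 0.05. The summed-index rule resolves an
ambiguity in how per-dataset indices are aggregated; we sum per edge
over datasets, which makes step 3 free one equality constraint (one new
parameter per dataset) at a time. The BIC gate plus the final pruning
keeps the search conservative: on homogeneous data it rarely frees
anything.

**Random effects.** When populations differ, the study-level sample
correlation vectors `r_i` themselves are modeled:
`r_i ~ N(mu(Omega), Sigma_i)` with `Sigma_i = V_i + T T'`. Here `V_i`
is the sampling covariance of study i's correlations — estimated first,
from saturated correlation fits, and then treated as known — and
`T T'` is the heterogeneity covariance, parameterized by its Cholesky
factor so it is positive semi-definite by construction. The reported
per-pair random-effect SDs are `sqrt(diag(T T'))`. Four variants come
from crossing how `V` is built (`individual` per-study fits vs one
`pooled` fit scaled per study by `nbar/n_i`) with how the likelihood is
evaluated (`averaged`, one covariance for all studies, fitting the mean
vector and scatter matrix; vs `per_study`, study-specific covariances,
which also supports studies with missing variables by subsetting the
mean and covariance). On homogeneous equal-n data the four variants
agree (estimate correlations > 0.98 in the tests). Fit indices are not
reported for random-effects fits: the fit function no longer evaluates
the likelihood of raw data, so chi-square-based indices are not
comparable across model families.

## Numerical choices

- **Optimizer.** `nlminb` with the analytic gradient. Proposals where
  `I - Omega` is singular, the implied scaling is non-positive, or a
  covariance fails its Cholesky factorization are rejected with an
  infinite fit value rather than an error, so line searches can back
  off. Convergence is declared only when the maximum absolute gradient
  entry is below the tolerance (1e-5 by default); the flag is honest
  and a non-converged fit says so.
- **Start values.** Networks start at `corr_to_ggm(R)` (or of the
  pooled matrix), shrunk geometrically toward zero if inadmissible;
  random-effects fits start `T` at 0.05 times the identity, since the
  exact boundary `T = 0` is a saddle of the profiled likelihood.
- **Gradient tolerance for random-effects fits** defaults to 1e-3: with
  `q(q+1)/2` Cholesky parameters (406 at p = 8) many directions are
  almost flat and the stricter tolerance buys no accuracy.
- **Rank-deficient information.** With few studies the Fisher
  information of the Cholesky block is structurally rank deficient (k
  rows cannot identify q(q+1)/2 covariance parameters). Ordinary fits
  treat a singular information as an error naming the non-identified
  parameters; random-effects fits instead use a Moore-Penrose
  pseudoinverse for the parameter covariance so that edge-level Wald
  tests and random-effect SDs remain available at small k. SEs of the
  heterogeneity parameters themselves should not be over-read in that
  regime.
- **Fit indices.** Log-likelihoods add the Gaussian constant
  `-(n/2) p ln(2*pi)` to the fit function, so AIC/BIC are on the
  standard scale; chi-square is `n (F - F_saturated)`; RMSEA is
  `sqrt(max(0, chi2 - df) / (df n))` scaled by `sqrt(k)` for k groups
  (the common multi-group convention).
- **Modification indices** are univariate score statistics
  `n g^2 / (4 I_partial)` with the candidate's fit-function gradient
  `g` and its information partialled for the current free parameters.
  They are validated behaviorally: chi-square(1) distributed when the
  constraint holds, and within 20% of the actual likelihood-ratio drop
  for moderate misfit.
- **Ties in pruning** cannot arise: all non-significant edges are
  removed in the same pass, so no ordering is involved.

## The synthetic-data generator

`generate_true_network()` emulates sparse psychometric networks: a
Watts-Strogatz ring lattice (each node tied to its four nearest
neighbors, 25% of edges rewired with the edge count preserved — 16 of
28 possible edges at 8 nodes, 32 of 120 at 16), weighted by a
diagonally dominant precision construction: off-diagonal magnitudes
uniform on (0.5, 1), diagonal 1.5 times the absolute row sums, then
standardized to partial correlations with signs set so 90% of edges are
positive. These defaults give a mean absolute edge weight near 0.17.
The (0.5, 1) magnitude range is the conventional default for this
weighting scheme; it is validated through the resulting weight scale
rather than assumed. Heterogeneity is injected by adding `N(0, re_sd^2 * C)` noise
to the true correlations, with `C` a random correlation matrix from a
C-vine construction (Beta-distributed partial correlations with
concentration 1, uniform over the space of correlation matrices),
redrawing until the perturbed matrix is positive definite — which is
why large `re_sd` values (above ~0.1) are impractical. Study data are
finite-sample: `n_i` uniform on 250..1000 standard Gaussian
observations per study, correlated by the perturbed matrix.

What passing simulations do and do not show: the generator draws exact
multivariate Gaussian data with complete cases and a correctly
specified sparse truth. Real questionnaire data are ordinal,
incomplete, and not generated by any sparse GGM, so the calibration
results (specificity = 1 - alpha, shrinking heterogeneity bias in k)
are statements about the estimator under its own assumptions, not about
robustness to violations of them.

## Problem sizes used in the checks

The shipped tests and the acceptance script run desk-scale versions of
the simulation design: 8-node networks, 8 homogeneous datasets with 50
replications for the specificity calibration; 20 replications for the
heterogeneity-harm direction; 32 datasets with 3-5 replications for
the random-effects conditions. These sizes were chosen so each check is
a few minutes at most on one CPU while keeping Monte-Carlo error well
inside the tolerance it is compared against.

## Known limitations

- Case-level missing data are not supported; only study-level missing
  variables (in per-study random-effects estimation) are.
- Polychoric/Spearman input is not computed by the package; any
  correlation matrix can be supplied, but the likelihood treats it as
  Pearson from Gaussian data.
- Correlation input uses a single n per study; pairwise-complete
  matrices with very uneven coverage deserve a more careful effective-n
  choice than the package makes.
- Absolute AIC/BIC values depend on the additive likelihood constant;
  comparisons are meaningful within the package, not against other
  software to the digit.
- Random-effects estimation beyond ~16 nodes becomes expensive (the
  Cholesky block grows with the fourth power of p).
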