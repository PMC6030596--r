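---
title: "Phylogenetic mixed models for seabird field metabolic rate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic mixed models for seabird field metabolic rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seabirdFMR)
```

## The problem and the model

Field metabolic rate (FMR, kJ day⁻¹) has been measured — by doubly
labelled water, heart-rate logging or time–energy budgets — in only a few
dozen seabird species, almost always during breeding. Cross-species
syntheses of those records face two obstacles: the records are clustered
(several per species, several per colony), and species are not
independent data points, because close relatives resemble each other
through shared ancestry. `seabirdFMR` addresses both with a Bayesian
phylogenetic mixed model, a meta-analytic cousin of the quantitative
genetics "animal model":

$$\log \mathrm{FMR}_i = \mathbf{x}_i^\top\boldsymbol\beta
  + a_{sp(i)} + s_{sp(i)} + c_{col(i)} + e_i,$$

with fixed effects drawn from {intercept, log mass, breeding phase
(incubation / brood / crèche, brood as baseline), absolute latitude,
species average brood size, colony-relative predation pressure}, and four
variance components: a phylogenetic species effect
$\mathbf{a}\sim N(0,\sigma^2_{phylo}A)$, an independent species effect
$\mathbf{s}\sim N(0,\sigma^2_{species}I)$ (the two share the species
grouping but have different correlation structure), a colony effect, and
a residual. $A$ is the Brownian-motion expectation: the shared
root-to-common-ancestor path length of each species pair, scaled by the
maximum root-to-tip depth so the diagonal is 1.

Phylogenetic heritability
$H^2 = \sigma^2_{phylo} / (\sigma^2_{phylo} + \sigma^2_{species} +
\sigma^2_{colony} + \sigma^2_{resid})$ indexes how much of the random
variation is attributable to phylogeny. Fixed-effect variance is
excluded from the denominator: $H^2$ is defined here as a share of the
*random* variance. Including the fixed-effect variance would be a
defensible alternative definition; it would shrink every reported $H^2$
and is not what "proportion of variance associated with the random effect
of phylogeny" most naturally reads as.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `log_base` | 10 | base of all log transforms; configurable to `exp(1)`; recorded in every fit. The source analyses do not state a base; base 10 gives back-transformed FMR magnitudes consistent with published coefficient tables (intercept ≈ 0.92 → ~8 kJ/day for a hypothetical 1 g bird, slope 0.64 per mass decade). |
| `fixed_effect_prior_var` | 1e8 | variance of the independent N(0, ·) coefficient priors — effectively flat on the scale of log₁₀ FMR. |
| `re_scale`, `re_df` | 1, 1 | inner inverse-Gamma (scale, df) of each random-effect variance under parameter expansion. |
| `expansion_mean`, `expansion_var` | 0, 625 | Gaussian prior on the working expansion scalar. Together with the inner IG(½, ½) this induces a half-Cauchy prior with scale 25 on each random-effect standard deviation — the conventional parameter-expanded choice. The source analyses state only that parameter-expanding priors were used, not their constants; these defaults are documented as conventional, not as reconstructed values. |
| `residual_scale`, `residual_df` | 1, 0.002 | weak inverse-Gamma IG(0.001, 0.001) on the residual variance. `residual_fixed` holds it at a known value (used by the closed-form oracle tests). |
| chain schedule | 260 000 / 60 000 / 200 | iterations / burn-in / thinning of the compiled analysis, retaining exactly 1000 draws; diagnostics and jackknife refits default to the reduced 26 000 / 6 000 / 20 schedule. |

## The sampler

Each Gibbs sweep updates, in a fixed order: the fixed effects (joint
Gaussian conditional); for each random term its effect vector (Gaussian
conditional; the phylogeny term uses the $A^{-1}$-structured precision)
followed by its working expansion scalar (a scalar Gaussian regression
update — effects are stored as $\alpha\cdot\boldsymbol\eta$ and the
reported variance component is $\alpha^2\sigma^2_\eta$); then each inner
variance and the residual variance (inverse-Gamma conditionals). One RNG
stream drives the whole chain, so a seed fully determines the output
byte-for-byte. The conditional deviance
$-2\log N(\mathbf{y}\mid X\boldsymbol\beta + \sum Z\mathbf{u},
\sigma^2_{resid}I)$ is recorded at each retained draw; DIC uses
$\bar D + p_D$ with $p_D = \bar D - D(\text{posterior means})$. The
deviance is *conditional* on the realized random effects (the marginal
alternative integrates them out); which one the original analysis used is
unknowable from the text, so the conditional form — what its software
reports by default — is the default here and is what the DIC tests
exercise.

The sweep is implemented in C++ (RcppArmadillo) for throughput; the
reference implementations in this field are likewise compiled. Its
correctness is established by tests rather than trust: exact-conjugate
models (known residual variance; no random terms) where the draws are iid
from a closed-form posterior; the ordinary-least-squares limit; and a
2-D grid-integration oracle for the phylogeny-plus-residual model, where
the fixed effects are integrated out analytically and the induced
half-Cauchy prior density is used exactly — the sampler's posterior
means of both variances and of $H^2$ match the grid to within a few
percent.

## Numerical choices

- **HPD intervals** are the shortest contiguous window of the sorted
  draws containing `ceiling(prob * n)` draws, ties broken by the lowest
  start index, so results are bit-stable. The primitive accepts any
  sample of ≥ 2 draws (its worked specification example uses 5);
  posterior summaries always pass 1000.
- **pMCMC** is `2·min(frac > 0, frac < 0)`, floored at `2/n`, capped at
  1 — a printed "<0.001" corresponds to the floor.
- **Non-ultrametric trees**: $A$ is scaled by the maximum root-to-tip
  depth and its diagonal then forced to 1 (equivalent to rescaling
  tip-specific terminal variance), with a warning recording the largest
  pre-adjustment deviation. Published supertrees are ultrametric; this
  path only guards degraded inputs.
- **Ridge**: `1e-8` is added to the diagonal of $A$ before factorization,
  reported via `message()`.
- **Species/colony matching** trims whitespace, collapses internal runs
  to `_`, and compares case-insensitively.
- **Prediction point estimate** is the back-transform of the mean linear
  predictor (a median-style estimate on the response scale). The
  log-normal mean would add half the predictive variance; that choice
  would entangle the point estimate with the interval mode, so it was
  not taken. Intervals are HPD over back-transformed per-draw
  predictions; consequently the point is not guaranteed to sit inside a
  skewed interval, though in practice it does.
- **New-species queries** have no estimated random effect; the default
  interval is confidence-style (fixed-effect uncertainty only). If the
  queried species matches a fitted level its posterior phylogenetic +
  species effect draws are added; `include_random_variance = TRUE` adds
  a per-draw Gaussian perturbation with the summed remaining variance
  components, giving a predictive interval. Whether the deployed
  calculator app reports confidence or predictive intervals is not
  stated anywhere; both modes are provided and labelled, neither claimed
  as "the" app's.
- **Jackknife** deletes one *record* (not one species or study) per
  refit — the finest deletion unit, and the only one that does not
  require deciding how to aggregate multi-record deletions. Study-level
  identity is carried in the data model but not modelled by default,
  since only phylogeny, species and colony random effects are attested.

## What the synthetic generator emulates — and what it does not

`simulate_observations()` draws data from *exactly* the model above:
coalescent-style ultrametric trees scaled to unit depth; record masses
log-uniform on [50 g, 10 kg]; colony latitudes uniform on [−75°, 75°];
phases uniform; species brood sizes in {1, 2, 3}; colony breeding-pair
counts log-uniform on [10², 10⁶]; one species per colony.
`paper_shaped_dataset()` fixes the shape to the published compilation
(98 records, 47 species, 64 study labels) with true coefficients at the
published posterior means and a low-signal variance regime
(σ² = 0.0015 / 0.008 / 0.005 / 0.028, so the plug-in truth
H² = 0.035 and total scatter ≈ ±25% around the allometry — a level
chosen once as field-plausible, since the compilation's variances are
not printed anywhere).

Real compilations violate these conventions in ways that matter for
interpretation: masses are species-clustered (here they are independent
per record, as specified, which makes the mass slope *easier* to separate
from species effects than in real data); colonies host multiple species;
records from one study share methodology (study identity is carried but
not modelled); and real trees are not coalescent draws. A green
parameter-recovery test therefore establishes sampler correctness under
the model's own assumptions — not robustness to model misspecification.

## Known limitations

- The low-signal $H^2$ regime exposes an honest limitation: with only 47
  species, a heavy-tailed parameter-expanded prior and coalescent trees
  (whose large average correlations make the phylogenetic variance
  partially confounded with the intercept), the marginal posterior of
  $\sigma^2_{phylo}$ has a fat right tail, so the posterior *mean* of
  $H^2$ sits well above a truth of 0.035 even though the posterior mode
  is near zero. The grid-integration oracle reproduces the same
  posterior mean, confirming this is a property of the model-prior-data
  triple, not of the sampler. One acceptance criterion asserts a mean
  posterior $H^2 < 0.15$ in this regime; it fails at ≈ 0.18 and is left
  failing, because the generator and priors are the stated world and the
  sampler is demonstrably correct against the oracle.
- Single-tree input only; no posterior tree samples, no tree inference,
  no downloads.
- Gaussian response only; no marginalized-deviance DIC, no WAIC/LOO.
- The CLI is a library surface plus a launcher script; there is no web
  UI.
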