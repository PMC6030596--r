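# seabirdFMR

Bayesian phylogenetic meta-analysis and prediction of **field metabolic
rate (FMR)** in breeding seabirds.

FMR — the total energy a free-ranging bird metabolizes per day (kJ day⁻¹)
— is a key quantity for seabird ecology and conservation, but it has been
measured in only a fraction of species and populations. This package is
for ecologists who want to (a) analyse literature-compiled FMR records
across species while accounting for shared ancestry, and (b) predict FMR
with uncertainty for populations where it has never been measured.

## The model

Log-transformed FMR is modelled as a Gaussian response in a phylogenetic
mixed model:

```
log FMR_i = β₀ + β_m · log(mass_i) + β_phase(i) + β_lat · |lat_i| [+ β_b · brood_i + β_r · logRPP_i]
            + a_{sp(i)} + s_{sp(i)} + c_{col(i)} + e_i

a ~ N(0, σ²_phylo · A)    s ~ N(0, σ²_species I)
c ~ N(0, σ²_colony I)     e ~ N(0, σ²_resid I)
```

where `A` is the Brownian-motion correlation matrix derived from a
phylogeny (shared root-to-ancestor path length, scaled to unit diagonal),
the breeding-phase factor has levels incubation / brood / crèche with
brood as baseline, and `logRPP = log(pairs · mass^(2/3))` is
colony-relative predation pressure. Fitting is by a Gibbs sampler with
**parameter-expanded priors** on the random-effect variances (inducing
heavy-tailed half-Cauchy-style priors on the effect standard deviations).
The package provides DIC model selection, highest-posterior-density (HPD)
intervals, pMCMC statistics, phylogenetic heritability
`H² = σ²_phylo / (σ²_phylo + σ²_species + σ²_colony + σ²_resid)`,
jackknife resampling, a synthetic-data generator with known ground truth,
and the prediction engine behind an FMR-calculator-style interface.

## Worked example

```r
library(seabirdFMR)

# a compilation-shaped synthetic dataset: 98 records, 47 species, 64 studies
sim  <- paper_shaped_dataset(seed = 42)
A    <- tree_to_correlation(sim$tree)
spec <- model_spec(fixed = c("log_mass", "phase", "abs_latitude"),
                   chain = chain_config(26000, 6000, 20, seed = 42))
fit  <- gibbs_fit(build_design(sim$observations, spec, A = A))
summarize_fit(fit)
```

```
Posterior summary (log base 10 )
           effect estimate lower_95 upper_95 p_mcmc
        intercept  0.92100  0.70700  1.13000  0.002
         log_mass  0.63600  0.58200  0.68900  0.002
 phase_incubation -0.05350 -0.15300  0.03090  0.244
     phase_creche  0.08650 -0.00920  0.18100  0.074
     abs_latitude  0.00384  0.00185  0.00545  0.002
variance components: phylogeny=0.005919, species=0.002499, colony=0.002583, residual=0.03204
phylogenetic heritability H2: mean = 0.119; s.d. = 0.117
DIC = -41.69 (pD = 18.58)
retained draws: 1000
```

The generator's true coefficients are 0.92 / 0.64 / −0.071 / 0.068 /
0.0048, so the fit recovers the allometric slope (0.636, HPD 0.582–0.689)
and latitude effect; the phase contrasts are small relative to one
replicate's noise, which the wide HPDs make visible. `p_mcmc = 0.002` is
the floor `2/n` at 1000 retained draws.

```r
predict_fmr(fit, species = "Pygoscelis adeliae", mass_g = 4000,
            latitude_deg = -65, phase = "creche")
```

```
FMR estimate: 3515.4 kJ/day (95% HPD 2556.0 - 4629.6)
  log base 10; fixed_effects; 95% HPD on the kJ/day scale
```

A 4 kg bird crèche-rearing at 65° S is estimated to spend ~3500 kJ/day;
the species is new to the model, so the interval reflects fixed-effect
uncertainty only (`mode = "fixed_effects"`; pass
`include_random_variance = TRUE` for a predictive interval, or a fitted
species name for its conditional effects).

The same pipeline is scriptable:

```sh
Rscript inst/cli/seabird-fmr simulate --paper-shaped --seed 1 --out-dir runs/sim
Rscript inst/cli/seabird-fmr fit --data runs/sim/data.csv --tree runs/sim/tree.nwk \
    --seed 1 --out-dir runs/fit
Rscript inst/cli/seabird-fmr predict --posterior runs/fit/posterior \
    --mass 4000 --latitude -65 --phase creche --out-dir runs/pred
```

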