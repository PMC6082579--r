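# fptrecruit

Diffusion-limited recruitment of DNA-repair proteins to the nucleus,
modelled as a first-passage-time (FPT) problem: a protein produced at
radius *r₀* diffuses (diffusion coefficient *D*) between a reflecting cell
membrane at *R* = 25 µm and an absorbing nuclear surface at *rₐ* = 5 µm.
The package provides

* the closed-form Laplace transform of the FPT density, its short-time
  (Lévy) and long-time (exponential) asymptotics, and the exact mean FPT;
* numerical Laplace inversion (fixed Talbot, Gaver–Stehfest cross-check)
  for the intermediate-time regime;
* a lattice kinetic Monte Carlo simulator (Rcpp core, fully seeded);
* recruitment curves averaged over a truncated-Gaussian distribution of
  starting radii;
* least-squares inference of the mean starting radius from observed
  curves (`fit_start_mean()`, a classed fit object with `print`,
  `summary`, `coef`, `predict`, `plot` and `residuals` methods), plus a
  bootstrap comparison of two proteins;
* a synthetic-data generator with ground truth, CSV/YAML/JSON I/O and a
  manifest-writing pipeline (`run_pipeline()`, CLI in `inst/cli/`).

Default parameter sets describe the MRN-complex proteins NBS1
(*D* = 2.5 µm²/s, start radii 14–20 µm) and MRE11 (*D* = 2.0 µm²/s,
11–17 µm); the model explains how NBS1 can arrive at damage sites more
slowly than MRE11 despite diffusing faster — it starts farther out.

## Worked example

```r
library(fptrecruit)

nbs1 <- protein_defaults("NBS1")
nbs1
#> Protein NBS1: D = 2.5 um^2/s, start radius 17 um (range 14-20 um)

mfpt(17, nbs1$D)   # exact mean first-passage time, seconds
#> [1] 276.5176

# synthetic "experiment" with known ground truth, then recover it
synth <- generate_curve(synthetic_spec(nbs1, true_mean = 17, seed = 11))
synth$curve
#> Recruitment curve (synthetic): 121 points, t in [0, 600] s, final fraction 0.9349

fit <- fit_start_mean(synth$curve, nbs1)
fit
#> Starting-radius fit (NBS1, analytic model): mean r0 = 17.25 um (SSE 0.04253, 121 points)
coef(fit)
#> r0_mean_um
#>      17.25

# the two-protein comparison
mre11 <- protein_defaults("MRE11")
fit2 <- fit_start_mean(
  generate_curve(synthetic_spec(mre11, true_mean = 14, seed = 12))$curve,
  mre11)
compare_proteins(fit, fit2, seed = 3)
#> Fitted mean starting radii: NBS1 17.25 um vs MRE11 14.00 um
#>   difference +3.25 um (bootstrap 95% CI 2.75 to 3.75, SE 0.25)
#>   faster-diffusing protein has the larger starting radius: TRUE

# kinetic Monte Carlo cross-check of the analytic mean
lat <- lattice_preset("coarse", D = nbs1$D)
lat
#> kMC lattice: 500 x 500 x 450 units of 100 x 100 x 100 nm, dt = 0.0006667 s (D = 2.5 um^2/s)
ens <- run_ensemble(nbs1, lat, n_replicas = 300, horizon = 1800,
                    base_seed = 1017, start_mode = "fixed", r0 = 17)
ens
#> FPT ensemble: 300 replicas (NBS1), horizon 1800 s, censored 0.00%
#>   mean uncensored FPT: 267.0 s
```

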