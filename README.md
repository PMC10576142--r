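# excat

Conformational exchange thermodynamics and catalytic-cycle kinetics
from methyl multiple-quantum CPMG relaxation dispersion.

Sparsely populated protein conformations — invisible to crystallography
— often carry the decisive steps of catalysis: substrate capture,
product release, inhibitor escape.  Methyl-TROSY MQ-CPMG relaxation
dispersion measures these states through the dependence of the
effective transverse relaxation rate on the refocusing-pulse frequency,
`R2,eff(nu_CPMG)`.  `excat` turns such data into a quantitative,
conformation-resolved model of an enzyme's catalytic cycle, developed
around the deacetylase HDAC8:

1. **Exchange layer.**  Global fits of dispersion profiles across
   static fields and temperatures to 2-site and 3-site (linear or
   bifurcated) exchange models with Eyring temperature dependence,

   `k_i->j = (kB*T/h) * exp(-(dH_ts - dH_i - T*(dS_ts - dS_i))/(R*T))`,

   yielding state populations `p_A, p_B, p_C`, exchange rates `k_ex`,
   and per-methyl `|dw(13C)|`; topology comparison by F-test and
   uncertainties by Monte Carlo resampling.

2. **Catalysis layer.**  A 93-state kinetic model — 18 internal
   conformations (L1 x L2,6 x CAT regions) for each of the five
   enzymatic species {E, ES, EPlysPace, EPace, EPlys}, plus S, Plys,
   Pace — with detailed-balanced, population-weighted binding edges,
   hydrolysis restricted to the all-bound conformation, and
   conformation-gated product/inhibitor release.  Stiff ODE integration
   (compiled RHS/Jacobian) yields progress curves, `v0 = d[Plys]/dt`,
   Michaelis-Menten `kcat` and `KM`, inhibitor `Kd` and the macroscopic
   off-rate (inverse residence time).  Candidate binding/release
   models are enumerated, fitted globally for
   {k_on, k_off_I, k_off_S = k_off_P, k_H} against multi-variant
   constraints, ranked by chi-squared, and cross-validated on a
   held-out mutant.

A synthetic-data module generates noisy multi-field/multi-temperature
CPMG datasets and "virtual mutants" from known ground truths, so the
entire pipeline is testable without downloads.

## Worked example

Simulate a two-site region on the default acquisition grid (14.1 and
18.8 T; 278, 288, 298 K), fit it back, and inspect the exchange
parameters:

```r
library(excat)

truth <- thermo_from_pop_kex(exchange_topology("two_site"),
                             p_minor = c(B = 0.05), kex = c("A-B" = 800))
ds  <- generate_cpmg_dataset(truth, n_methyls = 6, noise_frac = 0.02,
                             seed = 1)
fit <- fit_region(ds, exchange_topology("two_site"))
fit
#> Region fit: two_site
#>   chi2 = 385.7, dof = 386, chi2_red = 0.9992
#>   populations at 298 K: A=0.9501 B=0.0499
```

The minor-state population (true value 5%) and exchange rate (true
800 s^-1) are recovered within a few percent at 2% noise.  Pushing
intrinsic rates into the catalytic layer:

```r
tr <- synthetic_truth()           # full 3-region ground truth + cycle model
mm <- michaelis_menten(tr$space, tr$spec, tr$rates, tr$params,
                       assay_design(S_grid = c(0, exp(seq(log(1e-4), log(0.25),
                                                          length.out = 12))),
                                    n_t = 4000))
round(c(kcat = mm$kcat, KM_mM = mm$KM * 1e3), 3)
#>   kcat  KM_mM
#>  0.905 53.800
io <- inhibitor_observables(tr$space, tr$spec, tr$rates, tr$params)
round(c(Kd_uM = io$kd * 1e6, koff_macro = io$koff_macro), 3)
#> Kd_uM koff_macro
#> 32.172      0.096
```

`kcat` is below the microscopic hydrolysis rate (2 s^-1) because the
hydrolysis-competent conformation is only partially populated, and the
macroscopic inhibitor off-rate (0.096 s^-1) is ~1000-fold slower than
the microscopic one (100 s^-1): conformational gating controls the
residence time.  `hdac8_standin_inputs()` loads the packaged HDAC8
case-study tables (main-text constraint values plus a clearly labelled
synthetic stand-in for the unpublished exchange thermodynamics), and
`fit_global(model1_spec(space), ...)` reproduces the headline analysis
on them.

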