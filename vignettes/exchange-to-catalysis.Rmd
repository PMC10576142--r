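---
title: "From methyl CPMG dispersions to a conformation-resolved catalytic cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From methyl CPMG dispersions to a conformation-resolved catalytic cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excat)
```

## The scientific problem

Enzymes are not static: sparsely populated conformations that never show
up in crystal structures can carry the functionally decisive steps —
substrate capture, product release, inhibitor escape.  Methyl-TROSY
multiple-quantum (MQ) CPMG relaxation dispersion detects exactly these
states: it measures, per methyl group, the effective transverse
relaxation rate R2,eff as a function of the refocusing-pulse frequency
of a constant-time pulse train, and the shape of that dispersion encodes
the populations, exchange rates and chemical-shift differences of
conformations interconverting on the millisecond time scale.

`excat` implements a two-layer analysis for the deacetylase HDAC8 and
systems like it:

1. **Exchange layer** — globally fit MQ-CPMG dispersions acquired at
   several static fields and temperatures to two- or three-site exchange
   models with Eyring temperature dependence, yielding per-region state
   populations and microscopic rate constants at any temperature.
2. **Catalysis layer** — embed those intrinsic rates in a 93-state
   kinetic model of the full catalytic cycle, in which substrate
   binding, hydrolysis and product release are only possible from
   specific conformations, and predict macroscopic observables: k_cat,
   K_M, inhibitor K_d and the macroscopic inhibitor off-rate (the
   inverse residence time).

The bridge between the layers is the hypothesis that *intrinsic
conformational dynamics dictate catalysis*: a mutation changes the
populations and exchange rates of the conformations, and those changes
alone should account for the altered activity and inhibitor potency.

## The exchange layer

### Model

Each dynamic region (the loop clusters L1 and L2,6, and the catalytic
region CAT) samples 2 or 3 states: `A` (major) and minor states `B`,
`C`, connected either in a chain (linear, A&#8652;B&#8652;C) or with
both minors exchanging directly with the major state (bifurcated,
B&#8652;A&#8652;C).  Thermodynamics are parameterised by state
enthalpies/entropies relative to A and one transition-state
enthalpy/entropy per edge, so that populations follow the Boltzmann
distribution and rates follow the Eyring equation

$$k_{i \to j} = \kappa\,\frac{k_B T}{h}\,
  \exp\!\left(-\frac{(\Delta H^\ddagger - \Delta H_i)
  - T (\Delta S^\ddagger - \Delta S_i)}{R T}\right),$$

with transmission coefficient $\kappa = 1$ and CODATA-2018 constants.
Temperatures are taken in Kelvin exactly as given (298 K means
298.00 K; using 298.15 K instead shifts the prefactor by ~0.05%).
Because both rates of an edge share one transition state, detailed
balance $p_i k_{i\to j} = p_j k_{j \to i}$ holds by construction.
Enthalpies and entropies are temperature independent (no heat-capacity
term), which makes $\ln(p_B/p_A)$ affine in $1/T$ — the van't Hoff
behaviour the multi-temperature data constrain.

### Forward model for MQ-CPMG

The MQ experiment evolves zero- and double-quantum coherences, whose
per-state amplitudes propagate under
$K - R_2^{MQ} I - i\,\mathrm{diag}(\omega_H \mp \omega_C)$ where $K$ is
the exchange generator and $\omega_H$, $\omega_C$ are the 1H/13C
offsets of each state in rad/s at the given field.  Each 13C
180&deg; pulse interchanges ZQ and DQ; the single 1H 180&deg; pulse at
the centre of the constant-time train conjugates the amplitudes.  The
propagation is numerical — matrix exponentials per free-precession
delay with explicit interchange operators — because the three-site
topologies have no standard closed form.  Two properties anchor its
correctness in the tests:

* with the 1H offsets set to zero it reduces exactly to single-quantum
  13C CPMG, and matches an independently coded exact two-site closed
  form (cycle-matrix eigenvalues via the quadratic formula) to ~1e-13;
* the classic Carver–Richards closed form is reproduced within 1% in
  the intermediate-to-fast exchange regime.  Note that Carver–Richards
  is itself an approximation whose error grows to several percent at
  low pulse numbers in slow exchange (a documented property of the
  formula, reproduced by our exact reference); comparisons against it
  are therefore made in its validity regime, while the exact closed
  form covers the full regime.

The pulse train accommodates $n = 2\,T_{relax}\,\nu_{CPMG}$ refocusing
pulses; $n$ must be an even integer, so requested frequencies snap to
the nearest realizable value $n/(2 T_{relax})$ (with the default 30 ms
constant-time element, the lowest realizable frequency is 33.3 Hz).
Intensities convert to rates as
$R_{2,eff}(\nu) = -\ln(I_\nu / I_0)/T_{relax}$; non-positive
intensities are flagged as missing rather than failing a dataset.

The 1H offsets are fixed at 0.01 ppm.  Their residual contribution to
the dispersion is bounded by the fast-limit exchange broadening
$p_A p_B (\gamma_H/\gamma_C \cdot \Delta\omega_H)^2 / k_{ex}$
(~0.1 s^-1 under study conditions), which is below 0.5% of the
dispersion amplitude Rex; this is asserted in the tests.  MQ data carry
no sign information, so only $|\Delta\omega_C|$ is reported and stored.

### Global fitting

`fit_region()` fits all methyls of a region, across all fields and
temperatures, to a single thermodynamic model plus per-methyl
$|\Delta\omega_C|$ (shared across temperatures — shift differences are
assumed temperature independent).  Internally the thermodynamics are
parameterised as free energies at 298 K plus enthalpies, which turns
the identifiability guardrails (minor populations in [1e-4, 0.45],
$|\Delta\omega| \le 10$ ppm) into box bounds; exchange rates are kept
in [1, 1e5] s^-1 at all fitted temperatures by a soft penalty.  The
per-(methyl, field, temperature) intrinsic rate r2_mq0 enters R2,eff
*additively and exactly* (it commutes with the propagation), so it is
profiled out analytically at every objective evaluation — this removes
dozens of nuisance parameters from the optimizer — but still counts
against the degrees of freedom.

CPMG objectives are multimodal, so optimization is multi-start
(Levenberg–Marquardt from a grid over exchange rates
{100, 300, 1000, 3000} s^-1 and minor populations {0.01, 0.05, 0.15},
entropy seeds 0), keeping the best converged start.  The start list is
ordered so that truncated prefixes still span the rate grid.  Minor
states are relabelled after fitting so that $p_B \ge p_C$ at 298 K; for
the linear topology this relabelling flips which state sits in the
middle of the chain, so both middle assignments are effectively
explored.

Topologies are compared with the F statistic
$F = \frac{(\chi^2_a - \chi^2_b)/(dof_a - dof_b)}{\chi^2_b / dof_b}$
for the nested pair, and parameter uncertainties come from Monte Carlo
resampling: synthetic datasets drawn from the best-fit curves plus
Gaussian noise at the reported per-point sigma are refit and the
standard deviations of the refitted parameters reported.  Per-point
sigma, when not supplied, defaults to a 2% fractional noise floor.

## The catalysis layer

### The 93-state space

The enzyme's internal conformation is the direct product of the three
regions — 3 (L1) x 3 (L2,6) x 2 (CAT) = 18 conformations — and the
cycle involves five enzymatic species: free enzyme E, substrate-bound
ES, double-product EPlysPace, and the single-product species EPace and
EPlys.  With free substrate S and the two products Plys and Pace this
gives 5 x 18 + 3 = 93 states, indexed blockwise (E 1–18, ES 19–36,
EPlysPace 37–54, EPace 55–72, EPlys 73–90, then S, Plys, Pace).

Conformations are labelled *functionally* (bound-like, free-like,
release) rather than by the manifold-specific A/B/C letters, because
the shift-correlation analysis identifies the major state of the free
enzyme with a minor state of the inhibitor-bound enzyme and vice versa.
E and EPace sample the free-enzyme intrinsic dynamics; ES, EPlysPace
and EPlys sample the ligand-bound dynamics.  Region motions are assumed
uncorrelated, so the 18-conformation generator of each species is the
Kronecker sum of the three region generators and the conformational
populations are products of the region populations.

### Edges and detailed balance

A kinetic model specification declares which conformations carry which
edges:

* **substrate/inhibitor association and dissociation** through (usually
  two) binding-competent conformations, with association into site $i$
  weighted by $p(ES_i)/\sum_j p(ES_j)$ and dissociation by
  $p(E_i)/\sum_j p(E_j)$ — this weighting makes every binding edge
  individually satisfy detailed balance at equilibrium, which the tests
  verify to 1e-9 relative on every edge of the equilibrated network;
* **hydrolysis** (ES &rarr; EPlysPace), first order with rate k_H, only
  from the single conformation with all regions bound-like and CAT in
  state A; in D2O, k_H is divided by the solvent kinetic isotope effect
  factor 8.8 (consumed as a constant);
* **acetate release** from all conformations with L1 in the release
  state, fixed at the diffusion limit 1e6 s^-1;
* **lysine release** from the declared release conformation(s) with
  rate k_off_P (tied to k_off_S in the 4-parameter analysis).

Product release is irreversible (no rebinding terms): the cycle is
driven, and equilibrium-flux assertions apply to the binding-only
(k_H = 0) inhibitor network.

### Integration and observables

Progress curves are integrated with lsoda (automatic stiff/non-stiff
switching) with the right-hand side and the analytic Jacobian in
compiled code; rates span ~0.1–1e6 s^-1, so tolerances default to
rtol 1e-8, atol 1e-12 M.  Activity simulations start from the enzyme
distributed over the E conformations by their equilibrium populations;
the initial rate v0 = d[Plys]/dt is a linear regression over the
60–600 s window, repeated over a substrate grid (0 plus a log-spaced
series up to 250 mM, 50 points by default) and fit to the
Michaelis–Menten form.  The default time grid is 60,000 log-spaced
points between 1 us and 600 s; reducing it to a few thousand points
changes k_cat and K_M by well under 0.5% (asserted in the tests), so
the test-suite and the model-ranking scans use reduced grids, with the
documented default available for final numbers.

Inhibitor binding (k_H = 0) is equilibrated at E0 = I0 = 50 uM, giving
the macroscopic K_d = [E][I]/[EI] (sums over conformations); the
macroscopic off-rate is then obtained by removing free inhibitor and
disabling re-association (the infinite-dilution idealization of a
dilution experiment) and fitting total [EI](t) to a single exponential.
Because every binding edge is detailed-balanced, the equilibrium also
has a closed form, $K_d = (k_{off,I}/k_{on}) \cdot P_B/P_F$ with
$P_B$/$P_F$ the summed bound/free-manifold populations of the
binding-competent conformations, and the slow release mode is the
smallest eigenvalue of the gated 18 x 18 release generator.  These
closed forms are the `method = "steady"` fast path: they agree with the
ODE route to well under 1% (asserted) and make the large model-ranking
scans tractable.  Two consequences are worth noting: the macroscopic
K_d is a true equilibrium constant (invariant under concentration
changes), and the macroscopic off-rate can never exceed the
microscopic one — conformational gating only slows apparent release.

Small inner curve fits (the Michaelis–Menten hyperbola, the exponential
decay) use a deterministic damped Gauss–Newton with analytic Jacobians
rather than a packaged optimizer: they sit inside the outer
least-squares objective, so they must be smooth to machine precision
for the outer finite-difference Jacobians to be meaningful (and
minpack.lm's LM implementation keeps global C state, so it cannot be
nested).

### Model enumeration, global fitting and cross-validation

Candidate cycle models place the substrate sites (pairs of
conformations) and the lysine-release site; the default family over the
18-conformation manifold has choose(18,2) x 18 = 2754 members and
contains the two experimentally supported models: substrate enters
through (L1 bound-like, L2,6 release, CAT B) and (L1 bound-like, L2,6
free-like, CAT B), with lysine released from the L2,6 free-like
(model 1) or L2,6 release (model 2) member of the pair.  The published
count of candidate models (2,304) reflects additional feasibility
filters that are not spelled out; the enumeration scheme here is
configurable, documents its own count, and is required by the tests to
contain models 1 and 2 — the count itself is not enforced.

For each candidate, `fit_global()` fits {k_on, k_off_I,
k_off_S (= k_off_P), k_H} — optionally k_off_P free as a fifth
parameter, seeded from the 4-parameter optimum so the nested fit can
never end up worse — by bounded multi-start least squares in log space
against a constraint set of macroscopic observables across enzyme
variants, each variant carrying its own intrinsic rates.  Models are
ranked by chi-squared; because alternative models have equal dimension
(not nested), pairwise comparison uses a likelihood-ratio-style
$P = \Pr(\chi^2_{df} \ge \chi^2 - \chi^2_{best})$ with df = 1 by
default (configurable).  Cross-validation freezes the trained
parameters, swaps in the held-out variant's intrinsic rates, and
reports $\chi^2_{cv} = \sum_i (obs_i - calc_i)^2/\sigma_i^2$ over the
held-out observables and its reduced form (the squared form is used
throughout; a sum of unsquared residuals would not be a chi-squared).

## The synthetic-data generator

All tests run without external data.  `synthetic_truth()` fixes a
ground truth shaped like the study system — one two-site region and two
three-site regions per manifold, minor populations 1–15%, exchange
rates 100–3000 s^-1, and round global parameters (k_on 2e6 M^-1 s^-1,
k_off_S 2e5 s^-1, k_H 2 s^-1, k_off_I 100 s^-1) of the magnitudes
typical for a slow hydrolase with weak microscopic substrate affinity.
These defaults are the simulated study conditions; they are set once
and are not tuned per test.  `generate_cpmg_dataset()` forward-models
dispersion profiles on the default acquisition grid (14.1 and 18.8 T;
278, 288, 298 K; 30 ms constant time; approximately log-spaced
realizable frequencies from 33.3 Hz to 1 kHz — denser sampling at low
pulsing rates is what identifies slowly exchanging terminal states of
the linear topology, whose populations are otherwise degenerate with
their shift differences) and adds
i.i.d. Gaussian noise on R2,eff (2% by default) with a truthful sigma
column.  `generate_virtual_variant()` perturbs state free energies
through the enthalpies (so the shift applies at all temperatures),
rebuilds the rates, and produces noisy macroscopic observables through
the catalysis layer — the virtual mutants for model selection and
cross-validation.

What the generator does *not* emulate: peak overlap and lineshape
fitting, field-dependent intrinsic relaxation, temperature-dependent
shift differences, correlated noise between CPMG points, and any
structural realism in which conformations a mutation perturbs.  Passing
recovery tests therefore demonstrate the estimators are consistent and
correctly implemented under the stated noise model, not that real data
of this quality will constrain every parameter equally well.

## The HDAC8 stand-in case study

`hdac8_standin_inputs()` ships the case-study inputs.  The constraint
tables are assembled from printed values (k_cat = 0.90 s^-1 for
wild-type in H2O; the H2O/D2O activity ratio 6.2; relative activities
of 7% for L179A and 3% for M274A, which with the M274A specific
activity of 1.2 M^-1 s^-1 give a wild-type k_cat/K_M of ~40 M^-1 s^-1
and K_M ~ 22.5 mM; inhibitor K_d of 5, 110 and 116 uM and macroscopic
off-rates 0.13, 0.19 and 1.19 s^-1 for WT, L179A and M274A).  The
thermodynamic table is a *synthetic stand-in*: only the minor-state
populations printed in the main text are calibrated (CAT 6.6% free /
1.4% bound; the L2,6 population changes across variants), the exchange
rates and L1 populations are fixed once at round millisecond-regime
values, and the unprinted mutant bound-manifold populations are
propagated from the free manifold by applying the same per-state
free-energy shift in both manifolds (a mutation destabilises a physical
conformational state wherever it occurs).

With these inputs the model-1 global fit reproduces every activity
constraint essentially exactly (fitted k_H within a few percent of the
published 2.04 s^-1) and places K_d and the macroscopic off-rates at
the right order of magnitude with the right direction of change across
variants.  It does **not** reproduce the published reduced chi-squared
(~1.11) or the off-rate values quantitatively: those depend on the
exchange-rate values and mutant bound-manifold thermodynamics, which
have no publicly printed values that could be bundled here.  The acceptance checks report these quantities as
computed and the discrepancy is documented rather than absorbed into
tolerances.

## Numerical choices and limitations

* Problem sizes in the test-suite are scaled for a single CPU: regional
  fits use 2–6 methyls, 8–15 CPMG frequencies and truncated multi-start
  prefixes; ranking scans use the steady-state fast path with warm
  starts across seeds and a reduced substrate grid, with the full-sized
  defaults available through the exported functions.
* The steady-state activity route assumes negligible substrate
  depletion over the v0 window; the analytic-limit tests choose enzyme
  concentrations accordingly, and the ODE route remains the reference.
* Label assignment of fitted minor states to functional conformations
  follows the population ordering (p_B >= p_C); with well-separated
  minor populations this matches the shift-correlation assignment, but
  for nearly degenerate minors the mapping is not identifiable from
  dispersions alone.
* The F-test for topology comparison treats the profiled r2_mq0
  offsets as ordinary parameters in the dof count; with few points per
  curve this is mildly anticonservative.
* Monte Carlo uncertainty estimation refits from the best-fit start
  only; for strongly multimodal posteriors this underestimates the
  spread relative to a full multi-start per replicate.
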