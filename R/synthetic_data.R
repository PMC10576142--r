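#' Default synthetic ground truth
#'
#' A complete, fully-specified system resembling a three-region enzyme
#' with millisecond dynamics: one two-site region (CAT-like) and two
#' three-site loop regions, in both a free and a ligand-bound manifold,
#' plus a kinetic model (two substrate-binding conformations, one
#' lysine-release conformation) and global microkinetic parameters.
#' Minor-state populations are in the 1-15% range and exchange rates in
#' the 100-3000 s^-1 range; the global parameters are round values of
#' the magnitudes typical for a slow hydrolase with weak microscopic
#' substrate affinity.  These defaults define the simulated study
#' conditions used throughout the test-suite and are not tuned per run.
#'
#' @param dispersion_noise fractional Gaussian noise on R2,eff.
#' @param observable_noise fractional Gaussian noise on macroscopic
#'   observables.
#' @return list of class `synthetic_truth` with elements `space`,
#'   `rates` (a [region_rate_set()]), `spec`, `params`, `design`,
#'   `noise`.
#' @export
synthetic_truth <- function(dispersion_noise = 0.02,
                            observable_noise = 0.05) {
  topo2 <- exchange_topology("two_site")
  topob <- exchange_topology("bifurcated_three_site")
  topol <- exchange_topology("linear_three_site")
  free <- list(
    L1 = thermo_from_pop_kex(topob, c(B = 0.04, C = 0.03),
                             c("A-B" = 800, "A-C" = 300),
                             dH_state = c(B = 40, C = 25)),
    L26 = thermo_from_pop_kex(topob, c(B = 0.10, C = 0.05),
                              c("A-B" = 1500, "A-C" = 400),
                              dH_state = c(B = 35, C = 20)),
    CAT = thermo_from_pop_kex(topo2, c(B = 0.066), c("A-B" = 1200),
                              dH_state = c(B = 30)))
  bound <- list(
    L1 = thermo_from_pop_kex(topol, c(B = 0.06, C = 0.03),
                             c("A-B" = 900, "B-C" = 250),
                             dH_state = c(B = 35, C = 25)),
    L26 = thermo_from_pop_kex(topol, c(B = 0.08, C = 0.04),
                              c("A-B" = 1100, "B-C" = 350),
                              dH_state = c(B = 30, C = 20)),
    CAT = thermo_from_pop_kex(topo2, c(B = 0.014), c("A-B" = 2000),
                              dH_state = c(B = 25)))
  space <- build_state_space()
  rates <- region_rate_set(free, bound)
  spec <- kinetic_model_spec(
    space,
    substrate_sites = c(conf_index(space, L1 = "boundlike",
                                   L26 = "release", CAT = "B"),
                        conf_index(space, L1 = "boundlike",
                                   L26 = "freelike", CAT = "B")),
    lysine_sites = conf_index(space, L1 = "boundlike", L26 = "freelike",
                              CAT = "B"))
  params <- kinetic_params(k_on = 2e6, k_off_S = 2e5, k_H = 2,
                           k_off_I = 100)
  structure(list(space = space, rates = rates, spec = spec,
                 params = params,
                 noise = list(dispersion = dispersion_noise,
                              observable = observable_noise)),
            class = "synthetic_truth")
}

#' Default multi-field, multi-temperature CPMG acquisition grid
#'
#' Two static fields (14.1 and 18.8 T), three temperatures (278, 288,
#' 298 K) and CPMG frequencies between 20 and 1000 Hz on the realizable
#' grid of a 30 ms constant-time element.  The default frequency list is
#' approximately log-spaced (denser at low pulsing rates, where slowly
#' exchanging sparse states leave their signature), as in practical
#' dispersion acquisition schemes.
#'
#' @param B0_T fields, Tesla.
#' @param temps_K temperatures, K.
#' @param nu_cpmg requested CPMG frequencies, Hz.
#' @param T_relax constant-time delay, s.
#' @return data frame of acquisition conditions plus attributes.
#' @export
cpmg_acquisition_grid <- function(B0_T = c(14.1, 18.8),
                                  temps_K = c(278, 288, 298),
                                  nu_cpmg = c(2, 4, 6, 8, 10, 14, 18,
                                              24, 32, 40, 50, 60) /
                                    (2 * T_relax),
                                  T_relax = 0.030) {
  g <- expand.grid(B0_T = B0_T, temp_K = temps_K)
  attr(g, "nu_cpmg") <- nu_cpmg
  attr(g, "T_relax") <- T_relax
  g
}

#' Generate a noisy synthetic CPMG dispersion dataset
#'
#' Forward-models dispersion profiles for `n_methyls` methyl groups
#' under a known exchange model across an acquisition grid and adds
#' i.i.d. Gaussian noise; the `sigma_s` column reports the true noise
#' SD.  Per-methyl |dw_C| are drawn uniformly (default 0.5-3 ppm) and
#' the per-condition intrinsic MQ rates uniformly in 8-20 s^-1, both
#' reproducibly from `seed`.
#'
#' @param model a [thermo_exchange_model()] (the exchange ground truth).
#' @param grid a [cpmg_acquisition_grid()].
#' @param n_methyls number of methyl probes.
#' @param dw_range range of |dw_C| to draw, ppm.
#' @param noise_frac fractional noise on R2,eff (sigma = frac * R2,eff).
#' @param region region label stored in the dataset.
#' @param dw_H fixed 1H offset, ppm.
#' @param seed RNG seed (generation is a pure function of it).
#' @return a [dispersion_dataset()] with attributes `dw_true` (ppm
#'   matrix) and `r2_mq0_true`.
#' @export
generate_cpmg_dataset <- function(model, grid = cpmg_acquisition_grid(),
                                  n_methyls = 6, dw_range = c(0.5, 3),
                                  noise_frac = 0.02, region = "R1",
                                  dw_H = 0.01, seed = 1) {
  stopifnot(inherits(model, "thermo_exchange_model"))
  set.seed(seed)
  minors <- setdiff(model$topology$states, "A")
  methyls <- sprintf("m%02d", seq_len(n_methyls))
  dw_true <- matrix(runif(n_methyls * length(minors), dw_range[1],
                          dw_range[2]),
                    n_methyls, length(minors),
                    dimnames = list(methyls, minors))
  r2_true <- matrix(runif(nrow(grid) * n_methyls, 8, 20),
                    n_methyls, nrow(grid),
                    dimnames = list(methyls, NULL))
  T_relax <- attr(grid, "T_relax")
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    des <- suppressMessages(cpmg_design(grid$B0_T[ci],
                                        attr(grid, "nu_cpmg"), T_relax))
    for (mi in seq_len(n_methyls)) {
      sp <- spin_system(setNames(dw_true[mi, ], minors), dw_H,
                        r2_mq0 = r2_true[mi, ci])
      crv <- mq_dispersion(sp, model, des, T_K = grid$temp_K[ci])
      sig <- pmax(noise_frac * crv$r2eff_s, 1e-6)
      noisy <- if (noise_frac > 0) crv$r2eff_s + rnorm(nrow(crv), 0, sig)
               else crv$r2eff_s
      rows[[length(rows) + 1]] <- data.frame(
        methyl_id = methyls[mi], region = region,
        B0_T = grid$B0_T[ci], temp_K = grid$temp_K[ci],
        nu_cpmg_Hz = crv$nu_cpmg_Hz, r2eff_s = noisy,
        sigma_s = if (noise_frac > 0) sig else rep(1, nrow(crv)))
    }
  }
  out <- dispersion_dataset(do.call(rbind, rows))
  attr(out, "dw_true") <- dw_true
  attr(out, "r2_mq0_true") <- r2_true
  out
}

#' Generate a virtual enzyme variant
#'
#' Perturbs the state free energies of the intrinsic exchange models
#' (via their enthalpies, so the shift applies at all temperatures),
#' rebuilds the intrinsic rates, pushes them through the catalytic
#' network with the ground-truth kinetic model and parameters, and
#' returns the perturbed rate set together with noisy macroscopic
#' observables (kcat, KM, kcat/KM, Kd, macroscopic inhibitor off-rate).
#'
#' @param truth a [synthetic_truth()].
#' @param ddG named list of perturbations, kJ/mol:
#'   `list(free = list(L26 = c(B = 5)), bound = ...)`; positive values
#'   destabilise the state.
#' @param variant variant label.
#' @param noise_frac fractional Gaussian noise on the observables (0 for
#'   noiseless truth values).
#' @param design an [assay_design()] for the activity simulation.
#' @param method forward method, `"steady"` (default) or `"ode"`.
#' @param seed RNG seed.
#' @return list with `rates` (perturbed [region_rate_set()]),
#'   `observables` (a [constraint_set()] data frame) and `truth_values`.
#' @export
generate_virtual_variant <- function(truth, ddG = list(), variant = "mut",
                                     noise_frac = truth$noise$observable,
                                     design = assay_design(
                                       S_grid = c(0, exp(seq(log(1e-4),
                                                             log(0.25),
                                                             length.out = 14))),
                                       n_t = 4000),
                                     method = "steady", seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  rates <- truth$rates
  for (man in names(ddG)) for (reg in names(ddG[[man]])) {
    m <- rates[[man]][[reg]]
    shift <- ddG[[man]][[reg]]
    for (s in names(shift)) {
      m$dH_state[s] <- m$dH_state[s] + shift[s]
      p <- state_populations(m, 298)
      if (any(p < 1e-6))
        warning("perturbation drives a population below 1e-6 in ",
                man, "/", reg)
    }
    rates[[man]][[reg]] <- m
  }
  mm <- michaelis_menten(truth$space, truth$spec, rates, truth$params,
                         design, method = method)
  io <- inhibitor_observables(truth$space, truth$spec, rates,
                              truth$params, method = method)
  tv <- c(kcat = mm$kcat, KM = mm$KM, kcat_over_KM = mm$kcat / mm$KM,
          kd = io$kd, koff_macro = io$koff_macro)
  noisy <- tv * (1 + noise_frac * rnorm(length(tv)))
  obs <- data.frame(variant = variant, solvent = "H2O",
                    observable = names(tv), value = unname(noisy),
                    sd = pmax(unname(abs(tv)) * max(noise_frac, 0.01),
                              1e-12))
  list(rates = rates, observables = constraint_set(obs), truth_values = tv)
}
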