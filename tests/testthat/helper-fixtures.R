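# shared fixtures, built in code; heavier objects are memoized per test
# run so independent test files can reuse them cheaply

fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, fx_cache)) assign(key, builder(), fx_cache)
  get(key, fx_cache)
}

fx_two_site <- function(pB = 0.05, kex = 800)
  thermo_from_pop_kex(exchange_topology("two_site"), c(B = pB),
                      c("A-B" = kex), dH_state = c(B = 30),
                      dH_ts = c("A-B" = 60))

fx_bifurcated <- function()
  thermo_from_pop_kex(exchange_topology("bifurcated_three_site"),
                      c(B = 0.08, C = 0.03), c("A-B" = 900, "A-C" = 350),
                      dH_state = c(B = 35, C = 20))

fx_degenerate_space <- function()
  build_state_space(list(L1 = "boundlike", L26 = "boundlike", CAT = "A"))

fx_degenerate_rates <- function()
  region_rate_set(free = list(L1 = NULL, L26 = NULL, CAT = NULL),
                  bound = list(L1 = NULL, L26 = NULL, CAT = NULL),
                  maps = list(free = NULL, bound = NULL))

fx_degenerate_spec <- function(space = fx_degenerate_space())
  kinetic_model_spec(space, substrate_sites = 1, lysine_sites = 1,
                     hydrolysis_site = 1, acetate_sites = 1)

fx_truth <- function() fx_memo("truth", function() synthetic_truth())

# small, fast 2-site dataset + fit reused by several files
fx_small_fit <- function() fx_memo("small_fit", function() {
  grid <- cpmg_acquisition_grid(B0_T = c(14.1, 18.8),
                                temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 1000,
                                              length.out = 10))
  ds <- generate_cpmg_dataset(fx_two_site(), grid, n_methyls = 3,
                              noise_frac = 0.02, seed = 42)
  list(data = ds, fit = fit_region(ds, exchange_topology("two_site"),
                                   n_starts = 4))
})
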