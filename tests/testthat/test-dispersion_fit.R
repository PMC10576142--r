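test_that("dataset validation rejects malformed tables", {
  ds <- as.data.frame(fx_small_fit()$data)
  expect_s3_class(dispersion_dataset(ds), "dispersion_dataset")
  expect_error(dispersion_dataset(ds[, -7]), "missing columns")
  bad <- ds; bad$sigma_s[3] <- -1
  expect_error(dispersion_dataset(bad), "positive")
  dup <- rbind(ds, ds[1, ])
  expect_error(dispersion_dataset(dup), "duplicate")
})

test_that("noiseless two-site data are fit to machine accuracy", {
  grid <- cpmg_acquisition_grid(temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 1000,
                                              length.out = 8))
  truth <- fx_two_site()
  ds <- generate_cpmg_dataset(truth, grid, n_methyls = 2, noise_frac = 0,
                              seed = 7)
  fit <- fit_region(ds, exchange_topology("two_site"), n_starts = 4)
  expect_lt(fit$chi2_red, 1e-4)
  p <- state_populations(fit$model, 298)
  expect_equal(p[["B"]], 0.05, tolerance = 1e-3)
  dw_true <- attr(ds, "dw_true")
  expect_equal(unname(fit$dw[, "B"]), unname(dw_true[, "B"]),
               tolerance = 1e-3)
})

test_that("noisy two-site data recover the exchange parameters", {
  sf <- fx_small_fit()          # 2% noise, 3 methyls, 2 fields x 2 temps
  fit <- sf$fit
  expect_true(fit$converged)
  expect_lt(fit$chi2_red, 1.5)
  p <- state_populations(fit$model, 298)
  expect_lt(abs(p[["B"]] - 0.05) / 0.05, 0.15)
  K <- build_exchange_matrix(fit$model, 298)
  kex <- K[2, 1] + K[1, 2]
  expect_lt(abs(kex - 800) / 800, 0.10)
  # degrees of freedom: points minus thermo, shifts and profiled offsets
  expect_identical(fit$dof, fit$n_points - (4L + 3L + 12L))
})

test_that("the fit is a fixed point and the objective never worsens", {
  sf <- fx_small_fit()
  fit <- sf$fit
  refit <- fit_region(sf$data, fit$topology, starts = list(fit$theta))
  expect_equal(refit$chi2, fit$chi2, tolerance = 1e-6)
  # multi-start bookkeeping kept the best deviance of all starts
  expect_true(all(fit$start_deviances[is.finite(fit$start_deviances)] >=
                    fit$chi2 - 1e-6))
})

test_that("swapping minor-state labels leaves the bifurcated fit invariant", {
  grid <- cpmg_acquisition_grid(temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 1000,
                                              length.out = 8))
  truth <- fx_bifurcated()
  ds <- generate_cpmg_dataset(truth, grid, n_methyls = 2,
                              noise_frac = 0.02, seed = 5)
  topo <- exchange_topology("bifurcated_three_site")
  ctx <- excat:::fit_context(ds, topo)
  th <- excat:::default_starts(ctx)[[5]]
  sw <- function(x) chartr("BC", "CB", x)
  th_swap <- th
  names(th_swap) <- vapply(names(th), function(nm) {
    if (grepl("^(dG|dH)_[BC]$", nm) || grepl("^dw_", nm)) sw(nm)
    else if (grepl("ts_A-[BC]$", nm)) sw(nm) else nm
  }, "")
  th_swap <- th_swap[names(th)]
  r1 <- sum(excat:::fit_residuals(th, ctx)^2)
  r2 <- sum(excat:::fit_residuals(th_swap, ctx)^2)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("fitted minor states obey the p_B >= p_C ordering convention", {
  # relabelling machinery: a theta with p_C > p_B gets swapped
  grid <- cpmg_acquisition_grid(temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 800,
                                              length.out = 6))
  ds <- generate_cpmg_dataset(fx_bifurcated(), grid, n_methyls = 2,
                              noise_frac = 0, seed = 9)
  topo <- exchange_topology("bifurcated_three_site")
  ctx <- excat:::fit_context(ds, topo)
  th <- excat:::default_starts(ctx)[[1]]
  th[["dG_B"]] <- 12; th[["dG_C"]] <- 6   # p_C > p_B on purpose
  rl <- excat:::relabel_minors(th, ctx)
  expect_lt(rl$theta[["dG_B"]], rl$theta[["dG_C"]])
})

test_that("F-test comparison behaves for identical and nested fits", {
  fit <- fx_small_fit()$fit
  cmp <- compare_topologies(fit, fit)
  expect_identical(cmp$F, 0)
  expect_identical(cmp$p_value, 1)
  expect_error(compare_topologies(fit,
                                  structure(list(n_points = 1),
                                            class = "region_fit_result")),
               "same data")
})

test_that("three-site exchange is detected against a two-site null", {
  grid <- cpmg_acquisition_grid()
  truth <- fx_bifurcated()
  ds <- generate_cpmg_dataset(truth, grid, n_methyls = 4,
                              noise_frac = 0.02, seed = 21)
  fit2 <- fit_region(ds, exchange_topology("two_site"), n_starts = 4)
  fit3 <- fit_region(ds, exchange_topology("bifurcated_three_site"),
                     n_starts = 6)
  cmp <- compare_topologies(fit2, fit3)
  expect_lt(cmp$p_value, 1e-6)
  # and the parameters are recovered by the richer model
  p <- state_populations(fit3$model, 298)
  expect_lt(abs(p[["B"]] - 0.08) / 0.08, 0.15)
  expect_lt(abs(p[["C"]] - 0.03) / 0.03, 0.25)
  # the linear chain alternative also converges on these data
  fitl <- fit_region(ds, exchange_topology("linear_three_site"),
                     n_starts = 2)
  expect_true(is.finite(fitl$chi2_red))
})

test_that("two-site truth does not trigger spurious three-site detection", {
  grid <- cpmg_acquisition_grid(temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 1000,
                                              length.out = 8))
  pvals <- vapply(1:6, function(seed) {
    ds <- generate_cpmg_dataset(fx_two_site(), grid, n_methyls = 2,
                                noise_frac = 0.02, seed = 100 + seed)
    f2 <- fit_region(ds, exchange_topology("two_site"), n_starts = 4)
    f3 <- fit_region(ds, exchange_topology("bifurcated_three_site"),
                     n_starts = 3)
    compare_topologies(f2, f3)$p_value
  }, 0)
  expect_gte(sum(pvals > 0.05), 5)
})

test_that("Monte Carlo uncertainties are deterministic and calibrated", {
  sf <- fx_small_fit()
  mc1 <- monte_carlo_errors(sf$fit, n_mc = 25, seed = 3)
  mc2 <- monte_carlo_errors(sf$fit, n_mc = 25, seed = 3)
  expect_identical(mc1$param_sd, mc2$param_sd)
  expect_warning(monte_carlo_errors(sf$fit, n_mc = 5, seed = 1),
                 "n_mc")
  # ~68% of draws fall within 1 SD of the underlying truth
  mc <- monte_carlo_errors(sf$fit, n_mc = 40, seed = 4)
  pb <- mc$derived[, "p_B"]
  cover <- mean(abs(pb - 0.05) < sd(pb))
  expect_gte(cover, 0.45)
  expect_lte(cover, 0.9)
  # vanishing noise collapses the uncertainties
  grid <- cpmg_acquisition_grid(temps_K = c(288, 298),
                                nu_cpmg = seq(33.333, 800,
                                              length.out = 6))
  ds0 <- generate_cpmg_dataset(fx_two_site(), grid, n_methyls = 2,
                               noise_frac = 0, seed = 11)
  ds0$sigma_s <- 1e-4
  fit0 <- fit_region(ds0, exchange_topology("two_site"), n_starts = 2)
  mc0 <- monte_carlo_errors(fit0, n_mc = 20, seed = 5)
  expect_lt(mc0$derived_sd[["p_B"]], 1e-3)
})

test_that("chemical-shift utilities follow their closed forms", {
  expect_identical(compute_csp(0, 0, 1.5, 2.5), 0)
  expect_equal(compute_csp(3, 4, 1, 1), 5)
  expect_equal(compute_csp(1, 0, 2, 1), 0.5)
  expect_error(compute_csp(1, 1, 0, 1), "alpha")

  expect_equal(correlate_shift_sets(1:5, 2 * (1:5)), 1.0)
  expect_equal(correlate_shift_sets(1:5, -(1:5)), -1.0)
  # hand computation: cov = 4.7, sd_x^2 = 5, sd_y^2 = 4.5
  expect_equal(correlate_shift_sets(c(1, 2, 3, 4),
                                    c(1.1, 1.9, 3.2, 3.8)),
               4.7 / sqrt(5 * 4.5), tolerance = 1e-10)
  expect_error(correlate_shift_sets(1:2, 1:2), "at least 3")
  expect_error(correlate_shift_sets(c(1, 1, 1), 1:3), "zero variance")
})
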