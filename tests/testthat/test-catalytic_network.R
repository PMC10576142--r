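test_that("the full state space has the expected layout", {
  sp <- build_state_space()
  expect_identical(sp$n_states, 93L)
  expect_identical(sp$n_conf, 18L)
  expect_identical(nrow(sp$conf), 18L)
  expect_identical(sp$block$E, 1:18)
  expect_identical(sp$block$ES, 19:36)
  expect_identical(sp$block$EPlysPace, 37:54)
  expect_identical(sp$block$EPace, 55:72)
  expect_identical(sp$block$EPlys, 73:90)
  expect_identical(c(sp$iS, sp$iPlys, sp$iPace), c(91L, 92L, 93L))
  # one conformation per region collapses to the textbook 8-state scheme
  expect_identical(fx_degenerate_space()$n_states, 8L)
})

test_that("conformations can be looked up by region labels", {
  sp <- build_state_space()
  h <- conf_index(sp, L1 = "boundlike", L26 = "boundlike", CAT = "A")
  expect_length(h, 1)
  expect_identical(sp$conf$CAT[h], "A")
  expect_length(conf_index(sp, CAT = "B"), 9)
  expect_length(conf_index(sp, L1 = "release"), 6)
  expect_error(conf_index(sp, L9 = "x"), "unknown region")
})

test_that("degenerate network reproduces the textbook analytic limits", {
  sp <- fx_degenerate_space()
  rset <- fx_degenerate_rates()
  spec <- fx_degenerate_spec(sp)
  par <- kinetic_params(k_on = 1e6, k_off_S = 100, k_H = 10,
                        k_off_I = 50, k_off_P = 1e6)
  des <- assay_design(E0 = 1e-10,
                      S_grid = c(0, exp(seq(log(1e-6), log(3e-3),
                                            length.out = 16))),
                      n_t = 3000, t_max = 10, v0_window = c(1, 10))
  for (meth in c("ode", "steady")) {
    mm <- michaelis_menten(sp, spec, rset, par, des, method = meth)
    expect_equal(mm$kcat, 10, tolerance = 0.01)
    expect_equal(mm$KM, 110e-6, tolerance = 0.01)
    io <- inhibitor_observables(sp, spec, rset, par, method = meth)
    expect_equal(io$kd, 50e-6, tolerance = 0.01)    # k_off_I / k_on
    expect_equal(io$koff_macro, 50, tolerance = 0.01)
  }
})

test_that("degenerate progress curves match an independent 3-state integrator", {
  sp <- fx_degenerate_space()
  rset <- fx_degenerate_rates()
  spec <- fx_degenerate_spec(sp)
  par <- kinetic_params(k_on = 1e6, k_off_S = 100, k_H = 10,
                        k_off_I = 50, k_off_P = 1e6, k_off_ace = 1e6)
  net <- assemble_network(sp, spec, rset, par)
  times <- c(0, exp(seq(log(1e-5), log(5), length.out = 300)))
  E0 <- 1e-7; S0 <- 5e-4
  y0 <- numeric(sp$n_states); y0[sp$block$E] <- E0; y0[sp$iS] <- S0
  y <- simulate_progress(net, y0, times)
  # with effectively instantaneous product release the cycle reduces to
  # E + S <-> ES -> E + P
  ref <- oracle_mm_progress(1e6, 100, 10, E0, S0, times)
  expect_equal(y[, sp$iPlys][-1], unname(ref[-1, "P"]),
               tolerance = 1e-3)
})

test_that("equilibrated binding network has zero net flux on every edge", {
  truth <- fx_truth()
  net <- assemble_network(truth$space, truth$spec, truth$rates,
                          truth$params, mode = "inhibitor")
  sp <- truth$space
  y0 <- numeric(sp$n_states)
  y0[sp$block$E] <- 50e-6 * net$p_free
  y0[sp$iS] <- 50e-6
  y <- simulate_progress(net, y0, log_time_grid(1e-6, 2000, 3000))
  yeq <- y[nrow(y), ]
  enz <- seq_len(5 * sp$n_conf)
  # flux matrix over enzyme states: linear edges plus bilinear association
  Fw <- net$A[enz, enz] * rep(yeq[enz], each = length(enz))
  tr <- net$triples
  for (k in seq_len(nrow(tr)))
    Fw[tr[k, 2], tr[k, 1]] <- Fw[tr[k, 2], tr[k, 1]] +
      tr[k, 3] * yeq[sp$iS] * yeq[tr[k, 1]]
  imbalance <- abs(Fw - t(Fw)) / pmax(Fw + t(Fw), 1e-30)
  active <- (Fw + t(Fw)) > 1e-12 * max(Fw)
  diag(active) <- FALSE
  expect_lt(max(imbalance[active]), 1e-9)
})

test_that("enzyme mass is conserved along catalytic trajectories", {
  truth <- fx_truth()
  net <- assemble_network(truth$space, truth$spec, truth$rates,
                          truth$params)
  sp <- truth$space
  y0 <- numeric(sp$n_states)
  y0[sp$block$E] <- 0.4e-6 * net$p_free
  y0[sp$iS] <- 0.01
  y <- simulate_progress(net, y0, log_time_grid(1e-6, 600, 2000))
  enz <- rowSums(y[, seq_len(5 * sp$n_conf)])
  expect_lt(max(abs(enz - enz[1])) / enz[1], 1e-6)
  # and substrate + products balance the ligand mass
  lig <- y[, sp$iS] + y[, sp$iPlys] +
    rowSums(y[, c(sp$block$ES, sp$block$EPlysPace, sp$block$EPlys)])
  expect_lt(max(abs(lig - lig[1])) / lig[1], 1e-6)
})

test_that("trivial cases: no hydrolysis means no product, no enzyme means no change", {
  truth <- fx_truth()
  par0 <- kinetic_params(k_on = truth$params$k_on,
                         k_off_S = truth$params$k_off_S, k_H = 0,
                         k_off_I = truth$params$k_off_I)
  net0 <- assemble_network(truth$space, truth$spec, truth$rates, par0)
  sp <- truth$space
  y0 <- numeric(sp$n_states)
  y0[sp$block$E] <- 0.4e-6 * net0$p_free
  y0[sp$iS] <- 0.01
  y <- simulate_progress(net0, y0, log_time_grid(1e-6, 100, 500))
  expect_true(all(y[, sp$iPlys] == 0))
  expect_error(michaelis_menten(sp, truth$spec, truth$rates, par0),
               "no turnover")

  yE0 <- numeric(sp$n_states); yE0[sp$iS] <- 0.01
  net <- assemble_network(sp, truth$spec, truth$rates, truth$params)
  y2 <- simulate_progress(net, yE0, log_time_grid(1e-6, 100, 500))
  expect_equal(y2[, sp$iS], rep(0.01, nrow(y2)), tolerance = 1e-12)
  expect_true(all(y2[, seq_len(5 * sp$n_conf)] == 0))
})

test_that("solver tolerances and grid resolution are converged", {
  truth <- fx_truth()
  sp <- truth$space
  net <- assemble_network(sp, truth$spec, truth$rates, truth$params)
  y0 <- numeric(sp$n_states)
  y0[sp$block$E] <- 0.4e-6 * net$p_free
  y0[sp$iS] <- 0.02
  times <- log_time_grid(1e-6, 600, 1500)
  y_a <- simulate_progress(net, y0, times)
  y_b <- simulate_progress(net, y0, times, rtol = 5e-9, atol = 5e-13)
  pl_a <- y_a[nrow(y_a), sp$iPlys]; pl_b <- y_b[nrow(y_b), sp$iPlys]
  expect_lt(abs(pl_a - pl_b) / pl_b, 1e-4)

  des_coarse <- assay_design(S_grid = c(0, 1e-3, 1e-2, 0.1), n_t = 2000)
  des_fine <- assay_design(S_grid = c(0, 1e-3, 1e-2, 0.1), n_t = 12000)
  mm_c <- michaelis_menten(sp, truth$spec, truth$rates, truth$params,
                           des_coarse, method = "ode")
  mm_f <- michaelis_menten(sp, truth$spec, truth$rates, truth$params,
                           des_fine, method = "ode")
  expect_lt(abs(mm_c$kcat - mm_f$kcat) / mm_f$kcat, 0.005)
  expect_lt(abs(mm_c$KM - mm_f$KM) / mm_f$KM, 0.005)
})

test_that("steady-state and ODE routes agree on all macroscopic observables", {
  truth <- fx_truth()
  sp <- truth$space
  des <- assay_design(S_grid = c(0, exp(seq(log(1e-4), log(0.25),
                                            length.out = 10))),
                      n_t = 3000)
  mm_o <- michaelis_menten(sp, truth$spec, truth$rates, truth$params,
                           des, method = "ode")
  mm_s <- michaelis_menten(sp, truth$spec, truth$rates, truth$params,
                           des, method = "steady")
  expect_equal(mm_s$kcat, mm_o$kcat, tolerance = 0.005)
  expect_equal(mm_s$KM, mm_o$KM, tolerance = 0.005)
  io_o <- inhibitor_observables(sp, truth$spec, truth$rates,
                                truth$params, method = "ode")
  io_s <- inhibitor_observables(sp, truth$spec, truth$rates,
                                truth$params, method = "steady")
  expect_equal(io_s$kd, io_o$kd, tolerance = 0.01)
  expect_equal(io_s$koff_macro, io_o$koff_macro, tolerance = 0.01)
})

test_that("the macroscopic Kd is a true equilibrium constant", {
  truth <- fx_truth()
  io1 <- inhibitor_observables(truth$space, truth$spec, truth$rates,
                               truth$params, E0 = 50e-6, I0 = 50e-6,
                               method = "ode")
  io2 <- inhibitor_observables(truth$space, truth$spec, truth$rates,
                               truth$params, E0 = 5e-6, I0 = 5e-6,
                               t_eq = 2000, method = "ode")
  expect_equal(io2$kd, io1$kd, tolerance = 0.01)
})

test_that("conformational gating can only slow apparent inhibitor release", {
  truth <- fx_truth()
  io <- inhibitor_observables(truth$space, truth$spec, truth$rates,
                              truth$params, method = "steady")
  expect_lt(io$koff_macro, truth$params$k_off_I)
  # equality in the ungated 1-conformation limit
  sp1 <- fx_degenerate_space()
  io1 <- inhibitor_observables(sp1, fx_degenerate_spec(sp1),
                               fx_degenerate_rates(),
                               truth$params, method = "steady")
  expect_equal(io1$koff_macro, truth$params$k_off_I, tolerance = 1e-6)
})

test_that("fast intrinsic exchange approaches the pre-equilibrium limit", {
  truth <- fx_truth()
  sp <- truth$space
  speed <- function(m, f) {
    K <- build_exchange_matrix(m, 298)
    kex <- vapply(m$topology$edges,
                  function(e) K[e[2], e[1]] + K[e[1], e[2]], 0)
    p <- state_populations(m, 298)[-1]
    thermo_from_pop_kex(m$topology, p,
                        setNames(f * kex,
                                 vapply(m$topology$edges, function(e)
                                   paste(sort(e), collapse = "-"), "")),
                        dH_state = m$dH_state)
  }
  fast <- region_rate_set(
    free = lapply(truth$rates$free, speed, f = 10),
    bound = lapply(truth$rates$bound, speed, f = 10))
  des <- assay_design(S_grid = c(0, exp(seq(log(1e-4), log(0.25),
                                            length.out = 12))),
                      n_t = 3000)
  mm <- michaelis_menten(sp, truth$spec, fast, truth$params, des,
                         method = "steady")
  net <- assemble_network(sp, truth$spec, fast, truth$params)
  ratio_model <- mm$kcat / mm$KM
  ratio_limit <- oracle_preequilibrium_kcatKM(
    truth$params$k_on, truth$params$k_off_S, truth$params$k_H,
    net$p_free, net$p_bound, truth$spec$substrate_sites,
    truth$spec$hydrolysis_site)
  expect_equal(ratio_model, ratio_limit, tolerance = 0.05)
})

test_that("two-site gated binding matches the algebraic equilibrium", {
  truth <- fx_truth()
  net <- assemble_network(truth$space, truth$spec, truth$rates,
                          truth$params, mode = "inhibitor")
  sites <- truth$spec$substrate_sites
  kd_alg <- (truth$params$k_off_I / truth$params$k_on) *
    sum(net$p_bound[sites]) / sum(net$p_free[sites])
  io <- inhibitor_observables(truth$space, truth$spec, truth$rates,
                              truth$params, method = "ode")
  expect_equal(io$kd, kd_alg, tolerance = 0.01)
  # and the equilibrium concentrations agree with the scalar one-site
  # solution at that macroscopic Kd
  eq <- oracle_binding_equilibrium(kd_alg, 50e-6, 50e-6)
  y <- simulate_progress(net, excat:::cycle_initial_state(net, 50e-6,
                                                          50e-6),
                         log_time_grid(1e-6, 2000, 2000))
  yeq <- y[nrow(y), ]
  expect_equal(sum(yeq[truth$space$block$ES]), eq$EI, tolerance = 0.01)
})

test_that("model specs referencing unknown conformations are rejected", {
  sp <- build_state_space()
  expect_error(kinetic_model_spec(sp, substrate_sites = integer(0),
                                  lysine_sites = 1), "non-empty")
  expect_error(kinetic_model_spec(sp, substrate_sites = 25,
                                  lysine_sites = 1), "non-empty|manifold")
  expect_error(kinetic_model_spec(sp, substrate_sites = 1,
                                  lysine_sites = 99), "manifold")
})
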