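test_that("intensity-to-rate conversion follows the constant-time formula", {
  expect_identical(r2eff_from_intensities(2.5, 2.5, 0.04), 0)
  expect_equal(r2eff_from_intensities(exp(-1.5), 1, 0.03), 50.0)
  expect_equal(r2eff_from_intensities(0.9, 1, 0.03), -log(0.9) / 0.03)
  expect_equal(r2eff_from_intensities(0.9, 1, 0.03), 3.512,
               tolerance = 1e-4)
  expect_warning(r <- r2eff_from_intensities(c(0.5, -0.1, 0), 1, 0.03),
                 "non-positive")
  expect_true(is.na(r[2]) && is.na(r[3]) && is.finite(r[1]))
  expect_error(r2eff_from_intensities(1, -1, 0.03))
})

test_that("CPMG frequencies snap to even pulse counts", {
  des <- suppressMessages(cpmg_design(18.8, c(20, 150, 500, 1000)))
  expect_true(all(des$npulses %% 2 == 0))
  expect_equal(des$nu_cpmg, des$npulses / (2 * des$T_relax))
  # 20 Hz is not realizable with a 30 ms constant-time element
  expect_equal(des$nu_cpmg[1], 100 / 3, tolerance = 1e-6)
  expect_message(cpmg_design(18.8, 20), "snapped")
  expect_warning(suppressMessages(cpmg_design(18.8, c(20, 33.3))),
                 "duplicate")
})

test_that("no exchange broadening without shift differences", {
  m <- fx_two_site()
  des <- suppressMessages(cpmg_design(18.8, c(33.4, 100, 500, 1000)))
  crv <- mq_dispersion(spin_system(c(B = 0), dw_H = 0, r2_mq0 = 12.5),
                       m, des, T_K = 298)
  expect_equal(crv$r2eff_s, rep(12.5, 4), tolerance = 1e-10)
  # zero-exchange baseline: K = 0 recovers r2_mq0 even with dw != 0
  crv0 <- mq_dispersion(spin_system(c(B = 2), dw_H = 0, r2_mq0 = 9),
                        design = des, T_K = 298,
                        K = matrix(0, 2, 2,
                                   dimnames = list(c("A", "B"),
                                                   c("A", "B"))),
                        populations = c(1, 0))
  expect_equal(crv0$r2eff_s, rep(9, 4), tolerance = 1e-9)
})

test_that("MQ propagation matches the exact two-site closed form", {
  des <- suppressMessages(cpmg_design(18.8, seq(33.4, 1000,
                                                length.out = 12)))
  for (case in list(c(pB = 0.05, kex = 1000, dw = 2),
                    c(pB = 0.02, kex = 300, dw = 3),
                    c(pB = 0.12, kex = 2500, dw = 0.8))) {
    m <- thermo_from_pop_kex(exchange_topology("two_site"),
                             c(B = case[["pB"]]),
                             c("A-B" = case[["kex"]]))
    crv <- mq_dispersion(spin_system(c(B = case[["dw"]]), dw_H = 0,
                                     r2_mq0 = 8), m, des, 298)
    dw_rad <- case[["dw"]] * 1e-6 * codata$gamma_C * 18.8
    ex <- oracle_exact_sq_cpmg(8, case[["pB"]], case[["kex"]], dw_rad,
                               des$npulses, des$T_relax)
    expect_equal(crv$r2eff_s, ex, tolerance = 1e-9)
  }
})

test_that("MQ propagation agrees with Carver-Richards in its regime", {
  # intermediate-to-fast exchange, where the CR approximation is accurate
  des <- suppressMessages(cpmg_design(18.8, seq(33.4, 1000,
                                                length.out = 10)))
  m <- thermo_from_pop_kex(exchange_topology("two_site"), c(B = 0.03),
                           c("A-B" = 2000))
  crv <- mq_dispersion(spin_system(c(B = 1.5), dw_H = 0, r2_mq0 = 10),
                       m, des, 298)
  cr <- oracle_carver_richards(10, 0.03, 2000,
                               1.5e-6 * codata$gamma_C * 18.8,
                               des$nu_cpmg)
  expect_equal(crv$r2eff_s, cr, tolerance = 0.01)
})

test_that("fast-exchange limit reproduces pA*pB*dw^2/kex", {
  dw_rad <- 2e-6 * codata$gamma_C * 18.8
  kex <- 20 * dw_rad
  m <- thermo_from_pop_kex(exchange_topology("two_site"), c(B = 0.05),
                           c("A-B" = kex))
  des <- suppressMessages(cpmg_design(18.8, c(33.4, 4000)))
  crv <- mq_dispersion(spin_system(c(B = 2), dw_H = 0, r2_mq0 = 8), m,
                       des, 298)
  expect_equal(crv$r2eff_s[1] - 8, 0.95 * 0.05 * dw_rad^2 / kex,
               tolerance = 0.05)
})

test_that("the tiny fixed 1H offset has negligible effect", {
  m <- fx_two_site()
  des <- suppressMessages(cpmg_design(18.8, seq(33.4, 1000,
                                                length.out = 8)))
  c0 <- mq_dispersion(spin_system(c(B = 2), dw_H = 0, r2_mq0 = 8), m,
                      des, 298)
  c1 <- mq_dispersion(spin_system(c(B = 2), dw_H = 0.01, r2_mq0 = 8), m,
                      des, 298)
  # the residual 1H contribution is bounded by its fast-limit exchange
  # broadening (~0.1 s^-1 here); assert it is < 0.5% of the dispersion
  # amplitude Rex, the quantity the experiment measures
  rex0 <- rex(c0)
  expect_lt(max(abs(c1$r2eff_s - c0$r2eff_s)) / rex0, 0.005)
})

test_that("propagation is converged: substepping the delays changes nothing", {
  # free-precession delays are exact matrix exponentials; splitting each
  # delay into two half-steps (oracle with substeps = 2) must agree
  pB <- 0.05; kex <- 1000; dw <- 2e-6 * codata$gamma_C * 18.8
  des <- suppressMessages(cpmg_design(18.8, c(66.7, 333, 1000)))
  m <- thermo_from_pop_kex(exchange_topology("two_site"), c(B = pB),
                           c("A-B" = kex))
  crv <- mq_dispersion(spin_system(c(B = 2), dw_H = 0, r2_mq0 = 5), m,
                       des, 298)
  ex1 <- oracle_exact_sq_cpmg(5, pB, kex, dw, des$npulses, des$T_relax, 1)
  ex2 <- oracle_exact_sq_cpmg(5, pB, kex, dw, des$npulses, des$T_relax, 2)
  expect_equal(ex1, ex2, tolerance = 1e-10)
  expect_lt(max(abs(crv$r2eff_s - ex2) / ex2), 1e-3)
})

test_that("dispersion shape is invariant under joint rate/shift/frequency scaling", {
  # scaling all rates and shift offsets by c while the pulse train is
  # compressed in time by 1/c (so every CPMG frequency scales by c)
  # multiplies the exchange contribution to R2,eff by exactly c
  base_n <- c(4L, 10L, 24L, 60L)
  m <- fx_two_site(pB = 0.06, kex = 900)
  K <- build_exchange_matrix(m, 298)
  p <- as.numeric(state_populations(m, 298))
  dw <- c(0, 2e-6 * codata$gamma_C * 18.8)
  T_relax <- 0.03
  r_base <- excat:::mq_r2eff_cpp(K, 0, dw, c(0, 0), p, base_n, T_relax)
  for (cc in c(0.5, 2)) {
    r_scaled <- excat:::mq_r2eff_cpp(cc * K, 0, cc * dw, c(0, 0), p,
                                     base_n, T_relax / cc)
    expect_equal(r_scaled / cc, r_base, tolerance = 1e-8)
  }
})

test_that("exchange contribution quenches at high pulsing rates", {
  m <- fx_two_site(pB = 0.05, kex = 4000)
  des_lo <- suppressMessages(cpmg_design(18.8, 33.4))
  des_hi <- suppressMessages(cpmg_design(18.8, 4000))
  lo <- mq_dispersion(spin_system(c(B = 2), 0, 8), m, des_lo, 298)
  hi <- mq_dispersion(spin_system(c(B = 2), 0, 8), m, des_hi, 298)
  rex_lo <- lo$r2eff_s - 8
  expect_gt(rex_lo, 1)
  expect_lt(hi$r2eff_s - 8, 0.1 * rex_lo)
})

test_that("rex measures the low-minus-high frequency difference", {
  flat <- data.frame(nu_cpmg_Hz = c(50, 1000), r2eff_s = c(7, 7))
  expect_equal(rex(flat), 0)
  synth <- data.frame(nu_cpmg_Hz = c(33, 100, 400, 1000),
                      r2eff_s = c(25, 18, 12, 10))
  expect_equal(rex(synth), 15)
  expect_error(rex(data.frame(nu_cpmg_Hz = 50, r2eff_s = 3)),
               "two CPMG frequencies")
  # rex -> 0 as the minor population vanishes
  des <- suppressMessages(cpmg_design(18.8, c(33.4, 1000)))
  rexes <- vapply(c(0.05, 0.005, 5e-4), function(pB) {
    m <- thermo_from_pop_kex(exchange_topology("two_site"), c(B = pB),
                             c("A-B" = 1000))
    rex(mq_dispersion(spin_system(c(B = 2), 0, 8), m, des, 298))
  }, 0)
  expect_true(all(diff(rexes) < 0))
  # Rex vanishes proportionally to the minor population
  expect_lt(rexes[3] / rexes[1], 0.02)
})
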