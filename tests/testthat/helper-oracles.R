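# Independent oracles used across the test suite.  These are written
# against the literature closed forms / textbook schemes and never call
# the package's compiled propagation or network assembly.

# Classic Carver-Richards closed form for two-site single-quantum CPMG
# (equal intrinsic relaxation in both states).  tau_cp = 1/(2 nu) is the
# delay between successive refocusing pulses.  The formula is an
# approximation: its error grows at low pulse numbers in slow exchange.
oracle_carver_richards <- function(r20, pB, kex, dw_rad, nu) {
  pA <- 1 - pB
  psi <- kex^2 - dw_rad^2
  zeta <- -2 * dw_rad * kex * (pA - pB)
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * (1 + (psi + 2 * dw_rad^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw_rad^2) / root)
  tcp <- 1 / (2 * nu)
  etap <- (tcp / sqrt(2)) * sqrt(psi + root)
  etam <- (tcp / sqrt(2)) * sqrt(-psi + root)
  r20 + 0.5 * (kex - (1 / tcp) * acosh(Dp * cosh(etap) - Dm * cos(etam)))
}

# Exact two-site CPMG signal via closed-form 2x2 matrix exponentials
# (quadratic eigenvalue formula) and explicit products over the pulse
# train; detection of total transverse magnetization.
oracle_expm2 <- function(M) {
  tr <- (M[1, 1] + M[2, 2]) / 2
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  s <- sqrt(tr^2 - dt + 0i)
  sh <- if (abs(s) < 1e-12) 1 + s^2 / 6 else sinh(s) / s
  exp(tr) * (cosh(s) * diag(2) + sh * (M - tr * diag(2)))
}

oracle_exact_sq_cpmg <- function(r20, pB, kex, dw_rad, npulses, T_relax,
                                 substeps = 1) {
  K <- matrix(c(-pB * kex, pB * kex, (1 - pB) * kex, -(1 - pB) * kex), 2, 2)
  Mp <- K + 1i * diag(c(0, dw_rad))
  Mm <- K - 1i * diag(c(0, dw_rad))
  vapply(npulses, function(np) {
    delta <- T_relax / (2 * np)
    stepm <- function(M) {
      E <- oracle_expm2(M * (delta / substeps))
      out <- diag(2)
      for (i in seq_len(substeps)) out <- E %*% out
      out
    }
    Fp <- stepm(Mp); Fm <- stepm(Mm)
    U <- Fp %*% Fm %*% Fm %*% Fp      # one 2-pulse CPMG unit
    V <- diag(2)
    for (k in seq_len(np / 2)) V <- V %*% U
    v <- V %*% c(1 - pB, pB)
    r20 - log(abs(sum(v))) / T_relax
  }, 0)
}

# Textbook E + S <-> ES -> E + P integrator (pure R right-hand side,
# integrated with deSolve's R-function interface; independent of the
# package's compiled network code)
oracle_mm_progress <- function(kon, koff, kH, E0, S0, times) {
  rhs <- function(t, y, p) {
    with(as.list(y), {
      v_on <- kon * E * S; v_off <- koff * ES; v_h <- kH * ES
      list(c(E = -v_on + v_off + v_h, S = -v_on + v_off,
             ES = v_on - v_off - v_h, P = v_h))
    })
  }
  deSolve::lsoda(c(E = E0, S = S0, ES = 0, P = 0), times, rhs, NULL,
                 rtol = 1e-10, atol = 1e-14)
}

# analytic equilibrium of one-site binding E + I <-> EI at total
# concentrations e0, i0
oracle_binding_equilibrium <- function(kd, e0, i0) {
  b <- e0 + i0 + kd
  ei <- (b - sqrt(b^2 - 4 * e0 * i0)) / 2
  list(EI = ei, E = e0 - ei, I = i0 - ei)
}

# effective rates of the fast-exchange (pre-equilibrium) limit of the
# gated binding scheme; see the methods vignette
oracle_preequilibrium_kcatKM <- function(kon, koff, kH, p_free, p_bound,
                                         sites, hydro) {
  PB <- sum(p_bound[sites]); PF <- sum(p_free[sites])
  kon_eff <- kon * sum(p_free[sites] * p_bound[sites] / PB)
  koff_eff <- koff * sum(p_bound[sites] * p_free[sites] / PF)
  kH_eff <- kH * p_bound[hydro]
  kon_eff * kH_eff / (koff_eff + kH_eff)
}
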