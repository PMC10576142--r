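#' Convert CPMG peak intensities to effective relaxation rates
#'
#' `R2,eff(nu) = -ln(I_nu / I_0) / T_relax`, where `I_0` is the intensity
#' measured without the constant-time relaxation delay.  Non-positive
#' intensities cannot be converted; they are returned as `NA` and reported
#' via a warning so the caller can exclude them, rather than aborting a
#' whole dataset.
#'
#' @param I_nu peak intensity at CPMG frequency nu.
#' @param I_0 reference intensity (must be positive).
#' @param T_relax constant-time relaxation delay, s.
#' @return effective relaxation rate(s), s^-1.
#' @examples
#' r2eff_from_intensities(exp(-1.5), 1, 0.03)  # 50 s^-1
#' @export
r2eff_from_intensities <- function(I_nu, I_0, T_relax) {
  stopifnot(all(I_0 > 0), T_relax > 0)
  bad <- !is.na(I_nu) & I_nu <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive intensities flagged as missing")
    I_nu[bad] <- NA_real_
  }
  -log(I_nu / I_0) / T_relax
}

#' CPMG experimental design
#'
#' Static field, constant-time delay and the CPMG frequencies of the
#' pulse train.  The constant-time element accommodates
#' `n = 2 * T_relax * nu` refocusing pulses; `n` must be an even integer
#' (the single 1H inversion pulse sits between the two halves of the
#' train), so requested frequencies are snapped to the nearest realizable
#' value `n / (2 * T_relax)` and a message reports any adjustment.
#'
#' @param B0_T static magnetic field, Tesla.
#' @param nu_cpmg requested CPMG frequencies, Hz.
#' @param T_relax constant-time relaxation delay, s (default 0.030).
#' @return object of class `cpmg_design` with elements `B0_T`, `T_relax`,
#'   `nu_cpmg` (realized), `npulses`, `nu_requested`.
#' @export
cpmg_design <- function(B0_T, nu_cpmg, T_relax = 0.030) {
  stopifnot(B0_T > 0, T_relax > 0, all(nu_cpmg > 0))
  n <- 2L * pmax(1L, as.integer(round(T_relax * nu_cpmg)))
  nu <- n / (2 * T_relax)
  adj <- abs(nu - nu_cpmg) > 1e-9 * pmax(1, nu_cpmg)
  if (any(adj))
    message(sum(adj), " CPMG frequencies snapped to realizable values (",
            paste(sprintf("%g->%g", nu_cpmg[adj], nu[adj]), collapse = ", "), ")")
  if (anyDuplicated(nu))
    warning("duplicate CPMG frequencies after snapping")
  structure(list(B0_T = B0_T, T_relax = T_relax, nu_cpmg = nu,
                 npulses = n, nu_requested = nu_cpmg),
            class = "cpmg_design")
}

#' Spin system for a methyl group under exchange
#'
#' Chemical-shift offsets of the minor states relative to the major state
#' A.  Multiple-quantum data only determine `|dw|`, so 13C offsets are
#' stored non-negative; 1H offsets are fixed to a very small value
#' (0.01 ppm) by default, whose effect on the dispersion is negligible.
#' `r2_mq0` is the intrinsic MQ relaxation rate for the condition being
#' simulated, shared across exchanging states.
#'
#' @param dw_C named 13C offsets (ppm) per minor state, e.g.
#'   `c(B = 1.5, C = 0.8)`.
#' @param dw_H 1H offsets (ppm), recycled to the minor states.
#' @param r2_mq0 intrinsic MQ relaxation rate, s^-1.
#' @return object of class `spin_system`.
#' @export
spin_system <- function(dw_C, dw_H = 0.01, r2_mq0 = 10) {
  stopifnot(all(is.finite(dw_C)), all(is.finite(dw_H)), r2_mq0 >= 0)
  if (any(dw_C < 0)) {
    dw_C <- abs(dw_C)  # MQ data carry no sign information
  }
  if (length(dw_H) == 1) dw_H <- setNames(rep(dw_H, length(dw_C)), names(dw_C))
  structure(list(dw_C = dw_C, dw_H = dw_H, r2_mq0 = r2_mq0),
            class = "spin_system")
}

ppm_to_rad <- function(dw_ppm, B0_T, gamma) dw_ppm * 1e-6 * gamma * B0_T

# compiled MQ coherence propagation (see src/mq_cpmg.cpp)
mq_r2eff_cpp <- function(K, r2_mq0, dwC_rad, dwH_rad, p0, npulses, T_relax) {
  .Call("excat_mq_r2eff", K, as.numeric(r2_mq0), as.numeric(dwC_rad),
        as.numeric(dwH_rad), as.numeric(p0), as.integer(npulses),
        as.numeric(T_relax), PACKAGE = "excat")
}

#' Predict a multiple-quantum CPMG dispersion profile
#'
#' Numerically propagates the zero- and double-quantum coherence vector of
#' a methyl spin through the constant-time CPMG train under the given
#' exchange model: free-precession delays are exact matrix exponentials of
#' `K - R2*I -/+ i*diag(w)` for the current coherence order, each 13C
#' 180-degree pulse interchanges ZQ and DQ, and the central 1H inversion
#' conjugates the amplitudes.  The initial condition is weighted by the
#' equilibrium populations, and
#' `R2,eff(nu) = -ln(|s(T_relax)| / |s(0)|) / T_relax`.
#'
#' With all offsets zero the profile is flat at `r2_mq0`; with 1H offsets
#' zero the experiment reduces to single-quantum 13C CPMG.
#'
#' @param spin a [spin_system()].
#' @param model a [thermo_exchange_model()], evaluated at `T_K`; or pass
#'   `K` and `populations` directly.
#' @param design a [cpmg_design()].
#' @param T_K temperature, K.
#' @param K,populations optional explicit exchange generator (s^-1) and
#'   population vector overriding `model`.
#' @return object of class `dispersion_curve`: a data frame with columns
#'   `nu_cpmg_Hz`, `r2eff_s` and attributes `design`, `temp_K`.
#' @export
mq_dispersion <- function(spin, model = NULL, design, T_K = 298,
                          K = NULL, populations = NULL) {
  stopifnot(inherits(design, "cpmg_design"))
  if (is.null(K)) {
    stopifnot(inherits(model, "thermo_exchange_model"))
    K <- build_exchange_matrix(model, T_K)
    populations <- state_populations(model, T_K)
  }
  n <- nrow(K)
  states <- rownames(K)
  if (is.null(states)) states <- c("A", "B", "C")[seq_len(n)]
  dwC <- dwH <- setNames(numeric(n), states)
  minors <- setdiff(states, states[1])
  stopifnot(all(minors %in% names(spin$dw_C)))
  dwC[minors] <- spin$dw_C[minors]
  dwH[minors] <- spin$dw_H[minors]
  r2 <- mq_r2eff_cpp(K, spin$r2_mq0,
                     ppm_to_rad(dwC, design$B0_T, codata$gamma_C),
                     ppm_to_rad(dwH, design$B0_T, codata$gamma_H),
                     populations, as.integer(design$npulses),
                     design$T_relax)
  out <- data.frame(nu_cpmg_Hz = design$nu_cpmg, r2eff_s = as.numeric(r2))
  structure(out, class = c("dispersion_curve", "data.frame"),
            design = design, temp_K = T_K)
}

#' Exchange contribution to the dispersion
#'
#' `Rex = R2,eff(lowest nu) - R2,eff(highest nu)`, the difference between
#' the low-pulsing-rate limit and the high-pulsing-rate plateau.
#'
#' @param curve a `dispersion_curve` or any data frame with columns
#'   `nu_cpmg_Hz` and `r2eff_s`.
#' @param sigma optional per-point uncertainties; the result is checked to
#'   be at least `-3 * sigma`.
#' @return Rex in s^-1.
#' @export
rex <- function(curve, sigma = NULL) {
  stopifnot(all(c("nu_cpmg_Hz", "r2eff_s") %in% names(curve)))
  if (length(unique(curve$nu_cpmg_Hz)) < 2)
    stop("Rex needs a curve spanning at least two CPMG frequencies")
  r <- curve$r2eff_s[which.min(curve$nu_cpmg_Hz)] -
       curve$r2eff_s[which.max(curve$nu_cpmg_Hz)]
  if (!is.null(sigma) && r < -3 * max(sigma))
    warning("Rex more negative than -3 sigma; check the data")
  r
}
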