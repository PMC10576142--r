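#' Dispersion dataset
#'
#' Validate and class a table of effective relaxation rates: one row per
#' (methyl, field, temperature, CPMG frequency) with uncertainty.
#'
#' @param df data frame with columns `methyl_id`, `region`, `B0_T`,
#'   `temp_K`, `nu_cpmg_Hz`, `r2eff_s`, `sigma_s`.
#' @return the validated data frame with class `dispersion_dataset`.
#' @export
dispersion_dataset <- function(df) {
  need <- c("methyl_id", "region", "B0_T", "temp_K", "nu_cpmg_Hz",
            "r2eff_s", "sigma_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$sigma_s) | df$sigma_s <= 0))
    stop("sigma_s must be positive and finite")
  key <- do.call(paste, c(df[c("methyl_id", "B0_T", "temp_K",
                               "nu_cpmg_Hz")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (methyl, field, temperature, nu) rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  df <- df[order(df$methyl_id, df$B0_T, df$temp_K, df$nu_cpmg_Hz), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dispersion_dataset", "data.frame")
  df
}

# ---- internal parameterisation -------------------------------------------
#
# Global thermodynamic parameters are fitted as free energies at 298 K
# plus enthalpies (entropies follow as (dH - dG)/298), which keeps the
# population/rate guardrails expressible as simple box bounds; per-methyl
# |dw_C| are shared across temperatures and fields.  The per-(methyl,
# field, temperature) intrinsic rate r2_mq0 enters R2,eff additively and
# exactly (it commutes with the propagation), so it is profiled out
# analytically at every objective evaluation but still counted in the
# degrees of freedom.

T_REF <- 298

fit_context <- function(data, topology, T_relax = 0.030) {
  minors <- setdiff(topology$states, "A")
  labs <- vapply(topology$edges, edge_label, "")
  methyls <- unique(data$methyl_id)
  conds <- unique(data[c("B0_T", "temp_K")])
  rownames(conds) <- NULL
  if (nrow(conds) < 2)
    stop("need data spanning at least two fields or temperatures")
  cells <- list()
  for (m in methyls) for (ci in seq_len(nrow(conds))) {
    rows <- which(data$methyl_id == m & data$B0_T == conds$B0_T[ci] &
                    data$temp_K == conds$temp_K[ci])
    if (!length(rows)) next
    nu <- data$nu_cpmg_Hz[rows]
    cells[[length(cells) + 1]] <- list(
      m = m, ci = ci, rows = rows,
      npulses = 2L * pmax(1L, as.integer(round(T_relax * nu))),
      obs = data$r2eff_s[rows], sigma = data$sigma_s[rows],
      B0 = conds$B0_T[ci], temp = conds$temp_K[ci])
  }
  list(topology = topology, minors = minors, labs = labs,
       methyls = methyls, conds = conds, cells = cells,
       T_relax = T_relax, n_points = nrow(data),
       temps = sort(unique(conds$temp_K)))
}

theta_names <- function(ctx) {
  c(paste0("dG_", ctx$minors), paste0("dH_", ctx$minors),
    paste0("dGts_", ctx$labs), paste0("dHts_", ctx$labs),
    as.vector(outer(ctx$methyls, ctx$minors,
                    function(m, s) paste0("dw_", m, ".", s))))
}

theta_bounds <- function(ctx) {
  nm <- theta_names(ctx)
  lo <- hi <- setNames(numeric(length(nm)), nm)
  lo[grep("^dG_", nm)] <- 0.15;  hi[grep("^dG_", nm)] <- 23
  lo[grep("^dH_", nm)] <- -150;  hi[grep("^dH_", nm)] <- 250
  lo[grep("^dGts_", nm)] <- 40;  hi[grep("^dGts_", nm)] <- 80
  lo[grep("^dHts_", nm)] <- -50; hi[grep("^dHts_", nm)] <- 250
  lo[grep("^dw_", nm)] <- 0;     hi[grep("^dw_", nm)] <- 10
  list(lower = lo, upper = hi)
}

theta_to_model <- function(theta, ctx) {
  g <- function(p) theta[paste0(p, ctx$minors)]
  ge <- function(p) theta[paste0(p, ctx$labs)]
  dH <- setNames(g("dH_"), ctx$minors)
  dS <- setNames((g("dH_") - g("dG_")) / T_REF, ctx$minors)
  dHts <- setNames(ge("dHts_"), ctx$labs)
  dSts <- setNames((ge("dHts_") - ge("dGts_")) / T_REF, ctx$labs)
  thermo_exchange_model(ctx$topology, dH, dS, dHts, dSts)
}

theta_dw <- function(theta, ctx) {
  dw <- matrix(theta[as.vector(outer(ctx$methyls, ctx$minors,
                                     function(m, s) paste0("dw_", m, ".", s)))],
               nrow = length(ctx$methyls),
               dimnames = list(ctx$methyls, ctx$minors))
  dw
}

# model R2,eff without the r2_mq0 offset, per cell, plus profiled r2_mq0
predict_cells <- function(theta, ctx, dw_H = 0.01) {
  model <- theta_to_model(theta, ctx)
  Kp <- lapply(ctx$temps, function(Tk)
    list(K = suppressWarnings(build_exchange_matrix(model, Tk)),
         p = state_populations(model, Tk)))
  names(Kp) <- as.character(ctx$temps)
  dw <- theta_dw(theta, ctx)
  lapply(ctx$cells, function(cell) {
    kp <- Kp[[as.character(cell$temp)]]
    dwC <- c(0, dw[cell$m, ])
    dwH <- c(0, rep(dw_H, length(ctx$minors)))
    mod0 <- mq_r2eff_cpp(kp$K, 0,
                         ppm_to_rad(dwC, cell$B0, codata$gamma_C),
                         ppm_to_rad(dwH, cell$B0, codata$gamma_H),
                         kp$p, cell$npulses, ctx$T_relax)
    w <- 1 / cell$sigma^2
    r2hat <- sum(w * (cell$obs - mod0)) / sum(w)
    list(mod0 = mod0, r2hat = r2hat, calc = mod0 + r2hat)
  })
}

# guardrail penalties: keep all edge rates within [1, 1e5] s^-1 at every
# data temperature (soft hinge, zero inside the box)
rate_penalty <- function(theta, ctx) {
  model <- theta_to_model(theta, ctx)
  pen <- numeric(0)
  for (Tk in ctx$temps) {
    K <- suppressWarnings(build_exchange_matrix(model, Tk))
    k <- K[row(K) != col(K)]
    k <- k[k > 0]
    pen <- c(pen, 20 * pmax(0, log10(k / 1e5)), 20 * pmax(0, log10(1 / k)))
  }
  pen
}

fit_residuals <- function(theta, ctx, dw_H = 0.01) {
  pr <- predict_cells(theta, ctx, dw_H)
  res <- unlist(lapply(seq_along(ctx$cells), function(i)
    (ctx$cells[[i]]$obs - pr[[i]]$calc) / ctx$cells[[i]]$sigma))
  c(res, rate_penalty(theta, ctx))
}

default_starts <- function(ctx) {
  # ordered so that any prefix (n_starts < 12) still spans the kex grid
  combos <- list(c(1000, 0.05), c(300, 0.05), c(3000, 0.15),
                 c(100, 0.01), c(1000, 0.15), c(300, 0.01),
                 c(3000, 0.05), c(100, 0.05), c(1000, 0.01),
                 c(300, 0.15), c(3000, 0.01), c(100, 0.15))
  starts <- list()
  for (cmb in combos) {
    kex <- cmb[1]; p <- cmb[2]
    th <- setNames(numeric(length(theta_names(ctx))), theta_names(ctx))
    RT <- codata$R_kJ * T_REF
    for (i in seq_along(ctx$minors)) {
      s <- ctx$minors[i]
      pi <- p * ifelse(i == 1, 1, 0.7)        # break minor-state symmetry
      th[paste0("dG_", s)] <- -RT * log(pi / (1 - pi))
      th[paste0("dH_", s)] <- th[paste0("dG_", s)]   # dS seed = 0
    }
    kex_edge <- kex * c(1, 0.35)   # second edge seeded slower
    for (li in seq_along(ctx$labs)) {
      lab <- ctx$labs[li]
      sts <- strsplit(lab, "-")[[1]]
      p_all <- c(A = 1 - sum(p * c(1, 0.7)[seq_along(ctx$minors)]),
                 setNames(p * c(1, 0.7)[seq_along(ctx$minors)], ctx$minors))
      i <- sts[1]; j <- sts[2]
      k_ij <- kex_edge[li] * p_all[[j]] / (p_all[[i]] + p_all[[j]])
      dGi <- if (i == "A") 0 else th[paste0("dG_", i)]
      th[paste0("dGts_", lab)] <-
        dGi - RT * log(k_ij * codata$h / (codata$kB * T_REF))
      th[paste0("dHts_", lab)] <- th[paste0("dGts_", lab)]  # dS ts seed = 0
    }
    th[grep("^dw_", names(th))] <- 1.0
    starts[[length(starts) + 1]] <- th
  }
  starts
}

relabel_minors <- function(theta, ctx) {
  # tie-break: order minor states so p_B >= p_C at 298 K
  # (smaller dG at 298 K <=> larger population)
  if (length(ctx$minors) < 2 || theta[["dG_B"]] <= theta[["dG_C"]])
    return(list(theta = theta, ctx = ctx))
  sw <- function(s) ifelse(s == "B", "C", ifelse(s == "C", "B", s))
  rename <- function(nm) {
    vapply(nm, function(x) {
      if (grepl("^(dG|dH)_[BC]$", x)) {
        parts <- strsplit(x, "_")[[1]]
        paste0(parts[1], "_", sw(parts[2]))
      } else if (grepl("^(dGts|dHts)_", x)) {
        pre <- sub("_.*$", "", x)
        lab <- sub("^[^_]*_", "", x)
        st <- sw(strsplit(lab, "-")[[1]])
        paste0(pre, "_", paste(sort(st), collapse = "-"))
      } else if (grepl("^dw_", x)) {
        minor <- sub("^.*\\.", "", x)
        paste0(sub("\\.[^.]*$", "", x), ".", sw(minor))
      } else x
    }, "")
  }
  names(theta) <- rename(names(theta))
  topo <- ctx$topology
  if (topo$name == "linear_three_site")
    topo <- exchange_topology("linear_three_site",
                              middle = if (topo$middle == "B") "C" else "B")
  ctx2 <- ctx; ctx2$topology <- topo
  ctx2$labs <- vapply(topo$edges, edge_label, "")
  list(theta = theta[theta_names(ctx2)], ctx = ctx2)
}

#' Globally fit a dispersion dataset for one dynamic region
#'
#' Least-squares fit of all methyls, fields and temperatures of a region
#' to a single thermodynamic exchange model (Eyring temperature
#' dependence) plus per-methyl, temperature-independent |dw_C|; 1H
#' offsets are fixed at 0.01 ppm.  Objective:
#' `chi2 = sum((obs - calc)^2 / sigma^2)`.
#'
#' Initialisation uses a multi-start grid over exchange rates
#' {100, 300, 1000, 3000} s^-1 and minor populations {0.01, 0.05, 0.15}
#' (entropy seeds 0), because CPMG objectives are multimodal; the best
#' converged start is kept.  Box bounds keep minor populations within
#' [1e-4, 0.45], |dw| within [0, 10] ppm, and a soft penalty keeps all
#' rates within [1, 1e5] s^-1 at the fitted temperatures.
#'
#' @param data a [dispersion_dataset()] (one region).
#' @param topology an [exchange_topology()].
#' @param starts optional list of named start vectors (overrides the
#'   default grid).
#' @param n_starts optionally use only the first `n_starts` of the grid.
#' @param dw_H fixed 1H offset, ppm.
#' @param T_relax constant-time delay, s.
#' @param maxiter optimizer iteration cap per start.
#' @return object of class `region_fit_result`: the fitted
#'   `thermo_exchange_model`, `dw` matrix (ppm), profiled `r2_mq0`
#'   matrix, `chi2`, `dof`, `chi2_red`, `n_points`, `theta`, per-point
#'   `fitted` table, and bookkeeping about the starts.
#' @export
fit_region <- function(data, topology, starts = NULL, n_starts = NULL,
                       dw_H = 0.01, T_relax = 0.030, maxiter = 200) {
  data <- dispersion_dataset(as.data.frame(data))
  ctx <- fit_context(data, topology, T_relax)
  if (is.null(starts)) starts <- default_starts(ctx)
  if (!is.null(n_starts)) starts <- starts[seq_len(min(n_starts,
                                                       length(starts)))]
  b <- theta_bounds(ctx)
  best <- NULL
  history <- numeric(length(starts))
  for (si in seq_along(starts)) {
    th0 <- pmin(pmax(starts[[si]][theta_names(ctx)], b$lower), b$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = b$lower, upper = b$upper,
                         fn = fit_residuals, ctx = ctx, dw_H = dw_H,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, nprint = 0)),
      error = function(e) NULL)
    if (is.null(fit)) { history[si] <- NA; next }
    history[si] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("dispersion fit failed to converge from any start")
  rl <- relabel_minors(coef(best), ctx)
  theta <- rl$theta; ctx <- rl$ctx
  pr <- predict_cells(theta, ctx, dw_H)
  chi2 <- sum(unlist(lapply(seq_along(ctx$cells), function(i)
    ((ctx$cells[[i]]$obs - pr[[i]]$calc) / ctx$cells[[i]]$sigma)^2)))
  r2mat <- matrix(NA_real_, length(ctx$methyls), nrow(ctx$conds),
                  dimnames = list(ctx$methyls,
                                  paste0(ctx$conds$B0_T, "T/",
                                         ctx$conds$temp_K, "K")))
  fitted <- data
  fitted$calc <- NA_real_
  for (i in seq_along(ctx$cells)) {
    cell <- ctx$cells[[i]]
    r2mat[cell$m, cell$ci] <- pr[[i]]$r2hat
    fitted$calc[cell$rows] <- pr[[i]]$calc
  }
  n_free <- length(theta) + sum(!is.na(r2mat))
  dof <- ctx$n_points - n_free
  if (dof <= 0) stop("non-positive degrees of freedom (", dof, ")")
  structure(list(model = theta_to_model(theta, ctx),
                 topology = ctx$topology,
                 dw = theta_dw(theta, ctx), r2_mq0 = r2mat,
                 chi2 = chi2, dof = dof, chi2_red = chi2 / dof,
                 n_points = ctx$n_points, n_free = n_free,
                 theta = theta, fitted = fitted, dw_H = dw_H,
                 T_relax = T_relax, start_deviances = history,
                 converged = best$info %in% 1:4, ctx = ctx),
            class = "region_fit_result")
}

#' @export
print.region_fit_result <- function(x, ...) {
  cat("Region fit:", x$topology$name, "\n")
  cat(sprintf("  chi2 = %.4g, dof = %d, chi2_red = %.4g\n",
              x$chi2, x$dof, x$chi2_red))
  p <- state_populations(x$model, 298)
  cat("  populations at 298 K:",
      paste(sprintf("%s=%.4f", names(p), p), collapse = " "), "\n")
  invisible(x)
}

#' Compare two nested dispersion fits by F-test
#'
#' `F = ((chi2_a - chi2_b) / (dof_a - dof_b)) / (chi2_b / dof_b)` with
#' `a` the simpler model; the p-value is the upper tail of the F
#' distribution with `(dof_a - dof_b, dof_b)` degrees of freedom.
#'
#' @param fit_a,fit_b [fit_region()] results on the same data, with
#'   `fit_a` nested in (fewer parameters than) `fit_b`.
#' @return list with `F`, `p_value`, `df1`, `df2`.
#' @export
compare_topologies <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "region_fit_result"),
            inherits(fit_b, "region_fit_result"))
  if (fit_a$n_points != fit_b$n_points)
    stop("fits are not on the same data (different numbers of points)")
  if (fit_a$dof < fit_b$dof)
    stop("fit_a must be the simpler (nested) model")
  if (fit_a$dof == fit_b$dof) {
    eq <- isTRUE(all.equal(fit_a$chi2, fit_b$chi2, tolerance = 1e-12))
    return(list(F = 0, p_value = 1, df1 = 0, df2 = fit_b$dof,
                identical_fits = eq))
  }
  d1 <- fit_a$dof - fit_b$dof
  Fv <- max(0, (fit_a$chi2 - fit_b$chi2) / d1) / (fit_b$chi2 / fit_b$dof)
  list(F = Fv, p_value = pf(Fv, d1, fit_b$dof, lower.tail = FALSE),
       df1 = d1, df2 = fit_b$dof)
}

#' Monte Carlo parameter uncertainties
#'
#' Resamples synthetic datasets from the best-fit curves plus Gaussian
#' noise at the reported per-point sigma, refits each (starting from the
#' best-fit parameters), and returns the standard deviation of every
#' fitted parameter plus derived quantities (minor-state populations and
#' edge exchange rates at 298 K).  Deterministic for a given seed.
#'
#' @param fit a converged [fit_region()] result.
#' @param n_mc number of Monte Carlo replicates (>= 20 recommended).
#' @param seed RNG seed.
#' @param maxiter optimizer cap per refit.
#' @return list with `param_sd`, `derived_sd`, and the full `draws` /
#'   `derived` matrices.
#' @export
monte_carlo_errors <- function(fit, n_mc = 100, seed = 1, maxiter = 100) {
  stopifnot(inherits(fit, "region_fit_result"))
  if (n_mc < 20) warning("n_mc < 20 gives unreliable uncertainty estimates")
  ctx <- fit$ctx
  b <- theta_bounds(ctx)
  set.seed(seed)
  draws <- matrix(NA_real_, n_mc, length(fit$theta),
                  dimnames = list(NULL, names(fit$theta)))
  derived <- NULL
  calc <- fit$fitted$calc
  sig <- fit$fitted$sigma_s
  for (k in seq_len(n_mc)) {
    ctx_k <- ctx
    noise <- rnorm(length(calc), 0, sig)
    for (i in seq_along(ctx_k$cells))
      ctx_k$cells[[i]]$obs <- calc[ctx_k$cells[[i]]$rows] +
        noise[ctx_k$cells[[i]]$rows]
    ft <- tryCatch(
      minpack.lm::nls.lm(par = fit$theta, lower = b$lower, upper = b$upper,
                         fn = fit_residuals, ctx = ctx_k, dw_H = fit$dw_H,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(ft)) next
    draws[k, ] <- coef(ft)
    mdl <- theta_to_model(coef(ft), ctx_k)
    p <- state_populations(mdl, 298)
    K <- suppressWarnings(build_exchange_matrix(mdl, 298))
    kex <- vapply(ctx_k$topology$edges, function(e)
      K[e[2], e[1]] + K[e[1], e[2]], 0)
    d <- c(setNames(p[-1], paste0("p_", names(p)[-1])),
           setNames(kex, paste0("kex_",
                                vapply(ctx_k$topology$edges, edge_label, ""))))
    if (is.null(derived))
      derived <- matrix(NA_real_, n_mc, length(d),
                        dimnames = list(NULL, names(d)))
    derived[k, ] <- d
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2) stop("too few successful Monte Carlo refits")
  list(param_sd = apply(draws[ok, , drop = FALSE], 2, sd),
       derived_sd = apply(derived[ok, , drop = FALSE], 2, sd),
       draws = draws[ok, , drop = FALSE],
       derived = derived[ok, , drop = FALSE], n_ok = sum(ok))
}

#' Weighted chemical-shift perturbation
#'
#' `dCS = sqrt((ddH / alpha)^2 + (ddC / beta)^2)`, the standard weighted
#' methyl CSP with the 1H and 13C shift changes scaled by the chemical
#' shift dispersions `alpha`, `beta` of the methyl type.
#'
#' @param ddH,ddC 1H and 13C chemical-shift changes, ppm.
#' @param alpha,beta positive scale factors, ppm.
#' @return dimensionless CSP (vectorised).
#' @export
compute_csp <- function(ddH, ddC, alpha, beta) {
  stopifnot(all(alpha > 0), all(beta > 0))
  sqrt((ddH / alpha)^2 + (ddC / beta)^2)
}

#' Pearson correlation between two chemical-shift sets
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Pearson correlation coefficient.
#' @export
correlate_shift_sets <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with at least 3 entries")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in a shift set")
  cor(x, y)
}
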