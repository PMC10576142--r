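#' Experimental constraint set
#'
#' Macroscopic observables used to fit the global microkinetic
#' parameters: rows of (variant, solvent, observable, value, sd) with
#' observable one of `kcat` (s^-1), `KM` (M), `kcat_over_KM`
#' (M^-1 s^-1), `kd` (M), `koff_macro` (s^-1).  All values in SI units.
#'
#' @param df data frame with the columns above.
#' @return validated data frame of class `constraint_set`.
#' @export
constraint_set <- function(df) {
  need <- c("variant", "solvent", "observable", "value", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  okobs <- c("kcat", "KM", "kcat_over_KM", "kd", "koff_macro")
  if (!all(df$observable %in% okobs))
    stop("observable must be one of: ", paste(okobs, collapse = ", "))
  if (!all(df$solvent %in% c("H2O", "D2O"))) stop("solvent must be H2O or D2O")
  if (any(!is.finite(df$sd) | df$sd <= 0)) stop("sd must be positive")
  rownames(df) <- NULL
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Enumerate candidate kinetic models
#'
#' Generates the combinatorial family of kinetic model specifications in
#' which the substrate associates/dissociates through a pair of
#' conformations and the lysine product is released from a single
#' conformation (or a declared group).  Hydrolysis and acetate-release
#' sites are fixed by the model-specification defaults.  The default pools are all
#' conformations of the manifold; the shipped default family for the
#' 18-conformation space therefore has choose(18,2) x 18 = 2754 members
#' and contains the two experimentally supported models (see
#' [model1_spec()], [model2_spec()]).
#'
#' @param space a [build_state_space()] result.
#' @param substrate_pool conformation indices eligible as binding sites.
#' @param lysine_pool conformation indices eligible as single release
#'   sites.
#' @param lysine_groups optional list of index vectors used as grouped
#'   release sites instead of `lysine_pool` singletons.
#' @param include_single_site also include conformational-selection-type
#'   models where binding is restricted to one conformation.
#' @return list of [kinetic_model_spec()] objects (deduplicated), with a
#'   `count` attribute.
#' @export
enumerate_models <- function(space, substrate_pool = NULL,
                             lysine_pool = NULL, lysine_groups = NULL,
                             include_single_site = FALSE) {
  if (is.null(substrate_pool)) substrate_pool <- seq_len(space$n_conf)
  if (is.null(lysine_pool)) lysine_pool <- seq_len(space$n_conf)
  if (length(substrate_pool) < 2 && !include_single_site)
    stop("empty enumeration: substrate pool has fewer than 2 conformations")
  pairs <- if (length(substrate_pool) >= 2)
    utils::combn(sort(substrate_pool), 2, simplify = FALSE) else list()
  if (include_single_site)
    pairs <- c(pairs, as.list(sort(substrate_pool)))
  lys <- if (is.null(lysine_groups)) as.list(sort(lysine_pool))
         else lysine_groups
  out <- list()
  seen <- character(0)
  for (ss in pairs) for (ls in lys) {
    key <- paste(paste(ss, collapse = ","), paste(ls, collapse = ","),
                 sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1]] <- kinetic_model_spec(space, ss, ls)
  }
  if (!length(out)) stop("empty enumeration")
  attr(out, "count") <- length(out)
  out
}

#' The two experimentally supported kinetic models
#'
#' `model1_spec`: substrate binds/dissociates through the conformations
#' (L1 bound-like, L2,6 release, CAT B) and (L1 bound-like, L2,6
#' free-like, CAT B); lysine product released from (L1 bound-like, L2,6
#' free-like, CAT B).  `model2_spec` is identical except that lysine is
#' released from (L1 bound-like, L2,6 release, CAT B).
#' `conformational_selection_spec` restricts binding and release to the
#' hydrolysis-competent conformation itself.
#'
#' @param space a [build_state_space()] result.
#' @return a [kinetic_model_spec()].
#' @export
model1_spec <- function(space) {
  kinetic_model_spec(
    space,
    substrate_sites = c(conf_index(space, L1 = "boundlike",
                                   L26 = "release", CAT = "B"),
                        conf_index(space, L1 = "boundlike",
                                   L26 = "freelike", CAT = "B")),
    lysine_sites = conf_index(space, L1 = "boundlike", L26 = "freelike",
                              CAT = "B"))
}

#' @rdname model1_spec
#' @export
model2_spec <- function(space) {
  kinetic_model_spec(
    space,
    substrate_sites = c(conf_index(space, L1 = "boundlike",
                                   L26 = "release", CAT = "B"),
                        conf_index(space, L1 = "boundlike",
                                   L26 = "freelike", CAT = "B")),
    lysine_sites = conf_index(space, L1 = "boundlike", L26 = "release",
                              CAT = "B"))
}

#' @rdname model1_spec
#' @export
conformational_selection_spec <- function(space) {
  h <- conf_index(space, L1 = "boundlike", L26 = "boundlike", CAT = "A")
  kinetic_model_spec(space, substrate_sites = h, lysine_sites = h)
}

spec_id <- function(spec) {
  paste0("S", paste(spec$substrate_sites, collapse = "."),
         "_L", paste(spec$lysine_sites, collapse = "."))
}

# forward-compute the macroscopic observables required by a constraint
# table for one parameter set; one network evaluation per needed
# (variant, solvent, class) combination
forward_observables <- function(space, spec, rates_by_variant, params,
                                constraints, method = "steady",
                                design = NULL, T_K = 298) {
  if (is.null(design))
    design <- if (method == "steady")
      assay_design(S_grid = c(0, exp(seq(log(1e-4), log(0.25),
                                         length.out = 14))), n_t = 4000)
    else assay_design()
  calc <- numeric(nrow(constraints))
  for (v in unique(constraints$variant)) {
    rates <- rates_by_variant[[v]]
    if (is.null(rates)) stop("no intrinsic rates for variant: ", v)
    for (sv in unique(constraints$solvent[constraints$variant == v])) {
      idx <- which(constraints$variant == v & constraints$solvent == sv)
      obs <- constraints$observable[idx]
      if (any(obs %in% c("kcat", "KM", "kcat_over_KM"))) {
        mm <- michaelis_menten(space, spec, rates, params, design,
                               solvent = sv, T_K = T_K, method = method)
        calc[idx[obs == "kcat"]] <- mm$kcat
        calc[idx[obs == "KM"]] <- mm$KM
        calc[idx[obs == "kcat_over_KM"]] <- mm$kcat / mm$KM
      }
      if (any(obs %in% c("kd", "koff_macro"))) {
        io <- inhibitor_observables(space, spec, rates, params,
                                    T_K = T_K, method = method)
        calc[idx[obs == "kd"]] <- io$kd
        calc[idx[obs == "koff_macro"]] <- io$koff_macro
      }
    }
  }
  calc
}

#' Fit the global microkinetic parameters of a kinetic model
#'
#' Bounded multi-start least squares in log-parameter space for
#' {k_on, k_off_I, k_off_S (= k_off_P), k_H} (4-parameter mode) or with
#' k_off_P free (5-parameter mode), against a [constraint_set()] of
#' macroscopic observables for one or more enzyme variants.  D2O
#' constraints are computed with the hydrolysis rate divided by the
#' solvent kinetic isotope effect (8.8); the acetate off-rate is fixed
#' at the diffusion limit.  Forward-model failures at trial parameters
#' are absorbed as large residual penalties and logged.
#'
#' @param spec a [kinetic_model_spec()].
#' @param constraints a [constraint_set()].
#' @param rates_by_variant named list: variant -> [region_rate_set()].
#' @param space a [build_state_space()] result.
#' @param mode `"4-param"` or `"5-param"`.
#' @param method forward route, `"steady"` (fast, used in ranking scans)
#'   or `"ode"` (reference).
#' @param design optional [assay_design()].
#' @param starts list of named start vectors (natural units); defaults
#'   to a coarse grid.
#' @param kie solvent kinetic isotope effect factor.
#' @param maxiter optimizer cap per start.
#' @return object of class `model_fit_result` with the fitted
#'   [kinetic_params()], `chi2`, `chi2_red`, `dof`, per-constraint
#'   `fitted` table and bookkeeping.
#' @export
fit_global <- function(spec, constraints, rates_by_variant, space,
                       mode = c("4-param", "5-param"),
                       method = c("steady", "ode"), design = NULL,
                       starts = NULL, kie = 8.8, maxiter = 100) {
  mode <- match.arg(mode); method <- match.arg(method)
  constraints <- constraint_set(as.data.frame(constraints))
  pn <- c("k_on", "k_off_I", "k_off_S", "k_H")
  if (mode == "5-param") pn <- c(pn, "k_off_P")
  lower <- log10(c(k_on = 1e3, k_off_I = 1e-4, k_off_S = 1e-2,
                   k_H = 1e-4, k_off_P = 1e-2))[pn]
  upper <- log10(c(k_on = 1e10, k_off_I = 1e7, k_off_S = 1e8,
                   k_H = 1e4, k_off_P = 1e8))[pn]
  if (is.null(starts)) {
    starts <- list(c(k_on = 1e6, k_off_I = 100, k_off_S = 1e4, k_H = 1),
                   c(k_on = 1e7, k_off_I = 1e3, k_off_S = 1e6, k_H = 10),
                   c(k_on = 1e5, k_off_I = 10, k_off_S = 1e2, k_H = 0.1))
  }
  if (mode == "5-param") {
    # seed the 5-parameter fit from the 4-parameter optimum so the
    # nested fit can never end up worse
    pre <- fit_global(spec, constraints, rates_by_variant, space,
                      mode = "4-param", method = method, design = design,
                      starts = starts, kie = kie, maxiter = maxiter)
    starts <- c(list(c(k_on = pre$params$k_on, k_off_I = pre$params$k_off_I,
                       k_off_S = pre$params$k_off_S, k_H = pre$params$k_H)),
                starts)
  }
  starts <- lapply(starts, function(s) {
    if (mode == "5-param" && !"k_off_P" %in% names(s))
      s <- c(s, k_off_P = s[["k_off_S"]])
    s[pn]
  })
  n_fail <- 0L
  resfun <- function(lp) {
    p <- 10^lp
    prm <- kinetic_params(k_on = p[["k_on"]], k_off_S = p[["k_off_S"]],
                          k_H = p[["k_H"]], k_off_I = p[["k_off_I"]],
                          k_off_P = if (mode == "5-param") p[["k_off_P"]]
                                    else p[["k_off_S"]],
                          kie = kie)
    calc <- tryCatch(
      forward_observables(space, spec, rates_by_variant, prm,
                          constraints, method = method, design = design),
      error = function(e) { n_fail <<- n_fail + 1L; NULL })
    if (is.null(calc)) return(rep(1e3, nrow(constraints)))
    (constraints$value - calc) / constraints$sd
  }
  best <- NULL
  for (s in starts) {
    lp0 <- pmin(pmax(log10(s[pn]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = lp0, lower = lower, upper = upper,
                         fn = resfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("global fit failed from every start")
  p <- 10^coef(best)
  params <- kinetic_params(k_on = p[["k_on"]], k_off_S = p[["k_off_S"]],
                           k_H = p[["k_H"]], k_off_I = p[["k_off_I"]],
                           k_off_P = if (mode == "5-param") p[["k_off_P"]]
                                     else p[["k_off_S"]],
                           kie = kie)
  calc <- forward_observables(space, spec, rates_by_variant, params,
                              constraints, method = method, design = design)
  chi2 <- sum(((constraints$value - calc) / constraints$sd)^2)
  dof <- nrow(constraints) - length(pn)
  fitted <- cbind(as.data.frame(constraints), calc = calc)
  structure(list(spec = spec, spec_id = spec_id(spec), params = params,
                 chi2 = chi2, dof = dof,
                 chi2_red = if (dof > 0) chi2 / dof else NA_real_,
                 n_constraints = nrow(constraints), mode = mode,
                 method = method, fitted = fitted,
                 n_forward_failures = n_fail,
                 converged = best$info %in% 1:4),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat("Kinetic model fit [", x$spec_id, "] (", x$mode, ", ", x$method,
      ")\n", sep = "")
  cat(sprintf("  chi2 = %.4g (red. %.3g, dof %d)\n", x$chi2, x$chi2_red,
              x$dof))
  cat(sprintf("  k_on = %.3g /M/s, k_off_S = %.3g /s, k_H = %.3g /s, k_off_I = %.3g /s\n",
              x$params$k_on, x$params$k_off_S, x$params$k_H,
              x$params$k_off_I))
  invisible(x)
}

#' Rank fitted kinetic models
#'
#' Sorts fits (which must share the same constraints) by chi-squared and
#' reports, for every model, a likelihood-ratio-style P-value against
#' the best model: `P = Pr(chisq_df >= chi2 - chi2_best)` with `df = 1`
#' by default, a pragmatic comparison for equal-dimensional non-nested
#' candidates.
#'
#' @param results list of [fit_global()] results.
#' @param df degrees of freedom of the comparison statistic.
#' @return data frame with rank, model id, chi2, chi2_red, p_vs_best;
#'   the sorted fits are attached as attribute `fits`.
#' @export
rank_models <- function(results, df = 1) {
  stopifnot(length(results) >= 1)
  n <- vapply(results, function(r) r$n_constraints, 1)
  if (length(unique(n)) != 1)
    stop("fits do not share a common constraint set")
  chi2 <- vapply(results, function(r) r$chi2, 1)
  ord <- order(chi2)              # stable: ties keep input order
  tab <- data.frame(
    rank = seq_along(ord),
    model = vapply(results[ord], function(r) r$spec_id, ""),
    chi2 = chi2[ord],
    chi2_red = vapply(results[ord], function(r) r$chi2_red, 1),
    p_vs_best = stats::pchisq(pmax(0, chi2[ord] - min(chi2)), df = df,
                              lower.tail = FALSE))
  attr(tab, "fits") <- results[ord]
  tab
}

#' Cross-validate a fitted kinetic model on a held-out variant
#'
#' Forward-computes the held-out observables with the trained parameters
#' and the held-out variant's intrinsic rates, and returns
#' `cv_chi2 = sum((obs - calc)^2 / sigma^2)` and
#' `cv_chi2_red = cv_chi2 / n_heldout`.
#'
#' @param fit a [fit_global()] result.
#' @param heldout_rates [region_rate_set()] of the held-out variant.
#' @param heldout_obs [constraint_set()] of held-out observables.
#' @param space a [build_state_space()] result.
#' @param method forward route (defaults to the fit's).
#' @param design optional [assay_design()].
#' @return list with `cv_chi2`, `cv_chi2_red`, `n`, and the `fitted`
#'   table.
#' @export
cross_validate <- function(fit, heldout_rates, heldout_obs, space,
                           method = fit$method, design = NULL) {
  stopifnot(inherits(fit, "model_fit_result"))
  heldout_obs <- constraint_set(as.data.frame(heldout_obs))
  if (any(heldout_obs$variant %in% fit$fitted$variant))
    stop("held-out variant also appears in the training constraints")
  rv <- setNames(rep(list(heldout_rates), length(unique(heldout_obs$variant))),
                 unique(heldout_obs$variant))
  calc <- forward_observables(space, fit$spec, rv, fit$params,
                              heldout_obs, method = method, design = design)
  cv <- sum(((heldout_obs$value - calc) / heldout_obs$sd)^2)
  list(cv_chi2 = cv, cv_chi2_red = cv / nrow(heldout_obs),
       n = nrow(heldout_obs),
       fitted = cbind(as.data.frame(heldout_obs), calc = calc))
}
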