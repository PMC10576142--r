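#' Read a dispersion dataset CSV
#'
#' Schema: one optional metadata line starting with `#`, a header, then
#' columns `methyl_id, region, B0_T, temp_K, nu_cpmg_Hz, r2eff_s,
#' sigma_s`; alternatively intensity columns `intensity, intensity_ref,
#' T_relax_s` (plus `sigma_intensity` if available) which are converted
#' with [r2eff_from_intensities()] on load.  Duplicate (methyl, field,
#' temperature, nu) rows and non-positive uncertainties are rejected
#' with descriptive errors.
#'
#' @param path CSV file path.
#' @return a [dispersion_dataset()].
#' @export
load_dispersion_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (all(c("intensity", "intensity_ref", "T_relax_s") %in% names(df)) &&
      !"r2eff_s" %in% names(df)) {
    df$r2eff_s <- r2eff_from_intensities(df$intensity, df$intensity_ref,
                                         df$T_relax_s[1])
    if ("sigma_intensity" %in% names(df)) {
      # first-order propagation of the intensity uncertainty
      df$sigma_s <- df$sigma_intensity / (df$intensity * df$T_relax_s[1])
    }
    if (any(is.na(df$r2eff_s))) {
      warning("dropping ", sum(is.na(df$r2eff_s)),
              " rows with non-positive intensities")
      df <- df[!is.na(df$r2eff_s), , drop = FALSE]
    }
  }
  dispersion_dataset(df)
}

#' Write a dispersion dataset CSV
#'
#' @param data a [dispersion_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(data, path) {
  data <- dispersion_dataset(as.data.frame(data))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# excat dispersion dataset; units: B0_T Tesla,",
                    " temp_K Kelvin, nu_cpmg_Hz Hz, r2eff_s s^-1,",
                    " sigma_s s^-1"), con)
  write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' Write / read a region fit result as JSON
#'
#' Serializes the fitted thermodynamic parameters, per-methyl shifts,
#' profiled intrinsic rates, chi-squared statistics and (if present)
#' Monte Carlo uncertainties.
#'
#' @param fit a [fit_region()] result.
#' @param path output path.
#' @param mc optional [monte_carlo_errors()] result to embed.
#' @return `path` invisibly (writer); a list (reader).
#' @export
write_region_fit_json <- function(fit, path, mc = NULL) {
  stopifnot(inherits(fit, "region_fit_result"))
  doc <- list(
    topology = fit$topology$name,
    theta = as.list(fit$theta),
    dw_ppm = as.data.frame(fit$dw),
    r2_mq0 = as.data.frame(fit$r2_mq0),
    chi2 = fit$chi2, dof = fit$dof, chi2_red = fit$chi2_red,
    n_points = fit$n_points, n_free = fit$n_free,
    converged = fit$converged,
    populations_298K = as.list(state_populations(fit$model, 298)),
    param_sd = if (!is.null(mc)) as.list(mc$param_sd) else NULL,
    derived_sd = if (!is.null(mc)) as.list(mc$derived_sd) else NULL)
  if (!is.na(fit$topology$middle)) doc$middle <- fit$topology$middle
  doc <- doc[!vapply(doc, is.null, TRUE)]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_fit_json
#' @export
read_region_fit_json <- function(path) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)

#' Write fitted dispersion curves for plotting
#'
#' @param fit a [fit_region()] result.
#' @param path CSV output path.
#' @return `path` invisibly.
#' @export
write_fitted_curves_csv <- function(fit, path) {
  stopifnot(inherits(fit, "region_fit_result"))
  write.csv(as.data.frame(fit$fitted), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a kinetic model specification and parameters
#'
#' @param spec a [kinetic_model_spec()].
#' @param params a [kinetic_params()].
#' @param path YAML output path.
#' @return `path` invisibly (writer); a list with `spec` and `params`
#'   (reader, given a `space`).
#' @export
write_kinetic_config <- function(spec, params, path) {
  yaml::write_yaml(list(
    substrate_sites = spec$substrate_sites,
    lysine_sites = spec$lysine_sites,
    hydrolysis_site = spec$hydrolysis_site,
    acetate_sites = spec$acetate_sites,
    params = list(k_on = params$k_on, k_off_S = params$k_off_S,
                  k_H = params$k_H, k_off_I = params$k_off_I,
                  k_off_P = params$k_off_P, k_off_ace = params$k_off_ace,
                  kie = params$kie)), path)
  invisible(path)
}

#' @rdname write_kinetic_config
#' @param space a [build_state_space()] used to validate indices.
#' @export
read_kinetic_config <- function(path, space) {
  doc <- yaml::read_yaml(path)
  spec <- kinetic_model_spec(space,
                             substrate_sites = unlist(doc$substrate_sites),
                             lysine_sites = unlist(doc$lysine_sites),
                             hydrolysis_site = unlist(doc$hydrolysis_site),
                             acetate_sites = unlist(doc$acetate_sites))
  p <- doc$params
  params <- kinetic_params(k_on = p$k_on, k_off_S = p$k_off_S, k_H = p$k_H,
                           k_off_I = p$k_off_I, k_off_P = p$k_off_P,
                           k_off_ace = p$k_off_ace, kie = p$kie)
  list(spec = spec, params = params)
}

cli_usage <- function() {
  cat("usage: excat <command> [--flag value ...]\n",
      "commands:\n",
      "  synth cpmg      --seed <int> --out <csv> [--n-methyls n]\n",
      "                  [--topology two_site|bifurcated_three_site|linear_three_site]\n",
      "  fit-dispersion  --data <csv> --topology <name> --seed <int>\n",
      "                  [--n-mc n] [--n-starts n] --out <json>\n",
      "  simulate-cycle  --model <yaml> [--inhibitor] --out <json>\n",
      "  select-model    --constraints <csv> --seed <int> --out <json>\n",
      "                  [--n-models n]\n",
      "  cross-validate  --model <json> --heldout <csv> --out <json>\n",
      sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE; i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  flags
}

flag <- function(flags, name, default = NULL, required = FALSE) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (required) stop("missing required flag --", name)
    return(default)
  }
  v
}

#' Command-line dispatcher
#'
#' A thin shell interface over the package's functions (see
#' `inst/exec/excat` for the executable wrapper).  Returns an exit
#' status instead of quitting so it can be tested in-process: 0 on
#' success, 2 on usage errors, 1 on runtime failure.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cli_dispatch <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
    cli_usage(); return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  known <- c("synth", "fit-dispersion", "simulate-cycle", "select-model",
             "cross-validate")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd); cli_usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    if (cmd == "synth") cli_synth(argv[-1])
    else if (cmd == "fit-dispersion") cli_fit_dispersion(argv[-1])
    else if (cmd == "simulate-cycle") cli_simulate_cycle(argv[-1])
    else if (cmd == "select-model") cli_select_model(argv[-1])
    else cli_cross_validate(argv[-1])
    0L
  },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

cli_synth <- function(args) {
  if (!length(args) || !args[1] %in% c("cpmg", "variant"))
    stop("synth needs a sub-mode: cpmg or variant")
  mode <- args[1]
  flags <- parse_flags(args[-1])
  seed <- as.integer(flag(flags, "seed", 1))
  out <- flag(flags, "out", required = TRUE)
  if (mode == "cpmg") {
    topo <- exchange_topology(flag(flags, "topology", "two_site"))
    truth <- synthetic_truth()
    model <- if (topo$name == "two_site") truth$rates$free$CAT
             else truth$rates$free$L26
    ds <- generate_cpmg_dataset(model,
                                n_methyls = as.integer(flag(flags,
                                                            "n-methyls", 4)),
                                seed = seed)
    write_dispersion_csv(ds, out)
  } else {
    truth <- synthetic_truth()
    vv <- generate_virtual_variant(truth,
                                   ddG = list(free = list(L26 = c(B = 3))),
                                   variant = "virtual", seed = seed)
    write.csv(as.data.frame(vv$observables), out, row.names = FALSE)
  }
  message("wrote ", out)
}

cli_fit_dispersion <- function(args) {
  flags <- parse_flags(args)
  data <- load_dispersion_csv(flag(flags, "data", required = TRUE))
  topo <- exchange_topology(flag(flags, "topology", required = TRUE))
  out <- flag(flags, "out", required = TRUE)
  seed <- as.integer(flag(flags, "seed", 1))
  n_mc <- as.integer(flag(flags, "n-mc", 0))
  n_starts <- flag(flags, "n-starts", NULL)
  if (!is.null(n_starts)) n_starts <- as.integer(n_starts)
  fit <- fit_region(data, topo, n_starts = n_starts)
  mc <- if (n_mc > 0) monte_carlo_errors(fit, n_mc = n_mc, seed = seed)
        else NULL
  write_region_fit_json(fit, out, mc = mc)
  curves <- flag(flags, "curves", NULL)
  if (!is.null(curves)) write_fitted_curves_csv(fit, curves)
  message("wrote ", out, " (chi2_red = ", signif(fit$chi2_red, 4), ")")
}

cli_simulate_cycle <- function(args) {
  flags <- parse_flags(args)
  space <- build_state_space()
  truth <- synthetic_truth()
  cfgp <- flag(flags, "model", NULL)
  cfg <- if (!is.null(cfgp)) read_kinetic_config(cfgp, space)
         else list(spec = truth$spec, params = truth$params)
  out <- flag(flags, "out", required = TRUE)
  if (isTRUE(flag(flags, "inhibitor", FALSE))) {
    io <- inhibitor_observables(space, cfg$spec, truth$rates, cfg$params,
                                method = flag(flags, "method", "ode"))
    jsonlite::write_json(list(kd_M = io$kd, koff_macro_s = io$koff_macro),
                         out, auto_unbox = TRUE, digits = NA)
  } else {
    des <- assay_design(S_grid = c(0, exp(seq(log(1e-4), log(0.25),
                                              length.out = 14))),
                        n_t = as.integer(flag(flags, "n-t", 6000)))
    mm <- michaelis_menten(space, cfg$spec, truth$rates, cfg$params, des,
                           method = flag(flags, "method", "ode"))
    jsonlite::write_json(list(kcat_s = mm$kcat, KM_M = mm$KM,
                              v0 = mm$v0), out, auto_unbox = TRUE,
                         digits = NA)
  }
  message("wrote ", out)
}

cli_select_model <- function(args) {
  flags <- parse_flags(args)
  seed <- as.integer(flag(flags, "seed", 1))
  out <- flag(flags, "out", required = TRUE)
  n_models <- as.integer(flag(flags, "n-models", 12))
  truth <- synthetic_truth()
  space <- truth$space
  cpath <- flag(flags, "constraints", NULL)
  if (!is.null(cpath)) {
    if (!file.exists(cpath)) stop("no such constraints file: ", cpath)
    constraints <- constraint_set(read.csv(cpath, comment.char = "#",
                                           stringsAsFactors = FALSE))
    rates <- setNames(rep(list(truth$rates),
                          length(unique(constraints$variant))),
                      unique(constraints$variant))
  } else {
    set.seed(seed)
    wt <- generate_virtual_variant(truth, ddG = list(), variant = "wt",
                                   seed = seed)
    mut <- generate_virtual_variant(truth,
                                    ddG = list(free = list(L26 = c(B = 4))),
                                    variant = "mutA", seed = seed + 1)
    constraints <- constraint_set(rbind(as.data.frame(wt$observables),
                                        as.data.frame(mut$observables)))
    rates <- list(wt = wt$rates, mutA = mut$rates)
  }
  pool <- c(truth$spec$substrate_sites, truth$spec$lysine_sites,
            conf_index(space, L1 = "boundlike", L26 = "boundlike",
                       CAT = "B"))
  models <- enumerate_models(space, substrate_pool = unique(pool),
                             lysine_pool = unique(pool))
  models <- models[seq_len(min(n_models, length(models)))]
  fits <- lapply(models, function(m)
    fit_global(m, constraints, rates, space, method = "steady"))
  tab <- rank_models(fits)
  best <- attr(tab, "fits")[[1]]
  jsonlite::write_json(list(
    ranking = tab,
    best = list(spec_id = best$spec_id,
                substrate_sites = best$spec$substrate_sites,
                lysine_sites = best$spec$lysine_sites,
                params = list(k_on = best$params$k_on,
                              k_off_S = best$params$k_off_S,
                              k_H = best$params$k_H,
                              k_off_I = best$params$k_off_I),
                chi2 = best$chi2, chi2_red = best$chi2_red)),
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", out)
}

cli_cross_validate <- function(args) {
  flags <- parse_flags(args)
  modelp <- flag(flags, "model", required = TRUE)
  heldp <- flag(flags, "heldout", required = TRUE)
  out <- flag(flags, "out", required = TRUE)
  truth <- synthetic_truth()
  space <- truth$space
  doc <- jsonlite::read_json(modelp, simplifyVector = TRUE)
  spec <- kinetic_model_spec(space,
                             substrate_sites = doc$best$substrate_sites,
                             lysine_sites = doc$best$lysine_sites)
  params <- kinetic_params(k_on = doc$best$params$k_on,
                           k_off_S = doc$best$params$k_off_S,
                           k_H = doc$best$params$k_H,
                           k_off_I = doc$best$params$k_off_I)
  held <- constraint_set(read.csv(heldp, comment.char = "#",
                                  stringsAsFactors = FALSE))
  fit <- structure(list(spec = spec, spec_id = spec_id(spec),
                        params = params, method = "steady",
                        fitted = data.frame(variant = character(0))),
                   class = "model_fit_result")
  cv <- cross_validate(fit, truth$rates, held, space)
  jsonlite::write_json(list(cv_chi2 = cv$cv_chi2,
                            cv_chi2_red = cv$cv_chi2_red, n = cv$n),
                       out, auto_unbox = TRUE, digits = NA)
  message("wrote ", out)
}
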