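#' Conformational state space of the catalytic cycle
#'
#' The enzyme samples a set of internal conformations given by the direct
#' product of independent dynamic regions.  For HDAC8 these are the two
#' loop clusters L1 and L2,6 (three states each: a bound-like
#' conformation, a free-like conformation and a release conformation C)
#' and the catalytic region CAT (two states A and B), giving
#' 3 x 3 x 2 = 18 conformations.  Each of the five enzymatic species
#' {E, ES, EPlysPace, EPace, EPlys} carries the full set of
#' conformations; together with free substrate S and the two free
#' products Plys and Pace this yields 5 x 18 + 3 = 93 states.
#'
#' Conformations are labelled by *function* (bound-like / free-like /
#' release), not by the manifold-specific A/B/C letters of the exchange
#' fits, because the major state of the free enzyme is the free-like
#' conformation while the major state of the inhibitor-bound enzyme is
#' the bound-like one.
#'
#' @param region_states named list giving the state labels of each
#'   region; the default is the HDAC8 layout.  A degenerate space with
#'   one label per region (a single conformation) is allowed and gives
#'   the textbook 5 + 3 = 8 state scheme.
#' @return object of class `state_space` with elements `conf` (data frame
#'   of conformations), `n_conf`, `n_states`, `species`, `block` (named
#'   list of index ranges), `iS`, `iPlys`, `iPace`, and `index` /
#'   `state_names`.
#' @examples
#' sp <- build_state_space()
#' sp$n_states   # 93
#' sp$n_conf     # 18
#' @export
build_state_space <- function(region_states = list(
    L1  = c("boundlike", "freelike", "release"),
    L26 = c("boundlike", "freelike", "release"),
    CAT = c("A", "B"))) {
  stopifnot(length(region_states) >= 1, all(lengths(region_states) >= 1))
  regions <- names(region_states)
  # last region varies fastest; conf index consistent with Kronecker sums
  grid <- do.call(expand.grid, c(rev(lapply(region_states, as.character)),
                                 stringsAsFactors = FALSE))
  grid <- grid[, regions, drop = FALSE]
  n_conf <- nrow(grid)
  species <- c("E", "ES", "EPlysPace", "EPace", "EPlys")
  block <- lapply(seq_along(species), function(k)
    ((k - 1L) * n_conf + 1L):(k * n_conf))
  names(block) <- species
  n_states <- 5L * n_conf + 3L
  state_names <- c(
    unlist(lapply(species, function(s) paste0(s, ".", seq_len(n_conf)))),
    "S", "Plys", "Pace")
  structure(list(region_states = region_states, conf = grid,
                 n_conf = n_conf, n_states = n_states, species = species,
                 block = block, iS = 5L * n_conf + 1L,
                 iPlys = 5L * n_conf + 2L, iPace = 5L * n_conf + 3L,
                 state_names = state_names),
            class = "state_space")
}

#' Find conformation indices by region labels
#'
#' @param space a [build_state_space()] result.
#' @param ... region label constraints, e.g. `L1 = "boundlike"`,
#'   `CAT = "B"`; unconstrained regions match everything.
#' @return integer vector of conformation indices (1..n_conf).
#' @export
conf_index <- function(space, ...) {
  sel <- list(...)
  keep <- rep(TRUE, space$n_conf)
  for (r in names(sel)) {
    if (!r %in% names(space$conf)) stop("unknown region: ", r)
    keep <- keep & space$conf[[r]] %in% sel[[r]]
  }
  which(keep)
}

#' Intrinsic region dynamics for the free and bound manifolds
#'
#' Pairs per-region thermodynamic exchange models with the mapping from
#' their A/B/C state letters to the functional conformation labels of the
#' state space.  The species E and EPace sample the free-enzyme dynamics;
#' ES, EPlysPace and EPlys sample the ligand-bound dynamics.
#'
#' @param free,bound named lists (one entry per region) of
#'   [thermo_exchange_model()] objects, or `NULL` for a static region.
#' @param maps named list with elements `free` and `bound`, each a list
#'   per region mapping state letters to functional labels.  Defaults to
#'   the HDAC8 assignment: in the free manifold A = free-like,
#'   B = bound-like, C = release; in the bound manifold A = bound-like,
#'   B = free-like, C = release; CAT keeps its A/B letters.
#' @return object of class `region_rate_set`.
#' @export
region_rate_set <- function(free, bound, maps = NULL) {
  if (is.null(maps)) {
    loopf <- c(A = "freelike", B = "boundlike", C = "release")
    loopb <- c(A = "boundlike", B = "freelike", C = "release")
    catm <- c(A = "A", B = "B")
    mk <- function(m, regs) setNames(lapply(regs, function(r)
      if (r == "CAT") catm else m), regs)
    maps <- list(free = mk(loopf, names(free)), bound = mk(loopb, names(bound)))
  }
  structure(list(free = free, bound = bound, maps = maps),
            class = "region_rate_set")
}

# per-manifold conformational generator and populations via Kronecker sums
conf_dynamics <- function(space, rates, manifold = c("free", "bound"), T_K) {
  manifold <- match.arg(manifold)
  models <- rates[[manifold]]
  maps <- rates$maps[[manifold]]
  regions <- names(space$region_states)
  Ks <- list(); ps <- list()
  for (r in regions) {
    labs <- space$region_states[[r]]
    nr <- length(labs)
    if (is.null(models[[r]])) {
      Ks[[r]] <- matrix(0, nr, nr); ps[[r]] <- rep(1 / nr, nr)
    } else {
      K <- build_exchange_matrix(models[[r]], T_K)
      p <- state_populations(models[[r]], T_K)
      mp <- maps[[r]]
      if (!setequal(unname(mp[rownames(K)]), labs))
        stop("state map for region ", r, " does not cover labels: ",
             paste(labs, collapse = ","))
      ord <- match(labs, unname(mp[rownames(K)]))
      Ks[[r]] <- K[ord, ord, drop = FALSE]
      ps[[r]] <- as.numeric(p[ord])
    }
  }
  n <- space$n_conf
  Kc <- matrix(0, n, n)
  sizes <- vapply(Ks, nrow, 1L)
  for (k in seq_along(regions)) {
    left <- if (k > 1) prod(sizes[seq_len(k - 1)]) else 1L
    right <- if (k < length(regions)) prod(sizes[(k + 1):length(regions)]) else 1L
    Kc <- Kc + kronecker(diag(left), kronecker(Ks[[k]], diag(right)))
  }
  p <- Reduce(kronecker, ps)
  list(K = Kc, p = as.numeric(p))
}

#' Kinetic model specification
#'
#' Declares which conformations carry the bimolecular and chemical edges
#' of the catalytic cycle: the (usually two) conformations through which
#' substrate / inhibitor associates and dissociates, the conformation(s)
#' from which the lysine product is released, the conformations releasing
#' acetate (fixed: all with L1 in the release state), and the single
#' hydrolysis-competent conformation (fixed: all regions bound-like, CAT
#' in state A).
#'
#' @param space a [build_state_space()] result.
#' @param substrate_sites integer conformation indices (see
#'   [conf_index()]); must be non-empty.
#' @param lysine_sites integer conformation indices.
#' @param hydrolysis_site single conformation index; default the
#'   all-bound conformation (or conformation 1 in degenerate spaces).
#' @param acetate_sites conformation indices; default all with
#'   `L1 == "release"` (or all conformations if the space has no release
#'   label).
#' @return object of class `kinetic_model_spec`.
#' @export
kinetic_model_spec <- function(space, substrate_sites, lysine_sites,
                               hydrolysis_site = NULL, acetate_sites = NULL) {
  stopifnot(inherits(space, "state_space"))
  if (is.null(hydrolysis_site)) {
    hydrolysis_site <- conf_index(space, L1 = "boundlike", L26 = "boundlike",
                                  CAT = "A")
    if (length(hydrolysis_site) == 0) hydrolysis_site <- 1L
  }
  if (is.null(acetate_sites)) {
    acetate_sites <- if ("L1" %in% names(space$conf) &&
                         "release" %in% space$conf$L1)
      conf_index(space, L1 = "release") else seq_len(space$n_conf)
  }
  ok <- function(i) all(i >= 1 & i <= space$n_conf)
  if (!length(substrate_sites) || !ok(substrate_sites))
    stop("substrate_sites must be non-empty conformation indices")
  if (!length(lysine_sites) || !ok(lysine_sites) || !ok(hydrolysis_site) ||
      !ok(acetate_sites))
    stop("model sites outside the conformational manifold")
  structure(list(substrate_sites = sort(unique(as.integer(substrate_sites))),
                 lysine_sites = sort(unique(as.integer(lysine_sites))),
                 hydrolysis_site = as.integer(hydrolysis_site[1]),
                 acetate_sites = sort(unique(as.integer(acetate_sites)))),
            class = "kinetic_model_spec")
}

#' Global microkinetic parameters
#'
#' The bimolecular and chemical rate constants shared by the whole cycle:
#' association `k_on` (substrate and inhibitor), substrate dissociation
#' `k_off_S`, lysine-product dissociation `k_off_P` (tied to `k_off_S` in
#' the 4-parameter fit), hydrolysis `k_H` (with a solvent kinetic isotope
#' effect `k_H(H2O) = kie * k_H(D2O)`), microkinetic inhibitor off-rate
#' `k_off_I`, and the acetate off-rate fixed at the diffusion limit
#' 1e6 s^-1 unless overridden.
#'
#' @param k_on association rate, M^-1 s^-1.
#' @param k_off_S,k_off_P,k_off_I,k_off_ace off-rates, s^-1.
#' @param k_H hydrolysis rate in H2O, s^-1.
#' @param kie solvent kinetic isotope effect factor (default 8.8).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on, k_off_S, k_H, k_off_I,
                           k_off_P = k_off_S, k_off_ace = 1e6, kie = 8.8) {
  v <- c(k_on = k_on, k_off_S = k_off_S, k_H = k_H, k_off_I = k_off_I,
         k_off_P = k_off_P, k_off_ace = k_off_ace, kie = kie)
  if (!all(is.finite(v)) || any(v[names(v) != "k_H"] <= 0) || k_H < 0)
    stop("kinetic parameters must be finite and positive (k_H >= 0)")
  structure(as.list(v), class = "kinetic_params")
}

#' Assemble the catalytic-cycle rate equations
#'
#' Builds the right-hand side of the concentration ODEs over all states:
#' a linear generator containing the intrinsic conformational exchange of
#' every species (free-enzyme dynamics for E and EPace, bound dynamics
#' for ES, EPlysPace and EPlys), the hydrolysis edge, the product-release
#' edges, and ligand dissociation; plus bilinear association terms for
#' E_i + S -> ES_i at the binding-competent conformations.
#'
#' Association into site i is weighted by
#' `p(ES_i) / sum_j p(ES_j)` and dissociation from site i by
#' `p(E_i) / sum_j p(E_j)` (sums over the binding-competent sites), which
#' makes every binding edge satisfy detailed balance at equilibrium.
#'
#' @param space a [build_state_space()] result.
#' @param spec a [kinetic_model_spec()].
#' @param rates a [region_rate_set()].
#' @param params a [kinetic_params()].
#' @param mode `"substrate"` for the catalytic cycle, `"inhibitor"` for
#'   binding of a non-hydrolysable ligand (k_H = 0, off-rate `k_off_I`).
#' @param solvent `"H2O"` or `"D2O"` (divides k_H by the KIE factor).
#' @param T_K temperature for the intrinsic rates, K.
#' @param association one of `"on"`, `"off"`; `"off"` removes the
#'   bimolecular association terms (used for off-rate simulations at
#'   infinite dilution).
#' @return object of class `cycle_network` with the linear generator `A`,
#'   association triples, and the manifold populations.
#' @export
assemble_network <- function(space, spec, rates, params,
                             mode = c("substrate", "inhibitor"),
                             solvent = c("H2O", "D2O"), T_K = 298,
                             association = c("on", "off")) {
  mode <- match.arg(mode); solvent <- match.arg(solvent)
  association <- match.arg(association)
  stopifnot(inherits(space, "state_space"),
            inherits(spec, "kinetic_model_spec"),
            inherits(params, "kinetic_params"))
  dyn_f <- conf_dynamics(space, rates, "free", T_K)
  dyn_b <- conf_dynamics(space, rates, "bound", T_K)
  n <- space$n_states; nc <- space$n_conf
  A <- matrix(0, n, n)
  manifold <- c(E = "free", ES = "bound", EPlysPace = "bound",
                EPace = "free", EPlys = "bound")
  for (s in space$species) {
    b <- space$block[[s]]
    A[b, b] <- A[b, b] + (if (manifold[[s]] == "free") dyn_f$K else dyn_b$K)
  }
  k_H <- if (mode == "inhibitor") 0 else params$k_H
  if (solvent == "D2O") k_H <- k_H / params$kie
  k_off <- if (mode == "inhibitor") params$k_off_I else params$k_off_S

  sites <- spec$substrate_sites
  pb <- dyn_b$p[sites]; pf <- dyn_f$p[sites]
  wb <- pb / sum(pb); wf <- pf / sum(pf)
  add <- function(from, to, k) {
    A[to, from] <<- A[to, from] + k
    A[from, from] <<- A[from, from] - k
  }
  gain <- function(from, to, k) A[to, from] <<- A[to, from] + k  # no drain

  # ligand dissociation ES_i -> E_i + S (weighted)
  for (k in seq_along(sites)) {
    i <- sites[k]
    add(space$block$ES[i], space$block$E[i], k_off * wf[k])
    gain(space$block$ES[i], space$iS, k_off * wf[k])
  }
  # hydrolysis at the single competent conformation
  if (k_H > 0)
    add(space$block$ES[spec$hydrolysis_site],
        space$block$EPlysPace[spec$hydrolysis_site], k_H)
  # acetate release (L1 in release conformation), diffusion-limited
  for (i in spec$acetate_sites) {
    add(space$block$EPlysPace[i], space$block$EPlys[i], params$k_off_ace)
    gain(space$block$EPlysPace[i], space$iPace, params$k_off_ace)
    add(space$block$EPace[i], space$block$E[i], params$k_off_ace)
    gain(space$block$EPace[i], space$iPace, params$k_off_ace)
  }
  # lysine-product release from the release-competent conformations
  for (i in spec$lysine_sites) {
    add(space$block$EPlysPace[i], space$block$EPace[i], params$k_off_P)
    gain(space$block$EPlysPace[i], space$iPlys, params$k_off_P)
    add(space$block$EPlys[i], space$block$E[i], params$k_off_P)
    gain(space$block$EPlys[i], space$iPlys, params$k_off_P)
  }
  triples <- if (association == "on") {
    cbind(iE = space$block$E[sites], iES = space$block$ES[sites],
          c = params$k_on * wb)
  } else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("iE", "iES", "c")))
  structure(list(A = A, triples = triples, space = space, spec = spec,
                 params = params, mode = mode, solvent = solvent, T_K = T_K,
                 p_free = dyn_f$p, p_bound = dyn_b$p,
                 K_free = dyn_f$K, K_bound = dyn_b$K, k_off = k_off,
                 k_H = k_H),
            class = "cycle_network")
}

pack_parms <- function(net) {
  n <- net$space$n_states
  if (n > 96) stop("state space too large for the compiled RHS (max 96)")
  tri <- net$triples
  v <- c(n, net$space$iS - 1, nrow(tri), as.numeric(net$A),
         if (nrow(tri)) as.numeric(t(cbind(tri[, 1] - 1, tri[, 2] - 1,
                                           tri[, 3]))) else numeric(0))
  maxlen <- 3 + 96 * 96 + 3 * 96
  c(v, numeric(maxlen - length(v)))
}

#' Logarithmically spaced time grid
#'
#' @param t_min,t_max range, s.
#' @param n number of points.
#' @return numeric vector of length `n` (log-spaced), with 0 prepended if
#'   `from_zero` is TRUE.
#' @param from_zero prepend t = 0.
#' @export
log_time_grid <- function(t_min = 1e-6, t_max = 600, n = 60000,
                          from_zero = TRUE) {
  g <- exp(seq(log(t_min), log(t_max), length.out = n))
  if (from_zero) c(0, g) else g
}

#' Integrate the catalytic-cycle ODEs
#'
#' Stiff integration (lsoda, which switches automatically between stiff
#' and non-stiff methods) of the assembled network with an analytic
#' Jacobian, both evaluated in compiled code.  Rates in the network span
#' ~1e-1 to 1e6 s^-1, so tight tolerances are used by default.
#'
#' @param net a [assemble_network()] result.
#' @param y0 initial concentrations (M), length `n_states`.
#' @param times output time grid, s (see [log_time_grid()]).
#' @param rtol,atol relative / absolute (M) solver tolerances.
#' @param check verify non-negativity and enzyme-mass conservation.
#' @return matrix of concentrations, `length(times) x n_states`, with
#'   `times` as attribute.
#' @export
simulate_progress <- function(net, y0, times, rtol = 1e-8, atol = 1e-12,
                              check = TRUE) {
  stopifnot(inherits(net, "cycle_network"),
            length(y0) == net$space$n_states)
  out <- deSolve::lsoda(y = y0, times = times, func = "cycle_derivs",
                        parms = pack_parms(net), dllname = "excat",
                        initfunc = "cycle_init", jacfunc = "cycle_jac",
                        jactype = "fullusr", rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed: istate = ", attr(out, "istate")[1])
  y <- unname(out[, -1, drop = FALSE])
  if (check) {
    scale <- max(sum(y0), atol)
    if (min(y) < -1e4 * atol - 1e-10 * scale)
      stop("negative concentrations beyond solver tolerance: min = ",
           format(min(y)))
    enz <- seq_len(5 * net$space$n_conf)
    e_tot <- rowSums(y[, enz, drop = FALSE])
    if (e_tot[1] > 0 &&
        max(abs(e_tot - e_tot[1])) > 1e-6 * e_tot[1] + 1e4 * atol)
      warning("enzyme mass drift exceeds 1e-6 relative")
  }
  colnames(y) <- net$space$state_names
  attr(y, "times") <- times
  y
}

#' Assay design for activity simulations
#'
#' Enzyme concentration, substrate grid, time grid and the window over
#' which the initial rate is measured.  Defaults follow the fluorogenic
#' deacetylation assay conditions: E0 = 0.4 uM (mid-range of the
#' 0.2-0.8 uM series), 50 substrate concentrations between 0 and 250 mM
#' (0 plus a log-spaced series), 60,000 log-spaced time points between
#' 1 us and 600 s, and v0 from the 60-600 s window.
#'
#' @param E0 enzyme concentration, M.
#' @param S_grid substrate concentrations, M (must include 0).
#' @param n_t number of log-spaced time points.
#' @param t_min,t_max time range, s.
#' @param v0_window two times (s) bracketing the initial-rate regression.
#' @return object of class `assay_design`.
#' @export
assay_design <- function(E0 = 0.4e-6,
                         S_grid = c(0, exp(seq(log(5e-5), log(0.25),
                                               length.out = 49))),
                         n_t = 60000, t_min = 1e-6, t_max = 600,
                         v0_window = c(60, 600)) {
  stopifnot(E0 >= 0, any(S_grid == 0), all(S_grid >= 0),
            t_min > 0, t_max > v0_window[1], v0_window[2] > v0_window[1])
  structure(list(E0 = E0, S_grid = sort(unique(S_grid)), n_t = n_t,
                 t_min = t_min, t_max = t_max, v0_window = v0_window),
            class = "assay_design")
}

# initial condition: enzyme distributed over E conformations by their
# equilibrium populations, ligand in the free pool
cycle_initial_state <- function(net, E0, S0) {
  y0 <- numeric(net$space$n_states)
  y0[net$space$block$E] <- E0 * net$p_free
  y0[net$space$iS] <- S0
  y0
}

# steady-state initial rate at fixed [S]: solve the linear enzyme
# subsystem (association entering as pseudo-first-order edges) for its
# conservative steady state and return the lysine-release flux.
steady_v0 <- function(net, E0, S0) {
  nc <- net$space$n_conf
  enz <- seq_len(5 * nc)
  M <- net$A[enz, enz, drop = FALSE]
  tri <- net$triples
  for (k in seq_len(nrow(tri))) {
    iE <- tri[k, 1]; iES <- tri[k, 2]; c_i <- tri[k, 3]
    M[iES, iE] <- M[iES, iE] + c_i * S0
    M[iE, iE] <- M[iE, iE] - c_i * S0
  }
  # M is a conservative generator (columns sum to zero over the enzyme
  # block), so one balance row is redundant: replace it by the total-
  # enzyme constraint and solve the square system
  b <- numeric(5 * nc); b[5 * nc] <- E0
  last_row <- M[5 * nc, ]
  M[5 * nc, ] <- 1
  y <- tryCatch(solve(M, b), error = function(e) {
    M[5 * nc, ] <- last_row
    tryCatch(qr.solve(rbind(M, 1), c(numeric(5 * nc), E0)),
             error = function(e2) stop("steady-state solve failed: ",
                                       conditionMessage(e2)))
  })
  lys <- net$spec$lysine_sites
  sum(net$params$k_off_P *
        (y[net$space$block$EPlysPace[lys]] + y[net$space$block$EPlys[lys]]))
}

# Deterministic damped Gauss-Newton for the small inner curve fits.
# minpack.lm's nls.lm keeps global C state and must not be nested inside
# an outer nls.lm objective; this pure-R Levenberg-style iteration with
# analytic Jacobians converges to machine precision, which keeps the
# outer fit's finite-difference Jacobians clean.
gauss_newton_ls <- function(par, fn, jac, maxit = 100) {
  r <- fn(par); f <- sum(r * r); lam <- 1e-3
  for (it in seq_len(maxit)) {
    J <- jac(par)
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    repeat {
      step <- tryCatch(solve(H + lam * diag(diag(H) + 1e-300,
                                            length(par)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        newp <- par + as.numeric(step)
        rn <- fn(newp); fnew <- sum(rn * rn)
        if (is.finite(fnew) && fnew <= f) { improved <- TRUE; break }
      }
      lam <- lam * 10
      if (lam > 1e14) break
    }
    if (!improved) break
    done <- (f - fnew) <= 1e-15 * (f + 1e-300)
    par <- newp; r <- rn; f <- fnew
    lam <- max(lam / 10, 1e-12)
    if (done) break
  }
  par
}

fit_michaelis_menten <- function(S, v0, E0) {
  ok <- is.finite(v0)
  S <- S[ok]; v0 <- v0[ok]
  if (max(v0) <= 0) stop("no turnover: initial rates are non-positive")
  kcat0 <- max(v0) / E0
  KM0 <- S[which.min(abs(v0 - max(v0) / 2))]
  if (KM0 <= 0) KM0 <- stats::median(S[S > 0])
  # parameters on log scale; analytic Jacobian of the hyperbola
  fn <- function(p) v0 - E0 * exp(p[1]) * S / (S + exp(p[2]))
  jac <- function(p) {
    kcat <- exp(p[1]); KM <- exp(p[2])
    den <- S + KM
    cbind(-E0 * kcat * S / den,              # d r / d log kcat
          E0 * kcat * S * KM / den^2)        # d r / d log KM
  }
  par <- gauss_newton_ls(c(log(kcat0), log(KM0)), fn, jac)
  c(kcat = exp(par[[1]]), KM = exp(par[[2]]))
}

#' Michaelis-Menten parameters of the catalytic network
#'
#' Simulates progress curves over the substrate grid, measures the
#' initial rate `v0 = d[Plys]/dt` by linear regression over the
#' `v0_window`, and fits `v0 = E0 * kcat * S / (S + KM)`.
#'
#' `method = "steady"` replaces the time integration by the conservative
#' steady state of the linear enzyme subsystem at fixed [S] (the
#' pseudo-steady-state initial rate, valid when substrate depletion over
#' the window is negligible); it is used for large model-ranking scans
#' and agrees with the ODE route to well under 1% under assay conditions.
#'
#' @param space,spec,rates,params network ingredients, see
#'   [assemble_network()].
#' @param design an [assay_design()].
#' @param solvent `"H2O"` or `"D2O"`.
#' @param T_K temperature, K.
#' @param method `"ode"` (reference) or `"steady"` (fast).
#' @return list with `kcat` (s^-1), `KM` (M), and the `v0` table.
#' @export
michaelis_menten <- function(space, spec, rates, params,
                             design = assay_design(), solvent = "H2O",
                             T_K = 298, method = c("ode", "steady")) {
  method <- match.arg(method)
  net <- assemble_network(space, spec, rates, params, mode = "substrate",
                          solvent = solvent, T_K = T_K)
  if (net$k_H <= 0) stop("no turnover: k_H = 0")
  S_grid <- design$S_grid
  v0 <- numeric(length(S_grid))
  if (method == "steady") {
    for (j in seq_along(S_grid))
      v0[j] <- if (S_grid[j] == 0) 0 else steady_v0(net, design$E0, S_grid[j])
  } else {
    times <- log_time_grid(design$t_min, design$t_max, design$n_t)
    win <- times >= design$v0_window[1] & times <= design$v0_window[2]
    if (sum(win) < 3) stop("v0 window contains fewer than 3 time points")
    for (j in seq_along(S_grid)) {
      if (S_grid[j] == 0) { v0[j] <- 0; next }
      y <- simulate_progress(net, cycle_initial_state(net, design$E0,
                                                      S_grid[j]), times)
      v0[j] <- coef(lm(y[win, net$space$iPlys] ~ times[win]))[[2]]
    }
  }
  mm <- fit_michaelis_menten(S_grid, v0, design$E0)
  list(kcat = mm[["kcat"]], KM = mm[["KM"]],
       v0 = data.frame(S = S_grid, v0 = v0), method = method)
}

#' Macroscopic inhibitor observables
#'
#' Binding of a non-hydrolysable inhibitor (k_H = 0): the system is
#' equilibrated at concentrations `E0`, `I0`, giving the macroscopic
#' dissociation constant `Kd = [E_free][I_free]/[EI]` (sums over all
#' conformations); the macroscopic off-rate is then obtained by removing
#' free inhibitor and disabling re-association (infinite-dilution
#' idealization) and fitting total `[EI](t)` to `A * exp(-k t)`.
#'
#' `method = "steady"` uses the closed-form equilibrium implied by
#' detailed balance, `Kd = (k_off_I / k_on) * PB / PF` with `PB`/`PF` the
#' summed bound/free-manifold populations of the binding-competent
#' conformations, and the slowest relaxation eigenvalue of the gated
#' release generator for the off-rate.
#'
#' @inheritParams michaelis_menten
#' @param E0,I0 enzyme and inhibitor concentrations, M.
#' @param t_eq equilibration time, s.
#' @param n_t time-grid size.
#' @return list with `kd` (M) and `koff_macro` (s^-1).
#' @export
inhibitor_observables <- function(space, spec, rates, params,
                                  E0 = 50e-6, I0 = 50e-6, T_K = 298,
                                  t_eq = 600, n_t = 6000,
                                  method = c("ode", "steady")) {
  method <- match.arg(method)
  net <- assemble_network(space, spec, rates, params, mode = "inhibitor",
                          T_K = T_K)
  sites <- spec$substrate_sites
  if (method == "steady") {
    PB <- sum(net$p_bound[sites]); PF <- sum(net$p_free[sites])
    kd <- (params$k_off_I / params$k_on) * PB / PF
    nc <- space$n_conf
    D <- net$K_bound
    wf <- net$p_free[sites] / PF
    for (k in seq_along(sites))
      D[sites[k], sites[k]] <- D[sites[k], sites[k]] - params$k_off_I * wf[k]
    koff <- -max(Re(eigen(D, only.values = TRUE)$values))
    return(list(kd = kd, koff_macro = koff, method = method))
  }
  times <- log_time_grid(1e-6, t_eq, n_t)
  y <- simulate_progress(net, cycle_initial_state(net, E0, I0), times)
  nfin <- nrow(y)
  EI <- function(row) sum(row[space$block$ES])
  Ef <- function(row) sum(row[space$block$E])
  # equilibrium check: complex concentration stable over the last decade
  if (abs(EI(y[nfin, ]) - EI(y[round(nfin * 0.9), ])) >
      1e-3 * max(EI(y[nfin, ]), 1e-15))
    warning("binding equilibration incomplete at t_eq; increase t_eq")
  yeq <- y[nfin, ]
  kd <- Ef(yeq) * yeq[space$iS] / EI(yeq)
  # dilution: remove free ligand, disable association, follow the decay
  net0 <- assemble_network(space, spec, rates, params, mode = "inhibitor",
                           T_K = T_K, association = "off")
  y0 <- yeq; y0[space$iS] <- 0
  kguess <- {
    PF <- sum(net$p_free[sites])
    params$k_off_I * sum(net$p_bound[sites] * net$p_free[sites] / PF) /
      max(sum(net$p_bound[sites]), 1e-12)
  }
  t_dec <- min(max(t_eq, 5 / max(kguess, 1e-6)), 1e5)
  times2 <- log_time_grid(1e-6, t_dec, n_t)
  y2 <- simulate_progress(net0, y0, times2)
  ei <- apply(y2[, space$block$ES, drop = FALSE], 1, sum)
  fn <- function(p) ei - exp(p[1]) * exp(-exp(p[2]) * times2)
  jac <- function(p) {
    A <- exp(p[1]); k <- exp(p[2])
    e <- exp(-k * times2)
    cbind(-A * e, A * e * k * times2)
  }
  par <- gauss_newton_ls(c(log(ei[1]), log(max(kguess, 1e-6))), fn, jac)
  list(kd = unname(kd), koff_macro = exp(par[[2]]), method = method)
}
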