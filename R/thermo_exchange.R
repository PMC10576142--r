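#' Exchange topologies
#'
#' Construct the connectivity of a 2- or 3-site conformational exchange
#' model.  States are labelled `A` (major) then `B`, `C` (minor, ordered by
#' population at 298 K).  Three topologies are supported:
#'
#' * `two_site`: A <-> B
#' * `bifurcated_three_site`: B <-> A <-> C (the major state exchanges
#'   independently with both minor states)
#' * `linear_three_site`: a chain with a configurable middle state,
#'   A <-> B <-> C by default (`middle = "B"`) or A <-> C <-> B
#'   (`middle = "C"`)
#'
#' @param name one of `"two_site"`, `"linear_three_site"`,
#'   `"bifurcated_three_site"`.
#' @param middle for the linear topology, which minor state sits between
#'   the other two (`"B"` or `"C"`).
#' @return An object of class `exchange_topology` with elements `name`,
#'   `states` (character), `edges` (list of unordered state pairs) and
#'   `middle`.
#' @examples
#' exchange_topology("two_site")
#' exchange_topology("linear_three_site", middle = "C")
#' @export
exchange_topology <- function(name = c("two_site", "linear_three_site",
                                       "bifurcated_three_site"),
                              middle = "B") {
  name <- match.arg(name)
  middle <- match.arg(middle, c("B", "C"))
  edges <- switch(name,
    two_site              = list(c("A", "B")),
    bifurcated_three_site = list(c("A", "B"), c("A", "C")),
    linear_three_site     = if (middle == "B") {
      list(c("A", "B"), c("B", "C"))
    } else {
      list(c("A", "C"), c("C", "B"))
    })
  states <- if (name == "two_site") c("A", "B") else c("A", "B", "C")
  structure(list(name = name, states = states, edges = edges,
                 middle = if (name == "linear_three_site") middle else NA),
            class = "exchange_topology")
}

edge_label <- function(edge) paste(sort(edge), collapse = "-")

#' Thermodynamic exchange model
#'
#' Bundle a topology with the state and transition-state thermodynamics
#' that define populations and exchange rates at any temperature.  The
#' major state A is the reference (Delta H_A = Delta S_A = 0); each minor
#' state carries an enthalpy and entropy relative to A, and each edge
#' carries a transition-state enthalpy and entropy relative to A.
#' Enthalpies and entropies are temperature independent (no heat-capacity
#' term).
#'
#' @param topology an [exchange_topology()].
#' @param dH_state,dS_state named numeric vectors (one entry per minor
#'   state, e.g. `c(B = 20)`), kJ/mol and kJ/mol/K.
#' @param dH_ts,dS_ts named numeric vectors (one entry per edge, names as
#'   `"A-B"`, `"B-C"`, ...), kJ/mol and kJ/mol/K, measured relative to A.
#' @param kappa transmission coefficient of the Eyring prefactor.
#' @return An object of class `thermo_exchange_model`.
#' @seealso [state_populations()], [build_exchange_matrix()],
#'   [thermo_from_pop_kex()]
#' @export
thermo_exchange_model <- function(topology, dH_state, dS_state, dH_ts, dS_ts,
                                  kappa = 1) {
  stopifnot(inherits(topology, "exchange_topology"))
  minors <- setdiff(topology$states, "A")
  labs <- vapply(topology$edges, edge_label, "")
  chk <- function(x, nms, what) {
    if (is.null(names(x))) names(x) <- nms
    if (!setequal(names(x), nms) || length(x) != length(nms))
      stop("need one ", what, " entry for each of: ", paste(nms, collapse = ", "))
    if (!all(is.finite(x))) stop("non-finite ", what)
    x[nms]
  }
  m <- structure(list(
    topology = topology,
    dH_state = chk(dH_state, minors, "dH_state"),
    dS_state = chk(dS_state, minors, "dS_state"),
    dH_ts = chk(dH_ts, labs, "dH_ts"),
    dS_ts = chk(dS_ts, labs, "dS_ts"),
    kappa = kappa), class = "thermo_exchange_model")
  m
}

#' Eyring rate from activation enthalpy and entropy
#'
#' `k = kappa * (kB*T/h) * exp(-(dH - T*dS) / (R*T))`, with the activation
#' parameters measured from the departing state.  Temperatures are taken
#' in Kelvin exactly as given: 298 K means 298.00 K, and using 298.15 K
#' instead changes the prefactor by about 0.05%.
#'
#' @param dH_ts_rel activation enthalpy, kJ/mol.
#' @param dS_ts_rel activation entropy, kJ/mol/K.
#' @param T_K absolute temperature, K.
#' @param kappa transmission coefficient (default 1).
#' @return rate in s^-1 (vectorised).
#' @examples
#' eyring_rate(0, 0, 298.15)   # kB*T/h = 6.21e12 s^-1
#' eyring_rate(60, 0, 298.15)  # ~190 s^-1
#' @export
eyring_rate <- function(dH_ts_rel, dS_ts_rel, T_K, kappa = 1) {
  if (!all(is.finite(dH_ts_rel)) || !all(is.finite(dS_ts_rel)) ||
      !all(is.finite(T_K)))
    stop("non-finite input to eyring_rate()")
  if (any(T_K <= 0)) stop("temperature must be positive")
  kappa * (codata$kB * T_K / codata$h) *
    exp(-(dH_ts_rel - T_K * dS_ts_rel) / (codata$R_kJ * T_K))
}

state_dG <- function(model, T_K) {
  dG <- c(A = 0, model$dH_state - T_K * model$dS_state)
  dG[model$topology$states]
}

#' Equilibrium state populations
#'
#' Boltzmann populations `p_i \propto exp(-dG_i / (R*T))` with the major
#' state A as free-energy reference.
#'
#' @param model a [thermo_exchange_model()].
#' @param T_K absolute temperature, K.
#' @return named numeric vector summing to 1.
#' @export
state_populations <- function(model, T_K) {
  stopifnot(inherits(model, "thermo_exchange_model"), T_K > 0)
  w <- exp(-state_dG(model, T_K) / (codata$R_kJ * T_K))
  w / sum(w)
}

#' Exchange rate matrix at a temperature
#'
#' Build the generator `K` of the unimolecular exchange network:
#' `K[j, i]` is the rate i -> j (s^-1), obtained from the Eyring equation
#' with the barrier measured from state i (`dH_ts(edge) - dH_i`,
#' `dS_ts(edge) - dS_i`); diagonals are set so that every column sums to
#' zero, and entries for non-edges are zero.  Detailed balance
#' `p_i K[j,i] = p_j K[i,j]` holds by construction because both rates on
#' an edge share one transition state.
#'
#' @inheritParams state_populations
#' @return an `n x n` matrix with state labels as dimnames.
#' @export
build_exchange_matrix <- function(model, T_K) {
  stopifnot(inherits(model, "thermo_exchange_model"), T_K > 0)
  states <- model$topology$states
  n <- length(states)
  dH <- c(A = 0, model$dH_state)[states]
  dS <- c(A = 0, model$dS_state)[states]
  K <- matrix(0, n, n, dimnames = list(states, states))
  for (e in model$topology$edges) {
    lab <- edge_label(e)
    for (pair in list(e, rev(e))) {
      i <- pair[1]; j <- pair[2]  # i -> j
      bH <- model$dH_ts[[lab]] - dH[[i]]
      bG <- bH - T_K * (model$dS_ts[[lab]] - dS[[i]])
      if (bG < 0)
        warning(sprintf("negative barrier (%.2f kJ/mol) for %s -> %s at %g K",
                        bG, i, j, T_K))
      K[j, i] <- eyring_rate(bH, model$dS_ts[[lab]] - dS[[i]], T_K,
                             model$kappa)
    }
  }
  diag(K) <- -colSums(K)
  K
}

#' Construct a thermodynamic model from populations and exchange rates
#'
#' Convenience inverse parameterisation: choose minor-state populations
#' and edge exchange rates (`k_ex = k_ij + k_ji`) at a reference
#' temperature plus state/transition-state enthalpies, and solve for the
#' entropies that reproduce them.  Useful for seeding fits and for
#' building synthetic ground truths.
#'
#' @param topology an [exchange_topology()].
#' @param p_minor named vector of minor-state populations at `T_ref`.
#' @param kex named vector (by edge label, e.g. `"A-B"`) of exchange rates
#'   `k_ij + k_ji` at `T_ref`, s^-1.
#' @param dH_state,dH_ts enthalpies, kJ/mol (defaults give mildly
#'   temperature-dependent populations and barriers typical of
#'   millisecond loop motions).
#' @param T_ref reference temperature, K.
#' @return a [thermo_exchange_model()].
#' @export
thermo_from_pop_kex <- function(topology, p_minor, kex,
                                dH_state = NULL, dH_ts = NULL, T_ref = 298) {
  minors <- setdiff(topology$states, "A")
  labs <- vapply(topology$edges, edge_label, "")
  if (is.null(dH_state)) dH_state <- setNames(rep(30, length(minors)), minors)
  if (is.null(dH_ts)) dH_ts <- setNames(rep(70, length(labs)), labs)
  p_minor <- p_minor[minors]; kex <- kex[labs]
  RT <- codata$R_kJ * T_ref
  pA <- 1 - sum(p_minor)
  stopifnot(pA > 0, all(p_minor > 0), all(kex > 0))
  dG_state <- -RT * log(p_minor / pA)
  dS_state <- (dH_state[minors] - dG_state) / T_ref
  # forward rate A->s (or between the two states of the edge): on edge (i,j)
  # with i the state nearer A in the chain, k_ij = kex * p_j/(p_i+p_j)
  p_all <- c(A = pA, p_minor)
  dG_all <- c(A = 0, dG_state)
  dS_ts <- dH_ts
  for (k in seq_along(topology$edges)) {
    e <- topology$edges[[k]]; lab <- labs[k]
    i <- e[1]; j <- e[2]
    k_ij <- kex[[lab]] * p_all[[j]] / (p_all[[i]] + p_all[[j]])
    # k_ij = (kB T/h) exp(-(dG_ts - dG_i)/RT)  =>  dG_ts
    dG_ts <- dG_all[[i]] - RT * log(k_ij * codata$h / (codata$kB * T_ref))
    dS_ts[[lab]] <- (dH_ts[[lab]] - dG_ts) / T_ref
  }
  thermo_exchange_model(topology, dH_state[minors],
                        setNames(dS_state, minors),
                        dH_ts[labs], dS_ts[labs])
}

#' @export
print.thermo_exchange_model <- function(x, ...) {
  cat("Thermodynamic exchange model:", x$topology$name, "\n")
  p <- state_populations(x, 298)
  cat("  populations at 298 K:",
      paste(sprintf("%s=%.4f", names(p), p), collapse = " "), "\n")
  K <- suppressWarnings(build_exchange_matrix(x, 298))
  for (e in x$topology$edges)
    cat(sprintf("  k_ex(%s) at 298 K: %.4g s^-1\n", edge_label(e),
                K[e[2], e[1]] + K[e[1], e[2]]))
  invisible(x)
}

#' Serialize / deserialize a thermodynamic exchange model
#'
#' Models round-trip through a small YAML document with declared units
#' (kJ/mol, kJ/mol/K).
#'
#' @param model a [thermo_exchange_model()].
#' @param path file path.
#' @return `write_thermo_model` returns `path` invisibly;
#'   `read_thermo_model` returns the model.
#' @export
write_thermo_model <- function(model, path) {
  doc <- list(
    topology = model$topology$name,
    middle = if (!is.na(model$topology$middle)) model$topology$middle else NULL,
    units = list(energy = "kJ/mol", entropy = "kJ/mol/K"),
    kappa = model$kappa,
    dH_state = as.list(model$dH_state), dS_state = as.list(model$dS_state),
    dH_ts = as.list(model$dH_ts), dS_ts = as.list(model$dS_ts))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_thermo_model
#' @export
read_thermo_model <- function(path) {
  doc <- yaml::read_yaml(path)
  topo <- exchange_topology(doc$topology,
                            middle = if (!is.null(doc$middle)) doc$middle else "B")
  thermo_exchange_model(topo,
                        unlist(doc$dH_state), unlist(doc$dS_state),
                        unlist(doc$dH_ts), unlist(doc$dS_ts),
                        kappa = if (is.null(doc$kappa)) 1 else doc$kappa)
}
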