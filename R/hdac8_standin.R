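#' HDAC8 stand-in inputs for the headline catalytic-cycle analysis
#'
#' Loads the packaged input tables for the HDAC8 case study: a
#' *synthetic stand-in* for the per-region exchange thermodynamics of
#' wild-type HDAC8 and the L179A / M274A mutants, and the macroscopic
#' constraint tables assembled from values printed in the study's main
#' text.
#'
#' Only the minor-state populations that are printed in the main text
#' are calibrated (CAT 6.6% free / 1.4% bound; the L2,6 changes across
#' variants); the exchange rates and L1 populations are fixed synthetic
#' choices at realistic millisecond-regime values, so analyses driven by
#' the *rates* (notably macroscopic off-rate gating) are illustrative
#' rather than reproductions.  See the package vignette.
#'
#' @return list with `rates_by_variant` (named list of
#'   [region_rate_set()] for WT, L179A, M274A), `constraints` (the
#'   8-constraint training [constraint_set()]: kcat and KM for WT in
#'   H2O, kcat/KM for WT in D2O and for L179A, Kd and macroscopic
#'   off-rate for WT and L179A) and `heldout` (the 3 M274A observables).
#' @export
hdac8_standin_inputs <- function() {
  path <- function(f) system.file("extdata", f, package = "excat",
                                  mustWork = TRUE)
  tab <- read.csv(path("hdac8_thermo_standin_synthetic.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)
  build_region <- function(row) {
    topo <- exchange_topology(row$topology)
    labs <- vapply(topo$edges, edge_label, "")
    if (row$topology == "two_site") {
      thermo_from_pop_kex(topo, c(B = row$p_B),
                          setNames(row$kex_1, labs))
    } else {
      thermo_from_pop_kex(topo, c(B = row$p_B, C = row$p_C),
                          setNames(c(row$kex_1, row$kex_2), labs))
    }
  }
  rates_by_variant <- list()
  for (v in unique(tab$variant)) {
    man <- function(m) {
      sub <- tab[tab$variant == v & tab$manifold == m, ]
      setNames(lapply(seq_len(nrow(sub)),
                      function(i) build_region(sub[i, ])), sub$region)
    }
    rates_by_variant[[v]] <- region_rate_set(free = man("free"),
                                             bound = man("bound"))
  }
  list(rates_by_variant = rates_by_variant,
       constraints = constraint_set(
         read.csv(path("hdac8_constraints_maintext.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)),
       heldout = constraint_set(
         read.csv(path("hdac8_heldout_m274a_maintext.csv"),
                  comment.char = "#", stringsAsFactors = FALSE)))
}
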