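#' Generic rapid-equilibrium kinetic scheme
#'
#' A small graph representation of an enzyme occupancy scheme: named states
#' connected by reversible edges that are either pure conformational
#' equilibria (dimensionless constant \code{K}, meaning
#' \code{[to]/[from] = K}) or ligand-binding steps (dissociation constant
#' \code{K} in uM, meaning \code{[to]/[from] = c/K} at ligand concentration
#' \code{c}), plus exactly one irreversible catalytic edge leaving the
#' catalytically competent state at rate \code{kcat}. Used by
#' \code{\link{steady_state_rate_oracle}} to validate the closed-form rate
#' laws by brute-force occupancy algebra.
#'
#' Every closed loop of reversible edges must satisfy detailed balance
#' (the product of equilibrium factors around the loop is 1); this is
#' verified numerically by the oracle to within 1e-12.
#'
#' @param states character vector of state names.
#' @param edges data.frame with columns \code{from}, \code{to} (state
#'   names), \code{type} (\code{"equilibrium"} or \code{"binding"}), and
#'   \code{K} (dimensionless constant or Kd in uM).
#' @param catalytic_state name of the state catalysis proceeds from.
#' @param kcat catalytic rate constant (s^-1, bp/s or nt/s).
#' @return Object of class \code{"kinetic_scheme"}.
#' @seealso \code{\link{scheme_ordered}}, \code{\link{scheme_capture}}
#' @export
kinetic_scheme <- function(states, edges, catalytic_state, kcat) {
  stopifnot(is.character(states), !anyDuplicated(states),
            all(c("from", "to", "type", "K") %in% names(edges)),
            all(edges$from %in% states), all(edges$to %in% states),
            all(edges$type %in% c("equilibrium", "binding")),
            all(is.finite(edges$K)), all(edges$K > 0),
            catalytic_state %in% states,
            is.finite(kcat), kcat > 0)
  structure(list(states = states, edges = edges,
                 catalytic_state = catalytic_state, kcat = kcat),
            class = "kinetic_scheme")
}

#' Scheme for the ordered polymerase mechanism
#'
#' Pol <-> Pol.base (K1, capture) -> Pol.base.dNTP (binding, Kd_nt) ->
#' incorporation at kcat. K1 must be > 0 (a zero capture equilibrium has no
#' finite edge constant; the closed form handles that boundary).
#'
#' @param p an \code{\link{ordered_params}} object with \code{K1 > 0}.
#' @return A \code{\link{kinetic_scheme}}.
#' @export
scheme_ordered <- function(p) {
  stopifnot(inherits(p, "ordered_params"), p$K1 > 0)
  kinetic_scheme(
    states = c("Pol", "Pol.base", "Pol.base.dNTP"),
    edges = data.frame(
      from = c("Pol", "Pol.base"),
      to = c("Pol.base", "Pol.base.dNTP"),
      type = c("equilibrium", "binding"),
      K = c(p$K1, p$Kd_nt)),
    catalytic_state = "Pol.base.dNTP",
    kcat = p$kcat)
}

#' Scheme for a helicase base-capture mechanism variant
#'
#' Variant A: H <-> H* (K1) <-> H*.T (binding). Variant B: H <-> H.T
#' (binding) <-> H.T* (K2), where H.T* is the captured dTTP-bound state.
#' Variant C carries all four states and all four edges; the dTTP-binding
#' edge into the captured state is computed from detailed balance around the
#' cycle (\code{Kd' = K1 * Kd_t / K2}), never supplied independently.
#'
#' @param p a \code{\link{capture_params}} object with positive capture
#'   equilibria for the edges its variant uses (variant C additionally needs
#'   \code{K1 > 0} so the cycle closure is finite).
#' @return A \code{\link{kinetic_scheme}}.
#' @export
scheme_capture <- function(p) {
  stopifnot(inherits(p, "capture_params"))
  switch(p$variant,
    A = {
      stopifnot(p$K1 > 0)
      kinetic_scheme(
        states = c("H", "Hcap", "Hcap.T"),
        edges = data.frame(
          from = c("H", "Hcap"), to = c("Hcap", "Hcap.T"),
          type = c("equilibrium", "binding"), K = c(p$K1, p$Kd_t)),
        catalytic_state = "Hcap.T", kcat = p$kcat)
    },
    B = {
      stopifnot(p$K2 > 0)
      kinetic_scheme(
        states = c("H", "H.T", "Hcap.T"),
        edges = data.frame(
          from = c("H", "H.T"), to = c("H.T", "Hcap.T"),
          type = c("binding", "equilibrium"), K = c(p$Kd_t, p$K2)),
        catalytic_state = "Hcap.T", kcat = p$kcat)
    },
    C = {
      stopifnot(p$K1 > 0, p$K2 > 0)
      kinetic_scheme(
        states = c("H", "Hcap", "H.T", "Hcap.T"),
        edges = data.frame(
          from = c("H", "H", "H.T", "Hcap"),
          to = c("Hcap", "H.T", "Hcap.T", "Hcap.T"),
          type = c("equilibrium", "binding", "equilibrium", "binding"),
          K = c(p$K1, p$Kd_t, p$K2, p$K1 * p$Kd_t / p$K2)),
        catalytic_state = "Hcap.T", kcat = p$kcat)
    })
}

#' Numeric steady-state rate from a kinetic scheme
#'
#' Independent brute-force evaluation of any rapid-equilibrium mechanism:
#' relative state occupancies are propagated over a spanning tree of the
#' reversible-edge graph, every remaining edge is checked for detailed
#' balance (relative deviation <= 1e-12, so any inconsistent cycle is
#' rejected), occupancies are normalized, and the rate returned is
#' \code{kcat} times the occupancy of the catalytic state. Intended as the
#' validation oracle for the closed-form rate laws.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param c ligand concentration, uM (vector, >= 0).
#' @return Rates, same length as \code{c}.
#' @export
steady_state_rate_oracle <- function(scheme, c) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and non-negative")
  vapply(c, function(conc) .oracle_one(scheme, conc), numeric(1))
}

.oracle_one <- function(scheme, conc) {
  states <- scheme$states
  ed <- scheme$edges
  # occupancy factor [to]/[from] of each edge at this ligand concentration
  fac <- ifelse(ed$type == "binding", conc / ed$K, ed$K)
  logocc <- stats::setNames(rep(NA_real_, length(states)), states)
  logocc[[1L]] <- 0
  # binding edges at conc = 0 have factor 0: the bound state is unoccupied
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ed))) {
      f <- ed$from[i]; t <- ed$to[i]
      if (!is.na(logocc[[f]]) && is.na(logocc[[t]])) {
        logocc[[t]] <- logocc[[f]] + log(fac[i])
        changed <- TRUE
      } else if (!is.na(logocc[[t]]) && is.na(logocc[[f]])) {
        if (fac[i] == 0)
          stop("state '", t, "' unreachable forward at zero ligand; ",
               "occupancy system singular")
        logocc[[f]] <- logocc[[t]] - log(fac[i])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(logocc))
    stop("occupancy system singular: unreachable state(s) ",
         paste(states[is.na(logocc)], collapse = ", "))
  # detailed-balance check: every edge must agree with the assigned
  # occupancies; a loop with product != 1 fails here
  for (i in seq_len(nrow(ed))) {
    lhs <- logocc[[ed$to[i]]]
    rhs <- logocc[[ed$from[i]]] +
      (if (fac[i] > 0) log(fac[i]) else -Inf)
    if (is.infinite(lhs) && is.infinite(rhs)) next
    if (abs(lhs - rhs) > 1e-12 * max(1, abs(lhs), abs(rhs)))
      stop("detailed balance violated on edge ", ed$from[i], " -> ",
           ed$to[i])
  }
  occ <- exp(logocc - max(logocc))
  scheme$kcat * occ[[scheme$catalytic_state]] / sum(occ)
}
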