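#' Fraction of duplex unwound under the n-step sequential model
#'
#' The cumulative probability that \code{n} sequential exponential steps of
#' rate \code{k} have all completed by time \code{t} -- the Erlang(n, k)
#' first-passage CDF, i.e. the regularized lower incomplete gamma function of
#' order \code{n} evaluated at \code{k*t}.
#'
#' @param t time, s (vector, >= 0).
#' @param n number of steps (integer >= 1).
#' @param k per-step rate constant, s^-1 (> 0).
#' @return Fraction unwound in [0, 1], same length as \code{t}.
#' @examples
#' erlang_fraction_unwound(log(2) / 7, n = 1, k = 7)  # 0.5
#' @export
erlang_fraction_unwound <- function(t, n, k) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative")
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single value >= 1")
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive rate")
  stats::pgamma(t, shape = n, rate = k)
}

#' Model fluorescence trace of the n-step unwinding reaction
#'
#' \code{baseline + amplitude * erlang_fraction_unwound(t, n_steps,
#' step_rate)}. For \code{n_steps > 1} the trace shows the characteristic
#' presteady-state lag before the fluorescence rise.
#'
#' @param times sorted non-negative times, s.
#' @param p an \code{\link{nstep_params}} object.
#' @return Fluorescence values (a.u.), same length as \code{times}.
#' @export
nstep_trace <- function(times, p) {
  stopifnot(inherits(p, "nstep_params"))
  if (is.unsorted(times)) stop("'times' must be sorted increasing")
  p$baseline +
    p$amplitude * erlang_fraction_unwound(times, p$n_steps, p$step_rate)
}

#' Average unwinding rate implied by n-step parameters
#'
#' The macroscopic base-pair unwinding rate: step size times step rate,
#' \code{duplex_length * step_rate / n_steps}, equal to duplex length divided
#' by the mean first-passage time \code{n/k}.
#'
#' @param p an \code{\link{nstep_params}} object.
#' @return Average unwinding rate, bp/s.
#' @export
average_unwinding_rate <- function(p) {
  stopifnot(inherits(p, "nstep_params"))
  p$step_size * p$step_rate
}

#' Hyperbolic rate law
#'
#' \code{rate = kcat * c / (Km + c)}: the phenomenological dependence of the
#' average unwinding rate on nucleotide concentration.
#'
#' @param c nucleotide concentration, uM (vector, >= 0).
#' @param p a \code{\link{hyperbolic_params}} object.
#' @return Rates, same units as \code{kcat}.
#' @export
hyperbolic_rate <- function(c, p) {
  stopifnot(inherits(p, "hyperbolic_params"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and non-negative")
  p$kcat * c / (p$Km + c)
}

#' Rate law of the ordered polymerase mechanism
#'
#' Rapid-equilibrium rate of the ordered base-capture -> dNTP-binding ->
#' incorporation scheme: \code{kcat * c / (Kd_nt * (1 + 1/K1) + c)}. The
#' apparent Km is \code{Kd_nt * (1 + 1/K1)} while the apparent kcat equals
#' \code{kcat} independent of K1, analogous to a competitive mechanism:
#' harder base capture (smaller K1) raises Km but not the saturating rate.
#'
#' @param c dNTP concentration, uM (vector, >= 0).
#' @param p an \code{\link{ordered_params}} object.
#' @return Rates, bp/s. If \code{K1 = 0} the apparent Km is infinite; zero
#'   rates are returned with attribute \code{degenerate = TRUE}.
#' @export
ordered_rate <- function(c, p) {
  stopifnot(inherits(p, "ordered_params"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and non-negative")
  if (p$K1 == 0)
    return(structure(rep(0, length(c)), degenerate = TRUE))
  p$kcat * c / (p$Kd_nt * (1 + 1 / p$K1) + c)
}

#' Rate laws of the helicase base-capture mechanisms (variants A, B, C)
#'
#' Rapid-equilibrium occupancy rate laws. With \code{x = c / Kd_t}:
#' \describe{
#'   \item{A}{\code{kcat * K1 * x / (1 + K1 + K1 * x)}, i.e. hyperbolic with
#'     apparent Km \code{Kd_t*(1+K1)/K1} and saturating rate \code{kcat}.}
#'   \item{B}{\code{kcat * K2 * x / (1 + x + K2 * x)}: saturating rate
#'     \code{kcat*K2/(1+K2)}, apparent Km \code{Kd_t/(1+K2)}.}
#'   \item{C}{\code{kcat * K2 * x / (1 + K1 + x + K2 * x)}: the random-order
#'     cycle with the captured-state dTTP-binding edge fixed by detailed
#'     balance. Saturating rate \code{kcat*K2/(1+K2)}, apparent Km
#'     \code{Kd_t*(1+K1)/(1+K2)}. Reduces exactly to B at K1 = 0.}
#' }
#'
#' @param c dTTP concentration, uM (vector, >= 0).
#' @param p a \code{\link{capture_params}} object.
#' @return Rates, nt/s. Degenerate capture equilibria (K1 = 0 for variant A,
#'   K2 = 0 for B/C) return zero rates with attribute
#'   \code{degenerate = TRUE}.
#' @export
capture_model_rate <- function(c, p) {
  stopifnot(inherits(p, "capture_params"))
  if (any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and non-negative")
  x <- c / p$Kd_t
  switch(p$variant,
    A = {
      if (p$K1 == 0)
        return(structure(rep(0, length(c)), degenerate = TRUE))
      p$kcat * p$K1 * x / (1 + p$K1 + p$K1 * x)
    },
    B = {
      if (p$K2 == 0)
        return(structure(rep(0, length(c)), degenerate = TRUE))
      p$kcat * p$K2 * x / (1 + x + p$K2 * x)
    },
    C = {
      if (p$K2 == 0)
        return(structure(rep(0, length(c)), degenerate = TRUE))
      p$kcat * p$K2 * x / (1 + p$K1 + x + p$K2 * x)
    })
}

#' Apparent hyperbolic limits of a mechanistic rate law
#'
#' Every mechanism here is exactly hyperbolic in nucleotide concentration;
#' this returns its closed-form apparent (kcat, Km).
#'
#' @param p an \code{\link{ordered_params}} or \code{\link{capture_params}}
#'   object.
#' @return A \code{\link{hyperbolic_params}} object; for a degenerate
#'   mechanism (capture equilibrium 0) a list with \code{kcat = 0},
#'   \code{Km = Inf} and attribute \code{degenerate = TRUE}.
#' @examples
#' capture_model_limits(ordered_params(K1 = 1/3, Kd_nt = 10, kcat = 160))
#' @export
capture_model_limits <- function(p) {
  degen <- structure(list(kcat = 0, Km = Inf), degenerate = TRUE)
  if (inherits(p, "ordered_params")) {
    if (p$K1 == 0) return(degen)
    return(hyperbolic_params(kcat = p$kcat,
                             Km = p$Kd_nt * (1 + 1 / p$K1)))
  }
  stopifnot(inherits(p, "capture_params"))
  switch(p$variant,
    A = {
      if (p$K1 == 0) return(degen)
      hyperbolic_params(kcat = p$kcat,
                        Km = p$Kd_t * (1 + p$K1) / p$K1)
    },
    B = {
      if (p$K2 == 0) return(degen)
      hyperbolic_params(kcat = p$kcat * p$K2 / (1 + p$K2),
                        Km = p$Kd_t / (1 + p$K2))
    },
    C = {
      if (p$K2 == 0) return(degen)
      hyperbolic_params(kcat = p$kcat * p$K2 / (1 + p$K2),
                        Km = p$Kd_t * (1 + p$K1) / (1 + p$K2))
    })
}
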