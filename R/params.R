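#' Parameters of the n-step sequential unwinding model
#'
#' Duplex unwinding is described as \code{n_steps} sequential irreversible
#' steps of equal size \code{s = duplex_length / n_steps} (bp) and equal rate
#' constant \code{step_rate} (s^-1). The observable fluorescence trace is
#' \code{baseline + amplitude * F(t)}, where \code{F} is the Erlang
#' first-passage CDF of the n-step chain.
#'
#' @param n_steps integer >= 1, number of sequential unwinding steps.
#' @param step_rate per-step rate constant, s^-1 (> 0).
#' @param duplex_length base pairs to unwind (> 0).
#' @param baseline fluorescence offset, arbitrary units.
#' @param amplitude fluorescence change on full unwinding, a.u. (> 0).
#' @return An object of class \code{"nstep_params"}: a list with the five
#'   fields plus the derived \code{step_size} (bp/step).
#' @examples
#' p <- nstep_params(n_steps = 40, step_rate = 150, duplex_length = 40)
#' average_unwinding_rate(p)  # 150 bp/s
#' @export
nstep_params <- function(n_steps, step_rate, duplex_length,
                         baseline = 0, amplitude = 1) {
  n_steps <- as.integer(round(n_steps))
  stopifnot(length(n_steps) == 1L, n_steps >= 1L,
            is.finite(step_rate), step_rate > 0,
            is.finite(duplex_length), duplex_length > 0,
            is.finite(baseline), is.finite(amplitude), amplitude > 0)
  structure(list(n_steps = n_steps, step_rate = step_rate,
                 duplex_length = duplex_length, baseline = baseline,
                 amplitude = amplitude,
                 step_size = duplex_length / n_steps),
            class = "nstep_params")
}

#' @export
print.nstep_params <- function(x, ...) {
  cat("n-step unwinding model parameters\n")
  cat(sprintf("  n_steps       : %d\n", x$n_steps))
  cat(sprintf("  step_rate     : %.6g s^-1\n", x$step_rate))
  cat(sprintf("  duplex_length : %.6g bp (step size %.4g bp)\n",
              x$duplex_length, x$step_size))
  cat(sprintf("  baseline      : %.6g a.u.\n", x$baseline))
  cat(sprintf("  amplitude     : %.6g a.u.\n", x$amplitude))
  cat(sprintf("  average unwinding rate: %.6g bp/s\n",
              average_unwinding_rate(x)))
  invisible(x)
}

#' Phenomenological hyperbolic (Michaelis-Menten-type) rate-law parameters
#'
#' The apparent maximal unwinding rate \code{kcat} (bp/s or nt/s) and the
#' nucleotide concentration at half-maximal rate \code{Km} (uM) of
#' \code{rate = kcat * c / (Km + c)}.
#'
#' @param kcat maximal rate (> 0), bp/s or nt/s.
#' @param Km half-saturating concentration (> 0), uM.
#' @return Object of class \code{"hyperbolic_params"}.
#' @export
hyperbolic_params <- function(kcat, Km) {
  stopifnot(is.finite(kcat), kcat > 0, is.finite(Km), Km > 0)
  structure(list(kcat = kcat, Km = Km), class = "hyperbolic_params")
}

#' @export
print.hyperbolic_params <- function(x, ...) {
  cat(sprintf("hyperbolic rate law: kcat = %.6g, Km = %.6g uM\n",
              x$kcat, x$Km))
  invisible(x)
}

#' Parameters of the ordered three-step polymerase mechanism
#'
#' The polymerase at a primer-template junction first captures the next
#' template base (equilibrium \code{K1}, dimensionless; Pol_n <-> Pol_n.base),
#' then binds the incoming dNTP (dissociation constant \code{Kd_nt}, uM), and
#' finally incorporates it (rate \code{kcat}, bp/s). Under rapid equilibrium
#' the scheme is hyperbolic in dNTP with apparent \code{Km = Kd_nt*(1 + 1/K1)}
#' and apparent kcat equal to \code{kcat} -- base-capture behaves like a
#' purely competitive step: it raises Km without touching the saturating rate.
#'
#' @param K1 base-capture equilibrium constant, dimensionless (>= 0; 0 is a
#'   degenerate boundary where the rate is identically 0).
#' @param Kd_nt dNTP dissociation constant, uM (> 0).
#' @param kcat incorporation rate at saturation, bp/s (> 0).
#' @return Object of class \code{"ordered_params"}.
#' @examples
#' ordered_params(K1 = 1/3, Kd_nt = 10, kcat = 160)  # apparent Km 40 uM
#' @export
ordered_params <- function(K1, Kd_nt, kcat) {
  stopifnot(is.finite(K1), K1 >= 0, is.finite(Kd_nt), Kd_nt > 0,
            is.finite(kcat), kcat > 0)
  structure(list(K1 = K1, Kd_nt = Kd_nt, kcat = kcat),
            class = "ordered_params")
}

#' @export
print.ordered_params <- function(x, ...) {
  cat("ordered base-capture/dNTP-binding/incorporation mechanism\n")
  cat(sprintf("  K1 = %.6g, Kd_nt = %.6g uM, kcat = %.6g bp/s\n",
              x$K1, x$Kd_nt, x$kcat))
  lim <- capture_model_limits(x)
  if (isTRUE(attr(lim, "degenerate")))
    cat("  degenerate: K1 = 0, rate identically zero\n")
  else
    cat(sprintf("  apparent kcat = %.6g, apparent Km = %.6g uM\n",
                lim$kcat, lim$Km))
  invisible(x)
}

#' Parameters of the helicase base-capture / dTTP-binding mechanisms
#'
#' Three rapid-equilibrium schemes for how the leading helicase subunit
#' couples capture of the next template base to dTTP binding:
#' \describe{
#'   \item{A (capture then bind)}{H <-> H* (K1), then H* + T <-> H*.T (Kd_t);
#'     catalysis from H*.T. Saturating rate is \code{kcat} regardless of K1.}
#'   \item{B (bind then capture)}{H + T <-> H.T (Kd_t), then H.T <-> H.T*
#'     (K2); catalysis from H.T*. Saturating rate \code{kcat*K2/(1+K2)}.}
#'   \item{C (random order)}{both routes; the fourth edge (dTTP binding to
#'     the captured state) is fixed by detailed balance around the cycle,
#'     never a free parameter. Reduces exactly to B at K1 = 0.}
#' }
#'
#' @param K1 capture equilibrium in the dTTP-free state, dimensionless
#'   (>= 0). Ignored by variant B.
#' @param K2 capture equilibrium in the dTTP-bound state, dimensionless
#'   (>= 0). Ignored by variant A.
#' @param Kd_t dTTP dissociation constant, uM (> 0).
#' @param kcat turnover at full capture and saturating dTTP, nt/s (> 0).
#' @param variant one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @return Object of class \code{"capture_params"}.
#' @examples
#' capture_params(K1 = 0.5, K2 = 1, Kd_t = 90, kcat = 130, variant = "C")
#' @export
capture_params <- function(K1 = NA_real_, K2 = NA_real_, Kd_t, kcat,
                           variant = c("C", "A", "B")) {
  variant <- match.arg(variant)
  if (variant == "A") K2 <- NA_real_
  if (variant == "B") K1 <- NA_real_
  if (variant %in% c("A", "C"))
    stopifnot(is.finite(K1), K1 >= 0)
  if (variant %in% c("B", "C"))
    stopifnot(is.finite(K2), K2 >= 0)
  stopifnot(is.finite(Kd_t), Kd_t > 0, is.finite(kcat), kcat > 0)
  structure(list(K1 = K1, K2 = K2, Kd_t = Kd_t, kcat = kcat,
                 variant = variant),
            class = "capture_params")
}

#' @export
print.capture_params <- function(x, ...) {
  lab <- c(A = "A (capture then bind)", B = "B (bind then capture)",
           C = "C (random order)")[x$variant]
  cat(sprintf("helicase base-capture mechanism, variant %s\n", lab))
  cat(sprintf("  K1 = %s, K2 = %s, Kd_t = %.6g uM, kcat = %.6g nt/s\n",
              format(x$K1), format(x$K2), x$Kd_t, x$kcat))
  lim <- capture_model_limits(x)
  if (isTRUE(attr(lim, "degenerate")))
    cat("  degenerate: capture equilibrium 0, rate identically zero\n")
  else
    cat(sprintf("  apparent kcat = %.6g nt/s, apparent Km = %.6g uM\n",
                lim$kcat, lim$Km))
  invisible(x)
}
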