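#' Gillespie first-passage times of the n-step unwinding chain
#'
#' Stochastic-simulation oracle for the n-step model: each molecule's
#' unwinding time is simulated step by step as the sum of \code{n_steps}
#' independent exponential waiting times of rate \code{step_rate} (the exact
#' Gillespie trajectory of a linear irreversible chain). Sample mean
#' converges to \code{n/k}.
#'
#' @param p an \code{\link{nstep_params}} object.
#' @param n_molecules number of molecules to simulate (>= 1).
#' @param seed integer seed; the generator touches no global random state
#'   outside the call.
#' @return Numeric vector of \code{n_molecules} unwinding times, s.
#' @export
gillespie_first_passage <- function(p, n_molecules, seed) {
  stopifnot(inherits(p, "nstep_params"), n_molecules >= 1)
  .with_seed(seed, {
    # one waiting time per (molecule, step); column sums = first passages
    colSums(matrix(stats::rexp(p$n_steps * n_molecules, rate = p$step_rate),
                   nrow = p$n_steps))
  })
}

#' Simulate a stopped-flow unwinding trace
#'
#' Analytic mode adds i.i.d. Gaussian noise to the closed-form
#' \code{\link{nstep_trace}}; stochastic mode reports
#' \code{baseline + amplitude *} (fraction of \code{n_molecules} whose
#' Gillespie first-passage time is <= t), emulating a finite ensemble of
#' unwinding molecules. Identical seed gives bit-identical output.
#'
#' @param p an \code{\link{nstep_params}} object.
#' @param times sampling times, s (default 500 points over ~4 mean
#'   first-passage times).
#' @param noise_sd additive Gaussian noise sd, a.u. (default 2\% of
#'   amplitude; analytic mode only).
#' @param seed integer seed.
#' @param mode \code{"analytic"} or \code{"stochastic"}.
#' @param n_molecules ensemble size for stochastic mode.
#' @param dip_rate optional post-rise decay rate (s^-1) of the amplitude, a
#'   nuisance term emulating the slow fluorescence dip sometimes seen after
#'   the unwinding plateau with combined enzymes; default \code{NULL} (off).
#' @return A \code{trace_dataset}: data.frame with columns \code{time_s},
#'   \code{intensity} and a \code{metadata} attribute.
#' @export
simulate_trace <- function(p, times = NULL, noise_sd = 0.02 * p$amplitude,
                           seed = 1L, mode = c("analytic", "stochastic"),
                           n_molecules = 1000L, dip_rate = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "nstep_params"), noise_sd >= 0)
  if (is.null(times))
    times <- seq(0, 4 * p$n_steps / p$step_rate, length.out = 500L)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  frac <- switch(mode,
    analytic = erlang_fraction_unwound(times, p$n_steps, p$step_rate),
    stochastic = {
      stopifnot(n_molecules >= 1)
      fp <- gillespie_first_passage(p, n_molecules, seed)
      vapply(times, function(t) mean(fp <= t), numeric(1))
    })
  # optional nuisance dip: the unwound-state amplitude decays slowly after
  # the rise (a fluorophore artifact, not part of the mechanism)
  if (!is.null(dip_rate)) {
    stopifnot(dip_rate > 0)
    t50 <- stats::qgamma(0.5, shape = p$n_steps, rate = p$step_rate)
    frac <- frac * exp(-dip_rate * pmax(times - t50, 0))
  }
  intensity <- p$baseline + p$amplitude * frac
  if (mode == "analytic" && noise_sd > 0)
    intensity <- intensity +
      .with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  structure(data.frame(time_s = times, intensity = intensity),
            metadata = list(n_steps = p$n_steps, step_rate = p$step_rate,
                            duplex_length = p$duplex_length,
                            baseline = p$baseline, amplitude = p$amplitude,
                            noise_sd = noise_sd, mode = mode, seed = seed),
            class = c("trace_dataset", "data.frame"))
}

#' Simulate a rate-vs-concentration titration
#'
#' Rates are the mechanistic model rate at each concentration times
#' \code{(1 + Gaussian(0, relative_noise))}, truncated at zero, with
#' reported per-point errors \code{relative_noise * model rate}. Default
#' grids mirror typical stopped-flow designs: 8 log-spaced points, dTTP
#' 25-2000 uM or dNTPs 5-1000 uM.
#'
#' @param p an \code{\link{ordered_params}}, \code{\link{capture_params}} or
#'   \code{\link{hyperbolic_params}} object.
#' @param conc_grid concentrations, uM; default 8 log-spaced points
#'   25-2000 uM for helicase (capture) models, 5-1000 uM otherwise.
#' @param relative_noise multiplicative Gaussian noise (default 0.03).
#' @param seed integer seed.
#' @param metadata optional named list merged into the dataset metadata
#'   (e.g. GC percent, enzyme condition).
#' @return A \code{titration_dataset}: data.frame with columns
#'   \code{conc_uM}, \code{rate}, \code{rate_sd} and a \code{metadata}
#'   attribute.
#' @export
simulate_titration <- function(p, conc_grid = NULL, relative_noise = 0.03,
                               seed = 1L, metadata = list()) {
  stopifnot(relative_noise >= 0)
  if (is.null(conc_grid)) {
    conc_grid <- if (inherits(p, "capture_params"))
      exp(seq(log(25), log(2000), length.out = 8L))
    else exp(seq(log(5), log(1000), length.out = 8L))
  }
  if (length(conc_grid) == 0) stop("empty concentration grid")
  mu <- model_rate(conc_grid, p)
  rate <- if (relative_noise > 0) {
    pmax(mu * (1 + .with_seed(seed,
      stats::rnorm(length(mu), 0, relative_noise))), 0)
  } else mu
  structure(data.frame(conc_uM = conc_grid, rate = rate,
                       rate_sd = relative_noise * mu),
            metadata = c(list(model = class(p)[1L],
                              params = unclass(p),
                              relative_noise = relative_noise, seed = seed),
                         metadata),
            class = c("titration_dataset", "data.frame"))
}

# dispatch helper: rate of any supported model object
model_rate <- function(c, p) {
  if (inherits(p, "ordered_params")) ordered_rate(c, p)
  else if (inherits(p, "capture_params")) capture_model_rate(c, p)
  else if (inherits(p, "hyperbolic_params")) hyperbolic_rate(c, p)
  else stop("unsupported model object of class ", class(p)[1L])
}

#' Specify true 2-aminopurine fold changes for panel simulation
#'
#' An effect specification is a data.frame with one row per (construct,
#' condition): the probe position as offset from the primer 3' end N, the
#' probed strand, junction/internal context, the primer-end-to-junction gap,
#' the condition label, the true fold change over the DNA-only intensity,
#' and the relative noise sd. The DNA-only condition has fold 1 by
#' definition and need not be listed; it is added automatically.
#'
#' @param probe_position integer offsets N+k (k >= 1).
#' @param strand \code{"leading"} or \code{"lagging"}.
#' @param context \code{"junction"}, \code{"internal"} or \code{"ssDNA"}.
#' @param gap_nt unpaired template nucleotides between primer end and
#'   junction (0-3).
#' @param condition condition label, e.g. \code{"+DNAP"}.
#' @param fold true fold change (> 0).
#' @param noise relative noise sd (>= 0).
#' @return data.frame of class \code{"ap_effect_spec"}.
#' @export
ap_effect_spec <- function(probe_position, strand, context, gap_nt,
                           condition, fold, noise = 0.03) {
  d <- data.frame(probe_position = as.integer(probe_position),
                  strand = strand, context = context,
                  gap_nt = as.integer(gap_nt), condition = condition,
                  fold = fold, noise = noise)
  stopifnot(all(d$probe_position >= 1), all(d$gap_nt >= 0),
            all(d$fold > 0), all(d$noise >= 0),
            all(d$strand %in% c("leading", "lagging")),
            all(d$context %in% c("junction", "internal", "ssDNA")))
  class(d) <- c("ap_effect_spec", "data.frame")
  d
}

#' Simulate a corrected 2-aminopurine intensity panel
#'
#' Intensities are \code{reference * fold * (1 + Gaussian(0, noise))}; a
#' DNA-only row (fold 1) is emitted for every construct in the spec. The
#' reported \code{intensity_sd} is \code{reference * fold * noise}.
#'
#' @param spec an \code{\link{ap_effect_spec}}.
#' @param seed integer seed.
#' @param reference DNA-only intensity per construct, a.u. (default 100).
#' @return An \code{ap_panel}: data.frame with columns \code{construct_id},
#'   \code{probe_position}, \code{strand}, \code{context}, \code{gap_nt},
#'   \code{condition}, \code{intensity}, \code{intensity_sd}.
#' @export
simulate_ap_panel <- function(spec, seed = 1L, reference = 100) {
  stopifnot(inherits(spec, "ap_effect_spec"), reference > 0)
  key <- with(spec, paste(probe_position, strand, context, gap_nt,
                          sep = "/"))
  constructs <- unique(data.frame(
    construct_id = key, probe_position = spec$probe_position,
    strand = spec$strand, context = spec$context, gap_nt = spec$gap_nt,
    stringsAsFactors = FALSE))
  dna <- constructs
  dna$condition <- "DNA"
  dna$fold <- 1
  dna$noise <- 0
  rows <- rbind(dna,
                cbind(construct_id = key,
                      spec[, c("probe_position", "strand", "context",
                               "gap_nt", "condition", "fold", "noise")]))
  mu <- reference * rows$fold
  eps <- .with_seed(seed, stats::rnorm(nrow(rows), 0, 1))
  rows$intensity <- pmax(mu * (1 + rows$noise * eps), .Machine$double.eps)
  rows$intensity_sd <- mu * rows$noise
  rows$fold <- NULL
  rows$noise <- NULL
  rownames(rows) <- NULL
  class(rows) <- c("ap_panel", "data.frame")
  rows
}

#' Canonical qualitative 2-AP effect patterns
#'
#' Ready-made effect specifications encoding the qualitative footprint
#' findings for the T7 replisome enzymes, for worked examples and tests:
#' \describe{
#'   \item{\code{ap_pattern_dnap()}}{polymerase alone: lagging-strand
#'     increases at N+1, N+2 and at N+3 probed internally, none at N+4 and
#'     none at N+3 probed at the junction; leading strand increase at N+1,
#'     none at N+2, decrease at N+3 (template-base contact).}
#'   \item{\code{ap_pattern_helicase(gaps)}}{helicase alone: increase at the
#'     junction base pair only, at every primer-end-to-junction gap, never
#'     at the second base pair from the junction.}
#'   \item{\code{ap_pattern_synergy(gaps, synergy_gaps)}}{junction-probe
#'     fold changes for +DNAP, +helicase and +both at each gap; the
#'     combined-enzyme fold exceeds additivity only at \code{synergy_gaps}.}
#' }
#'
#' @param gaps integer gaps to include (default 0:3).
#' @param synergy_gaps gaps at which combined melting is synergistic
#'   (default 0:1).
#' @param up fold change used for a clear increase (default 1.6).
#' @param noise relative noise sd for every row (default 0.03).
#' @return An \code{\link{ap_effect_spec}}.
#' @name ap_patterns
NULL

#' @rdname ap_patterns
#' @export
ap_pattern_dnap <- function(noise = 0.03, up = 1.6) {
  rbind(
    # gap-0 fork, lagging strand: junction bp N+1 plus internal N+2..N+4
    ap_effect_spec(1L, "lagging", "junction", 0L, "+DNAP", up, noise),
    ap_effect_spec(2:4, "lagging", "internal", 0L, "+DNAP",
                   c(up, up, 1.0), noise),
    # disambiguating forks: the same absolute positions probed at the
    # junction (gap 1 puts N+2 at the junction, gap 2 puts N+3 there)
    ap_effect_spec(2:3, "lagging", "junction", 1:2, "+DNAP",
                   c(up, 1.0), noise),
    # leading-strand template bases: contact evidence
    ap_effect_spec(1L, "leading", "junction", 0L, "+DNAP", up, noise),
    ap_effect_spec(2:3, "leading", "internal", 0L, "+DNAP",
                   c(1.0, 1 / up), noise))
}

#' @rdname ap_patterns
#' @export
ap_pattern_helicase <- function(gaps = 0:3, noise = 0.03, up = 1.6) {
  rbind(
    ap_effect_spec(gaps + 1L, "lagging", "junction", gaps, "+helicase",
                   rep(up, length(gaps)), noise),
    ap_effect_spec(gaps + 2L, "lagging", "internal", gaps, "+helicase",
                   rep(1.0, length(gaps)), noise))
}

#' @rdname ap_patterns
#' @export
ap_pattern_synergy <- function(gaps = 0:3, synergy_gaps = 0:1,
                               noise = 0.02, up = 1.4) {
  both <- ifelse(gaps %in% synergy_gaps, 3.2, 2 * up - 1)
  rbind(
    ap_effect_spec(gaps + 1L, "lagging", "junction", gaps, "+DNAP",
                   rep(up, length(gaps)), noise),
    ap_effect_spec(gaps + 1L, "lagging", "junction", gaps, "+helicase",
                   rep(up, length(gaps)), noise),
    ap_effect_spec(gaps + 1L, "lagging", "junction", gaps, "+both",
                   both, noise))
}

# evaluate expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
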