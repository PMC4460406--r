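#' Fit the n-step sequential model to a stopped-flow unwinding trace
#'
#' Nonlinear least squares of \code{baseline + amplitude * Erlang(n, k) CDF}
#' against an observed trace. For each candidate step count \code{n} the
#' per-step rate \code{k} is optimized on a log scale while baseline and
#' amplitude, which enter linearly, are solved exactly by linear least
#' squares; \code{n} is either fixed or profiled over an integer grid and
#' chosen by minimal SSE, with ties (within 0.1\% of the minimum) resolved
#' toward smaller \code{n} (parsimony). The average unwinding rate follows
#' from the winning fit as \code{duplex_length * k / n}.
#'
#' @param trace a \code{trace_dataset} (from \code{\link{simulate_trace}} or
#'   \code{\link{read_trace}}), or any data.frame with columns
#'   \code{time_s} and \code{intensity}.
#' @param duplex_length duplex length to unwind, bp (> 0).
#' @param n_mode \code{"profile"} (default) to profile \code{n} over
#'   \code{n_range}, or \code{"fixed"} to use \code{n_fixed}.
#' @param n_range integer candidates for the profile (default 2:80).
#' @param n_fixed the fixed step count when \code{n_mode = "fixed"}.
#' @param truncate_plateau if TRUE, restrict the fit window to data up to
#'   the first time the smoothed trace exceeds 98\% of its maximum, a guard
#'   against a slow post-plateau fluorescence dip.
#' @param rate_span multiplicative search span around the initializer
#'   \code{k0 = n / t_half} for the 1-D rate optimization (default 100).
#' @return An object of class \code{"nstep_fit"}: fitted
#'   \code{\link{nstep_params}}, \code{sse}, approximate standard errors
#'   (\code{param_errors}), the \code{n_profile} (n vs SSE) when profiled,
#'   and \code{status} (\code{"converged"}, \code{"boundary"} or
#'   \code{"degenerate"}).
#' @examples
#' p <- nstep_params(40, 150, 40, baseline = 0.1, amplitude = 1)
#' tr <- simulate_trace(p, noise_sd = 0, seed = 1)
#' fit <- fit_nstep(tr, duplex_length = 40, n_mode = "fixed", n_fixed = 40)
#' coef(fit)
#' @export
fit_nstep <- function(trace, duplex_length,
                      n_mode = c("profile", "fixed"), n_range = 2:80,
                      n_fixed = NULL, truncate_plateau = FALSE,
                      rate_span = 100) {
  n_mode <- match.arg(n_mode)
  stopifnot(duplex_length > 0,
            all(c("time_s", "intensity") %in% names(trace)))
  t <- trace$time_s
  y <- trace$intensity
  if (length(t) < 20L)
    stop("need at least 20 time points spanning the rise")
  if (truncate_plateau) {
    sm <- stats::fitted(stats::smooth.spline(t, y))
    cut <- which(sm >= min(sm) + 0.98 * (max(sm) - min(sm)))[1L]
    keep <- seq_len(max(cut, 20L))
    t <- t[keep]; y <- y[keep]
  }

  # deterministic initializer: extrema for baseline/amplitude, half-rise
  # time for the rate
  b0 <- min(y); a0 <- max(y) - b0
  if (a0 <= 0) a0 <- .Machine$double.eps
  t_half <- t[which(y - b0 >= a0 / 2)[1L]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t[t > 0])

  fit_one_n <- function(n) {
    k0 <- n / t_half
    obj <- function(logk) .nstep_lin(t, y, n, exp(logk))$sse
    opt <- stats::optimize(obj, interval = log(k0) + c(-1, 1) * log(rate_span),
                           tol = 1e-10)
    c(list(n = n, k = exp(opt$minimum),
           at_boundary = min(abs(opt$minimum - (log(k0) +
             c(-1, 1) * log(rate_span)))) < 1e-6),
      .nstep_lin(t, y, n, exp(opt$minimum)))
  }

  cands <- if (n_mode == "fixed") {
    stopifnot(!is.null(n_fixed), n_fixed >= 1)
    as.integer(round(n_fixed))
  } else as.integer(n_range)
  fits <- lapply(cands, fit_one_n)
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  # parsimony tie-break: smallest n within 0.1% of the minimal SSE
  best <- which(sses <= min(sses) * 1.001)[1L]
  f <- fits[[best]]

  status <- "converged"
  if (f$at_boundary) status <- "boundary"
  # amplitude indistinguishable from zero at ~95% confidence -> degenerate
  if (!is.finite(f$amp_se) || f$amp <= 0 || f$amp < 2 * f$amp_se)
    status <- "degenerate"

  params <- if (f$amp > 0)
    nstep_params(f$n, f$k, duplex_length, baseline = f$base,
                 amplitude = f$amp) else NULL
  structure(list(
    params = params,
    average_rate = if (!is.null(params)) average_unwinding_rate(params)
                   else NA_real_,
    sse = f$sse,
    param_errors = c(step_rate = f$k_se, baseline = f$base_se,
                     amplitude = f$amp_se),
    n_profile = data.frame(n = cands, sse = sses),
    status = status,
    n_mode = n_mode,
    data = data.frame(time_s = t, intensity = y)),
    class = "nstep_fit")
}

# linear sub-problem: given (n, k), solve baseline + amplitude * F by OLS
# and return coefficients, SSE and curvature-based standard errors
.nstep_lin <- function(t, y, n, k) {
  F <- stats::pgamma(t, shape = n, rate = k)
  X <- cbind(1, F)
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  sse <- sum(r^2)
  m <- length(y)
  sigma2 <- sse / max(m - 3, 1)
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  base_se <- amp_se <- k_se <- NA_real_
  if (!is.null(XtXinv)) {
    base_se <- sqrt(sigma2 * XtXinv[1, 1])
    amp_se <- sqrt(sigma2 * XtXinv[2, 2])
    # rate se from the gradient of F wrt k (Gauss-Newton approximation)
    dFdk <- stats::dgamma(t, shape = n, rate = k) * t / k
    J <- cbind(X, fit$coefficients[2] * dFdk)
    JtJ <- crossprod(J)
    v <- tryCatch(chol2inv(chol(JtJ)), error = function(e) NULL)
    if (!is.null(v)) k_se <- sqrt(sigma2 * v[3, 3])
  }
  list(base = unname(fit$coefficients[1]), amp = unname(fit$coefficients[2]),
       sse = sse, base_se = base_se, amp_se = amp_se, k_se = k_se)
}

#' @export
print.nstep_fit <- function(x, ...) {
  cat("n-step model fit (", x$status, ")\n", sep = "")
  if (!is.null(x$params)) {
    cat(sprintf("  n = %d, step_rate = %.5g s^-1, step size = %.4g bp\n",
                x$params$n_steps, x$params$step_rate, x$params$step_size))
    cat(sprintf("  baseline = %.5g, amplitude = %.5g (a.u.)\n",
                x$params$baseline, x$params$amplitude))
    cat(sprintf("  average unwinding rate = %.5g bp/s\n", x$average_rate))
  }
  cat(sprintf("  SSE = %.5g over %d points\n", x$sse, nrow(x$data)))
  invisible(x)
}

#' @export
coef.nstep_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(n_steps = NA, step_rate = NA,
                                       baseline = NA, amplitude = NA))
  with(object$params, c(n_steps = n_steps, step_rate = step_rate,
                        baseline = baseline, amplitude = amplitude))
}

#' @export
fitted.nstep_fit <- function(object, ...) {
  nstep_trace(object$data$time_s, object$params)
}

#' @export
residuals.nstep_fit <- function(object, ...) {
  object$data$intensity - fitted(object)
}

#' @export
predict.nstep_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(fitted(object))
  nstep_trace(times, object$params)
}

#' @export
summary.nstep_fit <- function(object, ...) {
  print(object)
  cat("  approximate standard errors:\n")
  print(round(object$param_errors, 6))
  if (object$n_mode == "profile") {
    prof <- object$n_profile
    cat(sprintf("  n profiled over %d..%d; SSE minimum at n = %d\n",
                min(prof$n), max(prof$n), object$params$n_steps))
  }
  invisible(object)
}

#' @export
plot.nstep_fit <- function(x, ...) {
  plot(x$data$time_s, x$data$intensity, pch = 16, cex = 0.4,
       col = "grey40", xlab = "time (s)", ylab = "fluorescence (a.u.)",
       main = sprintf("n-step fit: n = %d, rate = %.3g bp/s",
                      x$params$n_steps, x$average_rate), ...)
  tt <- seq(min(x$data$time_s), max(x$data$time_s), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.nstep_fit <- function(object, nsim = 1, seed = 1L, ...) {
  noise <- stats::sd(residuals(object))
  lapply(seq_len(nsim), function(i)
    simulate_trace(object$params, times = object$data$time_s,
                   noise_sd = noise, seed = seed + i - 1L))
}

#' Model-free lag time of a rising trace
#'
#' The presteady-state lag is estimated without assuming the n-step model:
#' the trace is smoothed with a cubic smoothing spline, the point of
#' maximal slope is located, and the lag is the time-axis intercept of the
#' tangent at that point relative to the starting baseline:
#' \code{lag = t* - (y(t*) - y0) / slope(t*)}.
#'
#' @param trace data.frame with \code{time_s} and \code{intensity}.
#' @param grid_points evaluation grid size for the smoothed derivative.
#' @return List of class \code{"lag_estimate"} with \code{lag} (s),
#'   \code{t_max_slope}, \code{max_slope} and \code{status}
#'   (\code{"ok"} or \code{"undefined"} for flat or falling traces).
#' @export
estimate_lag <- function(trace, grid_points = 2000L) {
  stopifnot(all(c("time_s", "intensity") %in% names(trace)))
  t <- trace$time_s; y <- trace$intensity
  rng <- diff(range(y))
  if (rng <= 0 || stats::cor(t, y) < 0.2)
    return(structure(list(lag = NA_real_, status = "undefined"),
                     class = "lag_estimate"))
  ss <- stats::smooth.spline(t, y)
  tt <- seq(min(t), max(t), length.out = grid_points)
  yy <- stats::predict(ss, tt)$y
  dd <- stats::predict(ss, tt, deriv = 1)$y
  i <- which.max(dd)
  if (dd[i] <= 0)
    return(structure(list(lag = NA_real_, status = "undefined"),
                     class = "lag_estimate"))
  y0 <- yy[1L]
  lag <- tt[i] - (yy[i] - y0) / dd[i]
  structure(list(lag = lag, t_max_slope = tt[i], max_slope = dd[i],
                 status = "ok"), class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("lag = %.5g s (max slope %.4g at t = %.4g s)\n",
                x$lag, x$max_slope, x$t_max_slope))
  else cat("lag undefined (flat or non-rising trace)\n")
  invisible(x)
}
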