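#' Fit the hyperbolic rate law to a titration dataset
#'
#' Weighted nonlinear least squares of \code{rate = kcat*c/(Km + c)} against
#' rate-vs-concentration data (Levenberg-Marquardt on log-parameterized
#' kcat and Km, which enforces positivity without penalties). Weights are
#' \code{1/rate_sd^2} when per-point errors are present and positive,
#' otherwise unit. Designs that cannot constrain the plateau -- fewer than 4
#' distinct concentrations, or no concentration at least twice the fitted
#' Km -- are flagged \code{under_determined} (with correspondingly wide
#' standard errors) rather than refused.
#'
#' @param d a \code{titration_dataset} or data.frame with columns
#'   \code{conc_uM}, \code{rate} and optionally \code{rate_sd}.
#' @return Object of class \code{"hyperbola_fit"}: \code{params}
#'   (\code{\link{hyperbolic_params}}), \code{se} (delta-method standard
#'   errors of kcat and Km), \code{sse}, \code{aic},
#'   \code{under_determined} flag, and the data.
#' @examples
#' d <- simulate_titration(hyperbolic_params(150, 80), relative_noise = 0)
#' coef(fit_hyperbola(d))
#' @export
fit_hyperbola <- function(d) {
  stopifnot(all(c("conc_uM", "rate") %in% names(d)))
  cc <- d$conc_uM; r <- d$rate
  if (any(cc < 0)) stop("concentrations must be non-negative")
  w <- rep(1, length(r))
  if (!is.null(d$rate_sd) && all(is.finite(d$rate_sd)) &&
      all(d$rate_sd > 0)) w <- 1 / d$rate_sd^2
  kcat0 <- max(r) * 1.2 + .Machine$double.eps
  Km0 <- cc[which(r >= max(r) / 2)[1L]]
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(cc[cc > 0])
  res_fun <- function(p)
    sqrt(w) * (r - exp(p[1]) * cc / (exp(p[2]) + cc))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(log(kcat0), log(Km0)), fn = res_fun,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, se = c(kcat = NA, Km = NA),
                          sse = NA_real_, aic = NA_real_,
                          under_determined = TRUE, data = d),
                     class = "hyperbola_fit"))
  }
  kcat <- exp(fit$par[1]); Km <- exp(fit$par[2])
  sse <- sum((r - kcat * cc / (Km + cc))^2)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2))
  # delta method back to the natural scale
  se <- c(kcat = kcat * sqrt(vc[1, 1]), Km = Km * sqrt(vc[2, 2]))
  under <- length(unique(cc)) < 4L || max(cc) < 2 * Km
  n <- length(r)
  structure(list(params = hyperbolic_params(kcat, Km), se = se,
                 sse = sse, aic = n * log(sse / n) + 2 * 3,
                 under_determined = under, data = d),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("hyperbolic fit failed (under-determined design)\n")
    return(invisible(x))
  }
  cat(sprintf("hyperbolic fit: kcat = %.5g +/- %.3g, Km = %.5g +/- %.3g uM\n",
              x$params$kcat, x$se["kcat"], x$params$Km, x$se["Km"]))
  cat(sprintf("  SSE = %.5g over %d points%s\n", x$sse, nrow(x$data),
              if (x$under_determined) "  [under-determined]" else ""))
  invisible(x)
}

#' @export
coef.hyperbola_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(kcat = NA_real_, Km = NA_real_))
  c(kcat = object$params$kcat, Km = object$params$Km)
}

#' @export
predict.hyperbola_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$data$conc_uM
  hyperbolic_rate(conc, object$params)
}

#' @export
residuals.hyperbola_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.hyperbola_fit <- function(x, ...) {
  d <- x$data
  plot(d$conc_uM, d$rate, pch = 16, xlab = "[nucleotide] (uM)",
       ylab = "rate", main = sprintf("kcat = %.3g, Km = %.3g uM",
                                     x$params$kcat, x$params$Km), ...)
  if (!is.null(d$rate_sd) && any(d$rate_sd > 0))
    graphics::arrows(d$conc_uM, d$rate - d$rate_sd, d$conc_uM,
                     d$rate + d$rate_sd, angle = 90, code = 3,
                     length = 0.03)
  cc <- seq(0, max(d$conc_uM), length.out = 300)
  graphics::lines(cc, predict(x, cc), col = "firebrick", lwd = 2)
  invisible(x)
}

# Gaussian-likelihood AIC: k free parameters + 1 for the error variance
.aic_sse <- function(sse, n, k_free) n * log(sse / n) + 2 * (k_free + 1)

#' Global fit of the ordered polymerase mechanism across titrations
#'
#' Fits \code{\link{ordered_rate}} simultaneously to several titration
#' datasets (typically one per GC content): one base-capture equilibrium
#' \code{K1} per dataset, a single shared \code{kcat} floated globally, and
#' \code{Kd_nt} held fixed. Equilibrium constants and kcat are optimized on
#' the log scale (Levenberg-Marquardt, cost tolerance 1e-12).
#'
#' @param datasets list of titration datasets (columns \code{conc_uM},
#'   \code{rate}, optional \code{rate_sd}).
#' @param Kd_nt fixed dNTP dissociation constant, uM (default 10).
#' @return Object of class \code{"mechanism_fit"} with \code{model =
#'   "ordered"}, per-dataset \code{K1} estimates with standard errors, the
#'   shared \code{kcat}, the echoed fixed constants, pooled \code{sse} and
#'   \code{aic}.
#' @export
fit_ordered_global <- function(datasets, Kd_nt = 10) {
  stopifnot(is.list(datasets), length(datasets) >= 2L, Kd_nt > 0)
  keep <- vapply(datasets, function(d) max(d$rate) > 1e-9 * Kd_nt,
                 logical(1))
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " dataset(s) with all-zero rates")
    datasets <- datasets[keep]
  }
  stopifnot(length(datasets) >= 2L)
  nd <- length(datasets)
  kcat0 <- max(vapply(datasets, function(d) max(d$rate), numeric(1))) * 1.1
  K10 <- vapply(datasets, function(d) {
    h <- fit_hyperbola(d)
    if (is.null(h$params) || h$params$Km <= Kd_nt) 1
    else Kd_nt / (h$params$Km - Kd_nt)
  }, numeric(1))
  wts <- lapply(datasets, .titration_weights)
  res_fun <- function(p) {
    kcat <- exp(p[1]); K1 <- exp(p[-1])
    unlist(lapply(seq_len(nd), function(i) {
      d <- datasets[[i]]
      mu <- kcat * d$conc_uM / (Kd_nt * (1 + 1 / K1[i]) + d$conc_uM)
      sqrt(wts[[i]]) * (d$rate - mu)
    }))
  }
  fit <- minpack.lm::nls.lm(par = c(log(kcat0), log(K10)), fn = res_fun,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 1000))
  kcat <- exp(fit$par[1]); K1 <- exp(fit$par[-1])
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, nd + 1, nd + 1))
  sse <- sum(res_fun(fit$par)^2)
  npts <- sum(vapply(datasets, nrow, integer(1)))
  labels <- .dataset_labels(datasets)
  structure(list(
    model = "ordered",
    per_dataset = data.frame(dataset = labels, K1 = K1,
                             K1_se = K1 * sqrt(diag(vc)[-1]),
                             apparent_Km = Kd_nt * (1 + 1 / K1)),
    shared = c(kcat = kcat),
    shared_se = c(kcat = kcat * sqrt(vc[1, 1])),
    fixed = list(Kd_nt = Kd_nt),
    sse = sse, n_points = npts,
    aic = .aic_sse(sse, npts, nd + 1L),
    boundary = any(abs(fit$par) > log(1e8)),
    datasets = datasets),
    class = "mechanism_fit")
}

#' Fit the helicase base-capture model variants to titrations
#'
#' Fits each of the mechanism variants A (capture then bind), B (bind then
#' capture) and C (random order) to each dataset by least squares on
#' \code{\link{capture_model_rate}}, with \code{Kd_t} and \code{kcat} held
#' fixed at their independently measured values. Free parameters per
#' dataset: \code{K1} (A), \code{K2} (B), or both (C); optimized on the log
#' scale. All requested variants are returned for ranking with
#' \code{\link{select_model}}.
#'
#' @param datasets list of titration datasets (each with \code{conc_uM},
#'   \code{rate}, optional \code{rate_sd}).
#' @param Kd_t fixed dTTP dissociation constant, uM (default 90).
#' @param kcat fixed single-stranded-DNA translocation rate, nt/s
#'   (default 130).
#' @param variants which variants to fit (default all three).
#' @return Named list of \code{"mechanism_fit"} objects, one per variant.
#' @export
fit_capture_models <- function(datasets, Kd_t = 90, kcat = 130,
                               variants = c("A", "B", "C")) {
  stopifnot(is.list(datasets), length(datasets) >= 1L, Kd_t > 0, kcat > 0)
  variants <- match.arg(variants, several.ok = TRUE)
  labels <- .dataset_labels(datasets)
  out <- lapply(variants, function(v)
    .fit_capture_variant(datasets, labels, v, Kd_t, kcat))
  names(out) <- variants
  out
}

.fit_capture_variant <- function(datasets, labels, variant, Kd_t, kcat) {
  npar <- if (variant == "C") 2L else 1L
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    w <- .titration_weights(d)
    res_fun <- function(p) {
      pp <- exp(p)
      prm <- switch(variant,
        A = capture_params(K1 = pp[1], Kd_t = Kd_t, kcat = kcat,
                           variant = "A"),
        B = capture_params(K2 = pp[1], Kd_t = Kd_t, kcat = kcat,
                           variant = "B"),
        C = capture_params(K1 = pp[1], K2 = pp[2], Kd_t = Kd_t,
                           kcat = kcat, variant = "C"))
      sqrt(w) * (d$rate - capture_model_rate(d$conc_uM, prm))
    }
    start <- rep(log(0.5), npar)
    fit <- minpack.lm::nls.lm(par = start, fn = res_fun,
                              control = minpack.lm::nls.lm.control(
                                ftol = 1e-12, ptol = 1e-12,
                                maxiter = 1000))
    est <- exp(fit$par)
    vc <- tryCatch(stats::vcov(fit), error = function(e)
      matrix(NA_real_, npar, npar))
    se <- est * sqrt(diag(vc))
    data.frame(dataset = labels[i],
               K1 = if (variant %in% c("A", "C")) est[1] else NA_real_,
               K1_se = if (variant %in% c("A", "C")) se[1] else NA_real_,
               K2 = switch(variant, A = NA_real_, B = est[1], C = est[2]),
               K2_se = switch(variant, A = NA_real_, B = se[1], C = se[2]),
               sse = sum(res_fun(fit$par)^2),
               n = nrow(d),
               boundary = any(abs(fit$par) > log(1e8)))
  })
  per <- do.call(rbind, rows)
  sse <- sum(per$sse); npts <- sum(per$n)
  structure(list(
    model = paste0("capture_", variant),
    per_dataset = per[, setdiff(names(per), c("sse", "n"))],
    shared = numeric(0), shared_se = numeric(0),
    fixed = list(Kd_t = Kd_t, kcat = kcat),
    sse = sse, n_points = npts,
    aic = .aic_sse(sse, npts, npar * length(datasets)),
    boundary = any(per$boundary),
    datasets = datasets),
    class = "mechanism_fit")
}

.titration_weights <- function(d) {
  if (!is.null(d$rate_sd) && all(is.finite(d$rate_sd)) &&
      all(d$rate_sd > 0)) 1 / d$rate_sd^2 else rep(1, nrow(d))
}

.dataset_labels <- function(datasets) {
  lab <- names(datasets)
  if (is.null(lab) || any(!nzchar(lab)))
    lab <- vapply(seq_along(datasets), function(i) {
      md <- attr(datasets[[i]], "metadata")
      if (!is.null(md$GC_percent)) paste0("GC", md$GC_percent)
      else paste0("dataset", i)
    }, character(1))
  lab
}

#' @export
print.mechanism_fit <- function(x, ...) {
  cat(sprintf("mechanism fit: %s\n", x$model))
  cat("  fixed constants: ",
      paste(names(x$fixed), unlist(x$fixed), sep = " = ",
            collapse = ", "), "\n", sep = "")
  if (length(x$shared))
    cat(sprintf("  shared kcat = %.5g +/- %.3g\n",
                x$shared["kcat"], x$shared_se["kcat"]))
  print(x$per_dataset, row.names = FALSE, digits = 4)
  cat(sprintf("  pooled SSE = %.5g, AIC = %.4g (%d points)%s\n",
              x$sse, x$aic, x$n_points,
              if (isTRUE(x$boundary)) "  [boundary-pinned parameter]"
              else ""))
  invisible(x)
}

#' @export
coef.mechanism_fit <- function(object, ...) {
  c(object$shared,
    stats::setNames(object$per_dataset$K1,
                    paste0("K1.", object$per_dataset$dataset))[
                      !is.na(object$per_dataset$K1)],
    stats::setNames(object$per_dataset$K2,
                    paste0("K2.", object$per_dataset$dataset))[
                      !is.na(object$per_dataset$K2)])
}

#' Rank mechanism fits by AIC
#'
#' Compares mechanism fits performed on identical data, ranks them by
#' Gaussian-likelihood AIC, and declares a winner only when the runner-up
#' trails by at least \code{delta_aic} (default 2, the standard evidence
#' cutoff); otherwise the verdict is \code{"indistinguishable"}.
#'
#' @param results list of \code{"mechanism_fit"} objects on the same data.
#' @param delta_aic evidence threshold on the AIC gap (default 2).
#' @return Object of class \code{"model_ranking"}: a ranking table
#'   (model, aic, delta_aic), the \code{winner} (model id or
#'   \code{"indistinguishable"}), and the threshold used.
#' @export
select_model <- function(results, delta_aic = 2) {
  stopifnot(is.list(results), length(results) >= 2L,
            all(vapply(results, inherits, logical(1), "mechanism_fit")))
  pooled <- lapply(results, function(r)
    do.call(rbind, lapply(r$datasets, function(d)
      d[, c("conc_uM", "rate")])))
  for (i in seq_along(pooled)[-1])
    if (!isTRUE(all.equal(pooled[[1]], pooled[[i]],
                          check.attributes = FALSE)))
      stop("mechanism fits were not performed on identical datasets")
  aic <- vapply(results, `[[`, numeric(1), "aic")
  ord <- order(aic)
  tab <- data.frame(model = vapply(results, `[[`, character(1), "model"),
                    aic = aic)[ord, ]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  winner <- if (nrow(tab) >= 2 && tab$delta_aic[2L] >= delta_aic)
    tab$model[1L] else "indistinguishable"
  structure(list(ranking = tab, winner = winner,
                 delta_aic_threshold = delta_aic),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  print(x$ranking, row.names = FALSE, digits = 5)
  cat("winner:", x$winner,
      sprintf("(threshold delta AIC >= %g)\n", x$delta_aic_threshold))
  invisible(x)
}
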