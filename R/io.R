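#' Package run configuration
#'
#' Central record of the fixed constants, fitting options and call
#' thresholds used across the analyses, so that every report can echo
#' exactly what was assumed. Defaults: \code{Kd_nt} = 10 uM (dNTP
#' dissociation constant of the polymerase on primer-template DNA),
#' \code{Kd_t} = 90 uM (helicase dTTP constant from single-stranded-DNA
#' translocation), \code{helicase_kcat} = 130 nt/s (single-stranded-DNA
#' translocation rate), response-call thresholds \code{delta} = 0.2 and
#' \code{z} = 2, model-evidence cutoff \code{delta_aic} = 2, step-count
#' profile 2..80. The convention that mechanism variant A is
#' capture-then-bind (and B bind-then-capture) is part of the config.
#'
#' @param ... named overrides of any default.
#' @return Named list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  cfg <- list(
    Kd_nt = 10, Kd_t = 90, helicase_kcat = 130,
    n_range = c(2L, 80L), fit_tol = 1e-12,
    delta = 0.2, z = 2, delta_aic = 2,
    variant_convention = "A = capture then bind; B = bind then capture",
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$Kd_nt > 0, cfg$Kd_t > 0, cfg$helicase_kcat > 0,
            cfg$delta >= 0, cfg$z >= 0, cfg$delta_aic >= 0)
  structure(cfg, class = "run_config")
}

#' Read and write the run configuration
#'
#' JSON serialization that round-trips losslessly.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param path file path.
#' @return \code{read_config} returns the \code{run_config}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$n_range <- as.integer(x$n_range)
  x$seed <- as.integer(x$seed)
  do.call(run_config, x)
}

# JSON sidecar path for a CSV
.sidecar <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

.write_with_sidecar <- function(df, path, metadata) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, .sidecar(path), auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE)
  invisible(path)
}

.read_with_sidecar <- function(path, required, what) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("malformed CSV '", path, "': ", conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  char_cols <- c("strand", "context", "condition", "construct_id")
  for (col in setdiff(required, char_cols)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(what, " file '", path, "', column '", col, "', line ",
           bad[1L] + 1L, ": non-numeric or missing value")
    df[[col]] <- vals
  }
  md <- if (file.exists(.sidecar(path)))
    jsonlite::read_json(.sidecar(path), simplifyVector = TRUE) else NULL
  attr(df, "metadata") <- md
  df
}

#' Read and write stopped-flow trace datasets
#'
#' CSV with columns \code{time_s}, \code{intensity}; dataset metadata goes
#' to a \code{.meta.json} sidecar next to the CSV.
#'
#' @param trace a \code{trace_dataset} (or compatible data.frame).
#' @param path CSV file path.
#' @return \code{read_trace} returns a \code{trace_dataset}.
#' @export
write_trace <- function(trace, path) {
  .write_with_sidecar(trace[, c("time_s", "intensity")], path,
                      attr(trace, "metadata"))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- .read_with_sidecar(path, c("time_s", "intensity"), "trace")
  if (is.unsorted(df$time_s)) stop("trace times must be sorted: ", path)
  class(df) <- c("trace_dataset", "data.frame")
  df
}

#' Read and write rate-vs-concentration titration datasets
#'
#' CSV with columns \code{conc_uM}, \code{rate} and optional
#' \code{rate_sd}; metadata in a JSON sidecar.
#'
#' @param d a \code{titration_dataset}.
#' @param path CSV file path.
#' @return \code{read_titration} returns a \code{titration_dataset}.
#' @export
write_titration <- function(d, path) {
  keep <- intersect(c("conc_uM", "rate", "rate_sd"), names(d))
  .write_with_sidecar(d[, keep], path, attr(d, "metadata"))
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  df <- .read_with_sidecar(path, c("conc_uM", "rate"), "titration")
  if (any(df$conc_uM < 0)) stop("negative concentration in ", path)
  class(df) <- c("titration_dataset", "data.frame")
  df
}

#' Read and write 2-AP intensity panels
#'
#' CSV with columns \code{construct_id}, \code{probe_position},
#' \code{strand}, \code{context}, \code{gap_nt}, \code{condition},
#' \code{intensity}, \code{intensity_sd}.
#'
#' @param panel an \code{ap_panel}.
#' @param path CSV file path.
#' @return \code{read_ap_panel} returns an \code{ap_panel}.
#' @export
write_ap_panel <- function(panel, path) {
  .write_with_sidecar(panel, path, attr(panel, "metadata"))
}

#' @rdname write_ap_panel
#' @export
read_ap_panel <- function(path) {
  cols <- c("construct_id", "probe_position", "strand", "context",
            "gap_nt", "condition", "intensity", "intensity_sd")
  df <- .read_with_sidecar(path, cols, "2-AP panel")
  allowed <- c("DNA", "+DNAP", "+helicase", "+both", "+SSB", "+DNAP+SSB",
               "+helicase+SSB")
  bad <- setdiff(unique(df$condition), allowed)
  if (length(bad))
    stop("unknown condition label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  class(df) <- c("ap_panel", "data.frame")
  df
}

#' Write a fit report as JSON
#'
#' Serializes any of the package's fit or inference results (n-step fits,
#' hyperbolic fits, mechanism fits, model rankings, footprints, synergy-gap
#' results) to JSON with full double precision (17 significant digits), so
#' regression comparisons are exact. Fixed constants used by a fit are
#' embedded verbatim.
#'
#' @param x a result object.
#' @param path output JSON path.
#' @param config optional \code{\link{run_config}} echoed into the report.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path, config = NULL) {
  payload <- .report_payload(x)
  if (!is.null(config)) payload$config <- unclass(config)
  payload$package_version <- as.character(utils::packageVersion("unwindr"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}

.report_payload <- function(x) {
  if (inherits(x, "nstep_fit"))
    list(kind = "nstep_fit", status = x$status,
         params = if (!is.null(x$params)) unclass(x$params),
         average_unwinding_rate = x$average_rate, sse = x$sse,
         param_errors = as.list(x$param_errors),
         n_profile = x$n_profile)
  else if (inherits(x, "hyperbola_fit"))
    list(kind = "hyperbola_fit",
         params = if (!is.null(x$params)) unclass(x$params),
         se = as.list(x$se), sse = x$sse, aic = x$aic,
         under_determined = x$under_determined)
  else if (inherits(x, "mechanism_fit"))
    list(kind = "mechanism_fit", model = x$model,
         per_dataset = x$per_dataset, shared = as.list(x$shared),
         shared_se = as.list(x$shared_se), fixed = x$fixed,
         sse = x$sse, aic = x$aic, boundary = x$boundary)
  else if (inherits(x, "model_ranking"))
    list(kind = "model_ranking", ranking = x$ranking, winner = x$winner,
         delta_aic_threshold = x$delta_aic_threshold)
  else if (inherits(x, "footprint_result"))
    list(kind = "footprint", condition = x$condition, status = x$status,
         melted_bp = x$melted_bp,
         contacted_template_bases = x$contacted_template_bases,
         thresholds = as.list(x$thresholds), calls = x$calls)
  else if (inherits(x, "synergy_gap"))
    list(kind = "synergy_gap", max_gap = x$max_gap, status = x$status,
         per_gap = x$per_gap)
  else stop("no report writer for class ", class(x)[1L])
}
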