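#' Read a loading time-course table
#'
#' CSV with columns `condition`, `fraction_loaded`, a time column (`time_s`
#' in seconds or `time_min` in minutes, converted) and optionally
#' `replicate` and `source`. Rows failing validation are reported by row
#' number.
#'
#' @param path CSV file path.
#' @return Loading dataset (data frame with columns `condition`, `time_s`,
#'   `fraction_loaded`, `replicate`, `source`).
#' @export
read_timecourse_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"condition" %in% names(tab))
    stop("missing required column 'condition'", call. = FALSE)
  if (!"fraction_loaded" %in% names(tab))
    stop("missing required column 'fraction_loaded'", call. = FALSE)
  if ("time_s" %in% names(tab)) {
    time_s <- tab$time_s
  } else if ("time_min" %in% names(tab)) {
    time_s <- tab$time_min * 60
  } else {
    stop("missing time column: need 'time_s' or 'time_min'", call. = FALSE)
  }
  if (!is.numeric(time_s) || anyNA(time_s))
    stop("non-numeric time in row(s): ",
         paste(which(is.na(suppressWarnings(as.numeric(time_s)))),
               collapse = ", "), call. = FALSE)
  bad_t <- which(time_s < 0)
  if (length(bad_t) > 0)
    stop("negative time in row(s): ", paste(bad_t, collapse = ", "),
         call. = FALSE)
  frac <- tab$fraction_loaded
  if (!is.numeric(frac) || anyNA(frac))
    stop("non-numeric fraction_loaded", call. = FALSE)
  bad_f <- which(frac < 0 | frac > 1)
  if (length(bad_f) > 0)
    stop("fraction_loaded outside [0, 1] in row(s): ",
         paste(bad_f, collapse = ", "), call. = FALSE)
  data.frame(
    condition = as.character(tab$condition),
    time_s = time_s,
    fraction_loaded = frac,
    replicate = if ("replicate" %in% names(tab)) tab$replicate else 1L,
    source = if ("source" %in% names(tab)) as.character(tab$source)
             else "manual")
}

#' Write / read a global-fit report
#'
#' Writes three files under `dir`: `parameters.json` (rates, standard
#' errors, RSS, convergence flag, seed), `fitted_curves.csv` (one row per
#' condition x time) and `summary.txt` (human-readable). The JSON is
#' written at full precision and round-trips through [read_fit_report()].
#'
#' @param fit A `global_fit` from [fit_global_two_state()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, dir) {
  stopifnot(inherits(fit, "global_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params_path <- file.path(dir, "parameters.json")
  curves_path <- file.path(dir, "fitted_curves.csv")
  summary_path <- file.path(dir, "summary.txt")
  jsonlite::write_json(
    list(model = "two_state_loading",
         shared_k3 = fit$k3, k3_se = fit$k3_se,
         total = fit$total, rss = fit$rss, n_obs = fit$n_obs,
         converged = fit$converged, seed = fit$seed,
         bounds = fit$bounds, conditions = fit$conditions),
    params_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(fit$fitted, curves_path, row.names = FALSE)
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(fit)), con)
  invisible(c(parameters = params_path, curves = curves_path,
              summary = summary_path))
}

#' @rdname write_fit_report
#' @param dir Directory previously written by [write_fit_report()].
#' @return `read_fit_report`: list with `parameters` and `fitted` (curves
#'   data frame).
#' @export
read_fit_report <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "parameters.json"),
                                simplifyVector = TRUE)
  fitted <- utils::read.csv(file.path(dir, "fitted_curves.csv"))
  list(parameters = params, fitted = fitted)
}

#' Read a run configuration
#'
#' YAML file with optional blocks `seeds`, `optimizer` (starts, bounds,
#' tolerances), `mixture` (K_max, restarts, bound policy, threshold),
#' `dataset` (manual window) and `output_dir`; missing entries fall back to
#' package defaults.
#'
#' @param path YAML file path.
#' @return Named list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    seeds = list(global = 1L),
    optimizer = list(n_starts = 8L, bounds = c(1e-6, 1e4)),
    mixture = list(K_max = 6L, restarts = 20L,
                   bound_policy = "threshold", bound_threshold = 15),
    dataset = list(manual_window = c(30, 600)),
    output_dir = ".")
  out <- utils::modifyList(defaults, cfg)
  if (!is.numeric(unlist(out$seeds)) ||
      any(unlist(out$seeds) != round(unlist(out$seeds))))
    stop("seeds must be integers", call. = FALSE)
  out
}
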