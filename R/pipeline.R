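#' Configuration for a model run
#'
#' Bundles everything a run needs: exactly one input source (a preset
#' name or a scenario CSV), the sweep kind, optional axis / spectrum /
#' parameter overrides, the output directory and an optional seed
#' (only used by downstream consumers that sample scenarios).
#'
#' @param preset A preset name (see [preset_scenario()]); mutually
#'   exclusive with `scenario_file`.
#' @param scenario_file Path to a scenario CSV (see [read_scenarios()]);
#'   rows are evaluated individually (`sweep = "single"` only).
#' @param sweep One of `"spectral"`, `"doc"`, `"regimes"`, `"single"`.
#'   `"regimes"` runs the spectral sweep at the three nitrate/nitrite
#'   regimes (fig4, fig5, fig6), one CSV each.
#' @param A0_values,S_values,doc_values Optional axis overrides.
#' @param spectrum_path Optional solar-spectrum table override.
#' @param params A [photo_params()] registry.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer seed recorded in the run log.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(preset = NULL, scenario_file = NULL,
                       sweep = c("spectral", "doc", "regimes", "single"),
                       A0_values = default_A0_axis(),
                       S_values = default_S_axis(),
                       doc_values = default_doc_axis(),
                       spectrum_path = NULL, params = photo_params(),
                       out_dir = ".", seed = NULL) {
  sweep <- match.arg(sweep)
  if (is.null(preset) == is.null(scenario_file)) {
    stop("give exactly one input source: 'preset' or 'scenario_file'")
  }
  if (!is.null(preset)) preset_scenario(preset)  # validate the name now
  if (!is.null(scenario_file) && !file.exists(scenario_file)) {
    stop("scenario file not found: ", scenario_file)
  }
  if (!is.null(scenario_file) && sweep != "single") {
    stop("a scenario file runs with sweep = \"single\" only")
  }
  structure(list(preset = preset, scenario_file = scenario_file,
                 sweep = sweep, A0_values = A0_values,
                 S_values = S_values, doc_values = doc_values,
                 spectrum_path = spectrum_path, params = params,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

single_sweep <- function(scenarios, solar, params, preset) {
  rows <- lapply(scenarios, function(scn) {
    result_row(scn, evaluate_scenario(scn, solar, params))
  })
  as_sweep_table(do.call(rbind, rows), "single", list(), preset, params)
}

#' Execute a configured run and write its outputs
#'
#' Builds the solar field, runs the configured sweep(s), and writes one
#' annotated CSV per sweep plus a `run_log.txt` (registry hash, spectrum
#' source, timings). Re-running the same configuration rewrites
#' bit-identical CSVs (the log differs only in its timestamp/timing
#' lines).
#'
#' @param config A [run_config()].
#' @return Named character vector of the written CSV paths, invisibly.
#' @examples
#' \donttest{
#' out <- run_pipeline(run_config(preset = "fig2", sweep = "spectral",
#'                                out_dir = tempdir()))
#' read_sweep(out[["spectral"]])[1:3, 1:5]
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spath <- if (is.null(config$spectrum_path)) default_spectrum_path()
           else config$spectrum_path

  scenarios <- if (!is.null(config$scenario_file)) {
    read_scenarios(config$scenario_file)
  } else {
    list(preset_scenario(config$preset))
  }
  depth <- scenarios[[1L]]$depth
  solar <- solar_field(depth, path = config$spectrum_path)

  label <- if (!is.null(config$preset)) config$preset else "file"
  outputs <- character(0)
  emit <- function(sweep, name) {
    p <- file.path(config$out_dir, sprintf("sweep_%s_%s.csv", name, label))
    write_sweep(sweep, p, spectrum_source = spath)
    outputs[[name]] <<- p
  }

  if (config$sweep == "spectral") {
    emit(spectral_grid_sweep(scenarios[[1L]], config$A0_values,
                             config$S_values, solar, config$params,
                             preset = label), "spectral")
  } else if (config$sweep == "doc") {
    emit(doc_sweep(scenarios[[1L]], config$doc_values, solar,
                   config$params, preset = label), "doc")
  } else if (config$sweep == "regimes") {
    for (nm in c("fig4", "fig5", "fig6")) {
      scn <- preset_scenario(nm)
      scn$cdom <- scenarios[[1L]]$cdom
      scn$depth <- depth
      emit(spectral_grid_sweep(scn, config$A0_values, config$S_values,
                               solar, config$params, preset = nm), nm)
    }
  } else {
    emit(single_sweep(scenarios, solar, config$params, label), "single")
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("timestamp: %s", format(t0, "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("input: %s", label),
    sprintf("sweep: %s", config$sweep),
    sprintf("params_hash: %s", params_hash(config$params)),
    sprintf("spectrum_source: %s", spath),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("outputs: %s", paste(outputs, collapse = ", ")),
    sprintf("elapsed_s: %.2f",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    log_path)
  invisible(outputs)
}

#' Quick base-graphics view of a sweep table
#'
#' Spectral sweeps are drawn as steady-state concentration versus
#' spectral slope, one line per A0; DOC sweeps as a log-log curve versus
#' DOC.
#'
#' @param sweep A `"sweep_table"` (or a data frame read back with
#'   [read_sweep()]).
#' @param response Column to plot (default `"ss_3CDOM"`).
#' @param ... Passed on to [graphics::matplot()] / [graphics::plot()].
#' @return The sweep, invisibly.
#' @export
plot_sweep <- function(sweep, response = "ss_3CDOM", ...) {
  df <- as.data.frame(sweep)
  if (!response %in% names(df)) stop("no column '", response, "'")
  if (length(unique(df$S)) > 1L && length(unique(df$A0)) >= 1L) {
    s_vals <- sort(unique(df$S))
    a_vals <- sort(unique(df$A0))
    m <- matrix(NA_real_, length(s_vals), length(a_vals))
    for (j in seq_along(a_vals)) {
      sub <- df[df$A0 == a_vals[j], ]
      m[match(sub$S, s_vals), j] <- sub[[response]]
    }
    graphics::matplot(s_vals, m, type = "b", pch = 16, lty = 1,
                      xlab = "spectral slope S (nm-1)", ylab = response,
                      ...)
    graphics::legend("topright", legend = sprintf("A0 = %.2f", a_vals),
                     col = seq_along(a_vals), pch = 16, cex = 0.7)
  } else {
    graphics::plot(df$DOC, df[[response]], log = "xy", type = "b",
                   pch = 16, xlab = "DOC (mgC/L)", ylab = response, ...)
  }
  invisible(sweep)
}
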