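.preset_names <- c("fig2", "fig4", "fig5", "fig6", "central")

#' Named water-chemistry presets
#'
#' The fixed scenarios of the model study. All share 3 m depth,
#' DOC = 5 mgC/L, 1e-3 M HCO3-, 1e-5 M CO3^2- and the central CDOM
#' spectrum (A0 = 0.45 L mgC-1 cm-1, S = 0.015 nm-1); they differ in the
#' nitrate/nitrite regime:
#' * `fig2`, `fig4`, `central`: 1e-4 M NO3-, 1e-6 M NO2- (intermediate;
#'   base conditions of the triplet-CDOM surface and the regime with a
#'   minimum in the hydroxyl-radical vs spectral-slope curve),
#' * `fig5`: 1e-6 M NO3-, 1e-8 M NO2- (nitrogen species minor; CDOM
#'   dominates hydroxyl-radical production),
#' * `fig6`: 1e-3 M NO3-, 1e-5 M NO2- (nitrogen species dominant).
#'
#' @param name One of `"fig2"`, `"fig4"`, `"fig5"`, `"fig6"`, `"central"`.
#' @return A [water_scenario()].
#' @examples
#' preset_scenario("fig5")
#' @export
preset_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% .preset_names)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(.preset_names, collapse = ", "))
  }
  n_levels <- switch(name,
    fig2 = , fig4 = , central = c(no3 = 1e-4, no2 = 1e-6),
    fig5 = c(no3 = 1e-6, no2 = 1e-8),
    fig6 = c(no3 = 1e-3, no2 = 1e-5))
  water_scenario(depth = 3, doc = 5,
                 no3 = n_levels[["no3"]], no2 = n_levels[["no2"]],
                 hco3 = 1e-3, co3 = 1e-5,
                 cdom = cdom_spectrum(0.45, 0.015))
}

#' Environmentally plausible sampling ranges for random scenarios
#'
#' Default bounds reproduce the studied spans for the spectral parameters
#' and DOC (A0 in \[0.30, 0.60\] L mgC-1 cm-1, S in \[0.012, 0.018\] nm-1,
#' DOC in \[0.5, 50\] mgC/L); nitrate and nitrite span the three studied
#' regimes, carbonate species bracket the typical freshwater levels, and
#' depth covers well-lit epilimnia. Concentration-like fields (DOC and
#' all molar concentrations) are sampled log-uniformly since they span
#' orders of magnitude; A0, S and depth are sampled uniformly.
#'
#' @param A0,S,doc,no3,no2,hco3,co3,depth Length-2 numeric `c(lo, hi)`
#'   bounds for each field.
#' @return An object of class `"scenario_ranges"`.
#' @export
scenario_ranges <- function(A0 = c(0.30, 0.60), S = c(0.012, 0.018),
                            doc = c(0.5, 50), no3 = c(1e-6, 1e-3),
                            no2 = c(1e-8, 1e-5), hco3 = c(1e-4, 5e-3),
                            co3 = c(1e-7, 1e-4), depth = c(0.5, 10)) {
  scale <- c(A0 = "linear", S = "linear", doc = "log", no3 = "log",
             no2 = "log", hco3 = "log", co3 = "log", depth = "linear")
  bounds <- list(A0 = A0, S = S, doc = doc, no3 = no3, no2 = no2,
                 hco3 = hco3, co3 = co3, depth = depth)
  for (k in names(bounds)) {
    b <- bounds[[k]]
    if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) ||
        b[1L] >= b[2L]) {
      stop(sprintf("'%s' bounds must be numeric c(lo, hi) with lo < hi", k))
    }
    if (scale[[k]] == "log" && b[1L] <= 0) {
      stop(sprintf("'%s' is log-sampled; its lower bound must be > 0", k))
    }
  }
  structure(list(bounds = bounds, scale = scale),
            class = "scenario_ranges")
}

# run code with the global RNG state saved/restored, seeded explicitly
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Sample random water scenarios
#'
#' Draws `n` independent scenarios with every field sampled on its stated
#' scale within the bounds of `ranges`. The seed is a mandatory argument
#' and the same `(n, seed, ranges)` always yields the identical sequence;
#' the global RNG state is left untouched.
#'
#' @param n Number of scenarios (>= 0).
#' @param seed Integer seed (required; no hidden global randomness).
#' @param ranges A [scenario_ranges()].
#' @return A list of [water_scenario()] objects (length `n`).
#' @examples
#' sample_scenarios(3, seed = 42)
#' @export
sample_scenarios <- function(n, seed, ranges = scenario_ranges()) {
  stopifnot(inherits(ranges, "scenario_ranges"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a single non-negative integer")
  }
  if (missing(seed)) stop("'seed' must be given explicitly")
  n <- as.integer(n)
  if (n == 0L) return(list())
  draw <- function(field) {
    b <- ranges$bounds[[field]]
    if (ranges$scale[[field]] == "log") {
      exp(stats::runif(n, log(b[1L]), log(b[2L])))
    } else {
      stats::runif(n, b[1L], b[2L])
    }
  }
  with_seed(seed, {
    vals <- lapply(stats::setNames(nm = names(ranges$bounds)), draw)
    lapply(seq_len(n), function(i) {
      water_scenario(depth = vals$depth[i], doc = vals$doc[i],
                     no3 = vals$no3[i], no2 = vals$no2[i],
                     hco3 = vals$hco3[i], co3 = vals$co3[i],
                     cdom = cdom_spectrum(vals$A0[i], vals$S[i]))
    })
  })
}

scenario_to_row <- function(scn) {
  data.frame(depth = scn$depth, doc = scn$doc, no3 = scn$no3,
             no2 = scn$no2, hco3 = scn$hco3, co3 = scn$co3,
             A0 = scn$cdom$A0, S = scn$cdom$S)
}

row_to_scenario <- function(row) {
  water_scenario(depth = row$depth, doc = row$doc, no3 = row$no3,
                 no2 = row$no2, hco3 = row$hco3, co3 = row$co3,
                 cdom = cdom_spectrum(row$A0, row$S))
}

#' Write / read a scenario batch as CSV
#'
#' One scenario per row, columns `depth, doc, no3, no2, hco3, co3, A0, S`.
#' Values are written at full double precision so a read-back reproduces
#' the scenarios exactly.
#'
#' @param scenarios A list of [water_scenario()] objects.
#' @param path File path.
#' @return `write_scenarios()`: `path`, invisibly. `read_scenarios()`:
#'   a list of [water_scenario()] objects.
#' @export
write_scenarios <- function(scenarios, path) {
  stopifnot(all(vapply(scenarios, inherits, TRUE, "water_scenario")))
  df <- do.call(rbind, lapply(scenarios, scenario_to_row))
  cols <- vapply(df, function(x) sprintf("%.17g", x), character(nrow(df)))
  cols <- matrix(cols, nrow = nrow(df))
  lines <- c(paste(names(df), collapse = ","),
             apply(cols, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("depth", "doc", "no3", "no2", "hco3", "co3", "A0", "S")
  if (!all(need %in% names(df))) {
    stop("scenario file must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) row_to_scenario(df[i, ]))
}
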