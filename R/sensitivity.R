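default_A0_axis <- function() seq(0.30, 0.60, by = 0.05)
default_S_axis  <- function() seq(0.012, 0.018, by = 0.001)

#' Default dissolved-organic-carbon sweep axis
#'
#' 24 log-spaced values over 0.5--50 mgC/L, the span covering the vast
#' majority of surface-water environments.
#'
#' @param n Number of points (default 24).
#' @param range Length-2 bounds in mgC/L.
#' @return Ascending numeric vector.
#' @export
default_doc_axis <- function(n = 24, range = c(0.5, 50)) {
  10^seq(log10(range[1L]), log10(range[2L]), length.out = n)
}

result_row <- function(scn, res) {
  fr <- res$oh_source_fractions
  data.frame(A0 = scn$cdom$A0, S = scn$cdom$S, DOC = scn$doc,
             R_3CDOM = res$rates[["R_3CDOM"]],
             ss_3CDOM = res$conc[["ss_3CDOM"]],
             ss_1O2 = res$conc[["ss_1O2"]],
             ss_OH = res$conc[["ss_OH"]],
             ss_CO3 = res$conc[["ss_CO3"]],
             frac_OH_CDOM = fr[["cdom"]],
             frac_OH_NO3 = fr[["no3"]],
             frac_OH_NO2 = fr[["no2"]])
}

as_sweep_table <- function(df, kind, axes, preset, params) {
  structure(df, class = c("sweep_table", "data.frame"),
            sweep_kind = kind, axes = axes, preset = preset,
            params_hash = params_hash(params))
}

check_axis <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) ||
      is.unsorted(x, strictly = TRUE)) {
    stop(sprintf("'%s' must be a non-empty strictly ascending numeric axis",
                 name))
  }
  as.numeric(x)
}

#' Sweep the CDOM spectral parameters over an (A0, S) grid
#'
#' Evaluates the steady-state model at every combination of `A0_values`
#' and `S_values` on an otherwise fixed scenario. Row order is
#' deterministic: A0 outer, S inner. The default axes form the 7 x 7
#' matrix A0 = 0.30..0.60 (step 0.05) by S = 0.012..0.018 (step 0.001)
#' around the central freshwater point (0.45, 0.015).
#'
#' @param base A [water_scenario()] supplying everything except (A0, S).
#' @param A0_values,S_values Strictly ascending axes.
#' @param solar A `"volumetric_photon_flux"`.
#' @param params A [photo_params()] registry.
#' @param preset Optional preset name recorded in the table metadata.
#' @return A `"sweep_table"` data frame with one row per grid cell and
#'   columns `A0, S, DOC, R_3CDOM, ss_3CDOM, ss_1O2, ss_OH, ss_CO3,
#'   frac_OH_CDOM, frac_OH_NO3, frac_OH_NO2`.
#' @examples
#' scn <- preset_scenario("fig2")
#' sol <- solar_field(scn$depth)
#' sw <- spectral_grid_sweep(scn, solar = sol)
#' range(sw$ss_3CDOM)
#' @export
spectral_grid_sweep <- function(base, A0_values = default_A0_axis(),
                                S_values = default_S_axis(), solar,
                                params = photo_params(), preset = NA) {
  stopifnot(inherits(base, "water_scenario"))
  A0_values <- check_axis(A0_values, "A0_values")
  S_values <- check_axis(S_values, "S_values")
  rows <- vector("list", length(A0_values) * length(S_values))
  i <- 0L
  for (a0 in A0_values) {
    for (s in S_values) {
      scn <- base
      scn$cdom <- cdom_spectrum(a0, s)
      i <- i + 1L
      rows[[i]] <- result_row(scn, evaluate_scenario(scn, solar, params))
    }
  }
  as_sweep_table(do.call(rbind, rows), "spectral",
                 list(A0 = A0_values, S = S_values), preset, params)
}

#' Sweep dissolved organic carbon at fixed CDOM spectral parameters
#'
#' @param base A [water_scenario()]; its CDOM spectrum and chemistry are
#'   held fixed while DOC takes each value of `doc_values`.
#' @param doc_values Strictly ascending positive DOC axis (mgC/L);
#'   default [default_doc_axis()].
#' @inheritParams spectral_grid_sweep
#' @return A `"sweep_table"` with one row per DOC value; `ss_3CDOM` is
#'   non-decreasing down the table.
#' @export
doc_sweep <- function(base, doc_values = default_doc_axis(), solar,
                      params = photo_params(), preset = NA) {
  stopifnot(inherits(base, "water_scenario"))
  doc_values <- check_axis(doc_values, "doc_values")
  if (any(doc_values <= 0)) stop("'doc_values' must be positive")
  rows <- lapply(doc_values, function(doc) {
    scn <- base
    scn$doc <- doc
    result_row(scn, evaluate_scenario(scn, solar, params))
  })
  as_sweep_table(do.call(rbind, rows), "doc",
                 list(DOC = doc_values), preset, params)
}

#' Find the DOC giving a target steady-state triplet concentration
#'
#' Inverts the (monotone) map DOC -> [3CDOM*]ss at the base scenario's
#' fixed spectral parameters, by bisection on log10(DOC) over `bracket`
#' to a relative tolerance of `tol` on DOC. Used to express a change in
#' CDOM spectral quality as the equivalent change in CDOM quantity.
#'
#' @param target_ss Target steady-state triplet concentration, mol L-1.
#' @param base A [water_scenario()] fixing everything but DOC.
#' @param solar A `"volumetric_photon_flux"`.
#' @param params A [photo_params()] registry.
#' @param bracket Length-2 DOC bracket in mgC/L (default `c(1e-2, 1e3)`).
#' @param tol Relative tolerance on the returned DOC (default 1e-3).
#' @return The matching DOC, mgC/L.
#' @export
match_equivalent_doc <- function(target_ss, base, solar,
                                 params = photo_params(),
                                 bracket = c(1e-2, 1e3), tol = 1e-3) {
  stopifnot(inherits(base, "water_scenario"))
  if (!is.numeric(target_ss) || length(target_ss) != 1L || target_ss <= 0) {
    stop("'target_ss' must be a single positive concentration")
  }
  ss_at <- function(doc) {
    scn <- base
    scn$doc <- doc
    evaluate_scenario(scn, solar, params)$conc[["ss_3CDOM"]]
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  ss_lo <- ss_at(lo); ss_hi <- ss_at(hi)
  if (target_ss < ss_lo || target_ss > ss_hi) {
    stop(sprintf(paste0("target %.4e M outside the attainable range ",
                        "[%.4e, %.4e] M for DOC in [%g, %g] mgC/L"),
                 target_ss, ss_lo, ss_hi, lo, hi))
  }
  llo <- log10(lo); lhi <- log10(hi)
  while (lhi - llo > tol / log(10)) {
    mid <- (llo + lhi) / 2
    if (ss_at(10^mid) < target_ss) llo <- mid else lhi <- mid
  }
  10^((llo + lhi) / 2)
}

#' Locate the extremum of a value-versus-spectral-slope series
#'
#' Returns the grid S at which `values` is smallest, with no sub-grid
#' interpolation (the grid resolution is the model's resolution), and a
#' classification of where it sits. Ties break toward the smaller S.
#'
#' @param S Strictly ascending spectral-slope axis (>= 3 points).
#' @param values Numeric values at each S.
#' @return List with `S_at_min`, `value`, and `kind` (one of
#'   `"interior"`, `"left_edge"`, `"right_edge"`).
#' @export
locate_extremum <- function(S, values) {
  S <- as.numeric(S); values <- as.numeric(values)
  if (length(S) < 3L) stop("at least 3 points are needed")
  if (length(values) != length(S)) stop("'S' and 'values' lengths differ")
  if (is.unsorted(S, strictly = TRUE)) stop("'S' must be strictly ascending")
  i <- which.min(values)  # first minimum -> smaller S on ties
  kind <- if (i == 1L) "left_edge" else
    if (i == length(S)) "right_edge" else "interior"
  list(S_at_min = S[i], value = values[i], kind = kind)
}

#' Write / read a sweep table as annotated CSV
#'
#' Numeric cells are written in scientific notation with 6 significant
#' digits; a `#` header block records the sweep kind, preset, parameter
#' registry hash and spectrum source.
#'
#' @param sweep A `"sweep_table"`.
#' @param path File path.
#' @param spectrum_source Optional string recorded in the header.
#' @return `write_sweep()`: `path`, invisibly. `read_sweep()`: a data
#'   frame (metadata lines are skipped).
#' @export
write_sweep <- function(sweep, path, spectrum_source = NA) {
  stopifnot(inherits(sweep, "sweep_table"))
  hdr <- c(
    sprintf("# sweep_kind: %s", attr(sweep, "sweep_kind")),
    sprintf("# preset: %s", attr(sweep, "preset")),
    sprintf("# params_hash: %s", attr(sweep, "params_hash")),
    sprintf("# spectrum_source: %s", spectrum_source),
    "# units: concentrations mol L-1, rates mol L-1 s-1, DOC mgC L-1,",
    "#        A0 L mgC-1 cm-1, S nm-1; fractions unitless")
  df <- as.data.frame(sweep)
  cells <- vapply(df, function(x) sprintf("%.6e", x), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  writeLines(c(hdr, paste(names(df), collapse = ","),
               apply(cells, 1L, paste, collapse = ",")), path)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
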