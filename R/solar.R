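# Physical constants (SI, 2019 redefinition)
.h_planck   <- 6.62607015e-34  # J s
.c_light    <- 2.99792458e8    # m s-1
.n_avogadro <- 6.02214076e23   # mol-1

#' Wavelength grid for spectral calculations
#'
#' A strictly ascending, uniformly spaced wavelength grid in nanometres.
#' The default covers 290--800 nm at 1 nm: sunlight at the surface starts
#' near 290 nm, and the exponential CDOM absorbance tail still absorbs
#' appreciably well into the visible, so the integration band extends to
#' the red end of the packaged solar tabulation.
#'
#' @param from,to Band limits in nm; must lie within \[280, 800\].
#' @param by Grid step in nm (default 1).
#' @return A numeric vector of wavelengths with class `"spectral_grid"`.
#' @examples
#' g <- spectral_grid(290, 500)
#' range(g)
#' @export
spectral_grid <- function(from = 290, to = 800, by = 1) {
  if (!is.numeric(from) || !is.numeric(to) || !is.numeric(by) ||
      length(from) != 1L || length(to) != 1L || length(by) != 1L) {
    stop("'from', 'to' and 'by' must be single numbers")
  }
  if (by <= 0) stop("grid step must be positive")
  if (to <= from) stop("'to' must exceed 'from'")
  wl <- seq(from, to, by = by)
  as_spectral_grid(wl)
}

#' Validate a numeric vector as a spectral grid
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @return The vector with class `"spectral_grid"`; errors if the grid is
#'   not strictly ascending, not uniform, or outside \[280, 800\] nm.
#' @keywords internal
#' @export
as_spectral_grid <- function(wavelengths) {
  wl <- as.numeric(wavelengths)
  if (length(wl) < 2L) stop("a spectral grid needs at least two wavelengths")
  d <- diff(wl)
  if (any(d <= 0)) stop("spectral grid must be strictly ascending")
  if (max(d) - min(d) > 1e-9) {
    stop("spectral grid step must be uniform (to within 1e-9 nm)")
  }
  if (wl[1L] < 280 - 1e-9 || wl[length(wl)] > 800 + 1e-9) {
    stop("spectral grid must lie within [280, 800] nm")
  }
  structure(wl, class = "spectral_grid")
}

# trapezoidal integral of y(x) on an arbitrary ascending x
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

.spectral_field <- function(grid, values, class, extra = list()) {
  grid <- as_spectral_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop("'values' must have one entry per grid wavelength")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("spectral values must be finite and non-negative")
  }
  structure(c(list(grid = grid, values = values), extra), class = class)
}

#' Construct spectral field objects
#'
#' Low-level constructors pairing a [spectral_grid()] with non-negative
#' per-wavelength values: `areal_irradiance()` in W m-2 nm-1 and
#' `areal_photon_flux()` in Einstein m-2 s-1 nm-1.
#'
#' @param grid A [spectral_grid()] (or numeric wavelengths in nm).
#' @param values Non-negative numeric vector, one value per wavelength.
#' @return An object of class `"areal_irradiance"` or
#'   `"areal_photon_flux"`.
#' @export
areal_irradiance <- function(grid, values) {
  .spectral_field(grid, values, "areal_irradiance")
}

#' @rdname areal_irradiance
#' @export
areal_photon_flux <- function(grid, values) {
  .spectral_field(grid, values, "areal_photon_flux")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d points)\n",
              x[1L], x[length(x)], x[2L] - x[1L], length(x)))
  invisible(x)
}

# two-column (nm, value) plain-text table with '#' comments
read_spectral_table <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("wavelength", "value"))
  if (nrow(tab) < 2L || any(diff(tab$wavelength) <= 0)) {
    stop("spectral table must have >= 2 rows with ascending wavelengths: ",
         path)
  }
  tab
}

# interpolate a table onto a grid, erroring outside its support
interp_table <- function(tab, grid, what) {
  lo <- tab$wavelength[1L]
  hi <- tab$wavelength[nrow(tab)]
  if (grid[1L] < lo - 1e-9 || grid[length(grid)] > hi + 1e-9) {
    stop(sprintf("%s tabulation covers %g-%g nm; requested grid %g-%g nm",
                 what, lo, hi, grid[1L], grid[length(grid)]))
  }
  stats::approx(tab$wavelength, tab$value, xout = grid, rule = 2)$y
}

default_spectrum_path <- function() {
  system.file("extdata", "solar_spectrum_synthetic.txt",
              package = "cdomphoto", mustWork = TRUE)
}

#' Clear-sky surface solar spectrum, normalised to the reference UV band
#'
#' Interpolates the packaged clear-sky irradiance table (a synthetic
#' mid-latitude equinox-noon spectrum; see the table header for its
#' construction) onto `grid` and rescales it so that the integral over
#' 290--400 nm equals 22 W m-2, the fair-weather UV irradiance used as
#' the model's fixed illumination. Because of the rescaling, only the
#' table's spectral shape matters, never its absolute scale.
#'
#' @param grid A [spectral_grid()]. Must cover 290--400 nm so the
#'   normalisation band can be evaluated.
#' @param path Optional path to an alternative two-column table
#'   (nm, W m-2 nm-1; `#` comments).
#' @param uv_target Band-integrated UV irradiance to normalise to
#'   (W m-2 over 290--400 nm; default 22).
#' @return An object of class `"areal_irradiance"` with fields `grid` and
#'   `values` (W m-2 nm-1).
#' @examples
#' sp <- build_default_spectrum(spectral_grid())
#' band_irradiance(sp, 290, 400)  # 22
#' @export
build_default_spectrum <- function(grid, path = NULL, uv_target = 22) {
  grid <- as_spectral_grid(grid)
  if (is.null(path)) path <- default_spectrum_path()
  tab <- read_spectral_table(path)
  vals <- interp_table(tab, grid, "solar spectrum")
  raw <- .spectral_field(grid, vals, "areal_irradiance",
                         extra = list(source = path))
  uv <- band_irradiance(raw, 290, 400)
  if (uv <= 0) stop("packaged spectrum has zero irradiance in 290-400 nm")
  raw$values <- raw$values * (uv_target / uv)
  raw
}

#' Band-integrated irradiance
#'
#' Trapezoidal integral of a spectral irradiance over \[`lo`, `hi`\] nm,
#' with linear interpolation at the band edges when they fall between
#' grid points.
#'
#' @param spec An `"areal_irradiance"` object.
#' @param lo,hi Band limits in nm, inside the grid range, `hi > lo`.
#' @return Irradiance in W m-2.
#' @export
band_irradiance <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "areal_irradiance"))
  if (hi <= lo) stop("'hi' must exceed 'lo'")
  g <- as.numeric(spec$grid)
  if (lo < g[1L] - 1e-9 || hi > g[length(g)] + 1e-9) {
    stop(sprintf("band [%g, %g] outside grid range [%g, %g] nm",
                 lo, hi, g[1L], g[length(g)]))
  }
  inner <- g[g > lo & g < hi]
  x <- c(lo, inner, hi)
  y <- stats::approx(g, spec$values, xout = x)$y
  trapz(x, y)
}

#' Convert spectral irradiance to spectral photon flux
#'
#' Wavelength-wise energy-to-photon conversion: a photon at wavelength
#' `lambda` (in metres) carries energy `h c / lambda`, so the molar photon
#' flux is `irradiance * lambda / (h c N_A)` (Einstein m-2 s-1 nm-1; one
#' Einstein is one mole of photons).
#'
#' @param spec An `"areal_irradiance"` object.
#' @return An `"areal_photon_flux"` object (Einstein m-2 s-1 nm-1).
#' @export
to_photon_flux <- function(spec) {
  stopifnot(inherits(spec, "areal_irradiance"))
  lam_m <- as.numeric(spec$grid) * 1e-9
  vals <- spec$values * lam_m / (.h_planck * .c_light * .n_avogadro)
  .spectral_field(spec$grid, vals, "areal_photon_flux")
}

#' Column-averaged volumetric photon flux density
#'
#' Converts an areal photon flux (photons crossing the surface of a
#' well-mixed column) into the volumetric spectral photon flux density
#' `p0(lambda)` seen by the column: photons entering 1 m2 divided by the
#' column volume, `1000 * depth` litres.
#'
#' @param flux An `"areal_photon_flux"` object.
#' @param depth Water-column depth in metres (> 0).
#' @return A `"volumetric_photon_flux"` object (Einstein L-1 s-1 nm-1)
#'   with field `depth`.
#' @export
to_volumetric <- function(flux, depth) {
  stopifnot(inherits(flux, "areal_photon_flux"))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    stop("'depth' must be a single positive number (m)")
  }
  .spectral_field(flux$grid, flux$values / (1000 * depth),
                  "volumetric_photon_flux", extra = list(depth = depth))
}

#' Build the volumetric solar field for a scenario in one call
#'
#' Convenience wrapper: packaged spectrum on `grid`, converted to photon
#' flux and column-averaged at `depth`.
#'
#' @inheritParams build_default_spectrum
#' @param depth Water depth in metres.
#' @return A `"volumetric_photon_flux"` object.
#' @export
solar_field <- function(depth, grid = spectral_grid(), path = NULL) {
  to_volumetric(to_photon_flux(build_default_spectrum(grid, path = path)),
                depth)
}
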