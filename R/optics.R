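#' CDOM absorption spectrum parameters
#'
#' The specific (per unit DOC, per cm) absorbance of chromophoric
#' dissolved organic matter is modelled as an exponential decay with
#' wavelength, `A1(lambda) = A0 * exp(-S * lambda)`:
#' `A0` (L mgC-1 cm-1) is the pre-exponential factor reflecting
#' chromophore density, and `S` (nm-1) the spectral slope, inversely
#' related to CDOM molecular weight. Representative freshwater values are
#' A0 = 0.45 and S = 0.015.
#'
#' @param A0 Pre-exponential factor, L mgC-1 cm-1 (> 0).
#' @param S Spectral slope, nm-1 (> 0).
#' @return An object of class `"cdom_spectrum"`.
#' @examples
#' specific_absorbance(cdom_spectrum(0.45, 0.015), 300)
#' @export
cdom_spectrum <- function(A0 = 0.45, S = 0.015) {
  if (!is.numeric(A0) || length(A0) != 1L || A0 <= 0) {
    stop("'A0' must be a single positive number (L mgC-1 cm-1)")
  }
  if (!is.numeric(S) || length(S) != 1L || S <= 0) {
    stop("'S' must be a single positive number (nm-1)")
  }
  structure(list(A0 = A0, S = S), class = "cdom_spectrum")
}

#' @export
print.cdom_spectrum <- function(x, ...) {
  cat(sprintf("<cdom_spectrum> A0 = %g L mgC-1 cm-1, S = %g nm-1\n",
              x$A0, x$S))
  invisible(x)
}

#' Specific CDOM absorbance at given wavelengths
#'
#' Evaluates `A1(lambda) = A0 * exp(-S * lambda)`, the decadic absorbance
#' per cm of path and per mgC/L of DOC.
#'
#' @param cdom A [cdom_spectrum()].
#' @param wavelength Wavelengths in nm (vectorised, > 0).
#' @return Specific absorbance, L mgC-1 cm-1.
#' @export
specific_absorbance <- function(cdom, wavelength) {
  stopifnot(inherits(cdom, "cdom_spectrum"))
  if (any(wavelength <= 0)) stop("wavelengths must be positive")
  cdom$A0 * exp(-cdom$S * wavelength)
}

#' Water-chemistry scenario
#'
#' One well-mixed water column: depth, dissolved organic carbon, nitrate,
#' nitrite, bicarbonate and carbonate concentrations, and the CDOM
#' spectral parameters. Defaults are the base conditions of the model
#' study: 3 m depth, DOC = 5 mgC/L, 1e-4 M NO3-, 1e-6 M NO2-, 1e-3 M
#' HCO3-, 1e-5 M CO3^2-, (A0, S) = (0.45, 0.015).
#'
#' @param depth Water depth, m (> 0).
#' @param doc Dissolved organic carbon, mgC L-1 (>= 0).
#' @param no3,no2,hco3,co3 Molar concentrations of NO3-, NO2-, HCO3- and
#'   CO3^2- (mol L-1, >= 0).
#' @param cdom A [cdom_spectrum()].
#' @return An object of class `"water_scenario"`.
#' @export
water_scenario <- function(depth = 3, doc = 5, no3 = 1e-4, no2 = 1e-6,
                           hco3 = 1e-3, co3 = 1e-5,
                           cdom = cdom_spectrum()) {
  num1 <- function(x, name, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (strict) x <= 0 else x < 0)) {
      stop(sprintf("'%s' must be a single %s number", name,
                   if (strict) "positive" else "non-negative"))
    }
    as.numeric(x)
  }
  stopifnot(inherits(cdom, "cdom_spectrum"))
  structure(list(depth = num1(depth, "depth", strict = TRUE),
                 doc = num1(doc, "doc"),
                 no3 = num1(no3, "no3"), no2 = num1(no2, "no2"),
                 hco3 = num1(hco3, "hco3"), co3 = num1(co3, "co3"),
                 cdom = cdom),
            class = "water_scenario")
}

#' @export
print.water_scenario <- function(x, ...) {
  cat(sprintf(paste0("<water_scenario> depth %g m, DOC %g mgC/L, ",
                     "NO3- %.3g M, NO2- %.3g M, HCO3- %.3g M, CO3^2- %.3g M, ",
                     "A0 %g, S %g\n"),
              x$depth, x$doc, x$no3, x$no2, x$hco3, x$co3,
              x$cdom$A0, x$cdom$S))
  invisible(x)
}

eps_table_path <- function(species = c("no3", "no2")) {
  species <- match.arg(species)
  system.file("extdata", sprintf("epsilon_%s_synthetic.txt", species),
              package = "cdomphoto", mustWork = TRUE)
}

#' Per-chromophore decadic column absorbance
#'
#' Decadic absorbance of the whole column (path `100 * depth` cm) for the
#' three competing chromophores:
#' `A_CDOM = 100 d DOC A0 exp(-S lambda)`,
#' `A_NO3 = eps_NO3(lambda) * [NO3-] * 100 d`, and likewise for nitrite.
#' Molar absorption coefficients come from the packaged tables
#' (overridable); absorbers other than these three are neglected, CDOM
#' being the dominant freshwater absorber over the modelled band.
#'
#' @param scenario A [water_scenario()].
#' @param grid A [spectral_grid()].
#' @param eps_no3_path,eps_no2_path Optional alternative molar-absorption
#'   tables (nm, M-1 cm-1; `#` comments).
#' @return An object of class `"chromophore_absorbance"`: list with
#'   `grid`, per-species vectors `cdom`, `no3`, `no2`, and `total`.
#' @export
column_absorbance <- function(scenario, grid,
                              eps_no3_path = NULL, eps_no2_path = NULL) {
  stopifnot(inherits(scenario, "water_scenario"))
  grid <- as_spectral_grid(grid)
  path_cm <- 100 * scenario$depth
  a_cdom <- path_cm * scenario$doc *
    specific_absorbance(scenario$cdom, as.numeric(grid))
  if (is.null(eps_no3_path)) eps_no3_path <- eps_table_path("no3")
  if (is.null(eps_no2_path)) eps_no2_path <- eps_table_path("no2")
  eps3 <- interp_table(read_spectral_table(eps_no3_path), grid,
                       "nitrate molar absorption")
  eps2 <- interp_table(read_spectral_table(eps_no2_path), grid,
                       "nitrite molar absorption")
  a_no3 <- eps3 * scenario$no3 * path_cm
  a_no2 <- eps2 * scenario$no2 * path_cm
  structure(list(grid = grid, cdom = a_cdom, no3 = a_no3, no2 = a_no2,
                 total = a_cdom + a_no3 + a_no2),
            class = "chromophore_absorbance")
}

#' Split absorbed photons among competing chromophores
#'
#' The fraction of incident photons absorbed by the column at each
#' wavelength is `1 - 10^(-A_tot)`; within it each chromophore `i`
#' receives the share `A_i / A_tot` (defined as 0 where `A_tot = 0`).
#' Absorbed photon rates are the trapezoidal wavelength integrals
#' `Pa_i = integral p0 * (1 - 10^-A_tot) * A_i / A_tot dlambda`.
#'
#' @param p0 A `"volumetric_photon_flux"` (Einstein L-1 s-1 nm-1).
#' @param absorbance A `"chromophore_absorbance"` on the same grid.
#' @return An object of class `"photon_budget"`: list with `pa` (named
#'   vector, Einstein L-1 s-1, elements `cdom`, `no3`, `no2`) and `total`.
#' @export
absorbed_photon_budget <- function(p0, absorbance) {
  stopifnot(inherits(p0, "volumetric_photon_flux"),
            inherits(absorbance, "chromophore_absorbance"))
  g1 <- as.numeric(p0$grid)
  g2 <- as.numeric(absorbance$grid)
  if (length(g1) != length(g2) || any(abs(g1 - g2) > 1e-9)) {
    stop("photon flux and absorbance are on different spectral grids")
  }
  a_tot <- absorbance$total
  f_abs <- 1 - 10^(-a_tot)
  share <- function(a_i) ifelse(a_tot > 0, a_i / a_tot, 0)
  pa <- c(cdom = trapz(g1, p0$values * f_abs * share(absorbance$cdom)),
          no3  = trapz(g1, p0$values * f_abs * share(absorbance$no3)),
          no2  = trapz(g1, p0$values * f_abs * share(absorbance$no2)))
  structure(list(pa = pa, total = trapz(g1, p0$values * f_abs)),
            class = "photon_budget")
}

#' @export
print.photon_budget <- function(x, ...) {
  cat("<photon_budget> (Einstein L-1 s-1)\n")
  cat(sprintf("  CDOM %.4e | NO3- %.4e | NO2- %.4e | total %.4e\n",
              x$pa[["cdom"]], x$pa[["no3"]], x$pa[["no2"]], x$total))
  invisible(x)
}
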