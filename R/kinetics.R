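#' Formation rate of CDOM excited triplet states
#'
#' `R_3CDOM = phi_3CDOM * Pa_CDOM`, the quantum yield applied to the
#' competition-corrected photon rate absorbed by CDOM.
#'
#' @param budget A `"photon_budget"` from [absorbed_photon_budget()].
#' @param params A [photo_params()] registry.
#' @return Formation rate, mol L-1 s-1.
#' @export
rate_3CDOM <- function(budget, params = photo_params()) {
  stopifnot(inherits(budget, "photon_budget"),
            inherits(params, "photo_params"))
  params$phi_3CDOM * budget$pa[["cdom"]]
}

#' Formation rate of singlet oxygen
#'
#' Triplet CDOM in aerated water is quenched essentially entirely by
#' dissolved O2, producing singlet oxygen with yield `f_delta` (~50%):
#' `R_1O2 = f_delta * R_3CDOM`.
#'
#' @param r_3CDOM Triplet formation rate, mol L-1 s-1.
#' @inheritParams rate_3CDOM
#' @return Formation rate, mol L-1 s-1.
#' @export
rate_1O2 <- function(r_3CDOM, params = photo_params()) {
  stopifnot(inherits(params, "photo_params"))
  params$f_delta * r_3CDOM
}

#' Hydroxyl-radical formation rate and source apportionment
#'
#' All three photosensitisers produce hydroxyl radicals:
#' `R_OH = phi_OH_CDOM * Pa_CDOM + phi_OH_NO3 * Pa_NO3 +
#' phi_OH_NO2 * Pa_NO2`. Source fractions are returned alongside; when
#' `R_OH = 0` they are `NA` (undefined).
#'
#' @inheritParams rate_3CDOM
#' @return List with `total` (mol L-1 s-1), `by_source` (named vector of
#'   the three terms) and `fractions` (named vector summing to 1, or NA).
#' @export
rate_OH <- function(budget, params = photo_params()) {
  stopifnot(inherits(budget, "photon_budget"),
            inherits(params, "photo_params"))
  terms <- c(cdom = params$phi_OH_CDOM * budget$pa[["cdom"]],
             no3  = params$phi_OH_NO3 * budget$pa[["no3"]],
             no2  = params$phi_OH_NO2 * budget$pa[["no2"]])
  total <- sum(terms)
  fractions <- if (total > 0) terms / total else
    c(cdom = NA_real_, no3 = NA_real_, no2 = NA_real_)
  list(total = total, by_source = terms, fractions = fractions)
}

#' First-order hydroxyl-radical sink budget
#'
#' Hydroxyl radicals are scavenged mainly by DOM and, usually to a lesser
#' extent, by inorganic carbon; nitrite is included because at high
#' nitrite its scavenging term becomes non-negligible. Terms:
#' `k_OH_DOM * DOC`, `k_OH_HCO3 * [HCO3-]`, `k_OH_CO3 * [CO3^2-]`,
#' `k_OH_NO2 * [NO2-]`.
#'
#' @param scenario A [water_scenario()].
#' @inheritParams rate_3CDOM
#' @return An object of class `"sink_budget"`: list with named `terms`
#'   (s-1) and their `total`.
#' @export
oh_sink <- function(scenario, params = photo_params()) {
  stopifnot(inherits(scenario, "water_scenario"),
            inherits(params, "photo_params"))
  terms <- c(dom  = params$k_OH_DOM * scenario$doc,
             hco3 = params$k_OH_HCO3 * scenario$hco3,
             co3  = params$k_OH_CO3 * scenario$co3,
             no2  = params$k_OH_NO2 * scenario$no2)
  structure(list(terms = terms, total = sum(terms)), class = "sink_budget")
}

#' @export
print.sink_budget <- function(x, ...) {
  cat("<sink_budget> (s-1)\n")
  cat(sprintf("  %s\n", paste(sprintf("%s %.3e", names(x$terms), x$terms),
                              collapse = " | ")))
  cat(sprintf("  total %.3e\n", x$total))
  invisible(x)
}

#' Carbonate-radical formation rate
#'
#' The main carbonate-radical source is hydroxyl-radical oxidation of
#' bicarbonate and carbonate; a secondary pathway is oxidation of
#' carbonate by triplet CDOM:
#' `R_CO3 = [OH]ss * (k_OH_HCO3 * [HCO3-] + k_OH_CO3 * [CO3^2-]) +
#' k_3CDOM_CO3 * [3CDOM*]ss * [CO3^2-]`.
#'
#' @param ss_OH,ss_3CDOM Steady-state hydroxyl-radical and triplet
#'   concentrations, mol L-1.
#' @param scenario A [water_scenario()].
#' @inheritParams rate_3CDOM
#' @return Formation rate, mol L-1 s-1.
#' @export
rate_CO3 <- function(ss_OH, ss_3CDOM, scenario, params = photo_params()) {
  stopifnot(inherits(scenario, "water_scenario"),
            inherits(params, "photo_params"))
  ss_OH * (params$k_OH_HCO3 * scenario$hco3 +
             params$k_OH_CO3 * scenario$co3) +
    params$k_3CDOM_CO3 * ss_3CDOM * scenario$co3
}

#' Steady-state closure for a short-lived transient
#'
#' `[X]ss = R / sum(k)`: formation rate divided by the total first-order
#' loss rate. A positive formation rate with no sink has no steady state
#' and is an error; zero formation gives zero concentration regardless of
#' the sink.
#'
#' @param rate Formation rate, mol L-1 s-1 (>= 0).
#' @param sink_total Total first-order sink, s-1 (>= 0).
#' @return Steady-state concentration, mol L-1.
#' @export
steady_state_linear <- function(rate, sink_total) {
  if (rate < 0 || sink_total < 0) stop("rate and sink must be non-negative")
  if (rate == 0) return(0)
  if (sink_total == 0) {
    stop("positive formation rate with zero total sink: no steady state")
  }
  rate / sink_total
}

#' Evaluate the full steady-state model for one scenario
#'
#' Composes the whole chain: per-chromophore column absorbances,
#' competitive absorbed-photon budget, formation rates, sink budgets and
#' steady-state concentrations of triplet CDOM, singlet oxygen, hydroxyl
#' radical and carbonate radical, plus the hydroxyl-radical source
#' apportionment among CDOM, nitrate and nitrite. Deterministic.
#'
#' @param scenario A [water_scenario()].
#' @param solar A `"volumetric_photon_flux"` (see [solar_field()]); its
#'   depth should match the scenario's.
#' @param params A [photo_params()] registry.
#' @param eps_no3_path,eps_no2_path Optional molar-absorption overrides.
#' @return An object of class `"steady_state"`: list with `rates` (named:
#'   `R_3CDOM`, `R_1O2`, `R_OH`, `R_CO3`; mol L-1 s-1), `conc` (named:
#'   `ss_3CDOM`, `ss_1O2`, `ss_OH`, `ss_CO3`; mol L-1),
#'   `oh_source_fractions` (cdom/no3/no2), `budget`, `oh_sink`, and the
#'   input `scenario`.
#' @examples
#' scn <- preset_scenario("fig2")
#' sol <- solar_field(scn$depth)
#' evaluate_scenario(scn, sol)
#' @export
evaluate_scenario <- function(scenario, solar, params = photo_params(),
                              eps_no3_path = NULL, eps_no2_path = NULL) {
  stopifnot(inherits(scenario, "water_scenario"),
            inherits(solar, "volumetric_photon_flux"))
  absorb <- column_absorbance(scenario, solar$grid,
                              eps_no3_path = eps_no3_path,
                              eps_no2_path = eps_no2_path)
  budget <- absorbed_photon_budget(solar, absorb)

  r3 <- rate_3CDOM(budget, params)
  r1 <- rate_1O2(r3, params)
  oh <- rate_OH(budget, params)
  sink_oh <- oh_sink(scenario, params)

  ss3 <- steady_state_linear(r3, params$k_q3)
  ss1 <- steady_state_linear(r1, params$k_d1O2)
  ssoh <- steady_state_linear(oh$total, sink_oh$total)

  rco3 <- rate_CO3(ssoh, ss3, scenario, params)
  ssco3 <- steady_state_linear(rco3, params$k_CO3_DOM * scenario$doc)

  structure(list(
    rates = c(R_3CDOM = r3, R_1O2 = r1, R_OH = oh$total, R_CO3 = rco3),
    conc = c(ss_3CDOM = ss3, ss_1O2 = ss1, ss_OH = ssoh, ss_CO3 = ssco3),
    oh_source_fractions = oh$fractions,
    budget = budget, oh_sink = sink_oh, scenario = scenario),
    class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>\n  formation rates (mol L-1 s-1):\n")
  cat(sprintf("    %s\n",
              paste(sprintf("%s %.3e", names(x$rates), x$rates),
                    collapse = " | ")))
  cat("  steady-state concentrations (mol L-1):\n")
  cat(sprintf("    %s\n",
              paste(sprintf("%s %.3e", names(x$conc), x$conc),
                    collapse = " | ")))
  fr <- x$oh_source_fractions
  cat(sprintf("  OH sources: CDOM %.3f | NO3- %.3f | NO2- %.3f\n",
              fr[["cdom"]], fr[["no3"]], fr[["no2"]]))
  invisible(x)
}
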