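# Shared fixtures: everything is built in code, nothing is downloaded.
sol3 <- solar_field(3)          # packaged spectrum, 3 m column
fig2 <- preset_scenario("fig2")

# evaluate one scenario against the shared 3 m solar field
eval3 <- function(scn, params = photo_params()) {
  evaluate_scenario(scn, sol3, params)
}

# band-integrated incident volumetric photon flux (Einstein L-1 s-1)
trapz_incident <- function(p0) {
  x <- as.numeric(p0$grid)
  y <- p0$values
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# clone a scenario with selected fields replaced
with_fields <- function(scn, ...) {
  over <- list(...)
  for (k in setdiff(names(over), c("A0", "S"))) scn[[k]] <- over[[k]]
  if (any(c("A0", "S") %in% names(over))) {
    scn$cdom <- cdom_spectrum(
      if ("A0" %in% names(over)) over$A0 else scn$cdom$A0,
      if ("S" %in% names(over)) over$S else scn$cdom$S)
  }
  scn
}
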