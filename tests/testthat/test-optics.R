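test_that("specific CDOM absorbance follows the exponential slope model", {
  expect_equal(specific_absorbance(cdom_spectrum(0.45, 0.015), 300),
               5.00e-3, tolerance = 1e-3)
  # a higher A0 / lower S spectrum lies above a lower A0 / higher S one
  wl <- 290:500
  hi <- specific_absorbance(cdom_spectrum(0.60, 0.012), wl)
  lo <- specific_absorbance(cdom_spectrum(0.30, 0.018), wl)
  expect_true(all(hi > lo))
  expect_error(cdom_spectrum(0, 0.015), "positive")
  expect_error(cdom_spectrum(0.45, -0.1), "positive")
  expect_error(specific_absorbance(cdom_spectrum(), c(300, -2)), "positive")
})

test_that("column absorbance composes path, DOC and the molar tables", {
  g <- spectral_grid()
  ab <- column_absorbance(fig2, g)
  at <- function(x, wl) x[match(wl, as.numeric(g))]
  expect_equal(at(ab$cdom, 300), 7.50, tolerance = 2e-3)
  expect_equal(at(ab$cdom, 450), 0.790, tolerance = 1e-3)
  # nitrate band maximum: eps = 7.2 M-1 cm-1 at 302 nm, 300 cm path, 1e-4 M
  expect_equal(max(ab$no3), 7.2 * 1e-4 * 300, tolerance = 1e-6)
  expect_equal(ab$total, ab$cdom + ab$no3 + ab$no2, tolerance = 1e-12)
  expect_true(all(ab$cdom >= 0 & ab$no3 >= 0 & ab$no2 >= 0))
  zero_doc <- with_fields(fig2, doc = 0)
  expect_equal(column_absorbance(zero_doc, g)$cdom,
               rep(0, length(g)))
})

test_that("CDOM dominates photon absorption at the fig2 base conditions", {
  g <- spectral_grid()
  ab <- column_absorbance(fig2, g)
  i <- match(300, as.numeric(g))
  expect_gt(ab$cdom[i] / ab$total[i], 0.95)
})

test_that("the absorbed-photon budget conserves photons", {
  scns <- c(list(fig2, preset_scenario("fig5"), preset_scenario("fig6")),
            sample_scenarios(20, seed = 101))
  for (scn in scns) {
    sol <- solar_field(scn$depth)
    b <- absorbed_photon_budget(sol, column_absorbance(scn, sol$grid))
    expect_true(all(b$pa >= 0))
    expect_equal(sum(b$pa), b$total, tolerance = 1e-9)
    expect_lte(b$total, trapz_incident(sol))
  }
})

test_that("a single absorber takes the whole budget; saturation absorbs all", {
  only_cdom <- with_fields(fig2, no3 = 0, no2 = 0)
  b <- absorbed_photon_budget(sol3, column_absorbance(only_cdom, sol3$grid))
  expect_equal(b$pa[["cdom"]], b$total)
  expect_equal(b$pa[["no3"]], 0)
  # enormous DOC: every incident photon is absorbed
  sat <- with_fields(only_cdom, doc = 1e6)
  bsat <- absorbed_photon_budget(sol3, column_absorbance(sat, sol3$grid))
  expect_equal(bsat$total, trapz_incident(sol3), tolerance = 1e-6)
})

test_that("Pa_CDOM is monotone in A0, S and DOC; DOC screens the N species", {
  pa <- function(scn) {
    absorbed_photon_budget(sol3, column_absorbance(scn, sol3$grid))$pa
  }
  scns <- c(list(fig2), sample_scenarios(10, seed = 202))
  for (scn in scns) {
    scn <- with_fields(scn, depth = 3)
    base <- pa(scn)
    expect_gt(pa(with_fields(scn, A0 = scn$cdom$A0 * 1.2))[["cdom"]],
              base[["cdom"]])
    expect_lt(pa(with_fields(scn, S = scn$cdom$S * 1.2))[["cdom"]],
              base[["cdom"]])
    up_doc <- pa(with_fields(scn, doc = scn$doc * 1.5))
    expect_gt(up_doc[["cdom"]], base[["cdom"]])
    if (scn$no3 > 0) expect_lt(up_doc[["no3"]], base[["no3"]])
    if (scn$no2 > 0) expect_lt(up_doc[["no2"]], base[["no2"]])
  }
})

test_that("budgets on 1 nm and 0.1 nm grids agree within 0.5%", {
  for (name in c("fig2", "fig5", "fig6")) {
    scn <- preset_scenario(name)
    s1 <- solar_field(scn$depth, spectral_grid(290, 800, 1))
    s01 <- solar_field(scn$depth, spectral_grid(290, 800, 0.1))
    b1 <- absorbed_photon_budget(s1, column_absorbance(scn, s1$grid))
    b01 <- absorbed_photon_budget(s01, column_absorbance(scn, s01$grid))
    expect_equal(b1$pa, b01$pa, tolerance = 5e-3)
    expect_equal(b1$total, b01$total, tolerance = 5e-3)
  }
})

test_that("mismatched grids are refused", {
  ab <- column_absorbance(fig2, spectral_grid(290, 500))
  expect_error(absorbed_photon_budget(sol3, ab), "different spectral grids")
})
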