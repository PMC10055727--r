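fake_budget <- function(cdom = 0, no3 = 0, no2 = 0) {
  structure(list(pa = c(cdom = cdom, no3 = no3, no2 = no2),
                 total = cdom + no3 + no2), class = "photon_budget")
}

test_that("triplet and singlet-oxygen formation rates are simple products", {
  p <- photo_params()
  expect_equal(rate_3CDOM(fake_budget(cdom = 2e-5),
                          photo_params(phi_3CDOM = 1.25e-3)), 2.5e-8)
  expect_equal(rate_3CDOM(fake_budget(cdom = 0), p), 0)
  expect_equal(rate_1O2(2e-10, photo_params(f_delta = 0.5)), 1e-10)
  expect_equal(rate_1O2(0, p), 0)
})

test_that("steady-state closure divides rate by total sink", {
  expect_equal(steady_state_linear(2.5e-8, 5e5), 5e-14)
  expect_equal(steady_state_linear(0, 0), 0)
  expect_equal(steady_state_linear(2e-10, 1e5),
               2 * steady_state_linear(1e-10, 1e5))
  expect_error(steady_state_linear(1e-10, 0), "no steady state")
  expect_error(steady_state_linear(-1, 1), "non-negative")
})

test_that("hydroxyl-radical sources combine the three photosensitisers", {
  p <- photo_params()
  oh <- rate_OH(fake_budget(cdom = 1e-7, no3 = 1e-10, no2 = 5e-11), p)
  expect_equal(oh$total,
               p$phi_OH_CDOM * 1e-7 + p$phi_OH_NO3 * 1e-10 +
                 p$phi_OH_NO2 * 5e-11)
  expect_equal(sum(oh$fractions), 1, tolerance = 1e-12)
  only_no3 <- rate_OH(fake_budget(no3 = 1e-10), p)
  expect_equal(only_no3$fractions[["no3"]], 1)
  dark <- rate_OH(fake_budget(), p)
  expect_equal(dark$total, 0)
  expect_true(all(is.na(dark$fractions)))
})

test_that("the hydroxyl-radical sink budget matches hand-computed terms", {
  scn <- with_fields(fig2, no2 = 0)
  sk <- oh_sink(scn, photo_params())
  # 5e4*5 + 8.5e6*1e-3 + 3.9e8*1e-5 = 2.5e5 + 8.5e3 + 3.9e3
  expect_equal(sk$total, 2.624e5, tolerance = 1e-3)
  expect_equal(unname(sk$terms[["dom"]]), 2.5e5)
  carb <- (sk$terms[["hco3"]] + sk$terms[["co3"]]) / sk$total
  expect_equal(carb, 0.0473, tolerance = 1e-2)
  empty <- water_scenario(depth = 3, doc = 0, no3 = 0, no2 = 0,
                          hco3 = 0, co3 = 0)
  expect_equal(oh_sink(empty, photo_params())$total, 0)
})

test_that("carbonate-radical formation has a dominant OH pathway", {
  p <- photo_params()
  scn <- fig2
  oh_path <- rate_CO3(1e-16, 0, scn, p)
  expect_equal(oh_path, 1.24e-12, tolerance = 1e-3)
  trip_path <- rate_CO3(0, 5e-16, scn, p)
  expect_equal(trip_path, 1e5 * 5e-16 * 1e-5)
  expect_lt(trip_path, oh_path / 100)   # secondary pathway indeed
  no_carb <- with_fields(scn, hco3 = 0, co3 = 0)
  expect_equal(rate_CO3(1e-16, 5e-16, no_carb, p), 0)
})

test_that("default registry makes singlet oxygen track triplet CDOM", {
  res <- eval3(fig2)
  expect_identical(res$conc[["ss_1O2"]], res$conc[["ss_3CDOM"]])
  # the identity is the algebraic consequence of f_delta = 0.5 and
  # k_q3 = 2 k_d1O2; breaking either breaks it
  res2 <- eval3(fig2, photo_params(f_delta = 0.25))
  expect_equal(res2$conc[["ss_1O2"]], res2$conc[["ss_3CDOM"]] / 2)
})

test_that("full evaluation is deterministic, non-negative and sane", {
  res <- eval3(fig2)
  expect_true(all(res$rates >= 0))
  expect_true(all(res$conc >= 0))
  expect_equal(sum(res$oh_source_fractions), 1, tolerance = 1e-9)
  expect_identical(res$conc, eval3(fig2)$conc)
  # dark water: nothing absorbs, all steady states vanish
  dark <- water_scenario(depth = 3, doc = 0, no3 = 0, no2 = 0,
                         hco3 = 1e-3, co3 = 1e-5)
  res0 <- eval3(dark)
  expect_equal(unname(res0$conc), rep(0, 4))
  # random scenarios: non-negativity and fraction closure hold throughout
  for (scn in sample_scenarios(25, seed = 303)) {
    r <- evaluate_scenario(scn, solar_field(scn$depth))
    expect_true(all(r$rates >= 0) && all(r$conc >= 0))
    expect_equal(sum(r$oh_source_fractions), 1, tolerance = 1e-9)
  }
})

test_that("triplet concentration rises with A0 and falls with S", {
  base <- eval3(fig2)$conc[["ss_3CDOM"]]
  expect_gt(eval3(with_fields(fig2, A0 = 0.60))$conc[["ss_3CDOM"]], base)
  expect_lt(eval3(with_fields(fig2, S = 0.018))$conc[["ss_3CDOM"]], base)
})

test_that("all rates and steady states are linear in the photon flux", {
  sol_x3 <- sol3
  sol_x3$values <- sol3$values * 3
  r1 <- eval3(fig2)
  r3 <- evaluate_scenario(fig2, sol_x3)
  expect_equal(r3$rates, 3 * r1$rates, tolerance = 1e-9)
  expect_equal(r3$conc, 3 * r1$conc, tolerance = 1e-9)
})

test_that("at fig5 nitrogen levels CDOM is the dominant OH source", {
  res <- eval3(preset_scenario("fig5"))
  expect_gt(res$oh_source_fractions[["cdom"]], 0.9)
})
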