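test_that("the spectral sweep covers the 7x7 grid deterministically", {
  sw <- spectral_grid_sweep(fig2, solar = sol3, preset = "fig2")
  expect_equal(nrow(sw), 49)
  # A0 outer, S inner ordering
  expect_equal(sw$A0, rep(seq(0.30, 0.60, 0.05), each = 7))
  expect_equal(sw$S, rep(seq(0.012, 0.018, 0.001), times = 7))
  sw2 <- spectral_grid_sweep(fig2, solar = sol3, preset = "fig2")
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(spectral_grid_sweep(fig2, A0_values = c(0.6, 0.3),
                                   solar = sol3), "ascending")
})

test_that("triplet extremes sit at the expected corners of the grid", {
  sw <- spectral_grid_sweep(fig2, solar = sol3)
  expect_equal(unlist(sw[which.max(sw$ss_3CDOM), c("A0", "S")]),
               c(A0 = 0.60, S = 0.012))
  expect_equal(unlist(sw[which.min(sw$ss_3CDOM), c("A0", "S")]),
               c(A0 = 0.30, S = 0.018))
  # finite-difference signs at every cell
  for (d in split(sw, sw$A0)) {
    expect_true(all(diff(d$ss_3CDOM[order(d$S)]) < 0))
  }
  for (d in split(sw, sw$S)) {
    expect_true(all(diff(d$ss_3CDOM[order(d$A0)]) > 0))
  }
})

test_that("the DOC sweep is monotone with a saturation plateau", {
  sw <- doc_sweep(fig2, solar = sol3)
  expect_equal(nrow(sw), 24)
  expect_true(all(diff(sw$ss_3CDOM) > 0))
  one <- doc_sweep(fig2, doc_values = 5, solar = sol3)
  expect_equal(nrow(one), 1)
  ss <- function(scn) eval3(scn)$conc[["ss_3CDOM"]]
  expect_gt(ss(with_fields(fig2, doc = 50)), ss(fig2))
  expect_gt(ss(fig2), ss(with_fields(fig2, doc = 0.5)))
  # both high-absorption scenarios sit on the total-absorption plateau
  plateau_a <- ss(with_fields(fig2, doc = 50))
  plateau_b <- ss(with_fields(fig2, A0 = 0.60, S = 0.012))
  expect_equal(plateau_a, plateau_b, tolerance = 0.1)
})

test_that("equivalent-DOC inversion recovers known points and is monotone", {
  ss <- function(scn) eval3(scn)$conc[["ss_3CDOM"]]
  # fixed point: the base scenario's own concentration maps to its DOC
  expect_equal(match_equivalent_doc(ss(fig2), fig2, sol3), 5,
               tolerance = 2e-3)
  # a lower target maps to a smaller DOC, a higher to a larger one
  d_lo <- match_equivalent_doc(ss(fig2) * 0.4, fig2, sol3)
  d_hi <- match_equivalent_doc(ss(fig2) * 1.5, fig2, sol3)
  expect_lt(d_lo, 5)
  expect_gt(d_hi, 5)
  expect_error(match_equivalent_doc(ss(fig2) * 1e6, fig2, sol3),
               "attainable range")
})

test_that("spectral-quality corners are worth about a decade of DOC", {
  ss <- function(scn) eval3(scn)$conc[["ss_3CDOM"]]
  d_up <- match_equivalent_doc(ss(with_fields(fig2, A0 = 0.60, S = 0.012)),
                               fig2, sol3)
  d_dn <- match_equivalent_doc(ss(with_fields(fig2, A0 = 0.30, S = 0.018)),
                               fig2, sol3)
  expect_gte(d_up / d_dn, 10)
})

test_that("extremum location reports the grid argmin with tie-breaks", {
  S <- seq(0.012, 0.018, 0.001)
  ex <- locate_extremum(S, c(5, 3, 2, 1.5, 1.8, 2.5, 4))
  expect_equal(ex$S_at_min, 0.015)
  expect_equal(ex$kind, "interior")
  expect_equal(locate_extremum(S, seq_len(7))$kind, "left_edge")
  expect_equal(locate_extremum(S, rev(seq_len(7)))$kind, "right_edge")
  expect_equal(locate_extremum(S, rep(1, 7))$S_at_min, 0.012)
  expect_error(locate_extremum(S[1:2], c(1, 2)), "3 points")
})

test_that("sweep CSV round-trips through the annotated format", {
  sw <- spectral_grid_sweep(fig2, solar = sol3, preset = "fig2")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, tf, spectrum_source = "packaged")
  back <- read_sweep(tf)
  expect_equal(back$A0, sw$A0)
  expect_equal(back$S, sw$S)
  expect_equal(back$ss_3CDOM, sw$ss_3CDOM, tolerance = 1e-5)
  expect_true(any(grepl("params_hash", readLines(tf))))
})
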