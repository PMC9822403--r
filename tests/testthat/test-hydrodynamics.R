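test_that("tumbling rate follows Stokes-Einstein scalings and the closed form", {
  expect_equal(tumbling_rate(1e-9, 2, 293), tumbling_rate(1e-9, 1, 293) / 2)
  expect_equal(tumbling_rate(2e-9, 1, 293) / tumbling_rate(1e-9, 1, 293), 1 / 8)
  # frozen hand evaluation: 3 kB T / (4 pi eta r^3), r = 0.5 nm,
  # eta = 17.6 cp, T = 293 K
  expect_equal(tumbling_rate(0.5e-9, 17.6, 293), 438974823.5,
               tolerance = 1e-9)
})

test_that("Stokes-Einstein-Debye correlation time is eta*V-proportional and inverts the tumbling rate", {
  expect_equal(tau_c_sed(1e-27, 2, 293), 2 * tau_c_sed(1e-27, 1, 293))
  r <- 0.7e-9
  expect_equal(tau_c_sed(sphere_volume(r), 5, 300, cr_fit = 1),
               1 / tumbling_rate(r, 5, 300), tolerance = 1e-12)
  temps <- seq(273, 373, by = 10)
  taus <- vapply(temps, function(T) tau_c_sed(1e-27, 10, T), numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("rotational diffusion matches its closed form and tau_c * Dr is constant", {
  # frozen hand evaluation: kB T / (8 pi eta R^3), R = 1 nm, eta = 1 cp, 293 K
  expect_equal(rotational_diffusion(1e-9, 1, 293), 160957435.3,
               tolerance = 1e-9)
  expect_equal(rotational_diffusion(2e-9, 2, 293),
               rotational_diffusion(1e-9, 16, 293))   # quadruple R^3*eta twice over
  etas <- c(1, 5, 20, 100)
  prod <- vapply(etas, function(e) {
    tau_c_sed(sphere_volume(1e-9), e, 293) * rotational_diffusion(1e-9, e, 293)
  }, numeric(1))
  expect_equal(prod, rep(1 / 6, 4), tolerance = 1e-10)
})

test_that("R2/eta scales linearly with molecular weight (log-log slope 1)", {
  expect_equal(r2_over_eta_mw_scaling(2 * 282, 1e-3),
               2 * r2_over_eta_mw_scaling(282, 1e-3))
  # oleic acid (282 g/mol) vs methyl oleate (296 g/mol)
  expect_equal(r2_over_eta_mw_scaling(282, 1e-3) / r2_over_eta_mw_scaling(296, 1e-3),
               282 / 296)
  expect_identical(r2_over_eta_mw_scaling(282, 0), 0)
  mw <- c(100, 1000)
  slope <- diff(log(r2_over_eta_mw_scaling(mw, 2e-3))) / diff(log(mw))
  expect_equal(slope, 1, tolerance = 1e-12)
  expect_warning(r2_over_eta_mw_scaling(600, 1e-3, mwc_gmol = 500),
                 "entanglement")
})

test_that("unit boundary: centipoise round-trips exactly and bad inputs error", {
  expect_identical(relaxochain:::.pas_to_cp(relaxochain:::.cp_to_pas(17.6)), 17.6)
  expect_error(tumbling_rate(-1e-9, 1, 293), "positive")
  expect_error(tau_c_sed(1e-27, 0, 293), "positive")
  expect_error(rotational_diffusion(1e-9, 1, -5), "positive")
})
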