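test_that("the IR-CPMG forward model obeys its closed forms", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = 200, t2_ms = 150, weight = 3),
                        meta = fast_meta)
  # long recovery, short echo time: amplitude approaches the weight
  expect_equal(s$data[length(s$inversion_times_ms), 1], 3, tolerance = 0.02)
  # recovery null near tau = T1 * ln 2
  ir <- 1 - 2 * exp(-s$inversion_times_ms / 200)
  crossing <- s$inversion_times_ms[which.min(abs(ir))]
  expect_equal(crossing, 200 * log(2), tolerance = 0.2)
  # mixtures superpose linearly
  c1 <- data.frame(t1_ms = 100, t2_ms = 50, weight = 1)
  c2 <- data.frame(t1_ms = 500, t2_ms = 400, weight = 1)
  both <- simulate_ir_cpmg(rbind(c1, c2), meta = fast_meta)
  expect_equal(both$data,
               simulate_ir_cpmg(c1, meta = fast_meta)$data +
                 simulate_ir_cpmg(c2, meta = fast_meta)$data,
               tolerance = 1e-12)
})

test_that("components violating T1 >= T2 and empty lists are rejected", {
  expect_error(simulate_ir_cpmg(data.frame(t1_ms = 50, t2_ms = 100, weight = 1)),
               "T1 >= T2")
  expect_error(simulate_ir_cpmg(list()), "at least one")
  expect_error(make_ir_cpmg_mixture(list()), "at least one")
})

test_that("noiseless single-component inversion localizes the peak within one grid cell", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = 200, t2_ms = 150, weight = 1),
                        meta = fast_meta)
  m <- invert_t1t2(s, lambda_reg = 1e-6)
  cell <- (1e4 / 0.1)^(1 / (length(m$t1_grid_ms) - 1))   # grid spacing factor
  top <- m$peaks[1, ]
  expect_lt(abs(log(top$t1_ms / 200)), log(cell) * 1.001)
  expect_lt(abs(log(top$t2_ms / 150)), log(cell) * 1.001)
})

test_that("solver objective decreases monotonically and the map stays nonnegative", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = c(12, 600), t2_ms = c(10, 500),
                                   weight = c(2, 1)),
                        noise_sigma = 3 / 500, seed = 42)
  m <- invert_t1t2(s)
  expect_true(all(diff(m$objective) <= 0))
  expect_true(all(m$amplitude >= 0))
  expect_gt(sum(m$amplitude), 0)
  expect_true(all(diff(m$peaks$mass) <= 0))   # sorted by descending mass
  # peak maxima respect the physical constraint of the forward components
  expect_true(all(m$peaks$t1_ms >= m$peaks$t2_ms))
  # with the physical prior enabled, no mass sits on the T1 < T2 side
  mc <- invert_t1t2(s, enforce_t1_ge_t2 = TRUE)
  below <- outer(mc$t1_grid_ms, mc$t2_grid_ms, "<")
  expect_lt(sum(mc$amplitude[below]) / sum(mc$amplitude), 0.05)
  expect_true(all(diff(mc$objective) <= 0))
})

test_that("two well-separated components are recovered with their mass ratio", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = c(12, 600), t2_ms = c(10, 500),
                                   weight = c(2, 1)),
                        noise_sigma = 3 / 500, seed = 42)
  m <- invert_t1t2(s)
  expect_gte(nrow(m$peaks), 2)
  ratio <- m$peaks$mass[1] / m$peaks$mass[2]
  expect_lt(abs(ratio - 2) / 2, 0.20)
})

test_that("degenerate inputs: zero data gives a zero map, bad lambda errors", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = 100, t2_ms = 80, weight = 1),
                        meta = fast_meta)
  s$data[] <- 0
  m <- invert_t1t2(s, lambda_reg = 1e-4)
  expect_identical(sum(m$amplitude), 0)
  expect_identical(nrow(m$peaks), 0L)
  expect_error(invert_t1t2(s, lambda_reg = 0), "positive")
  expect_error(invert_t1t2(s, n_grid = 16), "at least 32")
})

test_that("an impossible iteration cap raises a diagnostic carrying the residual", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = 200, t2_ms = 150, weight = 1),
                        meta = fast_meta)
  expect_error(invert_t1t2(s, max_iter = 2), "did not converge")
})

test_that("map components are classified into the three qualitative classes", {
  inv <- function(t1, t2) {
    invert_t1t2(simulate_ir_cpmg(data.frame(t1_ms = t1, t2_ms = t2, weight = 1),
                                 meta = fast_meta),
                lambda_reg = 1e-5)
  }
  expect_true("high-viscosity/saturated" %in% classify_map(inv(5, 5))$labels)
  expect_true("aggregate/slow-rotation" %in% classify_map(inv(800, 100))$labels)
  expect_identical(classify_map(inv(150, 150))$labels, "free-fluid")
})

test_that("classification needs at least one peak", {
  s <- simulate_ir_cpmg(data.frame(t1_ms = 100, t2_ms = 80, weight = 1),
                        meta = fast_meta)
  s$data[] <- 0
  m <- invert_t1t2(s)
  expect_error(classify_map(m), "empty map")
})

test_that("gel diagnostic flags a T1 rise at constant T2 and nothing else", {
  series_for <- function(t1, t2) {
    simulate_ir_cpmg(data.frame(t1_ms = t1, t2_ms = t2, weight = 1),
                     meta = fast_meta)
  }
  m_200_150 <- invert_t1t2(series_for(200, 150), lambda_reg = 1e-5)
  m_600_150 <- invert_t1t2(series_for(600, 150), lambda_reg = 1e-5)
  m_210_40 <- invert_t1t2(series_for(210, 40), lambda_reg = 1e-5)

  expect_true(gel_shift_diagnostic(m_200_150, m_600_150)$flagged)
  expect_false(gel_shift_diagnostic(m_200_150, m_200_150)$flagged)
  expect_false(gel_shift_diagnostic(m_200_150, m_210_40)$flagged)   # T2 collapsed
})
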