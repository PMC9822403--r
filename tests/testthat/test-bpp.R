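test_that("fast-motion limit: T1 equals T2 and both follow the linear law", {
  p <- bpp_params()
  tau <- 1e-4 / p$omega0       # omega0 * tau_c = 1e-4, extreme narrowing
  expect_equal(t1_bpp(tau, p), t2_bpp(tau, p), tolerance = 1e-6)
  # 1/T1 -> (3/10) * C * 5 tau = (3/20) * C * 10 tau
  expect_equal(1 / t1_bpp(tau, p), 0.3 * p$dipolar_prefactor * 5 * tau,
               tolerance = 1e-6)
  expect_identical(t1_over_t2(0), 1)
})

test_that("T1 >= T2 across six decades of correlation time", {
  p <- bpp_params()
  tau <- exp(seq(log(1e-12), log(1e-3), length.out = 1000))
  t1 <- t1_bpp(tau, p); t2 <- t2_bpp(tau, p)
  expect_true(all(t2 <= t1 * (1 + 1e-9)))
})

test_that("T2 is strictly decreasing while T1 has a unique interior minimum", {
  p <- bpp_params()
  tau <- exp(seq(log(1e-12), log(1e-3), length.out = 4000))
  expect_true(all(diff(t2_bpp(tau, p)) < 0))
  t1 <- t1_bpp(tau, p)
  sign_changes <- sum(diff(sign(diff(t1))) != 0)
  expect_identical(sign_changes, 1L)                  # one minimum, no other turning point
  # dense-grid oracle for the minimum location: omega0 * tau_c ~ 0.616
  expect_equal(p$omega0 * tau[which.min(t1)], 0.616, tolerance = 0.01)
})

test_that("rate is linear in the dipolar prefactor and prefactor decreases with l", {
  p1 <- bpp_params()
  p2 <- bpp_params(dipolar_prefactor = 2 * p1$dipolar_prefactor)
  tau <- 1e-9
  expect_equal(t1_bpp(tau, p2), t1_bpp(tau, p1) / 2, tolerance = 1e-12)
  ls <- seq(1.5e-10, 3e-10, length.out = 20)
  pref <- vapply(ls, function(l) bpp_params(interproton_distance_m = l)$dipolar_prefactor,
                 numeric(1))
  expect_true(all(diff(pref) < 0))
})

test_that("T1/T2 ratio is the BPP quotient, monotone, and 1 at the origin", {
  p <- bpp_params()
  tau <- exp(seq(log(1e-11), log(1e-6), length.out = 50))
  expect_rel_equal(t1_bpp(tau, p) / t2_bpp(tau, p),
                   t1_over_t2(p$omega0 * tau), 1e-12)
  x <- seq(0, 100, length.out = 2000)
  expect_true(all(diff(t1_over_t2(x)) >= 0))
})

test_that("ratio inversion round-trips and rejects unphysical ratios", {
  p <- bpp_params()
  for (x in c(0.1, 1, 10)) {
    tau <- invert_tau_c_from_ratio(t1_over_t2(x), p)
    expect_equal(p$omega0 * tau, x, tolerance = 1e-8)
  }
  x <- exp(seq(log(1e-2), log(1e2), length.out = 25))
  back <- vapply(x, function(xi) {
    p$omega0 * invert_tau_c_from_ratio(t1_over_t2(xi), p)
  }, numeric(1))
  expect_rel_equal(back, x, 1e-8)
  expect_identical(invert_tau_c_from_ratio(1, p), 1e-13)  # lower bracket
  expect_error(invert_tau_c_from_ratio(0.999, p), "unphysical")
})

test_that("fast-motion linear law matches the full transverse rate when slow", {
  expect_identical(fast_motion_r2(1, 1, constant = 10), 10)
  expect_equal(fast_motion_r2(2e-9, 3e9), 2 * fast_motion_r2(1e-9, 3e9))
  p <- bpp_params()
  tau <- 1e-3 / p$omega0
  m2 <- p$dipolar_prefactor * (3 / 20)       # makes c * M2 = (3/20) * 10 * C
  expect_equal(fast_motion_r2(tau, m2, constant = 10), 1 / t2_bpp(tau, p),
               tolerance = 0.05)
})

test_that("domain errors are raised for non-positive inputs", {
  p <- bpp_params()
  expect_error(t1_bpp(0, p), "positive")
  expect_error(t2_bpp(-1e-9, p), "positive")
  expect_error(t1_over_t2(-0.1), "nonnegative")
  expect_error(fast_motion_r2(1e-9, -1), "positive")
  expect_error(bpp_params(larmor_frequency_mhz = 0), "positive")
})

test_that("theory curve tabulation carries consistent columns", {
  p <- bpp_params()
  tc <- bpp_theory_curve(n = 60, params = p)
  expect_named(tc, c("tau_c_s", "t1_s", "t2_s", "ratio"))
  expect_rel_equal(tc$ratio, tc$t1_s / tc$t2_s, 1e-10)
})
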