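test_that("the reference-table fit reproduces the published coefficients", {
  cal <- fit_calibration(table1)
  expect_identical(cal$n_samples, 17L)
  expect_lt(abs(abs(cal$slope_a) - 52.998), 0.01)
  expect_lt(abs(cal$intercept_b - (-1.5597)), 0.005)
  expect_gt(cal$slope_a, 0)          # CL rises with R2/eta across the table
  expect_gt(cal$r_squared, 0.9)
})

test_that("exact lines are fitted exactly and OLS invariances hold", {
  cal <- fit_calibration(collinear_records)
  expect_equal(cal$slope_a, 50, tolerance = 1e-10)
  expect_equal(cal$intercept_b, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)

  doubled <- fit_calibration(rbind(table1, table1))
  base <- fit_calibration(table1)
  expect_equal(doubled$slope_a, base$slope_a, tolerance = 1e-12)
  expect_equal(doubled$intercept_b, base$intercept_b, tolerance = 1e-12)

  shuffled <- fit_calibration(table1[sample.int(17), ])
  expect_equal(shuffled$slope_a, base$slope_a, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_calibration(collinear_records[1:2, ]), "at least 3")
  flat <- collinear_records
  flat$r2_over_eta <- 0.2
  expect_error(fit_calibration(flat), "zero variance")
})

test_that("predictions are monotone, flag extrapolation, and pass through the mean", {
  cal <- fit_calibration(table1)
  x <- seq(0.07, 0.49, length.out = 20)
  expect_true(all(diff(predict(cal, r2_over_eta = x)$cl) > 0))
  expect_true(predict(cal, r2_over_eta = 0.9)$extrapolated)
  expect_false(predict(cal, r2_over_eta = 0.3)$extrapolated)
  at_mean <- predict(cal, r2_over_eta = mean(cal$data$r2_over_eta))$cl
  expect_equal(at_mean, mean(cal$data$chain_length), tolerance = 1e-10)
})

test_that("the oleic acid row predicts 18 carbons", {
  cal <- fit_calibration(table1)
  p <- predict_chain_length(cal, r2_per_s = 6.524779, viscosity_cp = 17.6)
  expect_identical(p$cl_rounded, 18L)
  expect_false(p$extrapolated)
})

test_that("integer rounding breaks ties away from zero", {
  # slope 50, intercept 0: predictor 0.37 -> 18.5, which must round to 19
  cal <- fit_calibration(collinear_records)
  expect_identical(predict(cal, r2_over_eta = 0.37)$cl_rounded, 19L)
})

test_that("model methods expose coefficients, residuals and simulations coherently", {
  cal <- fit_calibration(table1)
  expect_named(coef(cal), c("b", "a"))
  expect_equal(unname(coef(cal)), c(cal$intercept_b, cal$slope_a))
  expect_length(residuals(cal), 17)
  expect_equal(unname(fitted(cal) + residuals(cal)), cal$data$chain_length,
               tolerance = 1e-12)
  s <- summary(cal)
  expect_s3_class(s, "summary.cl_calibration")
  expect_identical(nrow(s$residual_table), 17L)
  sims <- simulate(cal, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(17L, 3L))
})

test_that("leave-one-out errors behave as expected", {
  # perfectly collinear data: every held-out error is zero
  four <- rbind(collinear_records,
                data.frame(name = "d", chain_length = 20, r2_over_eta = 0.4,
                           state = "liquid"))
  loo <- loo_cross_validate(four)
  expect_equal(max(abs(loo$error)), 0, tolerance = 1e-9)

  loo1 <- loo_cross_validate(table1)
  expect_gte(attr(loo1, "loo_rmse"), attr(loo1, "in_sample_rmse"))

  # an injected gross outlier dominates the held-out errors
  spiked <- table1
  spiked$chain_length[5] <- 100
  loo2 <- loo_cross_validate(spiked)
  expect_identical(which.max(abs(loo2$error)), 5L)

  expect_error(loo_cross_validate(collinear_records), "at least 4")
})
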