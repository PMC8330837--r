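test_that("odd stages leave the pupil parameters bit-identical", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 1), defocus_coeffs(-0.8), cfg)
  fit <- fp_innm(stack, fp_control(stages = 1, epochs = 2))
  expect_identical(unname(fit$pupil$coeffs), rep(0, 9))
  expect_identical(fit$pupil$amp, fp_ctf(cfg))
  expect_equal(fit$stage_log$group, "object")
})

test_that("the data loss collapses on noiseless data without aberration", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 11), NULL, cfg)
  fit <- fp_innm(stack, fp_control(alpha1 = 0, alpha2 = 0))
  h <- fit$loss_history
  expect_equal(nrow(h), 50)                      # stages x epochs
  expect_lt(h$data[nrow(h)] / h$data[1], 0.01)

  # epoch-mean data loss is monotone-on-average across stages
  stage_means <- tapply(h$data, h$stage, mean)
  for (k in 2:length(stage_means)) {
    expect_lt(stage_means[k], 1.05 * stage_means[k - 1])
  }
})

test_that("reconstruction is reproducible bit-for-bit", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 2), defocus_coeffs(-0.8), cfg)
  ctl <- fp_control(stages = 4, epochs = 2, shuffle = TRUE, seed = 7)
  f1 <- fp_innm(stack, ctl)
  f2 <- fp_innm(stack, ctl)
  expect_identical(f1$object, f2$object)
  expect_identical(f1$pupil$coeffs, f2$pupil$coeffs)
  expect_identical(f1$loss_history$data, f2$loss_history$data)
})

test_that("the Zernike pupil model has L phase parameters, not a full map", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 3), defocus_coeffs(-0.5), cfg)
  fit <- fp_innm(stack, fp_control(stages = 2, epochs = 1, L = 9))
  expect_length(fit$pupil$coeffs, 9)
  expect_lt(length(fit$pupil$coeffs), cfg$lowres_size^2)
  # the phase map is fully determined by the coefficients
  expect_equal(fit$pupil$phase, pupil_phase(fit$pupil$coeffs,
                                            fit$pupil$basis))
})

test_that("a runaway step size triggers the divergence guard", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 4), NULL, cfg)
  expect_error(
    fp_innm(stack, fp_control(stages = 4, epochs = 2, lr_sample = 2e4,
                              alpha1 = 0, alpha2 = 0)),
    class = "fp_divergence")
})

test_that("pupil tilt is re-expressed as object registration (exact gauge)", {
  cfg <- small_cfg()
  truth_c <- c(0.3, -0.2, 0, -0.6, rep(0, 5))  # tilt + defocus
  stack <- fp_simulate(fp_phantom(64, seed = 5), truth_c, cfg)
  fit <- fp_innm(stack, fp_control())
  cc <- coef(fit)
  # tilt components are anchored to zero by convention
  expect_identical(unname(cc[1:2]), c(0, 0))
  # the non-tilt aberration is still recovered
  expect_equal(unname(cc[4]), -0.6, tolerance = 0.05 * 0.6)
  # and the gauge transfer does not change the predicted intensities:
  # the fit still explains the measured data
  h <- fit$loss_history
  pred <- fitted(fit)
  res <- mean(unlist(Map(function(a, b) (a - b)^2, pred, stack$images)))
  expect_lt(res, 5e-3 * mean(unlist(stack$images)^2))
})

test_that("per-epoch pupil accumulation is available and converges sanely", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 6), NULL, cfg)
  fit <- fp_innm(stack, fp_control(stages = 4, epochs = 2, accumulate = TRUE,
                                   alpha1 = 0, alpha2 = 0))
  h <- fit$loss_history
  expect_equal(nrow(h), 8)
  expect_lt(h$data[8], h$data[1])
})

test_that("recon methods expose the fit in the standard modelling idiom", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 7), defocus_coeffs(-0.8), cfg)
  fit <- fp_innm(stack, fp_control(stages = 4, epochs = 2))

  expect_s3_class(fit, "fp_recon")
  expect_named(coef(fit), paste0("Z", 1:9))
  expect_length(fitted(fit), length(stack$images))
  r <- residuals(fit)
  expect_equal(r[[1]], stack$images[[1]] - fitted(fit)[[1]])
  s <- summary(fit)
  expect_s3_class(s, "summary.fp_recon")
  expect_output(print(fit), "engine: innm")
  expect_output(print(s), "Zernike")
  # plotting runs without error on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
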