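test_that("a flat object under the ideal on-axis pupil gives a flat unit image", {
  cfg <- small_cfg()
  M <- 64L
  flat <- matrix(1 + 0i, M, M)
  I <- forward_intensity(flat, fp_ctf(cfg) * (1 + 0i), c(0L, 0L),
                         cfg$upsample_factor)
  expect_equal(I, matrix(1, 16, 16), tolerance = 1e-12)
})

test_that("Fourier-path forward equals the spatial-domain convolution oracle", {
  # 8x8 object, 4x4 low-res, random complex values, a tilted pupil
  s <- 2L; m <- 4L; M <- 8L
  obj <- random_complex(M, seed = 42)
  g <- fptycho:::freq_grid(m)
  amp <- (g$fx^2 + g$fy^2 < 1.8^2) * 1
  pupil <- amp * exp(1i * 0.3 * g$fx * amp)
  shift <- c(1L, -2L)
  I_fourier <- forward_intensity(obj, pupil, shift, s)

  # literal path: multiply by the tilted plane wave, convolve with the
  # inverse-transformed pupil, decimate, square the modulus
  xx <- matrix(0:(M - 1), M, M, byrow = TRUE); yy <- t(xx)
  w <- exp(-2i * pi * (shift[1] * yy + shift[2] * xx) / M)
  Chi <- fptycho:::embed_window(matrix(0i, M, M), pupil, c(0L, 0L))
  field <- stats::fft(stats::fft(obj * w) * fptycho:::ifftshift(Chi),
                      inverse = TRUE) / M^2
  I_spatial <- Mod(field[seq(1, M, by = s), seq(1, M, by = s)])^2
  expect_lt(rel_err(I_spatial, I_fourier), 1e-10)
})

test_that("total intensity obeys Parseval over the extracted passband", {
  s <- 2L; m <- 8L; M <- 16L
  obj <- random_complex(M, seed = 5)
  g <- fptycho:::freq_grid(m)
  pupil <- (g$fx^2 + g$fy^2 < 3^2) * (1 + 0i)
  shift <- c(2L, 1L)
  I <- forward_intensity(obj, pupil, shift, s)
  phi <- fptycho:::crop_window(fptycho:::ft2(obj), m, shift) * pupil
  expect_equal(sum(I), sum(Mod(phi)^2) / (m^2 * s^4), tolerance = 1e-10)
})

test_that("intensity is invariant to a global phase on the object", {
  cfg <- small_cfg()
  obj <- fp_phantom(64, seed = 3)
  st1 <- fp_simulate(obj, NULL, cfg)
  st2 <- fp_simulate(obj * exp(1i * 0.73), NULL, cfg)
  expect_equal(st1$images, st2$images, tolerance = 1e-12)
})

test_that("simulation is deterministic and matches the illumination table", {
  cfg <- small_cfg()
  obj <- fp_phantom(64, seed = 2)
  st1 <- fp_simulate(obj, defocus_coeffs(-0.8), cfg,
                     noise = fp_noise("gaussian", 0.01), seed = 9)
  st2 <- fp_simulate(obj, defocus_coeffs(-0.8), cfg,
                     noise = fp_noise("gaussian", 0.01), seed = 9)
  expect_identical(st1$images, st2$images)
  expect_equal(length(st1$images), nrow(st1$illumination))
  expect_true(all(vapply(st1$images, min, numeric(1)) >= 0))
  # ground truth is embedded
  expect_identical(st1$truth$object, obj)
  expect_equal(st1$truth$coeffs, defocus_coeffs(-0.8))
})

test_that("phantoms are bounded, seeded and distinct across seeds", {
  p1 <- fp_phantom(64, seed = 1)
  p1b <- fp_phantom(64, seed = 1)
  p2 <- fp_phantom(64, seed = 2)
  expect_identical(p1, p1b)
  expect_gt(mean(Mod(p1 - p2)) / mean(Mod(p1)), 0.01)
  expect_true(all(Mod(p1) >= 0.1 - 1e-12 & Mod(p1) <= 1 + 1e-12))
  expect_true(all(Arg(p1) >= -pi / 2 - 1e-12 & Arg(p1) <= pi / 2 + 1e-12))
  expect_error(fp_phantom(16), ">= 32")
})

test_that("noise specifications behave as declared", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 4), NULL, cfg)

  expect_identical(add_noise(stack, fp_noise("none"))$images, stack$images)
  expect_identical(add_noise(stack, fp_noise("gaussian", sigma = 0))$images,
                   stack$images)

  # Poisson: relative perturbation shrinks as 1 / sqrt(photon budget)
  rel_pert <- function(photons) {
    noisy <- add_noise(stack, fp_noise("poisson", photons = photons), seed = 2)
    num <- sqrt(mean(unlist(Map(function(a, b) (a - b)^2,
                                noisy$images, stack$images))))
    num / sqrt(mean(unlist(stack$images)^2))
  }
  r_small <- rel_pert(1e3)
  r_large <- rel_pert(1e5)
  expect_equal(r_small / r_large, 10, tolerance = 0.3)
  # non-negativity preserved
  noisy <- add_noise(stack, fp_noise("gaussian", 0.2), seed = 3)
  expect_true(all(vapply(noisy$images, min, numeric(1)) >= 0))
})

test_that("shifting by the center LED reduces to plain low-pass imaging", {
  cfg <- small_cfg()
  obj <- fp_phantom(64, seed = 6)
  stack <- fp_simulate(obj, NULL, cfg)
  ctr <- which(stack$illumination$pr == 0 & stack$illumination$pc == 0)[1]
  direct <- forward_intensity(obj, fp_ctf(cfg) * (1 + 0i), c(0L, 0L),
                              cfg$upsample_factor)
  expect_equal(stack$images[[ctr]], direct, tolerance = 1e-12)
})
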