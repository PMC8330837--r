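test_that("the initial guess upsamples the on-axis measurement with zero phase", {
  cfg <- small_cfg()
  stack <- fp_simulate(fp_phantom(64, seed = 1), NULL, cfg)
  g <- init_guess(stack, L = 9)
  expect_equal(dim(g$object), c(64L, 64L))
  expect_true(all(Arg(g$object) == 0))
  expect_identical(g$amp, fp_ctf(cfg))
  expect_equal(unname(g$coeffs), rep(0, 9))

  # flat unit center image -> flat unit object amplitude
  flat_stack <- stack
  ctr <- which(stack$illumination$pr == 0 & stack$illumination$pc == 0)[1]
  flat_stack$images[[ctr]] <- matrix(1, 16, 16)
  gf <- init_guess(flat_stack, L = 3)
  expect_equal(Mod(gf$object), matrix(1, 64, 64), tolerance = 1e-12)
})

test_that("aperture extraction matches explicit index arithmetic", {
  M <- 8L; m <- 4L
  O <- random_complex(M, seed = 11)
  g <- fptycho:::freq_grid(m)
  pupil <- (g$fx^2 + g$fy^2 < 1.8^2) * (1 + 0i)
  shift <- c(1L, -2L)
  got <- extract_aperture(O, pupil, shift)

  # oracle: the window's DC must land on the parent's DC + shift
  oracle <- matrix(0i, m, m)
  dcM <- floor(M / 2) + 1; dcm <- floor(m / 2) + 1
  for (i in 1:m) for (j in 1:m) {
    oracle[i, j] <- O[dcM + shift[1] + (i - dcm), dcM + shift[2] + (j - dcm)] *
      pupil[i, j]
  }
  expect_identical(got, oracle)

  # zero pupil amplitude blanks the field; off-grid shifts are rejected
  expect_equal(extract_aperture(O, pupil * 0, shift), matrix(0i, m, m))
  expect_error(extract_aperture(O, pupil, c(10L, 0L)), "off")
})

test_that("band-limited spectra pass unchanged through the ideal centered aperture", {
  M <- 16L; m <- 8L
  g <- fptycho:::freq_grid(m)
  disk <- (g$fx^2 + g$fy^2 < 3^2)
  O <- matrix(0i, M, M)
  O <- fptycho:::embed_window(O, disk * random_complex(m, seed = 2), c(0L, 0L))
  got <- extract_aperture(O, disk * (1 + 0i), c(0L, 0L))
  expect_identical(got[disk], fptycho:::crop_window(O, m)[disk])
})

test_that("amplitude replacement has the AP fixed-point and projection properties", {
  s <- 2L
  phi <- random_complex(4, seed = 21)
  E <- fptycho:::ift2(phi) / s^2
  self <- Mod(E)^2
  expect_lt(rel_err(ap_update(phi, self, s), phi), 1e-12)

  # direct DFT oracle on a different measurement
  set.seed(22); I <- matrix(runif(16), 4)
  Es <- idft2_ref(fptycho:::ifftshift(phi)) / s^2
  phasor <- ifelse(Mod(Es) > 0, Es / Mod(Es), 1 + 0i)
  oracle <- fptycho:::fftshift(dft2_ref(sqrt(I) * phasor)) * s^2
  got <- ap_update(phi, I, s)
  expect_lt(rel_err(got, oracle), 1e-10)

  # idempotent: a second application changes nothing
  expect_lt(rel_err(ap_update(got, I, s), got), 1e-12)

  # zero-modulus convention: phasor 1, so a flat unit measurement maps the
  # zero spectrum to a unit spatial field (delta at DC)
  zero <- matrix(0i, 4, 4)
  out <- ap_update(zero, matrix(1, 4, 4), s)
  expect_equal(fptycho:::ift2(out) / s^2, matrix(1 + 0i, 4, 4),
               tolerance = 1e-12)

  expect_error(ap_update(phi, -I, s), ">= 0")
})

test_that("total variation matches the printed worked example and scales", {
  # image [[0, 1], [2, 3]] with zero-padded forward differences
  x <- matrix(c(0, 2, 1, 3), 2)
  expect_equal(tv(x), sqrt(5) + 2 + 1)
  expect_equal(tv(x * 3), 3 * tv(x))            # eta = 1 homogeneity
  expect_equal(tv(matrix(7, 5, 5)), 0)
  expect_gt(tv(x, eta = 2), 0)
})

test_that("the TV gradient agrees with finite differences", {
  set.seed(33)
  x <- matrix(rnorm(49), 7)
  g <- fptycho:::tv_grad(x, eta = 1)
  h <- 1e-6
  for (k in c(1, 13, 25, 49)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    fd <- (tv(xp) - tv(xm)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-4)
  }
})

test_that("the combined loss reduces to the data term and matches direct sums", {
  s <- 2L
  phi_l <- random_complex(8, seed = 41)
  phi_h <- random_complex(8, seed = 42)
  same <- fp_total_loss(phi_l, phi_l)
  expect_equal(same$total, 0)

  plain <- fp_total_loss(phi_h, phi_l)
  expect_equal(plain$total, sum(Mod(phi_h - phi_l)^2))
  expect_equal(plain$tv_amp, 0)

  full <- fp_total_loss(phi_h, phi_l, alpha1 = 0.2, alpha2 = 0.4, factor = s)
  Phi <- fptycho:::ift2(phi_h) / s^2
  expect_equal(full$total,
               sum(Mod(phi_h - phi_l)^2) + 0.2 * tv(Mod(Phi)) +
                 0.4 * tv(Arg(Phi)), tolerance = 1e-12)
})
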