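# Forward imaging model. A thin sample o(r) illuminated by the n-th LED's
# tilted plane wave is imaged through the objective; in the Fourier domain
# this samples the object spectrum O(k) on a shifted copy of the pupil:
# phi_n(k) = O(k + k_n) C(k), and the camera records |F^{-1} phi_n|^2 on
# the low-resolution grid. Downsampling is realized purely by cropping the
# central low-res window of the high-res spectrum; because the two grids
# share the same Fourier bin width this is exact. Intensities are scaled so
# a unit-amplitude flat object under the ideal on-axis pupil gives a flat
# image of ones.

#' Low-resolution intensity image for one illumination angle
#'
#' Fourier-domain forward model: shift-crop the high-resolution object
#' spectrum at the given aperture center, multiply by the complex pupil,
#' inverse transform, and square the modulus. Equivalent (to floating
#' precision) to the spatial-domain picture of multiplying the object by
#' the tilted plane wave, convolving with the coherent PSF and decimating.
#'
#' @param obj high-resolution complex object (side \code{factor} times the
#'   pupil side).
#' @param pupil complex pupil matrix on the low-resolution grid
#'   (amplitude times \code{exp(i phase)}).
#' @param shift integer aperture-center offset \code{c(pr, pc)} on the
#'   Fourier grid.
#' @param factor integer upsampling factor relating the two grids.
#' @return Real non-negative intensity matrix on the low-resolution grid.
#' @export
forward_intensity <- function(obj, pupil, shift = c(0L, 0L), factor) {
  m <- nrow(pupil)
  if (nrow(obj) != m * factor || ncol(obj) != ncol(pupil) * factor)
    stop("object side must be factor x pupil side", call. = FALSE)
  E <- lowres_field(ft2(obj), pupil, shift, factor)
  Re(E)^2 + Im(E)^2
}

# complex low-res field from a high-res spectrum (shared by simulator and
# reconstructors); the 1/factor^2 keeps the flat-field at unit amplitude
lowres_field <- function(O, pupil, shift, factor) {
  phi <- crop_window(O, nrow(pupil), shift) * pupil
  ift2(phi) / factor^2
}

#' Synthetic complex phantom
#'
#' Deterministic complex test object: the amplitude mixes smooth Gaussian
#' blobs with sharp bars and lies in [0.1, 1]; the phase is an independent
#' pattern of the same family scaled to [-pi/2, pi/2]. Stands in for the
#' natural test images used in the FP literature.
#'
#' @param size grid side, pixels (>= 32).
#' @param kind \code{"mixed"} (blobs + bars, default), \code{"smooth"}
#'   (blobs only) or \code{"bars"}.
#' @param seed integer seed; the same seed reproduces the phantom exactly.
#' @return Complex \code{size x size} matrix.
#' @export
fp_phantom <- function(size, kind = c("mixed", "smooth", "bars"), seed = 1L) {
  kind <- match.arg(kind)
  if (size < 32) stop("phantom size must be >= 32", call. = FALSE)
  with_seed(seed, {
    amp <- phantom_pattern(size, kind)
    ph <- phantom_pattern(size, kind)
    amp <- 0.1 + 0.9 * amp
    ph <- (ph - 0.5) * pi
    amp * exp(1i * ph)
  })
}

# scalar pattern in [0, 1]; consumes the current RNG stream
phantom_pattern <- function(size, kind) {
  x <- matrix(rep(seq(0, 1, length.out = size), each = size), size, byrow = TRUE)
  y <- t(x)
  z <- matrix(0, size, size)
  if (kind %in% c("mixed", "smooth")) {
    for (b in seq_len(8)) {
      cx <- stats::runif(1); cy <- stats::runif(1)
      s <- stats::runif(1, 0.05, 0.25); a <- stats::runif(1, -1, 1)
      z <- z + a * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    }
  }
  if (kind %in% c("mixed", "bars")) {
    nb <- 4L
    for (b in seq_len(nb)) {
      x0 <- stats::runif(1, 0.1, 0.8); w <- stats::runif(1, 0.02, 0.08)
      a <- stats::runif(1, 0.3, 1)
      horiz <- stats::runif(1) > 0.5
      u <- if (horiz) y else x
      z <- z + a * (u >= x0 & u < x0 + w)
    }
  }
  rng <- range(z)
  if (diff(rng) < .Machine$double.eps) return(matrix(0.5, size, size))
  (z - rng[1]) / diff(rng)
}

#' Noise specification for simulated stacks
#'
#' @param type \code{"none"}, \code{"gaussian"} or \code{"poisson"}.
#' @param sigma Gaussian standard deviation, as a fraction of the peak
#'   intensity of the stack.
#' @param photons Poisson photon budget: expected counts per unit
#'   intensity; relative fluctuations shrink as \code{1/sqrt(photons)}.
#' @return An object of class \code{fp_noise}.
#' @export
fp_noise <- function(type = c("none", "gaussian", "poisson"),
                     sigma = 0.02, photons = 1e4) {
  type <- match.arg(type)
  if (type == "gaussian" && sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (type == "poisson" && photons <= 0) stop("photons must be > 0", call. = FALSE)
  structure(list(type = type, sigma = sigma, photons = photons),
            class = "fp_noise")
}

#' Apply measurement noise to a stack
#'
#' Gaussian noise is additive with standard deviation
#' \code{sigma * max(I)}; Poisson noise draws
#' \code{rpois(photons * I) / photons}. Intensities are clipped at zero.
#'
#' @param stack an \code{\link{fp_simulate}} stack.
#' @param spec an \code{\link{fp_noise}} specification.
#' @param seed integer seed.
#' @return The stack with noisy images (ground truth retained).
#' @export
add_noise <- function(stack, spec, seed = 1L) {
  stopifnot(inherits(stack, "fp_stack"), inherits(spec, "fp_noise"))
  if (spec$type == "none" || (spec$type == "gaussian" && spec$sigma == 0))
    return(stack)
  peak <- max(vapply(stack$images, max, numeric(1)))
  stack$images <- with_seed(seed, lapply(stack$images, function(im) {
    noisy <- switch(spec$type,
      gaussian = im + stats::rnorm(length(im), sd = spec$sigma * peak),
      poisson = stats::rpois(length(im), pmax(im, 0) * spec$photons) / spec$photons)
    matrix(pmax(noisy, 0), nrow(im), ncol(im))
  }))
  stack$noise <- spec
  stack
}

#' Simulate a Fourier ptychography measurement stack
#'
#' Generates one low-resolution intensity image per LED from a known
#' complex object and a known Zernike aberration, using the same forward
#' model as the reconstructors. The ground truth (object and coefficients)
#' is embedded in the result for later evaluation. Simulation is noiseless
#' by default.
#'
#' @param object high-resolution complex matrix
#'   (side \code{lowres_size * upsample_factor}).
#' @param coeffs Zernike aberration coefficients, radians, for modes OSA
#'   1..L (piston excluded); \code{NULL} or all-zero for an ideal pupil.
#' @param cfg an \code{\link{fp_system}}.
#' @param noise an \code{\link{fp_noise}} spec (default: none).
#' @param seed integer seed for the noise draw.
#' @return Object of class \code{fp_stack}: list with \code{images}
#'   (list of matrices, ordered as \code{illumination$seq}),
#'   \code{illumination}, \code{config}, \code{truth}
#'   (\code{object}, \code{coeffs}), \code{noise}, \code{seed}.
#' @examples
#' cfg <- fp_system(lowres_size = 16, upsample_factor = 2,
#'                  led_rows = 3, led_cols = 3)
#' obj <- fp_phantom(32, seed = 7)
#' stack <- fp_simulate(obj, coeffs = NULL, cfg = cfg)
#' length(stack$images)
#' @export
fp_simulate <- function(object, coeffs = NULL, cfg = fp_system(),
                        noise = fp_noise("none"), seed = 1L) {
  stopifnot(inherits(cfg, "fp_system"))
  M <- hires_size(cfg)
  if (!all(dim(object) == c(M, M)))
    stop("object must be ", M, "x", M, " for this configuration", call. = FALSE)
  ill <- led_illumination(cfg)
  amp <- fp_ctf(cfg)
  if (is.null(coeffs)) coeffs <- numeric(0)
  if (length(coeffs) > 0) {
    basis <- zernike_basis(length(coeffs), cfg, first = 1L)
    pupil <- amp * exp(1i * pupil_phase(coeffs, basis))
  } else {
    pupil <- amp * (1 + 0i)
  }
  O <- ft2(object)
  s <- cfg$upsample_factor
  images <- lapply(seq_len(nrow(ill)), function(n) {
    E <- lowres_field(O, pupil, c(ill$pr[n], ill$pc[n]), s)
    Re(E)^2 + Im(E)^2
  })
  stack <- structure(list(images = images, illumination = ill, config = cfg,
                          truth = list(object = object, coeffs = coeffs),
                          noise = fp_noise("none"), seed = seed),
                     class = "fp_stack")
  add_noise(stack, noise, seed)
}

#' @export
print.fp_stack <- function(x, ...) {
  m <- nrow(x$images[[1]])
  cat(sprintf("FP measurement stack: %d images of %dx%d (%s noise)\n",
              length(x$images), m, m, x$noise$type))
  cat(sprintf("  reconstruction grid %dx%d, synthetic NA %.3f\n",
              hires_size(x$config), hires_size(x$config),
              synthetic_na(x$config)))
  if (!is.null(x$truth)) cat("  ground truth embedded\n")
  invisible(x)
}
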