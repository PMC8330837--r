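# Core reconstruction primitives shared by the gradient-based engine and
# the ePIE baseline: initial guess, aperture extraction, the alternating-
# projection (AP) amplitude-replacement step, and total variation.

#' Initial object and pupil guess
#'
#' The object starts as the bilinearly upsampled square root of the
#' center-LED (on-axis) intensity with zero phase; the pupil starts as the
#' ideal binary CTF with zero Zernike coefficients.
#'
#' @param stack an \code{\link{fp_simulate}}-style stack.
#' @param L number of Zernike aberration modes in the pupil model.
#' @return List with \code{object} (complex high-res matrix), \code{amp}
#'   (pupil amplitude), \code{coeffs} (zeros), \code{basis}.
#' @export
init_guess <- function(stack, L = 9L) {
  stopifnot(inherits(stack, "fp_stack"))
  cfg <- stack$config
  ill <- stack$illumination
  ctr <- which(ill$pr == 0L & ill$pc == 0L & ill$na_ill == min(ill$na_ill))[1]
  if (is.na(ctr))
    stop("no on-axis (center LED) measurement in the stack", call. = FALSE)
  amp0 <- bilinear_resize(sqrt(pmax(stack$images[[ctr]], 0)), hires_size(cfg))
  basis <- zernike_basis(L, cfg, first = 1L)
  list(object = amp0 * (1 + 0i),
       amp = fp_ctf(cfg),
       coeffs = stats::setNames(numeric(L), paste0("Z", seq_len(L))),
       basis = basis)
}

#' Extract a pupil-filtered aperture from a high-resolution spectrum
#'
#' Crops the low-resolution window of the DC-centered spectrum centered at
#' the given Fourier pixel shift and multiplies it elementwise by the
#' complex pupil: \code{phi(k) = O(k + k_n) C(k)}.
#'
#' @param spectrum DC-centered complex high-res spectrum.
#' @param pupil complex pupil matrix (low-res grid).
#' @param shift integer \code{c(pr, pc)} aperture center.
#' @return Complex low-resolution aperture spectrum.
#' @export
extract_aperture <- function(spectrum, pupil, shift = c(0L, 0L)) {
  crop_window(spectrum, nrow(pupil), shift) * pupil
}

#' Alternating-projection amplitude replacement
#'
#' Transforms the aperture spectrum to the spatial plane, keeps the phase
#' (pixels with zero modulus get phasor 1), replaces the modulus with the
#' square root of the measured intensity, and transforms back. This is the
#' orthogonal projection of the field onto the measured-amplitude set; it
#' is idempotent, and a self-consistent field is a fixed point.
#'
#' @param phi_l complex aperture spectrum.
#' @param measured non-negative measured intensity image (same size).
#' @param factor upsampling factor of the stack the measurement came from
#'   (keeps the field scale consistent with \code{\link{forward_intensity}}).
#' @return Updated complex aperture spectrum \code{phi_h}.
#' @export
ap_update <- function(phi_l, measured, factor = 1L) {
  if (any(measured < 0)) stop("measured intensities must be >= 0", call. = FALSE)
  if (!all(dim(phi_l) == dim(measured)))
    stop("aperture and measurement sizes differ", call. = FALSE)
  E <- ift2(phi_l) / factor^2
  mod <- Mod(E)
  phasor <- ifelse(mod > 0, E / mod, 1 + 0i)
  ft2(sqrt(measured) * phasor) * factor^2
}

#' Total variation of an image
#'
#' Forward-difference total variation
#' \code{sum((dx^2 + dy^2)^(eta/2))} with zero differences at the last
#' row/column; \code{eta = 1} is the standard isotropic TV.
#'
#' @param image real matrix.
#' @param eta positive exponent (default 1).
#' @return Scalar TV value.
#' @examples
#' tv(matrix(c(0, 2, 1, 3), 2))  # sqrt(5) + 2 + 1
#' @export
tv <- function(image, eta = 1) {
  stopifnot(eta > 0)
  d <- tv_diffs(image)
  sum((d$dx^2 + d$dy^2)^(eta / 2))
}

# forward differences, zero-padded at the trailing edge
tv_diffs <- function(image) {
  n <- nrow(image); m <- ncol(image)
  dy <- rbind(image[-1, , drop = FALSE] - image[-n, , drop = FALSE],
              matrix(0, 1, m))
  dx <- cbind(image[, -1, drop = FALSE] - image[, -m, drop = FALSE],
              matrix(0, n, 1))
  list(dx = dx, dy = dy)
}

# gradient of tv() wrt the image; eps smooths the kink at zero gradient
tv_grad <- function(image, eta = 1, eps = 1e-8) {
  d <- tv_diffs(image)
  w <- (d$dx^2 + d$dy^2 + eps)^(eta / 2 - 1) * eta
  px <- w * d$dx
  py <- w * d$dy
  n <- nrow(image); m <- ncol(image)
  # negative divergence of (px, py): adjoint of the forward differences
  gx <- cbind(matrix(0, n, 1), px[, -m, drop = FALSE]) - px
  gy <- rbind(matrix(0, 1, m), py[-n, , drop = FALSE]) - py
  gx + gy
}

#' Combined data and total-variation loss for one illumination unit
#'
#' The data term is the squared L2 norm of the complex difference between
#' the AP-updated and modeled aperture spectra; the regularization terms
#' are the TV of the amplitude and of the (principal-value) phase of the
#' spatial-domain field of \code{phi_h}, weighted by \code{alpha1} and
#' \code{alpha2}. With both weights zero this is exactly the plain
#' spectral data loss.
#'
#' @param phi_h,phi_l complex aperture spectra (same size).
#' @param alpha1,alpha2 TV weights for amplitude and phase (>= 0).
#' @param eta TV exponent.
#' @param factor upsampling factor (field scale, as in
#'   \code{\link{ap_update}}).
#' @return List: \code{total}, \code{data}, \code{tv_amp}, \code{tv_phase}.
#' @export
fp_total_loss <- function(phi_h, phi_l, alpha1 = 0, alpha2 = 0, eta = 1,
                          factor = 1L) {
  stopifnot(all(dim(phi_h) == dim(phi_l)))
  d <- phi_h - phi_l
  data <- sum(Re(d)^2 + Im(d)^2)
  tva <- tvp <- 0
  if (alpha1 > 0 || alpha2 > 0) {
    Phi <- ift2(phi_h) / factor^2
    if (alpha1 > 0) tva <- tv(Mod(Phi), eta)
    if (alpha2 > 0) tvp <- tv(Arg(Phi), eta)
  }
  list(total = data + alpha1 * tva + alpha2 * tvp,
       data = data, tv_amp = tva, tv_phase = tvp)
}
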