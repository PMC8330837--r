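#' Classical alternating-projection reconstruction with ePIE pupil recovery
#'
#' The iterative baseline: for every LED, the corresponding aperture of the
#' object spectrum is extracted (pupil-filtered), amplitude-replaced with
#' the square root of the measurement, and the standard ePIE pair of
#' conjugate-weighted updates is applied to the object patch and the
#' (free-form, non-parametric) pupil:
#' \deqn{O \mathrel{+}= \alpha \frac{C^*}{\max |C|^2} (\phi_h - \phi_l),
#'       \quad
#'       C \mathrel{+}= \beta \frac{O^*}{\max |O|^2} (\phi_h - \phi_l).}
#' The pupil is masked to the NA disk after each update. With
#' \code{beta_pupil = 0} this reduces to plain AP-based Fourier
#' ptychography; with both step sizes 0 it is the identity.
#'
#' @param stack an \code{\link{fp_simulate}} stack.
#' @param iters number of full sweeps over the LED set (default 50).
#' @param alpha_obj,beta_pupil object and pupil step sizes (default 1).
#' @param init_pupil optional complex pupil to start from (and, with
#'   \code{beta_pupil = 0}, to hold fixed); default ideal CTF.
#' @return An object of class \code{fp_recon} (engine \code{"epie"}); the
#'   recovered pupil is a free-form complex map, so \code{coef} on the
#'   result decomposes its phase into Zernike coefficients.
#' @export
fp_epie <- function(stack, iters = 50L, alpha_obj = 1, beta_pupil = 1,
                    init_pupil = NULL) {
  stopifnot(inherits(stack, "fp_stack"), iters >= 1,
            alpha_obj >= 0, beta_pupil >= 0)
  cfg <- stack$config
  s <- cfg$upsample_factor
  m <- cfg$lowres_size
  M <- hires_size(cfg)
  N <- length(stack$images)
  ill <- stack$illumination
  guess <- init_guess(stack, L = 9L)
  disk <- fp_ctf(cfg) > 0

  O <- ft2(guess$object)
  P <- if (is.null(init_pupil)) guess$amp * (1 + 0i) else init_pupil
  shifts <- cbind(ill$pr, ill$pc)
  images <- stack$images
  hist <- numeric(iters)
  first <- NA_real_

  for (it in seq_len(iters)) {
    resid <- 0
    for (n in seq_len(N)) {
      W <- crop_window(O, m, shifts[n, ])
      phi_l <- W * P
      E <- ift2(phi_l) / s^2
      resid <- resid + sum(abs(sqrt(images[[n]]) - Mod(E)))
      phi_h <- ap_update(phi_l, images[[n]], s)
      dphi <- phi_h - phi_l
      W_new <- W + alpha_obj * Conj(P) / max(Mod(P)^2) * dphi
      if (beta_pupil > 0) {
        P <- P + beta_pupil * Conj(W) / max(Mod(W)^2) * dphi
        P[!disk] <- 0
      }
      O <- embed_window(O, W_new - W, shifts[n, ])
    }
    hist[it] <- resid
    if (is.na(first)) first <- resid
    if (resid > 1e3 * first)
      stop(errorCondition(sprintf(
        "ePIE diverged at iteration %d (residual %.3g > 1000 x initial %.3g)",
        it, resid, first), class = "fp_divergence"))
  }

  structure(list(
    object = ift2(O), spectrum = O,
    pupil = list(amp = Mod(P), coeffs = NULL, basis = guess$basis,
                 complex = P, phase = Arg(P) * disk),
    loss_history = data.frame(epoch = seq_len(iters), stage = NA_integer_,
                              group = "both", data = hist, tv_amp = 0,
                              tv_phase = 0, total = hist),
    stage_log = data.frame(stage = 1L, group = "both"),
    alpha = c(alpha1 = 0, alpha2 = 0),
    control = list(iters = iters, alpha_obj = alpha_obj,
                   beta_pupil = beta_pupil),
    engine = "epie", config = cfg, illumination = ill, images = images,
    truth = stack$truth, call = match.call()),
    class = "fp_recon")
}
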