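# Quantitative evaluation. Fourier ptychography recovers the object only
# up to a global phase (intensity measurements are blind to it), and only
# inside the synthetic-NA passband; both ambiguities are handled here
# before errors are reported.

#' Remove the global-phase ambiguity between two complex fields
#'
#' Multiplies the reconstruction by the unit phasor that maximizes the real
#' part of its inner product with the truth (closed form: the conjugate
#' phase of the inner product). If the inner product is exactly zero the
#' reconstruction is returned unchanged.
#'
#' @param recon,truth complex matrices of the same size.
#' @return The phase-aligned reconstruction.
#' @export
align_global_phase <- function(recon, truth) {
  stopifnot(all(dim(recon) == dim(truth)))
  ip <- sum(recon * Conj(truth))
  if (Mod(ip) == 0) return(recon)
  recon * Conj(ip) / Mod(ip)
}

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# low-pass a high-res complex field to the synthetic NA disk
band_limit_field <- function(x, cfg) {
  M <- nrow(x)
  r <- (synthetic_na(cfg) / cfg$wavelength_um) / freq_step(cfg)
  g <- freq_grid(M)
  ift2(ft2(x) * (g$fx^2 + g$fy^2 <= r^2))
}

#' Evaluate a reconstruction against ground truth
#'
#' Computes the relative L2 error of the amplitude, the RMSE of the
#' (wrapped) phase after global-phase alignment, and per-mode absolute
#' Zernike coefficient errors. By default the truth is first low-passed to
#' the synthetic-NA disk, since information beyond it is physically
#' unrecoverable from the measurements.
#'
#' @param result an \code{\link{fp_recon}}, or a complex matrix.
#' @param truth_obj complex ground-truth object; defaults to the ground
#'   truth embedded in the stack the result was fitted to.
#' @param truth_coeffs true Zernike coefficients (radians); defaults to the
#'   embedded ground truth.
#' @param band_limit low-pass the truth to the synthetic NA before
#'   comparison (default TRUE).
#' @return Object of class \code{fp_eval}: list with \code{amp_rel_error},
#'   \code{phase_rmse_rad}, \code{coeff_abs_error} (named vector, or NULL
#'   when no coefficients are available), \code{band_limited}.
#' @export
fp_evaluate <- function(result, truth_obj = NULL, truth_coeffs = NULL,
                        band_limit = TRUE) {
  if (inherits(result, "fp_recon")) {
    recon <- result$object
    cfg <- result$config
    if (is.null(truth_obj)) truth_obj <- result$truth$object
    if (is.null(truth_coeffs)) truth_coeffs <- result$truth$coeffs
    rec_coeffs <- coef(result)
  } else {
    recon <- result
    cfg <- NULL
    rec_coeffs <- NULL
  }
  if (is.null(truth_obj)) stop("no ground truth available", call. = FALSE)
  if (!all(dim(recon) == dim(truth_obj)))
    stop("reconstruction and truth sizes differ", call. = FALSE)
  truth <- truth_obj
  if (band_limit) {
    if (is.null(cfg))
      stop("band-limited comparison needs a system configuration; pass an ",
           "fp_recon or set band_limit = FALSE", call. = FALSE)
    truth <- band_limit_field(truth_obj, cfg)
  }
  aligned <- align_global_phase(recon, truth)
  amp_err <- sqrt(sum((Mod(aligned) - Mod(truth))^2) / sum(Mod(truth)^2))
  dphi <- wrap_phase(Arg(aligned) - Arg(truth))
  phase_rmse <- sqrt(mean(dphi^2))
  coeff_err <- NULL
  if (!is.null(rec_coeffs) && !is.null(truth_coeffs) &&
      length(truth_coeffs) > 0) {
    tc <- c(truth_coeffs, numeric(length(rec_coeffs)))[seq_along(rec_coeffs)]
    coeff_err <- abs(rec_coeffs - tc)
  }
  structure(list(amp_rel_error = amp_err, phase_rmse_rad = phase_rmse,
                 coeff_abs_error = coeff_err, band_limited = band_limit),
            class = "fp_eval")
}

#' @export
print.fp_eval <- function(x, ...) {
  cat("FP reconstruction evaluation",
      if (x$band_limited) "(truth band-limited to synthetic NA)\n" else "\n")
  cat(sprintf("  amplitude relative L2 error : %.4g\n", x$amp_rel_error))
  cat(sprintf("  phase RMSE                  : %.4g rad\n", x$phase_rmse_rad))
  if (!is.null(x$coeff_abs_error)) {
    cat("  |coefficient error| (rad)   :\n")
    print(round(x$coeff_abs_error, 4))
  }
  invisible(x)
}
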