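# S3 methods for fitted reconstructions.

#' Zernike coefficients of the recovered pupil
#'
#' For the gradient engine these are the fitted pupil-phase parameters
#' themselves; for the ePIE baseline, whose pupil is free-form, the
#' recovered pupil phase is decomposed onto the Zernike basis by least
#' squares.
#'
#' @param object an \code{fp_recon}.
#' @param ... unused.
#' @return Named numeric vector of coefficients (radians), OSA modes 1..L.
#' @export
coef.fp_recon <- function(object, ...) {
  if (!is.null(object$pupil$coeffs)) return(object$pupil$coeffs)
  stats::setNames(decompose_pupil(object$pupil$phase, object$pupil$basis),
                  paste0("Z", object$pupil$basis$index$j))
}

#' Predicted low-resolution intensities
#'
#' Runs the forward model with the fitted object and pupil for the given
#' illumination table. \code{fitted} predicts the stack the model was
#' fitted to; \code{residuals} returns measured minus fitted images.
#'
#' @param object an \code{fp_recon}.
#' @param illumination an illumination table (default: the one the model
#'   was fitted with).
#' @param ... unused.
#' @return A list of intensity matrices (\code{predict}, \code{fitted}) or
#'   of difference matrices (\code{residuals}).
#' @export
predict.fp_recon <- function(object, illumination = object$illumination, ...) {
  s <- object$config$upsample_factor
  lapply(seq_len(nrow(illumination)), function(n) {
    E <- lowres_field(object$spectrum, object$pupil$complex,
                      c(illumination$pr[n], illumination$pc[n]), s)
    Re(E)^2 + Im(E)^2
  })
}

#' @rdname predict.fp_recon
#' @export
fitted.fp_recon <- function(object, ...) predict(object)

#' @rdname predict.fp_recon
#' @export
residuals.fp_recon <- function(object, ...) {
  fit <- fitted(object)
  Map(function(meas, pred) meas - pred, object$images, fit)
}

#' @export
print.fp_recon <- function(x, ...) {
  M <- nrow(x$object)
  cat(sprintf("Fourier ptychography reconstruction (engine: %s)\n", x$engine))
  cat(sprintf("  object : %dx%d complex (synthetic NA %.3f)\n",
              M, M, synthetic_na(x$config)))
  if (!is.null(x$pupil$coeffs)) {
    cat("  pupil  : Zernike-parameterized phase, coefficients (rad):\n    ")
    cat(paste0(names(x$pupil$coeffs), "=",
               sprintf("%.3f", x$pupil$coeffs), collapse = " "), "\n")
  } else {
    cat("  pupil  : free-form complex map\n")
  }
  nh <- nrow(x$loss_history)
  cat(sprintf("  loss   : %.4g -> %.4g over %d epochs\n",
              x$loss_history$data[1], x$loss_history$data[nh], nh))
  invisible(x)
}

#' @export
summary.fp_recon <- function(object, ...) {
  h <- object$loss_history
  out <- list(engine = object$engine,
              n_images = length(object$images),
              epochs = nrow(h),
              data_first = h$data[1], data_last = h$data[nrow(h)],
              coeffs = if (!is.null(object$pupil$coeffs)) object$pupil$coeffs,
              alpha = object$alpha,
              stage_log = object$stage_log,
              eval = if (!is.null(object$truth$object))
                fp_evaluate(object) else NULL)
  class(out) <- "summary.fp_recon"
  out
}

#' @export
print.summary.fp_recon <- function(x, ...) {
  cat(sprintf("FP reconstruction summary (engine: %s)\n", x$engine))
  cat(sprintf("  %d measurements, %d epochs; data loss %.4g -> %.4g (x%.3g)\n",
              x$n_images, x$epochs, x$data_first, x$data_last,
              x$data_last / x$data_first))
  if (!is.null(x$coeffs)) {
    cat("  recovered Zernike coefficients (rad):\n")
    print(round(x$coeffs, 4))
  }
  cat(sprintf("  TV weights: alpha1 = %.3g, alpha2 = %.3g\n",
              x$alpha[1], x$alpha[2]))
  if (!is.null(x$eval)) {
    cat("  against embedded ground truth:\n")
    cat(sprintf("    amplitude rel. error %.4g, phase RMSE %.4g rad\n",
                x$eval$amp_rel_error, x$eval$phase_rmse_rad))
  }
  invisible(x)
}

#' Plot a reconstruction
#'
#' Side-by-side montage of the recovered amplitude, phase, pupil phase and
#' the loss trajectory.
#'
#' @param x an \code{fp_recon}.
#' @param ... unused.
#' @export
plot.fp_recon <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(2.5, 2.5, 2, 1))
  on.exit(graphics::par(op))
  img <- function(z, main) {
    graphics::image(t(z[rev(seq_len(nrow(z))), ]), col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  img(Mod(x$object), "amplitude")
  img(Arg(x$object), "phase")
  img(x$pupil$phase, "pupil phase")
  graphics::plot(x$loss_history$epoch, x$loss_history$data, type = "l",
                 log = "y", xlab = "epoch", ylab = "data loss",
                 main = "loss")
  invisible(x)
}
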