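# On-disk formats. A measurement stack is a multi-page 32-bit float TIFF
# (one page per LED, intensities normalized to [0, 1] by a scale recorded
# in the sidecar) plus a YAML sidecar carrying the system configuration,
# the illumination ordering, the noise spec and, for simulated data, the
# ground-truth Zernike coefficients; the ground-truth object travels as a
# separate two-page TIFF (amplitude, phase).

#' Write / read a measurement stack
#'
#' \code{write_stack} writes \code{<stem>.tif} (images),
#' \code{<stem>.yml} (sidecar) and, when ground truth is embedded,
#' \code{<stem>_truth.tif}. \code{read_stack} reverses it.
#'
#' @param stack an \code{\link{fp_simulate}} stack.
#' @param stem path stem (no extension).
#' @param bits 32 (float, default) or 16 (scaled unsigned integer).
#' @return \code{write_stack}: the stem, invisibly. \code{read_stack}: an
#'   \code{fp_stack}.
#' @export
write_stack <- function(stack, stem, bits = 32L) {
  stopifnot(inherits(stack, "fp_stack"), bits %in% c(16L, 32L))
  peak <- max(vapply(stack$images, max, numeric(1)), .Machine$double.eps)
  tiff::writeTIFF(lapply(stack$images, function(im) im / peak),
                  paste0(stem, ".tif"), bits.per.sample = as.integer(bits))
  side <- list(
    format = "fptycho-stack", version = 1L,
    intensity_scale = peak,
    config = unclass(stack$config),
    noise = unclass(stack$noise),
    seed = stack$seed,
    illumination = as.list(as.data.frame(stack$illumination)),
    truth_coeffs = if (!is.null(stack$truth) && length(stack$truth$coeffs))
      as.numeric(stack$truth$coeffs))
  yaml::write_yaml(side, paste0(stem, ".yml"))
  if (!is.null(stack$truth$object)) {
    obj <- stack$truth$object
    amp <- Mod(obj); ph <- Arg(obj)
    sc <- list(amp = max(amp, .Machine$double.eps))
    tiff::writeTIFF(list(amp / sc$amp, (ph + pi) / (2 * pi)),
                    paste0(stem, "_truth.tif"), bits.per.sample = 32L)
    side$truth_scale <- sc
    yaml::write_yaml(side, paste0(stem, ".yml"))
  }
  invisible(stem)
}

#' @rdname write_stack
#' @export
read_stack <- function(stem) {
  tif <- paste0(stem, ".tif"); yml <- paste0(stem, ".yml")
  if (!file.exists(tif) || !file.exists(yml))
    stop("stack files not found at stem: ", stem, call. = FALSE)
  side <- yaml::read_yaml(yml)
  if (!identical(side$format, "fptycho-stack"))
    stop("not an fptycho stack sidecar: ", yml, call. = FALSE)
  cfg <- do.call(fp_system,
                 side$config[names(side$config) %in% names(formals(fp_system))])
  pages <- tiff::readTIFF(tif, all = TRUE)
  images <- lapply(pages, function(p) p * side$intensity_scale)
  ill <- as.data.frame(side$illumination)
  class(ill) <- c("fp_illumination", "data.frame")
  truth <- NULL
  ttif <- paste0(stem, "_truth.tif")
  if (file.exists(ttif)) {
    tp <- tiff::readTIFF(ttif, all = TRUE)
    amp <- tp[[1]] * side$truth_scale$amp
    ph <- tp[[2]] * 2 * pi - pi
    truth <- list(object = amp * exp(1i * ph),
                  coeffs = as.numeric(side$truth_coeffs))
  } else if (!is.null(side$truth_coeffs)) {
    truth <- list(object = NULL, coeffs = as.numeric(side$truth_coeffs))
  }
  structure(list(images = images, illumination = ill, config = cfg,
                 truth = truth,
                 noise = do.call(fp_noise, side$noise),
                 seed = side$seed),
            class = "fp_stack")
}

#' Write a reconstruction result to a directory
#'
#' Writes amplitude and phase TIFFs of the recovered object, the pupil
#' phase TIFF, the Zernike coefficients as CSV, the loss history as CSV,
#' and a YAML manifest sufficient to reproduce the run.
#'
#' @param recon an \code{fp_recon}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_recon <- function(recon, dir) {
  stopifnot(inherits(recon, "fp_recon"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  amp <- Mod(recon$object)
  sc_amp <- max(amp, .Machine$double.eps)
  tiff::writeTIFF(amp / sc_amp, file.path(dir, "amplitude.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF((Arg(recon$object) + pi) / (2 * pi),
                  file.path(dir, "phase.tif"), bits.per.sample = 32L)
  pp <- recon$pupil$phase
  rng <- max(max(abs(pp)), .Machine$double.eps)
  tiff::writeTIFF((pp / rng + 1) / 2, file.path(dir, "pupil_phase.tif"),
                  bits.per.sample = 32L)
  cf <- coef(recon)
  write_coeffs(cf, file.path(dir, "coefficients.csv"))
  utils::write.csv(recon$loss_history, file.path(dir, "loss.csv"),
                   row.names = FALSE)
  ctl <- recon$control
  yaml::write_yaml(list(
    format = "fptycho-recon", version = 1L,
    engine = recon$engine,
    package_version = as.character(utils::packageVersion("fptycho")),
    amplitude_scale = sc_amp, pupil_phase_scale = rng,
    control = unclass(ctl)[!vapply(unclass(ctl), is.null, logical(1))],
    alpha = as.list(recon$alpha),
    config = unclass(recon$config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read a reconstruction result directory
#'
#' Reverses \code{\link{write_recon}}: reassembles the complex object from
#' the amplitude/phase TIFFs and scales in the manifest, and reads the
#' coefficients and loss history.
#'
#' @param dir directory written by \code{\link{write_recon}}.
#' @return List with \code{object} (complex matrix), \code{coeffs},
#'   \code{pupil_phase}, \code{loss_history}, \code{engine}, \code{config}.
#' @export
read_recon <- function(dir) {
  mf <- file.path(dir, "manifest.yml")
  if (!file.exists(mf)) stop("no manifest.yml in ", dir, call. = FALSE)
  man <- yaml::read_yaml(mf)
  if (!identical(man$format, "fptycho-recon"))
    stop("not an fptycho reconstruction manifest: ", mf, call. = FALSE)
  amp <- tiff::readTIFF(file.path(dir, "amplitude.tif")) * man$amplitude_scale
  ph <- tiff::readTIFF(file.path(dir, "phase.tif")) * 2 * pi - pi
  pp <- (tiff::readTIFF(file.path(dir, "pupil_phase.tif")) * 2 - 1) *
    man$pupil_phase_scale
  cfg <- do.call(fp_system,
                 man$config[names(man$config) %in% names(formals(fp_system))])
  list(object = amp * exp(1i * ph),
       coeffs = read_coeffs(file.path(dir, "coefficients.csv")),
       pupil_phase = pp,
       loss_history = utils::read.csv(file.path(dir, "loss.csv")),
       engine = man$engine, config = cfg)
}
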