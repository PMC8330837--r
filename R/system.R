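#' Optical system configuration for an LED-array Fourier ptychographic microscope
#'
#' Collects the geometric and optical parameters of the acquisition system:
#' illumination wavelength, LED grid geometry, objective numerical aperture
#' and magnification, camera pixel size, and the low-resolution /
#' high-resolution grid sizes. All downstream computations (wave vectors,
#' coherent transfer function, simulation, reconstruction) derive from this
#' object. The defaults describe a 15x15 LED matrix at 532 nm placed 90 mm
#' below the sample, imaged through a 2x / 0.1 NA objective onto a camera
#' with 3.45 um pixels, capturing 32x32 tiles reconstructed at 4x
#' upsampling (128x128).
#'
#' Derived quantities: the object-plane pixel pitch is
#' \code{camera_pixel_um / magnification}; the Fourier bin width (identical
#' on the low- and high-resolution grids, which is what makes Fourier-domain
#' aperture cropping exact) is \code{1 / (lowres_size * pitch)}.
#'
#' @param wavelength_um illumination wavelength in micrometers.
#' @param led_rows,led_cols LED grid dimensions.
#' @param led_pitch_mm distance between adjacent LEDs, mm.
#' @param led_distance_mm distance from the LED plane to the sample plane, mm.
#' @param na_obj objective numerical aperture, in (0, 1).
#' @param magnification objective magnification.
#' @param camera_pixel_um camera pixel size, micrometers.
#' @param lowres_size side length of the captured low-resolution images,
#'   pixels (even).
#' @param upsample_factor integer linear ratio between the high-resolution
#'   reconstruction grid and the low-resolution grid; at least 2.
#' @return An object of class \code{fp_system}.
#' @examples
#' cfg <- fp_system()
#' synthetic_na(cfg)    # ~0.50 for the default geometry
#' overlap_ratio(cfg)   # ~0.78
#' @export
fp_system <- function(wavelength_um = 0.532,
                      led_rows = 15L, led_cols = 15L,
                      led_pitch_mm = 4, led_distance_mm = 90,
                      na_obj = 0.1, magnification = 2,
                      camera_pixel_um = 3.45,
                      lowres_size = 32L, upsample_factor = 4L) {
  stopifnot(wavelength_um > 0, na_obj > 0, na_obj < 1,
            led_pitch_mm > 0, led_distance_mm > 0,
            magnification > 0, camera_pixel_um > 0,
            led_rows >= 1, led_cols >= 1)
  lowres_size <- as.integer(lowres_size)
  upsample_factor <- as.integer(upsample_factor)
  if (upsample_factor < 2L) stop("upsample_factor must be >= 2", call. = FALSE)
  if (lowres_size < 4L || lowres_size %% 2L != 0L)
    stop("lowres_size must be an even integer >= 4", call. = FALSE)
  cfg <- structure(list(
    wavelength_um = wavelength_um,
    led_rows = as.integer(led_rows), led_cols = as.integer(led_cols),
    led_pitch_mm = led_pitch_mm, led_distance_mm = led_distance_mm,
    na_obj = na_obj, magnification = magnification,
    camera_pixel_um = camera_pixel_um,
    lowres_size = lowres_size, upsample_factor = upsample_factor
  ), class = "fp_system")
  # fail early on non-physical geometry (cutoff must fit the grid)
  ctf_radius_px(cfg)
  cfg
}

# object-plane pixel pitch, micrometers
obj_pitch_um <- function(cfg) cfg$camera_pixel_um / cfg$magnification

# Fourier bin width shared by the low- and high-res grids, cycles/um
freq_step <- function(cfg) 1 / (cfg$lowres_size * obj_pitch_um(cfg))

hires_size <- function(cfg) cfg$lowres_size * cfg$upsample_factor

# pupil cutoff radius on the Fourier grid, pixels (fractional)
ctf_radius_px <- function(cfg) {
  r <- (cfg$na_obj / cfg$wavelength_um) / freq_step(cfg)
  if (r >= cfg$lowres_size / 2)
    stop("CTF cutoff radius (", round(r, 2), " px) reaches half the low-res ",
         "grid: the pupil would alias; increase lowres_size or reduce na_obj",
         call. = FALSE)
  r
}

#' @export
print.fp_system <- function(x, ...) {
  cat("Fourier ptychography system\n")
  cat(sprintf("  illumination : %dx%d LEDs, %.3g mm pitch, %.3g mm below sample, %g nm\n",
              x$led_rows, x$led_cols, x$led_pitch_mm, x$led_distance_mm,
              x$wavelength_um * 1000))
  cat(sprintf("  objective    : %gx / %.3g NA; camera pixel %.3g um\n",
              x$magnification, x$na_obj, x$camera_pixel_um))
  cat(sprintf("  grids        : %d -> %d px (upsample %dx), pitch %.4g um\n",
              x$lowres_size, hires_size(x), x$upsample_factor, obj_pitch_um(x)))
  cat(sprintf("  pupil cutoff : %.2f px;  synthetic NA %.3f;  overlap %.1f%%\n",
              ctf_radius_px(x), synthetic_na(x), 100 * overlap_ratio(x)))
  invisible(x)
}

#' LED illumination wave vectors
#'
#' Computes, for every LED of the grid, the dimensionless illumination
#' direction sines (NAx, NAy) and the corresponding integer pixel shift of
#' the sampled aperture on the high-resolution Fourier grid. The exact sine
#' (not the paraxial tangent) is used, since corner LEDs of a typical array
#' sit well outside the paraxial regime.
#'
#' Sign convention: an LED displaced by (dx, dy) mm from the optical axis
#' illuminates the sample with direction sines
#' \code{(-dx, -dy) / sqrt(dx^2 + dy^2 + h^2)} (h = LED-to-sample distance),
#' and the aperture extracted from the object spectrum is centered at the
#' Fourier pixel \code{round(na_shift / (wavelength * freq_step))}. The
#' simulator and both reconstruction engines share this table, so the
#' convention cancels end-to-end.
#'
#' LEDs are ordered center-outward (by illumination NA, ties broken by
#' azimuth), the standard acquisition/update ordering for Fourier
#' ptychography.
#'
#' @param cfg an \code{\link{fp_system}}.
#' @return A data frame of class \code{fp_illumination} with one row per
#'   LED: grid indices \code{row,col}, physical offsets \code{dx_mm,dy_mm},
#'   direction sines \code{nax,nay}, illumination NA \code{na_ill}, and
#'   integer Fourier pixel shifts \code{pr,pc} (row/column).
#' @examples
#' ill <- led_illumination(fp_system())
#' ill[1, c("na_ill", "pr", "pc")]  # center LED: on-axis, zero shift
#' @export
led_illumination <- function(cfg) {
  stopifnot(inherits(cfg, "fp_system"))
  h <- cfg$led_distance_mm
  rc <- expand.grid(row = seq_len(cfg$led_rows), col = seq_len(cfg$led_cols))
  # grid centered on the optical axis; x along columns, y along rows
  dy <- (rc$row - (cfg$led_rows + 1) / 2) * cfg$led_pitch_mm
  dx <- (rc$col - (cfg$led_cols + 1) / 2) * cfg$led_pitch_mm
  rr <- sqrt(dx^2 + dy^2 + h^2)
  nax <- -dx / rr
  nay <- -dy / rr
  na_ill <- sqrt(nax^2 + nay^2)
  # pixel shift of the aperture center on the (shared) Fourier grid
  pc <- as.integer(round(nax / cfg$wavelength_um / freq_step(cfg)))
  pr <- as.integer(round(nay / cfg$wavelength_um / freq_step(cfg)))
  ord <- order(na_ill, atan2(dy, dx), rc$row, rc$col)
  out <- data.frame(seq = seq_along(ord),
                    row = rc$row[ord], col = rc$col[ord],
                    dx_mm = dx[ord], dy_mm = dy[ord],
                    nax = nax[ord], nay = nay[ord], na_ill = na_ill[ord],
                    pr = pr[ord], pc = pc[ord])
  class(out) <- c("fp_illumination", "data.frame")
  out
}

#' Coherent transfer function of the objective
#'
#' Binary low-pass pupil on the low-resolution Fourier grid: 1 where the
#' radial spatial frequency is below \code{na_obj / wavelength}, 0 outside.
#' The grid is DC-centered.
#'
#' @param cfg an \code{\link{fp_system}}.
#' @return A \code{lowres_size x lowres_size} numeric 0/1 matrix.
#' @examples
#' C <- fp_ctf(fp_system())
#' C[17, 17]  # DC bin of a 32x32 grid -> 1
#' @export
fp_ctf <- function(cfg) {
  stopifnot(inherits(cfg, "fp_system"))
  m <- cfg$lowres_size
  r <- ctf_radius_px(cfg)
  g <- freq_grid(m)
  (g$fx^2 + g$fy^2 < r^2) * 1
}

#' Synthetic numerical aperture
#'
#' The resolution limit of the reconstruction: objective NA plus the largest
#' illumination NA across the LED array.
#'
#' @param cfg an \code{\link{fp_system}}.
#' @return Scalar synthetic NA.
#' @export
synthetic_na <- function(cfg) {
  cfg$na_obj + max(led_illumination(cfg)$na_ill)
}

#' Fourier-domain overlap ratio of adjacent apertures
#'
#' Fraction by which the pupil passbands of two adjacent LEDs overlap.
#' The default linear (1-D) definition is
#' \code{(2 na_obj - dNA) / (2 na_obj)} where \code{dNA} is the illumination
#' NA step between neighboring LEDs near the array center; the area
#' definition uses the lens-shaped intersection of the two pupil disks.
#' Both are clipped to [0, 1].
#'
#' @param cfg an \code{\link{fp_system}}.
#' @param method \code{"linear"} (default) or \code{"area"}.
#' @return Scalar overlap ratio in [0, 1].
#' @export
overlap_ratio <- function(cfg, method = c("linear", "area")) {
  method <- match.arg(method)
  h <- cfg$led_distance_mm
  p <- cfg$led_pitch_mm
  dna <- p / sqrt(p^2 + h^2)  # NA step one pitch off-axis
  R <- cfg$na_obj
  if (method == "linear") {
    ratio <- (2 * R - dna) / (2 * R)
  } else {
    d <- dna
    if (d >= 2 * R) {
      ratio <- 0
    } else {
      lens <- 2 * R^2 * acos(d / (2 * R)) - (d / 2) * sqrt(4 * R^2 - d^2)
      ratio <- lens / (pi * R^2)
    }
  }
  min(max(ratio, 0), 1)
}

#' Read / write a system configuration as YAML
#'
#' @param cfg an \code{\link{fp_system}}.
#' @param path file path.
#' @return \code{read_system} returns an \code{fp_system};
#'   \code{write_system} returns \code{path} invisibly.
#' @export
write_system <- function(cfg, path) {
  stopifnot(inherits(cfg, "fp_system"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  do.call(fp_system, x[names(x) %in% names(formals(fp_system))])
}
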