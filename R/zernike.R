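# Zernike polynomials on the pupil disk.
#
# Convention: OSA/ANSI single indexing j = (n(n+2) + m)/2, unnormalized
# radial polynomials (R_n^m(1) = 1; no sqrt(n+1) scaling), azimuthal factor
# cos(m theta) for m > 0, sin(|m| theta) for m < 0. The radial coordinate
# rho is the spatial frequency normalized by the objective cutoff
# na_obj / wavelength, so the basis lives exactly on the CTF support.

# OSA single index -> (n, m)
osa_nm <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  cbind(n = n, m = m)
}

# unnormalized radial polynomial R_n^|m|(rho)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Zernike basis on the pupil disk
#'
#' Evaluates the first \code{L} Zernike modes (OSA/ANSI single-index order,
#' unnormalized radial polynomials) on the low-resolution Fourier grid,
#' masked to the objective's NA disk. With \code{first = 0} the sequence
#' starts at piston; aberration models conventionally start at
#' \code{first = 1} (tilt), since piston is an unobservable global phase.
#'
#' @param L number of modes.
#' @param grid an \code{\link{fp_system}} (pupil grid and cutoff are
#'   derived), or a list with elements \code{size} (grid side, pixels) and
#'   \code{radius} (cutoff radius, pixels).
#' @param first OSA index of the first mode (default 0 = piston).
#' @return Object of class \code{zernike_basis}: list with \code{modes}
#'   (size x size x L array, zero outside the disk), \code{index}
#'   (data frame \code{j,n,m}), \code{mask} (logical disk), \code{radius}.
#' @examples
#' b <- zernike_basis(4, list(size = 32, radius = 10.4))
#' range(b$modes[, , 1][b$mask])  # piston: identically 1 on the disk
#' @export
zernike_basis <- function(L, grid, first = 0L) {
  stopifnot(L >= 1, first >= 0)
  if (inherits(grid, "fp_system")) {
    size <- grid$lowres_size
    radius <- ctf_radius_px(grid)
  } else {
    size <- grid$size
    radius <- grid$radius
  }
  if (radius < 4) stop("pupil radius below 4 pixels: grid too coarse for a ",
                       "Zernike fit", call. = FALSE)
  j <- seq.int(first, first + L - 1L)
  nm <- osa_nm(j)
  if (max(nm[, "n"]) > 20)
    stop("requested modes exceed radial order 20", call. = FALSE)
  g <- freq_grid(size)
  rho <- sqrt(g$fx^2 + g$fy^2) / radius
  theta <- atan2(g$fy, g$fx)
  mask <- rho <= 1
  modes <- array(0, dim = c(size, size, L))
  for (l in seq_len(L)) {
    n <- nm[l, "n"]; m <- nm[l, "m"]
    z <- zernike_radial(n, m, rho)
    if (m > 0) z <- z * cos(m * theta)
    if (m < 0) z <- z * sin(-m * theta)
    z[!mask] <- 0
    modes[, , l] <- z
  }
  structure(list(modes = modes,
                 index = data.frame(j = j, n = nm[, "n"], m = nm[, "m"]),
                 mask = mask, radius = radius, size = size),
            class = "zernike_basis")
}

#' @export
print.zernike_basis <- function(x, ...) {
  cat(sprintf("Zernike basis: %d modes (OSA %d..%d) on a %dx%d grid, cutoff %.2f px\n",
              nrow(x$index), min(x$index$j), max(x$index$j), x$size, x$size,
              x$radius))
  invisible(x)
}

#' Synthesize a pupil phase map from Zernike coefficients
#'
#' Weighted sum of the basis modes: the pupil phase is
#' \code{sum_l c_l Z_l(k)}, identically zero outside the NA disk.
#'
#' @param coeffs numeric vector of coefficients, radians; length must match
#'   the basis.
#' @param basis a \code{\link{zernike_basis}}.
#' @return A real phase map (matrix, radians).
#' @export
pupil_phase <- function(coeffs, basis) {
  stopifnot(inherits(basis, "zernike_basis"))
  L <- dim(basis$modes)[3]
  if (length(coeffs) != L)
    stop("coefficient vector length ", length(coeffs),
         " does not match basis with ", L, " modes", call. = FALSE)
  phase <- matrix(0, basis$size, basis$size)
  for (l in seq_len(L)) phase <- phase + coeffs[l] * basis$modes[, , l]
  phase
}

#' Least-squares Zernike decomposition of a pupil phase map
#'
#' Projects a (disk-masked) phase map onto the basis by regularized least
#' squares; a tiny ridge (1e-12) guards near-singular grids. Round trip
#' with \code{\link{pupil_phase}} recovers coefficients to numerical
#' precision.
#'
#' @param phase_map real matrix on the pupil grid, radians.
#' @param basis a \code{\link{zernike_basis}}.
#' @return Numeric coefficient vector (radians), named by OSA index.
#' @export
decompose_pupil <- function(phase_map, basis) {
  stopifnot(inherits(basis, "zernike_basis"))
  if (!all(dim(phase_map) == c(basis$size, basis$size)))
    stop("phase map does not match the basis grid", call. = FALSE)
  idx <- which(basis$mask)
  L <- dim(basis$modes)[3]
  G <- matrix(0, length(idx), L)
  for (l in seq_len(L)) G[, l] <- basis$modes[, , l][idx]
  A <- crossprod(G) + diag(1e-12, L)
  b <- crossprod(G, phase_map[idx])
  stats::setNames(drop(solve(A, b)), paste0("Z", basis$index$j))
}

#' Defocus distance to unnormalized defocus coefficient
#'
#' The pupil phase induced by a defocus of \code{z} is
#' \code{phi(rho) = (2 pi / lambda) z (sqrt(1 - NA^2 rho^2) - 1)} on the
#' unit disk. This function returns its least-squares projection onto the
#' unnormalized defocus mode \code{2 rho^2 - 1}; for small NA the closed
#' form is \code{-(2 pi / lambda) z NA^2 / 4}. 50 um of defocus at 532 nm
#' under a 0.1 NA objective gives about -1.48 rad.
#'
#' @param defocus_um defocus distance, micrometers (signed).
#' @param na objective numerical aperture, in (0, 1).
#' @param wavelength_um wavelength, micrometers.
#' @return Defocus coefficient, radians (odd and monotone in the defocus).
#' @examples
#' defocus_to_z20(50, 0.1, 0.532)   # ~ -1.48
#' @export
defocus_to_z20 <- function(defocus_um, na, wavelength_um) {
  stopifnot(na > 0, na < 1, wavelength_um > 0)
  if (defocus_um == 0) return(0)
  k0 <- 2 * pi / wavelength_um
  phi <- function(rho) k0 * defocus_um * (sqrt(1 - (na * rho)^2) - 1)
  # <phi, Z> / <Z, Z> over the unit disk; Z = 2 rho^2 - 1, <Z,Z> = pi/3
  num <- stats::integrate(function(r) phi(r) * (2 * r^2 - 1) * r,
                          0, 1, rel.tol = 1e-12)$value
  num / (1 / 6)
}

#' Read / write Zernike coefficient vectors
#'
#' CSV columns / JSON fields: \code{index} (OSA), \code{n}, \code{m},
#' \code{value_rad}.
#'
#' @param coeffs numeric coefficient vector, radians.
#' @param path file path (extension selects CSV vs JSON).
#' @param first OSA index of the first coefficient (default 1: aberrations
#'   exclude piston).
#' @return \code{read_coeffs} returns a named numeric vector.
#' @export
write_coeffs <- function(coeffs, path, first = 1L) {
  nm <- osa_nm(seq.int(first, first + length(coeffs) - 1L))
  df <- data.frame(index = seq.int(first, first + length(coeffs) - 1L),
                   n = nm[, "n"], m = nm[, "m"], value_rad = as.numeric(coeffs))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_coeffs
#' @export
read_coeffs <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  stats::setNames(df$value_rad, paste0("Z", df$index))
}
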