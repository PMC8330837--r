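# Fourier helpers. Convention used throughout the package:
#   * spatial arrays are plain matrices with the origin at [1, 1];
#   * spectra are stored DC-centered, with the zero-frequency bin at
#     [floor(n/2) + 1, floor(n/2) + 1].
# ft2()/ift2() convert between the two; they are exact inverses.

#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  i <- c(seq_len(d[1] - floor(d[1] / 2)) + floor(d[1] / 2), seq_len(floor(d[1] / 2)))
  j <- c(seq_len(d[2] - floor(d[2] / 2)) + floor(d[2] / 2), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x)
  i <- c(seq_len(floor(d[1] / 2)) + ceiling(d[1] / 2), seq_len(ceiling(d[1] / 2)))
  j <- c(seq_len(floor(d[2] / 2)) + ceiling(d[2] / 2), seq_len(ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

# spatial -> DC-centered spectrum (unnormalized DFT)
ft2 <- function(x) fftshift(stats::fft(x))

# DC-centered spectrum -> spatial (1/n^2-normalized inverse DFT)
ift2 <- function(X) stats::fft(ifftshift(X), inverse = TRUE) / length(X)

# index of the DC bin of a DC-centered grid of side n
dc_index <- function(n) floor(n / 2) + 1L

# DC-centered integer frequency coordinates of a side-n grid, as matrices
freq_grid <- function(n) {
  f <- seq_len(n) - dc_index(n)
  list(fy = matrix(f, n, n), fx = matrix(f, n, n, byrow = TRUE))
}

# crop the m x m window of a DC-centered N x N spectrum whose own DC bin
# sits at the parent's DC + (shift_r, shift_c); errors if off-grid
crop_window <- function(X, m, shift = c(0L, 0L)) {
  n <- nrow(X)
  r0 <- dc_index(n) + shift[1L] - dc_index(m)
  c0 <- dc_index(n) + shift[2L] - dc_index(m)
  if (r0 < 0L || c0 < 0L || r0 + m > n || c0 + m > n)
    stop("aperture shift (", shift[1L], ", ", shift[2L],
         ") moves the crop window off the spectrum grid", call. = FALSE)
  X[r0 + seq_len(m), c0 + seq_len(m), drop = FALSE]
}

# adjoint of crop_window: add a small m x m block into an N x N grid
embed_window <- function(X, block, shift = c(0L, 0L)) {
  n <- nrow(X)
  m <- nrow(block)
  r0 <- dc_index(n) + shift[1L] - dc_index(m)
  c0 <- dc_index(n) + shift[2L] - dc_index(m)
  X[r0 + seq_len(m), c0 + seq_len(m)] <- X[r0 + seq_len(m), c0 + seq_len(m)] + block
  X
}

# separable bilinear upsampling of a matrix to side `out` (used for the
# initial object guess; endpoints replicated). Corner-aligned: low-res
# pixel j maps to high-res pixel s*j, matching Fourier-domain decimation,
# so the initial guess is not displaced relative to the forward model.
bilinear_resize <- function(x, out) {
  n <- nrow(x)
  if (n == out) return(x)
  pos <- (seq_len(out) - 1) * n / out + 1
  pos <- pmin(pmax(pos, 1), n)
  tmp <- apply(x, 2L, function(col) stats::approx(seq_len(n), col, xout = pos)$y)
  t(apply(tmp, 1L, function(row) stats::approx(seq_len(n), row, xout = pos)$y))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
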