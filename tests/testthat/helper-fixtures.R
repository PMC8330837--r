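# Shared fixtures: all inputs are generated in code at test time.

# the acquisition geometry used throughout the package's validation:
# 15x15 LEDs at 532 nm, 4 mm pitch, 90 mm distance, 2x/0.1 NA, 3.45 um
# camera pixels, 32 -> 128 px reconstruction
paper_cfg <- function() fp_system()

# small, fast geometry: 16 -> 64 px, 9x9 LEDs with a wider pitch so the
# synthetic NA still reaches ~0.5
small_cfg <- function() {
  fp_system(lowres_size = 16, upsample_factor = 4,
            led_rows = 9, led_cols = 9, led_pitch_mm = 7)
}

# aberration vector with a single defocus component (OSA mode 4) among the
# first nine modes after piston
defocus_coeffs <- function(z20) c(0, 0, 0, z20, rep(0, 5))

# brute-force 2-D DFT matrices for oracle computations
dft_mat <- function(n) outer(0:(n - 1), 0:(n - 1),
                             function(j, k) exp(-2i * pi * j * k / n))
dft2_ref <- function(z) { Fm <- dft_mat(nrow(z)); Fm %*% z %*% Fm }
idft2_ref <- function(z) {
  Fm <- dft_mat(nrow(z)); (Conj(Fm) %*% z %*% Conj(Fm)) / length(z)
}

rel_err <- function(a, b) max(Mod(a - b)) / max(Mod(b))

random_complex <- function(n, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
}
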