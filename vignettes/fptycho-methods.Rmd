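---
title: "Fourier ptychographic reconstruction with Zernike aberration recovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier ptychographic reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The imaging model

Fourier ptychographic microscopy (FPM) records a sequence of low-resolution
intensity images of a thin sample under angle-varied plane-wave
illumination from an LED matrix. With the sample described by its complex
transmission $o(\mathbf r)$ and the $n$-th LED imposing a wave vector
$\mathbf k_n$, the camera records

$$ I_n(\mathbf r) \;=\; \bigl|\, \{o(\mathbf r)\, e^{i \mathbf k_n \cdot
\mathbf r}\} \ast \mathcal F^{-1}\{C(\mathbf k)\} \,\bigr|^2 , $$

where $C(\mathbf k)$ is the coherent transfer function (CTF) of the
objective: an ideal objective passes frequencies inside the disk
$|\mathbf k| < \mathrm{NA} \cdot 2\pi/\lambda$ unchanged. Equivalently, in
the Fourier domain each LED samples a shifted circular aperture of the
object spectrum $O(\mathbf k)$:

$$ \varphi_n(\mathbf k) = O(\mathbf k + \mathbf k_n)\, C(\mathbf k), $$

and the measurement is the squared modulus of its inverse transform on the
low-resolution grid. `fptycho` implements this forward model once
(`forward_intensity()`, `extract_aperture()`) and shares it between the
simulator and both reconstruction engines. Two conventions fix everything
else:

* **DC-centered spectra.** All spectra are stored with the zero-frequency
  bin at the array center; aperture extraction is a plain shifted crop.
  The low- and high-resolution grids share the same Fourier bin width
  ($1/(m \cdot \Delta x)$ with $m$ the capture side and $\Delta x$ the
  object-plane pixel pitch), so Fourier cropping is an exact downsampling
  model. Wave-vector-to-pixel conversion rounds to the nearest integer
  bin; sub-pixel shifts are out of scope.
* **Radiometric scale.** A unit-amplitude flat object under the ideal
  on-axis pupil yields a flat image of ones. No absolute radiometry is
  modeled.

Illumination angles use the exact sine, not the paraxial tangent: a corner
LED of a 15×15 array at 4 mm pitch and 90 mm distance sits at 24° off
axis, well outside the paraxial regime. For that reference geometry the
synthetic numerical aperture is $\mathrm{NA}_{obj} + \max_n
\mathrm{NA}_n \approx 0.50$ and the linear overlap of adjacent pupil
passbands is $\approx 78\%$ (the area-based definition, $\approx 72\%$, is
available via `overlap_ratio(cfg, "area")`).

## Aberrations as Zernike pupil phase

Real objectives aberrate: the pupil becomes $C(\mathbf k) = |C(\mathbf
k)|\, e^{i \angle C(\mathbf k)}$. Estimating $\angle C$ as a free map
(one parameter per pupil pixel) is badly conditioned — with a periodic LED
grid it picks up raster-grid artifacts. The package therefore
parameterizes the pupil phase in a Zernike basis on the NA disk,

$$ \angle C(\mathbf k) = \sum_{l=1}^{L} c_l Z_l(\mathbf k), $$

with OSA/ANSI single indexing, *unnormalized* radial polynomials (peak 1 at
the rim), and $\rho$ normalized by the objective cutoff so the basis lives
exactly on the CTF support. Piston is excluded (a global phase). The
default $L = 9$ — tilt through trefoil — covers the common microscope
aberrations; up to $L = 50$ is supported for severe cases. The
unnormalized convention matters for reporting: 50 µm of defocus at 532 nm
under a 0.1 NA objective corresponds to a defocus coefficient of about
$-1.48$ rad in this convention (`defocus_to_z20(50, 0.1, 0.532)`; the
orthonormal convention would give $-0.85$ for the same wavefront).

The pupil *amplitude* remains a free map on the disk (clamped to $[0,1]$),
optimized optionally (`optimize_pupil_amplitude`).

## The gradient reconstructor

`fp_innm()` treats reconstruction as fitting a differentiable forward
graph. The learnable parameters are the two-channel (real, imaginary)
high-resolution object spectrum, the Zernike coefficient vector, and the
pupil amplitude map. For each varying-angle illumination unit (VAIU — one
image plus its wave vector) the graph computes
$\varphi_n = O(\cdot + \mathbf k_n) C$, applies the alternating-projection
(AP) amplitude replacement

$$ \varphi^h_n = \mathcal F \bigl\{ \sqrt{I_n} \cdot
\mathrm{phasor}\{\mathcal F^{-1} \varphi_n\} \bigr\}, $$

and scores the spectral data loss $\|\varphi^h_n - \varphi_n\|_2^2$. The
AP step is the orthogonal projection of the field onto the set of fields
with the measured amplitude; by the projection theorem the gradient of the
data loss with respect to $\varphi_n$ is exactly $2(\varphi_n -
\varphi^h_n)$, and the chain rule through the (linear) crop and the
(elementwise) pupil product yields closed-form Wirtinger gradients for all
three parameter groups. These are the same gradients reverse-mode
automatic differentiation of the graph would produce; the test suite
verifies every pathway against central finite differences. Zero-modulus
pixels use phasor 1, avoiding the undefined 0/0 direction.

Two details of the replacement step are deliberate. First, the amplitude
constraint uses $\sqrt{I_n}$ — the physically meaningful quantity whose
fixed point is self-consistency. Second, the updated spectrum acts as the
projection *target*; its own dependence on the parameters contributes
nothing to the gradient (the projection residual is normal to the
constraint set).

### Update schedule and optimizers

The sample and the pupil have very different gradient scales and
sensitivities, so they are optimized in an alternating stage schedule
(default 10 stages × 5 epochs): odd stages update only the object, even
stages only the pupil, starting with the object against the ideal-CTF
assumption. Each group gets its own optimizer:

* **Object** — one batch gradient step per epoch: all VAIUs contribute to
  an accumulated spectrum gradient, which is then applied with step
  $\mathrm{lr}/2$ preconditioned by the spectral coverage map $\sum_n
  |P_n|^2$ (floored at 1). At `lr_sample = 1` with TV off this is the
  overlap-averaged AP replacement — the classical, fast-converging object
  update. Per-VAIU sequential object overwriting was rejected after
  experiments: the last LED to write each spectrum region stamps its phase
  preferentially, which translates the object by a fraction of a pixel and
  leaks a spurious tilt into the recovered pupil — the same tilt bias the
  free-form ePIE baseline exhibits.
* **Pupil phase and amplitude** — per-VAIU adaptive-moment (Adam) steps,
  `lr_pupil_phase = 1e-2` rad and `lr_pupil_amp = 1e-3`. These small,
  well-scaled groups benefit from per-parameter adaptivity; with the
  object held at truth this recovers an injected defocus of $-1.48$ rad to
  three decimals within ten epochs.

Setting `alternate = FALSE` reproduces the simultaneous single-optimizer
configuration (every group stepping with `lr_sample`); it fails
dramatically — coefficient errors of order $10^2$ rad — which is precisely
the failure mode that motivates the alternating schedule, and is asserted
as an ordering in the test suite. `accumulate = TRUE` extends per-epoch
accumulation to the pupil groups for users who want a pure batch method
(it then needs proportionally more stages or larger steps).

### The tilt–translation gauge

A pupil tilt $c_1 Z_1 + c_2 Z_2$ multiplies every aperture by the same
linear phase, which is exactly what a lateral translation of the object
does — up to a per-aperture constant phase that intensities cannot see.
The likelihood is therefore *exactly flat* along this two-parameter
direction: no data can apportion linear phase between "tilted pupil" and
"shifted sample". Following the wavefront-metrology convention that
piston, tip and tilt are displacement terms rather than aberrations,
`fp_innm()` anchors the gauge at the end of the run: the recovered tilt is
transferred into the object's registration (an exact symmetry operation
that leaves every predicted intensity unchanged) and the tilt coefficients
are reported as zero. The reconstruction may consequently sit a fraction
of a pixel off the ground-truth registration; evaluation metrics treat
this as part of the reconstruction error.

## Total-variation regularization

With automatic gradients, regularizers are cheap to add. The loss can be
augmented with total variation,

$$ \mathrm{TV}\{u\} = \sum_{x,y} \bigl( |u_{x+1,y} - u_{x,y}|^2 +
|u_{x,y+1} - u_{x,y}|^2 \bigr)^{\eta/2}, \qquad \eta = 1, $$

applied with weights $\alpha_1, \alpha_2$ to the amplitude and phase of
the sample. One modelling choice deserves a note: written on the
AP-updated low-resolution field, the amplitude-TV term would be constant —
that field's amplitude *is* the measurement — and would contribute no
gradient at all. The penalties therefore act on the amplitude and phase of
the current high-resolution object estimate, the only reading under which
TV can actually denoise the reconstruction. Phase TV operates on the
wrapped principal value; near $\pm\pi$ wraps it sees spurious edges, a
documented limitation. Numerical safeguards: the TV kink is smoothed with
$\varepsilon = 10^{-8}$ inside the square root, and the phase chain factor
$1/|o|$ is floored at 1% of the peak amplitude (it is unbounded where the
amplitude vanishes, exactly where phase is meaningless).

The weights default to an auto-balanced value, $\alpha_1 = \alpha_2 =
10^{-3} \cdot (\text{mean initial data loss}) / (\text{initial amplitude
TV})$, so the penalty starts three orders of magnitude below the data
term regardless of image scale; both are exposed in `fp_control()` and
weight selection beyond this heuristic remains manual.

## The ePIE baseline

`fp_epie()` implements the classical iterative reconstruction with
embedded pupil recovery for comparison: per LED, extract the aperture,
replace the amplitude, and apply the conjugate-weighted update pair

$$ O \mathrel{+}= \alpha \frac{C^*}{\max |C|^2} \Delta\varphi, \qquad
   C \mathrel{+}= \beta \frac{O^*}{\max |O|^2} \Delta\varphi, $$

with the pupil masked to the NA disk, free-form (no Zernike constraint).
The step-size normalization follows the standard ptychography literature;
step sizes default to 1 and 50 sweeps. Its recovered pupil phase can be
decomposed onto the Zernike basis (`coef()` on the result does this),
which reproduces the characteristic behavior that motivates the
parameterized pupil: the defocus component is found with the correct sign
and approximate magnitude, but tilt modes pick up a visible bias.

## The simulator and what it does (not) emulate

`fp_simulate()` generates stacks through the identical forward model from
a known complex phantom and known coefficients, embedding the ground truth
for evaluation. The default geometry is the reference system above: a
128×128 phantom imaged into 225 images of 32×32. `fp_phantom()` builds
deterministic complex objects with amplitude in $[0.1, 1]$ (smooth blobs
plus sharp bars) and an independent phase pattern in $[-\pi/2, \pi/2]$.
Noise is off by default — the validation conditions assume aberrated but
noiseless data; Gaussian (specified relative to the stack's peak
intensity) and Poisson (photon-budget) models are available. Note that
because dark-field images are orders of magnitude dimmer than
bright-field ones, Gaussian noise quoted relative to the peak buries the
dark field quickly: at 2% of peak, reconstructions degrade substantially
and the TV ordering, not absolute quality, is the meaningful comparison.

What passing the simulation suite does *not* show about real data: LED
position miscalibration, intensity falloff across the array, partial
coherence, sample thickness, and sensor quantization are all unmodeled;
the simulator shares the reconstructor's discretization (integer pixel
shifts, Fourier-crop downsampling), so model mismatch present in real
acquisitions is absent here.

## Validation problem sizes

The test suite exercises the full reference geometry (225 images of
32×32, 128×128 reconstruction) for the end-to-end checks — defocus
recovery within 5% on three phantom seeds, the alternate-updating and TV
ablation orderings, and the ePIE sign check — and a reduced 9×9-LED,
16→64 px geometry for unit-level convergence properties. Oracle
equivalences (spatial-domain forward model, direct-DFT amplitude
replacement, finite-difference gradients) run on 4×4 to 16×16 grids where
brute force is exact and fast.

## Known limitations

* Sub-pixel wave-vector shifts are rounded to the Fourier grid; LED
  miscalibration recovery is out of scope.
* Phase TV on wrapped phase penalizes $\pm\pi$ crossings.
* The divergence guard aborts when the epoch data loss exceeds 1000× the
  first epoch's; it does not attempt restarts.
* Aberration recovery is validated for smooth low-order pupils; free-form
  pupil amplitude estimation under strong noise is unregularized.
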