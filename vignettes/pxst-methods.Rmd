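---
title: "Ptychographic X-ray speckle tracking: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ptychographic X-ray speckle tracking: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pxst)
```

## The imaging model

A focused, divergent X-ray beam illuminates a thin sample placed a distance
$z_1$ downstream of the focus; a pixel detector a further distance $z$
downstream records the magnified shadow image (in-line hologram) of the
sample. For an ideal point source the image is a magnified copy of the
plane-wave hologram that would form a distance
$\bar z = z z_1/(z_1+z)$ behind the sample, scaled by $M = (z_1+z)/z_1$.
A real lens system adds aberrations. The forward model used throughout this
package is pseudo-geometric:

$$ I_n(\mathbf{x}) \;=\; W(\mathbf{x})\,
   I_\mathrm{ref}\!\left(\mathbf{u}(\mathbf{x}) - \Delta\mathbf{x}_n\right), $$

where $I_n$ is the $n$-th recorded frame, $W$ the white field (illumination
without the sample), $\Delta\mathbf{x}_n$ the sample translation,
$I_\mathrm{ref}$ the undistorted magnified hologram of the sample, and
$\mathbf{u}$ a pixel map tying each detector pixel to a reference-frame
coordinate. The map encodes the detector-plane phase $\Phi$ of the
illumination through

$$ \mathbf{u}(\mathbf{x}) = \mathbf{x} -
   \frac{\lambda z}{2\pi} \nabla\Phi(\mathbf{x}), $$

so recovering $\mathbf{u}$ recovers the wavefront: phase gradients, ray
angles $\Theta = (\lambda/2\pi)\nabla\Phi$, and, by 2D integration, $\Phi$
itself. For an astigmatic lens pair the two focal planes sit at different
distances $z_{1x}, z_{1y}$; all geometric quantities are computed per axis
and the scalar summaries are their means.

The model is valid for thin samples (projected thickness below
$\delta/(2\,\mathrm{NA})$, with $\delta$ the demagnified pixel and NA the
numerical aperture) and scan planes nearly perpendicular to the optical
axis (tilt below $\delta/\mathrm{FOV}$); `derive_geometry()` reports both
limits.

## The reconstruction loop

`run_pxst()` orchestrates:

1. **White field**: per-pixel median over the frames
   (`estimate_white_field()`). The median rejects the sample provided each
   pixel is unobstructed in at least half of the frames; for scans whose
   span is small compared to the sample, pass a measured empty-beam image
   via `white_field=`.
2. **Initialization**: the ideal astigmatic map $u_x = x\,z_{1x}/(z_{1x}+z)$,
   $u_y = y\,z_{1y}/(z_{1y}+z)$ (`initial_pixel_map()`), with $z_{1x},
   z_{1y}$ from the Thon-ring fit or the SSE scan (below).
3. **Reference synthesis** (`build_reference()`): every normalized sample
   $I_n(\mathbf{x})/W(\mathbf{x})$ is deposited at
   $\mathbf{u}(\mathbf{x})-\Delta\mathbf{x}_n$ by bilinear splatting with
   weight $W^2$; the reference is the weighted mean, with a coverage map.
4. **Map refinement** (`update_pixel_map()`): per detector pixel, the
   forward-model error summed over frames is minimized over integer
   reference-grid displacements, then refined to sub-pixel precision by
   two rounds of per-axis parabolic refinement on continuously re-evaluated
   errors (step 1/2 then 1/4 reference pixels).
5. **Integrability**: the displacement field is projected onto curl-free
   fields through its least-squares potential (`irrotational_projection()`).
6. **Translation refinement** (`update_translations()`): one global offset
   per frame, zero-mean over frames (gauge fixing).

The loop logs the total squared error and its per-sample mean; on noiseless
data the mean error is non-increasing, and two consecutive increases abort
the loop with a diagnostic.

### Numerical choices that matter

* **Reference pitch / oversampling.** The reference grid defaults to half
  the demagnified pixel (`ref_oversample = 2` in `run_pxst()`). With a
  one-delta pitch, bilinear splatting followed by bilinear reads leaves a
  model error of a few percent on fringe-scale structure, which biases the
  per-pixel minima by of order 0.1 reference pixels; halving the pitch
  makes the interpolation error sub-dominant. This is the one place where
  the package deliberately refines the obvious discretization.
* **Sub-pixel refinement.** A single 3-point parabola across the integer
  minimum is biased on non-quadratic error valleys; successive parabolic
  refinement with halving step and re-evaluated errors tracks the
  continuous minimum to a few hundredths of a pixel. The vertex is clamped
  to half the current step, and pixels whose best error is exactly zero
  skip refinement.
* **Degenerate pixels.** Two gates protect the map: an error-surface
  flatness test (relative contrast below `flat_tol`) and a frame-to-frame
  contrast variance test (`signal_tol`, relative to the scan's 90th
  percentile). Featureless pixels carry no tracking information; they keep
  their previous map value, are flagged, and — when regularization is
  active — inherit the value interpolated from informative neighbours.
* **Integration.** Phase integration solves the normal equations of a
  staggered forward-difference gradient with a DCT Poisson solver
  (reflective boundaries, zero-mean gauge), so
  `phase_gradient(integrate_gradient(g))` is an exact orthogonal projection
  and is idempotent to machine precision. Centre-sampled gradients use
  second-order one-sided stencils at the boundary; a first-order stencil
  would bias the dominant spherical term by half a pixel times its slope,
  which is enormous in this geometry.
* **Gauge.** A common shift of all translations against the map, and the
  absolute origin of the reference frame, are not observable. Translation
  corrections are constrained to zero mean; comparisons against ground
  truth in the tests remove the mean map offset first. The map's global
  affine part is attributed to the wavefront (defocus and tilt), not the
  sample.

## Defocus initialization

Fringes from sample edges imprint rings in the cumulative power spectrum
$\sum_n |\mathcal{F}(I_n/W - 1)|^2$. Detector-plane fringes of a magnified
hologram match a plane-wave system at the effective distance
$z_\mathrm{eff} = M^2\bar z = Mz$, so `fit_thon_rings()` correlates the
background-subtracted spectrum with
$\sin^2\!\big(\pi\lambda(z_{\mathrm{eff},x} f_x^2 +
z_{\mathrm{eff},y} f_y^2)\big)$ — the elliptical defocus interpolation used
by cryo-EM CTF estimators — over a candidate range, refining per-axis
values by Nelder–Mead. The background is a moving 30th percentile over
one-Fourier-pixel radial bins, and the fitted band defaults to
$[0.1, 0.8]\times$ Nyquist; both are package choices, made once. When the
fringing is too weak (correlation below threshold, or fewer than two rings
in the band) the fit reports failure and `scan_defocus_sse()` takes over:
it builds the quadratic map and reference for each candidate $z_1$ and
returns the candidate with the smallest forward-model error. Residual
errors in $z_1$ surface as defocus terms in the recovered phase and are
removed by `refine_defocus()`, which converts the fitted $x^2, y^2$ phase
coefficients back to per-axis distances via $a = \pi/(\lambda(z_1+z))$.

## Regularization for quasi-periodic samples

A sample with an (approximately) hexagonal lattice of constant $a$ admits
spurious registrations offset by one lattice vector: the data constrain
such pixels only through the aperiodic envelope, which can be weaker than
the photon noise. Greedy per-pixel updates then lock patches onto the wrong
lattice site, and the corrupted reference reinforces the error — the
recovered map develops step-like plateaus of height exactly $a$.
`update_pixel_map(reg_sigma=)` therefore convolves the *recovered pixel
shifts* — the accumulated deviation of the map from the ideal magnification
map, not the per-iteration increment — with a Gaussian kernel, and
`reg_schedule_linear()` reduces the kernel width linearly (20 pixels to 0
by default) over the iterations. Early iterations thus keep the map smooth
while the reference sharpens; by the time the kernel vanishes, each pixel's
correct branch is unambiguous. Smoothing the accumulated shift field rather
than the update is essential: increment smoothing lets drift from earlier
iterations accumulate unchecked. The search window shrinks alongside the
kernel (`search_radius` accepts one value per iteration): early iterations
may reach across a lattice constant, late iterations only fine-tune, so a
single noisy vote can no longer hop a branch once the kernel is gone.

This regime is delicate by nature. The demonstration in the test suite uses
a lattice of 601 nm with strongly absorbing motifs, an aperiodic envelope,
and a smooth aberration whose distortion approaches half a lattice constant
at the field edge: without regularization the greedy iteration locks the
edge zone one lattice constant off, with the schedule it does not. At lower
contrast or flux the branch signal-to-noise ratio falls below one and *no*
per-pixel scheme can end cleanly — a real limitation of the method, not of
the implementation.

## The synthetic-data generator

`simulate_scan()` emulates a full scan from a phantom
(`make_siemens_star()`, `make_hex_lattice_phantom()`,
`make_speckle_phantom()`, or any thickness map via
`phantom_from_thickness()`) and an aberrated pupil (`make_pupil_phase()`:
the per-axis quadratic of the astigmatic diverging beam plus a polynomial
residual on normalized detector coordinates).

* **Geometric mode** evaluates the forward model exactly: the reference
  hologram is the per-axis Fresnel propagation of the exit wave by
  $\bar z_x, \bar z_y$, band-limited (raised-cosine taper from 0.5 to 0.85
  of the target Nyquist) and resampled to the reconstruction pitch, then
  looked up through the true map. Band-limiting makes the generated data
  exactly representable by the tracking engine's bilinear interpolation,
  separating algorithm error from model error; it also stands in for the
  physical suppression of near-Nyquist content by detector pixel
  integration.
* **Wave mode** Fourier-shifts the transmission per frame, applies the
  residual pupil phase demagnified to the sample plane, and propagates by
  the per-axis effective defocus (the Fresnel scaling theorem maps the
  divergent-beam problem to this plane-wave problem exactly for quadratic
  illumination), so diffraction beyond the geometric model is present.

Poisson noise is applied to the expected counts with an explicit seed;
seeded simulations are bit-reproducible. The white-field envelope defaults
to a smooth low-order profile with ~10–15% variation; real white fields
also carry high-frequency structure from the lens layers, which the
generator does not model. Sample-plane grids default to half the
demagnified pixel. Detector read noise, partial coherence, point-spread
tails and beam drift are out of scope, so passing tests demonstrate
algorithmic correctness under the stated model, not robustness to every
instrumental effect.

## Wavefront analysis and metrology

`make_wavefront()` converts the converged map to phase gradients, integrates
them, and splits off the constant, tilt and defocus terms by weighted least
squares on raw monomials $\{1,x,y,x^2,y^2,xy\}$ — the support is
rectangular, so a Zernike basis would add nothing. `propagate_to_focus()`
forms $\sqrt{W}e^{i\Phi}$ and single-step scaled Fresnel transforms it to
planes near the lens focus; the transform is well-sampled exactly when the
target plane is near the focus, and the function refuses offsets whose
residual chirp would alias, naming the safe range. Axial intensity
projections are sums of the 2D intensity along the orthogonal axis.

`split_half_sensitivity()` assigns every (frame, pixel) sample to one of two
halves with a recorded seed, repeats the gradient refinement independently
per half with the reference and translations fixed, and reports the
standard deviation of the componentwise ray-angle difference
$\Theta_1-\Theta_2$ (the per-reconstruction uncertainty is that over
$\sqrt 2$). The noiseless limit of this figure measures pure interpolation
error and shrinks with scan redundancy. `phase_sensitivity()` propagates an
angular uncertainty to a phase uncertainty through an explicit transverse
correlation length — the propagation model is an assumption, exposed as a
parameter, and `implied_correlation_length()` inverts it.

Two resolution figures accompany the reference image: an edge-overlap
(Rayleigh-type) separation, for which two closed-form conventions
($\sqrt{\lambda\bar z}$ and $2\sqrt{\lambda\bar z}$) circulate in the
literature — `rayleigh_resolution()` exposes both and
`fresnel_edge_overlap_separation()` computes the criterion numerically from
the Fresnel edge profile (it lands between the two, at
$\approx 1.3\sqrt{\lambda\bar z}$) — and the Fourier power-spectrum cut-off
(`fps_resolution()`): the azimuthally averaged spectrum of the edge-tapered
image, a noise floor from the mean of the last 30 radial bins, and the
highest frequency still at twice the floor. The taper is an error-function
roll-off at the image boundary (default width 2% of the side), suppressing
the spectral leakage of the field edges without discarding the interior.

## Thickness retrieval

Two standard single-material inversions of the reference hologram are
provided, both using the effective defocus as the propagation distance:
`tie_thickness()` (Paganin-form transport-of-intensity: low-pass filter
$1/(1 + (\delta_r \bar z/\mu)k^2)$ then $-\mu^{-1}\log$), accurate at large
Fresnel numbers; and `ctf_thickness()` (Tikhonov-regularized division by
the weak-object transfer function
$2[(2\pi\delta_r/\lambda)\sin\chi + (\mu/2)\cos\chi]$,
$\chi=\pi\lambda\bar z f^2$), ideal for weak objects and exactly
self-inverse against `ctf_forward_image()` away from the transfer zeros.
Material constants ship as nominal gold and silica presets around 16–17 keV
(`material_constants()`); they are user inputs, not fitted.

## Problem sizes

The shipped tests run entirely on synthetic scans at desk scale: detectors
of 32–128 pixels per side, scans of 9–169 frames, phantoms of 160–512 grid
points per side, photon budgets of 150–3000 counts per pixel. These sizes
were chosen so the full suite exercises every stage — including the
aberration-recovery, quasi-periodic and metrology studies — in minutes on a
single core while keeping each test's discriminating power; the algorithms
contain nothing size-specific.

## Known limitations

* The white-field median needs scan spans comparable to the sample extent;
  smaller spans need an empty-beam exposure.
* Per-pixel updates assume locally unambiguous speckle; quasi-periodic
  samples need the regularization schedule *and* adequate branch
  signal-to-noise, as discussed above.
* The geometric forward model degrades as the sample leaves the near-field
  regime (effective Fresnel numbers well below ~0.3 for the features of
  interest) — the wave-mode simulator exists precisely to measure that gap.
* Thickness retrieval assumes a single material of constant density.
* The angular-sensitivity bound $\Delta\Theta = \delta_\mathrm{pix}
  \sigma_\mathrm{det}/(zM)$ is an idealization; the split-half estimate is
  the operational figure.
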