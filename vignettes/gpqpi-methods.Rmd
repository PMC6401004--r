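---
title: "Methods: simulating and reconstructing geometric-phase QPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing geometric-phase QPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpqpi)
```

This vignette records the scientific model behind `gpqpi`, the parameter
choices that matter, the numerical decisions taken where the design was
genuinely open, and what the synthetic experiments do and do not show
about real instruments.

## The physical model

The instrument class being simulated is a common-path quantitative phase
microscope in which the sample and reference waves travel the same optics
but carry orthogonal circular polarizations. A geometric-phase
(Pancharatnam–Berry) grating — a half-wave-like element whose anisotropy
axis orientation φ varies periodically in space — swaps the circular
handedness of each wave and imprints the achromatic phase ±2φ, deflecting
the two polarizations into opposite diffraction orders. After projection
on a common analyzer axis they interfere on the camera with a carrier
frequency that is *independent of wavelength*, which is what makes
single-shot off-axis holography possible with a 50 nm-wide thermal source.

`gpqpi` models this train at the level that determines the recorded data:

* **Jones calculus in the circular basis** (`jones.R`). The convention is
  fixed package-wide: LHCP is $(\hat x + i\hat y)/\sqrt 2$ from the
  receiver's viewpoint, so $e_L = (E_x - iE_y)/\sqrt2$. All operators
  (grating, waveplates, analyzer, ideal mirror) are unitary or projectors
  and tested to $10^{-12}$. The mirror is a pure handedness swap; real
  mirror phase shifts are absorbed into the background phase that the
  reconstruction removes anyway.

* **Incoherent spectral superposition** (`hologram.R`). The recorded
  intensity is the weighted sum over sampled spectral lines of the
  two-beam interference pattern, all lines sharing one carrier $\nu_c$.
  This is the fully incoherent, ideal point-imaging limit in which
  sideband demodulation restores the retardance exactly; it deliberately
  omits the partially coherent transfer function of a finite-NA system
  (an optional Gaussian PSF blur is available, full partial coherence is
  out of scope). The achromatic carrier is *imposed* rather than derived
  from the grating-plus-Fourier-lens geometry: achromaticity is a design
  property of this instrument class, and the downstream pipeline depends
  only on the property, not on its optical derivation.

* **Wavelength dependence by scene type** (`scenes.R`). Mirror scenes are
  dispersive in the only way that matters, $\Phi_s = 4\pi\,\delta z/\lambda$
  (reflection, double pass): this is what produces coherence gating, and
  the broadband fringe-contrast collapse beyond the coherence length
  $\lambda^2/\Delta\lambda = 7.2\ \mu m$ is verified against the spectral
  sum evaluated directly. Geometric-phase scenes (lens) are achromatic by
  physics; SLM retardance is treated as wavelength-independent across the
  50 nm band because liquid-crystal dispersion over that band is small
  relative to every tolerance used here and the devices are characterized
  by a single retardance per pixel.

## Reconstruction

Demodulation is the standard Fourier sideband method: multiply by
$e^{-2\pi i\,\nu_c\cdot(x,y)}$, FFT, keep a disk of radius $B$ at
baseband, inverse FFT; the argument of the result is the wrapped
retardance. Three numerical choices deserve comment:

* **Zero-order suppression and windowing.** The mean intensity is removed
  before windowing, and a Tukey window with a fixed 16-pixel taper is
  applied (wide fractional tapers distort a band that extends well past
  the excluded margin). For the lens experiment the window is *disabled*:
  the quadratic pattern takes equal values on opposite field edges, so the
  wrap-around discontinuity is mild, while a window's amplitude gradient
  couples to the chirp over the wide $1/B$ kernel and measurably worsens
  the result.

* **Filter taper.** A hard disk is used for smooth scenes. For scenes with
  sharp phase steps (SLM pixels, cell rims) a Gaussian-tapered filter
  (sd $B/2$) is used instead: a hard edge in the frequency plane rings in
  space with $1/x$ tails that bias the mean phase of a 20 µm pixel by far
  more than the quantity being measured.

* **Unwrapping** (`unwrap()`). Transform-based unweighted least squares:
  the wrapped Laplacian is assembled from wrapped first differences and
  the discrete Poisson equation solved under Neumann boundaries by even
  mirror extension and FFT, followed by a congruence step that snaps the
  smooth solution back to the measured values modulo $2\pi$. For smooth
  noiseless inputs whose true neighbor differences stay below $\pi$ the
  result is exact up to a global constant (tested to $10^{-9}$ on a
  six-wrap quadratic); residue counts are reported in the metadata. Piston
  *time series* (the piezo staircase) instead resolve their $2\pi$
  ambiguity against the commanded displacement, exactly as a staircase
  calibration is read out in practice.

## Acquisition geometries

One geometry per experiment class is fixed in `acquisition_geometry()` and
used by the experiment runners; the key constraint in each case is which
spatial frequencies must survive the sideband filter.

| geometry | grid | pitch (µm) | carrier (cyc/µm) | B (cyc/µm) | why |
|---|---|---|---|---|---|
| mirror | 512² | 0.5 | 0.35 | 0.15 hard | noise correlation length 1/B = 6.7 µm must sit well below the 20 µm ROIs of the σ_Z protocol, else the nine-ROI statistic is unstable |
| slm | 512² | 0.25 | 0.6 | 0.15 Gaussian | 20 µm pixels with near-π strokes need a wide, ringing-free filter; spatial reach ≈ 2 µm |
| lens | 1024² | 0.49 | 0.125 | 0.025 hard | ≈ 2× the highest local fringe frequency (0.012 cyc/µm) of the f = 100 mm quadratic over the 0.5 mm field; the fine pitch matches a 4-megapixel camera over that field |
| cells | 512² | 0.25 | 0.8 | 0.3 Gaussian | cell rims a few µm wide carry local frequencies near 0.3 cyc/µm; losing them silently drops whole 2π wrap counts from the cell interior. The filter's ≈ 1 µm spatial reach matches the diffraction limit of an NA 0.3 objective |

Border handling: quantitative comparisons exclude a 16-pixel margin
everywhere except the lens experiment, which excludes 64 pixels — edge
ringing of a band-limited demodulation penetrates $\sim 1/B \approx 33\ \mu m
\approx 68$ px, and no 16-pixel margin can contain it at a bandwidth
compatible with the calibrated noise level.

## Noise model and calibration

Three noise sources are modeled, each routed through one seeded generator
per run: per-frame Gaussian piston drift in height units (the dominant
temporal instability of a common-path system), Poisson shot noise after
scaling the mean intensity to a photon budget (default $10^4$ per pixel),
and additive Gaussian read noise expressed relative to the unit-amplitude
intensity scale so a calibrated value transfers between geometries.

The study conditions fix the *outputs* of the noise model, not its inputs:
the temporal protocol is driven at 0.83 nm per-frame drift, and the read
noise amplitude is calibrated so the reconstruction chain reports a
blank-area height std of 2.95 nm. The calibration measures the protocol's
own statistic (mean of the nine 20×20 µm² ROI standard deviations,
averaged over four pilot frames, three fixed-point iterations): with only
a few tens of noise-correlation cells per ROI the ROI sd runs a few
percent below the field sd, so calibrating on the field sd would bias
every downstream experiment. Intensity clipping at zero makes the
response mildly nonlinear, which the fixed-point iteration absorbs. The
calibrated amplitude is then treated as a camera property and reused by
the SLM and lens experiments with their own geometries.

## Protocols

* **Temporal stability.** 300 frames; ROI-mean height tracked in nine
  diffraction-spot ROIs (radius $0.61\lambda/\mathrm{NA} = 1.22\ \mu m$
  at NA 0.3) on a 3×3 lattice; per-ROI sd, summarized mean ± sd. ROI-mean
  rather than per-pixel deviations, consistent with an ROI the size of
  the diffraction spot.
* **Spatial noise.** Per-pixel sd of height in nine 20×20 µm² blank
  squares on a 3×3 lattice.
* **Staircase accuracy.** Mirror displaced 0–1 µm in 100 nm steps, five
  independent repeats, piston noise 0.83 nm plus shot noise; piston read
  out by circular mean; per-step ME and RMSE against ground truth.
* **SLM retardance.** Sample and non-addressed background holograms,
  background subtracted in wrapped arithmetic, difference unwrapped and
  re-anchored on the non-addressed area (programmed strokes near π
  straddle the wrap edge), per-pixel means over the interior 50% of each
  pixel (the rim is where optical resolution and crosstalk mix
  neighbors).
* **Lens.** End-to-end measurement; piston/tilt removed against the
  theoretical profile; worst absolute deviation over the field and the
  fitted focal length reported. Axial profiles in `lens_characterize()`
  use *direct Rayleigh–Sommerfeld summation* rather than the FFT
  angular-spectrum path: the on-axis oscillation pattern of a hard-edged
  aperture depends on slowly decaying edge-wave content, and any
  frequency-domain truncation (the mandatory anti-aliasing band limit, or
  aliasing without it) shifts the broad $N_F \approx 1$ maximum by one to
  three 0.5 mm axial steps — the direct sum, the closed-form Fresnel
  result and a radial quadrature all agree with each other. Angular
  spectrum remains the propagator for transverse planes, where it is
  validated against the direct oracle at the 1% level. The analytic
  profile assumes a circular aperture, so numerical comparisons use a
  circular mask of radius a = 0.25 mm even though the imaged field is
  square.

## Cell phantoms and segmentation

Phantom cells are disk-supported superpositions of Gaussian kernels
(equivalently, disks convolved with a 1.5 µm Gaussian): a flat interior
with a compact smooth rim. A single broad Gaussian is deliberately *not*
used — at least 8% of a Gaussian's mass lies below any contour a
segmenter would plausibly threshold at, which makes a 5% end-to-end mass
recovery unachievable regardless of the imaging chain. Per-cell amplitude
is normalized on the grid so the injected mass is exact; the phase map is
the inverse Davies relation of the density (α = 0.18 µm³/pg, double
pass), round-trip tested to $10^{-9}$.

Segmentation (EBImage primitives behind the package's surface): Gaussian
smoothing (1 µm), foreground by Otsu unless overridden, marker-controlled
watershed with h-maxima depth 10% of the dynamic range, then a per-cell
*half-maximum outline*: each label is trimmed to the contour at half its
own plateau density. The half-max contour of a symmetric rim sits exactly
at the disk radius, so label areas track cell growth multiplicatively — a
global-threshold contour offsets every radius by a constant rim width and
dilutes an injected 2%/frame area-growth slope by 10–15%. Mass is
integrated over a 5 µm-expanded support per label (`measure_cells(expand=)`),
capturing the rim that thresholding leaves outside; with `expand = 0` the
function computes exactly area = pixels × pitch², mean = mean over label,
mass = sum × pitch². Tracking is greedy maximum-overlap matching between
consecutive frames (minimum overlap 0.3 of the smaller label), which is
robust for confluent phantoms; trajectory identifiers are never reused.

Background for dry-mass maps is removed in two passes: a plain
piston + tilt fit, then a refit restricted to pixels below 10% of the
maximum — a plane fitted through the cells themselves is biased upward
and skims several percent off every cell's mass.

## Problem sizes and determinism

The experiment runners use the grids in the table above; the test suite
uses 64–512 px grids and the acceptance script runs the full-size
protocols (300 frames at 256², staircase 5×11 frames, SLM and lens at
512²/1024²), completing in well under a minute on one CPU. Every source
of randomness (scene placement, drift, shot and read noise, calibration
pilots) derives from explicit integer seeds; identical seeds give
bit-identical holograms, fixtures and reports.

## What passing tests do and do not show

The generator emulates the *geometry and statistics* of the instrument:
polarization-coded phase, achromatic carrier, coherence gating, piston
drift, photon and detector noise, resolvable SLM pixels, a quadratic lens
retardance, compact cells with known mass. It does not emulate optical
aberrations beyond low-order background, partially coherent transfer,
detector MTF, liquid-crystal dispersion, textured or overlapping cells,
or mitosis. Recovery results here therefore demonstrate the correctness
and internal consistency of the reconstruction and quantification chain
under the stated noise statistics — not the performance of any physical
instrument on real specimens.

## Known limitations

* The least-squares unwrapper degrades gracefully but is not
  residue-aware; heavily undersampled or very noisy wrap structures (cell
  rims outside the filter band) silently lose 2π counts — the cells
  geometry exists precisely to avoid this regime.
* The σ_Z protocol with nine ROIs has an irreducible ~10% sampling error
  per run at the mirror geometry's correlation length; reported values
  fluctuate accordingly.
* The carrier is a free configuration parameter; its mapping to grating
  period and Fourier-lens focal lengths is not modeled.
* Whether the grating's printed 9 µm period refers to the anisotropy-axis
  rotation or to the 2π phase ramp is ambiguous in this instrument class
  (the two differ by a factor 2 in deflection); `grating_deflection()`
  takes the *phase* period explicitly, and only that reading reproduces
  the 8° mutual angle at 600 nm.
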