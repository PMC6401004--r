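# gpqpi

Simulation and single-shot reconstruction for **geometric-phase quantitative
phase imaging** (QPI): an R package that models a common-path interference
microscope in which the sample and reference waves are coded in orthogonal
circular polarizations, deflected by a geometric-phase (Pancharatnam–Berry)
grating, and recorded as a single *achromatic* off-axis hologram under
broadband spatially incoherent light. The package is aimed at optics and
biophotonics researchers who want a faithful, fully synthetic testbed for
this class of instrument: every experiment the modality supports — mirror
metrology, SLM retardance mapping, polarization-directed lens
characterization, and live-cell dry-mass densitometry — is generated,
reconstructed, and quantified in code, with ground truth attached.

## The model

**Polarization coding.** The optical train is Jones calculus in the circular
basis (e_L, e_R). A geometric-phase element with local anisotropy-axis
orientation φ(x, y) swaps the circular handedness and imprints the
achromatic phase ±2φ, sending LHCP/RHCP into opposite diffraction orders
(mutual angle 2·arcsin(λ/Λ), ≈ 8° for a Λ = 9 µm phase period at 600 nm).

**Hologram formation.** Under spatially incoherent broadband illumination
the detector records an incoherent sum of two-beam patterns over the
spectrum S(λ), all sharing one carrier frequency ν_c (the achromatic
property of the design):

    I(x,y) = Σ_λ w_λ [ |s|² + |r|² + 2|s||r| cos( 2π ν_c·(x,y)
             + Φ_s(x,y;λ) − Φ_r(x,y;λ) + 2π·OPD/λ ) ]

with optional per-frame piston drift, Poisson shot noise at a stated photon
budget, and Gaussian read noise. Fringe contrast collapses once the OPD
exceeds the coherence length λ²/Δλ (7.2 µm for the 600/50 nm band).

**Reconstruction.** The retardance ΔΦ = Φ_s − Φ_r is restored from one
frame by Fourier sideband demodulation (carrier shift, circular low-pass of
radius B, inverse FFT), background compensation (stored reference or
low-order polynomial), and transform-based least-squares unwrapping with a
congruence step.

**Quantification.** Retardance maps convert to reflective double-pass
height δz = λΔΦ/(4π), or to cellular dry-mass surface density via the
Davies relation ρ = λΔΦ/(2π·α·passes) with specific refractive increment
α = 0.18 µm³/pg. Precision protocols report σ_T (temporal, diffraction-spot
ROIs) and σ_Z (spatial, nine 20×20 µm² blank areas); cells are segmented by
marker-controlled watershed and tracked by label overlap; geometric-phase
lenses are characterized by a quadratic focal-length fit
(φ = −π r²/(λf)), the Fresnel number N_F = a²/(λf), and axial intensity
profiles from the scalar diffraction integral, compared with the
closed-form Fresnel result I(z) ∝ (f/z)²·sinc²(u/2),
u = (π a²/λ)(1/z − 1/f).

## Worked example

Displace a mirror by 120 nm, record one broadband hologram, and recover the
height from a single shot:

```r
library(gpqpi)

scene <- mirror_scene(grid = 256, pitch = 0.5, dz = 120)      # dz in nm
holo  <- form_hologram(scene, make_spectrum(600, 50, 7),
                       carrier = c(0.35, 0),
                       noise = list(photon_budget = 1e4), seed = 1)
pm    <- reconstruct_phase(holo, bandwidth = 0.15)
piston_phase(pm)                       # 2.5161 rad  (theory 4*pi*120/600 = 2.5133)
phase_to_height(piston_phase(pm), 600) # 120.13 nm
```

The precision and lens protocols run the full chain end to end:

```r
run_stability(n_frames = 50, drift_nm = 0.83, seed = 1)
#> <stability_report>  sigma = 0.83 +/- 0.0122 nm over 9 ROIs (disk), 50 frame(s)

lens <- run_lens(seed = 1)
lens$max_abs_err   # 0.070 rad  (max |reconstructed - theoretical 2*phi|)
lens$f_mm          # 100.07 mm  (least-squares fit to the f = 100 mm lens)
```

The first says that with a 0.83 nm per-frame piston drift injected, the
temporal-stability protocol reads back 0.83 nm; the second that an
f = 100 mm polarization-directed lens simulated over a 0.5 × 0.5 mm² field
with calibrated background noise is restored to within 0.07 rad of the
theoretical retardance and its focal length recovered to 0.07%.

A command-line front end over the same runners lives in
`inst/scripts/gpqpi-run.R`:

```sh
Rscript inst/scripts/gpqpi-run.R stability --seed 1 n_frames=300
Rscript inst/scripts/gpqpi-run.R lens --seed 1 --out out/
```

## Layout

- `R/jones.R` — Jones calculus, geometric-phase grating, deflection angles
- `R/scenes.R` — synthetic scene generators with ground truth (mirror, SLM,
  lens, cell phantoms) and the sampled spectrum
- `R/hologram.R` — achromatic off-axis hologram formation, noise models,
  fringe diagnostics, TIFF+JSON I/O
- `R/reconstruct.R` — sideband demodulation, background compensation,
  least-squares unwrapping
- `R/quantify.R` — height/dry-mass conversion, σ_T / σ_Z / ME-RMSE protocols
- `R/cells.R` — watershed segmentation, morphometrics, overlap tracking
- `R/lensmap.R` — focal-length fit, Fresnel number, diffraction propagation
- `R/experiments.R` — calibrated end-to-end experiment runners, fixtures
- `vignettes/gpqpi-methods.Rmd` — the methods notes: model assumptions,
  parameter choices, numerical decisions, limitations
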