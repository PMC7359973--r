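---
title: "Dual-isotope SPECT dosimetry in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope SPECT dosimetry in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Holmium-166 microsphere radioembolization delivers beta radiation to liver
tumours; quantitative SPECT of the 81 keV Ho-166 photopeak is the basis of
its dosimetry. A second tracer, Tc-99m colloid, is attractive during the
same scan because it labels the healthy liver (Kupffer-cell uptake is
absent in tumours) and could automate healthy-tissue segmentation. The cost
is crosstalk: downscatter from higher-energy emissions of both isotopes
contaminates the 81 keV window, and Tc-99m's own 140 keV photopeak adds to
it. The clinical question is whether a simple window-based correction — a
single combined k-factor applied to a 118 keV estimation window — preserves
the accuracy of Ho-166 dosimetry when Tc-99m is present.

`duospect` reproduces this measurement chain entirely in silico: a digital
phantom with known activity, a four-window projection simulator with
crosstalk, OSEM reconstruction with the window-based correction, rigid
registration, voxel dosimetry, and the agreement statistics used to compare
the Ho-only and dual-isotope (DI) arms.

## Phantom

The phantom is a set of labelled ellipsoids — body, two lungs, a liver and
one tumour — voxelised on a 64 x 64 x 48 grid at 4.8 mm isotropic spacing
(the clinical matrix is accepted via `grid_shape`/`spacing`). Ellipsoids
are the simplest geometry that produces all three VOI types (an
ellipsoidal healthy-liver VOI, a tumour, and lungs to be eroded); the
phantom makes no attempt at anthropomorphic anatomy or respiratory motion.

Activity defaults emulate the clinical imaging condition: 250 MBq of
Ho-166 in the field of view at scan time and 50 MBq of Tc-99m colloid, a
5:1 ratio. Ho-166 covers the whole liver with a tumour-to-normal
concentration ratio of 4 (chosen to match the roughly fourfold
tumour-to-healthy mean dose ratio seen clinically); Tc-99m is uniform over
the healthy liver and exactly zero in tumour voxels. Concentrations are
normalised on the voxelised organs, so the integrated totals equal the
prescription to machine precision; activity outside the liver is a free
parameter (`background_fraction`, default 0 — no lung shunt is modelled).

Attenuation is organ-wise constant: soft tissue 0.18 cm^-1 at 81 keV and
0.155 cm^-1 at 140 keV (water-like values at those energies), lungs 0.3 of
soft tissue, air zero. Densities are 1.06 g/ml for soft tissue and
0.3 g/ml for lung, the same constants the dose model uses.

## Projection simulator

The acquisition model is parallel-beam: 120 angles over a circular 360
degree orbit, 15 s per projection, 4.8 mm detector pixels. (A non-circular
orbit would only modulate the per-angle radius, which a
distance-independent response never sees, so the circular orbit loses
nothing.) The projector rotates each transaxial slice into the camera
frame with a mass-preserving bilinear push — every voxel deposits its
activity onto its rotated position, so an unattenuated projection sums to
the volume's total at every angle exactly — attenuates each deposit by the
Beer-Lambert survival factor integrated to the detector, sums along rays,
and blurs with a distance-independent Gaussian detector response (FWHM
10 mm by default). The backprojector is its exact algebraic adjoint, which
the tests verify to 1e-6; OSEM's correctness rests on that identity.

Each energy window's expectation is a sum over (isotope, window) terms of
two kinds. Primary terms image an isotope's photopeak with full
attenuation at its photopeak energy. Downscatter terms represent photons
from higher-energy emissions detected at lower energy; lacking a
Monte-Carlo transport model (deliberately out of scope), they are modelled
as the same activity forward-projected with a wide Gaussian response
(FWHM 40 mm) and attenuation scaled by 0.5 — a standard surrogate for the
broad, low-frequency shape of object scatter that preserves exactly the
count-ratio structure a window-based correction relies on. The window
layout matches the dual-isotope spectrum: 81 keV holds Ho primary plus
both isotopes' downscatter, 118 keV downscatter only, 140 keV Tc primary
plus Ho downscatter, 170 keV Ho downscatter only, and Tc-99m contributes
nothing above 170 keV.

The default downscatter sensitivities are constructed so that each
isotope's 81:118 keV (and 140:170 keV) downscatter ratio is 1.15. The
combined correction factor is therefore 1.15 by construction, for any
activity distribution — this is the calibration anchor the default model
is built around, and `calibrate_k_factor()` re-derives the least-squares k
from the simulator's exact primary/downscatter decomposition whenever the
sensitivities are edited. Poisson noise is applied per window with
deterministic substreams derived from one master seed, so removing one
isotope leaves the other windows' draws unchanged.

## Reconstruction

`osem_reconstruct()` is standard OSEM: multiplicative EM updates over
angle subsets assigned round-robin by index stride (120 angles, 8 subsets,
10 iterations by default — 80 updates). The system model is the same
attenuated, PSF-blurred projector the simulator uses. The downscatter
estimate enters additively in the forward-model denominator
(`expected = forward(x) + scatter`); it is never subtracted from the
measured counts, which would break the Poisson statistics EM assumes. The
estimate itself is k times the estimation window, optionally smoothed with
a mass-normalised Gaussian (FWHM 20 mm by default — window estimates are
noisy, and normalised smoothing leaves the total estimate unchanged;
whether the clinical chain smoothed its estimate is not documented, so it
is exposed as configuration). Initialisation is a uniform positive volume
on the body support; iteration count is fixed (no convergence-based
stopping, matching clinical practice); non-negativity is automatic with EM.
The Ho-166 and Tc-99m reconstructions use identical machinery with their
respective photopeak/estimation window pairs — the correction is
isotope-agnostic.

Numerical details worth knowing: voxels a subset never sees get an
infinite sensitivity and therefore never update from zero; the
projection-domain denominator is clamped at 1e-12 so zero-count pixels are
well-defined; reconstructions come out in Bq/ml because the system model
carries the calibrated counts-per-Bq-s sensitivity. The optional display
filter is a mass-conserving Gaussian with sigma 4.2 mm.

## Registration and resampling

The DI acquisition is aligned to the Ho-only frame on the attenuation
maps (the CT surrogate), as done clinically. Instead of a stochastic
optimiser, `register_rigid()` uses a deterministic search — integer-voxel
translations within +/- 3 voxels at zero rotation, a one-dimensional sweep
over small rotations per axis, then Nelder-Mead over all six parameters.
The default similarity is normalised cross-correlation on the joint body
support. Mutual information (32 bins) is implemented and selectable, but
on piecewise-constant attenuation surrogates its histogram is nearly
degenerate — interpolation-created intermediate intensities penalise the
correctly aligned pose more than a small misalignment does — so
correlation, which is insensitive to that effect, is the default; on
textured clinical CT the usual preference for mutual information would
apply. Determinism keeps every test and
every experiment bit-reproducible. Identical inputs short-circuit to the
identity transform. Resampling pulls fixed-grid voxels through the inverse
transform: trilinear for continuous volumes, nearest-neighbour for labels;
coordinates that are integer up to rounding noise are snapped so
grid-aligned transforms move voxels exactly.

## Dosimetry

Reconstructions are rescaled so their integral equals the administered
activity (all activity is assumed inside the field of view), then
converted to absorbed dose with the local-deposition beta model:

Dose [Gy] = 15.87 [mJ/MBq] x (concentration [Bq/ml] x 1e-6) / density [g/ml]

15.87 mJ/MBq is the beta energy deposited per MBq of initial Ho-166
(96% of the emitted energy; the gamma remainder is ignored, as its long
range dilutes it far below the beta dose). The beta mean range (2.5 mm)
is below the voxel size, so each voxel keeps its own energy. The model
implies an exact bookkeeping identity the tests assert: body-integrated
energy equals 15.87 mJ per administered MBq.

VOIs follow the clinical rules: an ellipsoidal healthy-liver VOI of
~27.6 ml placed at the healthy-liver centroid and nudged away from the
tumour until disjoint (the clinical VOI volume is known but not its radii,
so a sphere of that volume is used); the tumour mask (the phantom's ground
truth stands in for manual delineation); and a lung mask thresholded from
the attenuation map (mu between 5% and 60% of soft tissue) and eroded by a
2 cm Euclidean ball to avoid partial-volume contamination at the edges.
VOIs below 25 ml are rejected from reporting — the recovery tests
themselves show reconstruction accuracy degrading as VOIs shrink toward
the resolution limit, which is the rationale for the rule. Automatic
segmentation from the images is also provided (`segment_healthy_from_tc()`
thresholds the Tc-99m image at 40% of maximum, `segment_tumor_from_ho()`
the Ho-166 image), and recovers the true masks with Dice >= 0.85 and
>= 0.7 respectively on the standard phantom.

## The paired experiment and its statistics

`run_paired_experiment()` chains the stages per seed — phantom, Ho-only
and DI acquisitions (same master seed, so the zero-Tc DI acquisition is
bit-identical to the Ho-only one), reconstructions with and without
correction, registration, VOI dosimetry — and then compares arms with the
agreement battery: Bland-Altman (sample SD with n-1 denominator; the
coefficient of reproducibility CRP = 1.96 x SD; limits of agreement
mean +/- CRP), Pearson correlation, a two-sided paired t-test, and
Cohen's kappa for paired categorical ratings. No multiple-testing
correction is applied. Quantiles use linear interpolation (type 7).

Default experiment size is 10 seeds on the 64 x 64 x 48 grid — about
three minutes on one CPU — with doses rescaled to a therapeutic-scale
5757 MBq administration. By default no inter-scan motion is applied (the
patient stays on the table between arms, and motion remains available via
`motion =`); registration still runs and must find the identity.

## What passing tests do and do not show

The simulator reproduces the *structure* of the dual-isotope problem —
window layout, attenuation, Poisson statistics, broad downscatter with a
known combined k — not its photon physics: no Monte-Carlo transport, no
septal penetration, no depth-dependent response, no photopeak self-scatter
(the last mirrors the clinical chain, which also left it uncorrected).
Consequently the in-silico experiment demonstrates that the window-based
correction removes the bias *this class of contamination* induces, in
every replicate, and that corrected DI dosimetry tracks Ho-only dosimetry
within a few percent on a 27.6 ml healthy VOI; it cannot certify the
numerical value of a clinical k-factor, which is scanner-specific and must
be calibrated on real spectra. Patient-level dose distributions and their
published agreement intervals derive from 65 clinical acquisitions and are
similarly outside what a desk-scale phantom can or should reproduce; only
their arithmetic (the Bland-Altman identities) is checked against printed
inputs.
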