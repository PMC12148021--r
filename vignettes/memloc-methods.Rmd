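---
title: "Quantifying membrane-proximal translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-proximal translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memloc)
```

## The problem

Single-molecule translation reporters (SunTag) make actively translating
mRNAs visible as bright fluorescent foci: dozens of single-chain antibodies
(scFv::GFP) bind the nascent peptide array on one polysome, so a
translation site is far brighter than a single mature protein. Together
with a fluorescent membrane marker imaged in a second channel, this allows
asking *where* a transcript is translated inside an embryo — in particular
whether translation of a cortical protein such as the ERM family
membrane–actin linker is enriched at the plasma membrane.

Turning those images into numbers requires a chain of classical
image-analysis steps, each with choices that affect the result: membrane
enhancement and cell segmentation, blob detection with intensity gating,
3D distances in physical units on anisotropic voxel grids, a randomized
null to calibrate the enrichment statistic, object-based colocalization
with an mRNA channel, line-scan intensity ratios, and a FRAP
correction/normalization chain. `memloc` implements this chain as a set of
small, composable functions, and ships a synthetic-scene generator with
full ground truth so that every stage is testable by parameter recovery
rather than by eye.

## Statistic at the core: the membrane-proximity fraction

For one embryo, translation spots are detected in 3D, each spot centre
gets its Euclidean distance (in µm) to the nearest membrane, and the
statistic is

$$ f = \frac{\#\{\text{spots with } d \le 0.35\ \mu m\}}{\#\text{spots}} $$

The 0.35 µm band is treated as a closed interval (the cutoff is
inclusive). Embryos enter the analysis only with at least 25 translation
spots. Because the expected value of $f$ under spatial randomness depends
on the embryo's geometry (a thin shell around every membrane occupies a
substantial volume fraction of small, packed cells), the statistic is
calibrated with a **z-flip null**: the spot channel alone is reversed
along the optical axis, the membrane channel and its segmentation stay
fixed, and the *identical* detection-plus-distance pipeline is re-run.
This destroys spot–membrane registration while preserving the spot
distribution's envelope within the embryo, and re-running the same code on
the flipped stack means any computational bias applies to both conditions.

## Pipeline stages and their parameters

### Membrane enhancement and segmentation

* `enhance_membrane()` sharpens with an unsharp mask
  (`seg_sharpen_amount`, default 1; `seg_sharpen_sigma_um`, default
  0.5 µm) and then *adds* a gradient-magnitude edge response
  (`seg_edge_gain`, default 0.2, unitless after rescaling by the smallest
  voxel size). The edge term is added to the sharpened signal rather than
  replacing it: a membrane is a *ridge*, and the gradient magnitude of a
  ridge has a valley exactly on the ridge line, which would carve a
  spurious basin into the watershed relief precisely where the barrier
  belongs. Keeping the signal makes the membrane the highest structure.
* `segment_cells()` floods the inverted, lightly smoothed relief
  (`seg_smooth_sigma_um`, default 0.3 µm) from its regional minima with a
  tolerance-merging watershed: minima whose prominence relative to their
  connecting saddle is below `seg_h_min` (intensity units, default 100,
  appropriate for a membrane peak of ~1000 ADU) are merged. This is the
  standard h-minima seeding, and the tolerance plays the role a
  commercial membrane-based segmenter exposes as a sensitivity slider.
  The watershed itself is implemented in compiled code with full 26-voxel
  connectivity, because the established R image packages process 3D
  arrays slice-wise in 2D.
* `embryo_mask()` thresholds the smoothed membrane channel (Otsu) and
  takes the per-slice convex hull of the thresholded signal along all
  three axis orientations; embryo cross-sections are convex, so the union
  of hulls is the interior. The hull reaches the *outer* edge of the
  blurred membrane shell, roughly one PSF sigma outside the true surface,
  so the mask is eroded by `shell_halfwidth_um` (default 0.25 µm).
* Dividing cells and neighbouring embryos are removed with user-supplied
  box ROIs (`exclusion_mask()`); there is deliberately no automatic
  mitosis detector, mirroring how such regions are excluded visually in
  practice.

### Distances

"Membrane" is defined as the boundary voxel set of the segmentation:
voxels inside a cell with a face-adjacent neighbour in a different cell or
outside the embryo. `distance_to_membrane()` computes an exact anisotropic
Euclidean distance transform of this set (Felzenszwalb–Huttenlocher
separable parabolic envelopes, one pass per axis, with per-axis physical
spacing), and spot centres sample the map by trilinear interpolation.
Distances are voxel-centre to voxel-centre; sub-voxel boundary
interpolation is not attempted, which bounds the discretization error by
half a voxel diagonal (≈ 0.22 µm at 0.4 × 0.13 × 0.13 µm voxels — the
dominant term is the coarse z-step, which is a property of the
acquisition, not of the algorithm). The transform is verified exactly
against a brute-force nearest-boundary search in the test suite.

### Spot detection

`detect_spots()` uses a difference-of-Gaussians band-pass at the expected
spot scale (`detect_scale_um`, default (0.4, 0.15, 0.15) µm ≈ the PSF),
thresholded at `detect_threshold`, with candidate regions split by the
same tolerance watershed run on the response (`detect_split_h`). The two
knobs map onto what proprietary blob finders call the *probability
threshold* and the *split sensitivity*: a lower threshold admits dimmer
blobs, and a smaller split depth separates maxima whose saddle dip is
shallower. Sub-voxel centres are response-weighted centroids;
`integrated_intensity` is the raw-image sum over an ellipsoidal
neighbourhood of radius 3 scale, minus its local background estimated as
the median of a 3–5 scale surrounding shell. All intensity gates
(>25,000 for translation spots in the overlap assay, >2,000 in the
counting assay, >50,000 for mRNA spots) are strict inequalities in
arbitrary detector units; they are camera-specific constants and must be
re-derived for any other sensor — for synthetic scenes they are set
relative to the simulated intensity law.

Two operating points are used in the tests, chosen once from the detector's
characteristics: sparse, noisy scenes use threshold 30 / split 30; dense
scenes (thousands of spots per embryo, where PSF overlap is the limiting
factor) use threshold 15 / split 10, which holds neighbouring spots apart
down to roughly 2.5 in-plane sigmas at the cost of admitting dimmer
candidates — acceptable because the dense recovery scenes are shot-noise
free.

### Colocalization

`match_spots()` performs object-based matching: iterated
mutual-nearest-neighbour pairing within a physical radius
(`match_radius_um`, default 0.3 µm ≈ two detected spot sigmas; the radius
any given acquisition used is rarely printed, so it is configuration).
Mutual-NN is deterministic, one-to-one, and equals the optimal assignment
when pairs are unique and well separated; the suite checks it against a
maximum-cardinality matching oracle in cluttered scenes. Overlap is
reported asymmetrically (matched translation spots over all translation
spots), as the assay defines it, and `probe_efficiency()` divides the
matched count by each channel's total.

### Line scans and enrichment ratios

`line_scan()` samples a profile at 1-pixel steps with bilinear
interpolation, averaged across a perpendicular width (30 px for apical
ratios, 20 px for FRAP, 15 px for the actin assay); the "peak histogram
intensity" of a wide-line profile is interpreted as the maximum of the
width-averaged profile, which is what an image-viewer plot-profile peak
reports. `enrichment_ratio()` averages three apical peaks and three
cytoplasmic region means and forms
$(\bar a - \bar b)/(\bar c - \bar b)$ after background subtraction; the
background-subtracted ratio is exactly invariant to a global gain, which
the suite asserts as an identity. Whether background subtraction applies
in a given assay is a per-assay choice: both modes are supported and
subtraction is the default whenever background regions are supplied.

### FRAP

`correct_trace()` applies, in order: background subtraction; acquisition
photobleaching correction by the reference region normalized to its mean
over the five pre-bleach frames; zero-baseline subtraction of the first
post-bleach frame (t = 0); normalization of the change against the
pre-bleach mean. The order is fixed by the assay's description and makes
the chain gain-invariant, the corrected value at t = 0 exactly zero, and
the chain an exact inverse of the simulator's corruption in the noiseless
case. One ambiguity is acknowledged: "normalized against pre-bleach
values" can also be read as normalizing by the *bleached amount* (so the
curve plateaus at the mobile fraction); both modes exist behind
`normalization =`, with the pre-bleach reading as default.

`fit_recovery()` exists for parameter recovery: it fits
$F(t) = M (1 - e^{-t \ln 2 / t_{1/2}})$ to the corrected post-bleach
series rescaled by the estimated bleach depth
$1 - B_{t_0}/\bar B_{pre}$, so $M$ is the standard mobile fraction — the
recovered fraction of the bleached signal — independent of how deep the
bleach was. The fit is bounded ($M \in [0, 1.5]$, $t_{1/2} > 0$),
multi-start over a half-time grid plus a coarse grid-search anchor that
also serves as the fallback for degenerate, immobile traces (where the
half-time is unidentifiable and flagged).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, at
a deliberately reduced scale:

* **Geometry** — an ellipsoidal embryo partitioned into `n_cells` cells by
  a seeded nearest-seed tessellation in physical coordinates (cells were
  real in the source experiments; a tessellation is the controllable
  stand-in). Default grids use 0.4 µm z-steps and 0.13 µm pixels, the
  acquisition geometry for this kind of imaging.
* **Membrane channel** — bright exactly on the boundary voxel set,
  blurred by an anisotropic Gaussian PSF stand-in, plus background and
  optional Poisson–Gaussian camera noise (off by default so tests can be
  exact).
* **Spots** — anisotropic Gaussians at continuous centres with lognormal
  peak amplitudes. Membrane-proximal spots are sampled uniformly from the
  band `d ≤ 0.35 µm`, the rest uniformly beyond it, so `p_membrane` is
  exactly recoverable; `p_membrane = NULL` places spots uniformly over
  the whole cell volume (the spatially random configuration the null
  control should reproduce). Ground-truth distances are defined as the
  trilinearly interpolated distance-map values at the true centres — the
  same quantity the pipeline estimates — so recovery error isolates
  detection and measurement error, while the distance map itself is
  validated independently against brute force.
* **Colocalization scenes** — mRNA spots with a controllable probability
  of carrying a partner spot (within a jitter radius) and per-channel
  detection efficiencies, with all pairings recorded.
* **FRAP traces** — the closed-form recovery corrupted by per-frame
  acquisition bleaching, background, and Gaussian noise, with the
  noiseless normalized curve stored as ground truth.

What the generator does **not** emulate: real optics (no
diffraction/optical-sectioning model beyond the Gaussian PSF),
autofluorescence and structured background, cell division and embryo
development, chromatic shifts between channels, and stage drift. Passing
the recovery suite therefore demonstrates the *computational* chain is
unbiased under its stated assumptions; it does not certify performance on
any particular microscope's data, whose gates and thresholds must be
recalibrated.

## Problem sizes and numerical choices in the test suite

The suite and the acceptance script run entirely on generated scenes,
sized for a laptop-class single core: dense-recovery embryos on a
56 × 200 × 200 voxel grid (≈ 22 × 26 × 26 µm at the default calibration)
with 2000 spots for p ∈ {0.3, 0.5, 0.8}; twenty 32 × 96 × 96 embryos with
250 spots each for the z-flip comparisons; 150-spot scenes at ≥ 4 σ
spacing and peak SNR ≈ 10 for the detection operating point; 1000-spot
channel pairs for colocalization; 50 noisy replicates for FRAP and ratio
Monte-Carlo checks. The dense grid size was chosen so that uniform
placement of 2000 spots does not push typical nearest-neighbour spacing
deep below 4 σ, where PSF-overlap merging — not the statistic — dominates
the error of any detector.

Other numerical choices: symmetric (reflecting) boundary handling in all
separable convolutions, which conserves total intensity for normalized
kernels; deterministic tie-breaks everywhere (flood order by descending
intensity then linear index; matching by ascending offset then ids); and
a single RNG seed per generator call (`withr::with_seed`) so that every
scene is bit-reproducible given its parameters.

## Known limitations

* Distances inherit up to half a voxel diagonal of discretization error;
  at 0.4 µm z-steps this is material relative to the 0.35 µm band, and it
  is the main reason recovered fractions carry a small residual bias at
  high membrane enrichment.
* The distance-rule categorization (nuclear pore / membrane / cytosol)
  replaces visual scoring with a reproducible rule; where a nuclear
  marker is absent, spots can only be assigned membrane/cytosol, as the
  original scoring also notes.
* The FRAP model is a single-component exponential; diffusion-reaction
  kinetics are out of scope.
* Intensity gates are not transferable across cameras; they are
  configuration, not constants.
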