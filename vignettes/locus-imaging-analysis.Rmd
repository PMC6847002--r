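---
title: "Quantifying genomic-locus detection, colocalization and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genomic-locus detection, colocalization and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotloci)
```

## Scope and model

CRISPR-based locus imaging labels a programmed genomic site with a
fluorescent reporter — here a dCas9/sgRNA complex read out either by a GFP
fusion or by FRET between two molecular beacons hybridized to an engineered
sgRNA. What the microscope delivers is a 3D fluorescence z-stack (or a 2D
time-lapse movie) in which each labeled locus appears as a diffraction-limited
bright spot over autofluorescent nuclear background. `spotloci` implements the
downstream quantification:

1. **Locus calling** in z-stacks: rolling-ball background subtraction, an
   anisotropic 3D Laplacian-of-Gaussian (LoG) filter, per-slice 2D maxima,
   and promotion to 3D maxima by a 5×5×5-voxel cube test. Each accepted 3D
   maximum is one locus; loci are counted per nucleus ROI.
2. **Two-channel colocalization**: a spot in the beacon/FRET channel counts
   as colocalized if a reference-channel 3D maximum lies within a centered
   7×7×7-voxel cube; the percentage is normalized by the number of beacon
   maxima.
3. **SNR**: `(spot maximum − background mean) / background sd` on the raw 2D
   image.
4. **Tracking**: per-frame LoG peak detection with subpixel centroid
   refinement, frame-to-frame linking by a linear assignment problem (LAP),
   and optional gap closing by a second assignment between track ends and
   starts.
5. **Dynamics**: the co-movement cross-correlation coefficient ρ between
   channel-paired trajectories, and per-track time-averaged mean squared
   displacement fitted as MSD = 4·D~eff~·Δτ^α^ with tracks classed diffusive
   (α < 1.2) or directed (α > 1.2).

A synthetic-microscopy generator with exact ground truth backs every stage,
so the pipeline is testable end to end without external data.

## The synthetic generator and what it emulates

`generate_stack()` renders diffraction-limited spots as anisotropic 3D
Gaussians over a uniform nuclear background, then applies Poisson shot noise,
additive Gaussian read noise and quantization — the dominant noise sources of
an EMCCD widefield acquisition (EMCCD excess noise and photobleaching are
deliberately not modeled). `simulate_tracks()` produces 2D trajectories with
per-axis Gaussian steps of variance 2·D·Δt plus an optional constant drift of
fixed random heading per particle, and adds Gaussian localization noise to
the reported positions; `render_movie()` turns these into image sequences
with the same camera model.

Defaults were chosen once, from the acquisition physics, and are plain
function arguments:

| parameter | default | rationale |
|---|---|---|
| `pixel_size` | 0.16 µm/px | typical 100×/EMCCD scale; all dynamics are in µm so any positive value works |
| `z_step` | 0.25 µm | standard z-increment for 3D locus stacks |
| `psf_sigma_lateral` | 1 px | diffraction: σ ≈ 0.21·λ/NA ≈ 0.1 µm for visible emission at NA 1.4, slightly broadened by pixelation |
| `psf_sigma_axial` | 1 slice | widefield axial extent ≈ 0.25 µm at this NA |
| `background_level` | 100 photons | autofluorescent nuclear background with shot noise sd ≈ 10 |
| `read_noise_sd` | 2 photons | back-illuminated EMCCD scale |
| spot `min_separation` | 6 voxels (~1 µm) | distinct genomic loci resolvable by widefield optics; requests below 2·σ are rejected as unresolvable |
| frame rates | 10 fps (co-movement), 50 fps (diffusion) | the two acquisition modes the tracking parameter sets belong to |

What the generator does **not** reproduce: spatially structured
autofluorescence, chromatic offsets between channels, spectral bleed-through,
focus drift, and EMCCD gain noise. Passing the bundled tests therefore
demonstrates that the *algorithms* are correct under the stated image model,
not that any particular biological detection efficiency would be reached on
real cells.

## Detection: choices behind each stage

**Rolling ball.** The background estimate is the grayscale opening of each
slice with a ball-shaped (hemispherical) structuring element — the literal
rolling-ball construction: the background under a pixel is the top of the
highest ball of the given radius that fits beneath the intensity surface.
A flat or slowly varying background is reproduced exactly (and hence removed);
a bright spot narrower than the ball is untouched. The radius default is 2 px,
the published setting; note this only "enhances particulate objects" when
spots are about as narrow as the ball, which is the case at the default PSF
scale.

**3D LoG.** The stack is smoothed with an anisotropic Gaussian
(`sigma_lateral` 2 px, `sigma_axial` 1 slice by default, accommodating
z-steps coarser than pixels) and the negated discrete Laplacian is returned,
so blob centers are maxima. Convolution uses replicate padding; stacks with
fewer than 3 slices fall back to per-slice 2D LoG with a warning.

**Threshold.** The published procedure sets the intensity threshold manually.
As a reproducible stand-in, `detect_loci()` defaults to
`median + 6·MAD` of the filtered voxels inside the ROI; a numeric threshold
can always be supplied instead. A small numerical floor (10⁻⁸ of the input
scale) keeps floating-point residue of featureless images below threshold.

**Maxima.** Per-slice maxima use the 8-neighbor rule: ≥ all neighbors and
strictly > at least one, so constant regions yield nothing; an equal-intensity
plateau contributes exactly one representative, the first in row-major scan
order. Edge pixels are excluded. The cube test promotes a 2D maximum to a
locus iff it is ≥ every voxel of its (truncated) 5×5×5 cube — non-strict, so
a maximum never disqualifies itself; exact ties within each other's cubes
keep the first in (slice, row, col) order. All indices are 1-based
`(slice, row, col)`, the R convention, and are documented as such in every
output.

**Colocalization.** Cube membership is the per-axis (Chebyshev) test
`|Δ| ≤ 3`, matching a "voxel cube" literally rather than a Euclidean ball.
Each beacon maximum counts at most one event; a single reference locus may
serve several beacon loci, since the definition imposes no one-to-one
matching. The percentage is undefined (an explicit error) when the beacon
channel has no maxima.

**SNR.** The background region is not specified by the formula; the default
is an annulus (inner radius 5 px, outer 10 px) around the spot, with an
explicit background-mask alternative (e.g. whole nucleus minus spots). No
exposure normalization is applied.

## Tracking: the assignment formulation

Linking is two sequential rectangular assignment problems, the "simple LAP"
contract: frame-to-frame links cost their squared displacement, candidate
links beyond the gating distance are forbidden, and every point may instead
remain unlinked at cost (1.05·gate)² — the conventional alternative-cost
choice. The solver is a shortest-augmenting-path (Jonker–Volgenant style)
implementation, exact, and verified in the test suite against exhaustive
enumeration of all matchings. Gap closing repeats the construction between
track ends and later track starts (frame difference 2 … max gap + 1,
distance ≤ gap gate) and merges chains transitively; with both gates zero —
the co-movement parameter set — it is the identity. No merging or splitting
events are modeled, as the published parameter sets do not enable them.
Peaks are refined to subpixel positions by an intensity-weighted centroid of
the non-negative LoG response over a (2·⌈σ⌉+1)² window — a deliberate,
simple choice; a Gaussian fit would be the natural upgrade. Tracks shorter
than 2 points are dropped before dynamics. Within a frame, peaks are
processed in (x, y) order so results do not depend on input-row order.

The two published parameter sets are built into `pipeline_config()`:
co-movement (10 fps): linking 0.5 µm, no gap closing; diffusion (50 fps):
linking 0.1 µm, gap closing 0.4 µm over up to 4 frames.

## Dynamics: ρ and the MSD fit

The co-movement coefficient is computed exactly as the printed formula
states, on raw 2D **position** vectors over the common frames of a pair:
numerator `⟨r_A·r_B⟩ − ⟨r_A⟩·⟨r_B⟩`, denominator the root of the product of
the per-track variance terms `⟨r²⟩ − ⟨r⟩²`. It is 1 for identical (or
positively scaled) trajectories, −1 for sign-flipped mean-centered ones, and
invariant under common translations. Because position vectors are strongly
autocorrelated, independent trajectories give a broad null distribution
centered at zero — the reason a displacement-based variant (the same formula
on frame-to-frame displacement vectors) is also provided behind
`method = "displacement"`; the position form is the default because it is
the printed one. Stationary tracks (zero variance) are a degeneracy error.

The MSD is time-averaged over all surviving point pairs at each integer lag,
with lags lost to gaps omitted and pair counts recorded. The fit is
unweighted OLS of log MSD on log Δτ over the first 25 % of available lags
(at least 2), per track; slope = α, intercept = log(4·D~eff~) with no bias
correction on the back-transform. Tracks with fewer than 15 lags, a fit
R² ≤ 0.8, or a zero MSD inside the fit window (log undefined) are rejected
with a recorded reason. α exactly at the 1.2 boundary is classed diffusive.
Lowering the R² bound can only accept more tracks, never fewer.

Two numerical notes: localization noise adds a constant 4·σ² to every MSD
lag, which flattens the low-lag slope — fitted α on noisy Brownian tracks is
therefore biased below 1 (≈ 0.7 at σ = 0.02 µm, D = 0.01 µm²/s, 50 fps),
while on noiseless tracks the median α is within 0.1 of 1. This is a
property of the estimator, not a defect; the diffusive/directed boundary at
1.2 is robust to it. Second, single-track time-averaged MSD values at large
lags are strongly correlated, which is why only the first quarter of lags is
fitted.

## Pipelines, formats and interface

`run_locus_pipeline()` orchestrates stacks → loci → counts → colocalization →
SNR; `run_dynamics_pipeline()` orchestrates movies → peaks → tracks → ρ or
MSD fits, selecting the published gate set by `mode`. Stacks and movies are
multi-page grayscale 16-bit TIFFs (RGB or ragged pages are format errors);
ground truth travels in CSV + JSON sidecars; configurations round-trip
through YAML with every default equal to the published value where one
exists. ROIs are supplied as labeled integer masks (or generated from the
synthetic nucleus truth) — interactive ROI drawing is out of scope. All
functionality is exposed as documented R functions; no shell entry point is
shipped, since an R session (or a two-line `Rscript -e`) is the natural way
this package is driven.

Problem sizes in the bundled tests were chosen so the whole suite runs in
well under a minute on one core: stacks of roughly 12×48×48 voxels, scenes
of up to 10 spots, movies of 30–100 frames, and 100–1000 simulated tracks
per Monte-Carlo check; each such size is stated where it is used.

## Known limitations

* The Gaussian PSF and uniform background are idealizations; detection
  thresholds tuned on synthetic data will need re-tuning on real stacks.
* The MAD-based automatic threshold is a stand-in for the published manual
  thresholding and is the least transferable parameter.
* Deconvolved stacks are not modeled; the pipeline analyzes raw intensities.
* FRET photophysics (efficiency, bleed-through) is entirely out of scope:
  the FRET channel is treated as just another intensity channel.
* The α classifier inherits the localization-noise bias described above;
  with very noisy localization a drifting track can be under-classified.
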