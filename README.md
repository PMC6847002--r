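# spotloci

Quantitative analysis of widefield fluorescence microscopy data from
CRISPR-based genomic-locus imaging experiments, in which a programmed,
possibly non-repetitive genomic site is labeled by a dCas9/sgRNA complex and
read out either through a fluorescent-protein fusion or through FRET between
two molecular beacons hybridized to an engineered sgRNA. Each labeled locus
appears as a diffraction-limited spot in a 3D z-stack or a 2D time-lapse
movie; everything downstream of the camera is what this package computes.

For microscopists and computational biologists, `spotloci` provides:

* **3D locus calling** — rolling-ball background subtraction, anisotropic 3D
  Laplacian-of-Gaussian filtering, per-slice 2D maxima, and a 5×5×5-voxel
  cube test that promotes a 2D maximum to a single locus; per-nucleus counts.
* **Two-channel colocalization** — a beacon/FRET maximum is an event iff a
  reference (EGFP) 3D maximum lies in its centered 7×7×7-voxel cube;
  `%coloc = 100 · events / beacon maxima`.
* **SNR** — `(i_spot,max − i_bg,mean) / i_bg,sd` on the raw 2D image.
* **Single-particle tracking** — LoG peak detection with subpixel centroids,
  linear-assignment (LAP) frame-to-frame linking, optional gap closing; the
  two published parameter sets (co-movement: link 0.5 µm, no gap closing at
  10 fps; diffusion: link 0.1 µm, gap 0.4 µm / ≤ 4 frames at 50 fps) are
  built into `pipeline_config()`.
* **Dynamics** — the co-movement cross-correlation coefficient
  ρ = (⟨r_A·r_B⟩ − ⟨r_A⟩·⟨r_B⟩) / [(⟨r_A²⟩ − ⟨r_A⟩²)(⟨r_B²⟩ − ⟨r_B⟩²)]^½
  for channel-paired trajectories, and per-track time-averaged MSD fitted as
  MSD = 4·D_eff·Δτ^α (log–log OLS over the first 25 % of lags, ≥ 15 lags,
  R² > 0.8), with α < 1.2 classed diffusive and α > 1.2 directed.
* **A synthetic-microscopy generator** with exact ground truth (Gaussian-PSF
  spots, Poisson + read noise, Brownian/drifting trajectories), so every
  stage is testable without external data.

## Worked example

```r
library(spotloci)

# a two-channel nucleus: 10 loci, half colocalized with a (0,1,1)-voxel offset
params <- acquisition_params(image_shape = c(14, 56, 56))
scene  <- generate_two_channel_scene(params, n_spots = 10, coloc_fraction = 0.5,
                                     offset_voxels = c(0, 1, 1), seed = 11)

config <- pipeline_config(acquisition = params)
labels <- matrix(0L, 56, 56)
labels[scene$truth_a$nucleus_mask] <- 1L
bundle <- run_locus_pipeline(config, list(scene$stack_b, scene$stack_a), roi = labels)

bundle$counts
#>   nucleus_id n_loci   channel
#> 1          1     10        MB
#> 2          1     10 reference
bundle$colocalization
#> 3D colocalization (7x7x7 cube): 5 / 10 MB maxima colocalized (50.0%)
round(mean(bundle$snr$snr, na.rm = TRUE), 1)
#> [1] 15.8
```

Both channels recover all 10 true loci; the constructed 50 % colocalized
fraction is reported exactly (the (0,1,1) offset lies inside the 7×7×7 cube),
and the mean spot SNR of ~16 reflects the simulated amplitudes over the
Poisson background.

```r
# diffusing loci at 50 fps: simulate, fit per-track MSD power laws
sim  <- simulate_tracks(n_particles = 50, n_frames = 100, frame_interval = 1/50,
                        D = 0.01, v = 0, loc_noise_sd = 0, seed = 2,
                        extent = c(40, 40))
fits <- fit_all_tracks(truth_to_tracks(sim), frame_interval = 1/50)
accepted <- subset(fits, motion_class != "rejected")
summary(accepted$alpha)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.5780  0.8751  0.9789  0.9748  1.0769  1.2827
median(accepted$d_eff)
#> [1] 0.008817011
table(accepted$motion_class)
#> diffusive  directed
#>        44         6

mass_ratio_percent(242, 1760)
#> mass ratio: 13.75% (reported as 14%)
```

The fitted diffusive exponents center on 1 (median 0.98) and the median
effective diffusion coefficient recovers the simulated 0.01 µm²/s within
12 %; a few single-track fits scatter past the 1.2 boundary, which is the
expected sampling variability of time-averaged MSD on 100-frame tracks.

## Conventions

Voxel indices are 1-based `(slice, row, col)` / `(z, y, x)`; subpixel movie
positions are micrometres with pixel centers at `(index − 1) · pixel_size`;
times are seconds. See the vignette
(`vignettes/locus-imaging-analysis.Rmd`) for the full account of the model,
parameter defaults and their rationale, and known limitations.
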