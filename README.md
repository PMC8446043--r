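# rnpdyn

Quantitative dynamics of RNP granules from time-lapse fluorescence
microscopy.

RNP granules are membrane-less condensates storing repressed mRNAs.  A
central question about any such condensate is whether it behaves like a
liquid — molecules exchange freely with the cytoplasm — or has hardened
into a gel, where exchange slows drastically while the granule's bulk
mobility, size and shape barely change.  `rnpdyn` implements the four
image-analysis read-outs that separate these scenarios on calibrated
`(t, y, x)` confocal stacks, plus seeded synthetic-data generators with
known ground truth so the whole chain is testable without any raw data:

* **DDM (differential dynamic microscopy)** — ensemble granule mobility
  without tracking.  From Fourier-space frame differences, the image
  structure function `D(q, Δt) = A(q)[1 − f(q, Δt)] + B` is calibrated
  (noise floor `B` from the high-q tail, amplitude `A(q)` from the
  large-lag plateau), inverted to the intermediate scattering function
  `f`, converted per wave vector to `MSD_q(Δt) = −(4/q²) ln f`,
  extrapolated linearly to `q → 0` over the band 0.4–0.8 µm⁻¹, and fitted
  by `MSD₀(Δt) = 4 D₀ Δt`.
* **FRAP by Gaussian spot broadening** — the azimuthally averaged
  bleach-depth profile is fitted per frame by `A(t) exp(−r²/σ(t)²) + B(t)`;
  free diffusion gives `σ²(t) = σ₀² + 4Dt`, and a 30 s linear fit yields
  `D`.  Robust against bright granules drifting through the bleached spot,
  which ruins classical recovery curves.
* **FLIP** — repeated bleaching of one region while granule and cytoplasm
  ROIs are monitored; traces are corrected by a constant background,
  normalized as `iₙ(t) = (Iₙ(t) − I_B)/(Iₙ,₀ − I_B)`, and summarised by the
  one-parameter fit of `exp(−(t/τ)^0.75)`.  A ±25% background-perturbation
  sweep checks that group differences don't hinge on the background
  estimate.
* **Morphometry** — frozen-threshold segmentation (4-connectivity),
  boundary-polygon shape factor `4πA/P²`, mutual-nearest-neighbour track
  linking, and Mann–Whitney size-distribution comparisons.

## Worked example

Simulate a granule movie at a known mobility and recover it with the full
DDM chain:

```r
library(rnpdyn)

mov <- simulate_brownian_movie(brownian_movie_config(
  n_particles = 150, diffusion_um2_s = 0.023,   # ground truth, um^2/s
  field_um = 45, pixel_size_um = 0.22,
  frame_interval_s = 10, n_frames = 180, noise_sigma = 3, seed = 1))

res <- ddm_pipeline(mov$sequence,
                    analysis_config(ddm = list(gamma = 1, min_lag_s = 0)))
res$calibration$B
#> [1] 18.00758        # noise floor; i.i.d. noise of SD 3 gives exactly 2*3^2
res$msd
#> MSDCurve: 120 lags, band 0.40-0.80 um^-1, D0 = 0.02181 +/- 0.00039 um^2/s
```

The recovered `D0` lands within the seed-to-seed spread (~0.006 µm²/s for
a single 30-minute movie) of the 0.023 µm²/s ground truth; averaging over
movies, as one would average over cells, centres on the truth.  The same
movie yields granule counts and shapes via `segment_granules()`, tracks
via `link_tracks()`, and the FLIP/FRAP chains run analogously
(`flip_pipeline()`, `frap_pipeline()`).

A command-line driver covers the same pipelines:

```sh
Rscript inst/cli/rnpdyn simulate --what brownian --seed 7 --out out/
Rscript inst/cli/rnpdyn ddm --input out/movie.tif --pixel-size 0.22 \
        --frame-interval 10 --out out/
```

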