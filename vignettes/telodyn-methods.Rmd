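---
title: "telodyn: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{telodyn: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodyn)
```

# Scope

`telodyn` quantifies the mobility of fluorescently tagged genomic loci from
time-lapse movies: spot detection, trajectory linking and filtering, drift
correction, time-averaged MSD estimation, anomalous- and confined-diffusion
fits, and 3D foci aggregation/colocalization. Everything operates on a
single unit convention — **nm for coordinates, seconds for time** — with
pixels and µm appearing only at I/O boundaries (`pixel_size`, `z_step`,
`dt`). MSD values are reported in µm².

# Generative models

The simulator states the world the rest of the package is tested against.

**Brownian motion.** Axis increments are i.i.d. Gaussian with variance
`2 D dt`, so the 2D ensemble MSD is `4 D t`.

**Fractional Brownian motion.** For a prescribed anomalous exponent
`α ∈ (0, 2]`, each axis is an exact fBm with Hurst exponent `H = α/2`,
scaled so the 2D ensemble MSD is `4 D_α t^α`. Generation uses circulant
embedding (Davies–Harte): the fractional-Gaussian-noise autocovariance is
embedded in a circulant matrix whose eigenvalues come from one FFT, and
conjugate-symmetric complex normals synthesize exact sample paths. If the
embedding ever produced a negative eigenvalue the sampler falls back to a
Cholesky factorization of the Toeplitz covariance. Euler-type
approximations were deliberately avoided: they bias the increment
correlations and hence the recovered exponent, which is exactly the
statistic the acceptance tests measure. At `α = 2` (`H = 1`) fBm
degenerates to ballistic motion with a random velocity; that limit is
handled explicitly.

**Confined + macroscopic motion.** Each axis is the sum of a *stationary*
Ornstein–Uhlenbeck process (stationary variance `A/4` per axis, relaxation
time `τ`, exact discrete-time update `x' = ρ x + N(0, (A/4)(1 − ρ²))` with
`ρ = e^(−dt/τ)`) and an independent Brownian motion with coefficient
`D_macro`. Initializing from the stationary distribution makes the
closed-form 2D ensemble MSD

`MSD(t) = A (1 − e^(−t/τ)) + 4 D_macro t`

hold exactly from `t = 0`, so the fit target is analytic rather than
asymptotic.

**Rendering.** Frames are constant background plus 2D Gaussian spots
(σ = `psf_sigma` px, default 1.3) at the true positions, with optional
Poisson shot noise and Gaussian read noise, written as uncompressed
multi-page TIFF. Drift is a deterministic per-frame offset (constant
velocity or sinusoid) applied identically to all particles — by
construction the component that centroid subtraction can remove.

**Defaults.** The acquisition defaults mirror a spinning-disk confocal
recording of nuclear loci: 512 × 512 frames, 4 frames/s for 120 s
(480 frames, `dt = 0.25 s`), 66.3 nm pixels (three pixels = 198.9 nm),
0.5 µm z-steps. No spot density, intensity or SNR is published for such
movies, so the noise defaults (`spot_intensity = 100`, `background = 10`,
`photon_scale = 1`, `read_noise = 2`, ~5–50 spots per nucleus) were chosen
once to give a realistic-but-comfortable SNR ≈ 10 and are not tuned per
test. `D_α = 0.01 µm²/s^α` puts one-second displacements near 200 nm,
a plausible scale for chromatin loci; exponent recovery is insensitive to
this choice because `α` is scale-free.

**What the generator does not emulate:** photobleaching, blinking,
EMCCD gain statistics, 3D PSFs (z-stacks are foci tables or simple blobs),
nuclear boundaries, and locus-locus interactions. A green recovery test
therefore establishes correctness of the estimators under the stated
model, not robustness to every imaging pathology.

# Detection

Single-scale Laplacian-of-Gaussian filtering at the expected spot width,
8-neighborhood local maxima (strict on half the neighborhood so plateaus
yield one peak), and a threshold that defaults to
`max(5·mad(response), 2% of peak response)` — the relative floor keeps
noiseless images from surfacing FFT ripple. Convolution uses
replicate-padding so a constant background produces zero response
everywhere including the border. Sub-pixel positions come from an
intensity-weighted centroid in a window of radius `2σ` (with a truncation
de-bias on the moment-based width); `refine = "gaussian"` performs full 2D
Gaussian least squares and should be used when accurate widths are needed,
e.g. for `estimate_spot_diameter()`, which returns the median FWHM
(`2√(2 ln 2)·σ`) over isolated spots. 3D detection refuses to run without
explicit voxel spacing — guessing isotropy on 66.3 nm × 500 nm voxels
would corrupt every distance-based measurement downstream.

Pixel convention: position (0, 0) is the center of the top-left pixel,
x along columns, y along rows, 0-based frames.

# Linking and filters

Linking is frame-by-frame **global greedy** assignment: all (open
trajectory, new spot) pairs within the radius are sorted by distance and
accepted one-to-one; ties break by lower trajectory id then spot index, so
the result is deterministic and invariant to spot order. Per-spot nearest
neighbor was rejected because it is ambiguous under ties and can assign
one spot to two trajectories. The default radius is 198.9 nm (three
pixels). Unmatched trajectories stay open for up to `max_gap_frames = 5`
frames with the radius growing by one base radius per elapsed frame,
capped at twice the base radius — a minimal gap-closing mechanism
consistent with the existence of the half-frames filter (gapped
trajectories must be able to exist for the filter to have meaning). Gap
frames are recorded as absent, never interpolated.

The loss filter keeps a trajectory iff it is present in at least
`⌈N/2⌉` frames: *exactly half present is kept*, since the rule discards
trajectories that lost *more than* half. At N = 480, presence in 240
frames survives, 239 does not. The cell filter then removes every
trajectory of any nucleus with fewer than 5 survivors. Both filters
together are idempotent.

Drift correction subtracts, per frame, the displacement of the nucleus
centroid (unweighted mean of all spots present that frame) relative to the
first frame where the nucleus has any spot — an anchored, reproducible
reference. Frames with zero spots get a linearly interpolated center and a
logged message.

# MSD estimation

`compute_msd()` averages squared displacements over all pairs of present
frames separated by exactly `n` frames. The published estimator normalizes
by `N − 1 − n`, one fewer than the `N − n` available pairs — an
index-origin artifact. Mode `"standard"` (default) divides by the true
pair count; mode `"literal"` reproduces the printed normalization by
dropping the final pair and dividing by `pairs − 1`, which coincides with
the printed formula on gap-free trajectories. The difference is `O(1/N)`
and invisible at 480 frames, but both behaviors are available rather than
silently "correcting" the source. The standard mode is verified against an
O(N²) brute-force double loop to 1e-12 relative on random gapped
trajectories.

`ensemble_msd()` averages per-trajectory curves lag-wise (mean across
trajectories, SE = sample SD / √count, lags with < 2 curves omitted).
Mean-of-curves was chosen over MSD-of-pooled-displacements because the
published average curves carry per-trajectory ± SE shading, which only the
former defines.

# Model fitting

Both fits are nonlinear least squares **on the linear MSD scale**,
unweighted; log-log regression is used only to initialize (and as a
flagged fallback). Fitting in log space would down-weight exactly the
lags that carry the confinement plateau.

*Anomalous:* bounds `D_α ≥ 0`, `α ∈ (0, 2]` (ballistic ceiling; fits at a
bound are flagged). The default fit range is the first 25% of available
lags, clamped to [5, 60] lags — long lags of a time-averaged MSD are
dominated by correlated noise. With 480-frame trajectories this fits lags
1–60 (0.25–15 s).

*Confined:* multi-start L-BFGS-B (τ from the half-rise, A from the late
plateau, D_macro from the tail slope, plus dispersed starts) followed by a
Gauss–Newton polish, bounds `A ≥ 0, τ > 0, D_macro ≥ 0`. The default fit
range is **all** supplied lags, unlike the anomalous fit: the plateau `A`
and the escape slope `4 D_macro t` are late-lag features and truncating to
the first quarter would make them unidentifiable. `D_micro = A/(4τ)` and
`L = √(A/2)` are computed from the fitted parameters. A curve that is
effectively linear yields `A → 0` with a warning and the slope in
`D_macro` (the Brownian limit nests inside the model).

**Identifiability caveat.** At the simulated scale (`A = 0.04 µm²`,
`τ = 2 s`, `D_macro = 1e-4 µm²/s`, 480 frames) a *single* trajectory's
TA-MSD cannot separate the small escape slope from plateau noise: per-
trajectory `D_macro` estimates pile up at the zero bound and their median
is meaningless. The package therefore validates confined-parameter
recovery on the fit of the *ensemble-mean* curve of 1000 trajectories
(all three parameters within a few percent), mirroring how average MSD
curves are fitted in practice; per-trajectory recovery is asserted only
for the identifiable plateau `A`.

Group summaries (`alpha_distribution()`) use fixed histogram bins of width
0.1 on [0, 2]; group comparison is a two-sided Welch t test implemented in
closed form so that the zero-variance/equal-means edge case returns
`p = 1` instead of erroring.

# Aggregation and colocalization

An aggregation is ≥ 2 foci "clustering together" within half a spot
diameter in 3D. This is implemented as **single linkage** — connected
components of the graph joining all pairs at distance ≤ d/2 (inclusive
boundary, via igraph) — so a chain of close foci counts as one aggregate;
complete linkage is available by flag. Distances are always computed in
physical nm after applying the anisotropic voxel spacing. Note the
aggregate *count* is not monotone in the cutoff (two aggregates can merge
into one); the monotone invariant, asserted by the tests, is the number of
foci belonging to aggregates.

Colocalization uses one-to-one greedy matching by ascending distance, so a
single channel-B focus can never be counted against several channel-A
foci; the fraction is matched-A over total-A. No distance criterion is
published for the original colocalization percentages, so the default
threshold is one spot diameter between centroids (configurable) and
numerical equality with published percentages is not claimed.

# Determinism and seeds

Every stochastic entry point takes a `seed`; the pipeline expands one root
seed into per-stage child seeds by a fixed affine map
(`child_seed()`), so stages can be re-run in isolation and a fixed seed
reproduces byte-identical outputs. All derived seeds stay below 2³¹.

# Known limitations

* The linker is a deterministic nearest-neighbor scheme; it does not
  implement the full linear-assignment cost matrices, Kalman motion
  propagation, or merge/split detection of heavyweight trackers such as
  u-track.
* No nucleus segmentation: spots belong to nucleus 0 unless a label mask
  is supplied.
* The TIFF codec is deliberately minimal (uncompressed grayscale baseline
  TIFF, 8/16-bit uint, 32-bit float); it exists because no TIFF reader is
  available in the dependency budget, and it is cross-validated against an
  independent implementation in the test suite.
* MSD analysis is 2D (movies track a fixed optical section); 3D analysis
  is limited to foci positions in stacks.
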