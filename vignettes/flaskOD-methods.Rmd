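---
title: "flaskOD: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flaskOD: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Optical density (OD) at 600 nm is the standard biomass proxy for
shake-flask cultivations, but it is normally measured offline: a sample is
drawn, diluted when the reading would leave the photometer's linear range,
and read in a cuvette. flaskOD implements a *software sensor* that
estimates OD non-invasively from ordinary colour photographs of the flask.
The premise is the one an experienced technician uses by eye: as biomass
accumulates, the medium's colour drifts monotonically — lighter (L up),
less red (a down), yellower (b up) — and that drift carries enough
information to recover OD once changing illumination and batch-to-batch
medium differences are controlled for.

## Pipeline

1. **Colour space.** Images (sRGB PNG/JPEG) are converted to CIE 1976
   L\*a\*b\* with the D65 reference white (`rgb_to_lab()`). CIELAB is
   approximately perceptually uniform, which matches a method derived from
   human visual inspection and makes Euclidean distance a sensible
   dissimilarity between pixel colours. The white point is not negotiable
   for consumer-camera sRGB material, so it is fixed rather than exposed.

2. **Segmentation.** Each frame's pixels are clustered in Lab by K-means
   (`segment_image()`), minimising
   $J = \sum_n \sum_k r_{nk} \lVert x_n - \mu_k \rVert^2$.
   The cluster count is fixed at $K = 9$ in routine use (chosen once "for
   safety" above the elbow of the $J$-vs-$K$ curve; `select_k_elbow()`
   reproduces that analysis on demand).

3. **ROI tracking.** The flask-medium cluster is chosen by the user on the
   first frame (interactively by index, or non-interactively as a reference
   Lab triple); its centre $\tilde c$ seeds a running reference
   $\bar c$. At every timepoint each of the four replicate frames is
   segmented independently, the cluster centre nearest to $\bar c$
   (Euclidean, lowest index on ties) is matched, and $\bar c$ is replaced
   by the mean of the four matched centres and stored as the measurement's
   ROI colour $c(i)$ (`track_roi()`). Whole-image mean colours are kept as
   illumination references.

4. **Regression.** With $f = g_{1,2,3} = \ln$, the design
   (`build_design_matrix()`) is
   $\hat y_i = \beta_0 + \beta_1 x_1 + \dots + \beta_9 x_9$, where
   $x_{1..3}$ are the log ROI colour, $x_{4..6}$ the log ROI colour of the
   experiment's *first retained* measurement (t = 0.5 h; the medium
   baseline), and $x_{7..9}$ the log whole-image reference. The response is
   $\ln$ OD; the t = 0 row is dropped because its OD is zero by the blank
   definition. OLS (`fit_ols()`) uses a rank-revealing QR and falls back to
   the minimum-norm SVD solution with a warning when the design is rank
   deficient (inevitable with a single experiment, where the baseline
   columns are constant). Predictions back-transform with `exp`
   (`predict_od()`).

5. **Assessment.** $R^2 = 1 - \sum_i (f(y_i)-\hat y_i)^2 / \sum_i
   (f(y_i)-\bar f)^2$; residual autocorrelation with the approximate 95%
   whiteness band $\pm 2/\sqrt{N}$ (0.108 at the campaign size N = 342);
   one-sample Kolmogorov–Smirnov normality on standardised residuals; and
   two cross-validation schemes (`cross_validate()`):
   leave-one-experiment-out (the headline prediction measure) and
   leave-one-out on seed-shuffled rows (for residual autocorrelation).
   Cross-validated $R^2$ is pooled over all held-out predictions, not
   averaged over folds, because the statistic is defined over all i.

```{r}
library(flaskOD)
spec <- campaign_spec(seed = 1)                  # the 18-experiment world
camp <- generate_campaign(spec, dir = "campaign")
cfg <- pipeline_config(manifest = camp$manifest, od_table = camp$summary,
                       out_dir = "out", roi_reference = c(27, 14.5, 27.5),
                       seed = 2)
res <- run_pipeline(cfg)
res$cv        # pooled leave-one-experiment-out R^2
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 9 | clusters per frame; above the elbow (~7) "for safety" |
| `n_restarts` | 5 | greedy k-means++ restarts; best objective wins |
| `subsample` | off | seeded pixel subsample for speed; all pixels are re-assigned to the fitted centres |
| `log_offset` | 0 | `log(v + c0)` colour transform; only needed if a reference channel crosses zero |
| `drop_t0` | TRUE | exclude the t = 0 blank row (OD 0 cannot be logged) |
| `seed` | required | every stochastic step (seeding, subsampling, row shuffles, the generator) derives from recorded seeds |

## K-means: why it is implemented here

The clustering itself is standard, but the sensor needs behaviours that
`stats::kmeans` does not expose: reproducible seeded restarts,
deterministic lowest-index tie-breaking, empty-cluster repair at the
farthest point, and a per-iteration trace asserting that $J$ never
increases. Three robustness measures, each validated on 1000 fresh random
instances:

- Restarts mix *greedy* k-means++ seeding (first two restarts;
  2 + ⌊log K⌋ candidates per step, keeping the one that most reduces the
  potential — scikit-learn's default) with plain k-means++ (remaining
  restarts). The greedy step is load-bearing on images: scenes are
  near-piecewise-constant in colour, so Lloyd iterations cannot migrate a
  centre across empty colour space — a missed colour mode at seeding time
  stays missed, and plain k-means++ misses small far regions often enough
  to matter. Plain restarts supply the diversity greedy seeding lacks on
  small unstructured data.
- For tiny inputs (`choose(n, K)` ≤ 70) Lloyd runs from *every* K-subset
  of points: complete, deterministic seeding.
- For small point sets (n ≤ 2048) a Hartigan–Wong single-point polish runs
  after Lloyd: rare global optima are unreachable by Lloyd from any
  seeding, and exact size-weighted single-point moves repair them. It is
  skipped at pixel scale, where single-point moves change $J$ negligibly
  and each sweep costs a full n × K pass.

Tests verify exhaustive-search optimality on all instances with ≤ 8 points
and K ≤ 3 against an independent assignment-enumeration oracle.

## The synthetic campaign

No images are distributed with the published study, so the package carries
a first-class generator (`generate_campaign()`) that emulates the
campaign's statistical structure: 18 experiments × 20 half-hourly
timepoints (0–9.5 h) × 4 replicate frames; two acquisition locations
(white background, poor contrast; blue background, good contrast)
following the published pattern; exponential growth
OD(t) = 0.01·exp(0.73·(t − 0.5)) calibrated to the published endpoints
(OD 0.01 at 0.5 h, ≈ 7.2 at 9.5 h) with OD(0) = 0 by the blank definition;
the bench dilution protocol (readings above 0.7 diluted by a power of ten,
lognormal noise applied to the diluted reading); and a medium colour that
drifts monotonically with OD.

Noise defaults state the emulated world and were chosen once: Lab pixel
noise sd 1.0 (a plausible smartphone sensor level at this scale),
per-timepoint global lightness offset sd 1.0 with quarter-strength
per-frame jitter (illumination drift; it moves the whole-image references,
which is exactly what $x_{7..9}$ exist to absorb), OD reading CV 5%
(routine photometry), and an inter-experiment medium-baseline shift of
sd 0.5 Lab units. The baseline spread is the one quantity with no
published analogue (same recipe, different batches); 0.5 Lab units —
sub-noticeable by eye — is the package's documented choice, set so that
the whole stated world meets its own design target (pooled LOEO R² ≥ 0.9
through the full image pipeline) with margin.

**Two colour models.** The default family is saturating,
channel = base + slope·ln(1 + 1.7·OD), calibrated to interpolate the
published colour-summary endpoints and finite at OD 0. This family is *not*
exactly representable by the log-log regression: even with every noise
source at zero the pooled R² plateaus near 0.97 — a deliberate, realistic
model-class mismatch. The second family, `colour_model = "loglinear"`
(channel = A·OD^γ, same endpoint calibration), lies exactly inside the
model class; it is the world used for the exactness acceptance check,
where the full pipeline's held-out R² must reach 1 to within 1e-9 as noise
→ 0. That check is run on frames rendered in memory at full precision:
8-bit PNG quantisation (~0.2 Lab units on dark colours) is part of any
real imaging path and would otherwise put a floor under the error.

**The rendered scene** is deliberately schematic — nine flat,
colour-separable regions (background, glass, cap, label, medium, shadow,
bench edge, clamp, label text) plus Gaussian pixel noise and the global
lightness offset — because colour-separability is the pipeline assumption
under test, not photorealism. Nine regions match the fixed K = 9 the way
the real images' cluster structure did; all non-medium colours stay ≥ ~20
Lab units from the medium's whole trajectory, and the closest region pair
sits at location 1 (white background vs white label), which is that
location's documented "poor contrast". A green pipeline test therefore
establishes correctness of segmentation, tracking, feature construction
and modelling under the stated assumptions; it does *not* establish
robustness to reflections, motion blur, HDR tone-mapping, or scenes whose
regions are not colour-separable — the published method itself falls back
to manual re-selection or cropping there, and the package mirrors that via
the mask/crop options rather than solving it.

## Numerical choices and edge cases

- **Log base.** Natural log throughout; the choice only relabels
  coefficients, and a test verifies back-transformed predictions are
  base-invariant.
- **Non-positive channels.** CIELAB a/b can legitimately cross zero; the
  default is a hard error naming the row and channel, with an opt-in
  offset transform `log(v + c0)` recorded in the model metadata. The
  synthetic scenes are built to keep reference means log-safe, as the
  published summary table's were.
- **Baseline indexing.** The published fixed-stride baseline index
  (c(20ℓ+1)) is inconsistent once the t = 0 rows are dropped; the package
  keys the baseline to the first retained measurement of the row's own
  experiment, which is the stated intent.
- **Rank deficiency.** Reported, warned about, and handled by the
  minimum-norm solution; held-out predictions remain exact in the
  noiseless world even under rank deficiency because the test rows lie on
  the training manifold.
- **Ties.** Nearest-centre matching and label assignment break ties by the
  lowest cluster index; clusters are relabelled largest-first per frame so
  user-facing indices are stable.
- **KS caveat.** Location and scale are estimated from the residuals
  themselves, so the nominal KS p-value is approximate (the Lilliefors
  situation); the report flags small samples as low-power.
- **Seeds.** Every stochastic step takes a caller seed; campaign,
  per-experiment, per-frame and per-restart seeds derive from it, and the
  same spec reproduces a campaign bit for bit, PNGs included.

## Known limitations

- EXIF orientation is not read (no EXIF parser in the supported stack);
  rotated phone images must be stored upright.
- The renderer has no camera model: no optics, tone-mapping, specular
  highlights, or motion blur (the published method lists moving-biomass
  imaging as future work).
- No interpolation of missing timepoints and no smoothing of colour
  trajectories; a missing timepoint is a hard, named error.
- Prediction intervals are out of scope (the original analysis reports
  none); only point predictions and pooled R² are produced.
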