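# Synthetic campaign generator.
#
# Emulates the measurement campaign the sensor was designed for: 18
# replicate yeast cultivations, imaged every 30 min from t = 0 to 9.5 h,
# four frames per timepoint, two acquisition locations (white background
# with poor contrast, blue background with good contrast), with the medium
# colour drifting monotonically with OD and a global illumination jitter
# that moves the whole-image reference means. Everything is seeded and
# reproducible; ground truth (true OD, true medium colour, per-experiment
# medium masks) is emitted so that every pipeline stage can be checked
# against an oracle.

#' Specification of a synthetic measurement campaign
#'
#' Defaults state the emulated campaign: 18 experiments, 20 half-hourly
#' timepoints (0 to 9.5 h), 4 frames each, the published inoculum/location
#' pattern, exponential growth calibrated so that OD(0.5 h) = 0.01 and
#' OD(9.5 h) ~ 7.2, and a colour model calibrated to the published
#' colour-summary endpoints. Noise defaults (Lab pixel noise sd 1.0,
#' illumination offset sd 1.0 L units, OD reading CV 5%, inter-experiment
#' baseline colour sd 0.5 Lab units) are the package's calibrated "realistic
#' smartphone campaign" choice; see the methods vignette.
#'
#' @param n_experiments number of cultivations (default 18).
#' @param timepoints sampling times in hours (default `seq(0, 9.5, 0.5)`).
#' @param frames_per_timepoint replicate images per timepoint (default 4).
#' @param location integer vector (1 = white background, 2 = blue
#'   background) per experiment; default follows the published pattern for
#'   18 experiments and alternates otherwise.
#' @param inoculum_ml inoculum volumes per experiment (metadata only).
#' @param od0 OD at the end of the lag phase (default 0.01).
#' @param mu_g specific growth rate per hour (default 0.73).
#' @param lag_h lag-phase duration in hours (default 0.5).
#' @param colour_model `"log1p"` (default; saturating log response,
#'   calibrated to the published table) or `"loglinear"` (power law per
#'   channel, exactly log-log linear -- the in-model-class world used for
#'   exactness checks).
#' @param pixel_sd Gaussian pixel noise sd in Lab units.
#' @param illum_sd sd of the per-timepoint global lightness offset (a
#'   quarter of it is re-drawn per frame as within-timepoint jitter).
#' @param od_cv lognormal CV of the photometer reading.
#' @param baseline_sd sd of the per-experiment medium baseline colour shift
#'   (Lab units).
#' @param dilution_threshold OD reading above which the sample is diluted
#'   (default 0.7) by the smallest power of ten bringing it below.
#' @param image_size rendered image size `c(H, W)`; default `c(256, 341)`
#'   (the acquisition aspect scaled down by 3).
#' @param outlier inject one corrupted OD reading per campaign (default
#'   `FALSE`).
#' @param seed master seed; all randomness derives from it.
#' @return an `od_campaign_spec` list.
#' @export
campaign_spec <- function(n_experiments = 18L,
                          timepoints = seq(0, 9.5, by = 0.5),
                          frames_per_timepoint = 4L,
                          location = NULL, inoculum_ml = NULL,
                          od0 = 0.01, mu_g = 0.73, lag_h = 0.5,
                          colour_model = c("log1p", "loglinear"),
                          pixel_sd = 1.0, illum_sd = 1.0, od_cv = 0.05,
                          baseline_sd = 0.5, dilution_threshold = 0.7,
                          image_size = c(256L, 341L), outlier = FALSE,
                          seed = 1L) {
  colour_model <- match.arg(colour_model)
  n <- as.integer(n_experiments)
  if (n < 1L) stop("n_experiments must be >= 1")
  if (mu_g <= 0) stop("mu_g must be positive")
  if (any(c(pixel_sd, illum_sd, od_cv, baseline_sd) < 0))
    stop("noise levels must be >= 0")
  if (is.null(location)) {
    location <- if (n == 18L)
      c(1L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L,
        2L, 2L)
    else rep_len(c(1L, 2L), n)
  }
  if (length(location) != n || !all(location %in% 1:2))
    stop("location must give 1 or 2 for each experiment")
  if (is.null(inoculum_ml))
    inoculum_ml <- if (n == 18L) c(15, 15, 15, rep(10, 15)) else
      rep_len(10, n)
  structure(list(n_experiments = n, timepoints = timepoints,
                 frames_per_timepoint = as.integer(frames_per_timepoint),
                 location = location, inoculum_ml = inoculum_ml,
                 od0 = od0, mu_g = mu_g, lag_h = lag_h,
                 colour_model = colour_model,
                 pixel_sd = pixel_sd, illum_sd = illum_sd, od_cv = od_cv,
                 baseline_sd = baseline_sd,
                 dilution_threshold = dilution_threshold,
                 image_size = as.integer(image_size), outlier = outlier,
                 seed = as.integer(seed)),
            class = "od_campaign_spec")
}

#' Scale all noise sources of a campaign spec
#'
#' Multiplies `pixel_sd`, `illum_sd`, `od_cv` and `baseline_sd` by a common
#' factor; `scale_noise(spec, 0)` is the noiseless world.
#'
#' @param spec `od_campaign_spec`.
#' @param factor non-negative multiplier.
#' @return the rescaled spec.
#' @export
scale_noise <- function(spec, factor) {
  stopifnot(inherits(spec, "od_campaign_spec"), factor >= 0)
  for (f in c("pixel_sd", "illum_sd", "od_cv", "baseline_sd"))
    spec[[f]] <- spec[[f]] * factor
  spec
}

#' Simulate one experiment's OD trajectory and photometer readings
#'
#' True OD follows `OD(t) = od0 * exp(mu_g * max(0, t - lag))` with
#' `OD(0) = 0` (the medium at t = 0 is the photometer blank). Recorded OD
#' emulates the bench protocol: readings above the dilution threshold are
#' diluted by the smallest power of ten bringing them below it, lognormal
#' noise is applied to the *diluted* reading, and the result multiplied back
#' -- so late-time readings carry realistically scaled noise.
#'
#' @param spec `od_campaign_spec`.
#' @param seed integer seed for the reading noise.
#' @return data.frame with `time_h`, `od_true`, `od_recorded`,
#'   `dilution_factor`.
#' @export
generate_od_trajectory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "od_campaign_spec"))
  t <- spec$timepoints
  od_true <- ifelse(abs(t) < 1e-9, 0,
                    spec$od0 * exp(spec$mu_g * pmax(0, t - spec$lag_h)))
  record <- function() {
    vapply(od_true, function(od) {
      if (od <= 0) return(0)
      fct <- 10^max(0, ceiling(log10(od / spec$dilution_threshold)))
      diluted <- od / fct
      reading <- diluted * exp(stats::rnorm(1L, 0, spec$od_cv))
      reading * fct
    }, numeric(1))
  }
  od_recorded <- if (is.null(seed)) record()
                 else withr::with_seed(seed, record())
  fct <- 10^pmax(0, ceiling(log10(pmax(od_true, 1e-12) /
                                    spec$dilution_threshold)))
  fct[od_true <= 0] <- 1
  data.frame(time_h = t, od_true = od_true, od_recorded = od_recorded,
             dilution_factor = fct)
}

# Colour-model coefficients calibrated to the published summary endpoints:
# medium colour (26.83, 14.46, 27.55) at OD 0.01 and (44.93, 5.16, 35.66)
# at OD 7.18. L and b increase with OD, a decreases.
.COLOUR_ANCHOR <- list(od = c(0.01, 7.18),
                       low = c(26.83, 14.46, 27.55),
                       high = c(44.93, 5.16, 35.66))

#' Default colour-model coefficients
#'
#' `"log1p"`: `channel = base + slope * log(1 + k * od)` with
#' `base = (26.8, 14.5, 27.5)`, `slope = (7.0, -3.6, 3.2)`, `k = 1.7` --
#' a saturating response that interpolates the published endpoints and has
#' a finite colour at OD 0. `"loglinear"`: `channel = A * od^gamma` with
#' `A`, `gamma` solved exactly from the two anchors (OD clamped below at
#' `od_floor = 0.01`); this family is exactly log-log linear, i.e. inside
#' the regression's model class.
#'
#' @param model `"log1p"` or `"loglinear"`.
#' @return coefficient list for [od_to_lab()].
#' @export
colour_coefficients <- function(model = c("log1p", "loglinear")) {
  model <- match.arg(model)
  if (model == "log1p") {
    list(model = "log1p", base = c(26.8, 14.5, 27.5),
         slope = c(7.0, -3.6, 3.2), k = 1.7)
  } else {
    a <- .COLOUR_ANCHOR
    gamma <- log(a$high / a$low) / log(a$od[2] / a$od[1])
    A <- a$low / a$od[1]^gamma
    list(model = "loglinear", A = A, gamma = gamma, od_floor = a$od[1])
  }
}

#' Map optical density to the medium's CIELAB colour
#'
#' @param od non-negative OD value(s).
#' @param coefficients list from [colour_coefficients()] (default: the
#'   `"log1p"` family). A `shift` entry (Lab triple) models per-experiment
#'   medium-baseline differences: added to `base` (log1p) or to `A`
#'   (loglinear, staying within the log-log-linear class).
#' @return `n x 3` matrix with columns `L`, `a`, `b`; `L` and `b` increase
#'   and `a` decreases with OD.
#' @export
od_to_lab <- function(od, coefficients = colour_coefficients("log1p")) {
  if (any(od < 0)) stop("od must be >= 0")
  cf <- coefficients
  shift <- cf$shift %||% c(0, 0, 0)
  lab <- if (identical(cf$model, "loglinear")) {
    odc <- pmax(od, cf$od_floor)
    cbind((cf$A[1] + shift[1]) * odc^cf$gamma[1],
          (cf$A[2] + shift[2]) * odc^cf$gamma[2],
          (cf$A[3] + shift[3]) * odc^cf$gamma[3])
  } else {
    s <- log(1 + cf$k * od)
    cbind(cf$base[1] + shift[1] + cf$slope[1] * s,
          cf$base[2] + shift[2] + cf$slope[2] * s,
          cf$base[3] + shift[3] + cf$slope[3] * s)
  }
  colnames(lab) <- c("L", "a", "b")
  # plausibility guard for user-supplied coefficients
  probe <- lab[which.max(od), , drop = FALSE]
  if (probe[1] <= 0 || probe[1] >= 100 || probe[2] <= 0)
    warning("colour model leaves the plausible range (L in (0,100), a > 0)",
            " at OD ", max(od))
  lab
}

# ---- scene rendering ------------------------------------------------------

# Region palette in Lab. Location 1: white background -- poor contrast (it
# resembles the label and glass highlights); location 2: blue background --
# good contrast (blue is hardly expressed elsewhere in the scene). The blue
# is kept mild and the flask fills most of the close-up frame so that the
# whole-image mean stays log-safe (all three reference channels positive),
# as in the real campaign's summary tables.
# The scene carries nine colour-distinct regions so that the sensor's fixed
# K = 9 matches the scene's natural cluster structure (the real images'
# elbow analysis sat at 7-9); with fewer regions K-means would be forced to
# split the medium region and bias its tracked centre. Distinct regions are
# kept >= ~15 Lab units apart (>= ~20 from the medium's whole trajectory)
# so the 9-region partition is the clear K-means optimum; the closest pair
# sits at location 1 (white background vs white label) -- the "poor
# contrast" setting -- while location 2's blue background is farthest from
# everything, its "good contrast".
.scene_palette <- function(location) {
  if (location == 1L)
    list(background = c(82, 1, 6), glass = c(65, 0, 8),
         cap = c(55, 40, 50), label = c(96, 0, 14),
         shadow = c(48, 1, 2), bench = c(30, 2, 10),
         clamp = c(60, -5, -10), text = c(18, 2, -2))
  else
    list(background = c(40, 4, -25), glass = c(65, 0, 8),
         cap = c(55, 40, 50), label = c(96, 0, 14),
         shadow = c(22, 4, -18), bench = c(30, 2, 10),
         clamp = c(60, -5, -10), text = c(18, 2, -2))
}

# Palette matrix in region-code order (medium = code 5 inserted by caller).
.palette_matrix <- function(pal, medium_lab) {
  rbind(pal$background, pal$glass, pal$cap, pal$label,
        as.numeric(medium_lab), pal$shadow, pal$bench, pal$clamp,
        pal$text)
}

# Region geometry as an integer matrix (1 background, 2 glass body/neck,
# 3 cap, 4 label, 5 medium, 6 shadow, 7 bench edge, 8 clamp, 9 label
# text); memoised per image size.
.region_cache <- new.env(parent = emptyenv())
.scene_regions <- function(image_size) {
  key <- paste(image_size, collapse = "x")
  if (!is.null(.region_cache[[key]])) return(.region_cache[[key]])
  H <- image_size[1L]; W <- image_size[2L]
  if (H < 16L || W < 16L) stop("degenerate image size; need >= 16 x 16")
  rr <- matrix((seq_len(H) - 0.5) / H, H, W)
  cc <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)
  reg <- matrix(1L, H, W)
  body <- ((rr - 0.58) / 0.42)^2 + ((cc - 0.50) / 0.46)^2 <= 1
  neck <- rr >= 0.02 & rr <= 0.20 & cc >= 0.40 & cc <= 0.60
  shadow <- ((rr - 0.80) / 0.30)^2 + ((cc - 0.50) / 0.58)^2 <= 1
  reg[shadow & !(body | neck)] <- 6L                     # cast shadow
  reg[rr >= 0.95 & !(body | neck)] <- 7L                 # bench edge
  reg[rr <= 0.14 & !(body | neck) &
        ((cc >= 0.28 & cc <= 0.40) | (cc >= 0.60 & cc <= 0.72))] <- 8L
  reg[body | neck] <- 2L
  reg[rr <= 0.09 & cc >= 0.36 & cc <= 0.64] <- 3L        # cap
  label <- (rr >= 0.28 & rr <= 0.44) & body
  reg[label] <- 4L
  reg[label & rr >= 0.31 & rr <= 0.41 & cc >= 0.26 & cc <= 0.60] <- 9L
  medium <- ((rr - 0.70) / 0.24)^2 + ((cc - 0.50) / 0.36)^2 <= 1
  reg[medium] <- 5L
  .region_cache[[key]] <- reg
  reg
}

#' Render a schematic flask scene
#'
#' Composes a flat-region scene -- background (white or blue by location), a
#' flask silhouette with cap and label, and an elliptical medium region
#' filled with the requested colour -- in Lab space; adds per-pixel Gaussian
#' noise and a global additive lightness offset (the illumination drift)
#' over the whole frame; converts to sRGB (clipped to gamut). The exact
#' medium-region mask is returned as ground truth. The renderer is
#' deliberately schematic: the pipeline's assumption of colour-separable
#' regions is what is emulated, not photorealism.
#'
#' @param medium_lab Lab triple of the medium.
#' @param location 1 (white background) or 2 (blue background).
#' @param illum_offset additive offset on the L channel of every pixel.
#' @param pixel_sd Gaussian noise sd per Lab channel.
#' @param image_size `c(H, W)`, both >= 16.
#' @param seed integer seed for the pixel noise.
#' @return list with `rgb` (`image_rgb`), `mask` (logical `H x W`, medium
#'   pixels), `regions` (integer matrix), `palette`.
#' @export
render_scene <- function(medium_lab, location = 1L, illum_offset = 0,
                         pixel_sd = 0, image_size = c(256L, 341L),
                         seed = NULL) {
  medium_lab <- as.numeric(medium_lab)
  stopifnot(length(medium_lab) == 3L, location %in% 1:2)
  reg <- .scene_regions(image_size)
  pal <- .scene_palette(location)
  cols <- .palette_matrix(pal, medium_lab)
  H <- dim(reg)[1L]; W <- dim(reg)[2L]
  lab <- cols[as.vector(reg), , drop = FALSE]
  if (pixel_sd > 0) {
    noise <- function() matrix(stats::rnorm(length(lab), 0, pixel_sd),
                               nrow(lab), 3L)
    lab <- lab + if (is.null(seed)) noise()
                 else withr::with_seed(seed, noise())
  }
  lab[, 1L] <- lab[, 1L] + illum_offset
  rgb <- lab_to_rgb(lab)
  list(rgb = structure(array(rgb, c(H, W, 3L)), class = "image_rgb"),
       mask = reg == 5L, regions = reg, palette = pal)
}

# Expected whole-image mean Lab of a scene (area-fraction weighted palette
# plus the global offset on L): the analytic counterpart of mean_lab over a
# noiseless rendered frame, used by the ground-truth-bypass summary.
.scene_reference <- function(medium_lab, location, illum_offset,
                             image_size) {
  reg <- .scene_regions(image_size)
  pal <- .scene_palette(location)
  cols <- .palette_matrix(pal, medium_lab)
  frac <- tabulate(reg, nrow(cols)) / length(reg)
  drop(frac %*% cols) + c(illum_offset, 0, 0)
}

# ---- campaign generation --------------------------------------------------

# Per-experiment seeds: first n for the scene draws, second n for the OD
# reading noise. Derived once from the master seed.
.campaign_seeds <- function(spec) .derive_seeds(spec$seed,
                                                spec$n_experiments * 2L)

# All random draws of one experiment, in a fixed order so that rendered and
# summary-only campaigns (and in-memory re-renders) agree bit for bit.
.experiment_draws <- function(spec, e, exp_seeds = .campaign_seeds(spec)) {
  n_t <- length(spec$timepoints)
  n_f <- spec$frames_per_timepoint
  withr::with_seed(exp_seeds[e], list(
    baseline = stats::rnorm(3L, 0, spec$baseline_sd),
    illum = stats::rnorm(n_t, 0, spec$illum_sd),
    jitter = matrix(stats::rnorm(n_t * n_f, 0, spec$illum_sd / 4),
                    n_t, n_f),
    outlier_at = sample(which(spec$timepoints > 0), 1L),
    outlier_mult = exp(stats::runif(1L, log(3), log(15))),
    frame_seeds = matrix(sample.int(.Machine$integer.max, n_t * n_f),
                         n_t, n_f)
  ))
}

# Ground-truth state of one experiment (trajectory, medium colours, offsets).
.experiment_truth <- function(spec, e, exp_seeds = .campaign_seeds(spec)) {
  draws <- .experiment_draws(spec, e, exp_seeds)
  traj <- generate_od_trajectory(spec,
                                 seed = exp_seeds[spec$n_experiments + e])
  if (spec$outlier)
    traj$od_recorded[draws$outlier_at] <-
      traj$od_recorded[draws$outlier_at] * draws$outlier_mult
  cf <- colour_coefficients(spec$colour_model)
  cf$shift <- draws$baseline
  medium <- od_to_lab(traj$od_true, cf)
  frame_offset <- draws$illum + draws$jitter            # n_t x n_f
  list(draws = draws, traj = traj, medium = medium,
       frame_offset = frame_offset,
       mean_offset = rowMeans(frame_offset))
}

#' Render one experiment's frames in memory
#'
#' Re-creates, without touching the disk, exactly the frames that
#' [generate_campaign()] would write for experiment `e` of `spec` (same
#' seeds, same noise draws) -- but at full floating-point precision, i.e.
#' without the 8-bit PNG quantisation. Used to exercise the tracking
#' pipeline end to end where quantisation would mask exactness.
#'
#' @param spec `od_campaign_spec`.
#' @param e experiment index.
#' @return list with `frames` (list over timepoints of lists of
#'   `image_rgb`), `times`, `truth` (the experiment's ground-truth state).
#' @export
experiment_frames <- function(spec, e) {
  stopifnot(inherits(spec, "od_campaign_spec"))
  st <- .experiment_truth(spec, e)
  n_t <- length(spec$timepoints)
  n_f <- spec$frames_per_timepoint
  loc <- spec$location[e]
  frames <- lapply(seq_len(n_t), function(i)
    lapply(seq_len(n_f), function(j)
      render_scene(st$medium[i, ], location = loc,
                   illum_offset = st$frame_offset[i, j],
                   pixel_sd = spec$pixel_sd,
                   image_size = spec$image_size,
                   seed = st$draws$frame_seeds[i, j])$rgb))
  list(frames = frames, times = spec$timepoints, truth = st)
}

#' Generate a full synthetic campaign
#'
#' Produces, per experiment: an OD trajectory with photometer readings, a
#' per-experiment medium-baseline colour shift, per-timepoint illumination
#' offsets with per-frame jitter, and -- when `render = TRUE` -- the
#' rendered frames written as PNGs with an image manifest and per-experiment
#' ground-truth medium masks. A colour-summary table computed directly from
#' ground truth (bypassing segmentation: ROI = true medium colour plus
#' illumination, reference = analytic scene mean) is always produced, so the
#' feature/model stages can be tested in isolation. All randomness derives
#' from `spec$seed`; the same spec yields bit-identical output.
#'
#' @param spec `od_campaign_spec`.
#' @param dir output directory (required when `render = TRUE`); created if
#'   missing.
#' @param render render and write the frames (default `TRUE` when `dir` is
#'   given).
#' @param write_masks write per-experiment medium masks (PNG) under
#'   `dir/masks` (default `TRUE` when rendering).
#' @return an `od_campaign`: list with `spec`, `ground_truth` (data.frame:
#'   per experiment x timepoint true/recorded OD, intrinsic and observed
#'   medium colour, illumination offsets), `summary` (measurement table in
#'   the standard layout), `manifest` (or `NULL`), `mask_paths`, `dir`.
#' @export
generate_campaign <- function(spec, dir = NULL, render = !is.null(dir),
                              write_masks = render) {
  stopifnot(inherits(spec, "od_campaign_spec"))
  if (render && is.null(dir))
    stop("render = TRUE requires an output directory")
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_e <- spec$n_experiments
  t <- spec$timepoints
  n_t <- length(t)
  n_f <- spec$frames_per_timepoint
  exp_seeds <- .campaign_seeds(spec)

  gt <- list(); summ <- list(); manifest <- list()
  mask_paths <- character(0)
  for (e in seq_len(n_e)) {
    st <- .experiment_truth(spec, e, exp_seeds)
    draws <- st$draws; traj <- st$traj; medium <- st$medium
    frame_offset <- st$frame_offset; mean_offset <- st$mean_offset
    loc <- spec$location[e]

    ref <- t(vapply(seq_len(n_t), function(i)
      .scene_reference(medium[i, ], loc, mean_offset[i], spec$image_size),
      numeric(3)))
    gt[[e]] <- data.frame(
      experiment_id = e, location = loc, time_h = t,
      od_true = traj$od_true, od_recorded = traj$od_recorded,
      L_medium = medium[, 1], a_medium = medium[, 2], b_medium = medium[, 3],
      illum_offset = draws$illum, mean_frame_offset = mean_offset,
      L_observed = medium[, 1] + mean_offset,
      a_observed = medium[, 2], b_observed = medium[, 3])
    summ[[e]] <- data.frame(
      experiment_id = e, time_h = t,
      L = medium[, 1] + mean_offset, a = medium[, 2], b = medium[, 3],
      Lref = ref[, 1], aref = ref[, 2], bref = ref[, 3],
      od = traj$od_recorded)

    if (render) {
      edir <- file.path(dir, sprintf("exp%02d", e))
      dir.create(edir, showWarnings = FALSE)
      for (i in seq_len(n_t)) {
        for (j in seq_len(n_f)) {
          sc <- render_scene(medium[i, ], location = loc,
                             illum_offset = frame_offset[i, j],
                             pixel_sd = spec$pixel_sd,
                             image_size = spec$image_size,
                             seed = draws$frame_seeds[i, j])
          p <- file.path(edir, sprintf("t%04.1f_f%d.png", t[i], j))
          write_image(sc$rgb, p)
          manifest[[length(manifest) + 1L]] <- data.frame(
            experiment_id = e, location = loc,
            inoculum_ml = spec$inoculum_ml[e], time_h = t[i], frame = j,
            path = p)
        }
      }
      if (write_masks) {
        mdir <- file.path(dir, "masks")
        dir.create(mdir, showWarnings = FALSE)
        mp <- file.path(mdir, sprintf("exp%02d.png", e))
        write_mask(.scene_regions(spec$image_size) == 5L, mp)
        mask_paths[e] <- mp
      }
    }
  }

  gt <- do.call(rbind, gt)
  summ <- do.call(rbind, summ)
  manifest <- if (length(manifest)) do.call(rbind, manifest)
  if (!is.null(dir)) {
    write_colour_summary(summ, file.path(dir, "summary.csv"))
    write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    if (!is.null(manifest))
      write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(spec = spec, ground_truth = gt, summary = summ,
                 manifest = manifest, mask_paths = mask_paths, dir = dir),
            class = "od_campaign")
}

#' @export
print.od_campaign <- function(x, ...) {
  cat("Synthetic campaign:", x$spec$n_experiments, "experiments x",
      length(x$spec$timepoints), "timepoints x",
      x$spec$frames_per_timepoint, "frames",
      if (!is.null(x$manifest)) paste0("(", nrow(x$manifest),
                                       " rendered frames)") else
        "(summary only)", "\n")
  invisible(x)
}
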