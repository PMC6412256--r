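# Synthetic campaign generator: trajectories, colour model, renderer,
# campaign determinism.

test_that("growth trajectories are calibrated and dilution bookkeeping holds", {
  spec <- campaign_spec(seed = 1)
  tr <- generate_od_trajectory(spec, seed = 2)
  expect_equal(tr$od_true[tr$time_h == 0], 0)
  expect_equal(tr$od_true[tr$time_h == 0.5], 0.01)
  # endpoint within 2-fold of the published trajectory's 7.18
  expect_gt(tr$od_true[tr$time_h == 9.5], 7.18 / 2)
  expect_lt(tr$od_true[tr$time_h == 9.5], 7.18 * 2)

  # zero noise: exactly exponential after the lag, readings == truth
  spec0 <- scale_noise(spec, 0)
  tr0 <- generate_od_trajectory(spec0, seed = 3)
  expect_equal(tr0$od_recorded, tr0$od_true)
  t_post <- tr0$time_h[tr0$time_h >= 0.5]
  expect_equal(tr0$od_true[tr0$time_h >= 0.5],
               0.01 * exp(0.73 * (t_post - 0.5)), tolerance = 1e-12)

  # dilution: reading above threshold scaled down by a power of ten and
  # back up, so the noiseless recorded value is the true value
  expect_equal(tr0$dilution_factor[tr0$od_true > 0.7 &
                                     tr0$od_true <= 7] , rep(10, sum(
                                       tr0$od_true > 0.7 & tr0$od_true <= 7)))
  expect_error(generate_od_trajectory(campaign_spec(mu_g = -1)),
               "mu_g")
})

test_that("od_to_lab is calibrated to the published endpoints", {
  at0 <- od_to_lab(0)
  expect_equal(unname(at0[1, ]), c(26.8, 14.5, 27.5))
  # monotone: L, b up, a down
  lab <- od_to_lab(seq(0, 8, 0.25))
  expect_true(all(diff(lab[, "L"]) > 0))
  expect_true(all(diff(lab[, "a"]) < 0))
  expect_true(all(diff(lab[, "b"]) > 0))
  # late-time a approaches the published ~5
  expect_lt(abs(od_to_lab(7.18)[1, "a"] - 5.16), 0.6)

  # log-log-linear family interpolates the anchors exactly
  cl <- colour_coefficients("loglinear")
  expect_equal(unname(od_to_lab(0.01, cl)[1, ]), c(26.83, 14.46, 27.55),
               tolerance = 1e-9)
  expect_equal(unname(od_to_lab(7.18, cl)[1, ]), c(44.93, 5.16, 35.66),
               tolerance = 1e-9)
  expect_error(od_to_lab(-1), ">= 0")
  expect_warning(od_to_lab(10, list(model = "log1p", base = c(5, 1, 1),
                                    slope = c(-3, 1, 1), k = 1)),
                 "plausible")
})

test_that("render_scene composes the stated regions with ground truth", {
  med <- c(30, 12, 28)
  sc <- render_scene(med, location = 2, image_size = c(48, 64))
  expect_equal(dim(sc$rgb), c(48, 64, 3))
  expect_true(any(sc$mask))
  # zero noise: mask mean equals the requested colour up to conversion
  lab <- rgb_to_lab(sc$rgb)
  expect_lt(max(abs(mean_lab(lab, sc$mask) - med)), 1e-6)
  # all nine regions present
  expect_equal(sort(unique(as.vector(sc$regions))), 1:9)

  # the blue background sits farther from the medium trajectory than the
  # white one (its "good contrast")
  ods <- seq(0, 7.5, 0.5)
  meds <- od_to_lab(ods)
  dmin <- vapply(1:2, function(loc) {
    bg <- flaskOD:::.scene_palette(loc)$background
    min(sqrt(rowSums(sweep(meds, 2, bg)^2)))
  }, numeric(1))
  expect_gt(dmin[2], dmin[1])

  # frames differ only through seeded jitter
  a <- render_scene(med, 1, pixel_sd = 1, seed = 5, image_size = c(48, 64))
  b <- render_scene(med, 1, pixel_sd = 1, seed = 5, image_size = c(48, 64))
  c <- render_scene(med, 1, pixel_sd = 1, seed = 6, image_size = c(48, 64))
  expect_identical(a$rgb, b$rgb)
  expect_false(identical(a$rgb, c$rgb))
  expect_error(render_scene(med, 1, image_size = c(4, 4)), "degenerate")
})

test_that("campaigns are bit-reproducible and structured as specified", {
  spec <- campaign_spec(n_experiments = 2, timepoints = seq(0, 1.5, 0.5),
                        image_size = c(32, 42), seed = 9)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  c1 <- generate_campaign(spec, dir = d1)
  c2 <- generate_campaign(spec, dir = d2)
  expect_identical(c1$summary, c2$summary)
  expect_identical(c1$ground_truth, c2$ground_truth)
  p1 <- file.path(d1, "exp01", "t00.5_f2.png")
  p2 <- file.path(d2, "exp01", "t00.5_f2.png")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(nrow(c1$manifest), 2 * 4 * 4)
  expect_true(all(file.exists(c1$manifest$path)))
  expect_true(file.exists(file.path(d1, "masks", "exp02.png")))

  # rendered frame's whole-image mean matches the analytic reference
  img <- rgb_to_lab(load_image(p1))
  gt <- c1$ground_truth
  s <- c1$summary
  row <- which(s$experiment_id == 1 & s$time_h == 0.5)
  expect_lt(abs(mean_lab(img)[["L"]] - s$Lref[row]), 0.5)
})

test_that("reference means track the injected illumination offset", {
  camp <- generate_campaign(campaign_spec(n_experiments = 2, seed = 23),
                            render = FALSE)
  for (e in 1:2) {
    g <- camp$ground_truth[camp$ground_truth$experiment_id == e, ]
    s <- camp$summary[camp$summary$experiment_id == e, ]
    # remove the medium-drift component of Lref, then the rest is the
    # injected global offset
    drift_free <- resid(lm(s$Lref ~ g$L_medium))
    expect_gt(cor(drift_free, g$mean_frame_offset), 0.9)
  }
})

test_that("the default colour family sits deliberately outside the model class", {
  # even with every noise source at zero, the saturating (log1p) colour
  # response caps the log-log regression's held-out R^2 near 0.97 -- the
  # documented realistic model-class mismatch (the loglinear family, in
  # contrast, reaches 1 exactly; see the cross-validation tests)
  spec0 <- scale_noise(campaign_spec(seed = 40), 0)
  cv <- suppressWarnings(cross_validate(
    build_design_matrix(generate_campaign(spec0, render = FALSE)$summary),
    "loeo"))
  expect_gt(cv$r_squared, 0.95)
  expect_lt(cv$r_squared, 0.995)
})

test_that("outlier injection corrupts exactly one reading", {
  spec <- campaign_spec(n_experiments = 1, seed = 3)
  base <- generate_campaign(spec, render = FALSE)
  spec$outlier <- TRUE
  out <- generate_campaign(spec, render = FALSE)
  ratio <- out$summary$od / base$summary$od
  changed <- which(is.finite(ratio) & abs(ratio - 1) > 1e-12)
  expect_length(changed, 1L)
  expect_gt(ratio[changed], 3 - 1e-9)
})
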