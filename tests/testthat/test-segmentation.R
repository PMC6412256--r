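# K-means clustering, elbow selection, matching, ROI tracking.

test_that("kmeans_cluster solves the separable and closed-form cases", {
  px <- rbind(matrix(0, 50, 3),
              cbind(100, matrix(0, 50, 2)))
  km <- kmeans_cluster(px, 2, seed = 1)
  expect_equal(km$J, 0)
  expect_setequal(km$centres[, 1], c(0, 100))
  expect_equal(length(unique(km$labels[1:50])), 1L)

  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  km1 <- kmeans_cluster(x, 1, seed = 1)
  expect_equal(km1$centres[1, ], colMeans(x))
  expect_equal(km1$J, sum(sweep(x, 2, colMeans(x))^2))

  expect_error(kmeans_cluster(x, 0), "K must be")
  expect_error(kmeans_cluster(x[0, , drop = FALSE], 2), "empty")
  expect_warning(kmeans_cluster(matrix(1, 10, 3), 3), "distinct")
})

test_that("kmeans_cluster attains the exhaustive-search optimum", {
  # fixed 6-point instance
  x6 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
              c(10, 10, 10), c(11, 10, 10), c(10, 11, 9))
  J_opt <- kmeans_bruteforce_J(x6, 2)
  km <- kmeans_cluster(x6, 2, seed = 5, n_restarts = 20)
  expect_lte(km$J, J_opt * (1 + 1e-9) + 1e-8)

  # property: 50 random instances, n <= 8, K <= 3 (absolute epsilon covers
  # the different floating-point summation orders of the two routes)
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(3:8, 1); K <- sample(2:3, 1)
      x <- matrix(runif(n * 3, 0, 50), n, 3)
      km <- kmeans_cluster(x, K, seed = i, n_restarts = 20)
      expect_lte(km$J, kmeans_bruteforce_J(x, K) * (1 + 1e-9) + 1e-8)
    }
  })
})

test_that("objective is non-increasing and invariant to pixel order", {
  set.seed(11)
  x <- matrix(rnorm(300, sd = 10), 100, 3)
  for (s in 1:5) {
    km <- kmeans_cluster(x, 4, seed = s)
    expect_true(all(diff(km$J_trace) <= 1e-8 * (1 + km$J_trace[-1])))
  }
  # order invariance of the attained optimum needs data where the optimum
  # is reliably found, i.e. separated clusters
  blobs <- withr::with_seed(15, rbind(matrix(rnorm(90, 0, 1), ncol = 3),
                                      matrix(rnorm(90, 30, 1), ncol = 3),
                                      matrix(rnorm(90, -30, 1), ncol = 3)))
  km_a <- kmeans_cluster(blobs, 3, seed = 7, n_restarts = 10)
  perm <- withr::with_seed(8, sample(nrow(blobs)))
  km_b <- kmeans_cluster(blobs[perm, ], 3, seed = 7, n_restarts = 10)
  expect_equal(km_a$J, km_b$J, tolerance = 1e-9)
  expect_identical(kmeans_cluster(x, 3, seed = 7)$centres,
                   kmeans_cluster(x, 3, seed = 7)$centres)  # deterministic
})

test_that("elbow selection finds blob count and degenerate cases", {
  withr::with_seed(21, {
    blobs <- rbind(matrix(rnorm(150, 0, 1), ncol = 3),
                   matrix(rnorm(150, 40, 1), ncol = 3),
                   sweep(matrix(rnorm(150, 0, 1), ncol = 3), 2,
                         c(0, 80, 0), `+`))
  })
  sel <- select_k_elbow(blobs, Kmax = 6, seed = 31)
  expect_equal(sel$K, 3L)
  expect_equal(nrow(sel$curve), 6L)
  expect_true(all(diff(sel$curve$J) <= 1e-6))

  expect_warning(sel1 <- select_k_elbow(matrix(5, 20, 3), Kmax = 4),
                 "distinct")
  expect_equal(sel1$K, 1L)
})

test_that("match_cluster picks nearest centre with lowest-index ties", {
  km <- list(centres = rbind(c(0, 0, 0), c(10, 10, 10)))
  expect_equal(match_cluster(km, c(0, 0, 0))$distance, 0)
  m <- match_cluster(km, c(1, 1, 1))
  expect_equal(m$index, 1L)
  expect_equal(m$centre, c(0, 0, 0))
  # exactly equidistant
  tie <- match_cluster(km, c(5, 5, 5))
  expect_equal(tie$index, 1L)
  expect_error(match_cluster(list(centres = NULL), c(0, 0, 0)), "centres")
})

test_that("segment_image recovers stripes and handles degenerate images", {
  cols <- rbind(c(20, 5, 5), c(60, -10, 30), c(90, 0, -20))
  img <- structure(array(NA_real_, c(9, 6, 3)), class = "image_lab")
  for (s in 1:3) img[(3 * s - 2):(3 * s), , ] <-
    rep(cols[s, ], each = 18)
  seg <- segment_image(img, 3, seed = 2)
  expect_equal(seg$J, 0)
  expect_equal(sort(seg$centres[, 1]), sort(cols[, 1]))
  expect_equal(dim(seg$label_matrix), c(9, 6))
  # each stripe one label
  expect_equal(length(unique(seg$label_matrix[1, ])), 1L)

  expect_warning(seg1 <- segment_image(uniform_lab(c(50, 0, 0)), 9,
                                       seed = 1),
                 "distinct")
  expect_equal(seg1$K, 1L)
  expect_equal(unique(as.vector(seg1$label_matrix)), 1L)

  # subsampled fit assigns every pixel and clusters are size-ordered
  set.seed(5)
  noisy <- structure(array(rnorm(40 * 30 * 3, 50, 20), c(40, 30, 3)),
                     class = "image_lab")
  seg2 <- segment_image(noisy, 4, seed = 9, subsample = 300)
  expect_equal(sum(seg2$sizes), 40 * 30)
  expect_true(all(diff(seg2$sizes) <= 0))
})

test_that("track_roi follows Algorithm-1 bookkeeping", {
  # identical frames at all timepoints -> stored centres constant
  frames <- uniform_frames(replicate(3, c(30, 10, 25), simplify = FALSE))
  tr <- suppressWarnings(track_roi(frames, K = 1, initial = 1, seed = 1))
  expect_equal(nrow(tr$centres), 3L)
  expect_true(all(abs(sweep(tr$centres, 2, c(30, 10, 25))) < 1e-9))
  expect_equal(unname(tr$c_tilde), c(30, 10, 25))
  expect_equal(tr$reference[1, ], c(Lref = 30, aref = 10, bref = 25))

  # c_bar is the arithmetic mean of the four matched centres
  cols <- list(c(20, 4, 10), c(24, 8, 14), c(22, 6, 12), c(26, 10, 16))
  one_tp <- list(lapply(cols, uniform_lab))
  tr2 <- suppressWarnings(track_roi(one_tp, K = 1, initial = 1, seed = 1))
  expect_equal(unname(tr2$centres[1, ]), c(23, 7, 13))

  # errors and warnings
  expect_error(suppressWarnings(
    track_roi(list(one_tp[[1]], NULL), K = 1, initial = 1, seed = 1)),
    "missing timepoint")
  expect_warning(track_roi(list(list(uniform_lab(c(1, 2, 3)))), K = 1,
                           initial = 1, seed = 1),
                 "only 1 frame")
  expect_error(suppressWarnings(
    track_roi(one_tp, K = 1, initial = 5, seed = 1)), "out of range")
})

test_that("noiseless tracking stays on the medium cluster", {
  spec <- scale_noise(campaign_spec(n_experiments = 2,
                                    timepoints = seq(0, 3, 0.5),
                                    image_size = c(48, 64), seed = 77), 0)
  camp <- generate_campaign(spec, render = FALSE)
  for (e in 1:2) {
    ef <- experiment_frames(spec, e)
    tr <- suppressWarnings(track_roi(ef$frames, K = 9,
                                     initial = c(27, 14.5, 27.5),
                                     seed = 3 + e, n_restarts = 2))
    truth <- camp$ground_truth[camp$ground_truth$experiment_id == e, ]
    err <- sqrt(rowSums((tr$centres -
      cbind(truth$L_observed, truth$a_observed, truth$b_observed))^2))
    expect_lt(max(err), 1e-6)   # never switched to a background cluster
  }
})
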