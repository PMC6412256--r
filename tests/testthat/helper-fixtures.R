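# Shared test helpers: small in-code fixtures and oracles.

# Independent sRGB -> CIELAB oracle values, frozen from scikit-image
# (skimage.color.rgb2lab, D65 / CIE 1976): an implementation the package
# shares no code with.
skimage_lab_oracle <- function() {
  list(
    rgb = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1),
                c(0.2, 0.4, 0.6), c(0.8, 0.5, 0.1), c(0.1, 0.7, 0.3),
                c(0.5, 0.5, 0.5)),
    lab = rbind(c(53.2406, 80.0923, 67.2028),
                c(87.7351, -86.1830, 83.1797),
                c(32.2957, 79.1856, -107.8573),
                c(100.0000, -0.0025, 0.0047),
                c(42.0080, -0.1540, -32.8429),
                c(60.0882, 22.5284, 61.1731),
                c(63.9824, -58.9342, 41.1705),
                c(53.3890, -0.0015, 0.0028)))
}

# Exhaustive K-means oracle: global minimum of J over every assignment of
# n points to K clusters (centres = assigned-group means). Feasible for
# n <= 8, K <= 3.
kmeans_bruteforce_J <- function(x, K) {
  n <- nrow(x)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  for (r in seq_len(nrow(grid))) {
    asg <- grid[r, ]
    J <- 0
    for (k in unique(asg)) {
      xs <- x[asg == k, , drop = FALSE]
      mu <- colMeans(xs)
      J <- J + sum(sweep(xs, 2, mu)^2)
    }
    if (J < best) best <- J
  }
  best
}

# A uniform-colour Lab frame.
uniform_lab <- function(lab, H = 8, W = 10) {
  structure(array(rep(lab, each = H * W), c(H, W, 3)),
            class = "image_lab")
}

# Frames list (timepoints x frames) of uniform images, colours given as a
# list over timepoints of 3-vectors.
uniform_frames <- function(colours, n_frames = 4, H = 8, W = 10) {
  lapply(colours, function(cl) replicate(n_frames, uniform_lab(cl, H, W),
                                         simplify = FALSE))
}

# Tiny rendered campaign on disk, cached per-session across test files.
.tiny_cache <- new.env(parent = emptyenv())
tiny_campaign <- function() {
  if (is.null(.tiny_cache$camp)) {
    spec <- campaign_spec(n_experiments = 4,
                          timepoints = seq(0, 2.5, by = 0.5),
                          image_size = c(48, 64), seed = 404L)
    dir <- file.path(tempdir(), "flaskod-tiny-campaign")
    unlink(dir, recursive = TRUE)
    .tiny_cache$camp <- generate_campaign(spec, dir = dir)
  }
  .tiny_cache$camp
}

# Random well-conditioned design with known coefficients; x4-x6 vary across
# two synthetic "experiments" so the full model is identifiable.
random_design <- function(n = 60, seed = 1, sigma = 0,
                          beta = c(0.5, 1.2, -0.7, 0.3, 0.9, -1.1, 0.2,
                                   0.4, -0.3, 0.8)) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 9), n, 9)
    d <- as.data.frame(X)
    names(d) <- paste0("x", 1:9)
    d$experiment_id <- rep(1:2, length.out = n)
    d$time_h <- rep(seq(0.5, by = 0.5, length.out = n / 2), 2)
    d$response <- drop(cbind(1, X) %*% beta) + rnorm(n, 0, sigma)
    d
  })
}
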