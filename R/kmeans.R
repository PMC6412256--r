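# K-means clustering of pixels in CIELAB space.
#
# Objective: J = sum_n sum_k r_nk ||x_n - mu_k||^2, minimised by Lloyd
# iterations from k-means++ starts. Implemented here (rather than delegated)
# because the sensor needs seeded, reproducible restarts, lowest-index
# tie-breaks, empty-cluster repair, and a per-iteration J trace.

# Squared Euclidean distances, n x K.
.dist2 <- function(x, centres) {
  d2 <- -2 * x %*% t(centres)
  d2 <- sweep(d2, 1L, rowSums(x^2), `+`)
  d2 <- sweep(d2, 2L, rowSums(centres^2), `+`)
  pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii): the first centre is uniform;
# each subsequent centre is drawn with probability proportional to the
# squared distance to the nearest chosen centre. With `greedy = TRUE` (the
# refinement that is scikit-learn's default) each step draws
# 2 + floor(log(K)) candidates and keeps the one that most reduces the
# total potential. The greedy step matters on images: scenes are
# near-piecewise-constant in colour, so Lloyd iterations cannot migrate a
# centre across empty colour space and seeding must hit every colour mode.
# Plain seeding explores more and complements it on small unstructured
# data, so restarts mix the two. Uses the current RNG stream.
.kmeanspp_init <- function(x, K, greedy = TRUE) {
  n <- nrow(x)
  n_cand <- if (greedy) 2L + as.integer(floor(log(K))) else 1L
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  d2 <- .dist2(x, x[idx[1L], , drop = FALSE])[, 1L]
  for (k in seq_len(K)[-1L]) {
    if (sum(d2) <= 0) {           # remaining points coincide with a centre
      idx[k] <- sample.int(n, 1L)
    } else if (n_cand == 1L) {
      idx[k] <- sample.int(n, 1L, prob = d2)
    } else {
      cand <- sample.int(n, n_cand, replace = TRUE, prob = d2)
      pot <- vapply(cand, function(i)
        sum(pmin(d2, .dist2(x, x[i, , drop = FALSE])[, 1L])), numeric(1))
      idx[k] <- cand[which.min(pot)]
    }
    d2 <- pmin(d2, .dist2(x, x[idx[k], , drop = FALSE])[, 1L])
  }
  x[idx, , drop = FALSE]
}

# Hartigan-Wong single-point refinement: repeatedly apply the best
# J-decreasing move of one point to another cluster (exact size-weighted
# criterion), until no single move improves. Strictly improves Lloyd
# fixpoints, which on small data can be trapped below the global optimum
# in configurations no seeding escapes.
.hartigan_refine <- function(x, labels, centres, max_moves = 200L) {
  K <- nrow(centres)
  sizes <- tabulate(labels, K)
  for (mv in seq_len(max_moves)) {
    d2 <- .dist2(x, centres)
    own <- d2[cbind(seq_along(labels), labels)]
    nA <- sizes[labels]
    remove_gain <- ifelse(nA > 1L, nA / (nA - 1) * own, 0)
    add_cost <- sweep(d2, 2L, sizes / (sizes + 1), `*`)
    add_cost[cbind(seq_along(labels), labels)] <- Inf
    delta <- add_cost - remove_gain           # n x K move costs
    delta[nA == 1L, ] <- Inf                  # never empty a cluster
    i <- arrayInd(which.min(delta), dim(delta))
    if (delta[i] >= -1e-10) break
    p <- i[1L]; from <- labels[p]; to <- i[2L]
    centres[from, ] <- (centres[from, ] * sizes[from] - x[p, ]) /
      (sizes[from] - 1L)
    centres[to, ] <- (centres[to, ] * sizes[to] + x[p, ]) /
      (sizes[to] + 1L)
    sizes[from] <- sizes[from] - 1L; sizes[to] <- sizes[to] + 1L
    labels[p] <- to
  }
  list(labels = labels, centres = centres)
}

# Assignment/update iterations from given centres until the assignment
# reaches a fixpoint (or the iteration cap).
.lloyd_core <- function(x, centres, max_iter, labels = integer(nrow(x))) {
  n <- nrow(x); K <- nrow(centres)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centres)
    new_labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: re-seed at the point farthest from its centre
    sizes <- tabulate(new_labels, K)
    while (any(sizes == 0L)) {
      k_empty <- which(sizes == 0L)[1L]
      dmin <- d2[cbind(seq_len(n), new_labels)]
      far <- which.max(dmin)
      centres[k_empty, ] <- x[far, ]
      d2[, k_empty] <- .dist2(x, centres[k_empty, , drop = FALSE])[, 1L]
      new_labels <- max.col(-d2, ties.method = "first")
      sizes <- tabulate(new_labels, K)
    }
    J <- sum(d2[cbind(seq_len(n), new_labels)])
    trace <- c(trace, J)
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged) break
    # update step: centre = mean of assigned points
    for (k in seq_len(K))
      centres[k, ] <- colMeans(x[labels == k, , drop = FALSE])
  }
  list(labels = labels, centres = centres, J = J, iterations = it,
       J_trace = trace)
}

# One full run: Lloyd to a fixpoint, then (for small point sets, where a
# single point carries weight and Lloyd traps below the optimum matter) a
# Hartigan-Wong polish; repeat until neither step moves anything. For
# image-scale data the polish is skipped: individual pixel moves change J
# negligibly and each sweep costs a full n x K pass.
.lloyd <- function(x, centres, max_iter) {
  trace <- numeric(0); iterations <- 0L
  labels <- integer(nrow(x))
  refine <- nrow(x) <= 2048L
  repeat {
    fit <- .lloyd_core(x, centres, max_iter, labels)
    trace <- c(trace, fit$J_trace)
    iterations <- iterations + fit$iterations
    if (!refine || nrow(fit$centres) == 1L || iterations >= max_iter) break
    ref <- .hartigan_refine(x, fit$labels, fit$centres)
    if (identical(ref$labels, fit$labels)) break
    centres <- ref$centres
    labels <- ref$labels
  }
  list(labels = fit$labels, centres = fit$centres, J = fit$J,
       iterations = iterations, J_trace = trace)
}

#' K-means clustering of Lab pixels
#'
#' Partitions `n` pixel colours into `K` clusters minimising the total
#' within-cluster squared Euclidean distance `J`. Lloyd iterations run from
#' k-means++ starts until the assignment reaches a fixpoint (or `max_iter`);
#' the best of `n_restarts` runs by `J` is returned. Fully deterministic for
#' a given `seed`. If the pixels contain fewer than `K` distinct colours,
#' `K` is lowered to that count with a warning.
#'
#' @param pixels `n x 3` numeric matrix of Lab triples (rows = pixels).
#' @param K number of clusters (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param n_restarts independent k-means++ starts (default 5).
#' @param max_iter Lloyd iteration cap per start (default 300).
#' @return an object of class `od_kmeans`: list with `K`, `centres`
#'   (`K x 3`), `labels` (length `n`, in `1..K`), `J`, `iterations`,
#'   `J_trace` (per-iteration objective of the winning start), `sizes`.
#' @export
kmeans_cluster <- function(pixels, K, seed = NULL, n_restarts = 5L,
                           max_iter = 300L) {
  x <- .as_pixel_matrix(pixels)
  if (nrow(x) < 1L) stop("empty pixel list")
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("K must be >= 1")
  K <- as.integer(K)
  n_distinct <- nrow(unique(x))
  if (n_distinct < K) {
    warning("only ", n_distinct, " distinct pixel colours; lowering K from ",
            K, " to ", n_distinct)
    K <- n_distinct
  }
  run_all <- function() {
    best <- NULL
    for (r in seq_len(max(1L, as.integer(n_restarts)))) {
      # first two restarts greedy (mode coverage), the rest plain
      # (diversity); best J wins either way
      centres <- .kmeanspp_init(x, K, greedy = r <= 2L)
      fit <- .lloyd(x, centres, max_iter)
      if (is.null(best) || fit$J < best$J) best <- fit
    }
    best
  }
  if (K > 1L && choose(nrow(x), K) <= 70) {
    # tiny data: random restarts are poorly diversified, so run Lloyd from
    # every K-subset of points instead (complete, deterministic seeding)
    best <- NULL
    for (cols in asplit(utils::combn(nrow(x), K), 2L)) {
      fit <- .lloyd(x, x[cols, , drop = FALSE], max_iter)
      if (is.null(best) || fit$J < best$J) best <- fit
    }
  } else {
    best <- if (is.null(seed)) run_all()
            else withr::with_seed(seed, run_all())
  }
  # invariant: J non-increasing across Lloyd iterations
  tr <- best$J_trace
  if (length(tr) > 1L && any(diff(tr) > 1e-8 * (1 + tr[-length(tr)])))
    stop("internal error: objective increased during Lloyd iterations")
  structure(list(K = K, centres = unname(best$centres),
                 labels = best$labels, J = best$J,
                 iterations = best$iterations, J_trace = tr,
                 sizes = tabulate(best$labels, K)),
            class = "od_kmeans")
}

.as_pixel_matrix <- function(pixels) {
  if (inherits(pixels, "image_lab")) return(lab_pixels(pixels))
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || ncol(pixels) != 3L)
    stop("pixels must be an n x 3 matrix of Lab triples")
  storage.mode(pixels) <- "double"
  unname(pixels)
}

#' @export
print.od_kmeans <- function(x, ...) {
  cat("K-means model: K =", x$K, " n =", length(x$labels),
      " J =", format(x$J, digits = 6),
      " iterations =", x$iterations, "\n")
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' Fits K-means for `K = 1..Kmax` and returns the smallest `K` after which
#' the relative improvement of the objective `J` drops below `threshold`,
#' i.e. the first `K` with `(J(K) - J(K+1)) / J(K) < threshold`. The full
#' curve (including the ratio of mean between-centre distance to mean
#' within-cluster distance, the quantity that "ceases to change" at the
#' elbow) is returned for inspection. In routine use the sensor fixes
#' `K = 9` instead of re-running this per image.
#'
#' @param pixels `n x 3` Lab matrix.
#' @param Kmax largest K to consider (>= 2); lowered with a warning when the
#'   data contain fewer distinct colours.
#' @param threshold relative-improvement cutoff (default 0.3: past the
#'   elbow, splitting a Gaussian-like cluster improves `J` by only ~10%,
#'   while pre-elbow drops are near-total, so 0.3 sits in the gap).
#' @param seed integer seed for the underlying K-means runs.
#' @param n_restarts restarts per K.
#' @return list with `K` (the chosen count) and `curve`, a data.frame with
#'   columns `K`, `J`, `ratio` (NA at K = 1), `rel_change`.
#' @export
select_k_elbow <- function(pixels, Kmax = 9L, threshold = 0.3, seed = NULL,
                           n_restarts = 5L) {
  x <- .as_pixel_matrix(pixels)
  if (Kmax < 2) stop("Kmax must be >= 2")
  n_distinct <- nrow(unique(x))
  if (n_distinct < Kmax) {
    warning("fewer distinct colours (", n_distinct, ") than Kmax; lowering")
    Kmax <- n_distinct
  }
  fits <- lapply(seq_len(Kmax), function(K)
    suppressWarnings(kmeans_cluster(x, K,
      seed = if (is.null(seed)) NULL else seed + K,
      n_restarts = n_restarts)))
  J <- vapply(fits, `[[`, numeric(1), "J")
  ratio <- vapply(fits, function(f) {
    if (f$K < 2L) return(NA_real_)
    between <- mean(dist(f$centres))
    within <- mean(sqrt(.dist2(x, f$centres)[cbind(seq_len(nrow(x)),
                                                   f$labels)]))
    if (within <= 0) Inf else between / within
  }, numeric(1))
  rel <- c((J[-length(J)] - J[-1L]) / ifelse(J[-length(J)] > 0,
                                             J[-length(J)], 1), NA)
  curve <- data.frame(K = seq_len(Kmax), J = J, ratio = ratio,
                      rel_change = rel)
  if (J[1L] <= 1e-12) return(list(K = 1L, curve = curve))
  flat <- which(rel[-length(rel)] < threshold)
  K_sel <- if (length(flat)) flat[1L] else Kmax
  list(K = as.integer(K_sel), curve = curve)
}

#' Segment a Lab image by K-means
#'
#' Runs [kmeans_cluster()] on the image's pixels (optionally on a seeded
#' random subsample for speed, with all pixels then assigned to the nearest
#' fitted centre and `J` recomputed over the full image). Clusters are
#' relabelled in decreasing size order so that cluster indices are stable
#' and meaningful when presented to a user.
#'
#' @param img `image_lab` array.
#' @param K number of clusters (sensor default 9).
#' @param seed integer seed.
#' @param subsample optional pixel count; when smaller than the image's pixel
#'   count, K-means is fitted on that many randomly chosen pixels.
#' @param n_restarts restarts passed to [kmeans_cluster()].
#' @return an `od_segmentation`: `od_kmeans` fields plus `label_matrix`
#'   (`H x W` integer matrix of cluster labels).
#' @export
segment_image <- function(img, K, seed = NULL, subsample = NULL,
                          n_restarts = 5L) {
  if (!inherits(img, "image_lab")) stop("img must be an image_lab array")
  x <- lab_pixels(img)
  n <- nrow(x)
  if (!is.null(subsample) && subsample < n) {
    idx <- if (is.null(seed)) sample.int(n, subsample)
           else withr::with_seed(seed + 1L, sample.int(n, subsample))
    fit <- kmeans_cluster(x[idx, , drop = FALSE], K, seed = seed,
                          n_restarts = n_restarts)
    d2 <- .dist2(x, fit$centres)
    labels <- max.col(-d2, ties.method = "first")
    fit$labels <- labels
    fit$J <- sum(d2[cbind(seq_len(n), labels)])
    fit$sizes <- tabulate(labels, fit$K)
  } else {
    fit <- kmeans_cluster(x, K, seed = seed, n_restarts = n_restarts)
  }
  # relabel clusters largest-first (deterministic; ties by old index)
  ord <- order(-fit$sizes, seq_len(fit$K))
  remap <- integer(fit$K); remap[ord] <- seq_len(fit$K)
  fit$centres <- fit$centres[ord, , drop = FALSE]
  fit$labels <- remap[fit$labels]
  fit$sizes <- fit$sizes[ord]
  fit$label_matrix <- matrix(fit$labels, dim(img)[1L], dim(img)[2L])
  class(fit) <- c("od_segmentation", "od_kmeans")
  fit
}

#' Match a cluster to a reference colour
#'
#' Returns the cluster whose centre is closest (Euclidean distance in Lab)
#' to `reference`; ties are broken by the lowest cluster index.
#'
#' @param model `od_kmeans` / `od_segmentation` object with >= 1 centre.
#' @param reference numeric Lab triple.
#' @return list with `index`, `centre` (Lab triple), `distance`.
#' @export
match_cluster <- function(model, reference) {
  centres <- model$centres
  if (is.null(centres) || nrow(centres) < 1L) stop("model has no centres")
  reference <- as.numeric(reference)
  if (length(reference) != 3L || !all(is.finite(reference)))
    stop("reference must be a finite Lab triple")
  d <- sqrt(rowSums(sweep(centres, 2L, reference)^2))
  k <- which.min(d)   # which.min takes the first (lowest-index) minimum
  list(index = k, centre = centres[k, ], distance = d[k])
}
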