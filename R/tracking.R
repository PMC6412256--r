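# Region-of-interest tracking across a time course.
#
# The flask-medium cluster is chosen once on the first frame, then followed
# through the campaign: each frame of each timepoint is segmented
# independently, the cluster nearest (Euclidean, Lab) to the running
# reference centre c_bar is matched, and c_bar is replaced by the mean of
# the matched centres of the timepoint's frames. The stored per-timepoint
# centre c(i) is that mean.

#' Track the region of interest across timepoints
#'
#' Implements nearest-centre ROI tracking. The first frame of the first
#' timepoint is segmented and the cluster of interest chosen there (by index
#' into the size-ordered segmentation, or by a reference Lab triple); its
#' centre becomes the initial reference `c_tilde` and the running reference
#' `c_bar = c_tilde`. Then, for every timepoint (including the first), each
#' of the (up to 4) replicate frames is segmented independently, the cluster
#' nearest to `c_bar` is matched per frame, `c_bar` is set to the arithmetic
#' mean of the matched centres, and that mean is stored as the timepoint's
#' ROI colour `c(i)`.
#'
#' Whole-image mean colours (the illumination references) are computed for
#' every frame as a byproduct, so each image is decoded only once.
#'
#' @param frames list over timepoints; each element a list of frames, where
#'   a frame is an `image_lab` array, an `image_rgb` array, or a file path
#'   (PNG/JPEG, loaded and converted on the fly). Timepoints normally hold 4
#'   frames; fewer triggers a warning and the mean runs over what is there.
#'   A `NULL` or empty timepoint is an error naming the gap.
#' @param K number of clusters per segmentation (default 9).
#' @param initial cluster choice on the first frame: a single integer index
#'   into the size-ordered clusters, or a numeric Lab triple to which the
#'   nearest centre is taken (the non-interactive "user choice").
#' @param seed integer master seed; per-frame seeds are derived from it.
#' @param subsample,n_restarts passed to [segment_image()].
#' @param keep_labels keep every frame's `H x W` label matrix and matched
#'   index (memory-hungry; default `FALSE`).
#' @return an `od_track`: list with `c_tilde`, `c_bar` (final), `centres`
#'   (`T x 3` matrix of stored `c(i)`), `matched` (`T`-list of per-frame
#'   matched centres), `matched_distance`, `reference` (`T x 3` matrix of
#'   per-timepoint whole-image mean colour, averaged over frames),
#'   `n_frames`, and (if `keep_labels`) `labels` and `matched_index`.
#' @export
track_roi <- function(frames, K = 9L, initial, seed = NULL, subsample = NULL,
                      n_restarts = 5L, keep_labels = FALSE) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of per-timepoint frame lists")
  n_t <- length(frames)
  for (t in seq_len(n_t)) {
    if (is.null(frames[[t]]) || length(frames[[t]]) == 0L)
      stop("missing timepoint: no frames at timepoint index ", t)
  }
  frame_seeds <- .derive_seeds(seed, n_t * 8L)
  seed_of <- function(t, j) frame_seeds[(t - 1L) * 8L + j]

  get_lab <- function(fr) {
    if (is.character(fr)) fr <- load_image(fr)
    if (inherits(fr, "image_rgb")) fr <- rgb_to_lab(fr)
    if (!inherits(fr, "image_lab"))
      stop("each frame must be an image array or a file path")
    fr
  }

  # user choice on the very first frame
  first_lab <- get_lab(frames[[1L]][[1L]])
  seg0 <- segment_image(first_lab, K, seed = seed_of(1L, 1L),
                        subsample = subsample, n_restarts = n_restarts)
  if (is.numeric(initial) && length(initial) == 3L) {
    c_tilde <- match_cluster(seg0, initial)$centre
  } else if (is.numeric(initial) && length(initial) == 1L) {
    k0 <- as.integer(initial)
    if (k0 < 1L || k0 > seg0$K)
      stop("initial cluster index out of range 1..", seg0$K)
    c_tilde <- seg0$centres[k0, ]
  } else {
    stop("initial must be a cluster index or a Lab triple")
  }
  c_bar <- c_tilde

  centres <- matrix(NA_real_, n_t, 3L,
                    dimnames = list(NULL, c("L", "a", "b")))
  reference <- matrix(NA_real_, n_t, 3L,
                      dimnames = list(NULL, c("Lref", "aref", "bref")))
  matched <- vector("list", n_t)
  matched_distance <- vector("list", n_t)
  n_frames <- integer(n_t)
  labels <- if (keep_labels) vector("list", n_t)
  matched_index <- if (keep_labels) vector("list", n_t)

  for (t in seq_len(n_t)) {
    fl <- frames[[t]]
    if (length(fl) < 4L)
      warning("timepoint ", t, " has only ", length(fl),
              " frame(s); averaging over those")
    mt <- matrix(NA_real_, length(fl), 3L)
    md <- numeric(length(fl))
    refs <- matrix(NA_real_, length(fl), 3L)
    if (keep_labels) {
      labels[[t]] <- vector("list", length(fl))
      matched_index[[t]] <- integer(length(fl))
    }
    for (j in seq_along(fl)) {
      lab <- get_lab(fl[[j]])
      refs[j, ] <- mean_lab(lab)
      seg <- segment_image(lab, K, seed = seed_of(t, j),
                           subsample = subsample, n_restarts = n_restarts)
      m <- match_cluster(seg, c_bar)
      mt[j, ] <- m$centre
      md[j] <- m$distance
      if (keep_labels) {
        labels[[t]][[j]] <- seg$label_matrix
        matched_index[[t]][j] <- m$index
      }
    }
    c_bar <- colMeans(mt)
    centres[t, ] <- c_bar
    reference[t, ] <- colMeans(refs)
    matched[[t]] <- mt
    matched_distance[[t]] <- md
    n_frames[t] <- length(fl)
  }

  structure(list(c_tilde = c_tilde, c_bar = c_bar, centres = centres,
                 reference = reference, matched = matched,
                 matched_distance = matched_distance, n_frames = n_frames,
                 K = K, seed = seed,
                 labels = if (keep_labels) labels,
                 matched_index = if (keep_labels) matched_index),
            class = "od_track")
}

#' @export
print.od_track <- function(x, ...) {
  cat("ROI track:", nrow(x$centres), "timepoints, K =", x$K, "\n")
  cat("  c_tilde =", paste(round(x$c_tilde, 2), collapse = ", "), "\n")
  cat("  final c_bar =", paste(round(x$c_bar, 2), collapse = ", "), "\n")
  invisible(x)
}

# Derive n reproducible sub-seeds (< 2^31) from a master seed without
# disturbing the caller's RNG stream; NULL master -> draw from current RNG.
.derive_seeds <- function(seed, n) {
  draw <- function() sample.int(.Machine$integer.max, n)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
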