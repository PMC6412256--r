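# Measurement summaries and the regression design matrix.
#
# A measurement i pairs the tracked ROI colour c(i) = (L, a, b) and the
# whole-image reference (Lref, aref, bref), each averaged over the four
# replicate frames of a timepoint, with the optical density y_i read off the
# photometer. The design matrix applies the log transform to every variable:
#   x1..x3 = log ROI colour of measurement i,
#   x4..x6 = log ROI colour of the experiment's FIRST RETAINED measurement
#            (t = 0.5 h once t = 0 is dropped) -- the medium-baseline terms,
#   x7..x9 = log whole-image reference of measurement i -- illumination terms,
#   response = log OD.
# The t = 0 h row is dropped: its OD is 0 by the blank definition and cannot
# be log-transformed.

#' Summarise one timepoint's frames into a measurement's colour part
#'
#' @param frames list of 1-4 `image_lab` arrays (the replicate frames).
#' @param roi_centres matrix (or list) of the per-frame matched ROI centres,
#'   one Lab triple per frame.
#' @return list with `roi` (mean matched centre, named L/a/b) and
#'   `reference` (mean whole-image colour, named Lref/aref/bref).
#' @export
summarize_timepoint <- function(frames, roi_centres) {
  if (length(frames) == 0L) stop("no frames to summarise")
  if (is.list(roi_centres)) roi_centres <- do.call(rbind, roi_centres)
  roi_centres <- matrix(as.numeric(roi_centres), ncol = 3L)
  if (nrow(roi_centres) != length(frames))
    stop("one ROI centre per frame is required")
  refs <- t(vapply(frames, mean_lab, numeric(3)))
  list(roi = setNames(colMeans(roi_centres), c("L", "a", "b")),
       reference = setNames(colMeans(refs), c("Lref", "aref", "bref")))
}

#' Assemble a measurement table from an ROI track
#'
#' @param track `od_track` from [track_roi()].
#' @param experiment_id scalar experiment identifier.
#' @param time_h numeric vector of timepoints (hours), one per tracked row.
#' @param od optional numeric vector of measured OD values (NA allowed at
#'   prediction time).
#' @return data.frame with columns `experiment_id`, `time_h`, `L`, `a`, `b`,
#'   `Lref`, `aref`, `bref`, `od`.
#' @export
measurements_from_track <- function(track, experiment_id, time_h, od = NULL) {
  stopifnot(inherits(track, "od_track"))
  n <- nrow(track$centres)
  if (length(time_h) != n)
    stop("time_h must have one entry per tracked timepoint")
  if (is.null(od)) od <- rep(NA_real_, n)
  if (length(od) != n) stop("od must have one entry per timepoint")
  data.frame(experiment_id = rep(experiment_id, n), time_h = time_h,
             L = track$centres[, 1], a = track$centres[, 2],
             b = track$centres[, 3],
             Lref = track$reference[, 1], aref = track$reference[, 2],
             bref = track$reference[, 3], od = od)
}

#' Build the log-log regression design matrix
#'
#' Applies the natural-log transform elementwise and constructs predictors
#' `x1..x9` and the response `log(od)` as described above. By default the
#' `t = 0` row of each experiment is dropped (OD 0 cannot be logged) and the
#' experiment's first *retained* measurement (normally t = 0.5 h) supplies
#' the baseline columns `x4..x6`.
#'
#' CIELAB `a`/`b` components can legitimately be non-positive; by default
#' that is an error naming the offending row and channel, but a positive
#' `log_offset` `c0` switches every colour transform to `log(v + c0)`
#' (recorded in the result's attributes and in serialised models).
#'
#' @param measurements data.frame as returned by
#'   [measurements_from_track()] / [read_colour_summary()]: columns
#'   `experiment_id`, `time_h`, `L`, `a`, `b`, `Lref`, `aref`, `bref`, `od`.
#' @param drop_t0 drop the `time_h == 0` rows (default `TRUE`).
#' @param log_offset offset `c0` in the colour transform `log(v + c0)`
#'   (default 0, i.e. a plain natural log).
#' @return data.frame with `experiment_id`, `time_h`, `x1`..`x9`, `response`
#'   (NA where `od` is NA); attributes `log_offset`, `drop_t0`.
#' @export
build_design_matrix <- function(measurements, drop_t0 = TRUE,
                                log_offset = 0) {
  req <- c("experiment_id", "time_h", "L", "a", "b", "Lref", "aref", "bref")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("measurements lack column(s): ",
                         paste(miss, collapse = ", "))
  m <- measurements
  if (!"od" %in% names(m)) m$od <- NA_real_
  if (drop_t0) m <- m[abs(m$time_h) > 1e-9, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements retained")
  m <- m[order(m$experiment_id, m$time_h), , drop = FALSE]

  g <- function(v, channel) {
    bad <- which(is.finite(v) & v + log_offset <= 0)
    if (length(bad))
      stop("non-positive value in channel '", channel, "' at row(s) ",
           paste(head(bad, 5L), collapse = ", "),
           " (experiment ", m$experiment_id[bad[1L]], ", t = ",
           m$time_h[bad[1L]], " h); consider a log_offset")
    log(v + log_offset)
  }

  x <- data.frame(experiment_id = m$experiment_id, time_h = m$time_h,
                  x1 = g(m$L, "L"), x2 = g(m$a, "a"), x3 = g(m$b, "b"),
                  x7 = g(m$Lref, "Lref"), x8 = g(m$aref, "aref"),
                  x9 = g(m$bref, "bref"))
  # baseline columns: first retained measurement of the row's own experiment
  first_idx <- tapply(seq_len(nrow(m)), m$experiment_id, function(i)
    i[which.min(m$time_h[i])])
  fmap <- unlist(first_idx)[as.character(m$experiment_id)]
  x$x4 <- x$x1[fmap]; x$x5 <- x$x2[fmap]; x$x6 <- x$x3[fmap]

  resp <- rep(NA_real_, nrow(m))
  has_od <- is.finite(m$od)
  if (any(m$od[has_od] <= 0))
    stop("OD must be positive to log-transform (experiment ",
         m$experiment_id[has_od & m$od <= 0][1L], "); drop the t = 0 row")
  resp[has_od] <- log(m$od[has_od])

  out <- x[, c("experiment_id", "time_h", paste0("x", 1:9))]
  out$response <- resp
  rownames(out) <- NULL
  attr(out, "log_offset") <- log_offset
  attr(out, "drop_t0") <- drop_t0
  out
}

#' Read or write a colour-summary table
#'
#' The CSV layout mirrors the field's published summary tables: columns
#' `time_h`, `Lref`, `aref`, `bref`, `L`, `a`, `b`, `OD`, optionally
#' preceded by `experiment_id` (absent means a single experiment, id 1).
#'
#' @param path CSV path.
#' @return `read_colour_summary()`: a measurement data.frame in the internal
#'   column order (see [build_design_matrix()]).
#' @export
read_colour_summary <- function(path) {
  d <- read.csv(path, check.names = TRUE)
  names(d) <- sub("^OD$", "od", names(d))
  if (!"experiment_id" %in% names(d)) d$experiment_id <- 1L
  req <- c("time_h", "Lref", "aref", "bref", "L", "a", "b", "od")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("colour summary lacks column(s): ",
                         paste(miss, collapse = ", "))
  d[, c("experiment_id", "time_h", "L", "a", "b",
        "Lref", "aref", "bref", "od")]
}

#' @rdname read_colour_summary
#' @param measurements measurement data.frame.
#' @export
write_colour_summary <- function(measurements, path) {
  keep <- c("experiment_id", "time_h", "Lref", "aref", "bref",
            "L", "a", "b", "od")
  d <- measurements[, intersect(keep, names(measurements))]
  names(d)[names(d) == "od"] <- "OD"
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write an experiment manifest
#'
#' The manifest maps images to campaign coordinates: columns
#' `experiment_id`, `location`, `inoculum_ml`, `time_h`, `frame`, `path`.
#'
#' @param path CSV path.
#' @return `read_manifest()`: the manifest data.frame.
#' @export
read_manifest <- function(path) {
  d <- read.csv(path, check.names = TRUE)
  req <- c("experiment_id", "time_h", "frame", "path")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "))
  d
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
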