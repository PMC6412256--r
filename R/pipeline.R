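# Manifest-driven orchestration of the full sensor pipeline.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run so that results are a pure
#' function of (config, inputs). All seeds are recorded in the output
#' metadata.
#'
#' @param manifest path to (or data.frame of) the image manifest.
#' @param od_table optional path to (or data.frame of) a colour-summary or
#'   OD table supplying measured OD per (experiment, timepoint) for
#'   training; omit for prediction-only runs.
#' @param out_dir output directory for the artefact bundle.
#' @param roi_reference the "user choice" of the region of interest: a Lab
#'   triple to which the first frame's nearest cluster centre is matched,
#'   or a single cluster index into the size-ordered first segmentation.
#' @param K clusters per segmentation (default 9).
#' @param seed master seed (default 42).
#' @param subsample optional pixel subsample per segmentation.
#' @param n_restarts K-means restarts (default 5).
#' @param drop_t0 drop the t = 0 rows before modelling (default TRUE).
#' @param log_offset colour-transform offset (default 0).
#' @param cv_scheme `"loeo"`, `"loo"`, or `"none"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, od_table = NULL, out_dir,
                            roi_reference, K = 9L, seed = 42L,
                            subsample = NULL, n_restarts = 5L,
                            drop_t0 = TRUE, log_offset = 0,
                            cv_scheme = c("loeo", "loo", "none")) {
  structure(list(manifest = manifest, od_table = od_table,
                 out_dir = out_dir, roi_reference = roi_reference,
                 K = as.integer(K), seed = as.integer(seed),
                 subsample = subsample, n_restarts = as.integer(n_restarts),
                 drop_t0 = drop_t0, log_offset = log_offset,
                 cv_scheme = match.arg(cv_scheme)),
            class = "pipeline_config")
}

#' Run the full sensor pipeline
#'
#' Executes segment -> track -> summarise -> design matrix -> fit ->
#' cross-validate -> diagnose on a manifest of images, and writes the
#' artefact bundle: a colour-summary CSV in the standard layout, the stored
#' per-measurement ROI centres, the fitted model JSON (with seeds and
#' transform metadata), the cross-validation and diagnostics JSON, and the
#' diagnostic plots (PDF).
#'
#' @param config `pipeline_config`.
#' @return (invisibly) a list with `measurements`, `design`, `fit`, `cv`,
#'   `diagnostics`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- if (is.character(config$manifest)) read_manifest(config$manifest)
         else config$manifest
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage: segmentation + tracking, per experiment
  exps <- sort(unique(man$experiment_id))
  exp_seeds <- .derive_seeds(config$seed, length(exps))
  meas <- vector("list", length(exps))
  for (k in seq_along(exps)) {
    e <- exps[k]
    me <- man[man$experiment_id == e, , drop = FALSE]
    times <- sort(unique(me$time_h))
    full <- seq(min(times), max(times), by = 0.5)
    gap <- setdiff(round(full, 3), round(times, 3))
    if (length(gap))
      stop("manifest missing timepoint(s) for experiment ", e, ": t = ",
           paste(gap, collapse = ", "), " h")
    frames <- lapply(times, function(tt)
      as.list(me$path[abs(me$time_h - tt) < 1e-9][order(
        me$frame[abs(me$time_h - tt) < 1e-9])]))
    track <- track_roi(frames, K = config$K,
                       initial = config$roi_reference,
                       seed = exp_seeds[k], subsample = config$subsample,
                       n_restarts = config$n_restarts)
    meas[[k]] <- measurements_from_track(track, e, times)
  }
  meas <- do.call(rbind, meas)

  # stage: join measured OD
  if (!is.null(config$od_table)) {
    odt <- if (is.character(config$od_table))
      read_colour_summary(config$od_table) else config$od_table
    odt <- odt[, c("experiment_id", "time_h", "od")]
    meas$od <- NULL
    meas <- merge(meas, odt, by = c("experiment_id", "time_h"),
                  all.x = TRUE, sort = FALSE)
    meas <- meas[order(meas$experiment_id, meas$time_h), ]
  }
  paths <- list(features = file.path(config$out_dir, "features.csv"))
  write_colour_summary(meas, paths$features)

  out <- list(measurements = meas, paths = paths)
  if (any(is.finite(meas$od))) {
    design <- build_design_matrix(meas, drop_t0 = config$drop_t0,
                                  log_offset = config$log_offset)
    fit <- fit_ols(design)
    cv <- if (config$cv_scheme != "none")
      cross_validate(design, scheme = config$cv_scheme,
                     seed = config$seed)
    diag <- diagnose_residuals(fit$residuals, fit$fitted)
    paths$model <- file.path(config$out_dir, "model.json")
    write_model_json(fit, paths$model, extra = list(
      seed = config$seed, K = config$K, n_restarts = config$n_restarts,
      subsample = config$subsample,
      cv = if (!is.null(cv)) list(scheme = cv$scheme,
                                  r_squared = cv$r_squared,
                                  residual_mean = cv$residual_mean,
                                  seed = cv$seed)))
    paths$diagnostics <- file.path(config$out_dir, "diagnostics.json")
    jsonlite::write_json(list(
      residual_mean = diag$residual_mean,
      autocorrelation = diag$autocorrelation,
      whiteness_ok = diag$whiteness_ok,
      ks = diag$ks,
      cv_r_squared = if (!is.null(cv)) cv$r_squared),
      paths$diagnostics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$plots <- file.path(config$out_dir, "diagnostics.pdf")
    tc <- if (!is.null(cv))
      data.frame(time_h = cv$time_h, observed_od = exp(cv$observed),
                 predicted_od = exp(cv$predicted))
    plot_diagnostics(diag, paths$plots, timecourse = tc)
    out <- c(out, list(design = design, fit = fit, cv = cv,
                       diagnostics = diag))
    out$paths <- paths
  }
  invisible(out)
}
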