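# Diagnostics report, model serialisation and plots.

#' Assemble a residual-diagnostics report
#'
#' Bundles the checks used to judge the regression: residual mean (should be
#' ~0 on the training set because an intercept is included), residual
#' autocorrelation with the `+/- 2/sqrt(n)` whiteness band, the KS normality
#' test on standardised residuals, and residual-vs-fitted pairs for
#' plotting.
#'
#' @param residuals ordered numeric residuals (training or held-out).
#' @param fitted optional fitted/predicted values paired with `residuals`.
#' @param max_lag autocorrelation lag cap (default 20).
#' @return an `od_diagnostics` list: `residual_mean`, `autocorrelation`,
#'   `whiteness_ok` (all lags within the band), `ks`, `pairs`.
#' @export
diagnose_residuals <- function(residuals, fitted = NULL, max_lag = 20L) {
  e <- as.numeric(residuals)
  ac <- residual_autocorrelation(e, max_lag = min(max_lag,
                                                  length(e) - 1L))
  structure(list(
    residual_mean = mean(e),
    autocorrelation = ac,
    whiteness_ok = all(abs(ac$acf) <= ac$bound),
    ks = ks_normality(e),
    pairs = if (!is.null(fitted)) data.frame(fitted = fitted, residual = e)
  ), class = "od_diagnostics")
}

#' @export
print.od_diagnostics <- function(x, ...) {
  cat("Residual diagnostics (n =", x$ks$n, ")\n")
  cat("  mean residual:", format(x$residual_mean, digits = 3), "\n")
  cat("  autocorrelation within +/-", round(x$autocorrelation$bound, 3),
      "at all lags:", x$whiteness_ok, "\n")
  cat("  KS normality: D =", format(x$ks$statistic, digits = 3),
      ", p =", format(x$ks$p_value, digits = 3),
      if (x$ks$low_power) " (low power)" else "", "\n")
  invisible(x)
}

#' Serialise a fitted model (and optional diagnostics) to JSON
#'
#' Stores coefficients, the transform specification (natural log with the
#' configured offset), training metadata and seeds, so a fit can be reloaded
#' and applied elsewhere.
#'
#' @param fit `od_fit`.
#' @param path output JSON path.
#' @param extra optional named list merged into the record (e.g. seeds,
#'   cross-validation summaries).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path, extra = list()) {
  rec <- c(list(
    coefficients = as.list(fit$beta),
    transform = list(f = "log", g = "log", log_offset = fit$log_offset),
    n = fit$n, r_squared = fit$r_squared, rank = fit$rank,
    rank_deficient = fit$rank_deficient, predictors = fit$predictors
  ), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta = unlist(rec$coefficients),
                 fitted = NULL, residuals = NULL,
                 r_squared = rec$r_squared, n = rec$n, rank = rec$rank,
                 rank_deficient = isTRUE(rec$rank_deficient),
                 predictors = rec$predictors,
                 log_offset = rec$transform$log_offset %||% 0),
            class = "od_fit")
}

#' Write the standard diagnostic plots to a PDF
#'
#' Three panels: residuals vs fitted values, the residual autocorrelation
#' with its whiteness band, and (when time metadata is available) observed
#' vs predicted OD over time.
#'
#' @param diag `od_diagnostics`.
#' @param path output PDF path.
#' @param timecourse optional data.frame with `time_h`, `observed_od`,
#'   `predicted_od` for the third panel.
#' @return `path`, invisibly.
#' @export
plot_diagnostics <- function(diag, path, timecourse = NULL) {
  pdf(path, width = 7, height = 5)
  on.exit(dev.off(), add = TRUE)
  if (!is.null(diag$pairs)) {
    plot(diag$pairs$fitted, diag$pairs$residual,
         xlab = "fitted (log OD)", ylab = "residual",
         main = "Residuals vs fitted")
    abline(h = 0, lty = 2)
  }
  ac <- diag$autocorrelation
  plot(ac$lag, ac$acf, type = "h", ylim = range(c(ac$acf, ac$bound,
                                                  -ac$bound)),
       xlab = "lag", ylab = "autocorrelation",
       main = sprintf("Residual autocorrelation (band +/- %.3f)",
                      ac$bound))
  abline(h = c(-ac$bound, 0, ac$bound), lty = c(3, 1, 3))
  if (!is.null(timecourse)) {
    plot(timecourse$time_h, timecourse$observed_od, pch = 1,
         xlab = "time (h)", ylab = "OD",
         main = "Observed and predicted OD over time")
    points(timecourse$time_h, timecourse$predicted_od, pch = 3, col = 2)
    legend("topleft", legend = c("observed", "predicted"),
           pch = c(1, 3), col = c(1, 2), bty = "n")
  }
  invisible(path)
}
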