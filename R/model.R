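# Ordinary least squares on the log-log design, goodness of fit, residual
# diagnostics and cross-validation.

#' Fit the OD regression by ordinary least squares
#'
#' Fits `response ~ 1 + x1 + ... + x9` (or whatever `x*` columns the design
#' carries) by least squares through a rank-revealing QR decomposition. With
#' data from a single experiment the baseline columns `x4..x6` are constant
#' and collinear with the intercept; rank deficiency is reported with a
#' warning and the minimum-norm solution (via the SVD pseudoinverse) is
#' returned, which still reproduces the fitted values exactly.
#'
#' @param design data.frame from [build_design_matrix()]: predictor columns
#'   matching `^x[0-9]+$` plus `response` (rows with NA response are
#'   dropped for fitting).
#' @return an `od_fit`: list with `beta` (named `beta0`, `beta1`, ...),
#'   `fitted`, `residuals`, `r_squared`, `n`, `rank`, `rank_deficient`,
#'   `predictors`, `log_offset`.
#' @export
fit_ols <- function(design) {
  pred <- grep("^x[0-9]+$", names(design), value = TRUE)
  if (!length(pred)) stop("design has no predictor columns x1, x2, ...")
  if (!"response" %in% names(design)) stop("design has no response column")
  d <- design[is.finite(design$response), , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 rows with a response to fit")
  X <- cbind(1, as.matrix(d[, pred, drop = FALSE]))
  y <- d$response
  qrX <- qr(X)
  p <- ncol(X)
  if (qrX$rank < p) {
    warning("design is rank deficient (rank ", qrX$rank, " of ", p,
            "); returning the minimum-norm least-squares solution. ",
            "With a single experiment x4-x6 are constant and collinear ",
            "with the intercept.")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  fitted <- unname(drop(X %*% beta))
  res <- y - fitted
  structure(list(beta = setNames(beta, c("beta0", sub("^x", "beta", pred))),
                 fitted = fitted, residuals = res,
                 r_squared = r_squared(y, fitted),
                 n = nrow(d), rank = qrX$rank,
                 rank_deficient = qrX$rank < p, predictors = pred,
                 log_offset = attr(design, "log_offset") %||% 0),
            class = "od_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.od_fit <- function(x, ...) {
  cat("OD regression fit: n =", x$n, " R^2 =",
      format(x$r_squared, digits = 4),
      if (x$rank_deficient) " (rank deficient)" else "", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed over all
#' pairs; negative values are possible (and meaningful) for out-of-sample
#' predictions worse than the mean.
#'
#' @param observed numeric vector (the transformed response `f(y)`).
#' @param predicted numeric vector of the same length.
#' @return a single number `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Predict optical density for new design rows
#'
#' Evaluates the linear predictor and back-transforms with `exp`, since the
#' response was fitted on the natural-log scale. Predictions are therefore
#' strictly positive.
#'
#' @param fit `od_fit` object.
#' @param design data.frame with the fit's predictor columns.
#' @param type `"od"` (back-transformed, default) or `"link"` (the linear
#'   predictor on the log scale).
#' @return numeric vector of predictions.
#' @export
predict_od <- function(fit, design, type = c("od", "link")) {
  type <- match.arg(type)
  miss <- setdiff(fit$predictors, names(design))
  if (length(miss)) stop("design lacks predictor(s): ",
                         paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(design[, fit$predictors, drop = FALSE]))
  eta <- unname(drop(X %*% fit$beta))
  if (type == "od") exp(eta) else eta
}

#' Sample autocorrelation of residuals with whiteness bounds
#'
#' Biased sample autocorrelation
#' `r_k = sum_{t<=n-k} (e_t - ebar)(e_{t+k} - ebar) / sum (e_t - ebar)^2`
#' for lags `1..max_lag`, with the approximate 95% whiteness band
#' `+/- 2/sqrt(n)` for an uncorrelated sequence. At n = 342 the band is
#' +/- 0.108 (3 decimals).
#'
#' @param residuals ordered numeric vector (order matters: for held-out
#'   residuals use the prediction order of the CV scheme).
#' @param max_lag largest lag (default `min(20, n - 1)`).
#' @return list with `lag`, `acf`, `bound` (`2/sqrt(n)`), `n`.
#' @export
residual_autocorrelation <- function(residuals, max_lag = NULL) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (is.null(max_lag)) max_lag <- min(20L, n - 1L)
  if (n <= max_lag || max_lag < 1L)
    stop("need n > max_lag >= 1")
  e <- e - mean(e)
  denom <- sum(e^2)
  if (denom <= 0) stop("residuals are constant; autocorrelation undefined")
  r <- vapply(seq_len(max_lag), function(k)
    sum(e[seq_len(n - k)] * e[(k + 1L):n]) / denom, numeric(1))
  list(lag = seq_len(max_lag), acf = r, bound = 2 / sqrt(n), n = n)
}

#' Kolmogorov-Smirnov test of residual normality
#'
#' Standardises the residuals (subtract the mean, divide by the sample
#' standard deviation) and applies the one-sample KS test against the
#' standard normal. Because the location and scale are estimated from the
#' same data, the nominal p-value is approximate (Lilliefors caveat);
#' `low_power` flags small samples where a non-rejection is weak evidence.
#'
#' @param residuals numeric vector, length >= 3.
#' @return list with `statistic`, `p_value`, `n`, `low_power`.
#' @export
ks_normality <- function(residuals) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 3L) stop("need at least 3 residuals")
  s <- sd(e)
  if (!is.finite(s) || s <= 0) stop("residuals have zero standard deviation")
  z <- (e - mean(e)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value, n = n,
       low_power = n < 30L)
}

#' Cross-validate the OD regression
#'
#' Two schemes: `"loeo"` (leave-one-experiment-out) holds out each
#' experiment in turn -- the sensor's main prediction-performance measure --
#' and `"loo"` (leave-one-out) first shuffles the rows with `seed` and then
#' holds out each single row. Held-out predictions are pooled and a single
#' R-squared computed over all of them; the held-out residual sequence (in
#' campaign order for LOEO, in shuffled order for LOO) feeds
#' [residual_autocorrelation()].
#'
#' @param design data.frame from [build_design_matrix()]; every row must
#'   have a finite response.
#' @param scheme `"loeo"` or `"loo"`.
#' @param seed integer seed for the LOO row shuffle (required for `"loo"`).
#' @param max_lag autocorrelation lag cap passed on.
#' @return an `od_cv`: list with `scheme`, `predicted` (held-out `yhat` on
#'   the log scale, design row order), `observed`, `r_squared` (pooled),
#'   `fold_betas` (matrix, one row per fold), `order` (row order used for
#'   the residual sequence), `autocorrelation`, `residual_mean`, `seed`.
#' @export
cross_validate <- function(design, scheme = c("loeo", "loo"), seed = NULL,
                           max_lag = 20L) {
  scheme <- match.arg(scheme)
  d <- design[is.finite(design$response), , drop = FALSE]
  n <- nrow(d)
  if (scheme == "loeo") {
    exps <- unique(d$experiment_id)
    if (length(exps) < 2L) stop("LOEO requires >= 2 experiments")
    folds <- lapply(exps, function(e) which(d$experiment_id == e))
    ord <- seq_len(n)
  } else {
    if (n < 3L) stop("LOO requires >= 3 rows")
    if (is.null(seed)) stop("LOO requires a seed for the row shuffle")
    ord <- withr::with_seed(seed, sample.int(n))
    folds <- as.list(ord)
  }
  predicted <- rep(NA_real_, n)
  fold_betas <- NULL
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    train <- d[-hold, , drop = FALSE]
    fit <- suppressWarnings(fit_ols(train))
    predicted[hold] <- predict_od(fit, d[hold, , drop = FALSE],
                                  type = "link")
    fold_betas <- rbind(fold_betas, fit$beta)
  }
  stopifnot(!anyNA(predicted))  # every row predicted exactly once
  res_seq <- (d$response - predicted)[ord]
  structure(list(scheme = scheme, predicted = predicted,
                 observed = d$response,
                 r_squared = r_squared(d$response, predicted),
                 fold_betas = fold_betas, order = ord,
                 autocorrelation = residual_autocorrelation(
                   res_seq, max_lag = min(max_lag, n - 1L)),
                 residual_mean = mean(res_seq), seed = seed,
                 experiment_id = d$experiment_id, time_h = d$time_h),
            class = "od_cv")
}

#' @export
print.od_cv <- function(x, ...) {
  cat("Cross-validation (", x$scheme, "): pooled R^2 =",
      format(x$r_squared, digits = 4),
      " mean residual =", format(x$residual_mean, digits = 3), "\n")
  invisible(x)
}
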