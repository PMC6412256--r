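# OLS fitting, R-squared, diagnostics, cross-validation.

test_that("fit_ols recovers noiseless coefficients and reports rank", {
  beta <- c(0.5, 1.2, -0.7, 0.3, 0.9, -1.1, 0.2, 0.4, -0.3, 0.8)
  d <- random_design(n = 60, seed = 2, sigma = 0, beta = beta)
  fit <- fit_ols(d)
  expect_lt(max(abs(fit$beta - beta)), 1e-8)
  expect_false(fit$rank_deficient)
  expect_lt(abs(sum(fit$residuals)), 1e-8 * fit$n)

  # single experiment: x4-x6 constant -> collinear with intercept
  camp <- generate_campaign(campaign_spec(n_experiments = 1, seed = 4),
                            render = FALSE)
  d1 <- build_design_matrix(camp$summary)
  expect_warning(fit1 <- fit_ols(d1), "rank deficient")
  expect_true(fit1$rank_deficient)
  # minimum-norm solution still reproduces the least-squares fit
  expect_equal(fit1$fitted,
               unname(lm.fit(cbind(1, as.matrix(d1[paste0("x", 1:9)])),
                             d1$response)$fitted.values),
               tolerance = 1e-8)
})

test_that("fit_ols equals the closed-form normal equations on a toy", {
  d <- data.frame(x1 = c(0, 1, 2), response = c(1, 3, 4),
                  experiment_id = 1, time_h = 1:3)
  fit <- fit_ols(d)
  # hand: slope = Sxy/Sxx = 3/2, intercept = ybar - slope*xbar
  expect_equal(unname(fit$beta), c(8 / 3 - 1.5, 1.5), tolerance = 1e-12)
})

test_that("r_squared implements its defining identity", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5)
  expect_lt(r_squared(obs, c(5, 5, 5)), 0)   # worse than the mean
  expect_error(r_squared(c(2, 2, 2), obs), "zero variance")
  expect_error(r_squared(obs, 1:4), "equal length")
  # invariance under affine rescaling of both series
  set.seed(1)
  o <- rnorm(30); p <- o + rnorm(30, 0, 0.3)
  expect_equal(r_squared(3 * o - 7, 3 * p - 7), r_squared(o, p),
               tolerance = 1e-12)
})

test_that("predict_od back-transforms to strictly positive OD", {
  fit <- structure(list(beta = c(beta0 = 0, beta1 = 1),
                        predictors = "x1", log_offset = 0),
                   class = "od_fit")
  expect_equal(predict_od(fit, data.frame(x1 = 0)), 1)        # exp(0)
  expect_equal(predict_od(fit, data.frame(x1 = log(7.18) - 0)), 7.18,
               tolerance = 1e-12)
  x <- data.frame(x1 = seq(-2, 2, 0.5))
  p <- predict_od(fit, x)
  expect_true(all(p > 0) && all(diff(p) > 0))  # exp is increasing
})

test_that("residual autocorrelation matches its definition and bounds", {
  # alternating sequence: biased lag-1 estimate -(n-1)/n
  n <- 50
  alt <- rep(c(1, -1), n / 2)
  ac <- residual_autocorrelation(alt, max_lag = 3)
  expect_equal(ac$acf[1], -(n - 1) / n, tolerance = 1e-12)

  # bound at the campaign size reproduces the printed +/- 0.108
  expect_equal(round(residual_autocorrelation(rnorm(342))$bound, 3), 0.108)

  # oracle: stats::acf (demeaned, biased estimator)
  set.seed(13)
  e <- rnorm(200)
  ac2 <- residual_autocorrelation(e, max_lag = 10)
  expect_equal(ac2$acf,
               drop(acf(e, lag.max = 10, plot = FALSE,
                        demean = TRUE)$acf)[-1],
               tolerance = 1e-12)

  # whiteness: iid residuals mostly inside the band
  set.seed(77)
  w <- residual_autocorrelation(rnorm(1000), max_lag = 30)
  expect_gte(mean(abs(w$acf) <= w$bound), 0.93)
  expect_error(residual_autocorrelation(rep(1, 50)), "constant")
  expect_error(residual_autocorrelation(1:3, max_lag = 5), "max_lag")
})

test_that("KS normality test behaves on known samples", {
  ks_n <- ks_normality(withr::with_seed(55, rnorm(300)))
  expect_gt(ks_n$p_value, 0.05)
  expect_false(ks_n$low_power)
  # against a standardised uniform the KS test has ~40% power at n = 300;
  # the frozen seed gives a representative rejection
  ks_u <- ks_normality(withr::with_seed(51, runif(300)))
  expect_lt(ks_u$p_value, 0.05)
  ks3 <- ks_normality(c(0.1, -0.2, 0.4))
  expect_true(ks3$low_power)
  expect_error(ks_normality(rep(1, 10)), "zero standard deviation")
})

test_that("cross-validation equals per-fold refits and predicts each row once", {
  # 2 experiments x 3 rows toy: compare with explicit refits
  d <- random_design(n = 6, seed = 10, sigma = 0.2)
  cv <- suppressWarnings(cross_validate(d, "loeo"))
  for (e in 1:2) {
    hold <- d$experiment_id == e
    fit <- suppressWarnings(fit_ols(d[!hold, ]))
    expect_equal(cv$predicted[hold],
                 predict_od(fit, d[hold, ], type = "link"),
                 tolerance = 1e-9)
  }

  d2 <- random_design(n = 24, seed = 20, sigma = 0.3)
  cv2 <- cross_validate(d2, "loo", seed = 6)
  expect_true(all(is.finite(cv2$predicted)))
  expect_setequal(cv2$order, seq_len(24))
  expect_error(cross_validate(d2, "loo"), "seed")

  # noiseless in-model campaign: held-out prediction is exact
  spec0 <- scale_noise(campaign_spec(colour_model = "loglinear",
                                     seed = 14), 0)
  d0 <- build_design_matrix(generate_campaign(spec0,
                                              render = FALSE)$summary)
  cv0 <- suppressWarnings(cross_validate(d0, "loeo"))
  expect_lt(abs(cv0$r_squared - 1), 1e-9)

  # training R^2 bounds the held-out R^2 (overfitting direction)
  camp <- generate_campaign(campaign_spec(seed = 31), render = FALSE)
  dn <- build_design_matrix(camp$summary)
  expect_gte(fit_ols(dn)$r_squared, cross_validate(dn, "loeo")$r_squared)
})

test_that("coefficient error shrinks with the noise level", {
  beta <- c(0.5, 1.2, -0.7, 0.3, 0.9, -1.1, 0.2, 0.4, -0.3, 0.8)
  mean_err <- vapply(c(0.5, 0.05, 0), function(sig) {
    errs <- vapply(1:20, function(s) {
      fit <- fit_ols(random_design(n = 80, seed = 100 + s, sigma = sig,
                                   beta = beta))
      mean(abs(fit$beta - beta))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
  expect_lt(mean_err[3], 1e-8)
})

test_that("model JSON round trips and diagnostics assemble", {
  d <- random_design(n = 40, seed = 3, sigma = 0.1)
  fit <- fit_ols(d)
  fp <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, fp, extra = list(seed = 42))
  back <- read_model_json(fp)
  expect_equal(unname(back$beta), unname(fit$beta), tolerance = 1e-12)
  expect_equal(predict_od(back, d), predict_od(fit, d), tolerance = 1e-9)

  diag <- diagnose_residuals(fit$residuals, fit$fitted)
  expect_lt(abs(diag$residual_mean), 1e-10)
  expect_s3_class(diag, "od_diagnostics")
  pp <- withr::local_tempfile(fileext = ".pdf")
  plot_diagnostics(diag, pp)
  expect_true(file.exists(pp))
})
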