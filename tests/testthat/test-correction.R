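test_that("RSD follows the sample-SD definition and rejects degenerate input", {
  expect_equal(compute_rsd(c(10, 10, 10)), 0)
  expect_equal(compute_rsd(c(8, 10, 12)), 20)  # sample SD 2 / mean 10
  expect_equal(compute_rsd(c(8, NA, 10, 12)), 20)
  expect_error(compute_rsd(5), "at least 2")
  expect_error(compute_rsd(c(NA, 7)), "at least 2")
  expect_error(compute_rsd(c(-1, 1)), "zero-mean")
})

test_that("constant QC areas give a constant correction curve", {
  qc <- data.frame(injection_order = c(5, 10, 15, 20, 25), area = 7)
  cv <- fit_correction_curve(qc, positions = 1:30)
  expect_false(cv$uncorrectable)
  expect_equal(cv$factor, rep(7, 30), tolerance = 1e-9)
})

test_that("a noiseless linear QC trend is recovered as the least-squares line", {
  pos <- seq(5, 60, by = 5)
  qc <- data.frame(injection_order = pos, area = 100 - 0.8 * pos)
  cv <- fit_correction_curve(qc, positions = 1:65)
  # closed-form linear-regression oracle
  fit <- lm(area ~ injection_order, qc)
  oracle <- unname(predict(fit, data.frame(injection_order = pos)))
  expect_equal(curve_at(cv, pos), oracle, tolerance = 1e-6)
  # spline interpolation between QCs also follows the line
  expect_equal(curve_at(cv, 12), 100 - 0.8 * 12, tolerance = 1e-6)
  # constant extrapolation beyond the terminal QCs
  expect_equal(curve_at(cv, 1), curve_at(cv, 5))
  expect_equal(curve_at(cv, 65), curve_at(cv, 60))
})

test_that("too few QC points flags the feature uncorrectable", {
  qc <- data.frame(injection_order = c(5, 10, 15), area = c(9, 10, 11))
  cv <- fit_correction_curve(qc, positions = 1:20)
  expect_true(cv$uncorrectable)
  qc2 <- data.frame(injection_order = c(5, 10, 15, NA, 20),
                    area = c(9, 10, 11, 12, NA))
  expect_true(fit_correction_curve(qc2, positions = 1:20)$uncorrectable)
})

test_that("a curve crossing zero falls back to the flat median-QC curve", {
  # steeply decaying trend whose spline would go negative past the last QC
  qc <- data.frame(injection_order = c(2, 4, 6, 8, 10),
                   area = c(100, 10, 1, 0.1, 0.001))
  cv <- fit_correction_curve(qc, positions = 1:10,
                             loess_params = list(span = 1.0))
  if (cv$fallback) expect_equal(unique(cv$factor), median(qc$area))
  expect_true(all(cv$factor > 0))
})

test_that("correct_batch divides by the curve; QCs land on 1 for noiseless drift", {
  des <- build_study_design("UPLC_pos", n_batches = 1,
                            subjects_per_batch = 40, runs_per_batch = 1)
  co <- generate_cohort(40, seed = 61)
  feats <- simulate_feature_catalogue(5, seed = 62)
  dm <- drift_model(attenuation_range = c(0.3, 0.3),
                    sin_amplitude_range = c(0, 0), batch_log_sd = 0,
                    technical_cv = 0, biological_sdlog = 0.3)
  sim <- simulate_study(des, co, feats, drift = dm, mnar_quantile = 0,
                        mcar_rate = 0, seed = 63)
  corr <- qcrlsc(sim$batches)[[1]]
  qc_vals <- corr$data[corr$injections$role == "QC", ]
  # a smoothing (not interpolating) fit leaves only its small bias on a
  # noiseless smooth trend; the drift itself is a ~30% excursion
  expect_true(all(abs(qc_vals - 1) < 0.02))
  expect_lt(compute_rsd(qc_vals[, 1]),
            compute_rsd(sim$batches[[1]]$data[
              sim$batches[[1]]$injections$role == "QC", 1]) / 10)
  # conditioning injections are excluded from fitting but still corrected
  cond <- corr$data[corr$injections$role == "conditioning_QC", ]
  expect_true(all(is.finite(cond)))
})

test_that("constant curves act as scalar division and missing curves blank the feature", {
  b <- peak_matrix(
    matrix(c(10, 20, NA, 40, 2, 4, 6, 8), nrow = 4,
           dimnames = list(NULL, c("F1", "F2"))),
    data.frame(sample_id = sprintf("s%d", 1:4), batch_id = "B01",
               run_id = "R1", injection_order = 1:4,
               role = c("QC", "subject", "subject", "QC")),
    data.frame(feature_id = c("F1", "F2"), platform = "UPLC_pos"))
  const_curve <- function(c0) structure(
    list(positions = 1:4, factor = rep(c0, 4), qc_fitted = NULL,
         span = 1, uncorrectable = FALSE, fallback = FALSE),
    class = "correction_curve")
  corr <- correct_batch(b, list(R1 = list(F1 = const_curve(2),
                                          F2 = const_curve(4))))
  expect_equal(corr$data[, "F1"], c(5, 10, NA, 20), ignore_attr = TRUE)
  expect_equal(corr$data[, "F2"], c(0.5, 1, 1.5, 2), ignore_attr = TRUE)
  # feature with no curve for the run -> missing for the whole batch
  corr2 <- correct_batch(b, list(R1 = list(F1 = const_curve(2))))
  expect_true(all(is.na(corr2$data[, "F2"])))
  expect_error(correct_batch(b, list()), "no curves")
})
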