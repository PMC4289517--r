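test_that("no drift, no noise: QC values are constant within a feature", {
  st <- simulate_clean_study()
  for (b in st$sim$batches) {
    qc <- b$data[b$injections$role == "QC", , drop = FALSE]
    expect_true(all(apply(qc, 2, function(v) diff(range(v)) == 0)))
  }
})

test_that("pure exponential attenuation reproduces the stated end-of-run ratio", {
  des <- build_study_design("UPLC_pos", n_batches = 1,
                            subjects_per_batch = 20, runs_per_batch = 1,
                            n_conditioning = 2)
  co <- generate_cohort(20, seed = 21)
  feats <- simulate_feature_catalogue(4, seed = 22)
  dm <- drift_model(attenuation_range = c(0.4, 0.4),
                    sin_amplitude_range = c(0, 0), batch_log_sd = 0,
                    technical_cv = 0, biological_sdlog = 0.3)
  sim <- simulate_study(des, co, feats, drift = dm, mnar_quantile = 0,
                        mcar_rate = 0, seed = 23)
  b <- sim$batches[[1]]
  qc <- b$data[b$injections$role == "QC", , drop = FALSE]
  qc_pos <- b$injections$injection_order[b$injections$role == "QC"]
  npos <- nrow(b$data)
  # independent evaluation of the stated drift law at the QC positions
  lambda <- -log(1 - 0.4) / (npos - 1)
  expected_ratio <- exp(-lambda * (max(qc_pos) - 1)) /
    exp(-lambda * (min(qc_pos) - 1))
  for (j in seq_len(ncol(qc)))
    expect_equal(qc[nrow(qc), j] / qc[1, j], expected_ratio,
                 tolerance = 1e-12)
  # last injection of the run sits at 60% of the run-start intensity
  expect_equal(exp(-lambda * (npos - 1)), 0.6, tolerance = 1e-12)
})

test_that("planted 1-SD gender effect shows up as a ~1 SD standardized shift", {
  des <- build_study_design("UPLC_pos", n_batches = 1,
                            subjects_per_batch = 1000, runs_per_batch = 1)
  co <- generate_cohort(1000, seed = 31)
  feats <- simulate_feature_catalogue(10, seed = 32)
  dm <- drift_model(attenuation_range = c(0, 0),
                    sin_amplitude_range = c(0, 0), batch_log_sd = 0,
                    technical_cv = 0, biological_sdlog = 0.5)
  ef <- effect_spec("gender", feats$feature_id[1:3], effect_size = 1)
  sim <- simulate_study(des, co, feats, drift = dm, effects = list(ef),
                        mnar_quantile = 0, mcar_rate = 0, seed = 33)
  lx <- sim$truth$biological_log
  g <- hypothesis_groups(co[match(rownames(lx), co$subject_id), ], "gender")
  smd <- vapply(1:3, function(j) {
    (mean(lx[g == "female", j]) - mean(lx[g == "male", j])) /
      sqrt((var(lx[g == "female", j]) + var(lx[g == "male", j])) / 2)
  }, numeric(1))
  expect_true(all(abs(smd - 1) < 0.2))
  # uninformative features carry no shift beyond Monte-Carlo error
  smd0 <- (mean(lx[g == "female", 5]) - mean(lx[g == "male", 5])) /
    sd(lx[, 5])
  expect_lt(abs(smd0), 0.2)
})

test_that("the emitted raw study is exactly truth x drift x noise with the mask", {
  des <- build_study_design("UPLC_pos", n_batches = 2,
                            subjects_per_batch = 20, runs_per_batch = 1)
  co <- generate_cohort(40, seed = 41)
  feats <- simulate_feature_catalogue(8, seed = 42)
  sim <- simulate_study(des, co, feats, drift = drift_model(),
                        mnar_quantile = 0.05, mcar_rate = 0.02, seed = 43)
  rec <- reconstruct_raw(sim$truth)
  for (b in seq_along(rec))
    expect_identical(rec[[b]], sim$batches[[b]]$data)
  # some missingness was actually injected
  expect_gt(mean(is.na(sim$batches[[1]]$data)), 0.02)
})

test_that("simulation is bit-reproducible from the seed and validates sizes", {
  des <- build_study_design("UPLC_pos", n_batches = 1,
                            subjects_per_batch = 20, runs_per_batch = 1)
  co <- generate_cohort(20, seed = 51)
  feats <- simulate_feature_catalogue(5, seed = 52)
  s1 <- simulate_study(des, co, feats, seed = 53)
  s2 <- simulate_study(des, co, feats, seed = 53)
  expect_identical(s1$batches[[1]]$data, s2$batches[[1]]$data)
  expect_identical(s1$truth$biological_log, s2$truth$biological_log)
  expect_error(simulate_study(des, generate_cohort(19, seed = 1), feats,
                              seed = 1), "subject slots")
  expect_error(
    simulate_study(des, co, feats,
                   effects = effect_spec("gender", "NOPE"), seed = 1),
    "absent from the catalogue")
})
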