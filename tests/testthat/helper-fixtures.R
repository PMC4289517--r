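# Shared fixture builders; everything is generated in code at test time.

# a hand-built integrated matrix with controllable QC/subject values
make_integrated <- function(subj, qc, feature_ids = colnames(subj),
                            platform = "UPLC_pos") {
  if (is.null(feature_ids))
    feature_ids <- sprintf("F%04d", seq_len(ncol(subj)))
  colnames(subj) <- feature_ids
  colnames(qc) <- feature_ids
  if (is.null(rownames(subj)))
    rownames(subj) <- sprintf("S%04d", seq_len(nrow(subj)))
  if (is.null(rownames(qc)))
    rownames(qc) <- sprintf("QC%03d", seq_len(nrow(qc)))
  structure(list(
    data = subj,
    subjects = data.frame(sample_id = rownames(subj), batch_id = "B01",
                          stringsAsFactors = FALSE),
    features = data.frame(feature_id = feature_ids, merged_id = feature_ids,
                          platform = platform, stringsAsFactors = FALSE),
    qc_data = qc,
    qc_meta = data.frame(sample_id = rownames(qc), batch_id = "B01",
                         run_id = "B01R1",
                         injection_order = seq_len(nrow(qc)),
                         stringsAsFactors = FALSE)),
    class = "integrated_matrix")
}

# small drift-free/noise-free simulated study with enough QCs per run for
# curve fitting (>= 4 interleaved QCs needs >= 16 subjects per run)
simulate_clean_study <- function(n_batches = 2, subjects_per_batch = 20,
                                 n_features = 6, seed = 11,
                                 biological_sdlog = 0.4) {
  des <- build_study_design("UPLC_pos", n_batches = n_batches,
                            subjects_per_batch = subjects_per_batch,
                            runs_per_batch = 1, n_conditioning = 2)
  co <- generate_cohort(attr(des, "n_subjects"), seed = seed + 1)
  feats <- simulate_feature_catalogue(n_features, seed = seed + 2)
  dm <- drift_model(attenuation_range = c(0, 0),
                    sin_amplitude_range = c(0, 0), batch_log_sd = 0,
                    technical_cv = 0, biological_sdlog = biological_sdlog)
  sim <- simulate_study(des, co, feats, drift = dm, mnar_quantile = 0,
                        mcar_rate = 0, seed = seed + 3)
  list(design = des, cohort = co, features = feats, sim = sim)
}

# labelled two-class matrix with planted mean shifts on the first
# `n_informative` features
make_labelled_matrix <- function(n = 100, p = 30, n_informative = 5,
                                 effect = 1.5, seed = 42) {
  withr::local_seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("F%04d", 1:p)))
  y <- factor(rep(c("a", "b"), length.out = n))
  if (n_informative > 0)
    x[y == "b", seq_len(n_informative)] <-
      x[y == "b", seq_len(n_informative)] + effect
  list(x = x, y = y, informative = colnames(x)[seq_len(n_informative)])
}
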