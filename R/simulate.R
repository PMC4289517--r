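# Simulation of raw multi-batch peak-area studies with known ground truth.
#
# Generative model for an injection at position p of run r in batch b:
#   subject:  area = biological_value(subject, feature)
#                    * batch_step(b, feature) * drift(p, feature, r)
#                    * technical_noise
#   QC:       area = pooled_value(feature)
#                    * batch_step(b, feature) * drift(p, feature, r)
#                    * technical_noise
# where drift(p) = exp(-lambda * p) * (1 + a * sin(2 * pi * p / P)) is a
# smooth strictly positive multiplicative attenuation (per feature, redrawn
# per run), batch_step is a log-normal per-batch sensitivity factor, and
# technical noise is log-normal with the stated CV. Pooled-QC injections
# share one fixed composition, so their only between-injection variance is
# technical. Missingness is MNAR left-censoring below a per-feature
# detection quantile plus a small MCAR component.

#' Simulate a metabolite feature catalogue
#'
#' Draws per-feature baseline abundances (log-normal across features),
#' m/z + retention time (UPLC platforms) or retention index (GC), and a
#' pooled-QC composition close to the population baseline.
#'
#' @param n_features number of features.
#' @param platform `"UPLC_pos"`, `"UPLC_neg"` or `"GCMS"`.
#' @param seed integer seed.
#' @return data.frame with columns `feature_id`, `platform`, `mz`, `rt`,
#'   `retention_index`, `annotation`, `msi_level`, `baseline`.
#' @export
simulate_feature_catalogue <- function(n_features, platform = "UPLC_pos",
                                       seed = NULL) {
  stop_if_not_scalar_count(n_features, "n_features")
  with_seed(seed, {
    fid <- sprintf("F%04d", seq_len(n_features))
    is_gc <- platform == "GCMS"
    data.frame(
      feature_id = fid,
      platform = platform,
      mz = if (is_gc) NA_real_ else round(stats::runif(n_features, 80, 1000), 4),
      rt = if (is_gc) NA_real_ else round(stats::runif(n_features, 0.5, 22), 3),
      retention_index = if (is_gc) round(stats::runif(n_features, 900, 3000), 1)
                        else NA_real_,
      annotation = NA_character_,
      msi_level = 4L,
      baseline = stats::rlnorm(n_features, meanlog = log(1e5), sdlog = 1),
      stringsAsFactors = FALSE)
  })
}

#' Instrument drift model parameters
#'
#' Defaults describe a realistic multi-batch run: per-run exponential
#' attenuation losing 20-40% of signal by the end of the run, a
#' low-frequency sinusoidal component (amplitude 5-15%, period 30-60
#' injections), between-batch sensitivity steps with 0.25 log-SD, 5%
#' technical CV on every injection and 0.7 biological log-SD between
#' subjects (inter-subject RSDs in the tens of percent and above, as seen
#' for serum metabolite features).
#'
#' @param attenuation_range fraction of signal lost by the last injection of
#'   a run, drawn per feature/run from `U(range)`.
#' @param sin_amplitude_range,sin_period_range sinusoid amplitude (relative)
#'   and period (injections).
#' @param batch_log_sd log-SD of the per-batch multiplicative step.
#' @param technical_cv technical coefficient of variation (QC replicate
#'   noise), as a fraction.
#' @param biological_sdlog between-subject log-SD of true abundances.
#' @return a `drift_model` list.
#' @export
drift_model <- function(attenuation_range = c(0.2, 0.4),
                        sin_amplitude_range = c(0.05, 0.15),
                        sin_period_range = c(30, 60),
                        batch_log_sd = 0.25,
                        technical_cv = 0.05,
                        biological_sdlog = 0.7) {
  stopifnot(all(attenuation_range >= 0), all(attenuation_range < 1),
            all(sin_amplitude_range >= 0), all(sin_amplitude_range < 1),
            batch_log_sd >= 0, technical_cv >= 0, biological_sdlog >= 0)
  structure(list(attenuation_range = attenuation_range,
                 sin_amplitude_range = sin_amplitude_range,
                 sin_period_range = sin_period_range,
                 batch_log_sd = batch_log_sd,
                 technical_cv = technical_cv,
                 biological_sdlog = biological_sdlog),
            class = "drift_model")
}

# evaluate drift factors at positions 1..n; normalised so the factor at the
# first injection of the run is exp(0) = 1 when the sinusoid is off
drift_factor <- function(positions, lambda, amp, period) {
  exp(-lambda * (positions - 1)) *
    (1 + amp * sin(2 * pi * (positions - 1) / period))
}

#' Planted covariate effect specification
#'
#' Describes which features carry a real group difference for one clinical
#' hypothesis, and how large it is in units of the biological (log-scale)
#' standard deviation. Effects are planted as shifts on the log-abundance
#' of the non-reference group(s).
#'
#' @param factor_name cohort column or hypothesis name understood by
#'   [hypothesis_groups()] (e.g. `"gender"`, `"bmi"`, `"smoking"`).
#' @param features character vector of informative feature ids.
#' @param effect_size shift in biological SD units (recycled per feature).
#' @param direction `+1`/`-1` per feature (recycled).
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(factor_name, features, effect_size = 1,
                        direction = 1) {
  stopifnot(is.character(features), length(features) > 0,
            all(is.finite(effect_size)))
  structure(list(factor_name = factor_name, features = features,
                 effect_size = rep_len(effect_size, length(features)),
                 direction = rep_len(direction, length(features))),
            class = "effect_spec")
}

#' Simulate a raw multi-batch peak-area study
#'
#' Emits one raw `peak_matrix` per batch plus the ground truth needed to
#' verify any downstream correction: drift-free abundances, the applied
#' drift/step factors, the technical-noise factors, the missingness mask and
#' the planted informative feature sets. Multiplying truth by drift and
#' noise and applying the mask reproduces the raw study exactly.
#'
#' @param study_design a `study_design` from [build_study_design()].
#' @param cohort a `cohort_table` with exactly as many subjects as the
#'   design has subject slots; batches partition the cohort in order.
#' @param features feature catalogue from [simulate_feature_catalogue()].
#' @param drift a [drift_model()].
#' @param effects list of [effect_spec()] objects (may be empty).
#' @param mnar_quantile detection-limit quantile below which a subject value
#'   is censored to missing (per feature), default 0.02.
#' @param mcar_rate additional completely-random missing rate, default 0.01.
#' @param seed integer seed; the study is bit-reproducible given the seed.
#' @return list with elements `batches` (list of raw `peak_matrix`) and
#'   `truth` (a `ground_truth` list).
#' @export
simulate_study <- function(study_design, cohort, features,
                           drift = drift_model(), effects = list(),
                           mnar_quantile = 0.02, mcar_rate = 0.01,
                           seed = NULL) {
  n_slots <- attr(study_design, "n_subjects")
  if (nrow(cohort) != n_slots)
    stop(sprintf("cohort has %d subjects but the design has %d subject slots",
                 nrow(cohort), n_slots), call. = FALSE)
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (ef in effects) {
    unknown <- setdiff(ef$features, features$feature_id)
    if (length(unknown))
      stop("effect_spec names features absent from the catalogue: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  m <- nrow(features)
  fid <- features$feature_id

  with_seed(seed, {
    # per-subject biological log-abundances (+ planted effects)
    logbio <- matrix(rep(log(features$baseline), each = nrow(cohort)),
                     nrow = nrow(cohort), ncol = m,
                     dimnames = list(cohort$subject_id, fid))
    logbio <- logbio + matrix(stats::rnorm(length(logbio), 0,
                                           drift$biological_sdlog),
                              nrow = nrow(cohort))
    for (ef in effects) {
      grp <- if (ef$factor_name %in% c("gender", "age4", "age2", "bmi", "bp",
                                       "smoking"))
        hypothesis_groups(cohort, ef$factor_name)
      else factor(cohort[[ef$factor_name]])
      if (is.null(grp) || all(is.na(grp)))
        stop("effect_spec factor not found in cohort: ", ef$factor_name,
             call. = FALSE)
      shifted <- !is.na(grp) & grp != levels(grp)[1]
      j <- match(ef$features, fid)
      shift <- ef$effect_size * ef$direction * drift$biological_sdlog
      logbio[shifted, j] <- sweep(logbio[shifted, j, drop = FALSE], 2, shift,
                                  `+`)
    }
    pooled <- features$baseline  # fixed pooled-QC composition

    batches <- vector("list", length(study_design))
    truth_rows <- list()
    subj_ptr <- 0L
    for (b in seq_along(study_design)) {
      batch_id <- names(study_design)[b]
      step <- exp(stats::rnorm(m, 0, drift$batch_log_sd))
      inj_list <- list(); val_list <- list()
      tru_list <- list(); dft_list <- list(); noi_list <- list()
      for (r in seq_along(study_design[[b]])) {
        run <- study_design[[b]][[r]]
        run_id <- names(study_design[[b]])[r]
        npos <- nrow(run)
        att <- stats::runif(m, drift$attenuation_range[1],
                            drift$attenuation_range[2])
        lambda <- -log(1 - att) / max(npos - 1, 1)
        amp <- stats::runif(m, drift$sin_amplitude_range[1],
                            drift$sin_amplitude_range[2])
        period <- stats::runif(m, drift$sin_period_range[1],
                               drift$sin_period_range[2])
        dmat <- t(vapply(seq_len(npos), function(p)
          drift_factor(p, lambda, amp, period), numeric(m)))
        if (any(dmat <= 0))
          stop("drift model produced a non-positive factor", call. = FALSE)
        is_subj <- run$role == "subject"
        sub_idx <- integer(npos)
        sub_idx[is_subj] <- subj_ptr + seq_len(sum(is_subj))
        subj_ptr <- subj_ptr + sum(is_subj)

        tru <- matrix(rep(pooled, each = npos), nrow = npos)
        tru[is_subj, ] <- exp(logbio[sub_idx[is_subj], , drop = FALSE])
        noise <- matrix(exp(stats::rnorm(npos * m, 0, drift$technical_cv)),
                        nrow = npos)
        dft <- sweep(dmat, 2, step, `*`)
        raw <- tru * dft * noise

        sample_id <- character(npos)
        sample_id[is_subj] <- cohort$subject_id[sub_idx[is_subj]]
        sample_id[!is_subj] <- sprintf(
          "%s_%s_p%03d", run_id,
          ifelse(run$role[!is_subj] == "QC", "QC", "CQC"),
          run$position[!is_subj])
        inj_list[[r]] <- data.frame(
          sample_id = sample_id, batch_id = batch_id, run_id = run_id,
          injection_order = run$position, role = run$role,
          stringsAsFactors = FALSE)
        val_list[[r]] <- raw
        tru_list[[r]] <- tru; dft_list[[r]] <- dft; noi_list[[r]] <- noise
      }
      inj <- do.call(rbind, inj_list)
      raw <- do.call(rbind, val_list)
      tru <- do.call(rbind, tru_list)
      dft <- do.call(rbind, dft_list)
      noi <- do.call(rbind, noi_list)

      # missingness: left-censor below the per-feature detection quantile of
      # the raw batch values, plus a small MCAR component
      mask <- matrix(FALSE, nrow(raw), ncol(raw))
      if (mnar_quantile > 0) {
        lod <- apply(raw, 2, stats::quantile, probs = mnar_quantile,
                     na.rm = TRUE)
        mask <- mask | sweep(raw, 2, lod, `<`)
      }
      if (mcar_rate > 0)
        mask <- mask | (matrix(stats::runif(length(raw)), nrow(raw)) < mcar_rate)
      raw_masked <- raw
      raw_masked[mask] <- NA_real_

      rownames(tru) <- rownames(dft) <- rownames(noi) <- rownames(mask) <-
        inj$sample_id
      colnames(tru) <- colnames(dft) <- colnames(noi) <- colnames(mask) <- fid
      batches[[b]] <- peak_matrix(raw_masked, inj, features)
      truth_rows[[b]] <- list(truth = tru, drift = dft, noise = noi,
                              missing = mask)
    }
    names(batches) <- names(study_design)
    names(truth_rows) <- names(study_design)
    informative <- lapply(effects, function(ef) ef$features)
    names(informative) <- vapply(effects, function(ef) ef$factor_name, "")
    truth <- structure(list(per_batch = truth_rows,
                            biological_log = logbio,
                            pooled = stats::setNames(pooled, fid),
                            informative = informative,
                            mnar_quantile = mnar_quantile,
                            mcar_rate = mcar_rate),
                       class = "ground_truth")
    list(batches = batches, truth = truth)
  })
}

#' Reconstruct the raw study from its ground truth
#'
#' Applies drift x noise x missingness to the stored drift-free abundances;
#' the result equals the emitted raw batches exactly (a consistency check on
#' the generator).
#'
#' @param truth a `ground_truth` from [simulate_study()].
#' @return list of raw matrices, one per batch.
#' @export
reconstruct_raw <- function(truth) {
  lapply(truth$per_batch, function(tb) {
    raw <- tb$truth * tb$drift * tb$noise
    raw[tb$missing] <- NA_real_
    raw
  })
}
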