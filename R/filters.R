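# Quality-assurance and information filters applied to the integrated
# matrix, in the pipeline's canonical order:
#   1. post-correction QC RSD tolerance (20% UPLC-MS, 30% GC-MS),
#   2. 80% presence across subject samples,
#   3. biological-information ratio: inter-subject RSD / QC RSD < 1.5
#      removed (strictly less; a ratio of exactly 1.5 is retained).

platform_rsd_tolerance <- function(platform) {
  if (grepl("^GC", platform)) 30 else 20
}

feature_qc_rsd <- function(im) {
  apply(im$qc_data, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else compute_rsd(v)
  })
}

feature_subject_rsd <- function(im) {
  apply(im$data, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else compute_rsd(v)
  })
}

#' Quality-assurance filter
#'
#' Removes features whose post-correction pooled-QC RSD exceeds the platform
#' tolerance (20% for UPLC-MS, 30% for GC-MS) and features present in fewer
#' than `min_presence` of the subject samples. Features with no computable
#' QC RSD (fewer than 2 QC observations) fail QC.
#'
#' @param im an `integrated_matrix`.
#' @param platform platform string (decides the RSD tolerance), defaults to
#'   the features' platform.
#' @param rsd_tolerance override the tolerance, percent.
#' @param min_presence minimum fraction of subject samples in which a
#'   feature must be present (default 0.8; a feature at exactly 80% is
#'   retained).
#' @return list with `matrix` (filtered `integrated_matrix`) and `report`
#'   (a `qa_report`: per-feature decisions with a single primary reason code
#'   per removed feature, plus summary counts).
#' @export
qa_filter <- function(im, platform = NULL,
                      rsd_tolerance = NULL, min_presence = 0.8) {
  platform <- platform %||% im$features$platform[1]
  tol <- rsd_tolerance %||% platform_rsd_tolerance(platform)
  qc_rsd <- feature_qc_rsd(im)
  presence <- colMeans(!is.na(im$data))
  # 'exceeds the tolerance': values at the tolerance within numerical
  # precision are retained
  fail_rsd <- is.na(qc_rsd) | qc_rsd > tol * (1 + 1e-9)
  fail_presence <- presence < min_presence
  reason <- rep(NA_character_, ncol(im$data))
  reason[fail_presence] <- "low_presence"
  reason[fail_rsd] <- "qc_rsd"           # primary reason: filter order
  keep <- !(fail_rsd | fail_presence)
  report <- structure(list(
    per_feature = data.frame(
      feature_id = im$features$merged_id %||% im$features$feature_id,
      qc_rsd = qc_rsd, presence = presence,
      pass = keep, reason = reason, stringsAsFactors = FALSE),
    rsd_tolerance = tol, min_presence = min_presence,
    n_in = ncol(im$data), n_out = sum(keep),
    n_fail_rsd = sum(fail_rsd),
    n_fail_presence = sum(fail_presence & !fail_rsd)),
    class = "qa_report")
  if (!any(keep))
    warning("qa_filter removed every feature", call. = FALSE)
  list(matrix = subset_features(im, keep), report = report)
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %d -> %d features (QC RSD tol %.0f%%, presence >= %.0f%%)\n",
              x$n_in, x$n_out, x$rsd_tolerance, 100 * x$min_presence))
  cat(sprintf("  failed QC RSD: %d; failed presence: %d\n",
              x$n_fail_rsd, x$n_fail_presence))
  invisible(x)
}

#' Biological-information filter
#'
#' A feature whose between-subject variation is comparable to the technical
#' variation of replicate QC injections carries no usable biological
#' information. Features with inter-subject RSD / QC RSD strictly below
#' `threshold` (default 1.5) are removed; a ratio of exactly `threshold` is
#' retained. A QC RSD of zero gives an infinite ratio: the feature is
#' retained and logged.
#'
#' @param im an `integrated_matrix` (normally after [qa_filter()]).
#' @param qc_rsds optional per-feature QC RSD vector; computed from the QC
#'   audit rows if omitted.
#' @param threshold removal threshold on the RSD ratio.
#' @return list with `matrix` and `report` (per-feature ratios and
#'   decisions).
#' @export
information_filter <- function(im, qc_rsds = NULL, threshold = 1.5) {
  qc_rsd <- qc_rsds %||% feature_qc_rsd(im)
  subj_rsd <- feature_subject_rsd(im)
  ratio <- ifelse(!is.na(qc_rsd) & qc_rsd == 0, Inf, subj_rsd / qc_rsd)
  keep <- is.na(ratio) | ratio >= threshold * (1 - 1e-9)
  zero_qc <- which(!is.na(qc_rsd) & qc_rsd == 0)
  report <- list(
    per_feature = data.frame(
      feature_id = im$features$merged_id %||% im$features$feature_id,
      subject_rsd = subj_rsd, qc_rsd = qc_rsd, ratio = ratio,
      pass = keep, stringsAsFactors = FALSE),
    threshold = threshold,
    n_in = ncol(im$data), n_out = sum(keep),
    n_removed = sum(!keep),
    zero_qc_rsd = length(zero_qc))
  if (length(zero_qc))
    message(length(zero_qc),
            " feature(s) had zero QC RSD; ratio set to +Inf and retained")
  list(matrix = subset_features(im, keep), report = report)
}
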