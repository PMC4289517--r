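# Injection-sequence layout of an analytical run: a block of conditioning
# QC injections that equilibrate the column, then subject injections with a
# pooled-QC injection at every `qc_interval`-th post-conditioning position.

#' Build the injection sequence for one analytical run
#'
#' Conditioning QCs occupy positions `1..n_conditioning`. Thereafter subjects
#' are interleaved so that every `qc_interval`-th post-conditioning injection
#' is a pooled QC, i.e. each group of `qc_interval - 1` subjects is followed
#' by a QC. The canonical layouts are 60 subjects with 10 conditioning QCs
#' (UPLC-MS, giving 85 injections of which 25 are QC roles) and 30 subjects
#' with 5 conditioning QCs (GC-MS).
#'
#' @param platform `"GCMS"`, `"UPLC_pos"` or `"UPLC_neg"`.
#' @param n_subjects number of subject injections.
#' @param n_conditioning number of conditioning QC injections (default 10 for
#'   UPLC platforms, 5 for GC-MS).
#' @param qc_interval a QC every `qc_interval`-th injection (default 5).
#' @return a `run_design` data.frame with columns `position` (1-based,
#'   consecutive) and `role` (`conditioning_QC`, `QC`, `subject`);
#'   attributes `platform` and `qc_interval`.
#' @examples
#' d <- build_run_design("UPLC_pos", 60)
#' nrow(d)                      # 85
#' sum(d$role != "subject")     # 25
#' @export
build_run_design <- function(platform = c("UPLC_pos", "UPLC_neg", "GCMS"),
                             n_subjects,
                             n_conditioning = if (platform == "GCMS") 5L else 10L,
                             qc_interval = 5L) {
  platform <- match.arg(platform)
  stop_if_not_scalar_count(n_subjects, "n_subjects")
  stop_if_not_scalar_count(n_conditioning, "n_conditioning")
  if (!is.numeric(qc_interval) || qc_interval < 2)
    stop("`qc_interval` must be >= 2", call. = FALSE)

  roles <- rep("conditioning_QC", n_conditioning)
  remaining <- n_subjects
  while (remaining > 0) {
    grp <- min(qc_interval - 1, remaining)
    roles <- c(roles, rep("subject", grp))
    remaining <- remaining - grp
    if (grp == qc_interval - 1) roles <- c(roles, "QC")
  }
  out <- data.frame(position = seq_along(roles), role = roles,
                    stringsAsFactors = FALSE)
  attr(out, "platform") <- platform
  attr(out, "qc_interval") <- as.integer(qc_interval)
  class(out) <- c("run_design", "data.frame")
  out
}

#' Multi-batch study layout
#'
#' Assembles the run designs of a whole study: `n_batches` analytical
#' batches, each split into `runs_per_batch` runs of
#' `subjects_per_batch / runs_per_batch` subjects. The canonical designs are
#' 10 batches of 120 subjects in 2 runs of 60 (UPLC-MS) or 4 runs of 30
#' (GC-MS).
#'
#' @inheritParams build_run_design
#' @param n_batches number of analytical batches.
#' @param subjects_per_batch subject injections per batch.
#' @param runs_per_batch analytical runs per batch (default 2 for UPLC, 4
#'   for GC-MS).
#' @return a `study_design`: list of batches, each a named list of
#'   `run_design` objects; attributes `platform`, `n_subjects`.
#' @export
build_study_design <- function(platform = c("UPLC_pos", "UPLC_neg", "GCMS"),
                               n_batches = 10L, subjects_per_batch = 120L,
                               runs_per_batch = if (platform == "GCMS") 4L else 2L,
                               n_conditioning = if (platform == "GCMS") 5L else 10L,
                               qc_interval = 5L) {
  platform <- match.arg(platform)
  stop_if_not_scalar_count(n_batches, "n_batches")
  stop_if_not_scalar_count(subjects_per_batch, "subjects_per_batch")
  if (subjects_per_batch %% runs_per_batch != 0)
    stop("`subjects_per_batch` must be divisible by `runs_per_batch`",
         call. = FALSE)
  per_run <- subjects_per_batch / runs_per_batch
  design <- lapply(seq_len(n_batches), function(b) {
    runs <- lapply(seq_len(runs_per_batch), function(r) {
      build_run_design(platform, per_run, n_conditioning, qc_interval)
    })
    names(runs) <- sprintf("B%02dR%d", b, seq_len(runs_per_batch))
    runs
  })
  names(design) <- sprintf("B%02d", seq_len(n_batches))
  attr(design, "platform") <- platform
  attr(design, "n_subjects") <- n_batches * subjects_per_batch
  class(design) <- "study_design"
  design
}
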