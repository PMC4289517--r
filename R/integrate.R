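# Batch integration: match high-quality features across corrected batches
# (by m/z ppm + retention-time window for UPLC, by library identity for GC),
# concatenate the normalized values, and un-normalize each merged feature by
# the median of its raw pooled-QC peak areas across all batches, restoring
# an interpretable intensity scale. Subjects become rows; corrected QC
# injections are retained separately for audit (QA filtering).

match_feature <- function(ref, feat, mz_ppm, rt_window) {
  if (!is.na(feat$retention_index) || is.na(feat$mz)) {
    # GC: match by library identity (annotation if present, else feature_id)
    key <- if (!is.na(feat$annotation) && nzchar(feat$annotation))
      feat$annotation else feat$feature_id
    ref_key <- ifelse(!is.na(ref$annotation) & nzchar(ref$annotation),
                      ref$annotation, ref$feature_id)
    hit <- which(ref_key == key)
    return(if (length(hit)) hit[1] else NA_integer_)
  }
  d_mz <- abs(ref$mz - feat$mz)
  d_rt <- abs(ref$rt - feat$rt)
  cand <- which(d_mz <= mz_ppm * feat$mz / 1e6 & d_rt <= rt_window)
  if (!length(cand)) return(NA_integer_)
  # ambiguity resolved by the nearest-m/z rule
  cand[which.min(d_mz[cand])]
}

#' Integrate corrected batches into one subjects x features matrix
#'
#' @param corrected_batches list of corrected `peak_matrix` objects from
#'   [correct_batch()] / [qcrlsc()] (must carry the `raw_qc` attribute).
#' @param mz_ppm m/z matching tolerance in ppm (UPLC features).
#' @param rt_window retention-time matching window, minutes (UPLC features).
#' @return an `integrated_matrix`: list with
#'   \describe{
#'     \item{data}{subjects x features matrix, un-normalized scale}
#'     \item{subjects}{data.frame `sample_id`, `batch_id`}
#'     \item{features}{feature catalogue + `n_batches`, `median_qc_area`,
#'       `presence`}
#'     \item{qc_data}{corrected QC injections x features, same scale}
#'     \item{qc_meta}{QC injection metadata}
#'   }
#' @export
integrate_study <- function(corrected_batches, mz_ppm = 10, rt_window = 0.2) {
  stopifnot(length(corrected_batches) >= 1)
  platforms <- unique(unlist(lapply(corrected_batches,
                                    function(b) unique(b$features$platform))))
  if (length(platforms) > 1)
    stop("batches must share a platform; got: ",
         paste(platforms, collapse = ", "), call. = FALSE)

  # build the merged feature reference by sequential tolerance matching
  # merged columns keep the representative feature_id of the batch where the
  # feature was first seen (made unique if two distinct features collide)
  ref <- corrected_batches[[1]]$features
  ref$merged_id <- make.unique(ref$feature_id)
  maps <- vector("list", length(corrected_batches))
  maps[[1]] <- ref$merged_id
  if (length(corrected_batches) > 1) {
    for (b in 2:length(corrected_batches)) {
      feats <- corrected_batches[[b]]$features
      map <- character(nrow(feats))
      for (j in seq_len(nrow(feats))) {
        hit <- match_feature(ref, feats[j, ], mz_ppm, rt_window)
        if (is.na(hit)) {
          new <- feats[j, ]
          new$merged_id <- utils::tail(make.unique(c(ref$merged_id,
                                                     new$feature_id)), 1)
          ref <- rbind(ref, new)
          map[j] <- new$merged_id
        } else map[j] <- ref$merged_id[hit]
      }
      maps[[b]] <- map
    }
  }
  merged_ids <- ref$merged_id
  m <- length(merged_ids)

  # pooled raw QC areas across batches -> overall expected QC peak area
  raw_qc_pool <- stats::setNames(vector("list", m), merged_ids)
  subj_rows <- list(); subj_meta <- list()
  qc_rows <- list(); qc_meta <- list()
  for (b in seq_along(corrected_batches)) {
    pm <- corrected_batches[[b]]
    map <- maps[[b]]
    raw_qc <- attr(pm, "raw_qc")
    if (is.null(raw_qc))
      stop("corrected batch lacks its raw QC audit (attribute 'raw_qc'); ",
           "use correct_batch()/qcrlsc()", call. = FALSE)
    is_subj <- pm$injections$role == "subject"
    is_qc <- pm$injections$role == "QC"

    expand <- function(vals) {
      out <- matrix(NA_real_, nrow(vals), m,
                    dimnames = list(rownames(vals), merged_ids))
      out[, map] <- vals
      out
    }
    subj_rows[[b]] <- expand(pm$data[is_subj, , drop = FALSE])
    subj_meta[[b]] <- data.frame(
      sample_id = pm$injections$sample_id[is_subj],
      batch_id = pm$injections$batch_id[is_subj], stringsAsFactors = FALSE)
    qc_rows[[b]] <- expand(pm$data[is_qc, , drop = FALSE])
    qc_meta[[b]] <- data.frame(
      sample_id = pm$injections$sample_id[is_qc],
      batch_id = pm$injections$batch_id[is_qc],
      run_id = pm$injections$run_id[is_qc],
      injection_order = pm$injections$injection_order[is_qc],
      stringsAsFactors = FALSE)
    for (j in seq_along(map))
      raw_qc_pool[[map[j]]] <- c(raw_qc_pool[[map[j]]], raw_qc[, j])
  }
  subj <- do.call(rbind, subj_rows)
  qc <- do.call(rbind, qc_rows)
  med_qc <- vapply(raw_qc_pool, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))

  # un-normalize: multiply by the overall expected (median) raw QC peak area
  subj <- sweep(subj, 2, med_qc, `*`)
  qc <- sweep(qc, 2, med_qc, `*`)

  n_batches <- Reduce(`+`, lapply(maps, function(map)
    as.integer(merged_ids %in% map)))
  features <- ref[order(ref$merged_id), , drop = FALSE]
  features <- features[match(merged_ids, features$merged_id), , drop = FALSE]
  features$n_batches <- n_batches
  features$median_qc_area <- med_qc
  features$presence <- colMeans(!is.na(subj))
  rownames(features) <- NULL

  structure(list(data = subj,
                 subjects = do.call(rbind, subj_meta),
                 features = features,
                 qc_data = qc,
                 qc_meta = do.call(rbind, qc_meta)),
            class = "integrated_matrix")
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf("<integrated_matrix> %d subjects x %d features (%d QC audit rows)\n",
              nrow(x$data), ncol(x$data), nrow(x$qc_data)))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$data))))
  invisible(x)
}

#' @export
dim.integrated_matrix <- function(x) dim(x$data)

# keep a column subset of an integrated matrix
subset_features <- function(im, keep) {
  structure(list(data = im$data[, keep, drop = FALSE],
                 subjects = im$subjects,
                 features = im$features[keep, , drop = FALSE],
                 qc_data = im$qc_data[, keep, drop = FALSE],
                 qc_meta = im$qc_meta),
            class = "integrated_matrix")
}
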