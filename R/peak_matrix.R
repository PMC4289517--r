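# The unit of correction: an injections x features peak-area table, with
# per-injection metadata (sample, batch, run, injection order, role) and a
# per-feature catalogue (platform, m/z + retention time for UPLC, retention
# index for GC, annotation, MSI level carried as passthrough metadata).

#' Construct a peak matrix
#'
#' @param data numeric matrix, injections in rows, features in columns;
#'   missing areas as `NA`, no negative areas.
#' @param injections data.frame with columns `sample_id`, `batch_id`,
#'   `run_id`, `injection_order`, `role` (one row per row of `data`).
#' @param features data.frame with columns `feature_id`, `platform` and
#'   either `mz` + `rt` (UPLC) or `retention_index` (GC); optional
#'   `annotation`, `msi_level`.
#' @return a `peak_matrix` object.
#' @export
peak_matrix <- function(data, injections, features) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  validate_peak_matrix_parts(data, injections, features)
  rownames(data) <- injections$sample_id
  colnames(data) <- features$feature_id
  structure(list(data = data, injections = injections, features = features),
            class = "peak_matrix")
}

validate_peak_matrix_parts <- function(data, injections, features) {
  req_inj <- c("sample_id", "batch_id", "run_id", "injection_order", "role")
  miss <- setdiff(req_inj, names(injections))
  if (length(miss))
    stop("injection table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"feature_id" %in% names(features))
    stop("feature table is missing required column(s): feature_id",
         call. = FALSE)
  if (nrow(injections) != nrow(data) || nrow(features) != ncol(data))
    stop("metadata dimensions do not match the data matrix", call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("peak areas must be non-negative", call. = FALSE)
  bad_role <- setdiff(unique(injections$role),
                      c("conditioning_QC", "QC", "subject"))
  if (length(bad_role))
    stop("invalid injection role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  for (run in unique(injections$run_id)) {
    ord <- injections$injection_order[injections$run_id == run]
    if (anyDuplicated(ord))
      stop(sprintf("duplicate injection_order within run '%s'", run),
           call. = FALSE)
  }
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id in feature table", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf(
    "<peak_matrix> %d injections x %d features (%d subject, %d QC, %d conditioning)\n",
    nrow(x$data), ncol(x$data),
    sum(x$injections$role == "subject"),
    sum(x$injections$role == "QC"),
    sum(x$injections$role == "conditioning_QC")))
  cat(sprintf("  batches: %s\n",
              paste(unique(x$injections$batch_id), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$data))))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$data)

# subset a peak matrix by injection rows
subset_injections <- function(pm, keep) {
  structure(list(data = pm$data[keep, , drop = FALSE],
                 injections = pm$injections[keep, , drop = FALSE],
                 features = pm$features),
            class = "peak_matrix")
}
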