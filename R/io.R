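# Canonical on-disk dialect: tab-separated tables with "NA" for missing
# cells and a provenance comment header (tool version, seed, config hash).
# A peak matrix is a pair of files: the injection x feature area table and
# a companion feature-metadata table.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  h <- sprintf("# metabodrift %s",
               as.character(utils::packageVersion("metabodrift")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", format(seed)))
  if (!is.null(config_hash)) h <- c(h, sprintf("# config_hash: %s",
                                               config_hash))
  h
}

write_tsv_with_header <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_skip_header <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA")
}

#' Write / read a peak matrix
#'
#' The area table has the metadata columns `sample_id`, `batch_id`,
#' `run_id`, `injection_order`, `role` followed by one column per feature;
#' missing cells are encoded `NA`. The companion feature table carries
#' `feature_id`, `platform`, `mz`, `rt`, `retention_index`, `annotation`,
#' `msi_level`. The round trip is lossless.
#'
#' @param pm a `peak_matrix`.
#' @param path area-table TSV path.
#' @param features_path feature-metadata TSV path (default: `path` with a
#'   `.features.tsv` suffix).
#' @param seed,config_hash optional provenance recorded in the header.
#' @return (`write`) the path, invisibly; (`read`) a `peak_matrix`.
#' @export
write_peak_matrix <- function(pm, path,
                              features_path = paste0(path, ".features.tsv"),
                              seed = NULL, config_hash = NULL) {
  df <- cbind(pm$injections, as.data.frame(pm$data, check.names = FALSE))
  write_tsv_with_header(df, path, seed, config_hash)
  feat <- pm$features
  for (col in c("mz", "rt", "retention_index", "annotation", "msi_level"))
    if (!col %in% names(feat)) feat[[col]] <- NA
  write_tsv_with_header(feat, features_path, seed, config_hash)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path,
                             features_path = paste0(path, ".features.tsv")) {
  df <- read_tsv_skip_header(path)
  req <- c("sample_id", "batch_id", "run_id", "injection_order", "role")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("peak matrix file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  inj <- df[req]
  vals <- as.matrix(df[setdiff(names(df), req)])
  storage.mode(vals) <- "double"
  feat <- read_tsv_skip_header(features_path)
  if (!"feature_id" %in% names(feat))
    stop("feature metadata file is missing required column(s): feature_id",
         call. = FALSE)
  reorder <- match(colnames(vals), feat$feature_id)
  if (anyNA(reorder))
    stop("feature metadata does not cover all feature columns", call. = FALSE)
  peak_matrix(vals, inj, feat[reorder, , drop = FALSE])
}

#' Write / read a cohort table
#'
#' TSV with `subject_id` plus covariate columns; any extra numeric columns
#' (e.g. a clinical-chemistry panel such as CHOL or TRIG) are carried
#' through untouched for the correlation stage. Validation: unique
#' `subject_id`, smoking in \{non, ex, current\}, parseable numerics,
#' SBP > DBP.
#'
#' @param cohort a `cohort_table`.
#' @param path TSV path.
#' @param seed,config_hash optional provenance header fields.
#' @return (`write`) the path invisibly; (`read`) a `cohort_table`.
#' @export
write_cohort <- function(cohort, path, seed = NULL, config_hash = NULL) {
  write_tsv_with_header(as.data.frame(cohort), path, seed, config_hash)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read_tsv_skip_header(path)
  if (!"subject_id" %in% names(df))
    stop("cohort file is missing required column(s): subject_id",
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in cohort file", call. = FALSE)
  for (col in intersect(c("age", "bmi", "sbp", "dbp"), names(df))) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("cohort column '%s' is not numeric", col), call. = FALSE)
  }
  if ("smoking" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$smoking)),
                   c("non", "ex", "current"))
    if (length(bad))
      stop("invalid smoking value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (all(c("sbp", "dbp") %in% names(df)) &&
      any(df$sbp <= df$dbp, na.rm = TRUE))
    stop("cohort has subject(s) with SBP <= DBP", call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a subjects x features matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path TSV path.
#' @param id_col name of the first (row-id) column.
#' @param seed,config_hash optional provenance header fields.
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id", seed = NULL,
                             config_hash = NULL) {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv_with_header(df, path, seed, config_hash)
}
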