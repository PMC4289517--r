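# QC-RLSC: quality-control-based robust LOESS signal correction.
#
# For each feature and each analytical run, a robust locally weighted
# regression (tricube weights, local linear fit, symmetric-family
# robustifying iterations) is fitted to the pooled-QC peak areas against
# injection order. A natural cubic spline is then interpolated through the
# LOESS fit across the whole run, held constant beyond the terminal QCs, and
# every injection of the run is divided by the curve value at its position.
# Conditioning QCs never enter the fit (they equilibrate the column) but are
# corrected for audit. The LOESS span is chosen per feature by
# leave-one-out cross-validation over a small grid, which keeps the curve
# from chasing random measurement error.

default_loess_params <- function() {
  list(span = "auto", span_grid = c(0.3, 0.5, 0.75, 1.0),
       degree = 1, family = "symmetric", iterations = 3, min_points = 4)
}

loess_fit_qc <- function(x, y, span, degree, family, iterations) {
  stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
               degree = degree, family = family,
               control = stats::loess.control(
                 surface = "direct",
                 iterations = iterations))
}

# leave-one-out CV error of a loess span on the QC points
loo_cv_error <- function(x, y, span, degree, family, iterations) {
  err <- vapply(seq_along(x), function(i) {
    fit <- tryCatch(
      suppressWarnings(loess_fit_qc(x[-i], y[-i], span, degree, family,
                                    iterations)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- tryCatch(suppressWarnings(stats::predict(fit, data.frame(x = x[i]))),
                     error = function(e) NA_real_)
    (pred - y[i])^2
  }, numeric(1))
  if (all(is.na(err))) NA_real_ else mean(err, na.rm = TRUE)
}

#' Fit a QC-RLSC correction curve for one feature in one run
#'
#' @param qc_points data.frame with columns `injection_order` and `area`
#'   (pooled-QC peak areas; conditioning QCs must already be excluded).
#' @param positions integer positions of the whole run at which the curve is
#'   evaluated (typically `1:n_injections`).
#' @param loess_params list overriding any of `span` (`"auto"` for LOO-CV
#'   selection over `span_grid`, or a number), `span_grid`, `degree`,
#'   `family`, `iterations`, `min_points`.
#' @return a `correction_curve`: list with `positions`, `factor` (strictly
#'   positive curve values), `qc_fitted`, `span`, `uncorrectable`,
#'   `fallback` flags.
#' @export
fit_correction_curve <- function(qc_points, positions,
                                 loess_params = list()) {
  lp <- utils::modifyList(default_loess_params(), loess_params)
  ok <- !is.na(qc_points$area)
  x <- qc_points$injection_order[ok]
  y <- qc_points$area[ok]
  out <- structure(list(positions = positions,
                        factor = rep(NA_real_, length(positions)),
                        qc_fitted = NULL, span = NA_real_,
                        uncorrectable = FALSE, fallback = FALSE),
                   class = "correction_curve")
  if (length(x) < lp$min_points) {
    out$uncorrectable <- TRUE
    return(out)
  }
  # constant QC series: the curve is that constant (robust LOESS is
  # numerically fragile when every residual is zero)
  if (diff(range(y)) <= 1e-10 * max(abs(y))) {
    out$factor <- rep(mean(y), length(positions))
    out$qc_fitted <- data.frame(injection_order = x, area = y,
                                fitted = mean(y))
    out$span <- 1.0
    return(out)
  }
  if (identical(lp$span, "auto")) {
    cv <- vapply(lp$span_grid, function(sp)
      loo_cv_error(x, y, sp, lp$degree, lp$family, lp$iterations), numeric(1))
    if (all(is.na(cv))) {
      span <- 1.0
    } else {
      # ties broken toward the larger (smoother) span
      best <- min(cv, na.rm = TRUE)
      span <- max(lp$span_grid[which(!is.na(cv) & cv <= best + 1e-12)])
    }
  } else span <- lp$span

  fit <- tryCatch(
    suppressWarnings(loess_fit_qc(x, y, span, lp$degree, lp$family,
                                  lp$iterations)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$uncorrectable <- TRUE
    return(out)
  }
  qc_fitted <- suppressWarnings(stats::predict(fit, data.frame(x = x)))
  # cubic spline through the LOESS values, constant beyond terminal QCs
  if (length(unique(x)) >= 2) {
    sp_fun <- stats::splinefun(x, qc_fitted, method = "natural")
    px <- pmin(pmax(positions, min(x)), max(x))
    curve <- sp_fun(px)
  } else curve <- rep(qc_fitted[1], length(positions))

  if (any(!is.finite(curve)) || any(curve <= 0)) {
    # non-positive fitted factor: fall back to a flat curve at the global
    # median QC area
    out$fallback <- TRUE
    curve <- rep(stats::median(y), length(positions))
    if (any(curve <= 0)) {
      out$uncorrectable <- TRUE
      return(out)
    }
    qc_fitted <- rep(curve[1], length(x))
  }
  out$factor <- curve
  out$qc_fitted <- data.frame(injection_order = x, area = y,
                              fitted = qc_fitted)
  out$span <- span
  out
}

#' Evaluate a correction curve at given positions
#' @param curve a `correction_curve`.
#' @param positions integer injection positions.
#' @return curve values (constant-extrapolated outside the fitted range).
#' @export
curve_at <- function(curve, positions) {
  idx <- match(positions, curve$positions)
  if (anyNA(idx))
    stop("correction curve not defined at requested position(s)",
         call. = FALSE)
  curve$factor[idx]
}

#' Fit correction curves for every feature of every run in a batch
#'
#' @param batch a raw `peak_matrix` for one analytical batch.
#' @param loess_params see [fit_correction_curve()].
#' @return nested list `curves[[run_id]][[feature_id]]`.
#' @export
fit_batch_curves <- function(batch, loess_params = list()) {
  runs <- unique(batch$injections$run_id)
  out <- lapply(runs, function(run) {
    in_run <- batch$injections$run_id == run
    ord <- batch$injections$injection_order[in_run]
    is_qc <- batch$injections$role[in_run] == "QC"  # conditioning excluded
    vals <- batch$data[in_run, , drop = FALSE]
    positions <- sort(ord)
    curves <- lapply(seq_len(ncol(vals)), function(j) {
      fit_correction_curve(
        data.frame(injection_order = ord[is_qc], area = vals[is_qc, j]),
        positions = positions, loess_params = loess_params)
    })
    names(curves) <- batch$features$feature_id
    curves
  })
  names(out) <- runs
  out
}

#' Apply correction curves to a batch
#'
#' Divides every cell by its feature's curve value at its injection
#' position, putting the batch on the normalized scale (QC values ~ 1).
#' Missing cells stay missing; features whose curve is flagged
#' uncorrectable (or absent) for a run become missing for that run, the
#' same convention as a feature undetected in a batch. The corrected
#' matrix keeps the raw QC areas as an attribute for later
#' un-normalization.
#'
#' @param batch a raw `peak_matrix`.
#' @param curves nested list from [fit_batch_curves()].
#' @return a normalized-scale `peak_matrix` with attribute `raw_qc`.
#' @export
correct_batch <- function(batch, curves) {
  runs <- unique(batch$injections$run_id)
  missing_runs <- setdiff(runs, names(curves))
  if (length(missing_runs))
    stop("no curves supplied for run(s): ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  corrected <- batch$data
  for (run in runs) {
    in_run <- which(batch$injections$run_id == run)
    ord <- batch$injections$injection_order[in_run]
    run_curves <- curves[[run]]
    for (j in seq_len(ncol(corrected))) {
      fid <- batch$features$feature_id[j]
      cv <- run_curves[[fid]]
      if (is.null(cv) || isTRUE(cv$uncorrectable)) {
        corrected[in_run, j] <- NA_real_
      } else {
        corrected[in_run, j] <- batch$data[in_run, j] / curve_at(cv, ord)
      }
    }
  }
  out <- peak_matrix(corrected, batch$injections, batch$features)
  qc_rows <- batch$injections$role == "QC"
  attr(out, "raw_qc") <- batch$data[qc_rows, , drop = FALSE]
  attr(out, "curves") <- curves
  out
}

#' One-call QC-RLSC for a whole study
#'
#' Fits per-run correction curves and applies them, batch by batch.
#'
#' @param batches list of raw `peak_matrix` objects.
#' @param loess_params see [fit_correction_curve()].
#' @return list of corrected `peak_matrix` objects.
#' @export
qcrlsc <- function(batches, loess_params = list()) {
  lapply(batches, function(b) correct_batch(b, fit_batch_curves(b, loess_params)))
}
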