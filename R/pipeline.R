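# End-to-end orchestration: simulate (or load) -> QC-RLSC correct ->
# integrate -> QA + information filters -> impute/scale + univariate screen
# -> consensus selection -> sample-size study, with stage toggles, a master
# seed and a JSON run report.

#' Assemble a pipeline configuration
#'
#' @param stages character vector of stage names to run, in canonical order
#'   `simulate`, `correct`, `integrate`, `qa`, `stats`, `select`,
#'   `samplesize` (`"all"` expands to every stage).
#' @param platform analytical platform for simulation.
#' @param n_batches,subjects_per_batch,runs_per_batch,n_features simulated
#'   study size (each run needs enough interleaved QCs for curve fitting:
#'   at least 16 subjects per run at the default QC interval).
#' @param drift list of [drift_model()] arguments.
#' @param effects list of [effect_spec()] argument lists (each with
#'   `factor_name`, `features`, `effect_size`).
#' @param hypothesis clinical hypothesis driving the stats/selection stages
#'   (see [hypothesis_groups()]).
#' @param rsd_tolerance,min_presence,ratio_threshold filter parameters.
#' @param loess_params LOESS settings (see [fit_correction_curve()]).
#' @param selection list: `B`, `k_max`, `classifier`, `eval_resamples`,
#'   `ntree`.
#' @param samplesize list: `sizes`, `B`, `classifiers`.
#' @param seed master seed (required when any stochastic stage is enabled).
#' @param input_peak_matrices character vector of peak-matrix TSV paths
#'   (one per batch) when not simulating.
#' @param input_cohort cohort TSV path when not simulating.
#' @param out_dir directory for artifacts (`NULL` = keep in memory only).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(stages = "all",
                            platform = "UPLC_pos",
                            n_batches = 2, subjects_per_batch = 40,
                            runs_per_batch = NULL, n_features = 50,
                            drift = list(), effects = list(),
                            hypothesis = "gender",
                            rsd_tolerance = NULL, min_presence = 0.8,
                            ratio_threshold = 1.5,
                            loess_params = list(),
                            selection = list(),
                            samplesize = list(),
                            seed = NULL,
                            input_peak_matrices = NULL,
                            input_cohort = NULL,
                            out_dir = NULL) {
  all_stages <- c("simulate", "correct", "integrate", "qa", "stats",
                  "select", "samplesize")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!"simulate" %in% stages && is.null(input_peak_matrices))
    stop("no input peak matrices and the simulate stage is disabled",
         call. = FALSE)
  if (is.null(seed))
    stop("a master seed is required", call. = FALSE)
  if (min_presence <= 0 || ratio_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  sel <- utils::modifyList(list(B = 100, k_max = 30, classifier = "random_forest",
                                eval_resamples = 20, ntree = 500), selection)
  ss <- utils::modifyList(list(sizes = seq(50, 650, 50), B = 100,
                               classifiers = "random_forest"), samplesize)
  cfg <- list(stages = stages, platform = platform, n_batches = n_batches,
              subjects_per_batch = subjects_per_batch,
              runs_per_batch = runs_per_batch,
              n_features = n_features, drift = drift, effects = effects,
              hypothesis = hypothesis, rsd_tolerance = rsd_tolerance,
              min_presence = min_presence, ratio_threshold = ratio_threshold,
              loess_params = loess_params, selection = sel, samplesize = ss,
              seed = seed, input_peak_matrices = input_peak_matrices,
              input_cohort = input_cohort, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # the scientific configuration, not where it lands
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes the enabled stages in canonical order and returns every
#' artifact plus a run report (per-stage feature/sample counts, parameters,
#' seed, wall-clock seconds). With `out_dir` set, artifacts are written as
#' provenance-headed TSVs and the report as JSON.
#'
#' @param config a `pipeline_config`.
#' @param verbose print stage progress messages.
#' @return list with the stage artifacts (`cohort`, `raw`, `truth`,
#'   `corrected`, `integrated`, `qa`, `info`, `screen`, `selection`,
#'   `samplesize` as applicable) and `report`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 stages = list())
  art <- list()
  stage_time <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$stages[[name]]$seconds <<- as.numeric(Sys.time() - ts)
    res
  }

  if ("simulate" %in% config$stages) {
    say("simulate: %d batches x %d subjects, %d features",
        config$n_batches, config$subjects_per_batch, config$n_features)
    design <- if (is.null(config$runs_per_batch))
      build_study_design(config$platform, config$n_batches,
                         config$subjects_per_batch)
    else
      build_study_design(config$platform, config$n_batches,
                         config$subjects_per_batch,
                         runs_per_batch = config$runs_per_batch)
    art$cohort <- generate_cohort(attr(design, "n_subjects"),
                                  include_clinical = TRUE,
                                  seed = derive_seed(config$seed, 11))
    feats <- simulate_feature_catalogue(config$n_features, config$platform,
                                        seed = derive_seed(config$seed, 12))
    effects <- lapply(config$effects, function(e) do.call(effect_spec, e))
    sim <- stage_time("simulate",
      simulate_study(design, art$cohort, feats,
                     drift = do.call(drift_model, config$drift),
                     effects = effects,
                     seed = derive_seed(config$seed, 13)))
    art$raw <- sim$batches
    art$truth <- sim$truth
    report$stages$simulate$n_batches <- length(art$raw)
    report$stages$simulate$n_features <- ncol(art$raw[[1]]$data)
    report$stages$simulate$n_injections <- sum(vapply(art$raw, nrow,
                                                      numeric(1)))
  } else {
    art$raw <- stage_time("load", lapply(config$input_peak_matrices,
                                         read_peak_matrix))
    if (!is.null(config$input_cohort))
      art$cohort <- read_cohort(config$input_cohort)
    report$stages$load$n_batches <- length(art$raw)
  }

  if ("correct" %in% config$stages) {
    say("correct: QC-RLSC over %d batches", length(art$raw))
    art$corrected <- stage_time("correct",
                                qcrlsc(art$raw, config$loess_params))
    report$stages$correct$n_batches <- length(art$corrected)
  }

  if ("integrate" %in% config$stages) {
    src <- art$corrected %||% art$raw
    art$integrated <- stage_time("integrate", integrate_study(src))
    report$stages$integrate$n_subjects <- nrow(art$integrated$data)
    report$stages$integrate$n_features <- ncol(art$integrated$data)
  }

  if ("qa" %in% config$stages) {
    qa <- stage_time("qa", qa_filter(art$integrated,
                                     rsd_tolerance = config$rsd_tolerance,
                                     min_presence = config$min_presence))
    info <- stage_time("qa", information_filter(
      qa$matrix, threshold = config$ratio_threshold))
    art$qa <- qa$report; art$info <- info$report
    art$integrated <- info$matrix
    report$stages$qa$n_in <- qa$report$n_in
    report$stages$qa$n_after_qa <- qa$report$n_out
    report$stages$qa$n_after_info <- info$report$n_out
  }

  needs_analysis <- any(c("stats", "select", "samplesize") %in% config$stages)
  if (needs_analysis) {
    if (is.null(art$cohort))
      stop("stats/selection stages need a cohort", call. = FALSE)
    x <- autoscale(impute_missing(art$integrated))
    co <- art$cohort[match(rownames(x), art$cohort$subject_id), ,
                     drop = FALSE]
    labels <- hypothesis_groups(co, config$hypothesis)
    art$analysis_matrix <- x
    art$labels <- labels
  }

  if ("stats" %in% config$stages) {
    art$screen <- stage_time("stats", univariate_screen(x, labels))
    report$stages$stats$n_features <- nrow(art$screen)
    report$stages$stats$n_p_below_05 <- sum(art$screen$p < 0.05)
  }

  if ("select" %in% config$stages) {
    s <- config$selection
    art$selection <- stage_time("select", consensus_select(
      x, labels, B = s$B, classifier = s$classifier,
      k_max = min(s$k_max, ncol(x)), eval_resamples = s$eval_resamples,
      ntree = s$ntree, seed = derive_seed(config$seed, 21)))
    report$stages$select$k_star <- art$selection$selection$k_star
    report$stages$select$accuracy <- art$selection$selection$accuracy_at_k_star
  }

  if ("samplesize" %in% config$stages) {
    s <- config$samplesize
    ok <- !is.na(labels)
    sizes <- s$sizes[s$sizes <= sum(ok)]
    art$samplesize <- stage_time("samplesize", accuracy_vs_n(
      x[ok, , drop = FALSE], labels[ok], sizes = sizes,
      classifiers = s$classifiers, B = s$B,
      seed = derive_seed(config$seed, 22)))
    report$stages$samplesize$n_sizes <- length(sizes)
  }

  report$wall_clock_seconds <- as.numeric(Sys.time() - t0)
  art$report <- report

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    ch <- report$config_hash
    if (!is.null(art$integrated))
      write_matrix_tsv(art$integrated$data,
                       file.path(config$out_dir, "integrated_matrix.tsv"),
                       seed = config$seed, config_hash = ch)
    if (!is.null(art$cohort))
      write_cohort(art$cohort, file.path(config$out_dir, "cohort.tsv"),
                   seed = config$seed, config_hash = ch)
    if (!is.null(art$screen))
      write_tsv_with_header(art$screen,
                            file.path(config$out_dir, "univariate_screen.tsv"),
                            seed = config$seed, config_hash = ch)
    if (!is.null(art$selection)) {
      write_tsv_with_header(art$selection$ranking,
                            file.path(config$out_dir, "consensus_ranking.tsv"),
                            seed = config$seed, config_hash = ch)
      jsonlite::write_json(
        list(hypothesis = config$hypothesis,
             k_star = art$selection$selection$k_star,
             selected = art$selection$selected,
             seed = config$seed),
        file.path(config$out_dir, "selection_manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    }
    if (!is.null(art$samplesize))
      write_tsv_with_header(art$samplesize,
                            file.path(config$out_dir, "sample_size_curve.tsv"),
                            seed = config$seed, config_hash = ch)
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  art
}
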