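#' Validate a pipeline configuration
#'
#' A configuration holds the input paths, the time point to analyse and
#' the modelling parameters for one end-to-end run. Unknown keys are
#' rejected so silently misspelled options cannot change an analysis.
#'
#' @param peak_table Path to the peak-table file (TSV).
#' @param standards Path to the internal-standards file (TSV), or `NULL`
#'   to skip normalisation.
#' @param metadata Path to the sample-metadata file (TSV with columns
#'   sample_id, group, timepoint, batch_id).
#' @param output_dir Directory for result files, or `NULL` to only
#'   return the bundle.
#' @param timepoint Time point to analyse (default `"T18"`).
#' @param n_folds,n_orthogonal,alpha,vip_threshold Modelling parameters.
#' @param normalize Run internal-standard normalisation (default `TRUE`
#'   when `standards` is given).
#' @param exclude_samples Character vector of sample ids removed before
#'   modelling (e.g. a known non-compliant control).
#' @param seed Integer recorded in the run manifest; the pipeline itself
#'   is deterministic.
#' @param ... Rejected: any other key is an error.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(peak_table, metadata, standards = NULL,
                            output_dir = NULL, timepoint = "T18",
                            n_folds = 7, n_orthogonal = 1, alpha = 0.05,
                            vip_threshold = 0.8,
                            normalize = !is.null(standards),
                            exclude_samples = character(0), seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0)
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  cfg <- list(peak_table = peak_table, metadata = metadata,
              standards = standards, output_dir = output_dir,
              timepoint = timepoint, n_folds = as.integer(n_folds),
              n_orthogonal = as.integer(n_orthogonal), alpha = alpha,
              vip_threshold = vip_threshold, normalize = isTRUE(normalize),
              exclude_samples = as.character(exclude_samples),
              seed = as.integer(seed))
  if (!timepoint %in% c("T0", "T18", "T48")) stop("invalid timepoint")
  if (cfg$n_folds < 2) stop("n_folds must be at least 2")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$normalize && is.null(cfg$standards))
    stop("normalize = TRUE requires a standards path")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(...)))
}

#' Run the full discriminant-analysis pipeline
#'
#' Stages run in order: read inputs, exclude listed samples,
#' internal-standard normalisation, subset to the analysis time point,
#' OPLS-DA fit, seven-fold cross-validation, jack-knife confidence
#' intervals, VIP, per-metabolite Welch t-tests, and effect-direction
#' calls. Every stage logs its parameters and the row/column counts it
#' worked on. The pipeline is a pure function of its inputs and
#' configuration: identical inputs give identical outputs.
#'
#' @param config A [pipeline_config()], or the path of a YAML file
#'   defining one.
#' @return List of class `pipeline_result` with elements `model`
#'   (summary list with R2X, R2Y(cum), Q2(cum) and the separation
#'   p-value), `per_metabolite` (data.frame with p(corr), VIP,
#'   jack-knife CI, significance flag, t-test p and direction call),
#'   `cv` (the `opls_cv`), `directions` (named call vector),
#'   `normalization` (or `NULL`), and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")

  peaks <- read_peak_table(config$peak_table)
  meta_df <- utils::read.table(config$metadata, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  meta <- sample_meta(meta_df$sample_id, meta_df$group, meta_df$timepoint,
                      meta_df$batch_id)
  pipeline_log("read", "%d samples x %d metabolites", nrow(peaks$areas),
               ncol(peaks$areas))

  if (length(config$exclude_samples) > 0) {
    unknown <- setdiff(config$exclude_samples, rownames(peaks$areas))
    if (length(unknown) > 0) stop("exclude_samples not found: ",
                                  paste(unknown, collapse = ", "))
    keep <- !rownames(peaks$areas) %in% config$exclude_samples
    peaks <- peak_table(peaks$areas[keep, , drop = FALSE],
                        missing = peaks$missing[keep, , drop = FALSE])
    meta <- meta[!meta$sample_id %in% config$exclude_samples, ]
    pipeline_log("exclude", "removed %d sample(s): %s; %d remain",
                 length(config$exclude_samples),
                 paste(config$exclude_samples, collapse = ", "),
                 nrow(peaks$areas))
  }

  norm <- NULL
  if (config$normalize) {
    std_df <- utils::read.table(config$standards, header = TRUE, sep = "\t",
                                row.names = 1, check.names = FALSE)
    std <- is_table(as.matrix(std_df))
    std <- is_table(std$areas[rownames(std$areas) %in% rownames(peaks$areas), ,
                              drop = FALSE])
    norm <- is_normalize(peaks, std)
    peaks <- norm$normalized
    pipeline_log("normalize", "%d internal standards, t1 range [%.3g, %.3g]",
                 length(norm$loadings), min(norm$t1_scores), max(norm$t1_scores))
  }

  m <- meta[match(rownames(peaks$areas), meta$sample_id), ]
  sel <- m$timepoint == config$timepoint
  if (sum(sel) < 4) stop("stage subset: fewer than 4 samples at ", config$timepoint)
  X <- peaks$areas[sel, , drop = FALSE]
  y <- m$group[sel]
  pipeline_log("subset", "timepoint %s: %d samples (%d active, %d placebo)",
               config$timepoint, sum(sel), sum(y == 1), sum(y == 0))

  model <- fit_opls(X, y, config$n_orthogonal)
  cv <- cross_validate(X, y, config$n_folds, config$n_orthogonal)
  model$q2_cum <- cv$q2
  pyt <- predicted_y_test(cv, y)
  pipeline_log("opls", "R2X = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f, p = %.4g",
               model$r2x, model$r2y_cum, cv$q2, pyt$p_value)

  jk <- jackknife_ci(X, y, config$n_folds, config$n_orthogonal, config$alpha)
  dirs <- call_directions(jk, model$vip, config$vip_threshold)
  tt <- metabolite_ttests(peak_table(peaks$areas[sel, , drop = FALSE],
                                     missing = peaks$missing[sel, , drop = FALSE]),
                          meta, timepoint = config$timepoint)
  pipeline_log("calls", "%d UP, %d DOWN, %d NONE; %d t-test p < 0.05",
               sum(dirs == "UP"), sum(dirs == "DOWN"), sum(dirs == "NONE"),
               sum(tt$p < 0.05, na.rm = TRUE))

  per_met <- data.frame(metabolite = jk$metabolite,
                        pcorr = unname(model$pcorr[jk$metabolite]),
                        vip = unname(model$vip[jk$metabolite]),
                        jk, dirs = unname(dirs[jk$metabolite]),
                        ttest_p = tt$p[match(jk$metabolite, tt$metabolite)],
                        stringsAsFactors = FALSE)
  per_met$metabolite.1 <- NULL
  names(per_met)[names(per_met) == "dirs"] <- "direction_call"

  result <- structure(list(
    model = list(r2x = model$r2x, r2y_cum = model$r2y_cum, q2_cum = cv$q2,
                 separation_p = pyt$p_value, n_samples = sum(sel)),
    per_metabolite = per_met, cv = cv, opls = model,
    directions = dirs, normalization = norm, config = config),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(config$output_dir,
                                      c("per_metabolite.tsv", "cv_predicted_y.tsv",
                                        "model_summary.json", "manifest.json"))),
            add = TRUE)
    utils::write.table(per_met, file.path(config$output_dir, "per_metabolite.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(cv$cv_predicted_y),
                 group = y, cv_predicted_y = unname(cv$cv_predicted_y)),
      file.path(config$output_dir, "cv_predicted_y.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(result$model,
                         file.path(config$output_dir, "model_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(package_version = as.character(utils::packageVersion("oplsmet")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    ok <- TRUE
    pipeline_log("write", "results written to %s", config$output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline result: n = %d, R2X = %.3f, R2Y(cum) = %.3f, Q2(cum) = %.3f, separation p = %.4g\n",
    x$model$n_samples, x$model$r2x, x$model$r2y_cum, x$model$q2_cum,
    x$model$separation_p))
  cat(sprintf("  direction calls: %d UP, %d DOWN, %d NONE\n",
              sum(x$directions == "UP"), sum(x$directions == "DOWN"),
              sum(x$directions == "NONE")))
  invisible(x)
}

#' Write the metadata and standards files a pipeline run expects
#'
#' Helper for turning a generated cohort into on-disk pipeline inputs.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @return Named list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(peak_table = file.path(dir, "peaks.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                standards = file.path(dir, "standards.tsv"))
  write_peak_table(cohort$peaks, paths$peak_table)
  utils::write.table(as.data.frame(cohort$meta), paths$metadata,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  std <- cbind(sample_id = rownames(cohort$standards$areas),
               as.data.frame(cohort$standards$areas))
  utils::write.table(std, paths$standards, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
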