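# File exchange formats. The canonical probability format is a long CSV
# (video_id, second_index, probability[, hidden_state]) with 0-based
# contiguous seconds per video, so any upstream tic detector can feed the
# pipeline.

#' Write a synthetic cohort to disk
#'
#' Writes `manifest.csv` (video_id, participant_id, group,
#' matched_partner_id, pair_id, manual_tic_count) and `probabilities.csv`
#' (long format) into `dir`.
#'
#' @param cohort A `"tic_cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- merge(cohort$videos,
                    cohort$participants[, c("participant_id", "matched_partner_id")],
                    by = "participant_id", sort = FALSE)
  manifest <- manifest[match(cohort$videos$video_id, manifest$video_id),
                       c("video_id", "participant_id", "group",
                         "matched_partner_id", "pair_id", "manual_tic_count")]
  paths <- c(manifest = file.path(dir, "manifest.csv"),
             probabilities = file.path(dir, "probabilities.csv"))
  utils::write.csv(manifest, paths[["manifest"]], row.names = FALSE)
  utils::write.csv(cohort$probabilities[, c("video_id", "second_index",
                                            "probability", "hidden_state")],
                   paths[["probabilities"]], row.names = FALSE)
  invisible(paths)
}

#' Read a long-format per-second tic-probability table
#'
#' Validates the schema on the way in: required columns, probabilities in
#' \[0, 1\], and per-video `second_index` contiguous from 0. Violations are
#' reported with the offending video and file row.
#'
#' @param path CSV file with header `video_id, second_index, probability`
#'   and optionally `hidden_state`.
#' @return Long data.frame ordered by video and second.
#' @export
read_probability_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "second_index", "probability")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("probability table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x$probability) | x$probability < 0 | x$probability > 1)
  if (length(bad))
    stop("probability outside [0, 1] at row ", bad[1] + 1L, " (video ",
         x$video_id[bad[1]], ")", call. = FALSE)
  x <- x[order(factor(x$video_id, levels = unique(x$video_id)), x$second_index), ,
         drop = FALSE]
  rownames(x) <- NULL
  for (v in unique(x$video_id)) {
    s <- x$second_index[x$video_id == v]
    expect <- seq(0L, length(s) - 1L)
    if (!identical(as.integer(s), expect)) {
      at <- which(as.integer(s) != expect)[1]
      stop("non-contiguous second_index for video ", v, " near row ",
           which(x$video_id == v)[at] + 1L,
           " (expected ", expect[at], ", found ", s[at], ")", call. = FALSE)
    }
  }
  x
}

#' Read a cohort manifest table
#'
#' @param path CSV with at least `video_id`, `participant_id`, `group`,
#'   `pair_id`.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "participant_id", "group", "pair_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("manifest ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$video_id))
    stop("manifest contains duplicated video_id", call. = FALSE)
  x
}

#' Pipeline configuration
#'
#' Collects all knobs of the end-to-end run: simulation settings (optional),
#' score thresholds, predictors, regression and decision settings, and the
#' hybrid-review settings. All randomness flows from the single `seed`.
#'
#' @param out_dir Output directory for all artifacts.
#' @param simulate Logical; generate a synthetic cohort first (otherwise
#'   `manifest` and `probabilities` paths must point to existing files).
#' @param manifest,probabilities Input paths when `simulate = FALSE`.
#' @param n_pairs,videos_per_participant,video_duration_s Cohort layout when
#'   simulating; see [sim_config()].
#' @param tic_threshold Tic-detection threshold on the per-second
#'   probabilities.
#' @param cluster_min_s Minimum tic-run length for a cluster, seconds.
#' @param predictors Character vector of score columns used in the model.
#' @param ridge Ridge stabilizer for the logistic fits.
#' @param decision_threshold GTS classification threshold.
#' @param confidence_threshold Hybrid confidence threshold in \[0.5, 1).
#' @param expert_accuracy Expert accuracy as a probability.
#' @param seed Master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "ticscreen_run",
                            simulate = TRUE,
                            manifest = NULL, probabilities = NULL,
                            n_pairs = 42, videos_per_participant = c(1, 4),
                            video_duration_s = 150,
                            tic_threshold = 0.5, cluster_min_s = 3,
                            predictors = c("proportion_tic_intervals",
                                           "clusters_per_minute"),
                            ridge = 1e-6, decision_threshold = 0.5,
                            confidence_threshold = 0.9, expert_accuracy = 0.95,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, simulate = isTRUE(simulate),
              manifest = manifest, probabilities = probabilities,
              n_pairs = n_pairs, videos_per_participant = videos_per_participant,
              video_duration_s = video_duration_s,
              tic_threshold = tic_threshold, cluster_min_s = cluster_min_s,
              predictors = predictors, ridge = ridge,
              decision_threshold = decision_threshold,
              confidence_threshold = confidence_threshold,
              expert_accuracy = expert_accuracy, seed = as.integer(seed))
  if (cfg$tic_threshold <= 0 || cfg$tic_threshold >= 1)
    stop("invalid pipeline_config field 'tic_threshold'", call. = FALSE)
  if (cfg$confidence_threshold < 0.5 || cfg$confidence_threshold >= 1)
    stop("invalid pipeline_config field 'confidence_threshold'", call. = FALSE)
  if (cfg$expert_accuracy < 0 || cfg$expert_accuracy > 1)
    stop("invalid pipeline_config field 'expert_accuracy'", call. = FALSE)
  if (!cfg$simulate) {
    if (is.null(cfg$manifest) || is.null(cfg$probabilities))
      stop("when simulate = FALSE, 'manifest' and 'probabilities' paths are required",
           call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"` object.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown pipeline config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full video-classification pipeline
#'
#' Executes simulate (optional) -> score -> classify -> hybrid, writing all
#' intermediate artifacts into `config$out_dir`:
#' `manifest.csv`, `probabilities.csv`, `scores.csv`, `predictions_<score>.csv`,
#' `metrics.csv`, `hybrid_<score>.json`, and `run_log.txt`. Deterministic and
#' idempotent given the same configuration and seed. One univariate model is
#' fitted per configured predictor.
#'
#' @param config A [pipeline_config()] object.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted models, hybrid reports, metrics
#'   table and artifact paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  say("ticscreen pipeline run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  say("ticscreen version: %s; R version: %s",
      as.character(utils::packageVersion("ticscreen")), R.version.string)
  say("seed: %d", config$seed)

  stage <- "simulate"
  result <- tryCatch({
    if (config$simulate) {
      say("[simulate] generating %d-pair cohort (%d-s videos)",
          config$n_pairs, config$video_duration_s)
      cohort <- generate_cohort(sim_config(
        n_pairs = config$n_pairs,
        videos_per_participant = config$videos_per_participant,
        video_duration_s = config$video_duration_s,
        expert_accuracy = config$expert_accuracy,
        seed = config$seed))
      paths <- write_cohort(cohort, config$out_dir)
      manifest <- read_manifest(paths[["manifest"]])
      prob <- read_probability_table(paths[["probabilities"]])
    } else {
      say("[simulate] skipped; reading %s", config$probabilities)
      manifest <- read_manifest(config$manifest)
      prob <- read_probability_table(config$probabilities)
    }

    stage <- "score"
    say("[score] threshold %.2f, cluster_min %d s",
        config$tic_threshold, as.integer(config$cluster_min_s))
    sc <- tic_scores(prob, threshold = config$tic_threshold,
                     cluster_min_s = config$cluster_min_s)
    sc <- merge(manifest, sc, by = "video_id", sort = FALSE)
    scores_path <- file.path(config$out_dir, "scores.csv")
    utils::write.csv(sc, scores_path, row.names = FALSE)

    stage <- "classify"
    fits <- list(); metrics <- list(); pred_paths <- character(0)
    for (pred in config$predictors) {
      if (!pred %in% names(sc))
        stop("predictor '", pred, "' not found among computed scores")
      say("[classify] leave-pair-out CV, predictor: %s", pred)
      fml <- stats::as.formula(paste("group ~", pred))
      fit <- suppressWarnings(
        ticreg(fml, sc, pair = "pair_id", ridge = config$ridge,
               decision_threshold = config$decision_threshold))
      fits[[pred]] <- fit
      pp <- file.path(config$out_dir, paste0("predictions_", pred, ".csv"))
      utils::write.csv(fit$cv, pp, row.names = FALSE)
      pred_paths <- c(pred_paths, pp)
      metrics[[pred]] <- data.frame(predictor = pred,
                                    balanced_accuracy = fit$balanced_accuracy,
                                    auroc = fit$roc$auroc)
      say("[classify] %s: balanced accuracy %.1f%%, AUROC %.3f",
          pred, fit$balanced_accuracy, fit$roc$auroc)
    }
    metrics <- do.call(rbind, metrics)
    metrics_path <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(metrics, metrics_path, row.names = FALSE)

    stage <- "hybrid"
    reports <- list(); hybrid_paths <- character(0)
    for (pred in config$predictors) {
      say("[hybrid] predictor %s, confidence threshold %.2f, expert accuracy %.0f%%",
          pred, config$confidence_threshold, 100 * config$expert_accuracy)
      rep <- run_hybrid(fits[[pred]], config$confidence_threshold,
                        config$expert_accuracy, seed = config$seed)
      reports[[pred]] <- rep
      hp <- file.path(config$out_dir, paste0("hybrid_", pred, ".json"))
      jsonlite::write_json(rep[setdiff(names(rep), "decisions")], hp,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      hybrid_paths <- c(hybrid_paths, hp)
    }
    say("run complete")
    list(fits = fits, hybrid = reports, metrics = metrics,
         paths = list(scores = scores_path, predictions = pred_paths,
                      metrics = metrics_path, hybrid = hybrid_paths,
                      log = log_path))
  }, error = function(e) {
    say("ERROR in stage [%s]: %s", stage, conditionMessage(e))
    stop("pipeline failed in stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
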