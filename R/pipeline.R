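#' Assemble and validate a run configuration
#'
#' One serializable object describing a full reproducible run: where the
#' cohort comes from (a synthetic [cohort_spec()] or a directory of NIfTI
#' volumes plus phenotype CSV), the model and training settings, the fold
#' count, the saliency parameters, and the master seed that every stage
#' derives its substreams from.
#'
#' @param cohort a [cohort_spec()] or a path to a cohort directory
#'   (see [read_cohort()]).
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param k number of cross-validation folds.
#' @param seed master run seed (fanned out to named substreams).
#' @param tasks tasks to evaluate and attribute.
#' @param n_rois synthetic atlas size (ignored for on-disk cohorts with
#'   their own atlas).
#' @param saliency list with `n_samples`, `noise_level`, `top_k`.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort, model = model_config(2, c(4, 8), dense_units = 32),
                       train = train_config(max_epochs = 40, patience = 10),
                       k = 3, seed = 1, tasks = c("age", "gender", "diagnosis"),
                       n_rois = 6,
                       saliency = list(n_samples = 5, noise_level = 0.20, top_k = 10)) {
  if (!inherits(cohort, "cohort_spec") && !is.character(cohort)) {
    stop_vbm("cohort must be a cohort_spec or a directory path", class = "vbmnet_validation_error")
  }
  stopifnot(inherits(model, "model_config"), inherits(train, "train_config"), k >= 3)
  bad <- setdiff(tasks, .TASKS)
  if (length(bad) > 0) stop_vbm("unknown task(s): %s", paste(bad, collapse = ", "),
                                class = "vbmnet_validation_error")
  structure(
    list(cohort = cohort, model = model, train = train, k = as.integer(k),
         seed = as.integer(seed), tasks = tasks, n_rois = as.integer(n_rois),
         saliency = saliency),
    class = "run_config"
  )
}

.log_line <- function(outdir, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(outdir)) cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
  invisible(NULL)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort described by `spec` (atlas, volumes,
#' phenotypes) and writes it under `outdir` with a manifest recording the
#' seed and checksums. Rerunning with the same spec reproduces identical
#' files.
#'
#' @param spec a [cohort_spec()].
#' @param outdir output directory (created if missing).
#' @param n_rois number of atlas ROIs to generate.
#' @return the manifest, invisibly.
#' @export
simulate_run <- function(spec, outdir, n_rois = 6) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    .log_line(NULL, "created output directory %s", outdir)
  }
  atlas <- generate_atlas(spec$shape, n_rois, seed = spec$seed)
  cohort <- generate_cohort(spec, atlas)
  manifest <- write_cohort(cohort, atlas, outdir)
  .log_line(outdir, "simulated %d subjects into %s", spec$n_subjects, outdir)
  invisible(manifest)
}

# evaluate one trained fold on its test set: per task, the task's own
# checkpoint; classification thresholds chosen on validation data only.
evaluate_fold <- function(fit, ss, split, tasks = .TASKS) {
  idx <- function(ids) match(ids, ss$phenotypes$subject_id)
  test_i <- idx(split$test_ids)
  val_i <- idx(split$val_ids)
  out <- list()
  for (task in tasks) {
    model <- checkpoint_model(fit, task)
    test_preds <- predict(model, subset_sample_set(ss, test_i))
    if (task == "age") {
      out[[task]] <- list(
        report = regression_metrics(ss$phenotypes$age[test_i], test_preds$age),
        predictions = test_preds$age)
    } else {
      val_preds <- predict(model, subset_sample_set(ss, val_i))
      labels_val <- ss$phenotypes[[task]][val_i]
      thr <- if (length(unique(labels_val)) < 2) 0.5 else
        select_operating_point(labels_val, val_preds[[task]])
      out[[task]] <- list(
        report = classification_metrics(ss$phenotypes[[task]][test_i],
                                        test_preds[[task]], thr),
        predictions = test_preds[[task]], threshold = thr)
    }
  }
  out
}

#' Extract a subject subset of a sample set
#'
#' @param ss a `sample_set`.
#' @param idx integer column indices.
#' @return a `sample_set` restricted to those subjects.
#' @export
subset_sample_set <- function(ss, idx) {
  structure(list(values = ss$values[, idx, drop = FALSE], shape = ss$shape,
                 phenotypes = ss$phenotypes[idx, , drop = FALSE]),
            class = "sample_set")
}

#' Run the full cross-validated pipeline
#'
#' End-to-end orchestration of one run: obtain the cohort (simulate or
#' load), build the stratified folds, train every round with per-task
#' checkpointing, evaluate each round's checkpoints on its untouched test
#' set (classification operating points chosen on validation data), compute
#' SmoothGrad attention maps over the test examples of every fold, aggregate
#' them, rank atlas ROIs, and write all artifacts under `outdir`:
#' `config.json`, `folds.json`, `history_fold<r>.csv`, `metrics.csv`
#' (per-fold rows plus mean/sd summary rows), `roi_<task>.csv`,
#' `attention_<task>.nii.gz` and `run.log`.
#'
#' @param config a [run_config()].
#' @param outdir run directory (created if missing).
#' @param resume reuse per-fold checkpoint files (`fold<r>_fit.rds`) found in
#'   `outdir`, skipping those folds' training.
#' @param verbose per-epoch logging.
#' @return object of class `vbmnet_run` with `fits`, `metrics`,
#'   `roi_tables`, `attention`, `folds`, `config`, invisibly.
#' @export
pipeline_run <- function(config, outdir, resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  .write_config_snapshot(config, file.path(outdir, "config.json"))

  stage <- "cohort"
  result <- tryCatch({
    if (inherits(config$cohort, "cohort_spec")) {
      atlas <- generate_atlas(config$cohort$shape, config$n_rois, seed = config$cohort$seed)
      cohort <- generate_cohort(config$cohort, atlas)
      .log_line(outdir, "generated synthetic cohort: %d subjects", config$cohort$n_subjects)
    } else {
      cohort <- read_cohort(config$cohort)
      atlas <- read_atlas(find_nifti(config$cohort, "atlas"),
                          file.path(config$cohort, "atlas_names.json"))
      .log_line(outdir, "loaded cohort from %s: %d subjects", config$cohort,
                nrow(cohort$phenotypes))
    }
    ss <- as_sample_set(cohort)

    stage <- "folds"
    strata <- setNames(ss$phenotypes$diagnosis, ss$phenotypes$subject_id)
    folds <- make_folds(strata, k = config$k, seed = derive_seed(config$seed, "folds"))
    write_folds_json(folds, file.path(outdir, "folds.json"))

    fits <- vector("list", config$k)
    fold_reports <- vector("list", config$k)
    fold_maps <- lapply(config$tasks, function(t) vector("list", config$k))
    names(fold_maps) <- config$tasks

    for (r in seq_len(config$k)) {
      stage <- sprintf("train (fold %d)", r)
      fit_path <- file.path(outdir, sprintf("fold%d_fit.rds", r))
      if (resume && file.exists(fit_path)) {
        fits[[r]] <- readRDS(fit_path)
        .log_line(outdir, "fold %d: training skipped, checkpoints loaded from %s",
                  r, basename(fit_path))
      } else {
        tc <- config$train
        tc$seed <- derive_seed(config$seed, "train", r)
        fits[[r]] <- train_fold(ss, folds[[r]], config$model, tc, verbose = verbose)
        saveRDS(fits[[r]], fit_path)
        for (task in .TASKS) {
          saveRDS(fits[[r]]$checkpoints[[task]],
                  file.path(outdir, sprintf("%d_%s_best.rds", r - 1, task)))
        }
        utils::write.csv(fits[[r]]$history,
                         file.path(outdir, sprintf("history_fold%d.csv", r)),
                         row.names = FALSE)
        .log_line(outdir, "fold %d: stopped at epoch %d (%s)", r,
                  fits[[r]]$stop_epoch, fits[[r]]$stop_reason)
      }

      stage <- sprintf("evaluate (fold %d)", r)
      fold_reports[[r]] <- evaluate_fold(fits[[r]], ss, folds[[r]], config$tasks)

      stage <- sprintf("saliency (fold %d)", r)
      test_i <- match(folds[[r]]$test_ids, ss$phenotypes$subject_id)
      for (task in config$tasks) {
        model <- checkpoint_model(fits[[r]], task)
        fold_maps[[task]][[r]] <- fold_attention_map(
          model, ss, test_i, task,
          n_samples = config$saliency$n_samples,
          noise_level = config$saliency$noise_level,
          seed = derive_seed(config$seed, "saliency", r))
      }
    }

    stage <- "report"
    metrics <- .metrics_table(fold_reports, config$tasks)
    utils::write.csv(metrics, file.path(outdir, "metrics.csv"), row.names = FALSE)

    stage <- "saliency aggregation"
    mask <- atlas$labels > 0
    attention <- list()
    roi_tables <- list()
    for (task in config$tasks) {
      agg <- aggregate_maps(fold_maps[[task]], mask = mask)
      attention[[task]] <- agg
      roi_tables[[task]] <- rank_rois(agg, atlas, top_k = config$saliency$top_k)
      roi_tables[[task]]$task <- task
      utils::write.csv(roi_tables[[task]],
                       file.path(outdir, sprintf("roi_%s.csv", task)), row.names = FALSE)
      ref_path <- file.path(outdir, sprintf("attention_%s.nii.gz", task))
      write_nifti_volume(agg$values, ref_path)
    }
    .log_line(outdir, "run complete: %d folds, %d tasks", config$k, length(config$tasks))
    structure(list(fits = fits, metrics = metrics, roi_tables = roi_tables,
                   attention = attention, folds = folds, reports = fold_reports,
                   atlas = atlas, config = config, outdir = outdir),
              class = "vbmnet_run")
  }, vbmnet_error = function(e) {
    stop_vbm("pipeline failed at stage '%s': %s", stage, conditionMessage(e),
             class = "vbmnet_pipeline_error")
  })
  invisible(result)
}

.metrics_table <- function(fold_reports, tasks) {
  rows <- list()
  for (r in seq_along(fold_reports)) {
    for (task in tasks) {
      rep <- fold_reports[[r]][[task]]$report
      if (task == "age") {
        rows[[length(rows) + 1]] <- data.frame(
          fold = r, task = task, n = rep$n, mae = rep$mae, r = rep$pearson_r,
          p_value = rep$p_value, r2 = rep$r2_score, precision = NA, recall = NA,
          f1 = NA, auc = NA, threshold = NA)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          fold = r, task = task, n = rep$n_positive + rep$n_negative, mae = NA,
          r = NA, p_value = NA, r2 = NA, precision = rep$precision,
          recall = rep$recall, f1 = rep$f1, auc = rep$auc_roc,
          threshold = rep$threshold)
      }
    }
  }
  tab <- do.call(rbind, rows)
  num_cols <- c("mae", "r", "r2", "precision", "recall", "f1", "auc")
  for (task in tasks) {
    sub <- tab[tab$task == task, ]
    for (stat in c("mean", "sd")) {
      row <- sub[1, ]
      row$fold <- NA
      row$task <- paste(task, stat)
      row$n <- sum(sub$n)
      for (cl in c(num_cols, "p_value", "threshold")) {
        row[[cl]] <- if (all(is.na(sub[[cl]]))) NA else
          if (stat == "mean") mean(sub[[cl]], na.rm = TRUE) else sd(sub[[cl]], na.rm = TRUE)
      }
      tab <- rbind(tab, row)
    }
  }
  rownames(tab) <- NULL
  tab
}

.write_config_snapshot <- function(config, path) {
  snap <- list(
    cohort = if (inherits(config$cohort, "cohort_spec")) {
      unclass(config$cohort[setdiff(names(config$cohort), "effects")])
    } else config$cohort,
    effects = if (inherits(config$cohort, "cohort_spec")) {
      lapply(config$cohort$effects, unclass)
    } else NULL,
    model = unclass(config$model),
    train = local({
      tr <- unclass(config$train)
      tr$weights <- as.numeric(tr$weights)
      tr
    }),
    k = config$k, seed = config$seed, tasks = config$tasks,
    n_rois = config$n_rois, saliency = config$saliency
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Consolidated report of a completed run
#'
#' Re-reads the artifacts of a [pipeline_run()] directory and produces one
#' summary object (and optionally JSON) with per-fold and aggregate metrics,
#' the thresholds used, and the top-ROI tables. Missing artifacts are
#' reported by name.
#'
#' @param run_dir the run directory.
#' @param json_out optional path for a consolidated JSON report.
#' @return list with `metrics`, `roi_tables`, `folds`, `config`.
#' @export
report_run <- function(run_dir, json_out = NULL) {
  required <- c("config.json", "folds.json", "metrics.csv")
  missing <- required[!file.exists(file.path(run_dir, required))]
  config <- tryCatch(jsonlite::read_json(file.path(run_dir, "config.json")),
                     error = function(e) NULL)
  tasks <- unlist(config$tasks %||% .TASKS)
  roi_files <- sprintf("roi_%s.csv", tasks)
  missing <- c(missing, roi_files[!file.exists(file.path(run_dir, roi_files))])
  if (length(missing) > 0) {
    stop_vbm("incomplete run in %s; missing: %s", run_dir,
             paste(missing, collapse = ", "), class = "vbmnet_io_error")
  }
  metrics <- read.csv(file.path(run_dir, "metrics.csv"), stringsAsFactors = FALSE)
  roi_tables <- lapply(setNames(roi_files, tasks), function(f) {
    read.csv(file.path(run_dir, f), stringsAsFactors = FALSE)
  })
  out <- list(metrics = metrics, roi_tables = roi_tables,
              folds = read_folds_json(file.path(run_dir, "folds.json")),
              config = config)
  if (!is.null(json_out)) {
    jsonlite::write_json(list(metrics = metrics, roi_tables = roi_tables,
                              config = config),
                         json_out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Read a run configuration from YAML
#'
#' Parses a YAML document into a [run_config()]. Unknown fields raise a
#' validation error listing them; absent sections fall back to the
#' constructor defaults. The `cohort` section is either
#' `{type: synthetic, n_subjects: ..., shape: ..., effects: [...]}` or
#' `{type: directory, path: ...}`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_vbm("the 'yaml' package is required to read YAML configs", class = "vbmnet_io_error")
  }
  doc <- yaml::read_yaml(path)
  known <- c("cohort", "model", "train", "k", "seed", "tasks", "n_rois", "saliency")
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0) {
    stop_vbm("unknown config field(s): %s", paste(bad, collapse = ", "),
             class = "vbmnet_validation_error")
  }
  ch <- doc$cohort %||% stop_vbm("config needs a 'cohort' section", class = "vbmnet_validation_error")
  cohort <- if (identical(ch$type, "directory")) {
    ch$path %||% stop_vbm("directory cohort needs 'path'", class = "vbmnet_validation_error")
  } else {
    effects <- lapply(ch$effects %||% list(), function(e) {
      effect_spec(e$target, unlist(e$roi_ids), e$magnitude, e$tissue %||% "GM")
    })
    args <- ch[setdiff(names(ch), c("type", "effects"))]
    args$effects <- effects
    if (!is.null(args$shape)) args$shape <- unlist(args$shape)
    if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
    do.call(cohort_spec, args)
  }
  args <- list(cohort = cohort)
  if (!is.null(doc$model)) {
    if (!is.null(doc$model$filters_per_block)) {
      doc$model$filters_per_block <- unlist(doc$model$filters_per_block)
      doc$model$conv_blocks <- doc$model$conv_blocks %||% length(doc$model$filters_per_block)
    }
    args$model <- do.call(model_config, doc$model)
  }
  if (!is.null(doc$train)) args$train <- do.call(train_config, doc$train)
  for (f in c("k", "seed", "tasks", "n_rois", "saliency")) {
    if (!is.null(doc[[f]])) args[[f]] <- if (f == "tasks") unlist(doc[[f]]) else doc[[f]]
  }
  do.call(run_config, args)
}

#' Evaluate a checkpointed model on another cohort
#'
#' Cross-cohort validation: apply a selected checkpoint (typically the best
#' fold model of one cohort, see [select_best_across_folds()]) to the full
#' sample of a different cohort.
#'
#' @param model an `mtcnn` (e.g. from [checkpoint_model()]).
#' @param samples target cohort (`sample_set`, `vbm_cohort` or list).
#' @param tasks which tasks to score.
#' @param thresholds named list of classification thresholds carried over
#'   from the source cohort's validation data (default 0.5).
#' @return named list of per-task reports.
#' @export
cross_evaluate <- function(model, samples, tasks = c("age", "gender"),
                           thresholds = list()) {
  ss <- as_sample_set(samples)
  preds <- predict(model, ss)
  out <- list()
  for (task in tasks) {
    if (task == "age") {
      out[[task]] <- regression_metrics(ss$phenotypes$age, preds$age)
    } else {
      thr <- thresholds[[task]] %||% 0.5
      out[[task]] <- classification_metrics(ss$phenotypes[[task]], preds[[task]], thr)
    }
  }
  out
}
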