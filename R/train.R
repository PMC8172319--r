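#' Training configuration
#'
#' Optimisation settings: adaptive-moment gradient descent (Adam) with
#' learning rate 1e-3 and moment decays 0.9 / 0.999, batch size 32, up to
#' 1000 epochs, and custom early stopping — training stops once `patience`
#' consecutive epochs pass in which none of the three per-task validation
#' losses improves on its running minimum (default 75 epochs).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 exponential decay rates of the first and second moment
#'   estimates.
#' @param adam_eps Adam denominator fuzz.
#' @param batch_size examples per gradient step.
#' @param max_epochs hard epoch cap.
#' @param patience epochs without any-task improvement before stopping; must
#'   be `< max_epochs`.
#' @param patience_mode `"global"` (default): one counter, reset whenever any
#'   task improves. `"per_task"`: each task keeps its own counter and
#'   training stops only when every counter has reached `patience`.
#' @param weights a [loss_weights()].
#' @param seed run seed; epoch shuffles and dropout draw from substreams
#'   derived from `(seed, epoch)`.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-7, batch_size = 32, max_epochs = 1000,
                         patience = 75, patience_mode = c("global", "per_task"),
                         weights = loss_weights(), seed = 1) {
  patience_mode <- match.arg(patience_mode)
  if (batch_size < 1) stop_vbm("batch_size must be >= 1", class = "vbmnet_config_error")
  if (patience >= max_epochs) {
    stop_vbm("patience (%d) must be smaller than max_epochs (%d)", patience,
             max_epochs, class = "vbmnet_config_error")
  }
  structure(
    list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         adam_eps = adam_eps, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         patience_mode = patience_mode, weights = weights, seed = as.integer(seed)),
    class = "train_config"
  )
}

.TASKS <- c("age", "gender", "diagnosis")

# Default engine: the C++ CNN. An engine is the triple of closures the
# training loop needs; tests substitute scripted mocks through the same
# surface.
cnn_engine <- function(ss, train_idx, val_idx, model_config, train_config,
                       input_shape) {
  model <- mtcnn(model_config, input_shape, seed = derive_seed(train_config$seed, "init"))
  # center the age output at the training-set mean age: the regression head
  # then only has to learn deviations, not the large constant offset
  model$params$head_age_b2 <- mean(ss$phenotypes$age[train_idx])
  ptr <- .model_engine(model)
  data <- cpp_data_create(ss$values, ss$phenotypes$age, ss$phenotypes$gender,
                          ss$phenotypes$diagnosis)
  tc <- train_config
  list(
    train_epoch = function(epoch) {
      set.seed(derive_seed(tc$seed, "epoch", epoch))
      order <- sample(train_idx) - 1L  # 0-based for the engine
      cpp_engine_train_epoch(ptr, data, order, tc$batch_size, tc$learning_rate,
                             tc$beta1, tc$beta2, tc$adam_eps,
                             as.numeric(tc$weights),
                             derive_seed(tc$seed, "dropout", epoch))
    },
    val_losses = function() {
      ev <- cpp_engine_eval(ptr, data, val_idx - 1L, 64L)
      setNames(as.numeric(ev$losses), .TASKS)
    },
    snapshot = function() cpp_engine_get_params(ptr),
    model = model
  )
}

#' Train one cross-validation round with per-task checkpointing
#'
#' Runs the training loop for one fold: every epoch the training set is
#' reshuffled (seed derived from `(seed, epoch)`, no class balancing) and
#' consumed in batches; at epoch end the three per-task validation losses
#' (MSE for age, BCE for gender and diagnosis) are computed in inference
#' mode. For each task, an epoch that strictly beats the task's running
#' minimum saves that task's checkpoint. Training stops when `patience`
#' consecutive epochs bring no improvement in any task, or at `max_epochs`.
#'
#' @param samples a `sample_set`, `vbm_cohort` or list of sample tensors
#'   covering all subjects in `split`.
#' @param split a `fold_split` from [make_folds()].
#' @param model_config a [model_config()].
#' @param train_config a [train_config()].
#' @param engine optional engine override (list with `train_epoch(epoch)`,
#'   `val_losses()`, `snapshot()`): used to script the loop in tests or to
#'   plug in an alternative model backend.
#' @param verbose print one line per epoch.
#' @return object of class `mtcnn_fit`: `checkpoints` (per task: `params`,
#'   `epoch`, `val_loss`), `history` (data.frame), `stop_epoch`,
#'   `stop_reason`, `model` (the architecture the parameters belong to),
#'   configs and the split.
#' @export
train_fold <- function(samples, split, model_config, train_config,
                       engine = NULL, verbose = FALSE) {
  if (length(split$train_ids) == 0 || length(split$val_ids) == 0) {
    stop_vbm("empty train or validation set in round %d", split$round_index,
             class = "vbmnet_input_error")
  }
  if (is.null(engine)) {
    ss <- as_sample_set(samples)
    idx_of <- function(ids) {
      i <- match(ids, ss$phenotypes$subject_id)
      if (anyNA(i)) {
        stop_vbm("split ids missing from samples: %s",
                 paste(head(ids[is.na(i)], 3), collapse = ", "),
                 class = "vbmnet_input_error")
      }
      i
    }
    engine <- cnn_engine(ss, idx_of(split$train_ids), idx_of(split$val_ids),
                         model_config, train_config, ss$shape)
  }

  best <- setNames(rep(Inf, 3), .TASKS)
  best_epoch <- setNames(rep(NA_integer_, 3), .TASKS)
  checkpoints <- setNames(vector("list", 3), .TASKS)
  counters <- setNames(rep(0L, 3), .TASKS)
  global_counter <- 0L
  history <- vector("list", train_config$max_epochs)
  stop_reason <- "max_epochs"
  stop_epoch <- train_config$max_epochs

  for (epoch in seq_len(train_config$max_epochs)) {
    train_loss <- engine$train_epoch(epoch)
    vl <- engine$val_losses()
    if (any(!is.finite(vl)) || !is.finite(train_loss)) {
      stop_vbm("non-finite loss at epoch %d", epoch, class = "vbmnet_numeric_error")
    }
    improved <- vl < best # strict decrease, min-delta 0
    snap <- NULL
    for (task in .TASKS[improved]) {
      if (is.null(snap)) snap <- engine$snapshot()
      best[task] <- vl[task]
      best_epoch[task] <- epoch
      checkpoints[[task]] <- list(params = snap, epoch = epoch, val_loss = unname(vl[task]))
    }
    counters <- ifelse(improved, 0L, counters + 1L)
    global_counter <- if (any(improved)) 0L else global_counter + 1L
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, val_age = unname(vl["age"]),
      val_gender = unname(vl["gender"]), val_diagnosis = unname(vl["diagnosis"]),
      patience_counter = if (train_config$patience_mode == "global") global_counter else min(counters)
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val age %.4f gender %.4f diagnosis %.4f  patience %d",
                      epoch, train_loss, vl["age"], vl["gender"], vl["diagnosis"],
                      history[[epoch]]$patience_counter))
    }
    stale <- if (train_config$patience_mode == "global") {
      global_counter >= train_config$patience
    } else {
      all(counters >= train_config$patience)
    }
    if (stale) {
      stop_reason <- "early_stopping"
      stop_epoch <- epoch
      break
    }
  }
  structure(
    list(checkpoints = checkpoints,
         best_epochs = best_epoch, best_val_losses = best,
         history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
         stop_epoch = stop_epoch, stop_reason = stop_reason,
         model = engine$model %||% NULL, model_config = model_config,
         train_config = train_config, split = split),
    class = "mtcnn_fit"
  )
}

#' @export
print.mtcnn_fit <- function(x, ...) {
  cat(sprintf("Multitask CNN fold fit (round %s): stopped at epoch %d (%s)\n",
              x$split$round_index %||% "?", x$stop_epoch, x$stop_reason))
  for (task in .TASKS) {
    cat(sprintf("  best %-9s: epoch %s, validation loss %.5f\n", task,
                x$best_epochs[task], x$best_val_losses[task]))
  }
  invisible(x)
}

#' @export
summary.mtcnn_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d epochs recorded; final train loss %.5f\n",
              nrow(object$history), tail(object$history$train_loss, 1)))
  invisible(object)
}

#' @export
plot.mtcnn_fit <- function(x, ...) {
  h <- x$history
  matplot(h$epoch, cbind(h$val_age, h$val_gender, h$val_diagnosis),
          type = "l", lty = 1, xlab = "epoch", ylab = "validation loss", ...)
  graphics::legend("topright", legend = .TASKS, col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Restore a task checkpoint as a predictable model
#'
#' @param fit an `mtcnn_fit`.
#' @param task `"age"`, `"gender"` or `"diagnosis"`.
#' @return an `mtcnn` with the checkpointed parameters.
#' @export
checkpoint_model <- function(fit, task = .TASKS) {
  task <- match.arg(task)
  if (is.null(fit$model)) stop_vbm("fit has no model (mock engine?)", class = "vbmnet_input_error")
  if (is.null(fit$checkpoints[[task]])) stop_vbm("no checkpoint for task '%s'", task, class = "vbmnet_input_error")
  .model_with_params(fit$model, fit$checkpoints[[task]]$params)
}

#' Select the best checkpoint of one task across folds
#'
#' Returns the fold checkpoint with the lowest task-specific validation loss
#' (validation data only; test data never influences selection). Ties go to
#' the lowest fold index.
#'
#' @param fits list of `mtcnn_fit` objects (one per fold).
#' @param task task name.
#' @return list with `fold` (1-based index into `fits`), `checkpoint`,
#'   `val_loss`.
#' @export
select_best_across_folds <- function(fits, task) {
  if (!task %in% .TASKS) stop_vbm("unknown task '%s'", task, class = "vbmnet_input_error")
  stopifnot(length(fits) >= 1)
  losses <- vapply(fits, function(f) f$best_val_losses[[task]], numeric(1))
  fold <- which.min(losses) # which.min takes the first (lowest index) on ties
  list(fold = fold, checkpoint = fits[[fold]]$checkpoints[[task]],
       val_loss = losses[fold])
}
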