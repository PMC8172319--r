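#' Configure the multitask 3D CNN
#'
#' Architecture knobs for the shared-body/three-head network. The topology is
#' fixed — per block batch-norm, then 3x3x3 convolution (ReLU, same padding),
#' then 3x3x3 max-pooling with stride 2; after the last block flatten,
#' dropout, a shared dense layer, and three task heads (each dense, then
#' batch-norm, then a 1-unit output: sigmoid for gender and diagnosis, linear
#' for age) — while widths and depth are configurable. An L2 penalty with
#' coefficient `l2_coefficient` applies to all convolutional and dense
#' kernels.
#'
#' Class encodings used throughout: gender positive class = female (1),
#' diagnosis positive class = disorder (1).
#'
#' @param conv_blocks number of conv blocks; must equal
#'   `length(filters_per_block)`.
#' @param filters_per_block integer vector of filters per block.
#' @param dense_units width of the shared dense layer.
#' @param head_units width of each head's dense layer.
#' @param dropout_rate dropout after flattening, in \[0, 1).
#' @param l2_coefficient weight-decay strength (>= 0).
#' @return object of class `model_config`.
#' @examples
#' model_config(conv_blocks = 2, filters_per_block = c(4, 8), dense_units = 32)
#' @export
model_config <- function(conv_blocks = 4, filters_per_block = c(8, 16, 32, 64),
                         dense_units = 256, head_units = 16,
                         dropout_rate = 0.5, l2_coefficient = 1e-3) {
  if (conv_blocks != length(filters_per_block) || conv_blocks < 1) {
    stop_vbm("conv_blocks (%d) must equal length(filters_per_block) (%d) and be >= 1",
             conv_blocks, length(filters_per_block), class = "vbmnet_config_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_vbm("dropout_rate must lie in [0, 1)", class = "vbmnet_config_error")
  }
  if (l2_coefficient < 0) stop_vbm("l2_coefficient must be >= 0", class = "vbmnet_config_error")
  structure(
    list(conv_blocks = as.integer(conv_blocks),
         filters_per_block = as.integer(filters_per_block),
         kernel = c(3L, 3L, 3L), pool_window = c(3L, 3L, 3L), pool_stride = c(2L, 2L, 2L),
         dense_units = as.integer(dense_units), head_units = as.integer(head_units),
         dropout_rate = dropout_rate, l2_coefficient = l2_coefficient),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Multitask 3D CNN config: %d block(s), filters (%s), dense %d, heads %d units\n",
              x$conv_blocks, paste(x$filters_per_block, collapse = ", "),
              x$dense_units, x$head_units))
  cat(sprintf("  dropout %.2f, L2 %.1e; encodings: gender 1 = female, diagnosis 1 = disorder\n",
              x$dropout_rate, x$l2_coefficient))
  invisible(x)
}

# spatial dims after each pooling (TF-style SAME: ceil(n/2))
.pool_trace <- function(shape, n_blocks) {
  out <- list(shape)
  d <- shape
  for (b in seq_len(n_blocks)) {
    d <- ceiling(d / 2)
    out[[b + 1]] <- d
  }
  out
}

#' Build a multitask 3D CNN model
#'
#' Instantiates the network for a given input grid, with He-initialised
#' weights drawn deterministically from `seed`. The returned object carries
#' the full parameter set as plain R arrays — it can be saved, restored and
#' compared — and is the unit that checkpointing, evaluation and saliency
#' operate on.
#'
#' @param config a [model_config()].
#' @param input_shape spatial dims of the (cubic or non-cubic) input grid.
#' @param seed initialisation seed.
#' @return object of class `mtcnn`: list with `config`, `input_shape`,
#'   `channels`, `params` (named list of arrays), `spatial_trace`.
#' @examples
#' m <- mtcnn(model_config(2, c(4, 8), dense_units = 32), input_shape = c(32, 32, 32))
#' m
#' @export
mtcnn <- function(config, input_shape, seed = 1) {
  stopifnot(inherits(config, "model_config"), length(input_shape) == 3)
  trace <- .pool_trace(input_shape, config$conv_blocks)
  for (b in seq_len(config$conv_blocks)) {
    if (any(trace[[b]] < 4)) {
      stop_vbm("input %s is too small for %d blocks: block %d would receive a %s grid",
               paste(input_shape, collapse = "x"), config$conv_blocks, b,
               paste(trace[[b]], collapse = "x"), class = "vbmnet_config_error")
    }
  }
  ptr <- cpp_engine_create(.engine_config(config, input_shape), as.integer(seed))
  structure(
    list(config = config, input_shape = as.integer(input_shape), channels = 2L,
         params = cpp_engine_get_params(ptr), spatial_trace = trace,
         init_seed = as.integer(seed)),
    class = "mtcnn"
  )
}

#' @rdname mtcnn
#' @export
build_model <- mtcnn

.engine_config <- function(config, input_shape) {
  list(shape = as.integer(input_shape), channels = 2L,
       filters = config$filters_per_block, dense_units = config$dense_units,
       head_units = config$head_units, dropout_rate = config$dropout_rate,
       l2_coefficient = config$l2_coefficient)
}

# materialize a C++ engine holding this model's parameters
.model_engine <- function(model) {
  ptr <- cpp_engine_create(.engine_config(model$config, model$input_shape), model$init_seed)
  cpp_engine_set_params(ptr, model$params)
  ptr
}

#' Count trainable parameters
#'
#' Sums kernel, bias and batch-norm scale/shift parameters; batch-norm
#' running statistics are buffers, not parameters, and are excluded.
#'
#' @param model an `mtcnn`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mtcnn"))
  nm <- names(model$params)
  keep <- !grepl("_(rmean|rvar)$", nm)
  sum(vapply(model$params[keep], length, integer(1)))
}

#' @export
print.mtcnn <- function(x, ...) {
  dims <- vapply(x$spatial_trace, paste, character(1), collapse = "x")
  cat("Multitask 3D CNN\n")
  cat(sprintf("  input : %s x 2 channels (GM, WM)\n", dims[1]))
  cat(sprintf("  spatial trace: %s\n", paste(dims, collapse = " -> ")))
  cat(sprintf("  parameters: %d trainable\n", count_parameters(x)))
  cat("  heads : age (linear), gender (sigmoid; 1 = female), diagnosis (sigmoid; 1 = disorder)\n")
  invisible(x)
}

#' @export
summary.mtcnn <- function(object, ...) {
  print(object)
  cat("  parameter tensors:\n")
  for (nm in names(object$params)) {
    if (grepl("_(rmean|rvar)$", nm)) next
    d <- dim(object$params[[nm]]) %||% length(object$params[[nm]])
    cat(sprintf("    %-24s %s\n", nm, paste(d, collapse = " x ")))
  }
  invisible(object)
}

#' @export
coef.mtcnn <- function(object, ...) object$params

#' Predict from a multitask 3D CNN
#'
#' Deterministic forward pass in inference mode (dropout off, batch-norm
#' using running statistics).
#'
#' @param object an `mtcnn` (or a task checkpoint restored into one).
#' @param newdata a `sample_set`, `vbm_cohort`, or list of sample tensors.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return data.frame with columns `age` (years), `gender`, `diagnosis`
#'   (probabilities of female / disorder).
#' @export
predict.mtcnn <- function(object, newdata, batch_size = 32, ...) {
  ss <- as_sample_set(newdata)
  if (!all(ss$shape == object$input_shape)) {
    stop_vbm("newdata grid %s does not match model input %s",
             paste(ss$shape, collapse = "x"), paste(object$input_shape, collapse = "x"),
             class = "vbmnet_shape_error")
  }
  ptr <- .model_engine(object)
  out <- cpp_engine_predict(ptr, ss$values, as.integer(batch_size))
  data.frame(age = out$age, gender = out$gender, diagnosis = out$diagnosis,
             row.names = ss$phenotypes$subject_id)
}

#' Loss weights of the joint objective
#'
#' @param w1,w2,w3 nonnegative weights for the age (MSE), gender (BCE) and
#'   diagnosis (BCE) loss terms; at least one must be positive. Defaults 1.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(w1 = 1, w2 = 1, w3 = 1) {
  w <- c(w1, w2, w3)
  if (any(w < 0) || all(w == 0)) {
    stop_vbm("loss weights must be >= 0 with at least one > 0", class = "vbmnet_config_error")
  }
  structure(as.numeric(w), names = c("age", "gender", "diagnosis"), class = "loss_weights")
}

.clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

.bce <- function(y, p) {
  p <- .clamp_prob(p)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Joint multitask objective
#'
#' The weighted sum of per-task batch-mean losses:
#' `w1 * MSE(age) + w2 * BCE(gender) + w3 * BCE(diagnosis)`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` before the logarithm. L2
#' penalties are part of the training loop, not of this objective.
#'
#' @param targets list with numeric `age`, binary `gender`, binary
#'   `diagnosis` (equal lengths, the batch).
#' @param preds list with the same names: predicted age and predicted
#'   probabilities.
#' @param weights a [loss_weights()] (default all 1).
#' @return scalar loss.
#' @examples
#' objective_loss(list(age = 10, gender = 1, diagnosis = 0),
#'                list(age = 12, gender = 0.5, diagnosis = 0.5))  # 4 + 2 log 2
#' @export
objective_loss <- function(targets, preds, weights = loss_weights()) {
  n <- length(targets$age)
  stopifnot(n >= 1, length(preds$age) == n, length(preds$gender) == n,
            length(preds$diagnosis) == n)
  vals <- c(targets$age, targets$gender, targets$diagnosis,
            preds$age, preds$gender, preds$diagnosis)
  if (any(!is.finite(vals))) stop_vbm("NaN or Inf in loss inputs", class = "vbmnet_input_error")
  unname(weights[1] * mean((targets$age - preds$age)^2) +
         weights[2] * .bce(targets$gender, preds$gender) +
         weights[3] * .bce(targets$diagnosis, preds$diagnosis))
}

#' @rdname objective_loss
#' @details `objective_loss_grad` returns the analytic gradient of the
#'   objective with respect to each prediction vector (used for gradient
#'   checking): `2 w1 (yhat - y)/n` for age and `w (p - y) / (p (1 - p)) / n`
#'   for the clamped cross-entropy terms.
#' @export
objective_loss_grad <- function(targets, preds, weights = loss_weights()) {
  n <- length(targets$age)
  gp <- .clamp_prob(preds$gender)
  dp <- .clamp_prob(preds$diagnosis)
  list(
    age = weights[1] * 2 * (preds$age - targets$age) / n,
    gender = ifelse(preds$gender > 1e-7 & preds$gender < 1 - 1e-7,
                    weights[2] * (gp - targets$gender) / (gp * (1 - gp)) / n, 0),
    diagnosis = ifelse(preds$diagnosis > 1e-7 & preds$diagnosis < 1 - 1e-7,
                       weights[3] * (dp - targets$diagnosis) / (dp * (1 - dp)) / n, 0)
  )
}

#' Gradient of a model's task output with respect to its input
#'
#' Generic used by the saliency machinery: returns `d output(task) / d input`
#' for each sample in `X`, evaluated in inference mode with the other heads
#' excluded from the differentiated scalar. Methods exist for `mtcnn`; any
#' object implementing this generic (e.g. an analytic toy model) can be fed
#' to [smoothgrad()].
#'
#' @param model the model object.
#' @param X input matrix, one flattened sample (voxels x channels,
#'   column-major) per column.
#' @param task `"age"`, `"gender"` or `"diagnosis"`.
#' @return matrix of the same dimensions as `X`.
#' @export
input_gradient <- function(model, X, task) UseMethod("input_gradient")

#' @export
input_gradient.mtcnn <- function(model, X, task) {
  task_idx <- match(task, c("age", "gender", "diagnosis")) - 1L
  if (is.na(task_idx)) stop_vbm("unknown task '%s'", task, class = "vbmnet_input_error")
  ptr <- .model_engine(model)
  cpp_engine_input_grad(ptr, X, task_idx)
}

# restore a checkpointed parameter set into a predictable model object
.model_with_params <- function(model, params) {
  out <- model
  out$params <- params
  out
}
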