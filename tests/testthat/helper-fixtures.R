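# shared fixtures and independent oracles used across test files

# brute-force O(n^2) pairwise AUC: P(score+ > score-) + 1/2 P(tie)
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive scan over every threshold between/around observed scores,
# maximizing the harmonic mean of sensitivity and specificity
scan_operating_point <- function(labels, scores) {
  u <- sort(unique(scores))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  hmean <- vapply(cands, function(thr) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  }, numeric(1))
  cands[which.max(hmean)]
}

# tiny masked tissue pair on an ellipsoidal brain
tiny_pair <- function(shape = c(8, 8, 8), seed = 1, id = "sub-0001") {
  set.seed(seed)
  mask <- vbmnet:::brain_ellipsoid_mask(shape)
  gm <- array(runif(prod(shape)), dim = shape)
  wm <- array(runif(prod(shape)), dim = shape)
  gm[!mask] <- -1
  wm[!mask] <- -1
  tissue_pair(gm, wm, subject_id = id)
}

tiny_sample <- function(shape = c(8, 8, 8), seed = 1, id = "sub-0001",
                        age = 12, gender = 1, diagnosis = 0) {
  stack_channels(tiny_pair(shape, seed, id),
                 list(subject_id = id, age = age, gender = gender,
                      diagnosis = diagnosis))
}

# small synthetic cohort as a sample_set (cached per call signature)
tiny_cohort <- function(n = 40, shape = c(16, 16, 16), effects = list(), seed = 5,
                        n_rois = 3) {
  atlas <- generate_atlas(shape, n_rois, seed = seed)
  spec <- cohort_spec(n, shape = shape, effects = effects, seed = seed)
  list(atlas = atlas, cohort = generate_cohort(spec, atlas))
}

tiny_model_config <- function() {
  model_config(1, c(3), dense_units = 8, head_units = 4, dropout_rate = 0.5)
}

# scripted mock engine: validation losses follow a fixed epochs x 3 matrix
mock_engine <- function(loss_mat) {
  current <- 0L
  list(
    train_epoch = function(epoch) {
      current <<- epoch
      1.0
    },
    val_losses = function() {
      setNames(as.numeric(loss_mat[current, ]), c("age", "gender", "diagnosis"))
    },
    snapshot = function() list(epoch = current)
  )
}

mock_split <- function() {
  structure(list(round_index = 0L, train_ids = "a", val_ids = "b",
                 test_ids = character(0)),
            class = "fold_split")
}

# analytic toy model: output_task = sum(w_task * x); input gradient is w_task
toy_linear_model <- function(w_by_task) {
  structure(list(w = w_by_task), class = "toy_linear")
}

input_gradient.toy_linear <- function(model, X, task) {
  matrix(rep(model$w[[task]], ncol(X)), ncol = ncol(X))
}
registerS3method("input_gradient", "toy_linear", input_gradient.toy_linear,
                 envir = asNamespace("vbmnet"))
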