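test_that("scripted loss sequences place checkpoints at each argmin", {
  set.seed(4)
  n_ep <- 20
  # distinct random walks with unique minima per task
  losses <- cbind(age = runif(n_ep, 1, 2), gender = runif(n_ep, 0.3, 0.9),
                  diagnosis = runif(n_ep, 0.5, 0.8))
  tc <- train_config(max_epochs = n_ep, patience = n_ep - 1)
  fit <- train_fold(NULL, mock_split(), tiny_model_config(), tc,
                    engine = mock_engine(losses))
  for (i in 1:3) {
    task <- c("age", "gender", "diagnosis")[i]
    expect_equal(unname(fit$best_epochs[task]), which.min(losses[seq_len(fit$stop_epoch), i]))
    expect_equal(unname(fit$best_val_losses[task]),
                 min(losses[seq_len(fit$stop_epoch), i]))
    expect_equal(fit$checkpoints[[task]]$params$epoch, unname(fit$best_epochs[task]))
  }
  expect_equal(nrow(fit$history), fit$stop_epoch)
})

test_that("training stops exactly patience epochs after the last improvement", {
  # all three losses constant from epoch e0 = 3 onwards
  e0 <- 3
  losses <- cbind(c(3, 2, 1, rep(1, 30)), c(0.9, 0.8, 0.7, rep(0.7, 30)),
                  c(0.7, 0.65, 0.6, rep(0.6, 30)))
  tc <- train_config(max_epochs = 33, patience = 7)
  fit <- train_fold(NULL, mock_split(), tiny_model_config(), tc,
                    engine = mock_engine(losses))
  expect_equal(fit$stop_epoch, e0 + 7)
  expect_equal(fit$stop_reason, "early_stopping")
  expect_equal(nrow(fit$history), fit$stop_epoch)

  # a strictly decreasing task keeps training alive to max_epochs
  n_ep <- 15
  losses2 <- cbind(seq(2, 1, length.out = n_ep), rep(0.7, n_ep), rep(0.7, n_ep))
  tc2 <- train_config(max_epochs = n_ep, patience = 3)
  fit2 <- train_fold(NULL, mock_split(), tiny_model_config(), tc2,
                     engine = mock_engine(losses2))
  expect_equal(fit2$stop_epoch, n_ep)
  expect_equal(fit2$stop_reason, "max_epochs")
  expect_equal(unname(fit2$best_epochs["age"]), n_ep)
})

test_that("a single improving task resets the global patience counter", {
  # gender improves at epoch 10, everything else flat after epoch 1
  losses <- cbind(rep(1, 30), c(0.9, rep(0.8, 8), 0.5, rep(0.8, 20)), rep(0.7, 30))
  tc <- train_config(max_epochs = 30, patience = 12)
  fit <- train_fold(NULL, mock_split(), tiny_model_config(), tc,
                    engine = mock_engine(losses))
  expect_equal(fit$stop_epoch, 10 + 12)
  expect_equal(unname(fit$best_epochs["gender"]), 10)
})

test_that("per-task patience mode stops only when every task is stale", {
  losses <- cbind(c(seq(2, 1, length.out = 10), rep(1, 20)),
                  c(0.9, rep(0.9, 29)), c(0.8, rep(0.8, 29)))
  tc <- train_config(max_epochs = 30, patience = 5, patience_mode = "per_task")
  fit <- train_fold(NULL, mock_split(), tiny_model_config(), tc,
                    engine = mock_engine(losses))
  # age last improves at epoch 10; all counters reach 5 at epoch 15
  expect_equal(fit$stop_epoch, 15)
})

test_that("best-across-folds selection takes the argmin with low-index ties", {
  fake_fit <- function(age_loss) {
    structure(list(best_val_losses = c(age = age_loss, gender = 1, diagnosis = 1),
                   checkpoints = list(age = list(params = list(tag = age_loss)))),
              class = "mtcnn_fit")
  }
  fits <- lapply(c(0.5, 0.3, 0.9), fake_fit)
  sel <- select_best_across_folds(fits, "age")
  expect_equal(sel$fold, 2)
  expect_equal(sel$val_loss, 0.3)

  tied <- lapply(c(0.4, 0.4, 0.6), fake_fit)
  expect_equal(select_best_across_folds(tied, "age")$fold, 1)
  expect_equal(select_best_across_folds(fits[2], "age")$fold, 1)
  expect_error(select_best_across_folds(fits, "height"), class = "vbmnet_input_error")
})

test_that("real training is reproducible and checkpoints rescore their losses", {
  tc_data <- tiny_cohort(n = 36, shape = c(16, 16, 16),
                         effects = list(effect_spec("age", 1, -0.02)), seed = 3)
  ss <- as_sample_set(tc_data$cohort)
  folds <- make_folds(setNames(ss$phenotypes$diagnosis, ss$phenotypes$subject_id),
                      k = 3, seed = 4)
  mc <- tiny_model_config()
  tr <- train_config(max_epochs = 5, patience = 3, seed = 9)
  fit1 <- train_fold(ss, folds[[1]], mc, tr)
  fit2 <- train_fold(ss, folds[[1]], mc, tr)
  # determinism (documented tolerance for nondeterministic BLAS backends)
  expect_equal(fit1$history$val_age, fit2$history$val_age, tolerance = 1e-3)
  expect_equal(fit1$history$train_loss, fit2$history$train_loss, tolerance = 1e-3)

  # checkpoint fidelity: restoring the best-age state reproduces its loss
  val_i <- match(folds[[1]]$val_ids, ss$phenotypes$subject_id)
  m_age <- checkpoint_model(fit1, "age")
  preds <- predict(m_age, subset_sample_set(ss, val_i))
  mse <- mean((ss$phenotypes$age[val_i] - preds$age)^2)
  expect_equal(mse, unname(fit1$best_val_losses["age"]), tolerance = 1e-5)
})

test_that("degenerate splits are rejected", {
  split <- structure(list(round_index = 0L, train_ids = character(0),
                          val_ids = "b", test_ids = "c"), class = "fold_split")
  expect_error(train_fold(NULL, split, tiny_model_config(), train_config()),
               class = "vbmnet_input_error")
})
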