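test_that("pooling halves spatial dims and config errors name the failing block", {
  m <- mtcnn(model_config(2, c(4, 8), dense_units = 32), c(32, 32, 32))
  expect_equal(m$spatial_trace, list(c(32, 32, 32), c(16, 16, 16), c(8, 8, 8)))

  expect_error(mtcnn(model_config(4, c(2, 2, 2, 2), dense_units = 8), c(8, 8, 8)),
               "block 3", class = "vbmnet_config_error")
  expect_error(model_config(2, c(4), dense_units = 8), class = "vbmnet_config_error")
  expect_error(model_config(1, c(4), dropout_rate = 1), class = "vbmnet_config_error")
})

test_that("parameter count matches the hand-computed per-layer formula", {
  cfg <- model_config(2, c(4, 8), dense_units = 32, head_units = 16)
  m <- mtcnn(cfg, c(32, 32, 32))
  # per block: BN gamma+beta (2*Cin) + conv kernel (27*Cin*Cout) + bias (Cout)
  block1 <- 2 * 2 + 27 * 2 * 4 + 4
  block2 <- 2 * 4 + 27 * 4 * 8 + 8
  flat <- 8 * 8 * 8 * 8
  dense <- flat * 32 + 32
  head <- 32 * 16 + 16 + 2 * 16 + 16 * 1 + 1
  expect_equal(count_parameters(m), block1 + block2 + dense + 3 * head)
})

test_that("classification outputs are probabilities and forward is deterministic", {
  m <- mtcnn(tiny_model_config(), c(8, 8, 8), seed = 2)
  samples <- lapply(1:6, function(i) tiny_sample(seed = i, id = paste0("s", i),
                                                 age = 6 + i, gender = i %% 2,
                                                 diagnosis = i %% 2))
  p1 <- predict(m, samples)
  p2 <- predict(m, samples)
  expect_identical(p1, p2) # inference mode: dropout off, running BN stats
  expect_true(all(p1$gender > 0 & p1$gender < 1))
  expect_true(all(p1$diagnosis > 0 & p1$diagnosis < 1))
})

test_that("objective loss reproduces closed-form cases", {
  # single sample: MSE (10 vs 12) + BCE(1, 0.5) + BCE(0, 0.5) = 4 + 2 ln 2
  loss <- objective_loss(list(age = 10, gender = 1, diagnosis = 0),
                         list(age = 12, gender = 0.5, diagnosis = 0.5))
  expect_equal(loss, 4 + 2 * log(2), tolerance = 1e-10)

  # near-perfect predictions: age term exactly zero, BCE at the clamp scale
  perfect <- objective_loss(list(age = 10, gender = 1, diagnosis = 0),
                            list(age = 10, gender = 1 - 1e-7, diagnosis = 1e-7))
  expect_lt(perfect, 3e-7)

  # zeroed weights reduce to plain age MSE
  t <- list(age = c(8, 12), gender = c(1, 0), diagnosis = c(0, 1))
  p <- list(age = c(9, 10), gender = c(0.2, 0.9), diagnosis = c(0.6, 0.4))
  expect_equal(objective_loss(t, p, loss_weights(1, 0, 0)),
               mean((t$age - p$age)^2))
  expect_error(objective_loss(list(age = NaN, gender = 1, diagnosis = 0),
                              list(age = 1, gender = 0.5, diagnosis = 0.5)),
               class = "vbmnet_input_error")
})

test_that("objective loss is permutation invariant and additive in weights", {
  set.seed(6)
  n <- 12
  t <- list(age = runif(n, 6, 20), gender = rbinom(n, 1, 0.5),
            diagnosis = rbinom(n, 1, 0.5))
  p <- list(age = runif(n, 6, 20), gender = runif(n, 0.05, 0.95),
            diagnosis = runif(n, 0.05, 0.95))
  perm <- sample(n)
  tp <- lapply(t, `[`, perm)
  pp <- lapply(p, `[`, perm)
  expect_equal(objective_loss(t, p), objective_loss(tp, pp))

  w <- c(0.3, 1.7, 2.1)
  parts <- c(objective_loss(t, p, loss_weights(1, 0, 0)),
             objective_loss(t, p, loss_weights(0, 1, 0)),
             objective_loss(t, p, loss_weights(0, 0, 1)))
  expect_equal(objective_loss(t, p, loss_weights(w[1], w[2], w[3])),
               sum(w * parts))
})

test_that("analytic objective gradient matches finite differences", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 6
    t <- list(age = runif(n, 6, 20), gender = rbinom(n, 1, 0.5),
              diagnosis = rbinom(n, 1, 0.5))
    p <- list(age = runif(n, 6, 20), gender = runif(n, 0.1, 0.9),
              diagnosis = runif(n, 0.1, 0.9))
    g <- objective_loss_grad(t, p)
    h <- 1e-6
    for (comp in c("age", "gender", "diagnosis")) {
      for (i in sample(n, 3)) {
        pp <- p; pp[[comp]][i] <- p[[comp]][i] + h
        pm <- p; pm[[comp]][i] <- p[[comp]][i] - h
        fd <- (objective_loss(t, pp) - objective_loss(t, pm)) / (2 * h)
        expect_equal(g[[comp]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("engine backprop agrees with finite differences on smooth parameters", {
  cfg <- model_config(1, c(2), dense_units = 4, head_units = 3, dropout_rate = 0)
  m <- mtcnn(cfg, c(8, 8, 8), seed = 3)
  ptr <- vbmnet:::.model_engine(m)
  set.seed(42)
  B <- 4
  D <- prod(c(8, 8, 8)) * 2
  X <- matrix(runif(D * B), D, B)
  ya <- runif(B, -1, 1)
  yg <- rbinom(B, 1, 0.5)
  yd <- rbinom(B, 1, 0.5)
  res <- vbmnet:::cpp_engine_loss_grads(ptr, X, ya, yg, yd, c(1, 1, 1), TRUE)
  params <- vbmnet:::cpp_engine_get_params(ptr)
  h <- 2e-3
  # tensors whose loss surface is smooth at this point (no ReLU/pool kinks
  # within +-h): head weights and batch-norm scales
  for (nm in c("head_age_W2", "head_gender_W2", "head_age_bn_gamma",
               "head_gender_bn_gamma", "block1_bn_gamma")) {
    g <- as.vector(res$grads[[nm]])
    for (i in seq_len(min(3, length(g)))) {
      pp <- params; pp[[nm]][i] <- params[[nm]][i] + h
      vbmnet:::cpp_engine_set_params(ptr, pp)
      lp <- vbmnet:::cpp_engine_loss_grads(ptr, X, ya, yg, yd, c(1, 1, 1), TRUE)$loss
      pp[[nm]][i] <- params[[nm]][i] - h
      vbmnet:::cpp_engine_set_params(ptr, pp)
      lm <- vbmnet:::cpp_engine_loss_grads(ptr, X, ya, yg, yd, c(1, 1, 1), TRUE)$loss
      vbmnet:::cpp_engine_set_params(ptr, params)
      fd <- (lp - lm) / (2 * h)
      expect_equal(g[i], fd, tolerance = 2e-2)
    }
  }
})

test_that("engine loss on a batch matches the R-level objective", {
  cfg <- tiny_model_config()
  m <- mtcnn(cfg, c(8, 8, 8), seed = 5)
  ptr <- vbmnet:::.model_engine(m)
  set.seed(9)
  B <- 5
  X <- matrix(runif(prod(c(8, 8, 8)) * 2 * B), ncol = B)
  ya <- runif(B, 6, 20)
  yg <- rbinom(B, 1, 0.5)
  yd <- rbinom(B, 1, 0.5)
  res <- vbmnet:::cpp_engine_loss_grads(ptr, X, ya, yg, yd, c(1, 1, 1), FALSE)
  preds <- vbmnet:::cpp_engine_predict(ptr, X, 8L)
  rloss <- objective_loss(list(age = ya, gender = yg, diagnosis = yd),
                          list(age = preds$age, gender = preds$gender,
                               diagnosis = preds$diagnosis))
  expect_equal(res$loss, rloss, tolerance = 1e-5)
})

test_that("model parameters survive a checkpoint round trip exactly", {
  m <- mtcnn(tiny_model_config(), c(8, 8, 8), seed = 7)
  ptr <- vbmnet:::.model_engine(m)
  params <- vbmnet:::cpp_engine_get_params(ptr)
  vbmnet:::cpp_engine_set_params(ptr, params)
  expect_identical(vbmnet:::cpp_engine_get_params(ptr), params)
})
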