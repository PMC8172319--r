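test_that("regression metrics match hand arithmetic and flag degenerate input", {
  r <- regression_metrics(c(8, 10, 12, 14), c(9, 9, 13, 13))
  expect_equal(r$mae, 1.0)
  expect_equal(r$r2_score, 1 - 4 / 20)
  expect_equal(r$n, 4)

  ident <- regression_metrics(c(8, 10, 12, 14), c(8, 10, 12, 14))
  expect_equal(ident$mae, 0)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$r2_score, 1)

  # constant predictions: prediction R2 = 0, correlation undefined but flagged
  const <- regression_metrics(c(8, 10, 12, 14), rep(11, 4))
  expect_equal(const$r2_score, 0)
  expect_true(is.na(const$pearson_r))
  expect_true(const$degenerate)

  zerovar <- regression_metrics(rep(5, 4), c(4, 5, 6, 5))
  expect_true(is.na(zerovar$r2_score))
  expect_true(zerovar$degenerate)
})

test_that("pearson p-value comes from the t transform with n-2 df", {
  set.seed(1)
  y <- rnorm(20)
  x <- y + rnorm(20)
  r <- regression_metrics(y, x)
  tt <- r$pearson_r * sqrt(18 / (1 - r$pearson_r^2))
  expect_equal(r$p_value, 2 * pt(-abs(tt), df = 18))
})

test_that("auc_roc equals the pairwise rank oracle, including ties", {
  labels <- c(0, 0, 1, 1, 0, 1)
  scores <- c(0.1, 0.4, 0.4, 0.8, 0.3, 0.9) # one cross-class tie at 0.4
  expect_equal(auc_roc(labels, scores), pairwise_auc(labels, scores))

  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)

  set.seed(7)
  null_auc <- auc_roc(rbinom(4000, 1, 0.5), rnorm(4000))
  expect_lt(abs(null_auc - 0.5), 0.05)

  expect_error(auc_roc(c(1, 1), c(0.2, 0.3)), class = "vbmnet_input_error")
})

test_that("auc_roc agrees with an independent ROC implementation", {
  set.seed(11)
  labels <- rbinom(60, 1, 0.4)
  scores <- rnorm(60) + labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc_roc(labels, scores), ref)
})

test_that("auc_roc score-negation symmetry holds", {
  set.seed(3)
  for (i in 1:10) {
    labels <- c(0, 1, rbinom(28, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE) # ties likely
    a1 <- auc_roc(labels, scores)
    a2 <- auc_roc(labels, -scores)
    expect_equal(a1 + a2, 1)
  }
})

test_that("operating point maximizes harmonic mean of sens and spec", {
  labels <- c(0, 0, 1, 1)
  scores <- c(0.1, 0.2, 0.8, 0.9)
  thr <- select_operating_point(labels, scores)
  expect_gt(thr, 0.2)
  expect_lte(thr, 0.8)
  cm <- classification_metrics(labels, scores, thr)
  expect_equal(cm$recall, 1)
  expect_equal(cm$precision, 1)

  expect_warning(t0 <- select_operating_point(c(0, 1, 0), c(0.5, 0.5, 0.5)),
                 "degenerate")
  expect_equal(t0, 0.5)
})

test_that("operating point matches the exhaustive scan and beats Youden on harmonic mean", {
  hmean_at <- function(labels, scores, thr) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  }
  set.seed(21)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(18, 1, 0.5))
    scores <- round(runif(20), 2)
    thr <- select_operating_point(labels, scores)
    expect_equal(hmean_at(labels, scores, thr),
                 hmean_at(labels, scores, scan_operating_point(labels, scores)))
    # Youden-maximizing threshold cannot beat the harmonic-mean argmax
    u <- sort(unique(scores))
    cands <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
    youden <- cands[which.max(vapply(cands, function(th) {
      pred <- scores >= th
      sum(pred & labels == 1) / sum(labels == 1) +
        sum(!pred & labels == 0) / sum(labels == 0)
    }, numeric(1)))]
    expect_gte(hmean_at(labels, scores, thr) + 1e-12,
               hmean_at(labels, scores, youden))
  }
})

test_that("classification metrics recover a scripted confusion table", {
  # TP = 8, FP = 2, FN = 2, TN = 8 at threshold 0.5
  labels <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  scores <- c(rep(0.9, 8), rep(0.9, 2), rep(0.1, 2), rep(0.1, 8))
  cm <- classification_metrics(labels, scores, 0.5)
  expect_equal(cm$precision, 0.8)
  expect_equal(cm$recall, 0.8)
  expect_equal(cm$f1, 0.8)

  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), 0.5)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  none <- classification_metrics(c(0, 1, 1), c(0.1, 0.2, 0.3), 0.9)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
})

test_that("metrics are invariant under joint permutation", {
  set.seed(5)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(30)
  perm <- sample(30)
  expect_equal(auc_roc(labels, scores), auc_roc(labels[perm], scores[perm]))
  expect_equal(select_operating_point(labels, scores),
               select_operating_point(labels[perm], scores[perm]))
  y <- rnorm(30)
  p <- rnorm(30)
  a <- regression_metrics(y, p)
  b <- regression_metrics(y[perm], p[perm])
  expect_equal(a$mae, b$mae)
  expect_equal(a$r2_score, b$r2_score)
})

test_that("confound check reproduces hand-computed volume statistics", {
  # build a 10-subject toy set with controlled voxel counts
  shape <- c(4, 4, 4)
  nvox <- prod(shape)
  n <- 10
  counts <- c(10, 20, 30, 40, 50, 15, 25, 35, 45, 55)
  gender <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  age <- c(6, 8, 10, 12, 14, 7, 9, 11, 13, 15)
  samples <- lapply(seq_len(n), function(i) {
    gm <- array(0, dim = shape)
    gm[seq_len(counts[i])] <- 0.5
    wm <- array(0, dim = shape)
    stack_channels(tissue_pair(gm, wm, sprintf("s%02d", i)),
                   list(age = age[i], gender = gender[i], diagnosis = 0))
  })
  cc <- confound_check(samples)
  expect_equal(cc$volumes, counts)
  expect_equal(cc$auc_gender, pairwise_auc(gender, counts))
  expect_equal(cc$r_age, cor(age, counts))
})
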