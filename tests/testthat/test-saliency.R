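test_that("smoothgrad on a linear toy model recovers |w| exactly at zero noise", {
  shape <- c(6, 6, 6)
  nvox <- prod(shape)
  set.seed(12)
  w_gm <- rnorm(nvox)
  w_wm <- rnorm(nvox)
  toy <- toy_linear_model(list(age = c(w_gm, w_wm)))
  sample <- tiny_sample(shape, seed = 1)
  map <- smoothgrad(toy, sample, "age", n_samples = 1, noise_level = 0)
  background <- sample[, , , 1] == -1 & sample[, , , 2] == -1
  expected <- (abs(w_gm) + abs(w_wm)) / 2 # voxelwise channel mean
  expected[as.vector(background)] <- 0
  expect_equal(as.vector(map$values), expected, tolerance = 1e-5)

  # scale covariance: c * w scales the map by |c|
  toy3 <- toy_linear_model(list(age = -3 * c(w_gm, w_wm)))
  map3 <- smoothgrad(toy3, sample, "age", n_samples = 1, noise_level = 0)
  expect_equal(map3$values, 3 * map$values, tolerance = 1e-5)

  # max collapse behind the flag
  mapmax <- smoothgrad(toy, sample, "age", n_samples = 1, noise_level = 0,
                       channel_collapse = "max")
  exp_max <- pmax(abs(w_gm), abs(w_wm))
  exp_max[as.vector(background)] <- 0
  expect_equal(as.vector(mapmax$values), exp_max, tolerance = 1e-5)
})

test_that("zero-noise single-sample smoothgrad equals the plain absolute gradient", {
  m <- mtcnn(tiny_model_config(), c(8, 8, 8), seed = 4)
  s <- tiny_sample(seed = 3)
  map <- smoothgrad(m, s, "gender", n_samples = 1, noise_level = 0)
  G <- abs(input_gradient(m, matrix(as.vector(s), ncol = 1), "gender"))
  nvox <- prod(dim(s)[1:3])
  plain <- (G[seq_len(nvox)] + G[nvox + seq_len(nvox)]) / 2
  plain[as.vector(s[, , , 1] == -1 & s[, , , 2] == -1)] <- 0
  expect_equal(as.vector(map$values), plain)
  expect_true(all(map$values >= 0))
  expect_equal(dim(map$values), dim(s)[1:3])

  # defaults keep shape and nonnegativity with noise on
  noisy <- smoothgrad(m, s, "gender", n_samples = 5, noise_level = 0.20, seed = 2)
  expect_true(all(noisy$values >= 0))
  expect_identical(smoothgrad(m, s, "gender", n_samples = 5, noise_level = 0.2, seed = 2)$values,
                   noisy$values) # deterministic given seed
  expect_error(smoothgrad(m, s, "height"), class = "vbmnet_input_error")
})

test_that("averaging more noisy samples reduces across-seed map variance", {
  m <- mtcnn(tiny_model_config(), c(8, 8, 8), seed = 6)
  s <- tiny_sample(seed = 5)
  maps_for <- function(n) {
    vapply(1:8, function(seed) {
      as.vector(smoothgrad(m, s, "age", n_samples = n, noise_level = 0.2,
                           seed = seed)$values)
    }, numeric(prod(dim(s)[1:3])))
  }
  var1 <- sum(apply(maps_for(1), 1, var))
  var5 <- sum(apply(maps_for(5), 1, var))
  expect_lt(var5, var1)
})

test_that("fold aggregation normalizes then averages", {
  # single fold, single example: normalized copy of the map
  v <- array(0, dim = c(2, 2, 2))
  v[1:6] <- c(2, 4, 6, 8, 10, 4)
  mask <- array(FALSE, dim = c(2, 2, 2))
  mask[1:6] <- TRUE
  m1 <- attention_map(v, "age")
  agg1 <- aggregate_maps(list(m1), mask = mask)
  expect_equal(agg1$values[1:6], (c(2, 4, 6, 8, 10, 4) - 2) / 8)

  # two identical folds: idempotent
  agg2 <- aggregate_maps(list(m1, m1), mask = mask)
  expect_equal(agg2$values, agg1$values)

  # two hand-built folds: normalize each then average voxelwise
  v2 <- array(0, dim = c(2, 2, 2))
  v2[1:6] <- c(1, 3, 5, 7, 9, 9)
  agg3 <- aggregate_maps(list(m1, attention_map(v2, "age")), mask = mask)
  n1 <- (c(2, 4, 6, 8, 10, 4) - 2) / 8
  n2 <- (c(1, 3, 5, 7, 9, 9) - 1) / 8
  expect_equal(agg3$values[1:6], (n1 + n2) / 2)

  # per-example lists are averaged inside each fold first
  agg4 <- aggregate_maps(list(list(m1, m1), list(attention_map(v2, "age"))), mask = mask)
  expect_equal(agg4$values, agg3$values)

  expect_error(aggregate_maps(list(m1, attention_map(array(0, dim = c(3, 2, 2)), "age"))),
               class = "vbmnet_shape_error")
})

test_that("ROI ranking follows the per-ROI mean with id tie-breaks", {
  atlas <- generate_atlas(c(16, 16, 16), 3, seed = 2)
  conc <- array(0, dim = c(16, 16, 16))
  conc[atlas$labels == 2] <- 1
  tab <- rank_rois(attention_map(conc, "age"), atlas, top_k = 3)
  expect_equal(tab$roi_id[1], 2)
  expect_equal(tab$rank, 1:3)

  unif <- array(0, dim = c(16, 16, 16))
  unif[atlas$labels > 0] <- 0.5
  tab2 <- rank_rois(attention_map(unif, "age"), atlas, top_k = 3)
  expect_equal(tab2$roi_id, 1:3) # equal statistics: ordered by ROI id

  # hand-built 4x4x4 case
  labels <- array(0L, dim = c(4, 4, 4))
  labels[1:8] <- 1L
  labels[9:16] <- 2L
  hand_atlas <- structure(list(labels = labels,
                               names = setNames(c("A", "B"), 1:2),
                               shape = c(4L, 4L, 4L)), class = "atlas_volume")
  vals <- array(0, dim = c(4, 4, 4))
  vals[1:8] <- c(1, 1, 1, 1, 2, 2, 2, 2)   # ROI 1 mean 1.5
  vals[9:16] <- c(4, 4, 4, 4, 0, 0, 0, 0)  # ROI 2 mean 2.0
  tab3 <- rank_rois(attention_map(vals, "gender"), hand_atlas, top_k = 2)
  expect_equal(tab3$roi_id, c(2, 1))
  expect_equal(tab3$statistic, c(2.0, 1.5))
  tab3s <- rank_rois(attention_map(vals, "gender"), hand_atlas, top_k = 2,
                     statistic = "sum")
  expect_equal(tab3s$statistic, c(16, 12))

  # an ROI listed in the names but absent from the grid is skipped with warning
  hand_atlas$names <- setNames(c("A", "B", "ghost"), 1:3)
  expect_warning(tab4 <- rank_rois(attention_map(vals, "gender"), hand_atlas, top_k = 5),
                 "no voxels")
  expect_equal(nrow(tab4), 2)
})

test_that("overlay export writes into the reference space", {
  ref_arr <- array(rnorm(512), dim = c(8, 8, 8))
  ref_path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(ref_arr, ref_path, voxel_mm = 2)
  v <- array(runif(512), dim = c(8, 8, 8))
  map <- attention_map(v, "age")
  out_path <- tempfile(fileext = ".nii.gz")
  export_overlay(map, ref_path, out_path)
  back <- RNifti::readNifti(out_path)
  expect_equal(as.vector(back), as.vector(v), tolerance = 1e-7)
  expect_true(all(back >= 0 & back <= 1))
  # voxel->world mapping matches the reference affine
  expect_equal(RNifti::xform(back), RNifti::xform(RNifti::readNifti(ref_path)),
               ignore_attr = TRUE)

  bad <- attention_map(array(0, dim = c(4, 4, 4)), "age")
  expect_error(export_overlay(bad, ref_path, out_path), class = "vbmnet_shape_error")
})

test_that("nearest-neighbour atlas resampling preserves labels", {
  atlas <- generate_atlas(c(16, 16, 16), 3, seed = 8)
  up <- resample_atlas_nearest(atlas, c(32, 32, 32))
  expect_equal(dim(up$labels), c(32, 32, 32))
  expect_setequal(unique(as.vector(up$labels)), unique(as.vector(atlas$labels)))
  # voxel (i,j,k) of a 2x upsampled grid maps back to its source voxel
  expect_equal(up$labels[15, 15, 15], atlas$labels[8, 8, 8])
  down <- resample_atlas_nearest(up, c(16, 16, 16))
  expect_equal(down$labels, atlas$labels)
})
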