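test_that("background masking matches a voxelwise oracle and is idempotent", {
  set.seed(2)
  shape <- c(6, 6, 6)
  gm <- array(runif(216), dim = shape)
  wm <- array(runif(216), dim = shape)
  pair <- tissue_pair(gm, wm, "s1")

  all_true <- apply_background_mask(pair, array(TRUE, dim = shape))
  expect_identical(all_true$gm, gm)

  all_false <- apply_background_mask(pair, array(FALSE, dim = shape))
  expect_true(all(all_false$gm == -1) && all(all_false$wm == -1))

  mask <- array((seq_len(216) %% 2) == 0, dim = shape) # checkerboard-ish
  masked <- apply_background_mask(pair, mask)
  expect_identical(masked$gm[mask], gm[mask])     # in-brain bit-exact
  expect_true(all(masked$gm[!mask] == -1))
  expect_identical(apply_background_mask(masked, mask), masked) # idempotent

  expect_error(apply_background_mask(pair, array(TRUE, dim = c(5, 6, 6))),
               class = "vbmnet_shape_error")
})

test_that("default brain mask is the union of positive-density voxels", {
  shape <- c(4, 4, 4)
  gm1 <- array(0, dim = shape); gm1[1:5] <- 0.5
  wm2 <- array(0, dim = shape); wm2[4:8] <- 0.5
  pairs <- list(tissue_pair(gm1, array(0, dim = shape), "a"),
                tissue_pair(array(0, dim = shape), wm2, "b"))
  m <- default_brain_mask(pairs)
  expect_equal(which(m), 1:8)
})

test_that("pad_to_cube pads with -1, centers, and conserves in-brain values", {
  p <- tiny_pair(c(8, 10, 8), seed = 3)
  out <- pad_to_cube(p, 12)
  expect_equal(dim(out$gm), c(12, 12, 12))
  # conservation: multiset of in-brain values unchanged
  expect_equal(sort(out$gm[out$gm != -1]), sort(p$gm[p$gm != -1]))
  expect_equal(sort(out$wm[out$wm != -1]), sort(p$wm[p$wm != -1]))
  # centering with the extra voxel on the high side: 8 -> 12 pads 2+2,
  # 10 -> 12 pads 1+1; 8 -> 13 would pad 2 low, 3 high
  odd <- pad_to_cube(tiny_pair(c(8, 8, 8), seed = 3), 13)
  expect_true(all(odd$gm[1:2, , ] == -1))
  expect_true(all(odd$gm[11:13, , ] == -1))

  same <- pad_to_cube(p, 12)
  expect_identical(pad_to_cube(same, 12), same) # identity once cubic
})

test_that("trimming removes only all-background planes", {
  shape <- c(8, 12, 8)
  gm <- array(-1, dim = shape)
  wm <- array(-1, dim = shape)
  gm[3:6, 5:8, 3:6] <- 0.5 # brain confined to the centre
  wm[3:6, 5:8, 3:6] <- 0.4
  pair <- tissue_pair(gm, wm, "s")
  out <- pad_to_cube(pair, 8)
  expect_equal(dim(out$gm), c(8, 8, 8))
  expect_equal(sum(out$gm == 0.5), 64)

  # an in-brain voxel in a plane that must be trimmed raises a data-loss error
  gm2 <- gm
  gm2[1, 2, 1] <- 0.3
  expect_error(pad_to_cube(tissue_pair(gm2, wm, "s"), 8),
               class = "vbmnet_data_loss_error")
  expect_error(pad_to_cube(pair, 4), class = "vbmnet_input_error")
})

test_that("channel stacking is bit-exact and invertible", {
  gm <- array(0.5, dim = c(4, 4, 4))
  wm <- array(0.3, dim = c(4, 4, 4))
  s <- stack_channels(tissue_pair(gm, wm, "s1"), list(age = 9, gender = 0, diagnosis = 1))
  expect_true(all(s[, , , 1] == 0.5))
  expect_true(all(s[, , , 2] == 0.3))

  p <- tiny_pair(seed = 4)
  s2 <- stack_channels(p, list(age = 10, gender = 1, diagnosis = 0))
  expect_equal(mean(s2[, , , 1]), mean(p$gm))
  expect_equal(mean(s2[, , , 2]), mean(p$wm))
  back <- unstack_channels(s2)
  expect_identical(back$gm, p$gm)
  expect_identical(back$wm, p$wm)
  expect_equal(back$subject_id, p$subject_id)
})

test_that("record files round-trip values and phenotypes", {
  samples <- lapply(1:10, function(i) {
    tiny_sample(seed = i, id = sprintf("s%02d", i), age = 5 + i,
                gender = i %% 2, diagnosis = (i + 1) %% 2)
  })
  path <- tempfile(fileext = ".vbnrec")
  write_records(samples, path)
  back <- read_records(path)
  expect_length(back, 10)
  # float32 storage: a second round trip is bit-exact
  path2 <- tempfile(fileext = ".vbnrec")
  write_records(back, path2)
  back2 <- read_records(path2)
  for (i in 1:10) {
    expect_identical(as.vector(back2[[i]]), as.vector(back[[i]]))
    expect_equal(as.vector(back[[i]]), as.vector(samples[[i]]), tolerance = 1e-7)
    ph <- attr(back[[i]], "phenotype")
    expect_equal(ph$age, 5 + i)
    expect_equal(ph$subject_id, sprintf("s%02d", i))
  }
})

test_that("record streaming handles empty files and reports truncation", {
  path <- tempfile()
  write_records(list(), path)
  expect_length(read_records(path), 0)

  samples <- lapply(1:3, function(i) tiny_sample(seed = i, id = paste0("s", i)))
  path2 <- tempfile()
  write_records(samples, path2)
  full_size <- file.size(path2)
  raw <- readBin(path2, "raw", full_size)
  writeBin(raw[1:(full_size - 100)], path2) # cut into the third record
  rd <- record_reader(path2)
  expect_s3_class(rd$read_next(), "sample_tensor")
  expect_s3_class(rd$read_next(), "sample_tensor")
  expect_error(rd$read_next(), "record 3", class = "vbmnet_parse_error")
  rd$close()

  notrec <- tempfile()
  writeBin(charToRaw("NOTAREC1"), notrec)
  expect_error(record_reader(notrec), class = "vbmnet_parse_error")
})

test_that("NIfTI volumes round-trip with voxel dimensions", {
  arr <- array(rnorm(512), dim = c(8, 8, 8))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(arr, path, voxel_mm = 1.5)
  back <- read_nifti_volume(path)
  expect_equal(as.vector(back), as.vector(arr))
  expect_equal(attr(back, "pixdim"), c(1.5, 1.5, 1.5))
})
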