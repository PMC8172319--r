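#' SmoothGrad attention map for one sample
#'
#' Gradient-based voxel attribution: the input is perturbed `n_samples` times
#' with zero-mean Gaussian noise whose standard deviation is
#' `noise_level * (max - min)` of the in-brain input values, the gradient of
#' the selected task's output with respect to the input is computed with the
#' other two heads excluded from the differentiated scalar, absolute values
#' are taken, the two tissue channels are collapsed voxelwise (mean by
#' default), and the per-perturbation maps are averaged. Background voxels
#' (exactly -1 in both channels) are zeroed in the result. At
#' `noise_level = 0, n_samples = 1` this reduces to the plain absolute input
#' gradient.
#'
#' @param model an `mtcnn` (or any object with an [input_gradient()] method).
#' @param sample a `sample_tensor` (4D array, 2 channels).
#' @param task `"age"`, `"gender"` or `"diagnosis"`.
#' @param n_samples number of noisy perturbations (>= 1; 5 by default).
#' @param noise_level noise scale as a fraction of the in-brain value range
#'   (0.20 by default).
#' @param seed RNG seed for the perturbations.
#' @param channel_collapse `"mean"` (default) or `"max"` across GM/WM.
#' @return object of class `attention_map`: list with `values` (nonnegative
#'   3D array), `task`, `provenance`.
#' @export
smoothgrad <- function(model, sample, task, n_samples = 5, noise_level = 0.20,
                       seed = 1, channel_collapse = c("mean", "max")) {
  channel_collapse <- match.arg(channel_collapse)
  if (!task %in% .TASKS) stop_vbm("unknown task '%s'", task, class = "vbmnet_input_error")
  stopifnot(n_samples >= 1, noise_level >= 0, length(dim(sample)) == 4)
  shape <- dim(sample)[1:3]
  x <- as.vector(sample)
  X <- matrix(rep(x, n_samples), ncol = n_samples)
  if (noise_level > 0) {
    inbrain_vals <- x[x != -1]
    sdv <- noise_level * (max(inbrain_vals) - min(inbrain_vals))
    set.seed(derive_seed(seed, "smoothgrad"))
    X <- X + matrix(rnorm(length(X), 0, sdv), nrow = nrow(X))
  }
  G <- abs(input_gradient(model, X, task))
  if (!all(is.finite(G))) stop_vbm("non-finite gradients in SmoothGrad", class = "vbmnet_numeric_error")
  nvox <- prod(shape)
  gm_part <- G[seq_len(nvox), , drop = FALSE]
  wm_part <- G[nvox + seq_len(nvox), , drop = FALSE]
  per_vox <- if (channel_collapse == "mean") (gm_part + wm_part) / 2 else pmax(gm_part, wm_part)
  values <- array(rowMeans(per_vox), dim = shape)
  background <- array(sample[, , , 1] == -1 & sample[, , , 2] == -1, dim = shape)
  values[background] <- 0
  attention_map(values, task,
                provenance = list(n_examples = 1L, n_samples = n_samples,
                                  noise_level = noise_level, seed = seed,
                                  channel_collapse = channel_collapse))
}

#' @rdname smoothgrad
#' @param values nonnegative 3D array.
#' @param provenance free-form list recording how the map was produced.
#' @export
attention_map <- function(values, task, provenance = list()) {
  stopifnot(length(dim(values)) == 3, all(values >= 0))
  structure(list(values = values, task = task, provenance = provenance),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat(sprintf("Attention map (%s): %s grid, max %.4g, %d nonzero voxels\n",
              x$task, paste(dim(x$values), collapse = "x"), max(x$values),
              sum(x$values > 0)))
  invisible(x)
}

#' Fold-averaged attention map over a set of examples
#'
#' Convenience wrapper computing [smoothgrad()] for many examples in batched
#' gradient calls and returning their voxelwise mean — the per-fold map that
#' [aggregate_maps()] then normalizes and averages across folds.
#'
#' @param model an `mtcnn`.
#' @param samples a `sample_set` (or coercible).
#' @param indices which columns (subjects) to attribute; default all.
#' @inheritParams smoothgrad
#' @param examples_per_batch how many examples share one gradient call.
#' @return an `attention_map` (mean over examples, not yet normalized).
#' @export
fold_attention_map <- function(model, samples, indices = NULL, task,
                               n_samples = 5, noise_level = 0.20, seed = 1,
                               channel_collapse = c("mean", "max"),
                               examples_per_batch = 8) {
  channel_collapse <- match.arg(channel_collapse)
  ss <- as_sample_set(samples)
  if (is.null(indices)) indices <- seq_len(ncol(ss$values))
  shape <- ss$shape
  nvox <- prod(shape)
  acc <- numeric(nvox)
  bg_any <- rep(TRUE, nvox)
  set.seed(derive_seed(seed, "smoothgrad", task))
  for (chunk in split(indices, ceiling(seq_along(indices) / examples_per_batch))) {
    base <- ss$values[, rep(chunk, each = n_samples), drop = FALSE]
    if (noise_level > 0) {
      for (j in seq_along(chunk)) {
        xin <- ss$values[, chunk[j]]
        vals <- xin[xin != -1]
        sdv <- noise_level * (max(vals) - min(vals))
        cols <- (j - 1) * n_samples + seq_len(n_samples)
        base[, cols] <- base[, cols] + matrix(rnorm(nrow(base) * n_samples, 0, sdv),
                                              nrow = nrow(base))
      }
    }
    G <- abs(input_gradient(model, base, task))
    gm_part <- G[seq_len(nvox), , drop = FALSE]
    wm_part <- G[nvox + seq_len(nvox), , drop = FALSE]
    per_vox <- if (channel_collapse == "mean") (gm_part + wm_part) / 2 else pmax(gm_part, wm_part)
    for (j in seq_along(chunk)) {
      cols <- (j - 1) * n_samples + seq_len(n_samples)
      acc <- acc + rowMeans(per_vox[, cols, drop = FALSE])
      xin <- ss$values[, chunk[j]]
      bg_any <- bg_any & (xin[seq_len(nvox)] == -1 & xin[nvox + seq_len(nvox)] == -1)
    }
  }
  values <- array(acc / length(indices), dim = shape)
  values[array(bg_any, dim = shape)] <- 0
  attention_map(values, task,
                provenance = list(n_examples = length(indices), n_samples = n_samples,
                                  noise_level = noise_level, seed = seed,
                                  channel_collapse = channel_collapse))
}

#' Aggregate attention maps across folds
#'
#' Per fold the maps of that fold's test examples are averaged voxelwise;
#' each fold average is then min-max normalized to \[0, 1\] over in-brain
#' voxels, and the normalized fold maps are averaged into the final map.
#'
#' @param maps_by_fold list with one element per fold; each element is either
#'   a single (already example-averaged) `attention_map` or a list of
#'   per-example maps.
#' @param mask logical in-brain mask; defaults to voxels that are nonzero in
#'   any fold average.
#' @return an `attention_map` with values in \[0, 1\].
#' @export
aggregate_maps <- function(maps_by_fold, mask = NULL) {
  stopifnot(length(maps_by_fold) >= 1)
  fold_mean <- lapply(maps_by_fold, function(f) {
    if (inherits(f, "attention_map")) return(f$values)
    stopifnot(length(f) >= 1)
    Reduce(`+`, lapply(f, function(m) if (inherits(m, "attention_map")) m$values else m)) / length(f)
  })
  shp <- dim(fold_mean[[1]])
  for (m in fold_mean) {
    if (!identical(dim(m), shp)) {
      stop_vbm("attention maps differ in shape across folds", class = "vbmnet_shape_error")
    }
  }
  if (is.null(mask)) mask <- Reduce(`|`, lapply(fold_mean, function(m) m != 0))
  normalized <- lapply(fold_mean, function(m) {
    v <- m[mask]
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant fold map; min-max normalization skipped")
      return(m)
    }
    out <- array(0, dim = shp)
    out[mask] <- (v - rng[1]) / (rng[2] - rng[1])
    out
  })
  task <- if (inherits(maps_by_fold[[1]], "attention_map")) maps_by_fold[[1]]$task else
    if (inherits(maps_by_fold[[1]][[1]], "attention_map")) maps_by_fold[[1]][[1]]$task else "unknown"
  attention_map(Reduce(`+`, normalized) / length(normalized), task,
                provenance = list(n_folds = length(maps_by_fold),
                                  normalization = "minmax_inbrain"))
}

#' Rank atlas ROIs by attention
#'
#' Intersects an attention map with a labelled atlas: for every ROI the
#' statistic is the mean attention over the ROI's voxels (the mean, not the
#' sum, so large ROIs are not automatically favoured; `statistic = "sum"` is
#' available). The top `top_k` ROIs are returned sorted by descending
#' statistic, ties broken toward the lower ROI id.
#'
#' @param map an `attention_map` (same grid as the atlas).
#' @param atlas an `atlas_volume`.
#' @param top_k number of ROIs to return.
#' @param statistic `"mean"` (default) or `"sum"` of attention per ROI.
#' @return data.frame with columns `roi_id`, `roi_name`, `statistic`, `rank`.
#' @export
rank_rois <- function(map, atlas, top_k = 10, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(map, "attention_map"), inherits(atlas, "atlas_volume"), top_k >= 1)
  if (!identical(dim(map$values), dim(atlas$labels))) {
    stop_vbm("map grid %s does not match atlas grid %s (resample first)",
             paste(dim(map$values), collapse = "x"),
             paste(dim(atlas$labels), collapse = "x"), class = "vbmnet_shape_error")
  }
  ids <- as.integer(names(atlas$names))
  stats <- numeric(0)
  kept <- integer(0)
  for (id in ids) {
    sel <- atlas$labels == id
    if (!any(sel)) {
      warning(sprintf("ROI %d ('%s') has no voxels; skipped", id, atlas$names[[as.character(id)]]))
      next
    }
    val <- if (statistic == "mean") mean(map$values[sel]) else sum(map$values[sel])
    kept <- c(kept, id)
    stats <- c(stats, val)
  }
  ord <- order(-stats, kept)
  take <- head(ord, top_k)
  data.frame(
    roi_id = kept[take],
    roi_name = unname(atlas$names[as.character(kept[take])]),
    statistic = stats[take],
    rank = seq_along(take),
    stringsAsFactors = FALSE
  )
}

#' Export an attention map as a NIfTI overlay
#'
#' Writes the map into the coordinate space of a reference volume so it can
#' be displayed in any standard viewer. Values are min-max scaled into
#' \[0, 1\] when they are not already inside that range; background stays 0.
#'
#' @param map an `attention_map`.
#' @param reference path to a NIfTI file, or an image read with RNifti, whose
#'   header (grid + affine) the overlay must share.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
export_overlay <- function(map, reference, path) {
  ref <- if (is.character(reference)) RNifti::readNifti(reference) else RNifti::asNifti(reference)
  if (!identical(dim(ref)[1:3], dim(map$values))) {
    stop_vbm("reference grid %s does not match map grid %s",
             paste(dim(ref), collapse = "x"), paste(dim(map$values), collapse = "x"),
             class = "vbmnet_shape_error")
  }
  v <- map$values
  if (max(v) > 1 || min(v) < 0) {
    rng <- range(v)
    v <- if (diff(rng) == 0) array(0, dim = dim(v)) else (v - rng[1]) / (rng[2] - rng[1])
  }
  out <- RNifti::asNifti(array(v, dim = dim(v)), reference = ref)
  RNifti::writeNifti(out, path)
  invisible(path)
}

#' Nearest-neighbour resampling of a labelled atlas onto another grid
#'
#' Utility for bringing an externally supplied parcellation onto the data
#' grid. Pure index-space nearest-neighbour mapping (no affine handling) — a
#' stand-in adequate for same-orientation grids; proper registration-aware
#' resampling is out of scope.
#'
#' @param atlas an `atlas_volume`.
#' @param target_shape integer vector of 3 target grid dims.
#' @return an `atlas_volume` on the target grid.
#' @export
resample_atlas_nearest <- function(atlas, target_shape) {
  stopifnot(inherits(atlas, "atlas_volume"), length(target_shape) == 3)
  src <- dim(atlas$labels)
  idx <- lapply(1:3, function(a) {
    pmin(pmax(round((seq_len(target_shape[a]) - 0.5) * src[a] / target_shape[a] + 0.5), 1), src[a])
  })
  labels <- atlas$labels[idx[[1]], idx[[2]], idx[[3]]]
  structure(list(labels = labels, names = atlas$names, shape = as.integer(target_shape)),
            class = "atlas_volume")
}
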