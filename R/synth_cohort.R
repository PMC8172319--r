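#' Generate a synthetic brain atlas
#'
#' Builds an ellipsoidal "brain" centred in the voxel grid and tiles its
#' interior with `n_rois` contiguous regions of interest (ROIs) by assigning
#' every in-brain voxel to its nearest randomly placed ROI seed point
#' (a Voronoi tessellation in voxel space). Voxels outside the brain are
#' labelled 0. The result plays the role a labelled anatomical parcellation
#' (e.g. AAL-style) plays for real data; a real atlas volume can be loaded
#' with [read_atlas()] and used through the same interface.
#'
#' @param shape integer vector of 3 grid dimensions (each >= 8).
#' @param n_rois number of regions (>= 1, at most the number of in-brain
#'   voxels).
#' @param seed integer; placement of ROI seed points is deterministic given
#'   the seed.
#' @return object of class `atlas_volume`: list with `labels` (3D integer
#'   array), `names` (named character vector, names are the ROI ids), `shape`.
#' @examples
#' atlas <- generate_atlas(c(16, 16, 16), n_rois = 3, seed = 7)
#' table(atlas$labels)
#' @export
generate_atlas <- function(shape, n_rois, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3)
  if (any(shape < 8)) stop_vbm("all grid dimensions must be >= 8", class = "vbmnet_input_error")
  if (n_rois < 1) stop_vbm("n_rois must be >= 1", class = "vbmnet_input_error")
  mask <- brain_ellipsoid_mask(shape)
  n_in <- sum(mask)
  if (n_rois > n_in) {
    stop_vbm("n_rois = %d exceeds the %d in-brain voxels available",
             n_rois, n_in, class = "vbmnet_capacity_error")
  }
  coords <- which(mask, arr.ind = TRUE)
  set.seed(derive_seed(seed, "atlas"))
  centers <- coords[sample(n_in, n_rois), , drop = FALSE]
  # nearest-seed assignment, one pass per ROI to keep memory linear in voxels
  best_d <- rep(Inf, n_in)
  best_k <- integer(n_in)
  for (k in seq_len(n_rois)) {
    d <- (coords[, 1] - centers[k, 1])^2 + (coords[, 2] - centers[k, 2])^2 +
      (coords[, 3] - centers[k, 3])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_k[upd] <- k
  }
  labels <- array(0L, dim = shape)
  labels[mask] <- best_k
  structure(
    list(labels = labels,
         names = setNames(sprintf("ROI_%03d", seq_len(n_rois)), seq_len(n_rois)),
         shape = shape),
    class = "atlas_volume"
  )
}

# Ellipsoid of semi-axes 0.42 * dim centred in the grid: a rough brain-shaped
# foreground covering ~30% of the cube, leaving genuine background to mask.
brain_ellipsoid_mask <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- 0.42 * shape
  x <- ((seq_len(shape[1]) - ctr[1]) / ax[1])^2
  y <- ((seq_len(shape[2]) - ctr[2]) / ax[2])^2
  z <- ((seq_len(shape[3]) - ctr[3]) / ax[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("Synthetic atlas: %s grid, %d ROIs, %d in-brain voxels\n",
              paste(x$shape, collapse = "x"), length(x$names), sum(x$labels > 0)))
  invisible(x)
}

#' Specify a regional effect to inject into a synthetic cohort
#'
#' An effect couples one phenotype to tissue density inside a set of atlas
#' ROIs, providing the known ground truth that downstream attribution must
#' recover. For `target = "age"` the density offset is
#' `magnitude * (age - mean age)` (units: density per year); for `"gender"`
#' and `"diagnosis"` it is a constant `magnitude` offset for the positive
#' class (female / diagnosed).
#'
#' @param target one of `"age"`, `"gender"`, `"diagnosis"`.
#' @param roi_ids integer ids of atlas ROIs carrying the effect.
#' @param magnitude finite density change per unit of target.
#' @param tissue `"GM"`, `"WM"` or `"both"`.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(target = c("age", "gender", "diagnosis"),
                        roi_ids, magnitude, tissue = c("GM", "WM", "both")) {
  target <- match.arg(target)
  tissue <- match.arg(tissue)
  if (!is.finite(magnitude)) stop_vbm("magnitude must be finite", class = "vbmnet_input_error")
  structure(list(target = target, roi_ids = as.integer(roi_ids),
                 magnitude = magnitude, tissue = tissue),
            class = "effect_spec")
}

#' Specify a synthetic VBM-like cohort
#'
#' Collects every knob of the generator. Defaults emulate the demographic
#' envelope of a paediatric ADHD-type cohort: ages uniform on 6-20 years,
#' 37% female, 39% diagnosed. Density baselines are 0.6 (gray matter) and
#' 0.5 (white matter) inside the brain, so injected effects of magnitude
#' 0.01-0.05 neither clip at \[0, 1\] nor vanish under the default noise.
#'
#' @param n_subjects cohort size.
#' @param shape voxel grid dimensions (default 32³; the full-resolution
#'   analogue would be 121x145x121).
#' @param age_range numeric `c(min, max)` years.
#' @param gender_balance fraction of the positive (female) class, in (0, 1).
#' @param diagnosis_balance fraction diagnosed, in \[0, 1).
#' @param effects list of [effect_spec()] objects (empty = pure-noise null
#'   cohort).
#' @param smoothing_sigma Gaussian smoothing in voxels applied to the
#'   signal field (emulates VBM smoothing).
#' @param noise_sd additive Gaussian noise, density units.
#' @param disorder_name tag for the diagnosed class, `"ASD"` or `"ADHD"`.
#' @param seed integer master seed; each subject draws from a substream
#'   derived from `(seed, subject index)`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, shape = c(32, 32, 32),
                        age_range = c(6, 20), gender_balance = 0.37,
                        diagnosis_balance = 0.39, effects = list(),
                        smoothing_sigma = 1.5, noise_sd = 0.05,
                        disorder_name = c("ADHD", "ASD"), seed = 1) {
  disorder_name <- match.arg(disorder_name)
  if (gender_balance <= 0 || gender_balance >= 1) {
    stop_vbm("gender_balance must lie strictly inside (0, 1)", class = "vbmnet_validation_error")
  }
  if (diagnosis_balance < 0 || diagnosis_balance >= 1) {
    stop_vbm("diagnosis_balance must lie in [0, 1)", class = "vbmnet_validation_error")
  }
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2], n_subjects >= 1)
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop_vbm("effects must be effect_spec objects", class = "vbmnet_validation_error")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), shape = as.integer(shape),
         age_range = age_range, gender_balance = gender_balance,
         diagnosis_balance = diagnosis_balance, effects = effects,
         smoothing_sigma = smoothing_sigma, noise_sd = noise_sd,
         disorder_name = disorder_name, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Separable truncated-Gaussian smoothing; rows renormalised so a constant
# field is preserved at the boundaries. sigma in voxels.
gauss_smooth_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  smooth_axis <- function(a, axis) {
    n <- dim(a)[axis]
    i <- seq_len(n)
    K <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
    K[abs(outer(i, i, `-`)) > ceiling(3 * sigma)] <- 0
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    sm <- array(K %*% matrix(ap, n), dim = dim(ap))
    aperm(sm, order(perm))
  }
  for (axis in 1:3) arr <- smooth_axis(arr, axis)
  arr
}

#' Generate a synthetic VBM-like cohort
#'
#' Produces per-subject gray- and white-matter density volumes plus a
#' phenotype table. Inside the brain each tissue starts from its baseline
#' density, every [effect_spec()] adds its phenotype-coupled offset inside
#' its ROIs, the signal field is Gaussian-smoothed, voxelwise Gaussian noise
#' is added, values are clipped to \[0, 1\], and background voxels are set to
#' exactly -1. Ages are uniform on `age_range`; gender and diagnosis are
#' Bernoulli draws at the configured balances. Every subject consumes its own
#' RNG substream derived from `(seed, subject index)`, so the cohort is fully
#' reproducible, including under partial regeneration.
#'
#' @param spec a [cohort_spec()].
#' @param atlas an `atlas_volume` with the same grid shape.
#' @return object of class `vbm_cohort`: list with `pairs` (list of
#'   `tissue_pair`), `phenotypes` (data.frame with subject_id, age, gender,
#'   diagnosis, disorder), `mask` (in-brain logical array), `spec`.
#' @export
generate_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "atlas_volume"))
  if (!all(spec$shape == atlas$shape)) {
    stop_vbm("cohort shape %s does not match atlas shape %s",
             paste(spec$shape, collapse = "x"), paste(atlas$shape, collapse = "x"),
             class = "vbmnet_validation_error")
  }
  valid_ids <- as.integer(names(atlas$names))
  for (e in spec$effects) {
    bad <- setdiff(e$roi_ids, valid_ids)
    if (length(bad) > 0) {
      stop_vbm("effect on '%s' references unknown ROI id(s): %s",
               e$target, paste(bad, collapse = ", "), class = "vbmnet_validation_error")
    }
  }
  mask <- atlas$labels > 0
  mean_age <- mean(spec$age_range)
  roi_masks <- lapply(spec$effects, function(e) atlas$labels %in% e$roi_ids)

  baseline <- list(gm = 0.6, wm = 0.5)
  pairs <- vector("list", spec$n_subjects)
  age <- numeric(spec$n_subjects)
  gender <- integer(spec$n_subjects)
  diagnosis <- integer(spec$n_subjects)
  nvox <- prod(spec$shape)
  for (i in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, "subject", i))
    age[i] <- runif(1, spec$age_range[1], spec$age_range[2])
    gender[i] <- rbinom(1, 1, spec$gender_balance)
    diagnosis[i] <- rbinom(1, 1, spec$diagnosis_balance)
    vols <- list(
      gm = array(ifelse(mask, baseline$gm, 0), dim = spec$shape),
      wm = array(ifelse(mask, baseline$wm, 0), dim = spec$shape)
    )
    for (j in seq_along(spec$effects)) {
      e <- spec$effects[[j]]
      offset <- switch(e$target,
        age = e$magnitude * (age[i] - mean_age),
        gender = e$magnitude * gender[i],
        diagnosis = e$magnitude * diagnosis[i]
      )
      sel <- roi_masks[[j]]
      for (tis in if (e$tissue == "both") c("gm", "wm") else tolower(e$tissue)) {
        vols[[tis]][sel] <- vols[[tis]][sel] + offset
      }
    }
    for (tis in c("gm", "wm")) {
      v <- gauss_smooth_3d(vols[[tis]], spec$smoothing_sigma)
      if (spec$noise_sd > 0) v <- v + array(rnorm(nvox, 0, spec$noise_sd), dim = spec$shape)
      v <- pmin(pmax(v, 0), 1)
      v[!mask] <- -1
      vols[[tis]] <- v
    }
    pairs[[i]] <- tissue_pair(vols$gm, vols$wm,
                              subject_id = sprintf("sub-%04d", i))
  }
  phen <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(spec$n_subjects)),
    age = age, gender = gender, diagnosis = diagnosis,
    disorder = ifelse(diagnosis == 1, spec$disorder_name, "HC"),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, phenotypes = phen, mask = mask, spec = spec),
            class = "vbm_cohort")
}

#' @export
print.vbm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic VBM cohort: %d subjects, %s grid\n",
              nrow(x$phenotypes), paste(x$spec$shape, collapse = "x")))
  cat(sprintf("  ages %.1f-%.1f y, %.0f%% female, %.0f%% %s, %d injected effect(s)\n",
              min(x$phenotypes$age), max(x$phenotypes$age),
              100 * mean(x$phenotypes$gender), 100 * mean(x$phenotypes$diagnosis),
              x$spec$disorder_name, length(x$spec$effects)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one pair of NIfTI volumes per subject (`<id>_gm.nii.gz`,
#' `<id>_wm.nii.gz`, 1.5 mm isotropic by default), a `phenotypes.csv` table,
#' the atlas as integer NIfTI plus a JSON ROI-name map, and a manifest JSON
#' recording the seed and per-file MD5 checksums.
#'
#' @param cohort a `vbm_cohort` from [generate_cohort()].
#' @param atlas the `atlas_volume` used to generate it.
#' @param dir output directory (created if missing).
#' @param voxel_mm isotropic voxel size recorded in the NIfTI headers.
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, atlas, dir, voxel_mm = 1.5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (p in cohort$pairs) {
    for (tis in c("gm", "wm")) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", p$subject_id, tis))
      write_nifti_volume(p[[tis]], f, voxel_mm = voxel_mm)
      files <- c(files, f)
    }
  }
  phen_path <- file.path(dir, "phenotypes.csv")
  write.csv(cohort$phenotypes, phen_path, row.names = FALSE)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_nifti_volume(atlas$labels, atlas_path, voxel_mm = voxel_mm)
  names_path <- file.path(dir, "atlas_names.json")
  jsonlite::write_json(as.list(atlas$names), names_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, phen_path, atlas_path, names_path)
  manifest <- list(
    seed = cohort$spec$seed,
    n_subjects = cohort$spec$n_subjects,
    shape = cohort$spec$shape,
    voxel_mm = voxel_mm,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort from a directory of NIfTI volumes
#'
#' Counterpart of [write_cohort()]; also accepts externally produced data
#' laid out the same way (per-subject `<id>_gm.nii[.gz]` / `<id>_wm.nii[.gz]`
#' plus `phenotypes.csv`).
#'
#' @param dir directory containing the volumes and `phenotypes.csv`.
#' @return list with `pairs` and `phenotypes` as in [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  phen <- read.csv(file.path(dir, "phenotypes.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(phen$subject_id, function(id) {
    gm <- read_nifti_volume(find_nifti(dir, paste0(id, "_gm")))
    wm <- read_nifti_volume(find_nifti(dir, paste0(id, "_wm")))
    tissue_pair(gm, wm, subject_id = id)
  })
  list(pairs = pairs, phenotypes = phen)
}

find_nifti <- function(dir, stem) {
  for (ext in c(".nii.gz", ".nii")) {
    f <- file.path(dir, paste0(stem, ext))
    if (file.exists(f)) return(f)
  }
  stop_vbm("no NIfTI file for '%s' in %s", stem, dir, class = "vbmnet_io_error")
}

#' Read a labelled atlas volume and its ROI name map
#'
#' @param nifti_path integer-labelled NIfTI volume (0 = background).
#' @param names_path optional JSON file mapping ROI id to name; defaults to
#'   `ROI_<id>` for every observed label.
#' @return an `atlas_volume`.
#' @export
read_atlas <- function(nifti_path, names_path = NULL) {
  labels <- read_nifti_volume(nifti_path)
  storage.mode(labels) <- "integer"
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (!is.null(names_path)) {
    nm <- jsonlite::read_json(names_path, simplifyVector = TRUE)
    names_vec <- setNames(unlist(nm), names(nm))
  } else {
    names_vec <- setNames(sprintf("ROI_%03d", ids), ids)
  }
  missing <- setdiff(as.character(ids), names(names_vec))
  if (length(missing) > 0) {
    stop_vbm("atlas labels without a name entry: %s", paste(missing, collapse = ", "),
             class = "vbmnet_validation_error")
  }
  structure(list(labels = labels, names = names_vec, shape = dim(labels)),
            class = "atlas_volume")
}
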