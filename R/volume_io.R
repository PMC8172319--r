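#' Construct a tissue volume pair
#'
#' One subject's co-registered gray-matter and white-matter density grids.
#' After masking (see [apply_background_mask()]) every voxel is either a
#' tissue density in \[0, 1\] or exactly -1 (background).
#'
#' @param gm,wm 3D numeric arrays of identical dimensions.
#' @param subject_id identifier string.
#' @return object of class `tissue_pair`.
#' @export
tissue_pair <- function(gm, wm, subject_id = "subject") {
  if (!identical(dim(gm), dim(wm))) {
    stop_vbm("GM and WM grids differ in shape (%s vs %s)",
             paste(dim(gm), collapse = "x"), paste(dim(wm), collapse = "x"),
             class = "vbmnet_shape_error")
  }
  stopifnot(length(dim(gm)) == 3)
  structure(list(gm = gm, wm = wm, shape = dim(gm), subject_id = subject_id),
            class = "tissue_pair")
}

#' @export
print.tissue_pair <- function(x, ...) {
  cat(sprintf("Tissue pair '%s': %s grid, %d background voxels\n", x$subject_id,
              paste(x$shape, collapse = "x"), sum(x$gm == -1)))
  invisible(x)
}

#' Set background voxels to -1
#'
#' Applies a brain mask to both tissue channels: voxels outside the mask are
#' assigned the value -1, in-brain voxels are left bit-exact. The -1 sentinel
#' (rather than 0) keeps background clearly separated from low but genuine
#' tissue probabilities. Idempotent.
#'
#' @param pair a [tissue_pair()].
#' @param brain_mask logical 3D array of the same shape (`TRUE` = in brain).
#' @return a masked `tissue_pair`.
#' @export
apply_background_mask <- function(pair, brain_mask) {
  stopifnot(inherits(pair, "tissue_pair"))
  if (!identical(dim(brain_mask), pair$shape)) {
    stop_vbm("mask shape %s does not match volume shape %s",
             paste(dim(brain_mask), collapse = "x"), paste(pair$shape, collapse = "x"),
             class = "vbmnet_shape_error")
  }
  gm <- pair$gm; wm <- pair$wm
  gm[!brain_mask] <- -1
  wm[!brain_mask] <- -1
  tissue_pair(gm, wm, subject_id = pair$subject_id)
}

#' Default cohort brain mask
#'
#' When no mask file is supplied, the brain mask is taken as the union over
#' the cohort of voxels with positive density in either tissue — every voxel
#' that carries tissue for at least one subject is kept.
#'
#' @param pairs list of [tissue_pair()] objects on a common grid.
#' @return logical 3D array.
#' @export
default_brain_mask <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  m <- array(FALSE, dim = pairs[[1]]$shape)
  for (p in pairs) m <- m | (p$gm > 0) | (p$wm > 0)
  m
}

# Centered pad/trim of one axis to length target; pad value -1.
# Returns the index mapping: list(src = indices kept, dst = where they land).
.axis_plan <- function(n, target) {
  if (n == target) return(list(src = seq_len(n), dst = seq_len(n)))
  if (n < target) {
    lo <- (target - n) %/% 2 # extra padding voxel goes on the high side
    list(src = seq_len(n), dst = lo + seq_len(n))
  } else {
    cut_lo <- (n - target) %/% 2 # extra trimmed plane comes off the high side
    list(src = cut_lo + seq_len(target), dst = seq_len(target))
  }
}

#' Pad and trim a volume to a cube
#'
#' Centers the grid inside a `target_edge`³ cube: short axes are padded with
#' -1 (background), long axes are trimmed — but only planes consisting
#' entirely of -1 voxels may be removed; trimming that would discard any
#' in-brain voxel raises a data-loss error. On an odd pad/trim remainder the
#' extra voxel goes to (comes off) the high side. The canonical use is
#' bringing 121x145x121 volumes to 128x128x128.
#'
#' @param x a [tissue_pair()] or a sample tensor (4D array from
#'   [stack_channels()]).
#' @param target_edge cube edge in voxels (>= 8).
#' @return same type as `x`, with every spatial dimension `target_edge`.
#' @export
pad_to_cube <- function(x, target_edge) {
  if (target_edge < 8) stop_vbm("target_edge must be >= 8", class = "vbmnet_input_error")
  if (inherits(x, "tissue_pair")) {
    gm <- .pad_array(x$gm, target_edge, x$subject_id)
    wm <- .pad_array(x$wm, target_edge, x$subject_id)
    return(tissue_pair(gm, wm, subject_id = x$subject_id))
  }
  if (is.array(x) && length(dim(x)) == 4) {
    phen <- attr(x, "phenotype")
    out <- vapply(seq_len(dim(x)[4]), function(ch) .pad_array(x[, , , ch], target_edge),
                  array(0, dim = rep(target_edge, 3)))
    attr(out, "phenotype") <- phen
    class(out) <- c("sample_tensor", class(out))
    return(out)
  }
  stop_vbm("pad_to_cube expects a tissue_pair or a 4D sample tensor", class = "vbmnet_input_error")
}

.pad_array <- function(a, target, id = "") {
  d <- dim(a)
  plans <- lapply(d, .axis_plan, target = target)
  # data-loss check: any in-brain (!= -1) voxel outside the kept window?
  for (axis in 1:3) {
    dropped <- setdiff(seq_len(d[axis]), plans[[axis]]$src)
    if (length(dropped) > 0) {
      sub <- switch(axis,
                    a[dropped, , , drop = FALSE],
                    a[, dropped, , drop = FALSE],
                    a[, , dropped, drop = FALSE])
      if (any(sub != -1)) {
        stop_vbm("trimming axis %d of '%s' would discard in-brain voxels", axis, id,
                 class = "vbmnet_data_loss_error")
      }
    }
  }
  out <- array(-1, dim = rep(target, 3))
  out[plans[[1]]$dst, plans[[2]]$dst, plans[[3]]$dst] <-
    a[plans[[1]]$src, plans[[2]]$src, plans[[3]]$src]
  out
}

#' Stack tissue channels into a sample tensor
#'
#' Builds the 4D model input (X, Y, Z, channel) with channel 1 = gray matter
#' and channel 2 = white matter, values bit-identical to the inputs, and
#' attaches the subject's phenotype record.
#'
#' @param pair a masked [tissue_pair()].
#' @param phenotype list or one-row data.frame with at least `age`, `gender`,
#'   `diagnosis` (and optionally `subject_id`, `disorder`).
#' @return a `sample_tensor`: 4D array with a `phenotype` attribute.
#' @export
stack_channels <- function(pair, phenotype = NULL) {
  stopifnot(inherits(pair, "tissue_pair"))
  out <- array(c(pair$gm, pair$wm), dim = c(pair$shape, 2))
  phen <- as.list(phenotype)
  phen$subject_id <- phen$subject_id %||% pair$subject_id
  attr(out, "phenotype") <- phen
  class(out) <- c("sample_tensor", class(out))
  out
}

#' @rdname stack_channels
#' @param tensor a `sample_tensor`.
#' @export
unstack_channels <- function(tensor) {
  stopifnot(length(dim(tensor)) == 4, dim(tensor)[4] == 2)
  phen <- attr(tensor, "phenotype")
  tissue_pair(array(tensor[, , , 1], dim = dim(tensor)[1:3]),
              array(tensor[, , , 2], dim = dim(tensor)[1:3]),
              subject_id = phen$subject_id %||% "subject")
}

#' Column-major sample matrix for a whole cohort
#'
#' Flattens a list of sample tensors into the dense container the training
#' engine consumes: a `(voxels * channels) x n` matrix (one column per
#' subject, GM voxels first, then WM) plus the phenotype table. A
#' `sample_set` passes through unchanged; a `vbm_cohort` is masked with its
#' own mask and stacked.
#'
#' @param samples list of `sample_tensor`s, a `vbm_cohort`, or a `sample_set`.
#' @return object of class `sample_set`: list with `values` (matrix),
#'   `shape`, `phenotypes` (data.frame).
#' @export
as_sample_set <- function(samples) {
  if (inherits(samples, "sample_set")) return(samples)
  if (inherits(samples, "vbm_cohort")) {
    phen <- samples$phenotypes
    samples <- lapply(seq_along(samples$pairs), function(i) {
      stack_channels(samples$pairs[[i]], phen[i, ])
    })
  }
  stopifnot(length(samples) >= 1)
  shape <- dim(samples[[1]])[1:3]
  values <- vapply(samples, function(s) as.vector(s), numeric(prod(shape) * 2))
  phen_list <- lapply(samples, attr, "phenotype")
  phenotypes <- data.frame(
    subject_id = vapply(phen_list, function(p) as.character(p$subject_id %||% NA), character(1)),
    age = vapply(phen_list, function(p) as.numeric(p$age %||% NA), numeric(1)),
    gender = vapply(phen_list, function(p) as.integer(p$gender %||% NA), integer(1)),
    diagnosis = vapply(phen_list, function(p) as.integer(p$diagnosis %||% NA), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, shape = shape, phenotypes = phenotypes),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d subjects, %s grid, 2 channels\n",
              ncol(x$values), paste(x$shape, collapse = "x")))
  invisible(x)
}

# ---- binary record container ------------------------------------------------
# Format "VBNREC", version 1: a documented, versioned serialized-record file.
#   bytes 0-5   magic "VBNREC"
#   int32       format version (1)
#   per record:
#     int32       header length H
#     H bytes     UTF-8 JSON: subject_id, age, gender, diagnosis, disorder, dims
#     float32[n]  sample values (column-major, prod(dims) elements)
# Values are stored in single precision; read(write(x)) is bit-exact at
# float32. The reader streams record by record and never loads the file whole.

.VBNREC_MAGIC <- charToRaw("VBNREC")
.VBNREC_VERSION <- 1L

#' Write sample tensors to a binary record file
#'
#' Serialises samples (values as float32 plus the phenotype header) into the
#' package's versioned record container, designed for streaming reads during
#' training. See [record_reader()] for incremental access.
#'
#' @param samples list of `sample_tensor` objects ([stack_channels()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(samples, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.VBNREC_MAGIC, con)
  writeBin(.VBNREC_VERSION, con, size = 4, endian = "little")
  for (s in samples) {
    phen <- attr(s, "phenotype")
    header <- jsonlite::toJSON(
      list(subject_id = phen$subject_id %||% NA, age = phen$age %||% NA,
           gender = phen$gender %||% NA, diagnosis = phen$diagnosis %||% NA,
           disorder = phen$disorder %||% NA, dims = dim(s)),
      auto_unbox = TRUE, null = "null", na = "null")
    hraw <- charToRaw(as.character(header))
    writeBin(length(hraw), con, size = 4, endian = "little")
    writeBin(hraw, con)
    writeBin(as.vector(s), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Stream records from a binary record file
#'
#' Returns a reader whose `$read_next()` yields one `sample_tensor` at a time
#' (or `NULL` at end of file) without ever holding the whole file in memory;
#' `$close()` releases the connection. A truncated or corrupt file raises a
#' parse error naming the offending record index.
#'
#' @param path a file written by [write_records()].
#' @return list with functions `read_next` and `close`.
#' @export
record_reader <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = length(.VBNREC_MAGIC))
  if (!identical(magic, .VBNREC_MAGIC)) {
    close(con)
    stop_vbm("'%s' is not a VBNREC record file", path, class = "vbmnet_parse_error")
  }
  version <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!identical(version, .VBNREC_VERSION)) {
    close(con)
    stop_vbm("unsupported record format version %s", version, class = "vbmnet_parse_error")
  }
  idx <- 0L
  open <- TRUE
  read_next <- function() {
    if (!open) stop_vbm("reader already closed", class = "vbmnet_parse_error")
    hlen <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(hlen) == 0) return(NULL) # clean end of file
    idx <<- idx + 1L
    fail <- function() {
      stop_vbm("record file truncated or corrupt at record %d", idx,
               class = "vbmnet_parse_error")
    }
    if (hlen <= 0) fail()
    hraw <- readBin(con, "raw", n = hlen)
    if (length(hraw) < hlen) fail()
    phen <- tryCatch(jsonlite::fromJSON(rawToChar(hraw)), error = function(e) fail())
    dims <- as.integer(phen$dims)
    if (length(dims) != 4) fail()
    n <- prod(dims)
    values <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    if (length(values) < n) fail()
    out <- array(values, dim = dims)
    phen$dims <- NULL
    attr(out, "phenotype") <- phen
    class(out) <- c("sample_tensor", class(out))
    out
  }
  close_fn <- function() {
    if (open) close(con)
    open <<- FALSE
    invisible(NULL)
  }
  list(read_next = read_next, close = close_fn)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rd <- record_reader(path)
  on.exit(rd$close())
  out <- list()
  repeat {
    s <- rd$read_next()
    if (is.null(s)) break
    out[[length(out) + 1L]] <- s
  }
  out
}

# ---- NIfTI helpers ----------------------------------------------------------

#' Read / write a single NIfTI volume
#'
#' Thin wrappers around RNifti keeping the package's conventions in one
#' place: plain R arrays in, 0-based voxel indices, identity orientation
#' scaled to an isotropic voxel size.
#'
#' @param arr 3D array to write.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel size in mm.
#' @return `read_nifti_volume` returns a plain 3D array with a `pixdim`
#'   attribute.
#' @export
write_nifti_volume <- function(arr, path, voxel_mm = 1.5) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- rep(voxel_mm, 3)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  out <- array(as.vector(im), dim = dim(im))
  attr(out, "pixdim") <- RNifti::pixdim(im)
  out
}
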