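#' Stratified k-fold train/validation/test splits
#'
#' Custom cross-validation scheme: subjects are stratified by diagnostic
#' status, shuffled with `seed`, and dealt into `k` partitions. In round `r`
#' (0-based) partition `r` is the test set; the remaining `k - 1` partitions,
#' taken in cyclic order `r+1, r+2, ...` modulo `k`, supply the first `k - 2`
#' as the training set and the last one as the validation set. Every subject
#' is therefore in exactly one test set across rounds, and train/validation/
#' test are disjoint within a round.
#'
#' Only the diagnosis label is balanced; gender and age are left to fall as
#' they may, matching a training regime with no class balancing at the batch
#' level.
#'
#' @param strata named vector (or factor) mapping subject id to diagnosis
#'   label; names are the subject ids. An unnamed vector uses its indices.
#' @param k number of folds (>= 3, so that train, validation and test are all
#'   nonempty).
#' @param seed integer shuffle seed.
#' @return list of `k` objects of class `fold_split`, each with
#'   `round_index` (0-based), `train_ids`, `val_ids`, `test_ids`.
#' @export
make_folds <- function(strata, k = 10, seed = 1) {
  if (k < 3) stop_vbm("k must be >= 3 (need disjoint train/val/test)", class = "vbmnet_input_error")
  ids <- names(strata)
  if (is.null(ids)) ids <- as.character(seq_along(strata))
  lab <- as.character(strata)
  tab <- table(lab)
  small <- names(tab)[tab < k]
  if (length(small) > 0) {
    stop_vbm("stratum '%s' has %d members, fewer than k = %d",
             small[1], tab[[small[1]]], k, class = "vbmnet_stratum_error")
  }
  # deal each stratum round-robin into k partitions after a seeded shuffle
  partitions <- vector("list", k)
  set.seed(derive_seed(seed, "folds"))
  for (s in names(tab)) {
    members <- sample(ids[lab == s])
    for (i in seq_along(members)) {
      p <- ((i - 1) %% k) + 1
      partitions[[p]] <- c(partitions[[p]], members[i])
    }
  }
  lapply(seq_len(k) - 1L, function(r) {
    rest <- ((r + seq_len(k - 1)) %% k) + 1L # cyclic order after the test partition
    structure(
      list(round_index = r,
           train_ids = unlist(partitions[rest[seq_len(k - 2)]], use.names = FALSE),
           val_ids = partitions[[rest[k - 1]]],
           test_ids = partitions[[r + 1L]]),
      class = "fold_split"
    )
  })
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("Fold round %d: %d train / %d validation / %d test subjects\n",
              x$round_index, length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

#' Export/import fold splits as JSON
#'
#' Serialises the exact membership of every round so a run can be re-created.
#'
#' @param folds list of `fold_split` objects from [make_folds()].
#' @param path file path for the JSON document.
#' @export
write_folds_json <- function(folds, path) {
  doc <- lapply(folds, function(f) {
    list(round_index = f$round_index, train_ids = f$train_ids,
         val_ids = f$val_ids, test_ids = f$test_ids)
  })
  jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_folds_json
#' @export
read_folds_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(doc)), function(i) {
    structure(
      list(round_index = as.integer(doc$round_index[i]),
           train_ids = unlist(doc$train_ids[i]),
           val_ids = unlist(doc$val_ids[i]),
           test_ids = unlist(doc$test_ids[i])),
      class = "fold_split"
    )
  })
}
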