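## Stratified repeated random subsampling (SRRS) and class-balanced
## training batches.

#' SRRS plan
#'
#' Fixed per-class validation and test counts; everything left over forms
#' the training set. 3 repetitions by default, 10 in confirmation runs.
#'
#' @param repetitions number of independent random divisions (>= 1).
#' @param validation named per-class validation counts.
#' @param test named per-class test counts.
#' @param seed integer seed; each repetition derives its own stream.
#' @return object of class `srrs_plan`.
#' @export
srrs_plan <- function(repetitions = 3L,
                      validation = c(MI = 5, MII = 5, PI = 5),
                      test = c(MI = 9, MII = 58, PI = 24),
                      seed = 0L) {
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (any(unlist(validation) < 0) || any(unlist(test) < 0))
    stop("per-class counts must be >= 0")
  structure(list(repetitions = as.integer(repetitions),
                 validation = unlist(validation), test = unlist(test),
                 seed = as.integer(seed)),
            class = "srrs_plan")
}

#' Stratified repeated random subsampling split
#'
#' For each repetition, draws the planned per-class validation and test
#' sets without replacement; the remaining records form the training set.
#' The three parts are pairwise disjoint and cover the dataset.
#'
#' @param manifest data.frame with columns `id` and `label`.
#' @param plan an [srrs_plan()].
#' @return object of class `split_assignment`: list of per-repetition
#'   lists with `train`, `validation`, `test` id vectors.
#' @export
srrs_split <- function(manifest, plan) {
  stopifnot(inherits(plan, "srrs_plan"))
  classes <- sort(unique(manifest$label))
  for (cls in union(names(plan$validation), names(plan$test))) {
    need <- sum(plan$validation[names(plan$validation) == cls],
                plan$test[names(plan$test) == cls])
    avail <- sum(manifest$label == cls)
    if (need > avail)
      stop("plan infeasible for class ", cls, ": needs ", need,
           " records, only ", avail, " available")
  }
  reps <- lapply(seq_len(plan$repetitions), function(r) {
    with_seed(derive_seed(plan$seed, r), {
      val <- character(0); tst <- character(0)
      for (cls in classes) {
        ids <- manifest$id[manifest$label == cls]
        nv <- if (cls %in% names(plan$validation)) plan$validation[[cls]] else 0L
        nt <- if (cls %in% names(plan$test)) plan$test[[cls]] else 0L
        pick <- sample(ids, nv + nt)
        val <- c(val, pick[seq_len(nv)])
        tst <- c(tst, pick[nv + seq_len(nt)])
      }
      list(train = setdiff(manifest$id, c(val, tst)),
           validation = val, test = tst)
    })
  })
  structure(list(repetitions = reps, plan = plan), class = "split_assignment")
}

#' Write / read a split assignment as JSON
#' @param split a `split_assignment`.
#' @param path JSON file path.
#' @return `path` (write) or a `split_assignment` (read).
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(lapply(split$repetitions, function(r)
    lapply(r, as.character)), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  reps <- jsonlite::read_json(path, simplifyVector = FALSE)
  reps <- lapply(reps, function(r) lapply(r, function(p) as.character(unlist(p))))
  structure(list(repetitions = reps), class = "split_assignment")
}

#' Draw one class-balanced training batch
#'
#' Exactly `batch_size / n_classes` ids per class, sampled with
#' replacement when a class has fewer records than its quota.
#'
#' @param train_by_class named list mapping class to its training ids.
#' @param batch_size total batch size, divisible by the number of classes
#'   (default 84, i.e. 28 per class for 3 classes).
#' @param seed integer seed for this draw.
#' @return character vector of `batch_size` record ids.
#' @export
balanced_batch <- function(train_by_class, batch_size = 84L, seed = 0L) {
  k <- length(train_by_class)
  if (k == 0 || any(!vapply(train_by_class, length, 0L) > 0))
    stop("every class must have at least one training record")
  if (batch_size %% k != 0)
    stop("batch_size ", batch_size, " is not divisible by ", k, " classes")
  quota <- batch_size %/% k
  with_seed(seed, {
    unlist(lapply(train_by_class, function(ids) {
      sample(ids, quota, replace = length(ids) < quota)
    }), use.names = FALSE)
  })
}

#' Deterministic per-epoch reseeding
#'
#' Gives each training epoch its own batch-composition seed so batches
#' vary across epochs while the whole run stays reproducible.
#'
#' @param epoch 1-based epoch index.
#' @param base_seed integer base seed.
#' @return integer seed.
#' @export
epoch_reseed <- function(epoch, base_seed) derive_seed(base_seed, epoch)
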