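## Rotation-grid x random-translation augmentation with an on-disk cache.
## The working-resolution base tensor (default 550 px) is rotated about
## its center on a deterministic angle grid, then placed into an expanded
## frame (default 590 px) at random integer offsets.

#' Augmentation configuration
#'
#' `output_side` must equal the base tensor side plus `shift_range`
#' (590 = 550 + 40 under defaults).
#'
#' @param n_rot number of rotations (default 12).
#' @param n_shift random translations per rotation (default 5).
#' @param shift_range total frame expansion in pixels (default 40); per-axis
#'   offsets are drawn uniformly from `0:shift_range`.
#' @param output_side side of the augmented tensors (default 590).
#' @param seed integer seed for the shift draws.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(n_rot = 12L, n_shift = 5L, shift_range = 40L,
                           output_side = 590L, seed = 0L) {
  if (n_rot < 1 || n_shift < 1) stop("n_rot and n_shift must be >= 1")
  if (shift_range < 0) stop("shift_range must be >= 0")
  structure(list(n_rot = as.integer(n_rot), n_shift = as.integer(n_shift),
                 shift_range = as.integer(shift_range),
                 output_side = as.integer(output_side), seed = as.integer(seed)),
            class = "augment_config")
}

#' Deterministic rotation angle grid
#'
#' The i-th angle (1-based) is `360 / n_rot * (i - 1)` degrees.
#'
#' @param n_rot number of rotations, at least 1.
#' @return numeric vector of `n_rot` distinct angles starting at 0.
#' @export
rotation_angles <- function(n_rot) {
  if (n_rot < 1) stop("n_rot must be >= 1")
  360 / n_rot * (seq_len(n_rot) - 1)
}

#' Expand one tensor into its augmentation variants
#'
#' Produces `n_rot * n_shift` tensors of side `output_side`. Mask channels
#' are rotated with nearest-neighbor resampling (stays binary), the image
#' channel bilinearly; vacated pixels are zero.
#'
#' @param t an `input_tensor` whose side equals
#'   `cfg$output_side - cfg$shift_range`.
#' @param cfg an [augment_config()].
#' @return list of `n_rot * n_shift` `input_tensor` objects.
#' @export
augment_tensor <- function(t, cfg = augment_config()) {
  stopifnot(inherits(t, "input_tensor"), inherits(cfg, "augment_config"))
  d <- dim(t$data)
  base <- cfg$output_side - cfg$shift_range
  if (d[1] != base || d[2] != base)
    stop("tensor side ", d[1], "x", d[2], " does not match expected base side ",
         base, " (= output_side - shift_range)")
  angles <- rotation_angles(cfg$n_rot)
  shifts <- with_seed(cfg$seed, {
    matrix(sample(0:cfg$shift_range, 2 * cfg$n_rot * cfg$n_shift, replace = TRUE),
           ncol = 2)
  })
  out <- vector("list", cfg$n_rot * cfg$n_shift)
  k <- 0L
  for (i in seq_len(cfg$n_rot)) {
    rot <- array(0, dim = d)
    for (ch in seq_len(d[3])) {
      bilinear <- t$channels[ch] == "oocyte_image"
      plane <- cpp_rotate(t$data[, , ch], angles[i], bilinear)
      rot[, , ch] <- if (bilinear) plane else binarize(plane)
    }
    for (j in seq_len(cfg$n_shift)) {
      k <- k + 1L
      off <- shifts[k, ]
      frame <- array(0, dim = c(cfg$output_side, cfg$output_side, d[3]))
      frame[off[1] + seq_len(base), off[2] + seq_len(base), ] <- rot
      out[[k]] <- structure(list(data = frame, channels = t$channels,
                                 id = t$id, label = t$label,
                                 rot = i, shift = j),
                            class = "input_tensor")
    }
  }
  out
}

#' Build (or reuse) an on-disk augmentation cache
#'
#' Stores one augmented tensor per (record, rotation, shift) triple under
#' `<directory>/<record_id>/rot<i>_shift<j>.bin` with a JSON manifest.
#' Re-running with identical inputs is a no-op.
#'
#' @param records list of `oocyte_record`s (already at working resolution).
#' @param selection a [channel_selection()].
#' @param cfg an [augment_config()]; per-record shift seeds are derived
#'   from `cfg$seed`.
#' @param directory cache directory.
#' @return cache manifest (list) of class `tensor_cache`, as also written
#'   to `<directory>/cache.json`.
#' @export
build_cache <- function(records, selection, cfg, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create cache directory ", directory)
  entries <- list()
  for (rec in records) {
    rdir <- file.path(directory, rec$id)
    dir.create(rdir, showWarnings = FALSE)
    rcfg <- cfg
    rcfg$seed <- derive_seed(cfg$seed, match(rec$id, vapply(records, `[[`, "", "id")))
    paths <- character(0)
    expected <- file.path(rdir, sprintf("rot%d_shift%d.bin",
                                        rep(seq_len(cfg$n_rot), each = cfg$n_shift),
                                        rep(seq_len(cfg$n_shift), cfg$n_rot)))
    if (all(file.exists(expected))) {
      paths <- expected
    } else {
      variants <- augment_tensor(assemble_tensor(rec, selection), rcfg)
      for (v in variants) {
        p <- file.path(rdir, sprintf("rot%d_shift%d.bin", v$rot, v$shift))
        write_tensor(v, p)
        paths <- c(paths, p)
      }
    }
    entries[[rec$id]] <- list(label = rec$label, paths = paths)
  }
  manifest <- structure(list(directory = directory, channels = selection$channels,
                             n_rot = cfg$n_rot, n_shift = cfg$n_shift,
                             output_side = cfg$output_side, entries = entries),
                        class = "tensor_cache")
  jsonlite::write_json(unclass(manifest), file.path(directory, "cache.json"),
                       auto_unbox = TRUE)
  manifest
}

#' In-memory tensor cache
#'
#' Holds base (unaugmented) tensors directly; the desk-scale counterpart
#' of [build_cache()] for experiments that skip the rotation grid.
#'
#' @param records list of `oocyte_record`s.
#' @param selection a [channel_selection()].
#' @return object of class `tensor_cache`.
#' @export
memory_cache <- function(records, selection) {
  entries <- list()
  for (rec in records)
    entries[[rec$id]] <- list(label = rec$label,
                              tensors = list(assemble_tensor(rec, selection)))
  structure(list(directory = NULL, channels = selection$channels,
                 n_rot = 1L, n_shift = 1L, entries = entries),
            class = "tensor_cache")
}

## Fetch one variant (index NULL = random under the supplied rng draw).
cache_variant <- function(cache, id, index = NULL) {
  e <- cache$entries[[id]]
  if (is.null(e)) stop("record '", id, "' is not in the cache")
  if (!is.null(e$tensors)) {
    if (is.null(index)) index <- sample.int(length(e$tensors), 1)
    e$tensors[[index]]
  } else {
    if (is.null(index)) index <- sample.int(length(e$paths), 1)
    read_tensor(e$paths[[index]])
  }
}

cache_ids <- function(cache) names(cache$entries)
cache_labels <- function(cache)
  vapply(cache$entries, `[[`, "", "label")
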