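## Record normalization and classifier input-tensor assembly.

#' Channel selection for the classifier input tensor
#'
#' @param channels character vector of canonical channel names (any order;
#'   tensors are always assembled in canonical order).
#' @param merge_fpb merge the fragmented first polar body into the first
#'   polar body channel before assembly. When set,
#'   `"fragmented_first_polar_body"` may not also be selected separately.
#' @return object of class `channel_selection`.
#' @export
channel_selection <- function(channels, merge_fpb = FALSE) {
  canon <- canonical_channels()
  bad <- setdiff(channels, canon)
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "),
         "; canonical channels are: ", paste(canon, collapse = ", "))
  if (anyDuplicated(channels)) stop("duplicate channel names in selection")
  if (merge_fpb && "fragmented_first_polar_body" %in% channels)
    stop("with merge_fpb, 'fragmented_first_polar_body' may not be a separate channel")
  ord <- canon[canon %in% channels]
  structure(list(channels = ord, merge_fpb = merge_fpb), class = "channel_selection")
}

#' Downscale a record to fit within a resolution limit
#'
#' Records larger than `limit` in either dimension are resampled (image
#' and all masks) to `limit x limit` with nearest-neighbor interpolation;
#' records already within the limit pass through unchanged.
#'
#' @param record an `oocyte_record`.
#' @param limit side limit in pixels (default 550).
#' @return the (possibly resampled) `oocyte_record`.
#' @export
normalize_resolution <- function(record, limit = 550L) {
  stopifnot(inherits(record, "oocyte_record"))
  d <- dim(record$image)
  if (all(d <= limit)) return(record)
  record$image <- resize_nearest(record$image, limit, limit)
  record$masks <- lapply(record$masks, resize_nearest, h = limit, w = limit)
  record
}

#' Zero-pad a record symmetrically to a square side
#'
#' Fixed-shape network inputs need a rule for images below the working
#' resolution; symmetric zero padding preserves centering.
#'
#' @param record an `oocyte_record`.
#' @param side target side in pixels.
#' @return padded `oocyte_record`.
#' @export
pad_record <- function(record, side = 550L) {
  d <- dim(record$image)
  if (all(d == side)) return(record)
  record$image <- pad_to(record$image, side, side)
  record$masks <- lapply(record$masks, pad_to, h = side, w = side)
  record
}

#' Merge the fragmented first polar body into the first polar body mask
#'
#' The FPB mask becomes the pixelwise union of FPB and FFPB; the FFPB
#' mask is emptied.
#'
#' @param record an `oocyte_record`.
#' @return modified `oocyte_record`.
#' @export
merge_fpb_masks <- function(record) {
  stopifnot(inherits(record, "oocyte_record"))
  u <- (record$masks$first_polar_body + record$masks$fragmented_first_polar_body) > 0
  record$masks$first_polar_body <- u * 1
  record$masks$fragmented_first_polar_body <- record$masks$fragmented_first_polar_body * 0
  record
}

#' Assemble the classifier input tensor from selected channels
#'
#' Channels are stacked in canonical order regardless of the order given
#' in the selection; the image channel is scaled to `[0, 1]`, mask
#' channels stay binary.
#'
#' @param record an `oocyte_record`.
#' @param selection a [channel_selection()].
#' @return object of class `input_tensor`: list with `data`
#'   (H x W x N array) and `channels` (names of length N).
#' @export
assemble_tensor <- function(record, selection) {
  stopifnot(inherits(record, "oocyte_record"), inherits(selection, "channel_selection"))
  if (selection$merge_fpb) record <- merge_fpb_masks(record)
  planes <- lapply(selection$channels, function(ch) {
    if (ch == "oocyte_image") record$image / 255 else record$masks[[ch]]
  })
  data <- array(unlist(planes), dim = c(dim(record$image), length(planes)))
  structure(list(data = data, channels = selection$channels, id = record$id,
                 label = record$label),
            class = "input_tensor")
}

#' @export
print.input_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<input_tensor> ", d[1], "x", d[2], "x", d[3], " [",
      paste(x$channels, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

## Simple binary tensor cache entry: data written as raw doubles with a
## JSON sidecar describing shape and channels.
write_tensor <- function(t, path) {
  con <- file(path, "wb")
  writeBin(as.vector(t$data), con, size = 8)
  close(con)
  jsonlite::write_json(list(dim = dim(t$data), channels = t$channels,
                            id = t$id, label = t$label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

read_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  v <- readBin(con, "double", n = prod(meta$dim), size = 8)
  close(con)
  structure(list(data = array(v, dim = meta$dim), channels = meta$channels,
                 id = meta$id, label = meta$label),
            class = "input_tensor")
}
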