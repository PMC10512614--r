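## Lightweight encoder-decoder semantic segmentation of the GV and
## FPB(+FFPB) regions, with detection-ratio-then-IoU snapshot selection.

#' Segmentation configuration
#'
#' @param input_side network input side in pixels. The published protocol
#'   works at 512; phantom experiments typically use 64-128.
#' @param epochs training epochs (published protocol: 200; desk scale:
#'   10-20).
#' @param lr Adam learning rate.
#' @param brightness_jitter multiplicative brightness jitter half-range
#'   applied during training (default 0.4).
#' @param rotation_aug random rotation augmentation (uniform over
#'   `[0, 360)` degrees).
#' @param base_filters width of the first encoder stage.
#' @param samples_per_epoch training images drawn per epoch (capped at
#'   the training-set size); `Inf` uses every image each epoch.
#' @param minibatch gradient-step size.
#' @param detect_px detection threshold in correctly marked pixels
#'   (default 100, applied at source geometry).
#' @param class_weighting weight the pixel loss by inverse class
#'   frequency. The GV/FPB classes cover a few percent of the pixels, and
#'   without a large pretrained encoder the unweighted loss collapses to
#'   all-background, so weighting defaults to on for this backend.
#' @param seed integer seed.
#' @return object of class `seg_config`.
#' @export
seg_config <- function(input_side = 512L, epochs = 20L, lr = 2e-3,
                       brightness_jitter = 0.4, rotation_aug = TRUE,
                       base_filters = 12L, samples_per_epoch = 40L,
                       minibatch = 4L, detect_px = 100L,
                       class_weighting = TRUE, seed = 0L) {
  if (input_side <= 0) stop("input_side must be positive")
  if (brightness_jitter < 0) stop("brightness_jitter must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(input_side = as.integer(input_side), epochs = as.integer(epochs),
                 lr = lr, brightness_jitter = brightness_jitter,
                 rotation_aug = isTRUE(rotation_aug),
                 base_filters = as.integer(base_filters),
                 samples_per_epoch = samples_per_epoch,
                 minibatch = as.integer(minibatch),
                 detect_px = as.integer(detect_px),
                 class_weighting = isTRUE(class_weighting), seed = as.integer(seed)),
            class = "seg_config")
}

#' Encoder-decoder architecture for 3-class pixel labeling
#'
#' Three stride-2 pooling stages (so the bottleneck sees most of the
#' oocyte and can separate locally identical structures by context), a
#' nearest-neighbor upsampling decoder and a skip connection from the
#' first encoder stage; 1x1 head producing background/GV/FPB logits.
#'
#' @param input_side input side in pixels (must be divisible by 8).
#' @param n_channels input channels (3: replicated grayscale).
#' @param base_filters first-stage width.
#' @return architecture list of class `seg_architecture`.
#' @export
seg_architecture <- function(input_side, n_channels = 3L, base_filters = 12L) {
  if (input_side %% 8 != 0) stop("input_side must be divisible by 8")
  f <- as.integer(base_filters)
  L <- list()
  add <- function(...) L[[length(L) + 1L]] <<- list(...)
  add(name = "enc1", kind = "conv", from = "input", kernel = 3L, stride = 1L,
      pad = 1L, filters = f)
  add(name = "relu_enc1", kind = "relu", from = "enc1")
  add(name = "pool1", kind = "maxpool", from = "relu_enc1", kernel = 2L, stride = 2L)
  add(name = "enc2", kind = "conv", from = "pool1", kernel = 3L, stride = 1L,
      pad = 1L, filters = 2L * f)
  add(name = "relu_enc2", kind = "relu", from = "enc2")
  add(name = "pool2", kind = "maxpool", from = "relu_enc2", kernel = 2L, stride = 2L)
  add(name = "enc3", kind = "conv", from = "pool2", kernel = 3L, stride = 1L,
      pad = 1L, filters = 3L * f)
  add(name = "relu_enc3", kind = "relu", from = "enc3")
  add(name = "pool3", kind = "maxpool", from = "relu_enc3", kernel = 2L, stride = 2L)
  add(name = "bottleneck", kind = "conv", from = "pool3", kernel = 3L, stride = 1L,
      pad = 1L, filters = 4L * f)
  add(name = "relu_bottleneck", kind = "relu", from = "bottleneck")
  add(name = "up3", kind = "upsample", from = "relu_bottleneck", factor = 2L)
  add(name = "dec3", kind = "conv", from = "up3", kernel = 3L, stride = 1L,
      pad = 1L, filters = 3L * f)
  add(name = "relu_dec3", kind = "relu", from = "dec3")
  add(name = "up2", kind = "upsample", from = "relu_dec3", factor = 2L)
  add(name = "dec2", kind = "conv", from = "up2", kernel = 3L, stride = 1L,
      pad = 1L, filters = 2L * f)
  add(name = "relu_dec2", kind = "relu", from = "dec2")
  add(name = "up1", kind = "upsample", from = "relu_dec2", factor = 2L)
  add(name = "skip", kind = "concat", from = c("up1", "relu_enc1"))
  add(name = "dec1", kind = "conv", from = "skip", kernel = 3L, stride = 1L,
      pad = 1L, filters = f)
  add(name = "relu_dec1", kind = "relu", from = "dec1")
  add(name = "head", kind = "conv", from = "relu_dec1", kernel = 1L, stride = 1L,
      pad = 0L, filters = 3L)
  arch <- structure(list(layers = L, input_side = as.integer(input_side),
                         n_channels = as.integer(n_channels)),
                    class = "seg_architecture")
  arch_shapes(arch)
  arch
}

#' Preprocess an image for the segmentation network
#'
#' Crops the bounding box (default: full frame; the box must enclose the
#' whole oocyte), bilinearly resizes to the working side, standardizes
#' the intensities to zero mean / unit variance (making the network
#' invariant to global brightness changes) and replicates the grayscale
#' plane to 3 channels.
#'
#' @param image grayscale matrix (0-255).
#' @param bbox `c(row1, row2, col1, col2)` or `NULL` for the full frame.
#' @param side output side (default 512).
#' @return `side x side x 3` array.
#' @export
preprocess_for_segmentation <- function(image, bbox = NULL, side = 512L) {
  if (!is.null(bbox)) {
    if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
      stop("degenerate bounding box")
    image <- image[bbox[1]:bbox[2], bbox[3]:bbox[4], drop = FALSE]
  }
  plane <- resize_bilinear(image / 255, side, side)
  plane <- (plane - mean(plane)) / (stats::sd(plane) + 1e-8)
  array(rep(plane, 3), dim = c(side, side, 3L))
}

#' Bounding box of the oocyte from image intensities
#'
#' Thresholds the (blurred, noisy) image against the dark background and
#' returns the enclosing box of above-threshold pixels, expanded by a
#' relative margin — the automatic counterpart of the manual cropping
#' that precedes segmentation.
#'
#' @param image grayscale matrix (0-255).
#' @param threshold background/foreground intensity cutoff.
#' @param margin box expansion as a fraction of its side.
#' @return `c(row1, row2, col1, col2)`; the full frame when nothing
#'   exceeds the threshold.
#' @export
detect_bbox <- function(image, threshold = 60, margin = 0.12) {
  hit <- image > threshold
  if (!any(hit)) return(c(1L, nrow(image), 1L, ncol(image)))
  rr <- range(which(rowSums(hit) > 0))
  cc <- range(which(colSums(hit) > 0))
  mr <- ceiling(margin * (rr[2] - rr[1] + 1))
  mc <- ceiling(margin * (cc[2] - cc[1] + 1))
  c(max(1L, rr[1] - mr), min(nrow(image), rr[2] + mr),
    max(1L, cc[1] - mc), min(ncol(image), cc[2] + mc))
}

## "Manual" oocyte box from the ground-truth structural masks.
mask_bbox <- function(rec, margin = 0.12) {
  support <- (rec$masks$zona_pellucida + rec$masks$perivitelline_space +
                rec$masks$clear_cytoplasm + rec$masks$germinal_vesicle +
                rec$masks$first_polar_body + rec$masks$fragmented_first_polar_body) > 0
  if (!any(support)) return(c(1L, nrow(rec$image), 1L, ncol(rec$image)))
  rr <- range(which(rowSums(support) > 0))
  cc <- range(which(colSums(support) > 0))
  mr <- ceiling(margin * (rr[2] - rr[1] + 1))
  mc <- ceiling(margin * (cc[2] - cc[1] + 1))
  c(max(1L, rr[1] - mr), min(nrow(rec$image), rr[2] + mr),
    max(1L, cc[1] - mc), min(ncol(rec$image), cc[2] + mc))
}

## Build (x, target) training pairs: ground-truth oocyte crop, resized
## to the working side. `plane` keeps the raw 0-1 intensities so
## photometric augmentation can act before standardization.
seg_pairs <- function(records, side) {
  lapply(records, function(rec) {
    box <- mask_bbox(rec)
    crop <- rec$image[box[1]:box[2], box[3]:box[4], drop = FALSE]
    x <- preprocess_for_segmentation(rec$image, box, side)
    plane <- resize_bilinear(crop / 255, side, side)
    gv_c <- rec$masks$germinal_vesicle[box[1]:box[2], box[3]:box[4], drop = FALSE]
    fpb_c <- binarize(rec$masks$first_polar_body +
                        rec$masks$fragmented_first_polar_body)[box[1]:box[2],
                                                               box[3]:box[4], drop = FALSE]
    gv <- resize_nearest(gv_c, side, side)
    fpb <- resize_nearest(fpb_c, side, side)
    tgt <- matrix(1L, side, side)
    tgt[gv > 0] <- 2L
    tgt[fpb > 0] <- 3L
    list(id = rec$id, x = x, plane = plane, target = tgt, record = rec)
  })
}

## Validation DR and mean IoU at full source geometry, through the
## automatic-crop prediction path.
seg_validate <- function(pairs, arch, wts, detect_px) {
  outcomes <- logical(0)
  inter <- c(gv = 0, fpb = 0); uni <- c(gv = 0, fpb = 0)
  snap <- structure(list(arch = arch, weights = wts), class = "seg_snapshot")
  for (p in pairs) {
    pm <- predict_masks(p$record$image, snap)
    truth_gv <- p$record$masks$germinal_vesicle
    truth_fpb <- binarize(p$record$masks$first_polar_body +
                            p$record$masks$fragmented_first_polar_body)
    if (sum(truth_gv) > 0)
      outcomes <- c(outcomes, region_detected(pm$germinal_vesicle, truth_gv, detect_px))
    if (sum(truth_fpb) > 0)
      outcomes <- c(outcomes, region_detected(pm$first_polar_body, truth_fpb, detect_px))
    inter["gv"] <- inter["gv"] + sum(pm$germinal_vesicle > 0 & truth_gv > 0)
    uni["gv"] <- uni["gv"] + sum(pm$germinal_vesicle > 0 | truth_gv > 0)
    inter["fpb"] <- inter["fpb"] + sum(pm$first_polar_body > 0 & truth_fpb > 0)
    uni["fpb"] <- uni["fpb"] + sum(pm$first_polar_body > 0 | truth_fpb > 0)
  }
  per_class_iou <- ifelse(uni > 0, inter / uni, 1)
  list(dr = if (length(outcomes)) mean(outcomes) else NA_real_,
       iou = mean(per_class_iou))
}

#' Train the segmentation network
#'
#' Per-pixel cross-entropy with Adam; training images get random
#' rotation and brightness-jitter augmentation. Each epoch records a
#' snapshot with its validation detection ratio (threshold
#' `cfg$detect_px` correctly marked pixels, evaluated at source
#' geometry) and mean IoU over the GV and FPB classes.
#'
#' @param records list of `oocyte_record`s (train + validation pool).
#' @param split list with `train` and `validation` id vectors; `NULL`
#'   trains and validates on all records.
#' @param cfg a [seg_config()].
#' @return list of class `seg_snapshots`: per-epoch entries with `epoch`,
#'   `loss`, `dr`, `iou`, `weights`, plus the architecture.
#' @export
train_segmenter <- function(records, split = NULL, cfg = seg_config()) {
  if (!length(records)) stop("empty dataset")
  ids <- vapply(records, `[[`, "", "id")
  names(records) <- ids
  if (is.null(split)) split <- list(train = ids, validation = ids)
  side <- cfg$input_side
  train_pairs <- seg_pairs(records[split$train], side)
  val_pairs <- seg_pairs(records[split$validation], side)
  arch <- seg_architecture(side, 3L, cfg$base_filters)
  wts <- nn_init_weights(arch, derive_seed(cfg$seed, 1L))
  opt <- adam_new(wts)
  snapshots <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    es <- epoch_reseed(epoch, cfg$seed)
    n_draw <- min(length(train_pairs), cfg$samples_per_epoch)
    batch <- with_seed(es, {
      idx <- sample.int(length(train_pairs), n_draw)
      lapply(train_pairs[idx], function(p) {
        angle <- if (cfg$rotation_aug) stats::runif(1, 0, 360) else 0
        gain <- 1 + stats::runif(1, -cfg$brightness_jitter, cfg$brightness_jitter)
        plane <- p$plane
        tgt <- p$target
        if (angle != 0) {
          plane <- cpp_rotate(plane, angle, TRUE)
          ## rotate the class map per class, nearest-neighbor
          tgt <- matrix(1L, side, side)
          gvp <- binarize(cpp_rotate((p$target == 2L) * 1, angle, FALSE))
          fpp <- binarize(cpp_rotate((p$target == 3L) * 1, angle, FALSE))
          tgt[gvp > 0] <- 2L
          tgt[fpp > 0] <- 3L
        }
        plane <- pmin(1, pmax(0, plane * gain))
        plane <- (plane - mean(plane)) / (stats::sd(plane) + 1e-8)
        list(x = array(rep(plane, 3), dim = c(side, side, 3L)), target = tgt)
      })
    })
    losses <- numeric(0)
    for (at in seq(1, length(batch), by = cfg$minibatch)) {
      chunk <- batch[at:min(at + cfg$minibatch - 1, length(batch))]
      x <- array(0, dim = c(side, side, 3L, length(chunk)))
      tgt <- array(1L, dim = c(side, side, length(chunk)))
      for (i in seq_along(chunk)) { x[, , , i] <- chunk[[i]]$x; tgt[, , i] <- chunk[[i]]$target }
      cw <- NULL
      if (cfg$class_weighting) {
        freq <- tabulate(tgt, 3) + 1
        cw <- pmin(sum(freq) / (3 * freq), 25)
      }
      fwd <- net_forward(arch, wts, x)
      ce <- pixel_xent(fwd$acts$head, tgt, cw)
      bwd <- net_backward(arch, wts, fwd, ce$dlogits)
      upd <- adam_step(wts, bwd$grads, opt, lr = cfg$lr)
      wts <- upd$wts; opt <- upd$state
      losses <- c(losses, ce$loss)
    }
    vs <- seg_validate(val_pairs, arch, wts, cfg$detect_px)
    snapshots[[epoch]] <- list(epoch = epoch, loss = mean(losses),
                               dr = vs$dr, iou = vs$iou, weights = wts)
  }
  structure(list(snapshots = snapshots, arch = arch, cfg = cfg),
            class = "seg_snapshots")
}

#' Select the best segmentation snapshot
#'
#' Among the snapshots with maximal detection ratio, picks the one with
#' maximal mean IoU; remaining ties go to the earliest epoch.
#'
#' @param snapshots a `seg_snapshots` object or plain list of snapshots.
#' @return one snapshot of class `seg_snapshot`.
#' @export
select_segmenter <- function(snapshots) {
  arch <- NULL; cfg <- NULL
  if (inherits(snapshots, "seg_snapshots")) {
    arch <- snapshots$arch; cfg <- snapshots$cfg
    snapshots <- snapshots$snapshots
  }
  if (!length(snapshots)) stop("no snapshots to select from")
  dr <- vapply(snapshots, `[[`, numeric(1), "dr")
  io <- vapply(snapshots, `[[`, numeric(1), "iou")
  cand <- which(dr == max(dr))
  best <- cand[which.max(io[cand])]
  snap <- snapshots[[best]]
  snap$arch <- arch
  snap$cfg <- cfg
  class(snap) <- "seg_snapshot"
  snap
}

## Argmax decode + nearest-neighbor restore to crop geometry.
predict_masks_raw <- function(x, arch, wts, out_dim) {
  xb <- array(x, dim = c(dim(x), 1L))
  fwd <- net_forward(arch, wts, xb)
  lg <- fwd$acts$head[, , , 1]
  cls <- apply(lg, c(1, 2), which.max)
  list(germinal_vesicle = resize_nearest((cls == 2) * 1, out_dim[1], out_dim[2]),
       first_polar_body = resize_nearest((cls == 3) * 1, out_dim[1], out_dim[2]))
}

#' Predict GV and FPB masks for one image
#'
#' Per-pixel argmax over background/GV/FPB, restored to the source
#' geometry with nearest-neighbor resampling. The two masks are disjoint
#' by construction. Optionally, connected components smaller than
#' `min_component_px` are suppressed — the same pixel threshold under
#' which the detection ratio refuses to count a region as found.
#'
#' @param image grayscale matrix (0-255).
#' @param snapshot a `seg_snapshot` from [select_segmenter()].
#' @param bbox oocyte bounding box `c(row1, row2, col1, col2)`; `NULL`
#'   locates the cell automatically with [detect_bbox()].
#' @param min_component_px suppress predicted components below this pixel
#'   count (0 = keep the raw argmax output).
#' @return named list of binary masks `germinal_vesicle`,
#'   `first_polar_body` at the full source image size.
#' @export
predict_masks <- function(image, snapshot, bbox = NULL, min_component_px = 0L) {
  if (is.null(snapshot$weights)) stop("snapshot carries no trained weights")
  if (is.null(bbox)) bbox <- detect_bbox(image)
  x <- preprocess_for_segmentation(image, bbox, snapshot$arch$input_side)
  crop_dim <- c(bbox[2] - bbox[1] + 1L, bbox[4] - bbox[3] + 1L)
  pm <- predict_masks_raw(x, snapshot$arch, snapshot$weights, crop_dim)
  pm <- lapply(pm, function(m) {
    full <- matrix(0, nrow(image), ncol(image))
    full[bbox[1]:bbox[2], bbox[3]:bbox[4]] <- m
    full
  })
  if (min_component_px > 0) pm <- lapply(pm, drop_small_components, min_component_px)
  pm
}

## Zero out connected components smaller than min_px.
drop_small_components <- function(mask, min_px) {
  if (sum(mask) == 0) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_px])
  matrix(as.vector(EBImage::imageData(lab)) %in% keep, nrow(mask), ncol(mask)) * 1
}
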