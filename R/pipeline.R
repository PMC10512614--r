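## End-to-end orchestration: image -> segmentation -> channel assembly ->
## classification, plus the configurable experiment driver.

#' Classify one oocyte image with the full two-stage pipeline
#'
#' Runs segmentation preprocessing, GV/FPB mask prediction, FPB merge,
#' 2-channel tensor assembly (padded/downscaled to the classifier input
#' side) and classification.
#'
#' @param image grayscale matrix (0-255) containing a single oocyte.
#' @param seg_snapshot a trained `seg_snapshot`.
#' @param clf_snapshot a trained `clf_snapshot` expecting the 2-channel
#'   FPB + GV input.
#' @param bbox optional oocyte bounding box for the segmentation crop.
#' @param min_component_px minimum predicted-component size kept in the
#'   mask hand-off; defaults to the segmenter's detection threshold
#'   (100 px), under which a region does not count as detected anyway.
#' @return list with `label`, `probs` and the intermediate `masks`.
#' @export
classify_image <- function(image, seg_snapshot, clf_snapshot, bbox = NULL,
                           min_component_px = NULL) {
  arch <- clf_snapshot$arch
  if (arch$n_channels != 2L)
    stop("classifier snapshot expects ", arch$n_channels,
         " channels; the pipeline provides the 2-channel FPB + GV input")
  if (is.null(min_component_px))
    min_component_px <- seg_snapshot$cfg$detect_px %||% 100L
  masks <- predict_masks(image, seg_snapshot, bbox, min_component_px)
  rec <- masks_to_record(image, masks)
  t <- pipeline_tensor(rec, arch$input_side)
  res <- classify(t, clf_snapshot)
  list(label = res$label, probs = res$probs, masks = masks)
}

## Wrap an image + predicted GV/FPB masks as an oocyte_record-shaped
## object (other regions empty; no label claim, so invariants that
## depend on the label are not enforced here).
masks_to_record <- function(image, masks, id = "query") {
  empty <- matrix(0, nrow(image), ncol(image))
  all_masks <- stats::setNames(rep(list(empty), length(canonical_regions())),
                               canonical_regions())
  all_masks$germinal_vesicle <- masks$germinal_vesicle
  all_masks$first_polar_body <- masks$first_polar_body
  structure(list(id = id, image = image, masks = all_masks, label = NA_character_),
            class = "oocyte_record")
}

## Normalize + pad a record and assemble the standard 2-channel tensor.
pipeline_tensor <- function(rec, input_side) {
  rec <- normalize_resolution(rec, input_side)
  rec <- pad_record(rec, input_side)
  assemble_tensor(rec, channel_selection(c("first_polar_body", "germinal_vesicle"),
                                         merge_fpb = TRUE))
}

#' Default pipeline experiment configuration
#'
#' Nested stage blocks mirroring the module configurations; every stage
#' seed derives deterministically from the global seed.
#'
#' @param seed global seed.
#' @param counts per-class phantom counts.
#' @param side phantom side in pixels.
#' @param plan an [srrs_plan()] (its seed is re-derived from `seed`).
#' @param clf a [train_config()] for the classifier.
#' @param seg a [seg_config()] for the segmenter.
#' @param out_dir optional artifact directory; `NULL` keeps everything in
#'   memory.
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 0L,
                            counts = c(MI = 100, MII = 100, PI = 100),
                            side = 128L,
                            plan = srrs_plan(repetitions = 1L,
                                             validation = c(MI = 10, MII = 10, PI = 10),
                                             test = c(MI = 20, MII = 20, PI = 20)),
                            clf = train_config(epochs = 15L, lr = 3e-3, minibatch = 12L),
                            seg = seg_config(input_side = 64L, epochs = 45L,
                                             lr = 1e-3, base_filters = 16L,
                                             samples_per_epoch = 48L),
                            out_dir = NULL) {
  plan$seed <- derive_seed(seed, 2L)
  clf$seed <- derive_seed(seed, 3L)
  seg$seed <- derive_seed(seed, 4L)
  structure(list(seed = as.integer(seed), counts = counts, side = as.integer(side),
                 phantom = phantom_params(side = side), plan = plan,
                 clf = clf, seg = seg, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized blocks: `seed`, `counts`, `side`, `srrs`
#' (`repetitions`/`validation`/`test`), `classifier` and `segmentation`
#' (fields of [train_config()] / [seg_config()]), `out_dir`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$counts)) args$counts <- unlist(y$counts)
  if (!is.null(y$side)) args$side <- y$side
  if (!is.null(y$srrs))
    args$plan <- do.call(srrs_plan, y$srrs)
  if (!is.null(y$classifier)) args$clf <- do.call(train_config, y$classifier)
  if (!is.null(y$segmentation)) args$seg <- do.call(seg_config, y$segmentation)
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(pipeline_config, args)
}

## Evaluate a classifier snapshot on a set of records, either from their
## ground-truth masks or through the segmentation path.
eval_records <- function(records, clf_snap, seg_snap = NULL, srrs_id = 1L) {
  truth <- vapply(records, `[[`, "", "label")
  pred <- vapply(records, function(rec) {
    if (is.null(seg_snap)) {
      t <- pipeline_tensor(rec, clf_snap$arch$input_side)
      classify(t, clf_snap)$label
    } else {
      classify_image(rec$image, seg_snap, clf_snap)$label
    }
  }, "")
  tally_from_predictions(truth, pred, srrs_id)
}

#' Run the configured end-to-end phantom experiment
#'
#' Stage sequence: phantom generation, SRRS split, classifier training on
#' ground-truth GV/FPB masks, segmenter training, then evaluation of the
#' selected snapshots on validation / test / all oocytes twice — once
#' from the manual (ground-truth) masks and once from the predicted
#' masks — yielding the paired quality-coefficient reports.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return list of class `pipeline_result`: `reports` (metrics_report per
#'   mask source and evaluation set), `seg` (selected snapshot with its
#'   DR/IoU), `clf` (selected snapshot), `splits`, `config`.
#' @export
run_experiment <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  ds <- generate_dataset(config$counts, config$phantom, derive_seed(config$seed, 1L))
  splits <- srrs_split(ds$manifest, config$plan)
  selection <- channel_selection(c("first_polar_body", "germinal_vesicle"),
                                 merge_fpb = TRUE)
  cache <- memory_cache(ds$records, selection)

  per_rep <- lapply(seq_along(splits$repetitions), function(r) {
    rep <- splits$repetitions[[r]]
    clf_cfg <- config$clf
    clf_cfg$seed <- derive_seed(config$clf$seed, r)
    arch <- build_architecture(reference_chromosome(), 2L, 1L, config$side)
    clf_snap <- select_snapshot(train_classifier(cache, rep, arch, clf_cfg))
    seg_cfg <- config$seg
    seg_cfg$seed <- derive_seed(config$seg$seed, r)
    seg_snaps <- train_segmenter(ds$records, rep, seg_cfg)
    seg_snap <- select_segmenter(seg_snaps)
    sets <- list(validation = ds$records[rep$validation],
                 test = ds$records[rep$test],
                 all = ds$records)
    tallies <- list()
    for (src in c("manual", "predicted"))
      for (set in names(sets))
        tallies[[paste(src, set, sep = ".")]] <-
          eval_records(sets[[set]], clf_snap,
                       if (src == "predicted") seg_snap else NULL, r)
    list(clf = clf_snap, seg = seg_snap, tallies = tallies)
  })

  reports <- list()
  for (key in names(per_rep[[1]]$tallies))
    reports[[key]] <- aggregate_metrics(lapply(per_rep, function(z) z$tallies[[key]]))
  res <- structure(list(reports = reports,
                        seg = per_rep[[1]]$seg, clf = per_rep[[1]]$clf,
                        per_rep = per_rep, splits = splits, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (key in names(x$reports))
    cat(sprintf("  %-20s Acc = %.5f\n", key, x$reports[[key]]$means[["ACC"]]))
  cat(sprintf("  segmenter: DR = %.3f, mean IoU = %.3f\n",
              x$seg$dr, x$seg$iou))
  invisible(x)
}

## Serialize the metric reports (CSV mirroring the coefficient x
## {validation, test, all} layout, plus JSON) into a directory.
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (src in c("manual", "predicted")) {
    tab <- sapply(c("validation", "test", "all"), function(set)
      res$reports[[paste(src, set, sep = ".")]]$means)
    utils::write.csv(round(tab, 5), file.path(dir, paste0("report_", src, ".csv")))
  }
  jsonlite::write_json(
    list(reports = lapply(res$reports, function(r) as.list(r$means)),
         segmentation = list(dr = res$seg$dr, iou = res$seg$iou),
         seed = res$config$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_split(res$splits, file.path(dir, "splits.json"))
  invisible(dir)
}
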