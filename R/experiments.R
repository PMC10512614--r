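## Refinement-phase experiment drivers over phantom datasets: the
## inception-depth sweep and the two-phase input-feature selection.
##
## Channel informativeness is scored with the mean per-class recall
## ("balanced" accuracy convention), under which chance level for three
## balanced classes is 1/3 and the 0.55 selection threshold separates
## informative channels from uninformative ones.

## Train on each SRRS repetition (with an independent training seed per
## repetition) and return the cross-repetition mean validation accuracy
## of the selected snapshots.
train_mean_acc <- function(records, manifest, selection, splits, arch, cfg) {
  cache <- memory_cache(records, selection)
  accs <- vapply(seq_along(splits$repetitions), function(r) {
    rcfg <- cfg
    rcfg$seed <- derive_seed(cfg$seed, r)
    snaps <- train_classifier(cache, splits$repetitions[[r]], arch, rcfg)
    select_snapshot(snaps)$val_acc
  }, numeric(1))
  mean(accs)
}

#' Inception-depth sweep
#'
#' Trains and evaluates one classifier per fire-block count, reporting
#' mean validation accuracy and analytic FLOPs at fixed chromosome.
#'
#' @param dataset list with `records` and `manifest` (see
#'   [generate_dataset()]).
#' @param blocks fire-block counts to sweep (default `c(4, 3, 2, 1, 0)`).
#' @param chrom a [chromosome()] shared across depths.
#' @param plan an [srrs_plan()].
#' @param cfg a [train_config()]; the `"balanced"` accuracy convention is
#'   used for the report.
#' @param channels channel selection for the input (default: all 15).
#' @return data.frame of class `depth_sweep`: `blocks`, `acc`, `flops`.
#' @export
depth_sweep <- function(dataset, blocks = c(4, 3, 2, 1, 0),
                        chrom = sweep_chromosome(),
                        plan = srrs_plan(), cfg = train_config(),
                        channels = canonical_channels()) {
  cfg$acc_convention <- "balanced"
  splits <- srrs_split(dataset$manifest, plan)
  side <- nrow(dataset$records[[1]]$image)
  selection <- channel_selection(channels)
  rows <- lapply(blocks, function(b) {
    arch <- build_architecture(chrom, length(selection$channels), b, side)
    acc <- tryCatch(
      train_mean_acc(dataset$records, dataset$manifest, selection, splits, arch, cfg),
      error = function(e) stop("depth ", b, ": ", conditionMessage(e)))
    data.frame(blocks = b, acc = acc, flops = count_flops(arch))
  })
  structure(do.call(rbind, rows), class = c("depth_sweep", "data.frame"))
}

new_feature_report <- function(phase, table, threshold, selected) {
  structure(list(phase = phase, table = table, threshold = threshold,
                 selected = selected),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat("<feature_selection_report> phase", x$phase,
      " threshold", x$threshold, "\n")
  print(x$table, row.names = FALSE)
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Phase-1 input-feature selection
#'
#' Trains one single-channel classifier per canonical channel and selects
#' the channels whose mean validation accuracy strictly exceeds the
#' threshold.
#'
#' @param dataset list with `records` and `manifest`.
#' @param plan an [srrs_plan()].
#' @param cfg a [train_config()].
#' @param threshold selection threshold on mean accuracy (default 0.55).
#' @param channels channels to sweep (default: all 15).
#' @param n_inception fire blocks in the swept structure.
#' @param chrom shared [chromosome()]; the default is [sweep_chromosome()],
#'   the pre-refinement structure width — the input sweeps historically
#'   precede the genetic filter-count refinement.
#' @return a `feature_selection_report` (phase 1); per-channel failures
#'   are recorded as `NA` rows without aborting the sweep.
#' @export
feature_phase1 <- function(dataset, plan = srrs_plan(), cfg = train_config(),
                           threshold = 0.55, channels = canonical_channels(),
                           n_inception = 1L, chrom = sweep_chromosome()) {
  cfg$acc_convention <- "balanced"
  splits <- srrs_split(dataset$manifest, plan)
  side <- nrow(dataset$records[[1]]$image)
  rows <- lapply(channels, function(ch) {
    acc <- tryCatch({
      selection <- channel_selection(ch)
      arch <- build_architecture(chrom, 1L, n_inception, side)
      train_mean_acc(dataset$records, dataset$manifest, selection, splits, arch, cfg)
    }, error = function(e) {
      warning("channel '", ch, "' failed: ", conditionMessage(e))
      NA_real_
    })
    data.frame(channel = ch, acc = acc, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  selected <- tab$channel[!is.na(tab$acc) & tab$acc > threshold]
  new_feature_report(1L, tab, threshold, selected)
}

#' Phase-2 input-feature selection
#'
#' Starting from the FPB + GV base, adds each remaining channel
#' individually and reports the paired mean validation accuracies
#' (base-only run included as the reference row), sorted by accuracy.
#'
#' @param dataset list with `records` and `manifest`.
#' @param base base channels (default FPB + GV, unmerged).
#' @param extras channels to add one at a time (default: all canonical
#'   channels not in the base).
#' @param plan,cfg,n_inception,chrom as in [feature_phase1()].
#' @return a `feature_selection_report` (phase 2).
#' @export
feature_phase2 <- function(dataset,
                           base = c("first_polar_body", "germinal_vesicle"),
                           extras = NULL,
                           plan = srrs_plan(), cfg = train_config(),
                           n_inception = 1L, chrom = sweep_chromosome()) {
  cfg$acc_convention <- "balanced"
  splits <- srrs_split(dataset$manifest, plan)
  side <- nrow(dataset$records[[1]]$image)
  if (is.null(extras))
    extras <- setdiff(canonical_channels(), base)
  ## base channels stay unmerged here: the gain from adding the FFPB
  ## channel is exactly what motivates the later FPB/FFPB merge
  run <- function(chs) {
    selection <- channel_selection(chs)
    arch <- build_architecture(chrom, length(selection$channels), n_inception, side)
    train_mean_acc(dataset$records, dataset$manifest, selection, splits, arch, cfg)
  }
  rows <- list(data.frame(channel = "(base only)", acc = run(base),
                          stringsAsFactors = FALSE))
  for (ch in extras) {
    acc <- tryCatch(
      run(c(base, ch)),
      error = function(e) {
        warning("channel '", ch, "' failed: ", conditionMessage(e))
        NA_real_
      })
    rows[[length(rows) + 1L]] <- data.frame(channel = ch, acc = acc,
                                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$acc, seq_len(nrow(tab))), ]
  rownames(tab) <- NULL
  new_feature_report(2L, tab, NA_real_, character(0))
}
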