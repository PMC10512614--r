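## Fire-block classification network family parameterized by a 6-gene
## filter-count chromosome, with analytic FLOPs accounting.

#' Filter-count chromosome
#'
#' Six even integers in `[2, 128]`: filters of the stem conv (3x3,
#' stride 2), the 1x1 conv that follows, the fire-block squeeze conv, the
#' fire 3x3 branch, the fire 1x1 branch, and the two head 1x1 convs.
#'
#' @param filters integer vector of length 6.
#' @return validated integer vector of class `chromosome`.
#' @export
chromosome <- function(filters) {
  filters <- as.integer(filters)
  if (length(filters) != 6) stop("chromosome must have exactly 6 genes")
  if (any(filters < 2 | filters > 128)) stop("filter counts must lie in [2, 128]")
  if (any(filters %% 2 != 0)) stop("filter counts must be even")
  structure(filters, class = "chromosome")
}

#' Reference chromosome of the published refined structure
#' @return `chromosome(c(32, 16, 8, 28, 28, 4))`.
#' @export
reference_chromosome <- function() chromosome(c(32L, 16L, 8L, 28L, 28L, 4L))

#' Sweep chromosome: the pre-refinement structure width
#'
#' The depth and input-feature sweeps precede the genetic filter-count
#' refinement, so they use a wider, SqueezeNet-scale structure. Wider
#' heads also train reliably on sparse single-mask inputs, which the
#' refined 4-filter head does not.
#'
#' @return `chromosome(c(64, 32, 16, 32, 32, 16))`.
#' @export
sweep_chromosome <- function() chromosome(c(64L, 32L, 16L, 32L, 32L, 16L))

#' Build the classifier architecture from a chromosome
#'
#' Topology: stem 3x3 stride-2 conv, ReLU, 3x3 stride-2 maxpool; 1x1
#' conv, ReLU, 3x3 stride-2 maxpool; then `n_inception` fire blocks
#' (1x1 squeeze; parallel 3x3-padded and 1x1 expand branches; depth
#' concatenation; 3x3 stride-2 maxpool with a one-pixel bottom/right pad);
#' then two 1x1 convs with ReLU, global average pooling, a 3-way fully
#' connected layer and softmax. Fire blocks share the squeeze/branch
#' genes; both head convs use the final gene.
#'
#' @param chrom a [chromosome()].
#' @param n_channels number of input channels.
#' @param n_inception number of fire blocks, 0 to 4.
#' @param input_side spatial input side in pixels (590 at the published
#'   working resolution).
#' @param dropout_rate dropout before the head convs (0 disables; the
#'   published table omits the dropout layer, so the default is 0).
#' @return architecture list of class `clf_architecture` consumable by
#'   [arch_shapes()], [count_flops()] and [train_classifier()].
#' @export
build_architecture <- function(chrom, n_channels = 2L, n_inception = 1L,
                               input_side = 590L, dropout_rate = 0) {
  chrom <- chromosome(chrom)
  if (n_inception < 0 || n_inception > 4) stop("n_inception must be in [0, 4]")
  if (n_channels < 1) stop("n_channels must be >= 1")
  g <- as.integer(chrom)
  L <- list()
  add <- function(...) L[[length(L) + 1L]] <<- list(...)
  add(name = "conv1", kind = "conv", from = "input", kernel = 3L, stride = 2L,
      pad = 0L, filters = g[1])
  add(name = "relu_conv1", kind = "relu", from = "conv1")
  add(name = "pool_conv1", kind = "maxpool", from = "relu_conv1", kernel = 3L, stride = 2L)
  add(name = "conv2", kind = "conv", from = "pool_conv1", kernel = 1L, stride = 1L,
      pad = 0L, filters = g[2])
  add(name = "relu_conv2", kind = "relu", from = "conv2")
  add(name = "pool_conv2", kind = "maxpool", from = "relu_conv2", kernel = 3L, stride = 2L)
  prev <- "pool_conv2"
  for (b in seq_len(n_inception)) {
    sq <- sprintf("squeeze%d", b)
    add(name = sq, kind = "conv", from = prev, kernel = 1L, stride = 1L,
        pad = 0L, filters = g[3])
    add(name = paste0("relu_", sq), kind = "relu", from = sq)
    add(name = sprintf("fire%d_3x3", b), kind = "conv", from = paste0("relu_", sq),
        kernel = 3L, stride = 1L, pad = 1L, filters = g[4])
    add(name = sprintf("relu_fire%d_3x3", b), kind = "relu", from = sprintf("fire%d_3x3", b))
    add(name = sprintf("fire%d_1x1", b), kind = "conv", from = paste0("relu_", sq),
        kernel = 1L, stride = 1L, pad = 0L, filters = g[5])
    add(name = sprintf("relu_fire%d_1x1", b), kind = "relu", from = sprintf("fire%d_1x1", b))
    add(name = sprintf("concat%d", b), kind = "concat",
        from = c(sprintf("relu_fire%d_3x3", b), sprintf("relu_fire%d_1x1", b)))
    add(name = sprintf("pool_block%d", b), kind = "maxpool", from = sprintf("concat%d", b),
        kernel = 3L, stride = 2L, pad_rb = 1L)
    prev <- sprintf("pool_block%d", b)
  }
  if (dropout_rate > 0) {
    add(name = "dropout", kind = "dropout", from = prev, rate = dropout_rate)
    prev <- "dropout"
  }
  add(name = "conv6", kind = "conv", from = prev, kernel = 1L, stride = 1L,
      pad = 0L, filters = g[6])
  add(name = "relu_conv6", kind = "relu", from = "conv6")
  add(name = "conv7", kind = "conv", from = "relu_conv6", kernel = 1L, stride = 1L,
      pad = 0L, filters = g[6])
  add(name = "relu_conv7", kind = "relu", from = "conv7")
  add(name = "global_pool", kind = "gap", from = "relu_conv7")
  add(name = "fully_connected", kind = "fc", from = "global_pool", filters = 3L)
  add(name = "softmax_output", kind = "softmax", from = "fully_connected")
  arch <- structure(list(layers = L, input_side = as.integer(input_side),
                         n_channels = as.integer(n_channels),
                         chromosome = chrom, n_inception = as.integer(n_inception)),
                    class = "clf_architecture")
  arch_shapes(arch)   # validates shape propagation
  arch
}

#' Analytic FLOPs count of an architecture
#'
#' Sums, over convolution and fully connected layers,
#' `output elements x kernel height x kernel width x input channels`
#' multiply-accumulate operations. `mac_factor = 1` (default) reports
#' MACs; `mac_factor = 2` counts the multiply and the add separately.
#'
#' @param arch an architecture list.
#' @param mac_factor 1 or 2.
#' @return non-negative numeric count.
#' @export
count_flops <- function(arch, mac_factor = 1) {
  shapes <- arch_shapes(arch)
  total <- 0
  for (ly in arch$layers) {
    if (ly$kind == "conv") {
      s_in <- shapes[[ly$from[1]]]
      s_out <- shapes[[ly$name]]
      total <- total + prod(s_out) * ly$kernel^2 * s_in[3]
    } else if (ly$kind == "fc") {
      s_in <- shapes[[ly$from[1]]]
      total <- total + s_in[3] * ly$filters
    }
  }
  total * mac_factor
}

#' Classifier training configuration
#'
#' @param epochs training epochs (each draws one fresh class-balanced
#'   batch, consumed in minibatches).
#' @param lr Adam learning rate.
#' @param batch_size balanced batch size (divisible by the class count).
#' @param minibatch gradient-step size the batch is chunked into.
#' @param seed integer seed governing initialization and batch draws.
#' @param snapshot_metric validation metric maximized by snapshot
#'   selection (`"ACC"`).
#' @param acc_convention per-class accuracy convention for the validation
#'   metric (see [per_class_metrics()]).
#' @param dropout_rate passed through to the architecture at train time.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, lr = 1e-3, batch_size = 84L, minibatch = 12L,
                         seed = 0L, snapshot_metric = "ACC",
                         acc_convention = "standard", dropout_rate = 0) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be positive")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), minibatch = as.integer(minibatch),
                 seed = as.integer(seed), snapshot_metric = snapshot_metric,
                 acc_convention = acc_convention, dropout_rate = dropout_rate),
            class = "train_config")
}

## Stack a list of input_tensors into an (H, W, C, N) array + label ints.
stack_tensors <- function(tensors) {
  d <- dim(tensors[[1]]$data)
  x <- array(0, dim = c(d, length(tensors)))
  for (i in seq_along(tensors)) x[, , , i] <- tensors[[i]]$data
  labs <- vapply(tensors, function(t) t$label %||% NA_character_, "")
  list(x = x, y = match(labs, maturity_classes()))
}

## Mean per-class ACC on a validation set.
validation_acc <- function(truth, predicted, convention) {
  tl <- tally_from_predictions(truth, predicted)
  mean(per_class_metrics(tl, convention)$ACC)
}

#' Train the classifier on cached tensors
#'
#' Cross-entropy loss with Adam. Each epoch draws one class-balanced
#' batch (fresh random composition per epoch via [epoch_reseed()]),
#' consumed in minibatch gradient steps; a snapshot with its validation
#' mean per-class accuracy is recorded per epoch.
#'
#' @param cache a `tensor_cache` covering all train and validation ids.
#' @param split one SRRS repetition: list with `train` and `validation`
#'   id vectors.
#' @param arch a `clf_architecture` whose input side/channels match the
#'   cached tensors.
#' @param cfg a [train_config()].
#' @return list of class `clf_snapshots`: per-epoch entries with
#'   `epoch`, `loss`, `val_acc` and `weights`, plus the architecture.
#' @export
train_classifier <- function(cache, split, arch, cfg = train_config()) {
  ids_needed <- c(split$train, split$validation)
  missing <- setdiff(ids_needed, cache_ids(cache))
  if (length(missing))
    stop("cache is missing record(s): ", paste(utils::head(missing, 10), collapse = ", "))
  labels <- cache_labels(cache)
  train_by_class <- split(split$train, labels[split$train])
  if (any(!maturity_classes() %in% names(train_by_class)))
    stop("training split lacks at least one class")

  val_tensors <- lapply(split$validation, function(id) cache_variant(cache, id, 1L))
  val <- stack_tensors(val_tensors)
  val_truth <- maturity_classes()[val$y]

  wts <- nn_init_weights(arch, derive_seed(cfg$seed, 1L))
  opt <- adam_new(wts)
  snapshots <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    es <- epoch_reseed(epoch, cfg$seed)
    batch_ids <- balanced_batch(train_by_class, cfg$batch_size, es)
    tensors <- with_seed(derive_seed(es, 7L),
      lapply(batch_ids, function(id) cache_variant(cache, id)))
    perm <- with_seed(derive_seed(es, 11L), sample(length(tensors)))
    tensors <- tensors[perm]
    losses <- numeric(0)
    for (at in seq(1, length(tensors), by = cfg$minibatch)) {
      chunk <- tensors[at:min(at + cfg$minibatch - 1, length(tensors))]
      mb <- stack_tensors(chunk)
      fwd <- net_forward(arch, wts, mb$x, train = TRUE,
                         dropout_seed = derive_seed(es, at))
      ce <- softmax_xent(fwd$acts$fully_connected, mb$y)
      bwd <- net_backward(arch, wts, fwd, ce$dlogits)
      upd <- adam_step(wts, bwd$grads, opt, lr = cfg$lr)
      wts <- upd$wts; opt <- upd$state
      losses <- c(losses, ce$loss)
    }
    pred <- predict_labels(arch, wts, val$x)
    snapshots[[epoch]] <- list(epoch = epoch, loss = mean(losses),
                               val_acc = validation_acc(val_truth, pred,
                                                        cfg$acc_convention),
                               weights = wts)
  }
  structure(list(snapshots = snapshots, arch = arch, cfg = cfg),
            class = "clf_snapshots")
}

## Forward a stacked batch and return predicted labels.
predict_labels <- function(arch, wts, x) {
  fwd <- net_forward(arch, wts, x)
  p <- matrix(fwd$out, nrow = 3)
  maturity_classes()[max.col(t(p), ties.method = "first")]
}

#' Select the best training snapshot
#'
#' Maximizes validation mean accuracy; ties go to the earliest epoch.
#'
#' @param snapshots a `clf_snapshots` object (or its `snapshots` list).
#' @return one snapshot of class `clf_snapshot` (with the architecture
#'   attached when available).
#' @export
select_snapshot <- function(snapshots) {
  arch <- NULL
  if (inherits(snapshots, "clf_snapshots")) {
    arch <- snapshots$arch
    snapshots <- snapshots$snapshots
  }
  if (!length(snapshots)) stop("no snapshots to select from")
  accs <- vapply(snapshots, `[[`, numeric(1), "val_acc")
  best <- snapshots[[which.max(accs)]]    # which.max takes the earliest tie
  best$arch <- arch
  class(best) <- "clf_snapshot"
  best
}

#' Classify one input tensor with a trained snapshot
#'
#' @param tensor an `input_tensor` matching the snapshot's input
#'   geometry.
#' @param snapshot a `clf_snapshot` from [select_snapshot()].
#' @return list with `label` and `probs` (named triple summing to 1).
#' @export
classify <- function(tensor, snapshot) {
  stopifnot(inherits(tensor, "input_tensor"))
  arch <- snapshot$arch
  d <- dim(tensor$data)
  if (d[1] != arch$input_side || d[2] != arch$input_side || d[3] != arch$n_channels)
    stop("tensor shape ", paste(d, collapse = "x"),
         " does not match the snapshot input ",
         arch$input_side, "x", arch$input_side, "x", arch$n_channels)
  x <- array(tensor$data, dim = c(d, 1L))
  fwd <- net_forward(arch, snapshot$weights, x)
  p <- as.vector(fwd$out)
  names(p) <- maturity_classes()
  list(label = names(p)[which.max(p)], probs = p)
}
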