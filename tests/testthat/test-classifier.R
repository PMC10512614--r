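# Independent shape/FLOPs oracle: explicit per-layer arithmetic, coded
# separately from the package's graph walker.
oracle_shapes_flops <- function(genes, n_channels, n_blocks, side) {
  conv_out <- function(s, k, st, p) (s + 2 * p - k) %/% st + 1
  pool_out <- function(s, k, st, pr) (s + pr - k) %/% st + 1
  flops <- 0
  s <- conv_out(side, 3, 2, 0); c_in <- n_channels
  flops <- flops + s^2 * 9 * c_in * genes[1]; c_in <- genes[1]   # stem conv
  s <- pool_out(s, 3, 2, 0)
  flops <- flops + s^2 * 1 * c_in * genes[2]; c_in <- genes[2]   # 1x1 conv
  s <- pool_out(s, 3, 2, 0)
  for (b in seq_len(n_blocks)) {
    flops <- flops + s^2 * c_in * genes[3]                       # squeeze
    flops <- flops + s^2 * 9 * genes[3] * genes[4]               # 3x3 branch (pad 1)
    flops <- flops + s^2 * 1 * genes[3] * genes[5]               # 1x1 branch
    c_in <- genes[4] + genes[5]
    s <- pool_out(s, 3, 2, 1)
  }
  flops <- flops + s^2 * c_in * genes[6]                         # head conv 1
  flops <- flops + s^2 * genes[6] * genes[6]                     # head conv 2
  flops <- flops + genes[6] * 3                                  # fully connected
  list(side = s, flops = flops)
}

test_that("chromosome validation enforces length, parity and bounds", {
  expect_s3_class(chromosome(c(2, 128, 64, 4, 6, 8)), "chromosome")
  expect_error(chromosome(c(2, 4)), "6 genes")
  expect_error(chromosome(c(3, 4, 6, 8, 10, 12)), "even")
  expect_error(chromosome(c(0, 4, 6, 8, 10, 12)), "\\[2, 128\\]")
  expect_error(chromosome(c(130, 4, 6, 8, 10, 12)), "\\[2, 128\\]")
})

test_that("the reference chromosome reproduces the published filter column and stem activation", {
  arch <- build_architecture(reference_chromosome(), 2, 1, 590)
  s <- arch_shapes(arch)
  expect_equal(s$conv1, c(294L, 294L, 32L))
  expect_equal(s$conv2[3], 16L)
  expect_equal(s$squeeze1, c(72L, 72L, 8L))
  expect_equal(s$fire1_3x3, c(72L, 72L, 28L))
  expect_equal(s$fire1_1x1[3], 28L)
  expect_equal(s$concat1, c(72L, 72L, 56L))
  expect_equal(s$pool_block1, c(36L, 36L, 56L))
  expect_equal(s$conv6, c(36L, 36L, 4L))
  expect_equal(s$conv7, c(36L, 36L, 4L))
  expect_equal(s$global_pool, c(1L, 1L, 4L))
  expect_equal(s$fully_connected[3], 3L)
})

test_that("zero inception blocks produce no concatenation layer", {
  arch <- build_architecture(reference_chromosome(), 2, 0, 128)
  kinds <- vapply(arch$layers, `[[`, "", "kind")
  expect_false("concat" %in% kinds)
  expect_error(build_architecture(reference_chromosome(), 2, 5, 590), "n_inception")
  expect_error(build_architecture(c(2, 4, 6, 8, 10, 12, 14), 2, 1, 590), "6 genes")
})

test_that("shape propagation matches the independent oracle on random chromosomes", {
  set.seed(9)
  for (i in 1:20) {
    genes <- 2 * sample(1:64, 6, replace = TRUE)
    blocks <- sample(0:2, 1)
    side <- sample(c(96, 128, 160), 1)
    arch <- build_architecture(chromosome(genes), 2, blocks, side)
    s <- arch_shapes(arch)
    expect_equal(s$relu_conv7[1], oracle_shapes_flops(genes, 2, blocks, side)$side)
  }
})

test_that("FLOPs match the independent per-layer count on reference and random structures", {
  cases <- list(
    list(genes = c(32, 16, 8, 28, 28, 4), ch = 2, blocks = 1, side = 590),
    list(genes = c(32, 16, 8, 28, 28, 4), ch = 1, blocks = 1, side = 590),
    list(genes = c(2, 2, 2, 2, 2, 2), ch = 1, blocks = 0, side = 96),
    list(genes = c(128, 128, 128, 128, 128, 128), ch = 15, blocks = 2, side = 160),
    list(genes = c(64, 32, 16, 24, 24, 8), ch = 14, blocks = 2, side = 550),
    list(genes = c(8, 10, 12, 14, 16, 18), ch = 3, blocks = 1, side = 128))
  for (cs in cases) {
    arch <- build_architecture(chromosome(cs$genes), cs$ch, cs$blocks, cs$side)
    expect_equal(count_flops(arch),
                 oracle_shapes_flops(cs$genes, cs$ch, cs$blocks, cs$side)$flops)
    expect_equal(count_flops(arch, 2), 2 * count_flops(arch))
  }
  # published reference structure: order-of-magnitude agreement with the
  # printed 160.60e6 under the 2-FLOPs-per-MAC convention
  ref <- count_flops(build_architecture(reference_chromosome(), 2, 1, 590), 2)
  expect_gt(ref, 160.60e6 / 2)
  expect_lt(ref, 160.60e6 * 2)
})

test_that("a tiny 1x1 convolution costs exactly one MAC", {
  arch <- list(layers = list(list(name = "c", kind = "conv", from = "input",
                                  kernel = 1L, stride = 1L, pad = 0L, filters = 1L)),
               input_side = 1L, n_channels = 1L)
  expect_equal(count_flops(arch), 1)
  expect_equal(count_flops(arch, 2), 2)
})

test_that("FLOPs are monotone in filter counts, input side, and block count", {
  base <- c(16, 16, 8, 12, 12, 6)
  f0 <- count_flops(build_architecture(chromosome(base), 2, 1, 128))
  for (g in 1:6) {
    up <- base; up[g] <- up[g] * 2
    expect_gte(count_flops(build_architecture(chromosome(up), 2, 1, 128)), f0)
  }
  expect_gt(count_flops(build_architecture(chromosome(base), 2, 1, 256)), f0)
  f_blocks <- vapply(0:2, function(b)
    count_flops(build_architecture(chromosome(base), 2, b, 128)), numeric(1))
  expect_true(all(diff(f_blocks) > 0))
})

test_that("snapshot selection is argmax with earliest-epoch ties", {
  snaps <- lapply(seq_along(c(0.5, 0.9, 0.8)), function(i)
    list(epoch = i, val_acc = c(0.5, 0.9, 0.8)[i], weights = list()))
  expect_equal(select_snapshot(snaps)$epoch, 2)
  ties <- lapply(1:4, function(i) list(epoch = i, val_acc = 0.7, weights = list()))
  expect_equal(select_snapshot(ties)$epoch, 1)
  expect_error(select_snapshot(list()), "no snapshots")
  set.seed(10)
  for (i in 1:1000) {
    accs <- round(runif(sample(2:10, 1)), 2)
    snaps <- lapply(seq_along(accs), function(k) list(epoch = k, val_acc = accs[k]))
    expect_equal(select_snapshot(snaps)$epoch, which.max(accs))
  }
})

test_that("one-epoch training on a handful of phantoms yields a finite snapshot", {
  recs <- fix_ds$records[c("MI_0001", "MI_0002", "MII_0001", "MII_0002",
                           "PI_0001", "PI_0002")]
  cache <- memory_cache(recs, fix_selection)
  split <- list(train = names(recs), validation = names(recs))
  arch <- build_architecture(reference_chromosome(), 2, 1, 64)
  out <- train_classifier(cache, split, arch,
                          train_config(epochs = 1, batch_size = 6, minibatch = 6, seed = 1))
  expect_length(out$snapshots, 1)
  expect_true(is.finite(out$snapshots[[1]]$loss))
  expect_true(out$snapshots[[1]]$val_acc >= 0 && out$snapshots[[1]]$val_acc <= 1)
  # missing cached records are reported
  expect_error(train_classifier(cache, list(train = c(names(recs), "ghost"),
                                            validation = names(recs)),
                                arch, train_config(epochs = 1)), "ghost")
})

test_that("loss approaches zero in the one-class separable limit", {
  # all targets identical: the head bias alone can drive the loss to zero
  arch <- build_architecture(chromosome(c(8, 8, 4, 8, 8, 4)), 2, 1, 31)
  wts <- nn_init_weights(arch, 1)
  opt <- oostage:::adam_new(wts)
  x <- array(runif(31 * 31 * 2 * 4), dim = c(31, 31, 2, 4))
  y <- rep(2L, 4)
  loss <- NA
  for (i in 1:60) {
    fwd <- oostage:::net_forward(arch, wts, x)
    ce <- oostage:::softmax_xent(fwd$acts$fully_connected, y)
    bwd <- oostage:::net_backward(arch, wts, fwd, ce$dlogits)
    upd <- oostage:::adam_step(wts, bwd$grads, opt, lr = 5e-2)
    wts <- upd$wts; opt <- upd$state
    loss <- ce$loss
  }
  expect_lt(loss, 0.05)
})

test_that("training separates the phantom classes from the GV/FPB channels", {
  cache <- memory_cache(fix_ds$records, fix_selection)
  split <- srrs_split(fix_ds$manifest,
                      srrs_plan(1, c(MI = 3, MII = 3, PI = 3),
                                c(MI = 2, MII = 2, PI = 2), seed = 1))$repetitions[[1]]
  arch <- build_architecture(reference_chromosome(), 2, 1, 64)
  out <- train_classifier(cache, split, arch,
                          train_config(epochs = 8, lr = 3e-3, seed = 3))
  losses <- vapply(out$snapshots, `[[`, numeric(1), "loss")
  expect_lt(losses[8], losses[1])
  expect_gte(select_snapshot(out)$val_acc, 0.9)
})

test_that("classification returns a normalized probability triple, deterministically", {
  recs <- fix_ds$records[c("MI_0001", "MII_0001", "PI_0001")]
  cache <- memory_cache(recs, fix_selection)
  split <- list(train = names(recs), validation = names(recs))
  arch <- build_architecture(chromosome(c(8, 8, 4, 8, 8, 4)), 2, 1, 64)
  snap <- select_snapshot(train_classifier(cache, split, arch,
                                           train_config(epochs = 1, batch_size = 3,
                                                        minibatch = 3, seed = 3)))
  t <- assemble_tensor(fix_ds$records$PI_0003, fix_selection)
  r1 <- classify(t, snap)
  expect_equal(sum(r1$probs), 1, tolerance = 1e-6)
  expect_true(all(r1$probs >= 0))
  expect_identical(classify(t, snap), r1)
  expect_equal(r1$label, names(which.max(r1$probs)))
  bad <- assemble_tensor(fix_ds$records$PI_0003, channel_selection("germinal_vesicle"))
  expect_error(classify(bad, snap), "does not match")
})
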