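# Finite-difference validation of the engine's analytic gradients, plus
# kernel-level checks against naive reference computations.

num_grad <- function(fun, wts, nm, part, idx, eps = 1e-6) {
  up <- wts; up[[nm]][[part]][idx] <- up[[nm]][[part]][idx] + eps
  dn <- wts; dn[[nm]][[part]][idx] <- dn[[nm]][[part]][idx] - eps
  (fun(up) - fun(dn)) / (2 * eps)
}

test_that("convolution forward matches a naive direct computation", {
  set.seed(5)
  x <- array(rnorm(7 * 7 * 2 * 1), dim = c(7, 7, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
  b <- rnorm(3)
  y <- oostage:::cpp_conv_fw(x, w, b, 2L, 1L)
  # naive loop with zero padding, stride 2, pad 1
  H <- 7; k <- 3; s <- 2; p <- 1
  Ho <- (H + 2 * p - k) %/% s + 1
  for (co in 1:3) for (io in 1:Ho) for (jo in 1:Ho) {
    acc <- b[co]
    for (ci in 1:2) for (u in 1:k) for (v in 1:k) {
      i <- (io - 1) * s + u - p; j <- (jo - 1) * s + v - p
      if (i >= 1 && i <= H && j >= 1 && j <= H)
        acc <- acc + x[i, j, ci, 1] * w[u, v, ci, co]
    }
    expect_equal(y[io, jo, co, 1], acc, tolerance = 1e-10)
  }
})

test_that("maxpool forward/backward match naive pooling incl. the padded edge", {
  set.seed(6)
  x <- array(rnorm(7 * 7 * 1 * 1), dim = c(7, 7, 1, 1))
  r <- oostage:::cpp_maxpool_fw(x, 3L, 2L, 1L)   # (7+1-3)/2+1 = 3
  expect_equal(dim(r$y), c(3L, 3L, 1L, 1L))
  for (io in 1:3) for (jo in 1:3) {
    ri <- ((io - 1) * 2 + 1):min((io - 1) * 2 + 3, 7)
    ci <- ((jo - 1) * 2 + 1):min((jo - 1) * 2 + 3, 7)
    expect_equal(r$y[io, jo, 1, 1], max(x[ri, ci, 1, 1]))
  }
})

test_that("analytic gradients agree with central differences on the classifier graph", {
  set.seed(7)
  arch <- build_architecture(chromosome(c(4, 4, 4, 6, 6, 4)), 2, 1, 31)
  wts <- nn_init_weights(arch, 2)
  x <- array(runif(31 * 31 * 2 * 3), dim = c(31, 31, 2, 3))
  y <- c(1L, 2L, 3L)
  lossf <- function(w) {
    fwd <- oostage:::net_forward(arch, w, x)
    oostage:::softmax_xent(fwd$acts$fully_connected, y)$loss
  }
  fwd <- oostage:::net_forward(arch, wts, x)
  ce <- oostage:::softmax_xent(fwd$acts$fully_connected, y)
  bwd <- oostage:::net_backward(arch, wts, fwd, ce$dlogits)
  for (nm in names(bwd$grads)) {
    for (rep in 1:3) {
      idx <- sample(length(wts[[nm]]$w), 1)
      expect_equal(bwd$grads[[nm]]$w[idx], num_grad(lossf, wts, nm, "w", idx),
                   tolerance = 1e-4)
    }
    idx <- sample(length(wts[[nm]]$b), 1)
    expect_equal(bwd$grads[[nm]]$b[idx], num_grad(lossf, wts, nm, "b", idx),
                 tolerance = 1e-4)
  }
})

test_that("analytic gradients agree with central differences on the segmenter graph", {
  set.seed(8)
  arch <- seg_architecture(8, 3, 4)
  wts <- nn_init_weights(arch, 3)
  x <- array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  tgt <- array(sample(1:3, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  cw <- c(0.5, 2, 3)
  lossf <- function(w) {
    fwd <- oostage:::net_forward(arch, w, x)
    oostage:::pixel_xent(fwd$acts$head, tgt, cw)$loss
  }
  fwd <- oostage:::net_forward(arch, wts, x)
  ce <- oostage:::pixel_xent(fwd$acts$head, tgt, cw)
  bwd <- oostage:::net_backward(arch, wts, fwd, ce$dlogits)
  for (nm in names(bwd$grads)) {
    idx <- sample(length(wts[[nm]]$w), 2)
    for (i in idx)
      expect_equal(bwd$grads[[nm]]$w[i], num_grad(lossf, wts, nm, "w", i),
                   tolerance = 1e-4)
  }
})

test_that("Adam drives a tiny least-squares-style objective downhill", {
  arch <- seg_architecture(8, 3, 4)
  wts <- nn_init_weights(arch, 4)
  opt <- oostage:::adam_new(wts)
  x <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  tgt <- array(rep(c(1L, 2L), each = 64), dim = c(8, 8, 2))
  losses <- numeric(50)
  for (i in 1:50) {
    fwd <- oostage:::net_forward(arch, wts, x)
    ce <- oostage:::pixel_xent(fwd$acts$head, tgt)
    bwd <- oostage:::net_backward(arch, wts, fwd, ce$dlogits)
    upd <- oostage:::adam_step(wts, bwd$grads, opt, lr = 1e-2)
    wts <- upd$wts; opt <- upd$state
    losses[i] <- ce$loss
  }
  expect_lt(losses[50], 0.1 * losses[1])
})

test_that("upsampling forward/backward are exact nearest-neighbor adjoints", {
  x <- array(rnorm(3 * 3 * 2 * 1), dim = c(3, 3, 2, 1))
  y <- oostage:::cpp_upsample_fw(x, 2L)
  expect_equal(dim(y), c(6L, 6L, 2L, 1L))
  expect_equal(y[1, 1, 1, 1], x[1, 1, 1, 1])
  expect_equal(y[2, 2, 1, 1], x[1, 1, 1, 1])
  dy <- array(1, dim = dim(y))
  dx <- oostage:::cpp_upsample_bw(dy, 2L)
  expect_true(all(dx == 4))
})
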