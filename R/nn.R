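## Minimal trainable CNN engine over the RcppArmadillo kernels.
##
## A network is a plain list: `layers` is a topologically ordered list of
## descriptors (kind, from, kernel, stride, pad, filters, ...) plus the
## input geometry.  Activations are (H, W, C, N) arrays; weights live in a
## named list keyed by layer name.

#' Propagate activation shapes through an architecture
#'
#' Walks the layer list and computes each layer's output shape
#' `(height, width, channels)`, validating consistency as it goes.
#'
#' @param arch architecture list as produced by [build_architecture()] or
#'   [seg_architecture()].
#' @return named list mapping layer name to an integer `c(H, W, C)`.
#' @export
arch_shapes <- function(arch) {
  shapes <- list(input = c(arch$input_side, arch$input_side, arch$n_channels))
  for (ly in arch$layers) {
    ins <- lapply(ly$from, function(nm) {
      s <- shapes[[nm]]
      if (is.null(s)) stop("layer '", ly$name, "' reads unknown layer '", nm, "'")
      s
    })
    s <- ins[[1]]
    out <- switch(ly$kind,
      conv = {
        k <- ly$kernel; p <- ly$pad %||% 0L; st <- ly$stride %||% 1L
        c((s[1] + 2 * p - k) %/% st + 1L, (s[2] + 2 * p - k) %/% st + 1L, ly$filters)
      },
      relu = s,
      dropout = s,
      maxpool = {
        k <- ly$kernel; st <- ly$stride; pr <- ly$pad_rb %||% 0L
        c((s[1] + pr - k) %/% st + 1L, (s[2] + pr - k) %/% st + 1L, s[3])
      },
      concat = {
        if (length(ins) < 2) stop("concat layer '", ly$name, "' needs >= 2 inputs")
        hw <- vapply(ins, function(z) z[1:2], numeric(2))
        if (any(hw != hw[, 1])) stop("concat '", ly$name, "' inputs differ in spatial size")
        c(s[1], s[2], sum(vapply(ins, function(z) z[3], numeric(1))))
      },
      upsample = c(s[1] * ly$factor, s[2] * ly$factor, s[3]),
      gap = c(1L, 1L, s[3]),
      fc = c(1L, 1L, ly$filters),
      softmax = s,
      stop("unknown layer kind '", ly$kind, "'")
    )
    if (any(out[1:2] < 1)) stop("layer '", ly$name, "' collapses to zero spatial size")
    shapes[[ly$name]] <- as.integer(out)
  }
  shapes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' He-style weight initialization for a network
#'
#' Convolution and fully connected layers get N(0, sqrt(2 / fan_in))
#' weights and zero biases.
#'
#' @param arch architecture list.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return named list of `list(w, b)` per parameterized layer.
#' @export
nn_init_weights <- function(arch, seed = 0L) {
  shapes <- arch_shapes(arch)
  with_seed(seed, {
    wts <- list()
    for (ly in arch$layers) {
      if (ly$kind == "conv") {
        cin <- shapes[[ly$from[1]]][3]
        k <- ly$kernel
        fan_in <- k * k * cin
        w <- array(stats::rnorm(k * k * cin * ly$filters, sd = sqrt(2 / fan_in)),
                   dim = c(k, k, cin, ly$filters))
        wts[[ly$name]] <- list(w = w, b = numeric(ly$filters))
      } else if (ly$kind == "fc") {
        cin <- shapes[[ly$from[1]]][3]
        w <- matrix(stats::rnorm(cin * ly$filters, sd = sqrt(2 / cin)), cin, ly$filters)
        wts[[ly$name]] <- list(w = w, b = numeric(ly$filters))
      }
    }
    wts
  })
}

## Forward pass. Returns list(out = last activation, acts, pools).
## `train` only matters for dropout layers.
net_forward <- function(arch, wts, x, train = FALSE, dropout_seed = 0L) {
  acts <- list(input = x)
  pools <- list()
  drops <- list()
  last <- "input"
  for (ly in arch$layers) {
    a <- acts[[ly$from[1]]]
    y <- switch(ly$kind,
      conv = cpp_conv_fw(a, wts[[ly$name]]$w, wts[[ly$name]]$b,
                         as.integer(ly$stride %||% 1L), as.integer(ly$pad %||% 0L)),
      relu = { a[a < 0] <- 0; a },
      dropout = {
        if (train && (ly$rate %||% 0) > 0) {
          m <- with_seed(dropout_seed, array(stats::runif(length(a)) >= ly$rate, dim = dim(a)))
          drops[[ly$name]] <- m
          a * m / (1 - ly$rate)
        } else a
      },
      maxpool = {
        r <- cpp_maxpool_fw(a, as.integer(ly$kernel), as.integer(ly$stride),
                            as.integer(ly$pad_rb %||% 0L))
        pools[[ly$name]] <- r$idx
        r$y
      },
      concat = {
        parts <- lapply(ly$from, function(nm) acts[[nm]])
        d <- dim(parts[[1]])
        cs <- vapply(parts, function(p) dim(p)[3], numeric(1))
        out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
        at <- 0L
        for (p in parts) {
          out[, , (at + 1L):(at + dim(p)[3]), ] <- p
          at <- at + dim(p)[3]
        }
        out
      },
      upsample = cpp_upsample_fw(a, as.integer(ly$factor)),
      gap = {
        d <- dim(a)
        m <- apply(a, c(3, 4), mean)           # (C, N)
        array(m, dim = c(1L, 1L, d[3], d[4]))
      },
      fc = {
        d <- dim(a)
        m <- matrix(a, nrow = d[3], ncol = d[4])  # (Cin, N); H=W=1 upstream
        z <- t(wts[[ly$name]]$w) %*% m + wts[[ly$name]]$b
        array(z, dim = c(1L, 1L, nrow(z), d[4]))
      },
      softmax = {
        d <- dim(a)
        m <- matrix(a, nrow = d[3], ncol = d[4])
        m <- exp(sweep(m, 2, apply(m, 2, max)))
        m <- sweep(m, 2, colSums(m), "/")
        array(m, dim = d)
      },
      stop("unknown layer kind '", ly$kind, "'")
    )
    acts[[ly$name]] <- y
    last <- ly$name
  }
  list(out = acts[[last]], acts = acts, pools = pools, drops = drops, last = last)
}

## Backward pass from gradient `dout` w.r.t. the last layer's output
## (softmax layers are expected to be bypassed: pass d/dlogits directly
## at the layer feeding the softmax). Returns list(grads, dx).
net_backward <- function(arch, wts, fwd, dout) {
  dacts <- list()
  dacts[[fwd$last]] <- dout
  grads <- list()
  add_grad <- function(nm, g) {
    if (is.null(dacts[[nm]])) dacts[[nm]] <<- g else dacts[[nm]] <<- dacts[[nm]] + g
  }
  for (ly in rev(arch$layers)) {
    dy <- dacts[[ly$name]]
    if (is.null(dy)) next
    a <- fwd$acts[[ly$from[1]]]
    switch(ly$kind,
      conv = {
        r <- cpp_conv_bw(a, wts[[ly$name]]$w, dy,
                         as.integer(ly$stride %||% 1L), as.integer(ly$pad %||% 0L))
        grads[[ly$name]] <- list(w = r$dw, b = r$db)
        add_grad(ly$from[1], r$dx)
      },
      relu = {
        g <- dy
        g[a <= 0] <- 0
        add_grad(ly$from[1], g)
      },
      dropout = {
        m <- fwd$drops[[ly$name]]
        add_grad(ly$from[1], if (is.null(m)) dy else dy * m / (1 - ly$rate))
      },
      maxpool = add_grad(ly$from[1],
        cpp_maxpool_bw(dim(a), fwd$pools[[ly$name]], dy)),
      concat = {
        at <- 0L
        for (nm in ly$from) {
          cc <- dim(fwd$acts[[nm]])[3]
          add_grad(nm, dy[, , (at + 1L):(at + cc), , drop = FALSE])
          at <- at + cc
        }
      },
      upsample = add_grad(ly$from[1], cpp_upsample_bw(dy, as.integer(ly$factor))),
      gap = {
        d <- dim(a)
        g <- array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
        add_grad(ly$from[1], g)
      },
      fc = {
        d <- dim(a)
        m <- matrix(a, nrow = d[3], ncol = d[4])
        dym <- matrix(dy, nrow = dim(dy)[3], ncol = d[4])
        grads[[ly$name]] <- list(w = m %*% t(dym), b = rowSums(dym))
        add_grad(ly$from[1], array(wts[[ly$name]]$w %*% dym, dim = d))
      },
      softmax = add_grad(ly$from[1], dy),   # only valid if dy is d/dlogits
      stop("unknown layer kind in backward: ", ly$kind)
    )
  }
  list(grads = grads, dx = dacts[["input"]])
}

## ---- Adam -------------------------------------------------------------

adam_new <- function(wts) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(wts)) {
    st$m[[nm]] <- lapply(wts[[nm]], function(p) p * 0)
    st$v[[nm]] <- lapply(wts[[nm]], function(p) p * 0)
  }
  st
}

adam_step <- function(wts, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      g <- grads[[nm]][[p]]
      st$m[[nm]][[p]] <- beta1 * st$m[[nm]][[p]] + (1 - beta1) * g
      st$v[[nm]][[p]] <- beta2 * st$v[[nm]][[p]] + (1 - beta2) * g * g
      mh <- st$m[[nm]][[p]] / bc1
      vh <- st$v[[nm]][[p]] / bc2
      wts[[nm]][[p]] <- wts[[nm]][[p]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(wts = wts, state = st)
}

## ---- losses -----------------------------------------------------------

## Cross-entropy over class logits (3 x N matrix view); y is an integer
## vector of 1-based class indices. Returns loss and d/dlogits.
softmax_xent <- function(logits, y) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[3], ncol = d[4])
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  n <- length(y)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  dp <- p
  dp[cbind(y, seq_len(n))] <- dp[cbind(y, seq_len(n))] - 1
  list(loss = loss, dlogits = array(dp / n, dim = d), probs = p)
}

## Per-pixel cross-entropy for segmentation. logits (H, W, K, N),
## target integer array (H, W, N) of 1-based class ids. Optional
## per-class weights counter the background/foreground pixel imbalance.
pixel_xent <- function(logits, target, class_weights = NULL) {
  d <- dim(logits)
  H <- d[1]; W <- d[2]; K <- d[3]; N <- d[4]
  m <- matrix(aperm(logits, c(3, 1, 2, 4)), nrow = K)   # K x (H*W*N)
  m <- sweep(m, 2, apply(m, 2, max))
  e <- exp(m)
  p <- sweep(e, 2, colSums(e), "/")
  tgt <- as.vector(target)                              # column order matches
  n <- length(tgt)
  wv <- if (is.null(class_weights)) rep(1, n) else class_weights[tgt]
  wn <- wv / sum(wv)
  loss <- -sum(wn * log(pmax(p[cbind(tgt, seq_len(n))], 1e-12)))
  dp <- sweep(p, 2, wn, "*")
  dp[cbind(tgt, seq_len(n))] <- dp[cbind(tgt, seq_len(n))] - wn
  dl <- aperm(array(dp, dim = c(K, H, W, N)), c(2, 3, 1, 4))
  list(loss = loss, dlogits = dl,
       probs = aperm(array(p, dim = c(K, H, W, N)), c(2, 3, 1, 4)))
}
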