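## Shared helpers: scoped RNG, seed derivation, raster primitives.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's RNG stream. All package randomness funnels through this.
#'
#' @param seed non-negative integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0)
    stop("seed must be a single non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a child seed from a base seed and a stream index
#'
#' Deterministic splitting of one user-facing seed into independent
#' per-stage / per-epoch streams, kept below 2^31.
#'
#' @param base integer base seed.
#' @param index non-negative integer stream index.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base, index) {
  b <- as.double(base) %% 2147483647
  i <- as.double(index) %% 2147483647
  as.integer((b * 48271 + i * 16807 + 12345) %% 2147483647)
}

## Nearest-neighbor resize of a 2-D matrix to (h, w).
resize_nearest <- function(m, h, w) {
  ri <- pmin(nrow(m), pmax(1L, as.integer(floor((seq_len(h) - 0.5) * nrow(m) / h) + 1L)))
  ci <- pmin(ncol(m), pmax(1L, as.integer(floor((seq_len(w) - 0.5) * ncol(m) / w) + 1L)))
  m[ri, ci, drop = FALSE]
}

## Bilinear resize via EBImage (used on image-intensity planes).
resize_bilinear <- function(m, h, w) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w, filter = "bilinear"))
}

## Zero-pad a 2-D matrix symmetrically up to (h, w) (centered; odd slack
## goes to the bottom/right edge).
pad_to <- function(m, h, w) {
  if (nrow(m) > h || ncol(m) > w) stop("pad_to: matrix larger than target")
  out <- matrix(0, h, w)
  r0 <- (h - nrow(m)) %/% 2
  c0 <- (w - ncol(m)) %/% 2
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

## Integer translation with zero fill (positive = down/right).
translate_int <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

## Filled ellipse mask: center (cy, cx), semi-axes (ry, rx), rotation phi.
ellipse_mask <- function(side, cy, cx, ry, rx, phi = 0) {
  y <- matrix(seq_len(side), side, side) - cy
  x <- matrix(seq_len(side), side, side, byrow = TRUE) - cx
  u <- cos(phi) * y + sin(phi) * x
  v <- -sin(phi) * y + cos(phi) * x
  (u / ry)^2 + (v / rx)^2 <= 1
}

binarize <- function(m) (m > 0.5) * 1
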