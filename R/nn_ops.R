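# Low-level neural-network primitives with hand-derived backward passes.
# All arrays are column-major (H, W, C); convolutions are "valid" with
# stride 1 on an input that has already been zero-padded.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_stable <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Linear indices of all filter-sized patches of an (H, W, C) array: one row
# per output position (output row index fastest), one column per
# within-patch offset (dh fastest, then dw, then channel). Patch extraction
# is then a single indexed read. Cached per shape: the index matrix is
# reused for every pair scored against the same architecture.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_patch_idx <- function(H, W, C, fh, fw) {
  key <- paste(H, W, C, fh, fw, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- H - fh + 1L; ow <- W - fw + 1L
  if (oh < 1 || ow < 1) stop("filter larger than input", call. = FALSE)
  poslin <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * H, "+"))
  off <- as.vector(outer(as.vector(outer(0:(fh - 1L), (0:(fw - 1L)) * H, "+")),
                         (0:(C - 1L)) * H * W, "+"))
  out <- list(idx = outer(poslin, off, "+"), oh = oh, ow = ow)
  .conv_idx_cache[[key]] <- out
  out
}

#' Convolution layer (valid, stride 1) with ReLU
#'
#' Applies `nf` filters to a pre-padded input and rectifies. The input may be
#' a plain matrix (treated as one channel) or an `(H, W, C)` array; filters
#' are an `(fh, fw, C, nf)` array. Output spatial size is
#' `(H - fh + 1) x (W - fw + 1)`.
#'
#' @param x input matrix or 3-d array.
#' @param filters `(fh, fw, C, nf)` weight array.
#' @param bias numeric vector of length `nf`.
#' @return `(oh, ow, nf)` array of rectified feature maps (attribute
#'   `cache` holds intermediates for the backward pass).
#' @examples
#' f <- array(1, c(1, 1, 1, 1))
#' conv_layer(matrix(c(-1, 2, 3, -4), 2), f, 0)[, , 1]  # ReLU of the input
#' @export
conv_layer <- function(x, filters, bias) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  dims <- dim(x); H <- dims[1]; W <- dims[2]; C <- dims[3]
  fd <- dim(filters)
  if (length(fd) != 4 || fd[3] != C)
    stop("filters must be (fh, fw, ", C, ", nf)", call. = FALSE)
  pi <- conv_patch_idx(H, W, C, fd[1], fd[2])
  patches <- matrix(x[as.vector(pi$idx)], nrow(pi$idx))
  Wmat <- matrix(filters, fd[1] * fd[2] * C, fd[4])
  Z0 <- patches %*% Wmat
  Z0 <- Z0 + rep(bias, each = nrow(Z0))
  mask <- Z0 > 0
  Z <- Z0 * mask
  out <- array(Z, c(pi$oh, pi$ow, fd[4]))
  attr(out, "cache") <- list(patches = patches, mask = mask, idx = pi$idx,
                             Wmat = Wmat, in_dim = dims, fdim = fd)
  out
}

# Backward through conv_layer. dZ: gradient w.r.t. the rectified output.
# Returns dW, db and (optionally) dx.
conv_layer_backward <- function(dZ, cache, need_dx = TRUE) {
  fd <- cache$fdim
  dZmat <- matrix(dZ, nrow(cache$mask), fd[4]) * cache$mask
  dW <- array(crossprod(cache$patches, dZmat), fd)
  db <- colSums(dZmat)
  dx <- NULL
  if (need_dx) {
    dpatch <- dZmat %*% t(cache$Wmat)
    dxv <- numeric(prod(cache$in_dim))
    rs <- rowsum(as.vector(dpatch), group = as.vector(cache$idx))
    dxv[as.integer(rownames(rs))] <- rs
    dx <- array(dxv, cache$in_dim)
  }
  list(dW = dW, db = db, dx = dx)
}

#' Max pooling
#'
#' Non-overlapping max pooling (stride defaults to the window); trailing
#' partial windows are dropped, and the window is truncated to the map size
#' when the map is smaller than the window. A general stride is supported
#' for completeness via a direct (slower) path.
#'
#' @param x matrix or `(H, W, C)` array.
#' @param window integer `c(Wm, Wp)` pooling window.
#' @param stride integer `c(s_r, s_c)`; defaults to `window`.
#' @return Pooled array (attribute `cache` for the backward pass when stride
#'   equals window).
#' @examples
#' max_pool(matrix(1:16, 4), c(2, 2))[, , 1]
#' @export
max_pool <- function(x, window = c(2L, 2L), stride = window) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  ph <- min(as.integer(window[1]), H); pw <- min(as.integer(window[2]), W)
  stride <- as.integer(stride)
  if (!identical(stride, as.integer(window)) &&
      !(stride[1] == ph && stride[2] == pw)) {
    return(max_pool_strided(x, c(ph, pw), stride))
  }
  oh <- H %/% ph; ow <- W %/% pw
  xc <- x[seq_len(oh * ph), seq_len(ow * pw), , drop = FALSE]
  m <- array(xc, c(ph, oh, pw, ow, C))
  m2 <- aperm(m, c(1, 3, 2, 4, 5))
  mm <- matrix(m2, ph * pw)
  am <- max.col(t(mm), ties.method = "first")
  pooled <- mm[cbind(am, seq_along(am))]
  out <- array(pooled, c(oh, ow, C))
  attr(out, "cache") <- list(am = am, ph = ph, pw = pw, oh = oh, ow = ow,
                             C = C, in_dim = d)
  out
}

max_pool_strided <- function(x, window, stride) {
  d <- dim(x)
  oh <- (d[1] - window[1]) %/% stride[1] + 1L
  ow <- (d[2] - window[2]) %/% stride[2] + 1L
  out <- array(0, c(oh, ow, d[3]))
  for (c in seq_len(d[3]))
    for (a in seq_len(oh))
      for (b in seq_len(ow)) {
        r0 <- (a - 1L) * stride[1] + 1L; c0 <- (b - 1L) * stride[2] + 1L
        out[a, b, c] <- max(x[r0:(r0 + window[1] - 1L),
                              c0:(c0 + window[2] - 1L), c])
      }
  out
}

max_pool_backward <- function(dout, cache) {
  with(cache, {
    dmm <- matrix(0, ph * pw, oh * ow * C)
    dmm[cbind(am, seq_along(am))] <- as.vector(dout)
    dm2 <- array(dmm, c(ph, pw, oh, ow, C))
    dm <- aperm(dm2, c(1, 3, 2, 4, 5))
    dxc <- array(dm, c(ph * oh, pw * ow, C))
    dx <- array(0, in_dim)
    dx[seq_len(ph * oh), seq_len(pw * ow), ] <- dxc
    dx
  })
}
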