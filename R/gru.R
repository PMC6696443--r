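# Gated recurrent unit, bidirectional path encoder and path-level attention,
# with hand-derived backward passes (backpropagation through time).

#' One GRU step
#'
#' Computes the update gate `z = sigmoid(Wz x + Uz h + bz)`, reset gate
#' `r = sigmoid(Wr x + Ur h + br)`, candidate state
#' `h~ = tanh(Wh x + r * (Uh h) + bh)` and the new state
#' `h' = (1 - z) * h + z * h~`. With `z` near 1 the state follows the
#' candidate; near 0 it carries the previous state through; a zero reset
#' gate makes the candidate forget all history.
#'
#' @param x input (node feature) vector.
#' @param h_prev previous hidden state.
#' @param params list with `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh` (input
#'   weights `hidden x length(x)`, recurrent weights `hidden x hidden`).
#' @return New hidden state vector (attribute `cache` holds gate values).
#' @export
gru_step <- function(x, h_prev, params) {
  p <- params
  if (ncol(p$Wz) != length(x) || ncol(p$Uz) != length(h_prev))
    stop("GRU parameter dimensions do not match the inputs", call. = FALSE)
  z <- sigmoid(drop(p$Wz %*% x + p$Uz %*% h_prev + p$bz))
  r <- sigmoid(drop(p$Wr %*% x + p$Ur %*% h_prev + p$br))
  Uh_h <- drop(p$Uh %*% h_prev)
  hc <- tanh(drop(p$Wh %*% x) + r * Uh_h + p$bh)
  h <- (1 - z) * h_prev + z * hc
  attr(h, "cache") <- list(x = x, h_prev = h_prev, z = z, r = r, hc = hc,
                           Uh_h = Uh_h)
  h
}

# Run a GRU over the rows of Xmat from zero initial state; returns final
# state and per-step caches.
gru_run <- function(Xmat, params) {
  h <- numeric(length(params$bz))
  caches <- vector("list", nrow(Xmat))
  for (t in seq_len(nrow(Xmat))) {
    h <- gru_step(Xmat[t, ], h, params)
    caches[[t]] <- attr(h, "cache")
    attributes(h) <- NULL
  }
  list(h = h, caches = caches)
}

# BPTT through a sequence of cached GRU steps; dh_final is the gradient at
# the last state. Accumulates into a gradient list shaped like the params.
gru_backward <- function(dh_final, caches, params, grads) {
  dh <- dh_final
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    dz <- (cc$hc - cc$h_prev) * dh
    dhc <- cc$z * dh
    dh_prev <- (1 - cc$z) * dh
    da_h <- (1 - cc$hc^2) * dhc
    grads$Wh <- grads$Wh + tcrossprod(da_h, cc$x)
    grads$bh <- grads$bh + da_h
    dr <- cc$Uh_h * da_h
    rda <- cc$r * da_h
    grads$Uh <- grads$Uh + tcrossprod(rda, cc$h_prev)
    dh_prev <- dh_prev + drop(crossprod(params$Uh, rda))
    da_z <- cc$z * (1 - cc$z) * dz
    grads$Wz <- grads$Wz + tcrossprod(da_z, cc$x)
    grads$Uz <- grads$Uz + tcrossprod(da_z, cc$h_prev)
    grads$bz <- grads$bz + da_z
    dh_prev <- dh_prev + drop(crossprod(params$Uz, da_z))
    da_r <- cc$r * (1 - cc$r) * dr
    grads$Wr <- grads$Wr + tcrossprod(da_r, cc$x)
    grads$Ur <- grads$Ur + tcrossprod(da_r, cc$h_prev)
    grads$br <- grads$br + da_r
    dh_prev <- dh_prev + drop(crossprod(params$Ur, da_r))
    dh <- dh_prev
  }
  grads
}

#' Encode a path bidirectionally
#'
#' Runs a forward GRU over the path's node features (first to last node) and
#' a backward GRU over the reversed sequence, both from zero initial state,
#' and concatenates the two final hidden states into the path
#' representation.
#'
#' @param path_feats `T x (Nr+Nd)` matrix of node feature vectors (rows in
#'   path order), `T >= 2`.
#' @param fwd,bwd GRU parameter lists (see [gru_step()]).
#' @return Numeric vector of length `2 * hidden_dim` (attribute `cache`
#'   holds the two step-cache lists).
#' @export
encode_path <- function(path_feats, fwd, bwd) {
  if (is.null(dim(path_feats)) || nrow(path_feats) < 2)
    stop("a path needs at least two nodes", call. = FALSE)
  ff <- gru_run(path_feats, fwd)
  bb <- gru_run(path_feats[rev(seq_len(nrow(path_feats))), , drop = FALSE],
                bwd)
  h <- c(ff$h, bb$h)
  attr(h, "cache") <- list(fwd = ff$caches, bwd = bb$caches)
  h
}

#' Path-level attention
#'
#' Scores each encoded path with `u_t = tanh(W_t h_t + b_t)` and
#' `s_t = u_p . u_t`, turns the scores into weights by a numerically stable
#' softmax, and pools the path vectors into `g = sum_t alpha_t h_t`. Paths
#' that look informative for the association receive larger weight.
#'
#' @param path_vecs list of path representation vectors (or a matrix with
#'   one row per path).
#' @param params list with `W_t` (`att_dim x 2*hidden`), `b_t`, `u_p`.
#' @return List of class `path_attention`: `alpha` (weights, sum to 1) and
#'   `g` (pooled vector), plus a `cache` element.
#' @export
attend <- function(path_vecs, params) {
  if (is.list(path_vecs)) {
    if (length(path_vecs) == 0) stop("no path vectors to attend over",
                                     call. = FALSE)
    Hm <- do.call(rbind, lapply(path_vecs, as.vector))
  } else {
    Hm <- as.matrix(path_vecs)
    if (nrow(Hm) == 0) stop("no path vectors to attend over", call. = FALSE)
  }
  U <- tanh(params$W_t %*% t(Hm) + params$b_t)     # att_dim x n
  s <- drop(crossprod(U, params$u_p))              # n
  alpha <- softmax_stable(s)
  g <- drop(crossprod(Hm, alpha))
  structure(list(alpha = alpha, g = g,
                 cache = list(Hm = Hm, U = U, s = s, alpha = alpha)),
            class = "path_attention")
}

# Backward through attend: dg -> gradients on W_t, b_t, u_p and each path
# vector (rows of dH).
attend_backward <- function(dg, cache, params, grads) {
  Hm <- cache$Hm; U <- cache$U; alpha <- cache$alpha
  n <- nrow(Hm)
  dH <- alpha %o% dg                    # from g = sum alpha_t h_t
  dalpha <- drop(Hm %*% dg)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  grads$u_p <- grads$u_p + drop(U %*% ds)
  dU <- params$u_p %o% ds               # att_dim x n
  dpre <- dU * (1 - U^2)
  grads$W_t <- grads$W_t + dpre %*% Hm
  grads$b_t <- grads$b_t + rowSums(dpre)
  dH <- dH + crossprod(dpre, params$W_t)
  list(grads = grads, dH = dH)
}

# ---- batched path encoding -------------------------------------------------
# Encodes all of a pair's equal-length paths at once with row-convention
# matrix algebra: states are (n_paths x hidden) matrices, so each GRU step
# costs one set of matmuls regardless of the number of paths. Numerically
# identical to encode_path() path by path (tested); used on the hot path of
# training and scoring. Paths of different lengths are grouped by length.

gru_run_batch <- function(Xsteps, params) {
  # Xsteps: list over time of (n x F) matrices
  n <- nrow(Xsteps[[1]])
  hid <- length(params$bz)
  H <- matrix(0, n, hid)
  caches <- vector("list", length(Xsteps))
  tWz <- t(params$Wz); tUz <- t(params$Uz)
  tWr <- t(params$Wr); tUr <- t(params$Ur)
  tWh <- t(params$Wh); tUh <- t(params$Uh)
  for (t in seq_along(Xsteps)) {
    Xt <- Xsteps[[t]]
    Z <- sigmoid(Xt %*% tWz + H %*% tUz + rep(params$bz, each = n))
    R <- sigmoid(Xt %*% tWr + H %*% tUr + rep(params$br, each = n))
    UhH <- H %*% tUh
    Hc <- tanh(Xt %*% tWh + R * UhH + rep(params$bh, each = n))
    Hnew <- (1 - Z) * H + Z * Hc
    caches[[t]] <- list(x = Xt, H_prev = H, z = Z, r = R, hc = Hc, Uh_h = UhH)
    H <- Hnew
  }
  list(H = H, caches = caches)
}

gru_backward_batch <- function(dH_final, caches, params, grads) {
  dH <- dH_final
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    dz <- (cc$hc - cc$H_prev) * dH
    dhc <- cc$z * dH
    dH_prev <- (1 - cc$z) * dH
    da_h <- (1 - cc$hc^2) * dhc
    grads$Wh <- grads$Wh + crossprod(da_h, cc$x)
    grads$bh <- grads$bh + colSums(da_h)
    dr <- cc$Uh_h * da_h
    rda <- cc$r * da_h
    grads$Uh <- grads$Uh + crossprod(rda, cc$H_prev)
    dH_prev <- dH_prev + rda %*% params$Uh
    da_z <- cc$z * (1 - cc$z) * dz
    grads$Wz <- grads$Wz + crossprod(da_z, cc$x)
    grads$Uz <- grads$Uz + crossprod(da_z, cc$H_prev)
    grads$bz <- grads$bz + colSums(da_z)
    dH_prev <- dH_prev + da_z %*% params$Uz
    da_r <- cc$r * (1 - cc$r) * dr
    grads$Wr <- grads$Wr + crossprod(da_r, cc$x)
    grads$Ur <- grads$Ur + crossprod(da_r, cc$H_prev)
    grads$br <- grads$br + colSums(da_r)
    dH_prev <- dH_prev + da_r %*% params$Ur
    dH <- dH_prev
  }
  grads
}

# pathX: list of T x F matrices. Returns Hm (n x 2*hidden) plus the grouped
# caches needed for the batched backward pass.
encode_paths_batch <- function(pathX, fwd, bwd) {
  lens <- vapply(pathX, nrow, integer(1))
  n <- length(pathX)
  hid <- length(fwd$bz)
  Hm <- matrix(0, n, 2L * hid)
  groups <- split(seq_len(n), lens)
  gcaches <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    members <- groups[[gi]]
    Tn <- lens[members[1]]
    Xf <- lapply(seq_len(Tn), function(t)
      do.call(rbind, lapply(pathX[members], function(m) m[t, ])))
    Xb <- Xf[rev(seq_len(Tn))]
    ff <- gru_run_batch(Xf, fwd)
    bb <- gru_run_batch(Xb, bwd)
    Hm[members, ] <- cbind(ff$H, bb$H)
    gcaches[[gi]] <- list(members = members, fwd = ff$caches, bwd = bb$caches)
  }
  list(Hm = Hm, gcaches = gcaches, hid = hid)
}

encode_paths_batch_backward <- function(dHm, enc, fwd, bwd, grads_f, grads_b) {
  hid <- enc$hid
  for (gc in enc$gcaches) {
    dblock <- dHm[gc$members, , drop = FALSE]
    grads_f <- gru_backward_batch(dblock[, seq_len(hid), drop = FALSE],
                                  gc$fwd, fwd, grads_f)
    grads_b <- gru_backward_batch(dblock[, hid + seq_len(hid), drop = FALSE],
                                  gc$bwd, bwd, grads_b)
  }
  list(grads_f = grads_f, grads_b = grads_b)
}
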