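# Model parameters, forward passes and the hand-derived full backward pass.
#
# Parameter container: a nested list
#   conv      - list per layer: W (fh, fw, Cin, nf) and b (nf)
#   Wl        - fully connected weights, flat_dim x fc_out_dim (no bias)
#   gru_f/gru_b - GRU parameter lists (Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh)
#   att       - W_t, b_t, u_p
#   head_c    - W (2 x fc_out_dim), b (2): softmax head on the local branch
#   head_g    - W (2 x 2*hidden), b (2): softmax head on the path branch
# Softmax component 2 is the "associated" class.

# Shapes of every intermediate map given the input feature width; validates
# that filters and pools fit. Filters/pools are truncated to the current map.
conv_plan <- function(feat_dim, cfg) {
  H <- 2L + 2L * cfg$padding[1]
  W <- feat_dim + 2L * cfg$padding[2]
  C <- 1L
  layers <- list()
  for (l in seq_along(cfg$n_filters)) {
    fh <- min(cfg$filter_height, H); fw <- min(cfg$filter_width, W)
    oh <- H - fh + 1L; ow <- W - fw + 1L
    if (oh < 1 || ow < 1) stop("conv filter does not fit layer ", l,
                               call. = FALSE)
    ph <- min(cfg$pool_window[1], oh); pw <- min(cfg$pool_window[2], ow)
    qh <- oh %/% ph; qw <- ow %/% pw
    if (qh < 1 || qw < 1) stop("pool window does not fit layer ", l,
                               call. = FALSE)
    layers[[l]] <- list(fh = fh, fw = fw, cin = C, nf = cfg$n_filters[l],
                        conv_h = oh, conv_w = ow, ph = ph, pw = pw,
                        out_h = qh, out_w = qw)
    H <- qh; W <- qw; C <- cfg$n_filters[l]
  }
  list(layers = layers, flat_dim = H * W * C)
}

runif_mat <- function(nr, nc, fan_in) {
  s <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_gru_params <- function(feat_dim, hidden) {
  list(Wz = runif_mat(hidden, feat_dim, feat_dim),
       Uz = runif_mat(hidden, hidden, hidden), bz = numeric(hidden),
       Wr = runif_mat(hidden, feat_dim, feat_dim),
       Ur = runif_mat(hidden, hidden, hidden), br = numeric(hidden),
       Wh = runif_mat(hidden, feat_dim, feat_dim),
       Uh = runif_mat(hidden, hidden, hidden), bh = numeric(hidden))
}

#' Initialize model parameters
#'
#' Seeded uniform initialization scaled by fan-in for all weight tensors;
#' biases start at zero.
#'
#' @param n_drugs,n_diseases network dimensions the model will be applied to.
#' @param conv_cfg a [conv_config()].
#' @param gru_cfg a [gru_config()].
#' @param seed integer seed.
#' @return Nested parameter list of class `cgardp_params`.
#' @export
init_params <- function(n_drugs, n_diseases, conv_cfg = conv_config(),
                        gru_cfg = gru_config(), seed = 1L) {
  feat_dim <- n_drugs + n_diseases
  plan <- conv_plan(feat_dim, conv_cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  conv <- lapply(plan$layers, function(L) {
    fan <- L$fh * L$fw * L$cin
    list(W = array(stats::runif(fan * L$nf, -1 / sqrt(fan), 1 / sqrt(fan)),
                   c(L$fh, L$fw, L$cin, L$nf)),
         b = numeric(L$nf))
  })
  hid <- gru_cfg$hidden_dim; att <- gru_cfg$attention_dim
  params <- list(
    conv = conv,
    Wl = runif_mat(plan$flat_dim, conv_cfg$fc_out_dim, plan$flat_dim),
    gru_f = init_gru_params(feat_dim, hid),
    gru_b = init_gru_params(feat_dim, hid),
    att = list(W_t = runif_mat(att, 2L * hid, 2L * hid),
               b_t = numeric(att),
               u_p = stats::runif(att, -1 / sqrt(att), 1 / sqrt(att))),
    head_c = list(W = runif_mat(2L, conv_cfg$fc_out_dim, conv_cfg$fc_out_dim),
                  b = numeric(2L)),
    head_g = list(W = runif_mat(2L, 2L * hid, 2L * hid), b = numeric(2L))
  )
  structure(params, class = "cgardp_params",
            feat_dim = feat_dim, plan = plan,
            conv_cfg = conv_cfg, gru_cfg = gru_cfg)
}

# Recursively map a function over the numeric leaves of one or more
# parallel nested lists (parameters, gradients, optimizer moments).
param_map <- function(f, ...) {
  lists <- list(...)
  first <- lists[[1]]
  if (is.list(first) && !is.numeric(first)) {
    out <- first
    for (nm in seq_along(first))
      out[[nm]] <- do.call(param_map, c(list(f), lapply(lists, `[[`, nm)))
    out
  } else {
    do.call(f, lists)
  }
}

zero_like <- function(params) param_map(function(x) x * 0, params)

param_leaves <- function(params, prefix = "") {
  if (is.list(params) && !is.numeric(params)) {
    nms <- names(params)
    if (is.null(nms)) nms <- as.character(seq_along(params))
    out <- list()
    for (k in seq_along(params))
      out <- c(out, param_leaves(params[[k]],
                                 paste0(prefix, if (nzchar(prefix)) "." else "",
                                        nms[k])))
    out
  } else {
    stats::setNames(list(params), prefix)
  }
}

#' Local (convolutional) forward pass
#'
#' Pads the pair feature matrix, applies the configured convolution + ReLU +
#' max-pool stack, flattens, and maps through the fully connected weights
#' and an elementwise sigmoid to yield the local pair representation `c`.
#'
#' @param pfm a [build_pair_matrix()] result (or a bare 2-row matrix).
#' @param params a `cgardp_params` object (or any list with `conv` and `Wl`).
#' @param cfg the [conv_config()] used to build `params`.
#' @param dropout_mask optional multiplicative mask on the flattened
#'   convolution output (training only).
#' @return Numeric vector `c` of length `fc_out_dim`, entries in (0, 1);
#'   attribute `cache` holds intermediates.
#' @export
local_forward <- function(pfm, params, cfg = conv_config(),
                          dropout_mask = NULL) {
  X <- if (inherits(pfm, "pair_features")) pfm$X else as.matrix(pfm)
  a <- pad_matrix(X, cfg$padding)
  dim(a) <- c(dim(a), 1L)
  caches <- vector("list", length(params$conv))
  for (l in seq_along(params$conv)) {
    a <- conv_layer(a, params$conv[[l]]$W, params$conv[[l]]$b)
    pooled <- max_pool(a, cfg$pool_window)
    caches[[l]] <- list(conv = attr(a, "cache"), pool = attr(pooled, "cache"))
    a <- pooled
    attr(a, "cache") <- NULL
  }
  v <- as.vector(a)
  if (!is.null(dropout_mask)) v <- v * dropout_mask
  if (length(v) != nrow(params$Wl))
    stop("flattened size ", length(v), " does not match Wl (",
         nrow(params$Wl), " rows)", call. = FALSE)
  pre <- drop(v %*% params$Wl)
  cvec <- sigmoid(pre)
  attr(cvec, "cache") <- list(layers = caches, v = v, cvec = cvec,
                              dropout_mask = dropout_mask)
  cvec
}

local_backward <- function(dc, cache, params, grads) {
  cvec <- cache$cvec
  dpre <- dc * cvec * (1 - cvec)
  grads$Wl <- grads$Wl + cache$v %o% dpre
  dv <- drop(params$Wl %*% dpre)
  if (!is.null(cache$dropout_mask)) dv <- dv * cache$dropout_mask
  da <- dv
  for (l in rev(seq_along(cache$layers))) {
    cl <- cache$layers[[l]]
    da <- max_pool_backward(da, cl$pool)
    cb <- conv_layer_backward(da, cl$conv, need_dx = l > 1)
    grads$conv[[l]]$W <- grads$conv[[l]]$W + cb$dW
    grads$conv[[l]]$b <- grads$conv[[l]]$b + cb$db
    da <- cb$dx
  }
  grads
}

#' Combine the two branch scores for a pair
#'
#' Applies the two softmax heads to the local representation `c` and the
#' pooled path representation `g`, then mixes them convexly:
#' `score = alpha1 * score_c + (1 - alpha1) * score_g`. When the pair has no
#' paths (`g_vec = NULL`) the combined score falls back to the local branch.
#' Component 2 of each score vector is the probability of association.
#'
#' @param c_vec local representation from [local_forward()].
#' @param g_vec pooled path representation from [attend()], or `NULL`.
#' @param params `cgardp_params` (uses `head_c`, `head_g`).
#' @param alpha1 convex mixing weight in `[0, 1]`.
#' @return List with `score` (length-2 simplex vector), `score_c`,
#'   `score_g` (`NULL` when no paths) and `prob` (association probability).
#' @export
pair_score <- function(c_vec, g_vec, params, alpha1 = 0.5) {
  stopifnot(alpha1 >= 0, alpha1 <= 1)
  score_c <- softmax_stable(drop(params$head_c$W %*% as.vector(c_vec) +
                                   params$head_c$b))
  if (is.null(g_vec)) {
    score <- score_c
    score_g <- NULL
  } else {
    score_g <- softmax_stable(drop(params$head_g$W %*% as.vector(g_vec) +
                                     params$head_g$b))
    score <- alpha1 * score_c + (1 - alpha1) * score_g
  }
  list(score = score, score_c = score_c, score_g = score_g,
       prob = score[2])
}

#' Combined cross-entropy loss
#'
#' Per-head binary cross-entropy on the softmax outputs, mixed with the same
#' convex weight as the score: `alpha1 * loss_c + (1 - alpha1) * loss_g`.
#' Log arguments are clipped at `1e-12`. When `score_g` is `NULL` (a pair
#' with no paths) the loss is the local-branch term alone.
#'
#' @param score_c,score_g length-2 softmax outputs (component 2 =
#'   associated); `score_g` may be `NULL`.
#' @param y_real binary label (1 = associated).
#' @param alpha1 convex mixing weight.
#' @return Nonnegative scalar loss.
#' @export
combined_loss <- function(score_c, score_g, y_real, alpha1 = 0.5) {
  if (!y_real %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  ce <- function(s) {
    p <- pmax(s, 1e-12)
    -(y_real * log(p[2]) + (1 - y_real) * log(p[1]))
  }
  if (is.null(score_g)) return(ce(score_c))
  alpha1 * ce(score_c) + (1 - alpha1) * ce(score_g)
}

# Full forward + backward for one labelled pair. pathX: list of T x F node
# feature matrices (possibly empty). Returns loss, per-branch scores and a
# gradient list shaped like params. Dropout masks, when supplied, are
# list(v = ..., paths = list(...)).
pair_loss_grads <- function(params, X, pathX, y, alpha1, conv_cfg,
                            masks = NULL, grads = NULL) {
  if (is.null(grads)) grads <- zero_like(params)
  use_paths <- alpha1 < 1 && length(pathX) > 0

  cvec <- local_forward(X, params, conv_cfg,
                        dropout_mask = masks$v)
  ccache <- attr(cvec, "cache"); attributes(cvec) <- NULL

  g <- NULL; att_out <- NULL; enc <- NULL
  if (use_paths) {
    enc <- encode_paths_batch(pathX, params$gru_f, params$gru_b)
    Hm <- enc$Hm
    if (!is.null(masks$paths))
      Hm <- Hm * do.call(rbind, masks$paths)
    att_out <- attend(Hm, params$att)
    g <- att_out$g
  }

  sc <- pair_score(cvec, g, params, alpha1)
  loss <- combined_loss(sc$score_c, sc$score_g, y, alpha1)

  yvec <- c(1 - y, y)
  w_c <- if (is.null(sc$score_g)) 1 else alpha1
  dlogit_c <- w_c * (sc$score_c - yvec)
  grads$head_c$W <- grads$head_c$W + dlogit_c %o% cvec
  grads$head_c$b <- grads$head_c$b + dlogit_c
  dc <- drop(crossprod(params$head_c$W, dlogit_c))
  grads <- local_backward(dc, ccache, params, grads)

  if (use_paths) {
    dlogit_g <- (1 - alpha1) * (sc$score_g - yvec)
    grads$head_g$W <- grads$head_g$W + dlogit_g %o% g
    grads$head_g$b <- grads$head_g$b + dlogit_g
    dg <- drop(crossprod(params$head_g$W, dlogit_g))
    ab <- attend_backward(dg, att_out$cache, params$att, grads$att)
    grads$att <- ab$grads
    dHm <- ab$dH
    if (!is.null(masks$paths)) dHm <- dHm * do.call(rbind, masks$paths)
    gb <- encode_paths_batch_backward(dHm, enc, params$gru_f, params$gru_b,
                                      grads$gru_f, grads$gru_b)
    grads$gru_f <- gb$grads_f
    grads$gru_b <- gb$grads_b
  }

  list(loss = loss, score = sc$score, score_c = sc$score_c,
       score_g = sc$score_g, grads = grads)
}
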