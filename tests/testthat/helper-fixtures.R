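# Shared fixtures and independent oracles used across the test files.

# A tiny fully specified 3-drug / 2-disease network.
tiny_network <- function() {
  R <- matrix(c(1, .6, .2,
                .6, 1, .3,
                .2, .3, 1), 3, 3, byrow = TRUE)
  D <- matrix(c(1, .7,
                .7, 1), 2, 2, byrow = TRUE)
  A <- matrix(c(1, 0,
                0, 1,
                1, 1), 3, 2, byrow = TRUE)
  hetero_network(R, D, A, c("ra", "rb", "rc"), c("dx", "dy"))
}

# Small random network with enough structure for path tests.
random_network <- function(n_drugs, n_diseases, seed, p_assoc = 0.35,
                           sim_hi = 0.5) {
  set.seed(seed)
  rand_sim <- function(n) {
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
  }
  A <- matrix(rbinom(n_drugs * n_diseases, 1, p_assoc), n_drugs, n_diseases)
  hetero_network(rand_sim(n_drugs), rand_sim(n_diseases), A,
                 sprintf("r%02d", seq_len(n_drugs)),
                 sprintf("d%02d", seq_len(n_diseases)))
}

# Independent exhaustive simple-path oracle: plain depth-first search over an
# explicit (Nr+Nd) x (Nr+Nd) weighted adjacency matrix, no shared code with
# enumerate_paths().
brute_force_paths <- function(net, i, j, sim_threshold, max_len,
                              exclude_direct = TRUE) {
  nr <- n_drugs(net); nd <- n_diseases(net)
  n <- nr + nd
  W <- matrix(0, n, n)
  W[seq_len(nr), seq_len(nr)] <- ifelse(net$R >= sim_threshold, net$R, 0)
  W[nr + seq_len(nd), nr + seq_len(nd)] <-
    ifelse(net$D >= sim_threshold, net$D, 0)
  W[seq_len(nr), nr + seq_len(nd)] <- net$A
  W[nr + seq_len(nd), seq_len(nr)] <- t(net$A)
  diag(W) <- 0
  target <- nr + j
  found <- list()
  dfs <- function(path, w) {
    v <- path[length(path)]
    if (v == target) {
      if (!(exclude_direct && length(path) == 2))
        found[[length(found) + 1L]] <<- list(nodes = path, weight = w)
      return()
    }
    if (length(path) >= max_len) return()
    for (u in which(W[v, ] > 0))
      if (!(u %in% path)) dfs(c(path, u), w * W[v, u])
  }
  dfs(i, 1)
  found
}

# Canonical string form of a path for set comparisons (node ids in the
# combined drug-then-disease indexing).
path_key <- function(nodes) paste(nodes, collapse = ">")

path_set_keys <- function(ps, nr) {
  vapply(ps$paths, function(p)
    path_key(p[, "index"] + ifelse(p[, "layer"] == 2L, nr, 0L)),
    character(1))
}

# Replace one leaf (by dotted path) inside a nested parameter list.
set_param_leaf <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts) {
    if (length(parts) == 0) return(value)
    key <- parts[1]
    idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
    x[[idx]] <- rec(x[[idx]], parts[-1])
    x
  }
  rec(params, parts)
}

# Central finite-difference gradient of a scalar function of the parameter
# list, at selected coordinates; returns the max relative error against the
# supplied analytic gradients.
max_grad_rel_error <- function(params, grads, loss_fn, n_coords = 3,
                               eps = 1e-5, seed = 1) {
  leaves_p <- cgardp:::param_leaves(params)
  leaves_g <- cgardp:::param_leaves(grads)
  stopifnot(identical(names(leaves_p), names(leaves_g)))
  set.seed(seed)
  maxrel <- 0
  for (nm in names(leaves_p)) {
    x <- leaves_p[[nm]]; g <- leaves_g[[nm]]
    for (q in sample(length(x), min(n_coords, length(x)))) {
      xp <- x; xp[q] <- xp[q] + eps
      xm <- x; xm[q] <- xm[q] - eps
      fd <- (loss_fn(set_param_leaf(params, nm, xp)) -
               loss_fn(set_param_leaf(params, nm, xm))) / (2 * eps)
      rel <- abs(fd - g[q]) / max(abs(fd), abs(g[q]), 1e-6)
      maxrel <- max(maxrel, rel)
    }
  }
  maxrel
}

# Small architecture used by the gradient and trainer tests.
small_conv_cfg <- function() {
  conv_config(filter_height = 2, filter_width = 3, n_filters = c(2, 3),
              padding = c(1, 2), pool_window = c(2, 2), fc_out_dim = 4)
}
small_gru_cfg <- function() gru_config(hidden_dim = 3, attention_dim = 2)
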