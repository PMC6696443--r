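# Layered configuration: package defaults < YAML file < explicit overrides.
# Every consumed key records where its value came from; unknown keys error.

#' Convolutional branch configuration
#'
#' @param filter_height,filter_width active window of each convolution
#'   filter (defaults 3 x 20); filters larger than the current map are
#'   truncated layer by layer.
#' @param n_filters integer vector, filters per convolution layer
#'   (default `c(16, 32)`).
#' @param padding zero padding `c(rows, cols)` applied to the pair feature
#'   matrix before the first layer (default `c(1, 10)`).
#' @param pool_window max-pooling window `c(Wm, Wp)` (default `c(2, 2)`,
#'   non-overlapping).
#' @param fc_out_dim length of the local representation `c` (default 32).
#' @return List of class `conv_config`.
#' @export
conv_config <- function(filter_height = 3L, filter_width = 20L,
                        n_filters = c(16L, 32L), padding = c(1L, 10L),
                        pool_window = c(2L, 2L), fc_out_dim = 32L) {
  cfg <- list(filter_height = as.integer(filter_height),
              filter_width = as.integer(filter_width),
              n_filters = as.integer(n_filters),
              padding = as.integer(padding),
              pool_window = as.integer(pool_window),
              fc_out_dim = as.integer(fc_out_dim))
  stopifnot(cfg$filter_height >= 1, cfg$filter_width >= 1,
            all(cfg$n_filters >= 1), all(cfg$padding >= 0),
            all(cfg$pool_window >= 1), cfg$fc_out_dim >= 1)
  structure(cfg, class = "conv_config")
}

#' Recurrent branch configuration
#'
#' @param hidden_dim GRU hidden state size (default 32).
#' @param attention_dim attention projection size (default 32).
#' @return List of class `gru_config`.
#' @export
gru_config <- function(hidden_dim = 32L, attention_dim = 32L) {
  structure(list(hidden_dim = as.integer(hidden_dim),
                 attention_dim = as.integer(attention_dim)),
            class = "gru_config")
}

#' Path enumeration configuration
#'
#' @param sim_threshold similarity cutoff for intra-layer edges (default 0.5).
#' @param max_len maximum nodes per path (default 3).
#' @param cap maximum paths kept per pair (default 8).
#' @param exclude_direct exclude the direct association edge (default TRUE).
#' @return List of class `path_config`.
#' @export
path_config <- function(sim_threshold = 0.5, max_len = 3L, cap = 8L,
                        exclude_direct = TRUE) {
  structure(list(sim_threshold = sim_threshold, max_len = as.integer(max_len),
                 cap = cap, exclude_direct = isTRUE(exclude_direct)),
            class = "path_config")
}

#' Training configuration
#'
#' @param alpha1 convex weight of the convolutional branch in the combined
#'   loss and score, in `[0, 1]` (default 0.5; 1 trains the convolutional
#'   branch alone).
#' @param dropout_rate dropout probability on the flattened convolution
#'   output and on path vectors during training (default 0.5).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay decoupled L2 weight decay applied with the Adam step
#'   (default 0, i.e. none).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param neg_ratio negatives sampled per positive (default 1).
#' @param mask_known zero each training pair's own association entry in its
#'   features (default TRUE).
#' @param seed integer seed controlling initialization, sampling, shuffling
#'   and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(alpha1 = 0.5, dropout_rate = 0.5,
                         learning_rate = 1e-3, weight_decay = 0,
                         epochs = 100L, batch_size = 32L, neg_ratio = 1,
                         mask_known = TRUE, seed = 1L) {
  if (alpha1 < 0 || alpha1 > 1) stop("alpha1 must lie in [0, 1]",
                                     call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(alpha1 = alpha1, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), neg_ratio = neg_ratio,
                 mask_known = isTRUE(mask_known), seed = as.integer(seed)),
            class = "train_config")
}

config_blocks <- c("cnn", "gru", "paths", "train", "synth", "eval")

default_run_config <- function() {
  list(cnn = unclass(conv_config()),
       gru = unclass(gru_config()),
       paths = unclass(path_config()),
       train = unclass(train_config()),
       synth = list(n_drugs = 80L, n_diseases = 60L, n_blocks = 8L,
                    within_block_sim = 0.7, between_block_sim = 0.2,
                    sim_noise_sd = 0.1, assoc_density_matched = 0.30,
                    assoc_density_unmatched = 0.02, seed = 1L),
       eval = list(n_folds = 5L, k_grid = c(10L, 20L, 30L, 60L), seed = 1L))
}

#' Load a layered run configuration
#'
#' Merges, in increasing precedence: package defaults, a YAML config file,
#' and explicit overrides. Each value's provenance (`default`, `file` or
#' `flag`) is recorded in the `provenance` attribute; keys not known to the
#' package are rejected.
#'
#' @param path optional path to a YAML file with any of the blocks
#'   `cnn`, `gru`, `paths`, `train`, `synth`, `eval`.
#' @param overrides optional named nested list of the same shape (highest
#'   precedence, recorded as `flag`).
#' @return Nested configuration list with a `provenance` attribute mapping
#'   dotted keys to their source.
#' @export
load_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  prov <- list()
  for (blk in names(cfg))
    for (key in names(cfg[[blk]]))
      prov[[paste(blk, key, sep = ".")]] <- "default"
  apply_layer <- function(layer, tag) {
    for (blk in names(layer)) {
      if (!blk %in% config_blocks)
        stop("unknown config block: ", blk, call. = FALSE)
      for (key in names(layer[[blk]])) {
        if (!key %in% names(cfg[[blk]]))
          stop("unknown config key: ", blk, ".", key, call. = FALSE)
        cfg[[blk]][[key]] <<- layer[[blk]][[key]]
        prov[[paste(blk, key, sep = ".")]] <<- tag
      }
    }
  }
  if (!is.null(path)) apply_layer(yaml::read_yaml(path), "file")
  if (!is.null(overrides)) apply_layer(overrides, "flag")
  attr(cfg, "provenance") <- prov
  cfg
}
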