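# Training: negative sampling, minibatch Adam, dropout, loss history.

#' Sample labelled training pairs
#'
#' Returns the supplied positive pairs (label 1) together with
#' `ceiling(neg_ratio * n_positives)` unknown pairs (`A[i, j] == 0`) sampled
#' uniformly without replacement (label 0). Deterministic given the seed.
#'
#' @param net a [hetero_network()].
#' @param fold_positives tibble/data frame with columns `drug`, `disease`
#'   (1-based indices) of positive pairs.
#' @param neg_ratio negatives per positive (> 0).
#' @param seed integer seed.
#' @param exclude optional tibble of `drug`, `disease` pairs that must not
#'   be sampled as negatives (e.g. held-out test positives).
#' @return Tibble with columns `drug`, `disease`, `label`.
#' @export
sample_training_pairs <- function(net, fold_positives, neg_ratio = 1,
                                  seed = 1L, exclude = NULL) {
  stopifnot(neg_ratio > 0)
  nr <- n_drugs(net); nd <- n_diseases(net)
  pos <- tibble::as_tibble(fold_positives[, c("drug", "disease")])
  n_neg <- ceiling(neg_ratio * nrow(pos))
  unknown <- which(net$A == 0)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl_lin <- (exclude$disease - 1L) * nr + exclude$drug
    unknown <- setdiff(unknown, excl_lin)
  }
  if (length(unknown) < n_neg)
    stop("not enough unknown pairs to sample ", n_neg, " negatives",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  neg_lin <- sample(unknown, n_neg)
  dplyr::bind_rows(
    dplyr::mutate(pos, label = 1),
    tibble::tibble(drug = ((neg_lin - 1L) %% nr) + 1L,
                   disease = ((neg_lin - 1L) %/% nr) + 1L,
                   label = 0)
  )
}

positive_pairs <- function(net) {
  idx <- which(net$A == 1, arr.ind = TRUE)
  tibble::tibble(drug = as.integer(idx[, 1]), disease = as.integer(idx[, 2]))
}

# Precompute the per-pair inputs (feature matrix and path node features)
# once; they are fixed for a given network and configuration.
build_pair_inputs <- function(net, pairs, conv_cfg, path_cfg, mask_known,
                              use_paths, edges = NULL, feats = NULL) {
  if (is.null(feats)) feats <- feature_rows(net)
  if (use_paths && is.null(edges))
    edges <- build_graph_edges(net, path_cfg$sim_threshold)
  nr <- n_drugs(net)
  lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$drug[k]; j <- pairs$disease[k]
    pfm <- build_pair_matrix(net, i, j, mask_known = mask_known)
    pathX <- list()
    if (use_paths) {
      ps <- enumerate_paths(edges, i, j, path_cfg$max_len, path_cfg$cap,
                            path_cfg$exclude_direct)
      mask_pair <- if (mask_known && net$A[i, j] == 1) c(i, j) else NULL
      pathX <- lapply(ps$paths, function(p)
        path_feature_matrix(feats, p, nr, mask_pair))
    }
    list(X = pfm$X, pathX = pathX)
  })
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps) - lr * weight_decay * p
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Train the association model
#'
#' Minimizes the mean combined cross-entropy over labelled pairs by
#' minibatch Adam. Positive pairs are all known associations of `net`
#' unless `pairs` is supplied; negatives are sampled by
#' [sample_training_pairs()]. Inverted dropout is applied to the flattened
#' convolution output and to path vectors during training only, so
#' inference needs no rescaling. With `alpha1 = 1` the path branch is
#' skipped entirely (local-branch ablation).
#'
#' @param net a [hetero_network()].
#' @param cfg a [train_config()].
#' @param conv_cfg a [conv_config()].
#' @param gru_cfg a [gru_config()].
#' @param path_cfg a [path_config()].
#' @param pairs optional tibble `drug`, `disease`, `label` of training
#'   pairs; when `NULL`, built from `net` and `cfg$neg_ratio`.
#' @return Object of class `cgardp_model`: trained `params`, the four
#'   configs, `loss_history` (mean loss per epoch) and the network
#'   dimensions.
#' @export
train_cgardp <- function(net, cfg = train_config(), conv_cfg = conv_config(),
                         gru_cfg = gru_config(), path_cfg = path_config(),
                         pairs = NULL) {
  if (is.null(pairs)) {
    pos <- positive_pairs(net)
    if (nrow(pos) == 0) stop("network has no positive pairs", call. = FALSE)
    pairs <- sample_training_pairs(net, pos, cfg$neg_ratio, cfg$seed)
  }
  use_paths <- cfg$alpha1 < 1
  inputs <- build_pair_inputs(net, pairs, conv_cfg, path_cfg,
                              cfg$mask_known, use_paths)
  params <- init_params(n_drugs(net), n_diseases(net), conv_cfg, gru_cfg,
                        seed = cfg$seed)
  state <- list(m = zero_like(params), v = zero_like(params), t = 0)
  keep <- 1 - cfg$dropout_rate
  n <- nrow(pairs)
  loss_history <- numeric(cfg$epochs)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(cfg$seed) + 1L)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- zero_like(params)
      for (k in batch) {
        inp <- inputs[[k]]
        masks <- NULL
        if (cfg$dropout_rate > 0) {
          masks <- list(
            v = stats::rbinom(nrow(params$Wl), 1, keep) / keep,
            paths = if (use_paths && length(inp$pathX) > 0)
              lapply(inp$pathX, function(.)
                stats::rbinom(2L * gru_cfg$hidden_dim, 1, keep) / keep)
          )
        }
        res <- pair_loss_grads(params, inp$X, inp$pathX, pairs$label[k],
                               cfg$alpha1, conv_cfg, masks, grads)
        grads <- res$grads
        epoch_loss <- epoch_loss + res$loss
      }
      grads <- param_map(function(g) g / length(batch), grads)
      upd <- adam_update(params, grads, state, cfg$learning_rate,
                         weight_decay = cfg$weight_decay)
      params <- upd$params; state <- upd$state
    }
    loss_history[epoch] <- epoch_loss / n
    if (!is.finite(loss_history[epoch]))
      stop("non-finite training loss at epoch ", epoch,
           " (lr = ", cfg$learning_rate, "); try a smaller learning rate",
           call. = FALSE)
  }

  structure(
    list(params = params, train_cfg = cfg, conv_cfg = conv_cfg,
         gru_cfg = gru_cfg, path_cfg = path_cfg,
         loss_history = loss_history,
         n_drugs = n_drugs(net), n_diseases = n_diseases(net),
         drug_ids = net$drug_ids, disease_ids = net$disease_ids),
    class = "cgardp_model"
  )
}

#' @export
print.cgardp_model <- function(x, ...) {
  cat("<cgardp_model> trained on ", x$n_drugs, " drugs x ", x$n_diseases,
      " diseases; alpha1 = ", x$train_cfg$alpha1, "; ",
      length(x$loss_history), " epochs, final loss ",
      signif(utils::tail(x$loss_history, 1), 4), "\n", sep = "")
  invisible(x)
}

# Score a set of pairs with a trained model (no dropout). Returns the
# association probability per pair.
score_pairs <- function(model, net, pairs, edges = NULL, feats = NULL) {
  use_paths <- model$train_cfg$alpha1 < 1
  inputs <- build_pair_inputs(net, pairs, model$conv_cfg, model$path_cfg,
                              model$train_cfg$mask_known, use_paths,
                              edges = edges, feats = feats)
  vapply(seq_len(nrow(pairs)), function(k) {
    inp <- inputs[[k]]
    cvec <- local_forward(inp$X, model$params, model$conv_cfg)
    attributes(cvec) <- NULL
    g <- NULL
    if (use_paths && length(inp$pathX) > 0) {
      enc <- encode_paths_batch(inp$pathX, model$params$gru_f,
                                model$params$gru_b)
      g <- attend(enc$Hm, model$params$att)$g
    }
    pair_score(cvec, g, model$params, model$train_cfg$alpha1)$prob
  }, numeric(1))
}

#' Score drug-disease pairs with a trained model
#'
#' @param object a `cgardp_model`.
#' @param net the [hetero_network()] providing the features (its dimensions
#'   must match the model).
#' @param pairs tibble with columns `drug` and `disease` (1-based indices);
#'   defaults to every pair.
#' @param ... unused.
#' @return `pairs` with an added `score` column (association probability).
#' @export
predict.cgardp_model <- function(object, net, pairs = NULL, ...) {
  if (n_drugs(net) != object$n_drugs || n_diseases(net) != object$n_diseases)
    stop("network dimensions do not match the trained model", call. = FALSE)
  if (is.null(pairs))
    pairs <- tidyr::expand_grid(drug = seq_len(n_drugs(net)),
                                disease = seq_len(n_diseases(net)))
  pairs <- tibble::as_tibble(pairs)
  pairs$score <- score_pairs(object, net, pairs)
  pairs
}

#' Rank novel candidate diseases for drugs
#'
#' Scores every unknown pair (`A[i, j] == 0`) for the requested drugs and
#' returns them ranked by descending score with a stable tie-break on
#' disease id. Known associations are excluded.
#'
#' @param net a [hetero_network()].
#' @param model a trained `cgardp_model`.
#' @param drugs drug ids or indices to rank candidates for; `NULL` for all.
#' @return Tibble `drug`, `disease`, `score`, `rank` (rank within drug).
#' @export
predict_associations <- function(net, model, drugs = NULL) {
  if (n_drugs(net) != model$n_drugs || n_diseases(net) != model$n_diseases)
    stop("network dimensions do not match the trained model", call. = FALSE)
  idx <- if (is.null(drugs)) seq_len(n_drugs(net))
         else if (is.character(drugs)) match(drugs, net$drug_ids)
         else as.integer(drugs)
  if (anyNA(idx) || any(idx < 1 | idx > n_drugs(net)))
    stop("unknown drug", call. = FALSE)
  pairs <- dplyr::filter(
    tidyr::expand_grid(drug = idx, disease = seq_len(n_diseases(net))),
    net$A[cbind(drug, disease)] == 0
  )
  if (nrow(pairs) == 0)
    return(tibble::tibble(drug = character(), disease = character(),
                          score = numeric(), rank = integer()))
  pairs$score <- score_pairs(model, net, pairs)
  pairs |>
    dplyr::mutate(disease_id = net$disease_ids[disease],
                  drug_id = net$drug_ids[drug]) |>
    dplyr::arrange(drug, dplyr::desc(score), disease_id) |>
    dplyr::group_by(drug) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(drug = drug_id, disease = disease_id, score, rank)
}
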