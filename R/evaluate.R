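# Five-fold cross-validation and per-drug ranking metrics.

#' Build a cross-validation fold plan
#'
#' Randomly partitions all known associations into `n_folds` near-equal
#' subsets (sizes differ by at most one) and samples, for each fold, a
#' matched number of unknown pairs as its negative test set; negative sets
#' are disjoint across folds. Deterministic given the seed.
#'
#' @param net a [hetero_network()].
#' @param n_folds number of folds (default 5).
#' @param seed integer seed.
#' @return List of class `fold_plan` with tibbles `positives` and
#'   `negatives` (columns `drug`, `disease`, `fold`) and the `seed`.
#' @export
make_folds <- function(net, n_folds = 5L, seed = 1L) {
  stopifnot(n_folds >= 2)
  pos <- positive_pairs(net)
  n_pos <- nrow(pos)
  if (n_pos < n_folds)
    stop("need at least as many positives as folds", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(n_folds), n_pos))
  pos$fold <- fold_of
  nr <- n_drugs(net)
  unknown <- which(net$A == 0)
  if (length(unknown) < n_pos)
    stop("not enough unknown pairs for matched negative sets", call. = FALSE)
  neg_lin <- sample(unknown, n_pos)
  neg <- tibble::tibble(drug = ((neg_lin - 1L) %% nr) + 1L,
                        disease = ((neg_lin - 1L) %/% nr) + 1L,
                        fold = fold_of)
  structure(list(positives = pos, negatives = neg, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Confusion counts and rates at a score threshold
#'
#' A pair is called positive when its score strictly exceeds `theta`.
#' Precision is defined as 0 when nothing is called positive.
#'
#' @param scores numeric vector.
#' @param labels binary vector of the same length.
#' @param theta decision threshold.
#' @return Tibble with one row: `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   `precision`, `recall`.
#' @export
confusion_at_threshold <- function(scores, labels, theta) {
  stopifnot(length(scores) == length(labels))
  pred <- scores > theta
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

check_two_classes <- function(labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("metric undefined: need at least one positive and one negative",
         call. = FALSE)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive outscores a random negative, ties counted half.
#'
#' @param scores numeric vector.
#' @param labels binary vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over all distinct score thresholds, descending: the
#' curve accrues `(recall_k - recall_{k-1}) * precision_k` at each threshold
#' group (ties handled as a single group).
#'
#' @param scores numeric vector.
#' @param labels binary vector.
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_last <- cumsum(rle(s)$lengths)     # last index of each tie group
  tp <- cumsum(y)[grp_last]
  n_called <- grp_last
  n_pos <- sum(y)
  prec <- tp / n_called
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Average recall among the top-k candidates
#'
#' For each drug, the fraction of its true test associations ranked in its
#' top `k` candidates; the curve is the unweighted mean over drugs. Drugs
#' without test positives are excluded by the caller.
#'
#' @param per_drug_rankings named list; each element is a drug's test labels
#'   ordered by decreasing predicted score.
#' @param k_grid integer vector of cutoffs.
#' @return Tibble `k`, `recall` (mean over drugs), nondecreasing in `k`.
#' @export
recall_at_k <- function(per_drug_rankings, k_grid) {
  if (length(per_drug_rankings) == 0)
    stop("no rankings supplied", call. = FALSE)
  per_drug <- vapply(per_drug_rankings, function(y) {
    if (length(y) == 0) stop("empty ranking", call. = FALSE)
    tot <- sum(y)
    if (tot == 0) stop("ranking without test positives", call. = FALSE)
    vapply(k_grid, function(k) sum(y[seq_len(min(k, length(y)))]) / tot,
           numeric(1))
  }, numeric(length(k_grid)))
  per_drug <- matrix(per_drug, nrow = length(k_grid))
  tibble::tibble(k = as.integer(k_grid), recall = rowMeans(per_drug))
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether `metric_a` tends to exceed `metric_b` across paired
#' observations (alternative: a > b). Zero differences are dropped; ties
#' among absolute differences receive midranks. The p-value is exact for
#' n <= 25 (computed by dynamic programming over the signed-rank generating
#' function, valid under ties) and uses the normal approximation with tie
#' correction otherwise.
#'
#' @param metric_a,metric_b equal-length numeric vectors (e.g. per-drug
#'   AUCs of two methods).
#' @return One-sided p-value.
#' @export
paired_wilcoxon <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_a - metric_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact tail P(W* >= W) where W* sums an independent random subset of
    # the ranks; doubled ranks keep the DP integral under midranks
    r2 <- as.integer(round(2 * r))
    probs <- numeric(sum(r2) + 1L)      # index = value + 1
    probs[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), probs[seq_len(length(probs) - rk)])
      probs <- (probs + shifted) / 2
    }
    w2 <- round(2 * W)
    sum(probs[(w2 + 1L):length(probs)])
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
}

#' Five-fold cross-validation of the association model
#'
#' For each fold, removes the held-out positives from the association
#' matrix (and hence from the pair features and path evidence), trains the
#' model on the remaining positives plus sampled negatives, scores each
#' drug's held-out candidates, and aggregates per-drug ranking metrics.
#' A drug's test set in a fold is its held-out positives plus either all
#' its unknown diseases not used as training negatives
#' (`test_set = "all_unknown"`, the default) or the fold's matched sampled
#' negatives (`test_set = "sampled"`). Deterministic given the seed.
#'
#' @param net a [hetero_network()].
#' @param train_cfg,conv_cfg,gru_cfg,path_cfg model configuration objects.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed driving the fold plan and per-fold training.
#' @param k_grid cutoffs for the top-k recall curve.
#' @param test_set candidate-set composition, see above.
#' @return Object of class `cgardp_cv` with tibbles `per_drug` (fold, drug,
#'   counts, AUC, AUPR), `scores` (every scored test pair), `recall_curve`,
#'   `summary` (per fold), and macro averages `macro_auc`, `macro_aupr`.
#' @export
cross_validate <- function(net, train_cfg = train_config(),
                           conv_cfg = conv_config(), gru_cfg = gru_config(),
                           path_cfg = path_config(), n_folds = 5L,
                           seed = 1L, k_grid = c(10L, 20L, 30L, 60L),
                           test_set = c("all_unknown", "sampled")) {
  test_set <- match.arg(test_set)
  plan <- make_folds(net, n_folds, seed)
  nr <- n_drugs(net); nd <- n_diseases(net)
  per_drug <- list(); scores_out <- list(); rankings <- list()

  for (f in seq_len(n_folds)) {
    test_pos <- dplyr::filter(plan$positives, fold == f)
    train_pos <- dplyr::filter(plan$positives, fold != f)

    A_train <- net$A
    A_train[cbind(test_pos$drug, test_pos$disease)] <- 0
    stopifnot(all(A_train[cbind(test_pos$drug, test_pos$disease)] == 0))
    net_train <- hetero_network(net$R, net$D, A_train, net$drug_ids,
                                net$disease_ids)

    fold_cfg <- train_cfg
    fold_cfg$seed <- as.integer(seed) * 100L + f
    pairs <- sample_training_pairs(net_train, train_pos, train_cfg$neg_ratio,
                                   seed = fold_cfg$seed, exclude = test_pos)
    model <- train_cgardp(net_train, fold_cfg, conv_cfg, gru_cfg, path_cfg,
                          pairs = pairs)

    train_neg <- dplyr::filter(pairs, label == 0)
    edges <- if (train_cfg$alpha1 < 1)
      build_graph_edges(net_train, path_cfg$sim_threshold) else NULL
    feats <- feature_rows(net_train)

    for (i in sort(unique(test_pos$drug))) {
      tp_j <- test_pos$disease[test_pos$drug == i]
      if (test_set == "all_unknown") {
        neg_j <- setdiff(which(net$A[i, ] == 0),
                         train_neg$disease[train_neg$drug == i])
      } else {
        neg_j <- plan$negatives$disease[plan$negatives$fold == f &
                                          plan$negatives$drug == i]
      }
      if (length(neg_j) == 0) next
      cand <- tibble::tibble(drug = i, disease = c(tp_j, neg_j),
                             label = rep(c(1, 0), c(length(tp_j),
                                                    length(neg_j))))
      cand$score <- score_pairs(model, net_train, cand, edges = edges,
                                feats = feats)
      cand <- dplyr::arrange(cand, dplyr::desc(score),
                             net$disease_ids[disease])
      per_drug[[length(per_drug) + 1L]] <- tibble::tibble(
        fold = f, drug = net$drug_ids[i],
        n_pos = length(tp_j), n_neg = length(neg_j),
        auc = roc_auc(cand$score, cand$label),
        aupr = pr_auc(cand$score, cand$label)
      )
      rankings[[length(rankings) + 1L]] <- cand$label
      scores_out[[length(scores_out) + 1L]] <- dplyr::mutate(
        cand, fold = f, drug = net$drug_ids[i],
        disease = net$disease_ids[disease])
    }
  }

  per_drug <- dplyr::bind_rows(per_drug)
  scores_tbl <- dplyr::bind_rows(scores_out)[, c("drug", "disease", "score",
                                                 "label", "fold")]
  curve <- recall_at_k(rankings, k_grid)
  summary_tbl <- per_drug |>
    dplyr::group_by(fold) |>
    dplyr::summarise(n_drugs = dplyr::n(), auc = mean(auc),
                     aupr = mean(aupr), .groups = "drop")
  structure(
    list(per_drug = per_drug, scores = scores_tbl, recall_curve = curve,
         summary = summary_tbl,
         macro_auc = mean(per_drug$auc), macro_aupr = mean(per_drug$aupr),
         n_folds = n_folds, seed = as.integer(seed),
         k_grid = as.integer(k_grid), test_set = test_set,
         alpha1 = train_cfg$alpha1),
    class = "cgardp_cv"
  )
}

#' @export
print.cgardp_cv <- function(x, ...) {
  cat("<cgardp_cv> ", x$n_folds, "-fold; macro AUC ",
      signif(x$macro_auc, 4), ", macro AUPR ", signif(x$macro_aupr, 4),
      " over ", nrow(x$per_drug), " drug-fold rankings\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report as JSON
#'
#' Serializes the report deterministically (fixed 10-digit numbers), so two
#' runs with identical seeds produce byte-identical files.
#'
#' @param cv a `cgardp_cv` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(cv, path) {
  payload <- list(
    seed = cv$seed, n_folds = cv$n_folds, alpha1 = cv$alpha1,
    test_set = cv$test_set,
    macro_auc = round(cv$macro_auc, 10),
    macro_aupr = round(cv$macro_aupr, 10),
    summary = as.data.frame(dplyr::mutate(cv$summary,
                                          dplyr::across(c(auc, aupr),
                                                        ~ round(.x, 10)))),
    recall_curve = as.data.frame(dplyr::mutate(cv$recall_curve,
                                               recall = round(recall, 10))),
    per_drug = as.data.frame(dplyr::mutate(cv$per_drug,
                                           dplyr::across(c(auc, aupr),
                                                         ~ round(.x, 10))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
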