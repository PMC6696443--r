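test_that("fold plans partition the positives with near-equal sizes", {
  net <- generate_network(n_drugs = 20, n_diseases = 15, n_blocks = 4,
                          seed = 2)
  plan <- make_folds(net, n_folds = 5, seed = 3)
  pos <- cgardp:::positive_pairs(net)
  expect_equal(nrow(plan$positives), nrow(pos))
  # partition: every positive appears exactly once
  expect_false(any(duplicated(plan$positives[, c("drug", "disease")])))
  sizes <- table(plan$positives$fold)
  expect_lte(diff(range(sizes)), 1)
  # matched negative sets, disjoint across folds, disjoint from positives
  expect_equal(nrow(plan$negatives), nrow(pos))
  expect_false(any(duplicated(plan$negatives[, c("drug", "disease")])))
  expect_true(all(net$A[cbind(plan$negatives$drug,
                              plan$negatives$disease)] == 0))
  # determinism
  expect_identical(make_folds(net, 5, seed = 3)$positives, plan$positives)
  # exact division example: 10 positives over 5 folds -> 2 each
  small <- hetero_network(diag(5), diag(4),
                          matrix(c(rep(1, 10), rep(0, 10)), 5, 4),
                          paste0("r", 1:5), paste0("d", 1:4))
  expect_true(all(table(make_folds(small, 5, seed = 1)$positives$fold) == 2))
})

test_that("confusion counts match hand counts on the 3-item example", {
  cm <- confusion_at_threshold(c(0.9, 0.8, 0.3), c(1, 0, 1), 0.5)
  expect_equal(cm$tp, 1); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 0); expect_equal(cm$fn, 1)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 0.5)
  # threshold below all scores: everything called positive
  cm_lo <- confusion_at_threshold(c(0.9, 0.8, 0.3), c(1, 0, 1), 0)
  expect_equal(cm_lo$recall, 1)
  expect_equal(cm_lo$fpr, 1)
  # threshold above all scores: nothing called, precision defined as 0
  cm_hi <- confusion_at_threshold(c(0.9, 0.8, 0.3), c(1, 0, 1), 1)
  expect_equal(cm_hi$tp + cm_hi$fp, 0)
  expect_equal(cm_hi$precision, 0)
})

test_that("roc_auc equals the pairwise concordance oracle and reference code", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1.0)
  set.seed(11)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    a <- roc_auc(scores, labels)
    # Mann-Whitney pairwise oracle, ties counted half
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(a, mean(cmp), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(12)
  for (k in 1:10) {
    labels <- c(1, 0, rbinom(18, 1, 0.5))
    scores <- round(runif(20), 2)
    expect_equal(roc_auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(runif(4), rep(1, 4)), "undefined")
})

test_that("pr_auc equals per-threshold step integration through the confusion counts", {
  # perfectly separated scores
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(13)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))
    a <- pr_auc(scores, labels)
    # oracle: walk the distinct thresholds with confusion_at_threshold
    thr <- sort(unique(scores), decreasing = TRUE)
    rec_prev <- 0; area <- 0
    for (t in thr) {
      cm <- confusion_at_threshold(scores, labels, t - 1e-12)
      area <- area + (cm$recall - rec_prev) * cm$precision
      rec_prev <- cm$recall
    }
    expect_equal(a, area, tolerance = 1e-9)
  }
})

test_that("recall_at_k averages per-drug recalls and is nondecreasing", {
  expect_equal(recall_at_k(list(a = c(1, 0, 1, 0)), 2)$recall, 0.5)
  expect_equal(recall_at_k(list(a = c(1, 0, 1, 0)), 10)$recall, 1)
  two <- recall_at_k(list(a = c(0, 1, 1, 0, 0), b = c(1, 1, 0, 0)),
                     k_grid = c(2, 4))
  expect_equal(two$recall[1], mean(c(1 / 2, 1)))
  set.seed(14)
  rankings <- lapply(1:8, function(i)
    sample(c(rep(1, sample(1:4, 1)), rep(0, sample(3:10, 1)))))
  names(rankings) <- paste0("r", 1:8)
  curve <- recall_at_k(rankings, 1:12)
  expect_true(all(diff(curve$recall) >= 0))
  expect_equal(tail(curve$recall, 1), 1)
  expect_error(recall_at_k(list(a = numeric(0)), 2), "empty")
})

test_that("paired_wilcoxon matches exhaustive sign-flip enumeration", {
  # constant positive shift, n = 8: all ranks positive, p = 1/2^8
  a <- 1:8 / 10 + 0.5; b <- 1:8 / 10
  expect_equal(paired_wilcoxon(a, b), 1 / 256)
  expect_error(paired_wilcoxon(a, a), "zero")
  # enumeration oracle
  set.seed(15)
  for (k in 1:50) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n), sample(1:2, 1))
    d <- d[d != 0]
    n <- length(d)
    if (n < 2) next
    p <- paired_wilcoxon(d, numeric(n))
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    # all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    expect_equal(p, mean(Ws >= W), tolerance = 1e-12)
  }
  # tie-free case agrees with the base implementation
  set.seed(16)
  d <- rnorm(10)
  expect_equal(paired_wilcoxon(d, numeric(10)),
               wilcox.test(d, alternative = "greater", exact = TRUE)$p.value,
               tolerance = 1e-12)
  # large-n normal path returns a sane one-sided p
  set.seed(17)
  big_a <- rnorm(40, mean = 0.3); big_b <- rnorm(40)
  p_big <- paired_wilcoxon(big_a, big_b)
  expect_gt(p_big, 0); expect_lt(p_big, 0.5)
})

test_that("cross-validation produces valid, leakage-free, seeded reports", {
  net <- generate_network(n_drugs = 24, n_diseases = 18, n_blocks = 3,
                          seed = 5)
  cfg <- train_config(epochs = 4, seed = 2)
  cv <- cross_validate(net, cfg, n_folds = 3, seed = 7,
                       k_grid = c(3, 6, 18))
  expect_true(all(cv$per_drug$auc >= 0 & cv$per_drug$auc <= 1))
  expect_true(all(cv$per_drug$aupr >= 0 & cv$per_drug$aupr <= 1))
  expect_true(all(diff(cv$recall_curve$recall) >= -1e-12))
  # no scored test pair was a training positive in its own fold:
  # every scored label-1 pair must be a held-out positive of that fold
  plan <- make_folds(net, 3, seed = 7)
  pos_key <- with(plan$positives,
                  paste(net$drug_ids[drug], net$disease_ids[disease], fold))
  scored_pos <- dplyr::filter(cv$scores, label == 1)
  expect_true(all(paste(scored_pos$drug, scored_pos$disease,
                        scored_pos$fold) %in% pos_key))
  # tidiers
  expect_identical(tidy(cv), cv$per_drug)
  expect_equal(glance(cv)$macro_auc, cv$macro_auc)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(cv, type = "auc"), "ggplot")
})

test_that("identical seeds give byte-identical serialized reports", {
  net <- generate_network(n_drugs = 18, n_diseases = 12, n_blocks = 3,
                          seed = 6)
  cfg <- train_config(epochs = 2, seed = 3)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.json"); f2 <- file.path(dir, "b.json")
  write_cv_report(cross_validate(net, cfg, n_folds = 3, seed = 4,
                                 k_grid = c(3, 6)), f1)
  write_cv_report(cross_validate(net, cfg, n_folds = 3, seed = 4,
                                 k_grid = c(3, 6)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
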