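test_that("pair_score mixes the two heads convexly", {
  set.seed(1)
  params <- init_params(4, 3, small_conv_cfg(), small_gru_cfg(), seed = 1)
  cvec <- runif(small_conv_cfg()$fc_out_dim)
  gvec <- rnorm(2 * small_gru_cfg()$hidden_dim)
  s1 <- pair_score(cvec, gvec, params, alpha1 = 1)
  expect_equal(s1$score, s1$score_c)
  s0 <- pair_score(cvec, gvec, params, alpha1 = 0)
  expect_equal(s0$score, s0$score_g)
  for (a in runif(5)) {
    s <- pair_score(cvec, gvec, params, alpha1 = a)
    expect_equal(sum(s$score), 1, tolerance = 1e-12)
    expect_equal(s$score, a * s$score_c + (1 - a) * s$score_g)
    expect_equal(s$prob, s$score[2])
  }
  # missing path representation falls back to the local head
  sna <- pair_score(cvec, NULL, params, alpha1 = 0.3)
  expect_equal(sna$score, sna$score_c)
  expect_null(sna$score_g)
})

test_that("combined_loss matches its closed forms", {
  # perfect prediction, local branch only
  expect_equal(combined_loss(c(0, 1), c(0.5, 0.5), 1, alpha1 = 1), 0)
  # uninformative heads: loss is ln 2 for either label
  expect_equal(combined_loss(c(.5, .5), c(.5, .5), 1, 0.5), log(2))
  expect_equal(combined_loss(c(.5, .5), c(.5, .5), 0, 0.5), log(2))
  # hand-computed mixture
  sc <- c(0.3, 0.7); sg <- c(0.8, 0.2)
  expect_equal(combined_loss(sc, sg, 1, 0.25),
               0.25 * -log(0.7) + 0.75 * -log(0.2))
  expect_equal(combined_loss(sc, sg, 0, 0.25),
               0.25 * -log(0.3) + 0.75 * -log(0.8))
  # nonnegative on random simplex points
  set.seed(2)
  for (k in 1:20) {
    p <- runif(2); p <- p / sum(p)
    q <- runif(2); q <- q / sum(q)
    expect_gte(combined_loss(p, q, rbinom(1, 1, .5), runif(1)), 0)
  }
  expect_error(combined_loss(c(.5, .5), c(.5, .5), 2, .5), "label")
  # missing path head: local term alone
  expect_equal(combined_loss(sc, NULL, 1, 0.25), -log(0.7))
})

test_that("negative sampling is seeded, matched in count, and label-correct", {
  net <- generate_network(n_drugs = 15, n_diseases = 10, n_blocks = 3,
                          seed = 4)
  pos <- cgardp:::positive_pairs(net)
  s1 <- sample_training_pairs(net, pos, neg_ratio = 1, seed = 5)
  s2 <- sample_training_pairs(net, pos, neg_ratio = 1, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * nrow(pos))
  expect_equal(sum(s1$label), nrow(pos))
  neg <- dplyr::filter(s1, label == 0)
  expect_true(all(net$A[cbind(neg$drug, neg$disease)] == 0))
  expect_false(any(duplicated(neg[, c("drug", "disease")])))
  # exclusions are honoured
  excl <- neg[1:5, c("drug", "disease")]
  s3 <- sample_training_pairs(net, pos, neg_ratio = 1, seed = 5,
                              exclude = excl)
  n3 <- dplyr::filter(s3, label == 0)
  expect_equal(nrow(dplyr::inner_join(n3, excl, by = c("drug", "disease"))), 0)
  # impossible requests error
  dense <- hetero_network(diag(2), diag(2), matrix(1, 2, 2),
                          c("r1", "r2"), c("d1", "d2"))
  expect_error(sample_training_pairs(dense, cgardp:::positive_pairs(dense),
                                     neg_ratio = 1, seed = 1),
               "not enough")
})

test_that("zero epochs returns the seeded initialization unchanged", {
  net <- generate_network(n_drugs = 10, n_diseases = 8, n_blocks = 2,
                          seed = 6)
  cfg <- train_config(epochs = 0, seed = 3)
  m <- train_cgardp(net, cfg, small_conv_cfg(), small_gru_cfg())
  ref <- init_params(10, 8, small_conv_cfg(), small_gru_cfg(), seed = 3)
  expect_equal(m$params$Wl, ref$Wl)
  expect_equal(m$params$gru_f$Wz, ref$gru_f$Wz)
  expect_length(m$loss_history, 0)
})

test_that("training reduces the loss on a small problem and is seed-deterministic", {
  net <- generate_network(n_drugs = 10, n_diseases = 8, n_blocks = 2,
                          assoc_density_matched = 0.5,
                          assoc_density_unmatched = 0.05, seed = 8)
  cfg <- train_config(epochs = 50, learning_rate = 3e-3, seed = 4,
                      dropout_rate = 0.2)
  m1 <- train_cgardp(net, cfg, small_conv_cfg(), small_gru_cfg())
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
  # loosely monotone trend: most epoch-to-epoch moves go down
  drops <- diff(m1$loss_history) < 0
  expect_gt(mean(drops), 0.6)
  m2 <- train_cgardp(net, cfg, small_conv_cfg(), small_gru_cfg())
  expect_equal(tail(m1$loss_history, 1), tail(m2$loss_history, 1),
               tolerance = 1e-6)
  expect_equal(m1$params$Wl, m2$params$Wl)
})

test_that("dropout disabled makes training and inference passes identical", {
  net <- generate_network(n_drugs = 8, n_diseases = 6, n_blocks = 2, seed = 9)
  cfg0 <- train_config(epochs = 0, dropout_rate = 0, seed = 2)
  m <- train_cgardp(net, cfg0, small_conv_cfg(), small_gru_cfg())
  # a masks-free training forward equals the scoring forward on the same
  # inputs (feature matrix and enumerated paths)
  inp <- cgardp:::build_pair_inputs(net, tibble::tibble(drug = 1, disease = 1),
                                    small_conv_cfg(), path_config(),
                                    mask_known = TRUE, use_paths = TRUE)[[1]]
  res <- cgardp:::pair_loss_grads(m$params, inp$X, inp$pathX, 1, 0.5,
                                  small_conv_cfg(), masks = NULL)
  p <- predict(m, net, tibble::tibble(drug = 1, disease = 1))
  expect_equal(res$score[2], p$score[1], tolerance = 1e-12)
})

test_that("tidiers expose the training trajectory and model facts", {
  net <- generate_network(n_drugs = 8, n_diseases = 6, n_blocks = 2, seed = 9)
  m <- train_cgardp(net, train_config(epochs = 2, seed = 1),
                    small_conv_cfg(), small_gru_cfg())
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "loss"))
  expect_equal(nrow(td), 2)
  gl <- glance(m)
  expect_equal(gl$n_drugs, 8)
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(autoplot(m), "ggplot")
})
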