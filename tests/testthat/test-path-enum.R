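test_that("edge construction follows the threshold and association rules", {
  net <- tiny_network()
  # threshold 1.0: no off-diagonal similarity reaches it
  e1 <- build_graph_edges(net, 1.0)
  expect_true(all(lengths(e1$drug_nbrs) == 0))
  expect_true(all(lengths(e1$dis_nbrs) == 0))
  # threshold 0.5: ra~rb (0.6) and dx~dy (0.7) only
  e <- build_graph_edges(net, 0.5)
  expect_equal(e$drug_nbrs[[1]], 2)
  expect_equal(e$drug_nbrs[[3]], integer(0))
  expect_equal(e$dis_nbrs[[1]], 2)
  # association edges mirror A; a complete A gives a complete bipartite graph
  allA <- hetero_network(diag(2), diag(2), matrix(1, 2, 2),
                         c("r1", "r2"), c("d1", "d2"))
  ea <- build_graph_edges(allA, 0.5)
  expect_equal(sum(lengths(ea$drug_assoc)), 4)
})

test_that("the worked example yields exactly the four canonical paths", {
  net <- worked_example_network()
  e <- build_graph_edges(net, 0.5)
  ps <- enumerate_paths(e, 1, 3, max_len = 3, cap = Inf,
                        exclude_direct = TRUE)
  expect_length(ps$paths, 4)
  keys <- path_set_keys(ps, n_drugs(net))
  # node ids: drugs 1..6, diseases 7..11; expected r1>r2>d3, r1>r6>d3,
  # r1>d1>d3, r1>d2>d3
  expect_setequal(keys, c("1>2>9", "1>6>9", "1>7>9", "1>8>9"))
  # exactly three drug-drug edges incident to r1
  expect_length(e$drug_nbrs[[1]], 3)
})

test_that("no intermediate connectivity means an empty path set, not an error", {
  net <- hetero_network(diag(3), diag(2),
                        matrix(c(0, 1, 0, 0, 0, 0), 3, 2),
                        paste0("r", 1:3), paste0("d", 1:2))
  e <- build_graph_edges(net, 0.5)
  ps <- enumerate_paths(e, 1, 2, exclude_direct = TRUE)
  expect_length(ps$paths, 0)
  expect_s3_class(ps, "path_set")
})

test_that("enumeration agrees with an exhaustive DFS oracle on random networks", {
  for (seed in 1:6) {
    net <- random_network(8, 6, seed)
    e <- build_graph_edges(net, 0.5)
    for (pair in list(c(1, 1), c(2, 5), c(7, 3))) {
      for (max_len in c(3, 4)) {
        ps <- enumerate_paths(e, pair[1], pair[2], max_len = max_len,
                              cap = Inf, exclude_direct = TRUE)
        oracle <- brute_force_paths(net, pair[1], pair[2], 0.5, max_len)
        expect_length(ps$paths, length(oracle))
        expect_setequal(path_set_keys(ps, 8),
                        vapply(oracle, function(o) path_key(o$nodes),
                               character(1)))
        # weights: match oracle per path
        if (length(oracle) > 0) {
          ow <- vapply(oracle, `[[`, numeric(1), "weight")
          names(ow) <- vapply(oracle, function(o) path_key(o$nodes),
                              character(1))
          expect_equal(unname(ow[path_set_keys(ps, 8)]), ps$weights)
          expect_true(all(ps$weights > 0 & ps$weights <= 1))
          expect_true(all(diff(ps$weights) <= 1e-12))  # sorted descending
        }
      }
    }
  }
})

test_that("enumeration agrees with igraph's simple-path enumeration", {
  skip_if_not_installed("igraph")
  net <- random_network(7, 5, seed = 42)
  thr <- 0.5
  nr <- 7; nd <- 5
  adj <- matrix(0, nr + nd, nr + nd)
  adj[1:nr, 1:nr] <- net$R >= thr
  adj[nr + 1:nd, nr + 1:nd] <- net$D >= thr
  diag(adj) <- 0
  adj[1:nr, nr + 1:nd] <- net$A
  adj[nr + 1:nd, 1:nr] <- t(net$A)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  e <- build_graph_edges(net, thr)
  for (pair in list(c(1, 2), c(3, 4), c(6, 1))) {
    ig <- igraph::all_simple_paths(g, pair[1], nr + pair[2], cutoff = 3)
    ig_keys <- vapply(ig, function(p) path_key(as.integer(p)), character(1))
    ig_keys <- setdiff(ig_keys, path_key(c(pair[1], nr + pair[2])))
    ps <- enumerate_paths(e, pair[1], pair[2], max_len = 4, cap = Inf)
    expect_setequal(path_set_keys(ps, nr), ig_keys)
  }
})

test_that("the cap keeps the highest-weight paths with a deterministic tie-break", {
  net <- worked_example_network()
  e <- build_graph_edges(net, 0.5)
  all4 <- enumerate_paths(e, 1, 3, cap = Inf)
  top2 <- enumerate_paths(e, 1, 3, cap = 2)
  expect_length(top2$paths, 2)
  expect_equal(top2$weights, all4$weights[1:2])
  expect_identical(path_set_keys(top2, 6), path_set_keys(all4, 6)[1:2])
  # rerunning gives the identical selection
  expect_identical(path_set_keys(enumerate_paths(e, 1, 3, cap = 2), 6),
                   path_set_keys(top2, 6))
})

test_that("node features match the pair-matrix rows and the construction", {
  net <- tiny_network()
  nr <- n_drugs(net); nd <- n_diseases(net)
  for (i in seq_len(nr)) {
    pf <- build_pair_matrix(net, i, 1, mask_known = FALSE)
    expect_equal(node_feature(net, "drug", i), pf$X[1, ])
  }
  for (l in seq_len(nd)) {
    v <- node_feature(net, "disease", l)
    expect_equal(v[nr + seq_len(nd)], unname(net$D[l, ]))
    expect_equal(v[seq_len(nr)], unname(net$A[, l]))
  }
  expect_error(node_feature(net, 3, 1), "layer")
  # identity network: drug feature is one-hot plus zeros
  idn <- hetero_network(diag(3), diag(2), matrix(0, 3, 2),
                        paste0("r", 1:3), paste0("d", 1:2))
  expect_equal(node_feature(idn, "drug", 2), c(0, 1, 0, 0, 0))
})

test_that("enumeration output is invariant to a relabeling-consistent row order", {
  net <- random_network(6, 5, seed = 11)
  perm_r <- c(3, 1, 2, 6, 5, 4)
  net2 <- hetero_network(net$R[perm_r, perm_r], net$D, net$A[perm_r, ],
                         net$drug_ids[perm_r], net$disease_ids)
  e1 <- build_graph_edges(net, 0.5)
  e2 <- build_graph_edges(net2, 0.5)
  inv <- order(perm_r)
  for (j in 1:5) {
    ps1 <- enumerate_paths(e1, 4, j, cap = Inf)
    ps2 <- enumerate_paths(e2, inv[4], j, cap = Inf)
    # same multiset of path weights and same drug-id sequences
    expect_equal(sort(ps1$weights), sort(ps2$weights))
    ids1 <- sort(vapply(ps1$paths, function(p)
      paste(ifelse(p[, "layer"] == 1, net$drug_ids[p[, "index"]],
                   net$disease_ids[p[, "index"]]), collapse = ">"),
      character(1)))
    ids2 <- sort(vapply(ps2$paths, function(p)
      paste(ifelse(p[, "layer"] == 1, net2$drug_ids[p[, "index"]],
                   net2$disease_ids[p[, "index"]]), collapse = ">"),
      character(1)))
    expect_identical(ids1, ids2)
  }
})
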