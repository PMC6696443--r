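#' Build the edge sets of the heterogeneous graph
#'
#' Thresholds the two similarity matrices into intra-layer edges and takes
#' the association matrix as the inter-layer edges. A drug-drug edge exists
#' between distinct drugs with similarity at least `sim_threshold` (weight =
#' the similarity value); likewise for diseases. A drug-disease edge exists
#' wherever `A[i, j] == 1` (weight 1).
#'
#' @param net a [hetero_network()].
#' @param sim_threshold similarity cutoff in `[0, 1]` (default 0.5).
#' @return An object of class `hetero_edges` holding adjacency lists for the
#'   four edge directions plus the weight matrices.
#' @examples
#' e <- build_graph_edges(worked_example_network())
#' e$drug_nbrs[[1]]  # drugs adjacent to r1
#' @export
build_graph_edges <- function(net, sim_threshold = 0.5) {
  stopifnot(sim_threshold >= 0, sim_threshold <= 1)
  nr <- n_drugs(net); nd <- n_diseases(net)
  Rm <- net$R; Dm <- net$D; Am <- net$A
  drug_nbrs <- lapply(seq_len(nr), function(i) {
    k <- unname(which(Rm[i, ] >= sim_threshold)); k[k != i]
  })
  dis_nbrs <- lapply(seq_len(nd), function(j) {
    l <- unname(which(Dm[j, ] >= sim_threshold)); l[l != j]
  })
  drug_assoc <- lapply(seq_len(nr), function(i) unname(which(Am[i, ] == 1)))
  dis_assoc <- lapply(seq_len(nd), function(j) unname(which(Am[, j] == 1)))
  structure(
    list(drug_nbrs = drug_nbrs, dis_nbrs = dis_nbrs,
         drug_assoc = drug_assoc, dis_assoc = dis_assoc,
         R = Rm, D = Dm, n_drugs = nr, n_diseases = nd,
         sim_threshold = sim_threshold),
    class = "hetero_edges"
  )
}

#' Enumerate simple drug-to-disease paths
#'
#' Depth-first enumeration of all simple paths from drug `i` to disease `j`
#' through the thresholded heterogeneous graph, with at most `max_len` nodes
#' per path. Each path is weighted by the product of its edge weights
#' (similarity values on intra-layer edges, 1 on association edges). When
#' more than `cap` paths exist only the `cap` highest-weight paths are kept;
#' ties are broken by the lexicographically smallest node sequence, and the
#' returned paths are ordered by decreasing weight. The two-node path using
#' the direct association edge `i -> j` is excluded when `exclude_direct` is
#' set, so the association being predicted never serves as its own evidence.
#'
#' @param edges a [build_graph_edges()] result.
#' @param i drug index; `j` disease index (1-based).
#' @param j disease index.
#' @param max_len maximum number of nodes per path (>= 3; default 3).
#' @param cap maximum number of paths kept (default 8; `Inf` for all).
#' @param exclude_direct drop the direct `i -> j` edge path (default TRUE).
#' @return An object of class `path_set`: list with `paths` (list of
#'   two-column matrices `layer`/`index`, layer 1 = drug, 2 = disease),
#'   `weights`, `drug_index`, `disease_index`. Zero paths is a valid result.
#' @examples
#' e <- build_graph_edges(worked_example_network())
#' ps <- enumerate_paths(e, 1, 3)
#' length(ps$paths)  # 4
#' @export
enumerate_paths <- function(edges, i, j, max_len = 3L, cap = 8L,
                            exclude_direct = TRUE) {
  stopifnot(inherits(edges, "hetero_edges"), max_len >= 3 || !exclude_direct)
  if (max_len < 2) stop("max_len must allow at least the two endpoints",
                        call. = FALSE)
  nr <- edges$n_drugs
  acc_paths <- list(); acc_w <- numeric(0); n_found <- 0L

  if (max_len == 3L) {
    # closed form for the default path length: i -> k -> j via a similar
    # drug k treating j, or i -> l -> j via a treated disease l similar to j
    if (!exclude_direct && j %in% edges$drug_assoc[[i]]) {
      n_found <- n_found + 1L
      acc_paths[[n_found]] <- cbind(layer = c(1L, 2L), index = c(i, j))
      acc_w[n_found] <- 1
    }
    ks <- intersect(edges$drug_nbrs[[i]], edges$dis_assoc[[j]])
    ks <- ks[ks != i]
    for (k in ks) {
      n_found <- n_found + 1L
      acc_paths[[n_found]] <- cbind(layer = c(1L, 1L, 2L), index = c(i, k, j))
      acc_w[n_found] <- edges$R[i, k]
    }
    ls <- intersect(edges$drug_assoc[[i]], edges$dis_nbrs[[j]])
    ls <- ls[ls != j]
    for (l in ls) {
      n_found <- n_found + 1L
      acc_paths[[n_found]] <- cbind(layer = c(1L, 2L, 2L), index = c(i, l, j))
      acc_w[n_found] <- edges$D[l, j]
    }
    return(finish_path_set(acc_paths, acc_w, n_found, i, j, nr, cap))
  }

  # DFS over (layer, index) nodes; node key = index for drugs, nr + index
  # for diseases, used for the simple-path visited set.
  visit <- function(layer, idx, key_path, layer_path, w) {
    depth <- length(key_path)
    if (layer == 2L && idx == j) {
      if (!(exclude_direct && depth == 2L)) {
        n_found <<- n_found + 1L
        acc_paths[[n_found]] <<- cbind(layer = layer_path,
                                       index = ifelse(layer_path == 1L,
                                                      key_path,
                                                      key_path - nr))
        acc_w[n_found] <<- w
      }
      return(invisible())
    }
    if (depth >= max_len) return(invisible())
    if (layer == 1L) {
      for (k in edges$drug_nbrs[[idx]]) {
        if (!(k %in% key_path))
          visit(1L, k, c(key_path, k), c(layer_path, 1L), w * edges$R[idx, k])
      }
      for (l in edges$drug_assoc[[idx]]) {
        if (!((nr + l) %in% key_path))
          visit(2L, l, c(key_path, nr + l), c(layer_path, 2L), w)
      }
    } else {
      for (l in edges$dis_nbrs[[idx]]) {
        if (!((nr + l) %in% key_path))
          visit(2L, l, c(key_path, nr + l), c(layer_path, 2L),
                w * edges$D[idx, l])
      }
      for (k in edges$dis_assoc[[idx]]) {
        if (!(k %in% key_path))
          visit(1L, k, c(key_path, k), c(layer_path, 1L), w)
      }
    }
    invisible()
  }
  visit(1L, i, i, 1L, 1)
  finish_path_set(acc_paths, acc_w, n_found, i, j, nr, cap)
}

# order by weight desc (lexicographic node-key sequence breaks ties), apply
# the cap, and wrap as a path_set
finish_path_set <- function(acc_paths, acc_w, n_found, i, j, nr, cap) {
  if (n_found > 0) {
    keys <- vapply(acc_paths, function(p) {
      paste(sprintf("%06d", p[, "index"] + ifelse(p[, "layer"] == 2L, nr, 0L)),
            collapse = "/")
    }, character(1))
    ord <- order(-acc_w, keys)
    acc_paths <- acc_paths[ord]; acc_w <- acc_w[ord]
    if (is.finite(cap) && n_found > cap) {
      acc_paths <- acc_paths[seq_len(cap)]
      acc_w <- acc_w[seq_len(cap)]
    }
  }
  structure(list(paths = acc_paths, weights = acc_w,
                 drug_index = i, disease_index = j),
            class = "path_set")
}

#' Per-node feature vector
#'
#' The feature vector a path node feeds to the recurrent encoder: a drug
#' node `k` contributes `c(R[k, ], A[k, ])`; a disease node `l` contributes
#' `c(A[, l], D[l, ])` — the same row conventions as the pair feature matrix.
#'
#' @param net a [hetero_network()].
#' @param layer 1 for drug, 2 for disease (or `"drug"`/`"disease"`).
#' @param index node index within its layer.
#' @return Numeric vector of length `Nr + Nd`.
#' @export
node_feature <- function(net, layer, index) {
  if (is.character(layer))
    layer <- match(match.arg(layer, c("drug", "disease")),
                   c("drug", "disease"))
  if (!layer %in% c(1, 2)) stop("layer must be drug (1) or disease (2)",
                                call. = FALSE)
  if (layer == 1) {
    stopifnot(index >= 1, index <= n_drugs(net))
    unname(c(net$R[index, ], net$A[index, ]))
  } else {
    stopifnot(index >= 1, index <= n_diseases(net))
    unname(c(net$A[, index], net$D[index, ]))
  }
}

# Precompute both layers' feature rows; rows of $drug / $disease are the
# node_feature vectors. Used on the hot path of training and scoring.
feature_rows <- function(net) {
  list(drug = unname(cbind(net$R, net$A)),
       disease = unname(cbind(t(net$A), net$D)))
}

# Stack a path's node features into a T x (Nr+Nd) matrix, optionally masking
# the pair's own association entries in the endpoint features (same two
# positions build_pair_matrix masks).
path_feature_matrix <- function(feats, path, nr, mask_pair = NULL) {
  Tn <- nrow(path)
  out <- matrix(0, Tn, ncol(feats$drug))
  for (t in seq_len(Tn)) {
    out[t, ] <- if (path[t, "layer"] == 1L) feats$drug[path[t, "index"], ]
                else feats$disease[path[t, "index"], ]
  }
  if (!is.null(mask_pair)) {
    i <- mask_pair[1]; j <- mask_pair[2]
    for (t in seq_len(Tn)) {
      if (path[t, "layer"] == 1L && path[t, "index"] == i) out[t, nr + j] <- 0
      if (path[t, "layer"] == 2L && path[t, "index"] == j) out[t, i] <- 0
    }
  }
  out
}
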