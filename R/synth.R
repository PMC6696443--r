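#' Generate a synthetic heterogeneous network with planted block structure
#'
#' Emulates the two biological premises the predictor relies on: drugs with
#' similar chemical substructure tend to treat similar diseases, and diseases
#' similar to a drug's indications are themselves likely indications. Drugs
#' and diseases are assigned round-robin to `n_blocks` latent blocks;
#' similarities are drawn from a clipped Gaussian whose mean is
#' `within_block_sim` for same-block pairs and `between_block_sim` otherwise,
#' then symmetrized with unit diagonal. Associations are Bernoulli with
#' elevated probability (`assoc_density_matched`) when drug and disease share
#' a block, making the association signal recoverable by a learner.
#'
#' Defaults define the package's standard simulation conditions: 80 drugs and
#' 60 diseases in 8 blocks, matched/unmatched association densities
#' 0.30/0.02, and block similarity means 0.7/0.2 with noise sd 0.1 (clearly
#' separated blocks under the default 0.5 path-edge threshold).
#'
#' @param n_drugs,n_diseases network dimensions.
#' @param n_blocks number of latent blocks shared by both node layers.
#' @param within_block_sim,between_block_sim mean similarity for same-block
#'   and cross-block pairs.
#' @param sim_noise_sd standard deviation of the Gaussian similarity noise.
#' @param assoc_density_matched,assoc_density_unmatched association
#'   probability for matched and unmatched drug-disease block pairs; the
#'   matched density must exceed the unmatched one.
#' @param seed integer seed; the network is deterministic given the seed.
#' @return A [hetero_network()] with block labels attached as attributes
#'   `drug_block` and `disease_block`.
#' @examples
#' net <- generate_network(n_drugs = 12, n_diseases = 9, n_blocks = 3, seed = 1)
#' net
#' @export
generate_network <- function(n_drugs = 80, n_diseases = 60, n_blocks = 8,
                             within_block_sim = 0.7, between_block_sim = 0.2,
                             sim_noise_sd = 0.1,
                             assoc_density_matched = 0.30,
                             assoc_density_unmatched = 0.02,
                             seed = 1L) {
  stopifnot(n_drugs >= n_blocks, n_diseases >= n_blocks, n_blocks >= 1)
  if (!(assoc_density_matched > assoc_density_unmatched))
    stop("matched association density must exceed the unmatched density",
         call. = FALSE)
  for (p in c(assoc_density_matched, assoc_density_unmatched))
    if (p <= 0 || p >= 1) stop("association densities must lie in (0, 1)",
                               call. = FALSE)
  if (sim_noise_sd < 0) stop("sim_noise_sd must be nonnegative", call. = FALSE)

  drug_block <- rep_len(seq_len(n_blocks), n_drugs)
  disease_block <- rep_len(seq_len(n_blocks), n_diseases)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  R <- block_similarity(drug_block, within_block_sim, between_block_sim,
                        sim_noise_sd)
  D <- block_similarity(disease_block, within_block_sim, between_block_sim,
                        sim_noise_sd)
  p_assoc <- ifelse(outer(drug_block, disease_block, "=="),
                    assoc_density_matched, assoc_density_unmatched)
  A <- matrix(stats::rbinom(n_drugs * n_diseases, 1, as.vector(p_assoc)),
              n_drugs, n_diseases)

  net <- hetero_network(R, D, A,
                        sprintf("r%03d", seq_len(n_drugs)),
                        sprintf("d%03d", seq_len(n_diseases)))
  attr(net, "drug_block") <- drug_block
  attr(net, "disease_block") <- disease_block
  net
}

block_similarity <- function(block, within, between, sd) {
  n <- length(block)
  mu <- ifelse(outer(block, block, "=="), within, between)
  M <- matrix(stats::rnorm(n * n, as.vector(mu), sd), n, n)
  M <- (M + t(M)) / 2
  M <- pmin(pmax(M, 0), 1)
  diag(M) <- 1
  M
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The six-drug, five-disease worked example network
#'
#' A fixed small network encoding the canonical worked example used
#' throughout the documentation and tests: drug r1 is similar to r2, r3 and
#' r6; disease d3 is similar to d1, d2 and d5; and the known associations are
#' r2-d3, r6-d3, r1-d1 and r1-d2. With the default edge threshold and a
#' three-node path limit, exactly four paths connect r1 to d3
#' (via r2, via r6, via d1 and via d2).
#'
#' @return A [hetero_network()] with 6 drugs and 5 diseases.
#' @examples
#' net <- worked_example_network()
#' sum(net$A)  # 4 known associations
#' @export
worked_example_network <- function() {
  drug_ids <- paste0("r", 1:6)
  disease_ids <- paste0("d", 1:5)
  R <- diag(6) * 0 + 0.2; diag(R) <- 1
  for (k in c(2, 3, 6)) { R[1, k] <- 0.8; R[k, 1] <- 0.8 }
  D <- diag(5) * 0 + 0.2; diag(D) <- 1
  for (l in c(1, 2, 5)) { D[3, l] <- 0.8; D[l, 3] <- 0.8 }
  A <- matrix(0, 6, 5)
  A[2, 3] <- 1; A[6, 3] <- 1; A[1, 1] <- 1; A[1, 2] <- 1
  hetero_network(R, D, A, drug_ids, disease_ids)
}

#' Shuffle the association matrix of a network
#'
#' Permutes all entries of `A` uniformly at random (preserving the number of
#' associations) so that associations become independent of the similarity
#' block structure. Used as a null control: a predictor trained on the
#' shuffled network should score near chance.
#'
#' @param net a `hetero_network`.
#' @param seed integer seed.
#' @return A `hetero_network` with permuted associations.
#' @export
shuffle_associations <- function(net, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  A <- net$A
  A[] <- sample(as.vector(A))
  out <- hetero_network(net$R, net$D, A, net$drug_ids, net$disease_ids)
  attr(out, "drug_block") <- attr(net, "drug_block")
  attr(out, "disease_block") <- attr(net, "disease_block")
  out
}
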