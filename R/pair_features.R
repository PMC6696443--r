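#' Build the per-pair feature matrix
#'
#' For a drug `i` and disease `j` the feature matrix `X` has two rows over
#' `Nr + Nd` columns: row 1 stacks the drug's similarity row `R[i, ]` with
#' its association row `A[i, ]`; row 2 stacks the disease's association
#' column `A[, j]` with its similarity row `D[j, ]`. These two rows juxtapose
#' the evidence the model reads locally: which drugs resemble `i`, which of
#' them are known to treat `j`, which diseases resemble `j`, and which of
#' those `i` is known to treat.
#'
#' When `mask_known = TRUE` and `A[i, j] == 1`, the two entries encoding the
#' pair's own association (column `Nr + j` of row 1 and column `i` of row 2)
#' are zeroed, so the label being predicted never appears in its own
#' features.
#'
#' @param net a [hetero_network()].
#' @param i drug index (1-based).
#' @param j disease index (1-based).
#' @param mask_known zero the pair's own association entries (default TRUE).
#' @return List of class `pair_features` with `X` (2 x (Nr+Nd)), `drug_index`,
#'   `disease_index` and `masked` (logical, whether entries were zeroed).
#' @examples
#' net <- worked_example_network()
#' pf <- build_pair_matrix(net, 1, 3)
#' dim(pf$X)
#' @export
build_pair_matrix <- function(net, i, j, mask_known = TRUE) {
  nr <- n_drugs(net); nd <- n_diseases(net)
  if (!(i >= 1 && i <= nr)) stop("drug index out of range", call. = FALSE)
  if (!(j >= 1 && j <= nd)) stop("disease index out of range", call. = FALSE)
  X <- rbind(c(net$R[i, ], net$A[i, ]),
             c(net$A[, j], net$D[j, ]))
  dimnames(X) <- NULL
  masked <- FALSE
  if (isTRUE(mask_known) && net$A[i, j] == 1) {
    X[1, nr + j] <- 0
    X[2, i] <- 0
    masked <- TRUE
  }
  structure(list(X = X, drug_index = i, disease_index = j, masked = masked),
            class = "pair_features")
}

#' Zero-pad a feature matrix
#'
#' Surrounds `X` with `p[1]` rows of zeros above and below and `p[2]` columns
#' of zeros left and right, so a convolution filter can see the matrix
#' boundary. The default padding for the standard architecture is `c(1, 10)`.
#'
#' @param X numeric matrix.
#' @param p integer vector `c(p_rows, p_cols)`, both nonnegative.
#' @return Matrix of dimension `(nrow(X) + 2 p[1]) x (ncol(X) + 2 p[2])`.
#' @examples
#' dim(pad_matrix(matrix(0, 2, 5), c(1, 10)))  # 4 x 25
#' @export
pad_matrix <- function(X, p = c(1L, 10L)) {
  p <- as.integer(p)
  if (length(p) != 2 || any(p < 0)) stop("p must be two nonnegative integers",
                                         call. = FALSE)
  if (all(p == 0L)) return(X)
  out <- matrix(0, nrow(X) + 2L * p[1], ncol(X) + 2L * p[2])
  out[p[1] + seq_len(nrow(X)), p[2] + seq_len(ncol(X))] <- X
  out
}
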