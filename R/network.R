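#' Heterogeneous drug-disease network
#'
#' Bundles the three matrices every other stage of the package reads: a
#' drug-drug similarity matrix `R` (values in `[0, 1]`, unit diagonal,
#' symmetric), a disease-disease similarity matrix `D` with the same
#' properties, and a binary drug-disease association matrix `A`. Row and
#' column labels are taken from the supplied id vectors and must be unique.
#'
#' Both similarity matrices are symmetrized as `(M + t(M)) / 2` when the
#' maximum absolute asymmetry is at most `asym_tol`; larger asymmetry is
#' treated as corrupt input and raises an error.
#'
#' @param R numeric `Nr x Nr` drug similarity matrix.
#' @param D numeric `Nd x Nd` disease similarity matrix.
#' @param A numeric `Nr x Nd` binary association matrix.
#' @param drug_ids character vector of `Nr` unique drug identifiers.
#' @param disease_ids character vector of `Nd` unique disease identifiers.
#' @param asym_tol maximum tolerated asymmetry before erroring (default `1e-6`).
#' @return An object of class `hetero_network` with elements `R`, `D`, `A`,
#'   `drug_ids`, `disease_ids`.
#' @examples
#' net <- hetero_network(diag(3), diag(2), matrix(0, 3, 2),
#'                       paste0("r", 1:3), paste0("d", 1:2))
#' n_drugs(net)
#' @export
hetero_network <- function(R, D, A, drug_ids, disease_ids, asym_tol = 1e-6) {
  R <- as.matrix(R); D <- as.matrix(D); A <- as.matrix(A)
  storage.mode(R) <- "double"; storage.mode(D) <- "double"
  storage.mode(A) <- "double"
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids", call. = FALSE)
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids", call. = FALSE)
  nr <- length(drug_ids); nd <- length(disease_ids)
  if (!all(dim(R) == c(nr, nr)))
    stop("R must be ", nr, "x", nr, " to match the drug ids", call. = FALSE)
  if (!all(dim(D) == c(nd, nd)))
    stop("D must be ", nd, "x", nd, " to match the disease ids", call. = FALSE)
  if (!all(dim(A) == c(nr, nd)))
    stop("A must be ", nr, "x", nd, call. = FALSE)
  R <- symmetrize_checked(R, "R", asym_tol)
  D <- symmetrize_checked(D, "D", asym_tol)
  if (any(R < 0 | R > 1)) stop("R entries must lie in [0, 1]", call. = FALSE)
  if (any(D < 0 | D > 1)) stop("D entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(diag(R) - 1) > 1e-8) || any(abs(diag(D) - 1) > 1e-8))
    stop("similarity matrices must have unit diagonal", call. = FALSE)
  diag(R) <- 1; diag(D) <- 1
  if (!all(A %in% c(0, 1)))
    stop("A entries must be binary (0/1)", call. = FALSE)
  dimnames(R) <- list(drug_ids, drug_ids)
  dimnames(D) <- list(disease_ids, disease_ids)
  dimnames(A) <- list(drug_ids, disease_ids)
  structure(
    list(R = R, D = D, A = A, drug_ids = drug_ids, disease_ids = disease_ids),
    class = "hetero_network"
  )
}

symmetrize_checked <- function(M, name, tol) {
  asym <- max(abs(M - t(M)))
  if (asym > tol)
    stop(name, " asymmetry ", format(asym), " exceeds tolerance ", tol,
         call. = FALSE)
  (M + t(M)) / 2
}

#' @rdname hetero_network
#' @param net a `hetero_network`.
#' @export
n_drugs <- function(net) length(net$drug_ids)

#' @rdname hetero_network
#' @export
n_diseases <- function(net) length(net$disease_ids)

#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network> ", n_drugs(x), " drugs x ", n_diseases(x),
      " diseases, ", sum(x$A), " known associations\n", sep = "")
  invisible(x)
}

read_labeled_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "")
  if (anyDuplicated(rownames(df)))
    stop("duplicate row ids in ", path, call. = FALSE)
  as.matrix(df)
}

#' Load a heterogeneous network from labeled TSV files
#'
#' Each file is UTF-8 tab-delimited with a header row of column ids and the
#' first column holding row ids. Ids in `R`/`D` must agree between rows and
#' columns; `A` rows must match `R`'s drugs and its columns `D`'s diseases.
#'
#' @param r_path,d_path,a_path paths to the drug similarity, disease
#'   similarity and association TSV files.
#' @return A validated [hetero_network()].
#' @seealso [write_network()]
#' @export
load_network <- function(r_path, d_path, a_path) {
  R <- read_labeled_tsv(r_path)
  D <- read_labeled_tsv(d_path)
  A <- read_labeled_tsv(a_path)
  if (!identical(rownames(R), colnames(R)))
    stop("R row/column ids disagree", call. = FALSE)
  if (!identical(rownames(D), colnames(D)))
    stop("D row/column ids disagree", call. = FALSE)
  if (!identical(rownames(A), rownames(R)))
    stop("A rows must match R's drug ids", call. = FALSE)
  if (!identical(colnames(A), rownames(D)))
    stop("A columns must match D's disease ids", call. = FALSE)
  hetero_network(R, D, A, rownames(R), rownames(D))
}

write_labeled_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a heterogeneous network to labeled TSV files
#'
#' @param net a `hetero_network`.
#' @param r_path,d_path,a_path output paths.
#' @return Invisibly, a character vector of the three paths written.
#' @export
write_network <- function(net, r_path, d_path, a_path) {
  write_labeled_tsv(net$R, r_path)
  write_labeled_tsv(net$D, d_path)
  write_labeled_tsv(net$A, a_path)
  invisible(c(r_path, d_path, a_path))
}

#' Cosine similarity between binary drug fingerprints
#'
#' Computes the full drug-drug cosine similarity matrix from a binary
#' substructure fingerprint matrix (drugs in rows, one column per
#' substructure bit; 869 bits in the standard public fingerprint). Rows that
#' are all zero have undefined cosine similarity; they are assigned
#' similarity 0 to every other drug and 1 to themselves so that the result
#' always satisfies the similarity-matrix invariants.
#'
#' @param bits binary matrix, drugs x fingerprint bits; rownames are drug ids.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal.
#' @examples
#' fp <- rbind(a = c(1, 1, 0), b = c(1, 0, 0))
#' cosine_drug_similarity(fp)[1, 2]  # 1 / sqrt(2)
#' @export
cosine_drug_similarity <- function(bits) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0, 1)))
    stop("fingerprint entries must be binary", call. = FALSE)
  if (all(bits == 0))
    stop("at least one fingerprint row must be nonzero", call. = FALSE)
  nrm <- sqrt(rowSums(bits^2))
  S <- tcrossprod(bits)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / denom, 0)
  S <- pmin(pmax((S + t(S)) / 2, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(rownames(bits), rownames(bits))
  S
}
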