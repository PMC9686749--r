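#' Identity-by-state genetic distance matrix
#'
#' `d(i, j) = 1 - DST(i, j)` over markers called in both samples (see
#' [pairwise_dst()]); zero diagonal, symmetric, `NA` for pairs sharing no
#' valid marker.
#'
#' @param g A [genotype_matrix()] with at least two samples.
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(g) {
  d <- 1 - pairwise_dst(g)
  diag(d) <- 0
  d
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' With `M` the dosage matrix and `p` the reference allele-b frequencies,
#' `Z = M - 2p` (missing dosages imputed to the marker mean `2p`) and
#' `G = Z Z' / (2 sum p (1 - p))`. Markers monomorphic at the frequencies
#' used are dropped from numerator and denominator. With in-sample
#' frequencies the matrix is column-centred: `G 1 ~ 0`.
#'
#' @param g A [genotype_matrix()].
#' @param freqs Either `"in-sample"` or a numeric vector of allele-b
#'   frequencies, one per marker.
#' @return A list of class `grm`: `G` (symmetric matrix with sample ids),
#'   `freqs` (frequencies used, `NA` at dropped markers), `n_markers_used`.
#' @export
grm_vanraden <- function(g, freqs = "in-sample") {
  d <- g$dosage
  if (identical(freqs, "in-sample")) {
    n_valid <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_valid, 1L))
    p[n_valid == 0L] <- NA_real_
  } else {
    if (length(freqs) != ncol(d))
      stop("need one frequency per marker (", ncol(d), ")")
    p <- as.numeric(freqs)
  }
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("all markers are monomorphic at the given frequencies")
  M <- d[, use, drop = FALSE]
  storage.mode(M) <- "double"
  pu <- p[use]
  center <- matrix(2 * pu, nrow(M), ncol(M), byrow = TRUE)
  Z <- M - center
  Z[is.na(Z)] <- 0  # missing imputed to the marker mean 2p
  denom <- 2 * sum(pu * (1 - pu))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$samples$id, g$samples$id)
  p_out <- p
  p_out[!use] <- NA_real_
  structure(list(G = G, freqs = p_out, n_markers_used = sum(use)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("VanRaden G matrix: ", nrow(x$G), " samples, ",
      x$n_markers_used, " markers\n", sep = "")
  cat("  mean diagonal: ", format(mean(diag(x$G)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of a relationship matrix
#'
#' Eigendecomposition of the (symmetric) G matrix; sample coordinates are
#' `eigenvector * sqrt(max(eigenvalue, 0))`, components ordered by
#' descending eigenvalue. Sign convention: in each component the loading of
#' largest magnitude is positive.
#'
#' @param G A `grm` object or a symmetric numeric matrix.
#' @param k Number of components to return (default all).
#' @return A list of class `grm_pca`: `eigenvalues` (all of them),
#'   `coordinates` (n x k), `var_explained` (fractions, over positive
#'   eigenvalues).
#' @export
grm_pca <- function(G, k = NULL) {
  if (inherits(G, "grm")) G <- G$G
  if (!isSymmetric(unname(G), tol = 1e-8))
    stop("relationship matrix must be symmetric")
  n <- nrow(G)
  if (is.null(k)) k <- n
  if (k > n) stop("k cannot exceed the number of samples")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    big <- which.max(abs(vec[, j]))
    if (vec[big, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- sweep(vec, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  pos <- pmax(e$values, 0)
  structure(list(eigenvalues = e$values,
                 coordinates = coords,
                 var_explained = if (sum(pos) > 0) pos / sum(pos) else pos),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("PCA of relationship matrix\n  top eigenvalues: ",
      paste(format(x$eigenvalues[seq_len(k)], digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
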