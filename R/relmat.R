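# Genomic (G) and blended single-step (H) relationship matrices.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum(p_j (1 - p_j)))` where `M` holds the 0/1/2 allele
#' counts centred at twice the observed allele frequency. Missing codes are
#' imputed to `2 p_j` (i.e. contribute zero after centring); monomorphic
#' markers are dropped.
#'
#' @param genotypes Numeric matrix of 0/1/2 codes (animals in rows, ids as
#'   rownames; `NA` allowed).
#' @return Dense symmetric genomic relationship matrix.
#' @export
#' @examples
#' g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), NULL))
#' build_G(g) # [[2, -2], [-2, 2]]
build_G <- function(genotypes) {
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes)
  if (!is.matrix(genotypes) || nrow(genotypes) < 2 || ncol(genotypes) < 1)
    stop("genotypes must be a matrix with >= 2 animals and >= 1 marker")
  if (is.null(rownames(genotypes))) stop("genotypes must have animal ids as rownames")
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  if (!any(keep)) stop("all markers are monomorphic")
  codes <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  M <- sweep(codes, 2, 2 * p)
  M[is.na(M)] <- 0
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  G
}

#' Blend pedigree and genomic relationships into the single-step H matrix
#'
#' The genomic matrix is first regressed towards the pedigree block,
#' `G* = lambda * G + (1 - lambda) * A22` (weight on the genomic
#' information), which also guarantees invertibility. H then equals A with
#' the genotyped block replaced by `G*` and the covariances with
#' non-genotyped animals updated through the standard partitioned identity
#' `H = A + [[T D T', T D], [D T', D]]` with `D = G* - A22` and
#' `T = A12 A22^-1`.
#'
#' @param A Dense numerator relationship matrix (ids as dimnames).
#' @param G Genomic relationship matrix for the genotyped subset.
#' @param lambda Blending weight on G in `[0, 1]` (default 0.95).
#' @return Dense H matrix in the id order of `A`.
#' @export
blend_H <- function(A, G, lambda = 0.95) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry ids as dimnames")
  gids <- rownames(G) %||% character(0)
  if (!length(gids)) return(A)
  if (!all(gids %in% ids)) stop("genotyped animals absent from A")
  g <- match(gids, ids)
  n <- setdiff(seq_along(ids), g)
  A22 <- A[g, g, drop = FALSE]
  Gs <- lambda * G + (1 - lambda) * A22
  A22inv <- tryCatch(solve(A22), error = function(e)
    stop("A22 is singular; a deeper pedigree for the genotyped animals is needed"))
  D <- Gs - A22
  H <- A
  H[g, g] <- Gs
  if (length(n)) {
    T12 <- A[n, g, drop = FALSE] %*% A22inv
    H[n, g] <- A[n, g, drop = FALSE] + T12 %*% D
    H[g, n] <- t(H[n, g])
    H[n, n] <- A[n, n, drop = FALSE] + T12 %*% D %*% t(T12)
  }
  H
}

#' Write a relationship matrix as sparse three-column text
#'
#' Lower triangle only, columns `id_i`, `id_j`, `value`; zeros are skipped.
#' This is the interchange format used by common mixed-model software.
#'
#' @param mat Symmetric relationship matrix with ids as dimnames.
#' @param path Output file path.
#' @param tol Entries with `|value| <= tol` are omitted.
#' @export
write_relmat <- function(mat, path, tol = 0) {
  ids <- rownames(mat)
  m <- as.matrix(mat)
  idx <- which(lower.tri(m, diag = TRUE) & abs(m) > tol, arr.ind = TRUE)
  out <- data.frame(id_i = ids[idx[, 1]], id_j = ids[idx[, 2]],
                    value = m[idx], stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
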