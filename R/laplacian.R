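## Combinatorial and persistent Laplacians.
##
## All chain groups carry the Kronecker-delta inner product on the simplex
## basis, so adjoints are matrix transposes.  The persistent up-term is built
## from an orthonormal basis (SVD null space) of the admissible subspace of
## (k+1)-chains at the larger scale whose boundary lands in the k-chains of
## the smaller scale; a Schur-complement construction of the same operator is
## kept as a verification oracle.

svd_nullspace <- function(mat, tol = 1e-10) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n == 0L) return(matrix(0, 0, 0))
  if (nrow(mat) == 0L) return(diag(n))
  sv <- svd(mat, nu = 0, nv = n)
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r >= n) matrix(0, n, 0) else sv$v[, (r + 1L):n, drop = FALSE]
}

pinv_psd <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) == 0L) return(A)
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 1)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / e$values[pos])
}

#' Combinatorial Laplacian of a sublevel complex
#'
#' `L_k = d_(k+1) d_(k+1)^T + d_k^T d_k` on the k-chains of the sublevel
#' complex at `eps`.  For `k = 0` this is the graph Laplacian of the
#' 1-skeleton.  When no k-simplices exist the result is a 0 x 0 matrix.
#'
#' @param fc a `filtered_complex`.
#' @param k chain dimension, `0 <= k <= max_dim`.  The up-term vanishes at
#'   `k = max_dim` because no higher simplices are stored.
#' @param eps scale.
#' @return A dense symmetric positive semidefinite matrix of size
#'   `N_k x N_k`.
#' @examples
#' fc <- rips_filtration(pairwise_distances(stretched_octahedron()))
#' eigen(combinatorial_laplacian(fc, 0, 1.5))$values
#' @export
combinatorial_laplacian <- function(fc, k, eps = Inf) {
  stopifnot(inherits(fc, "filtered_complex"))
  k <- as.integer(k)
  if (k < 0L || k > fc$max_dim)
    stop(sprintf("k must be between 0 and max_dim = %d", fc$max_dim))
  Bk <- boundary_matrix(fc, k, eps, "float")$matrix
  nk <- ncol(Bk)
  if (nk == 0L) return(matrix(0, 0, 0))
  L <- Matrix::crossprod(Bk)           # down term d_k^T d_k
  if (k < fc$max_dim) {
    Bk1 <- boundary_matrix(fc, k + 1L, eps, "float")$matrix
    if (ncol(Bk1) > 0L) L <- L + Matrix::tcrossprod(Bk1)
  }
  as.matrix(L)
}

#' Persistent boundary operator
#'
#' Restriction of the (k+1)-boundary at the larger scale to the largest
#' subspace of (k+1)-chains whose image lies in the k-chains of the smaller
#' scale.  The subspace is materialized as the SVD null space of the rows of
#' the boundary indexed by k-simplices present at `eps_j` but not at `eps_i`;
#' the returned matrix has rows indexed by the k-simplices of the smaller
#' complex and columns forming an orthonormal basis of the admissible
#' subspace.
#'
#' @param fc a `filtered_complex`.
#' @param k_plus_1 dimension of the mapped chains (`k + 1`).
#' @param eps_i,eps_j scales with `eps_i <= eps_j`.
#' @return List with `matrix` (the persistent boundary, dense), `rows`
#'   (k-simplices of the smaller complex), `basis` (orthonormal basis `Z` of
#'   the admissible subspace in the (k+1)-simplex basis at `eps_j`), and
#'   `rank` (its rank).
#' @export
persistent_boundary <- function(fc, k_plus_1, eps_i, eps_j) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (eps_i > eps_j) stop("eps_i must not exceed eps_j")
  k <- as.integer(k_plus_1) - 1L
  if (k < 0L || k_plus_1 > fc$max_dim)
    stop(sprintf("k_plus_1 must be between 1 and max_dim = %d", fc$max_dim))
  Bj <- boundary_matrix(fc, k + 1L, eps_j, "float")
  rows_j <- simplices_at(fc, k, eps_j)
  in_i <- rows_j$births <= eps_i
  B <- as.matrix(Bj$matrix)
  if (ncol(B) == 0L) {
    R <- matrix(0, sum(in_i), 0)
    return(list(matrix = R, rows = rows_j$simplices[in_i],
                basis = matrix(0, 0, 0), rank = 0L))
  }
  if (all(in_i)) {
    Z <- diag(ncol(B))
  } else {
    Z <- svd_nullspace(B[!in_i, , drop = FALSE])
  }
  R <- B[in_i, , drop = FALSE] %*% Z
  list(matrix = R, rows = rows_j$simplices[in_i], basis = Z,
       rank = real_rank(R))
}

make_spectrum <- function(k, eps_i, eps_j, values, zero_tol_rel = 1e-8,
                          zero_tol_abs = 1e-10) {
  values <- sort(values)
  zero_tol <- max(zero_tol_abs,
                  zero_tol_rel * max(values, 0))
  structure(list(k = k, eps_i = eps_i, eps_j = eps_j,
                 eigenvalues = values, zero_tol = zero_tol,
                 harmonic_multiplicity = sum(values < zero_tol),
                 lambda_min_positive = {
                   pos <- values[values >= zero_tol]
                   if (length(pos)) pos[1L] else NA_real_
                 },
                 n_k = length(values)),
            class = "laplacian_spectrum")
}

#' @export
print.laplacian_spectrum <- function(x, ...) {
  cat(sprintf(
    "<laplacian_spectrum> k=%d, scales (%.4g, %.4g): N_k=%d, harmonic=%d, lambda_min+=%s\n",
    x$k, x$eps_i, x$eps_j, x$n_k, x$harmonic_multiplicity,
    if (is.na(x$lambda_min_positive)) "none" else
      format(x$lambda_min_positive, digits = 6)))
  invisible(x)
}

#' Persistent Laplacian spectrum
#'
#' Spectrum of the persistent Laplacian acting on the k-chains of the
#' sublevel complex at `eps_i`, whose up-term uses the persistent boundary of
#' (k+1)-chains at `eps_j` (see [persistent_boundary()]).  The multiplicity
#' of the (numerically) zero eigenvalue equals the persistent Betti number
#' between the two scales, and at `eps_i = eps_j` the operator reduces to the
#' ordinary combinatorial Laplacian.
#'
#' @param fc a `filtered_complex`.
#' @param k chain dimension.
#' @param eps_i,eps_j scales with `eps_i <= eps_j`.
#' @param method `"nullspace"` (orthonormal admissible basis, the default) or
#'   `"schur"` (Schur complement of the up-Laplacian at `eps_j` onto the
#'   k-chains at `eps_i`; verification oracle).
#' @param zero_tol_rel,zero_tol_abs harmonic threshold: eigenvalues below
#'   `max(zero_tol_abs, zero_tol_rel * max(eigenvalue))` count as zero.
#' @return A `laplacian_spectrum` object: ascending `eigenvalues`,
#'   `harmonic_multiplicity`, `lambda_min_positive`, `zero_tol`.  When no
#'   k-simplices exist at `eps_i` the spectrum is empty (no error).
#' @examples
#' fc <- rips_filtration(pairwise_distances(octagon(2)))
#' persistent_laplacian(fc, 1, 1.6, 3.6)   # one harmonic class: the loop
#' @export
persistent_laplacian <- function(fc, k, eps_i, eps_j = eps_i,
                                 method = c("nullspace", "schur"),
                                 zero_tol_rel = 1e-8, zero_tol_abs = 1e-10) {
  stopifnot(inherits(fc, "filtered_complex"))
  method <- match.arg(method)
  if (eps_i > eps_j) stop("eps_i must not exceed eps_j")
  k <- as.integer(k)
  if (k < 0L || k > fc$max_dim)
    stop(sprintf("k must be between 0 and max_dim = %d", fc$max_dim))
  Bk <- boundary_matrix(fc, k, eps_i, "float")$matrix
  nk <- ncol(Bk)
  if (nk == 0L)
    return(make_spectrum(k, eps_i, eps_j, numeric(0),
                         zero_tol_rel, zero_tol_abs))
  L <- as.matrix(Matrix::crossprod(Bk))    # down term at eps_i
  if (k < fc$max_dim) {
    if (eps_i == eps_j) {
      Bk1 <- boundary_matrix(fc, k + 1L, eps_j, "float")$matrix
      if (ncol(Bk1) > 0L) L <- L + as.matrix(Matrix::tcrossprod(Bk1))
    } else if (method == "nullspace") {
      R <- persistent_boundary(fc, k + 1L, eps_i, eps_j)$matrix
      if (ncol(R) > 0L) L <- L + tcrossprod(R)
    } else {
      Bj <- boundary_matrix(fc, k + 1L, eps_j, "float")$matrix
      if (ncol(Bj) > 0L) {
        rows_j <- simplices_at(fc, k, eps_j)
        in_i <- rows_j$births <= eps_i
        Lup <- as.matrix(Matrix::tcrossprod(Bj))
        A_II <- Lup[in_i, in_i, drop = FALSE]
        if (any(!in_i)) {
          A_IO <- Lup[in_i, !in_i, drop = FALSE]
          A_OO <- Lup[!in_i, !in_i, drop = FALSE]
          A_II <- A_II - A_IO %*% pinv_psd(A_OO) %*% t(A_IO)
        }
        L <- L + A_II
      }
    }
  }
  vals <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  make_spectrum(k, eps_i, eps_j, vals, zero_tol_rel, zero_tol_abs)
}

#' Smallest-positive-eigenvalue curves across a scale grid
#'
#' For each dimension `k <= k_max` and each grid scale, the smallest
#' eigenvalue of the combinatorial Laplacian above the harmonic threshold
#' (the diagonal `eps_i = eps_j` case), together with the harmonic
#' multiplicity.  Entries are `NA` where no k-simplices exist or where the
#' spectrum is entirely harmonic.
#'
#' @param fc a `filtered_complex`.
#' @param k_max largest dimension (default 2).
#' @param grid sorted vector of scales.
#' @param ... passed to [persistent_laplacian()] (harmonic threshold).
#' @return A data frame with columns `k`, `eps`, `lambda_min_positive`,
#'   `harmonic_multiplicity`, `n_k`.
#' @export
spectrum_curves <- function(fc, k_max = 2L, grid, ...) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  rows <- list()
  for (k in 0:k_max) {
    for (eps in grid) {
      sp <- persistent_laplacian(fc, k, eps, eps, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, eps = eps,
        lambda_min_positive = sp$lambda_min_positive,
        harmonic_multiplicity = if (sp$n_k) sp$harmonic_multiplicity
                                else NA_integer_,
        n_k = sp$n_k)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
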