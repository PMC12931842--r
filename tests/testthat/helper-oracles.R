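# Independent oracles used across the suite.  They deliberately avoid the
# package's GF(2) reduction engine: ranks are taken over the reals with
# base::qr / base::svd on signed boundary matrices, and complexes are
# enumerated by brute force, so agreement with the package is a genuine
# two-route check.

random_cloud <- function(n, scale = 2) {
  ripstack::point_cloud(matrix(stats::runif(3 * n, 0, scale), ncol = 3))
}

# brute-force Vietoris-Rips: every vertex subset of size <= max_dim + 1 whose
# pairwise distances are all <= max_scale, with birth = max pairwise distance
brute_rips <- function(dm, max_dim, max_scale = Inf) {
  n <- nrow(dm)
  out <- list()
  for (s in 1:min(max_dim + 1L, n)) {
    subsets <- utils::combn(n, s)
    for (ci in seq_len(ncol(subsets))) {
      v <- subsets[, ci]
      b <- if (s == 1L) 0 else max(dm[v, v])
      if (b <= max_scale)
        out[[length(out) + 1L]] <- list(vertices = v, birth = b)
    }
  }
  out
}

real_null_basis <- function(mat, tol = 1e-9) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n == 0L) return(matrix(0, 0, 0))
  if (nrow(mat) == 0L) return(diag(n))
  sv <- svd(mat, nu = 0, nv = n)
  r <- sum(sv$d > tol * max(sv$d, 1))
  if (r >= n) matrix(0, n, 0) else sv$v[, (r + 1L):n, drop = FALSE]
}

qr_rank <- function(mat, tol = 1e-9) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) return(0L)
  qr(mat, tol = tol)$rank
}

# persistent Betti number over the reals from first principles:
# beta_k^{i,j} = dim Z_k(K_i) - dim( B_k(K_j) \cap Z_k(K_i) )
oracle_persistent_betti <- function(fc, k, eps_i, eps_j) {
  Bki <- as.matrix(ripstack::boundary_matrix(fc, k, eps_i, "float")$matrix)
  nk <- ncol(Bki)
  if (nk == 0L) return(0L)
  Z <- real_null_basis(Bki)
  keys_i <- vapply(ripstack::boundary_matrix(fc, k, eps_i)$cols,
                   function(v) paste(v, collapse = "|"), character(1))
  keys_j <- vapply(ripstack::boundary_matrix(fc, k, eps_j)$cols,
                   function(v) paste(v, collapse = "|"), character(1))
  Zbig <- matrix(0, length(keys_j), ncol(Z))
  Zbig[match(keys_i, keys_j), ] <- Z
  Bj <- if (k + 1L > fc$max_dim) matrix(0, length(keys_j), 0) else
    as.matrix(ripstack::boundary_matrix(fc, k + 1L, eps_j, "float")$matrix)
  rb <- qr_rank(Bj)
  rz <- ncol(Z)
  inter <- rb + rz - qr_rank(cbind(Bj, Zbig))
  rz - inter
}

# ordinary Betti numbers over the reals (rank-nullity on signed matrices)
oracle_betti <- function(fc, eps) {
  vapply(0:fc$max_dim, function(k) {
    B <- ripstack::boundary_matrix(fc, k, eps, "float")$matrix
    nk <- ncol(B)
    if (nk == 0L) return(0L)
    rk <- qr_rank(B)
    rk1 <- if (k + 1L > fc$max_dim) 0L else
      qr_rank(ripstack::boundary_matrix(fc, k + 1L, eps, "float")$matrix)
    as.integer(nk - rk - rk1)
  }, integer(1))
}

# maximal simplices of the sublevel complex by pairwise containment
brute_facets <- function(fc, eps) {
  present <- which(fc$births <= eps)
  sims <- fc$simplices[present]
  is_max <- vapply(seq_along(sims), function(a) {
    va <- sims[[a]]
    !any(vapply(seq_along(sims), function(b) {
      b != a && length(sims[[b]]) > length(va) && all(va %in% sims[[b]])
    }, logical(1)))
  }, logical(1))
  sims[is_max]
}

simplex_set_keys <- function(sims) {
  sort(vapply(sims, function(v) paste(v, collapse = "|"), character(1)))
}
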