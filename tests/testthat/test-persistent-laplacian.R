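test_that("combinatorial Laplacian reduces to the graph Laplacian at k = 0", {
  two <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  fc <- rips_filtration(pairwise_distances(two), max_dim = 1)
  L0 <- combinatorial_laplacian(fc, 0, 1)
  expect_equal(sort(eigen(L0, symmetric = TRUE)$values), c(0, 2))

  # 8-cycle at a scale just above the octagon's first critical radius:
  # closed-form spectrum 2 - 2 cos(2 pi m / 8)
  fo <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 2)
  L <- combinatorial_laplacian(fo, 0, 1.6)
  got <- sort(eigen(L, symmetric = TRUE)$values)
  expected <- sort(2 - 2 * cos(2 * pi * (0:7) / 8))
  expect_equal(got, expected, tolerance = 1e-9)
  expect_equal(sum(abs(got) < 1e-8), 1L)  # single component
})

test_that("every nonzero eigenvalue of a full simplex Laplacian equals n", {
  set.seed(5)
  for (n in c(4, 5, 6)) {
    pc <- random_cloud(n)
    dm <- pairwise_distances(pc)
    fc <- rips_filtration(dm, max_dim = n - 1)
    for (k in 0:2) {
      sp <- persistent_laplacian(fc, k, max(dm), max(dm))
      pos <- sp$eigenvalues[sp$eigenvalues > sp$zero_tol]
      expect_equal(pos, rep(n, length(pos)), tolerance = 1e-8)
    }
  }
})

test_that("spectra are positive semidefinite up to numerics", {
  set.seed(13)
  for (rep in 1:3) {
    pc <- random_cloud(6)
    dm <- pairwise_distances(pc)
    fc <- rips_filtration(dm, max_dim = 3)
    cs <- critical_scales(dm)
    for (i in seq_along(cs)) for (k in 0:2) {
      sp <- persistent_laplacian(fc, k, cs[i], cs[length(cs)])
      if (sp$n_k > 0)
        expect_gte(min(sp$eigenvalues),
                   -1e-8 * max(1, max(sp$eigenvalues)))
    }
  }
})

test_that("persistent Laplacian at equal scales is the ordinary Laplacian", {
  fc <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  for (eps in c(1.5, 2.0, 3.0)) for (k in 0:2) {
    L <- combinatorial_laplacian(fc, k, eps)
    if (nrow(L) == 0) next
    sp <- persistent_laplacian(fc, k, eps, eps)
    expect_equal(sp$eigenvalues, sort(eigen(L, symmetric = TRUE)$values),
                 tolerance = 1e-9)
  }
})

test_that("persistent boundary restricts to the admissible subspace", {
  fc <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  eps2 <- sqrt(3.25)
  # triangles at eps2 whose edges all exist at eps2: full boundary retained
  pb_same <- persistent_boundary(fc, 2, eps2, eps2)
  expect_equal(ncol(pb_same$matrix),
               sum(fc$dims == 2 & fc$births <= eps2))
  # strictly persistent pair: admissible columns' boundaries must vanish on
  # k-simplices missing at the smaller scale (checked via the basis)
  pb <- persistent_boundary(fc, 2, 1.5, eps2)
  B <- as.matrix(boundary_matrix(fc, 2, eps2, "float")$matrix)
  rows_j <- boundary_matrix(fc, 1, eps2)$cols
  births_j <- vapply(rows_j, function(v)
    max(pairwise_distances(stretched_octahedron())[v, v]), numeric(1))
  out_rows <- which(births_j > 1.5)
  if (length(out_rows) && ncol(pb$basis))
    expect_lt(max(abs(B[out_rows, , drop = FALSE] %*% pb$basis)), 1e-10)
  # a 4-point fixture where one triangle edge is missing at the small scale:
  # no admissible combination survives except those cancelling on it
  tri <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.9, 0),
                           c(10, 0, 0)))
  ft <- rips_filtration(pairwise_distances(tri), max_dim = 2)
  d12 <- max(pairwise_distances(tri)[1:3, 1:3])
  pb2 <- persistent_boundary(ft, 2, 1.0, d12)  # long edges absent at 1.0
  expect_equal(ncol(pb2$basis), 0L)            # single triangle, edge missing
})

test_that("harmonic multiplicity equals the persistent Betti number", {
  fc <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
  sp <- persistent_laplacian(fc, 1, 1.6, 3.6)
  expect_equal(sp$harmonic_multiplicity, 1L)

  set.seed(29)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    pc <- random_cloud(n)
    dm <- pairwise_distances(pc)
    f <- rips_filtration(dm, max_dim = 3)
    bc <- compute_barcode(f)
    cs <- critical_scales(dm)
    for (i in seq_along(cs)) for (j in i:length(cs)) for (k in 0:2) {
      sp <- persistent_laplacian(f, k, cs[i], cs[j])
      if (sp$n_k == 0) next
      expect_equal(sp$harmonic_multiplicity,
                   persistent_betti(f, k, cs[i], cs[j], barcode = bc),
                   info = sprintf("n=%d k=%d pair (%d,%d)", n, k, i, j))
    }
  }
})

test_that("null-space and Schur-complement constructions agree", {
  fixtures <- list(
    rips_filtration(pairwise_distances(octagon(2)), max_dim = 3),
    rips_filtration(pairwise_distances(stretched_octahedron()), max_dim = 3))
  for (fc in fixtures) {
    pairs <- list(c(1.6, 2.9), c(1.6, 3.6), c(2.9, 3.6), c(1.9, 2.1))
    for (p in pairs) for (k in 0:2) {
      a <- persistent_laplacian(fc, k, p[1], p[2], method = "nullspace")
      b <- persistent_laplacian(fc, k, p[1], p[2], method = "schur")
      expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-8,
                   info = sprintf("k=%d pair (%.2f, %.2f)", k, p[1], p[2]))
    }
  }
})

test_that("persistent Hodge decomposition dimensions add up", {
  set.seed(37)
  for (rep in 1:3) {
    pc <- random_cloud(6)
    dm <- pairwise_distances(pc)
    fc <- rips_filtration(dm, max_dim = 3)
    cs <- critical_scales(dm)
    i <- ceiling(length(cs) / 2); j <- length(cs)
    for (k in 0:2) {
      Bk <- boundary_matrix(fc, k, cs[i], "float")$matrix
      nk <- ncol(Bk)
      if (nk == 0) next
      sp <- persistent_laplacian(fc, k, cs[i], cs[j])
      pb <- persistent_boundary(fc, k + 1, cs[i], cs[j])
      expect_equal(nk, pb$rank + sp$harmonic_multiplicity + qr_rank(Bk))
    }
  }
})

test_that("spectrum is invariant under vertex relabeling", {
  set.seed(41)
  pc <- random_cloud(6)
  dm <- pairwise_distances(pc)
  perm <- sample(6)
  dmp <- dm[perm, perm]
  a <- rips_filtration(dm, max_dim = 3)
  b <- rips_filtration(dmp, max_dim = 3)
  cs <- critical_scales(dm)
  i <- cs[ceiling(length(cs) / 2)]; j <- cs[length(cs)]
  for (k in 0:2) {
    sa <- persistent_laplacian(a, k, i, j)
    sb <- persistent_laplacian(b, k, i, j)
    expect_equal(sa$eigenvalues, sb$eigenvalues, tolerance = 1e-8)
  }
})

test_that("spectrum curves report the smallest positive eigenvalue", {
  fo <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 2)
  sc <- spectrum_curves(fo, k_max = 1, grid = c(1.0, 1.6, 3.0))
  # before any edge: L0 is the zero matrix, no positive eigenvalue
  expect_true(is.na(sc$lambda_min_positive[sc$k == 0 & sc$eps == 1.0]))
  # 8-cycle algebraic connectivity (Fiedler value)
  expect_equal(sc$lambda_min_positive[sc$k == 0 & sc$eps == 1.6],
               2 - 2 * cos(2 * pi / 8), tolerance = 1e-9)
  # no 1-simplices at all below the first critical scale
  expect_equal(sc$n_k[sc$k == 1 & sc$eps == 1.0], 0L)
  expect_error(spectrum_curves(fo, 1, c(2, 1)), "sorted")
})
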