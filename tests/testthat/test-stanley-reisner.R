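unit_square <- function() {
  point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
}

test_that("minimal nonfaces generate the Stanley-Reisner ideal", {
  sq <- rips_filtration(pairwise_distances(unit_square()), max_dim = 3)
  gens <- minimal_nonfaces(sq, 1.0)
  expect_equal(simplex_set_keys(gens$generators), c("1|3", "2|4"))
  # full simplex: no nonfaces
  full <- minimal_nonfaces(sq, 2.0)
  expect_equal(length(full$generators), 0L)
  # octagon just above eps1: exactly the 20 non-adjacent pairs
  fo <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
  g8 <- minimal_nonfaces(fo, 1.6)
  expect_equal(length(g8$generators), 20L)
  expect_true(all(lengths(g8$generators) == 2L))
})

test_that("minimality: no generator contains another, none is a face", {
  set.seed(53)
  for (rep in 1:3) {
    fc <- rips_filtration(pairwise_distances(random_cloud(6)), max_dim = 3)
    eps <- stats::runif(1, 0.5, 2.5)
    gens <- minimal_nonfaces(fc, eps)$generators
    keys <- simplex_set_keys(fc$simplices[fc$births <= eps])
    for (a in seq_along(gens)) {
      expect_false(paste(gens[[a]], collapse = "|") %in% keys)
      for (b in seq_along(gens)) {
        if (a != b)
          expect_false(all(gens[[a]] %in% gens[[b]]))
      }
    }
  }
})

test_that("facet ideal intersection recovers the nonface criterion", {
  # a monomial lies in every facet ideal iff its support is a nonface
  set.seed(59)
  fc <- rips_filtration(pairwise_distances(random_cloud(5)), max_dim = 4)
  eps <- stats::runif(1, 0.8, 2)
  facets <- brute_facets(fc, eps)
  present <- simplex_set_keys(fc$simplices[fc$births <= eps])
  n <- fc$n_vertices
  for (s in 1:n) {
    subsets <- utils::combn(n, s)
    for (ci in seq_len(ncol(subsets))) {
      W <- subsets[, ci]
      in_every_facet_ideal <- all(vapply(facets, function(f)
        any(!(W %in% f)), logical(1)))
      is_nonface <- !(paste(W, collapse = "|") %in% present)
      expect_equal(in_every_facet_ideal, is_nonface)
    }
  }
})

test_that("ideals form a descending chain along the filtration", {
  fc <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  expect_true(ideal_chain_check(fc, c(1.0, 1.5, 2.0, 2.5, 3.0)))
  expect_true(ideal_chain_check(fc, 2.0))
  # corrupted chain: a generator at the larger scale that divides into no
  # earlier generator (the "face missing at larger scale" violation)
  good <- minimal_nonfaces(fc, 1.5)
  bad <- list(eps = 2.0,
              generators = list(c(1L, 2L)),   # an edge present at 1.5
              labels = fc$labels)
  class(bad) <- "sr_generators"
  expect_false(ideal_chain_check(list(good, bad)))
})

test_that("facet barcode matches the octagon and octahedron narratives", {
  eps <- 2 * 2 * sin((1:4) * pi / 8)
  fo <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
  fb <- facet_barcode(fo)
  v <- subset(fb, dim == 0)
  expect_equal(nrow(v), 8L)
  expect_equal(v$birth, rep(0, 8))
  expect_equal(v$death, rep(eps[1], 8), tolerance = 1e-9)
  # perimeter-edge facets die when triangles arrive at eps2
  e <- subset(fb, dim == 1 & abs(birth - eps[1]) < 1e-9)
  expect_equal(nrow(e), 8L)
  expect_equal(e$death, rep(eps[2], 8), tolerance = 1e-9)

  so <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  fbo <- facet_barcode(so)
  shell <- subset(fbo, dim == 2 & abs(birth - sqrt(3.25)) < 1e-9)
  expect_equal(nrow(shell), 8L)
  expect_equal(shell$death, rep(2.0, 8), tolerance = 1e-9)
})

test_that("live facets equal the brute-force maximal-simplex enumeration", {
  set.seed(61)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    pc <- random_cloud(n)
    dm <- pairwise_distances(pc)
    fc <- rips_filtration(dm, max_dim = 3)
    fb <- facet_barcode(fc)
    for (eps in critical_scales(dm)) {
      live <- fb[fb$birth <= eps & fb$death > eps, ]
      expected <- simplex_set_keys(brute_facets(fc, eps))
      got <- sort(vapply(strsplit(live$vertices, ","), function(lv)
        paste(match(lv, fc$labels), collapse = "|"), character(1)))
      expect_equal(got, expected, info = sprintf("n=%d eps=%.3f", n, eps))
    }
  }
})

test_that("facet persistence Betti counts interval containment", {
  eps <- 2 * 2 * sin((1:4) * pi / 8)
  fo <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
  fb <- facet_barcode(fo)
  expect_equal(facet_persistence_betti(fb, 0, 0, eps[1] - 0.01), 8L)
  expect_equal(facet_persistence_betti(fb, 0, 0, eps[1] + 0.01), 0L)
  # diagonal equals the facet count at that scale
  expect_equal(facet_persistence_betti(fb, 1, eps[1], eps[1]),
               sum(fb$dim == 1 & fb$birth <= eps[1] & fb$death > eps[1]))
  expect_error(facet_persistence_betti(fb, 0, 2, 1), "eps")
})

test_that("f-vectors count simplices; octahedron milestones reproduced", {
  so <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  f3 <- f_vector(so, 3.0)
  expect_equal(f3$f, c(1, 6, 15, 20, 15))
  expect_equal(f_vector(so, 2.0)$f[5], 9)
  expect_equal(f_vector(so, 1.0)$f, c(1, 6))   # vertices only
  expect_equal(sum(f3$h), f3$f[length(f3$f)])  # sum h_m = f_{d-1}
  expect_equal(f3$h[1], 1)
})

test_that("h/f binomial transforms invert each other", {
  expect_equal(h_from_f(c(1, 6, 12, 8)), c(1, 3, 3, 1))
  expect_equal(f_from_h(c(1, 3, 3, 1), 3), c(1, 6, 12, 8))
  expect_equal(h_from_f(1, 0), 1)
  # full simplex on n vertices: h = (1, 0, ..., 0)
  for (n in 3:6) {
    f <- c(1, vapply(1:n, function(s) choose(n, s), numeric(1)))
    expect_equal(h_from_f(f, n), c(1, rep(0, n)))
    expect_equal(f_from_h(c(1, rep(0, n)), n), f)
  }
  set.seed(67)
  for (rep in 1:5) {
    fc <- rips_filtration(pairwise_distances(random_cloud(6)), max_dim = 3)
    fv <- f_vector(fc, stats::runif(1, 0.5, 3))
    expect_equal(f_from_h(fv$h, fv$d), fv$f)
    expect_equal(h_from_f(fv$f, fv$d), fv$h)
  }
})

test_that("Hochster graded Betti numbers match hand-resolved ideals", {
  # unit square: I = (x1 x3, x2 x4), Koszul complex on two coprime monomials
  sq <- rips_filtration(pairwise_distances(unit_square()), max_dim = 3)
  tab <- graded_betti(sq, 1.0, strands = 1:2)
  expect_equal(gb_entry(tab, 1, 2), 2)
  expect_equal(gb_entry(tab, 2, 4), 1)
  expect_equal(sum(tab$value), 3)   # nothing else on strands 1-2

  # octahedron at eps2: three four-vertex cycles
  so <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  t2 <- graded_betti(so, sqrt(3.25), strands = 1:3)
  expect_equal(gb_entry(t2, 2, 4), 3)

  # full simplex: free ring, all entries vanish
  full <- graded_betti(sq, 2.0, strands = 1:3)
  expect_equal(nrow(full), 0L)
})

test_that("Hochster sums against independent real-rank reduced homology", {
  set.seed(71)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    pc <- random_cloud(n)
    fc <- rips_filtration(pairwise_distances(pc), max_dim = 3)
    eps <- stats::runif(1, 0.8, 2.5)
    tab <- graded_betti(fc, eps, strands = 1:2)
    for (j in 1:2) for (s in j:n) {
      expected <- 0L
      subsets <- utils::combn(n, s)
      for (ci in seq_len(ncol(subsets))) {
        W <- subsets[, ci]
        sub <- induced_subcomplex(fc, W, eps)
        if (length(sub$simplices) == 0) next
        b <- oracle_betti(sub, eps)
        expected <- expected + if (j == 1) b[1] - 1L else b[j]
      }
      expect_equal(gb_entry(tab, s - j, s), as.integer(expected),
                   info = sprintf("n=%d j=%d size=%d", n, j, s))
    }
  }
})

test_that("strand-1 connectivity route is enforced internally", {
  # the connected-components route runs inside graded_betti; a disagreement
  # aborts, so a clean run plus the oracle test above covers both routes
  fc <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 2)
  expect_silent(graded_betti(fc, 1.6, strands = 1))
})

test_that("Hochster budget guard refuses oversized complexes with guidance", {
  dd <- rips_filtration(pairwise_distances(dodecahedron(1.4)), max_dim = 2)
  expect_error(graded_betti(dd, 1.5), "subset_sizes")
  # restricted sizes pass the guard
  tab <- graded_betti(dd, 1.5, strands = 1, subset_sizes = 2)
  expect_equal(gb_entry(tab, 1, 2), choose(20, 2) - 30)  # disconnected pairs
  expect_error(graded_betti(dd, 1.5, strands = 1:3), "max_dim|subset_sizes")
})

test_that("persistent graded Betti at equal scales equals the static table", {
  set.seed(73)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    fc <- rips_filtration(pairwise_distances(random_cloud(n)), max_dim = 3)
    eps <- stats::runif(1, 0.8, 2.5)
    a <- graded_betti(fc, eps, strands = 1:3)
    b <- persistent_graded_betti(fc, eps, eps, strands = 1:3)
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("persistent strand at W = V recovers the persistent Betti number", {
  # octagon: the single loop class persists from just above eps1 to just
  # below eps3; in Hochster degree |V| this is strand 2 with i = 6
  fc <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
  tab <- persistent_graded_betti(fc, 1.6, 3.6, strands = 2, subset_sizes = 8)
  expect_equal(gb_entry(tab, 6, 8), 1)
  # coning off kills the contribution: a 4-cycle triangulated later
  sq <- rips_filtration(pairwise_distances(unit_square()), max_dim = 3)
  t4 <- persistent_graded_betti(sq, 1.0, sqrt(2), strands = 2,
                                subset_sizes = 4)
  expect_equal(nrow(t4), 0L)
})

test_that("persistent h- and f-vectors reproduce the diagonal pipelines", {
  so <- rips_filtration(pairwise_distances(stretched_octahedron()),
                        max_dim = 3)
  for (eps in c(1.5, sqrt(3.25), 2.0, 3.0)) {
    tab <- persistent_graded_betti(so, eps, eps, strands = 1:3)
    fv <- f_vector(so, eps)
    h <- persistent_h_vector(tab)
    expect_equal(h, fv$h, info = sprintf("eps=%.3f", eps))
    expect_equal(persistent_f_vector(h, fv$d), fv$f)
  }
  # full-simplex diagonal: only the convention term survives
  sq <- rips_filtration(pairwise_distances(unit_square()), max_dim = 3)
  tab <- persistent_graded_betti(sq, 2.0, 2.0, strands = 1:3)
  expect_equal(persistent_h_vector(tab)[1], 1)
  # linearity of the inverse transform
  h <- c(1, 3, 3, 1)
  expect_equal(f_from_h(3 * h, 3), 3 * f_from_h(h, 3))
})
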