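## Persistent Stanley-Reisner invariants: minimal nonfaces (ideal
## generators), facet persistence, f/h-vectors, and graded Betti numbers via
## Hochster's formula.  The ambient polynomial ring is represented implicitly
## by the vertex index set; graded Betti tables are keyed by homological
## degree i and internal degree i+j, rendered by strand j.

is_face_at <- function(fc, v, eps) {
  pos <- fc$index[simplex_key(v)]
  !is.na(pos) && fc$births[pos] <= eps
}

#' Minimal nonfaces (Stanley-Reisner ideal generators) at a scale
#'
#' The inclusion-minimal vertex subsets of size `2..max_size` that are not
#' simplices of the sublevel complex at `eps`: the supports of the minimal
#' squarefree monomial generators of the Stanley-Reisner ideal.  For a Rips
#' (flag) complex below the truncation dimension the minimal nonfaces are
#' exactly the non-edges; subsets of size `max_dim + 2` whose proper subsets
#' are all faces arise from the dimension truncation and are included so the
#' ideal always matches the stored complex.
#'
#' @param fc a `filtered_complex`.
#' @param eps scale.
#' @param max_size largest generator support considered; default
#'   `max_dim + 2`, which is exact for the stored complex.
#' @return Object of class `sr_generators`: list with `eps`, `generators`
#'   (list of strictly increasing integer vectors), `labels`.
#' @examples
#' fc <- rips_filtration(pairwise_distances(octagon(2)))
#' length(minimal_nonfaces(fc, 1.6)$generators)   # the 20 non-adjacent pairs
#' @export
minimal_nonfaces <- function(fc, eps, max_size = fc$max_dim + 2L) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (max_size < 2L) stop("max_size must be at least 2")
  n <- fc$n_vertices
  gens <- list()
  if (n < 2L)
    return(structure(list(eps = eps, generators = gens, labels = fc$labels),
                     class = "sr_generators"))
  for (s in 2:min(max_size, n)) {
    cand <- utils::combn(n, s)
    for (c_i in seq_len(ncol(cand))) {
      v <- cand[, c_i]
      if (is_face_at(fc, v, eps)) next
      minimal <- TRUE
      for (drop in seq_len(s)) {
        if (!is_face_at(fc, v[-drop], eps)) { minimal <- FALSE; break }
      }
      if (minimal) gens[[length(gens) + 1L]] <- v
    }
  }
  structure(list(eps = eps, generators = gens, labels = fc$labels),
            class = "sr_generators")
}

#' @export
print.sr_generators <- function(x, ...) {
  cat(sprintf("<sr_generators> %d minimal nonfaces at eps = %.4g\n",
              length(x$generators), x$eps))
  invisible(x)
}

#' Check that Stanley-Reisner ideals form a descending chain
#'
#' As the complex grows with the scale, its nonface set shrinks, so the
#' generated ideals must be nested descending.  Verified by monomial
#' membership: every generator at a later scale must lie in the ideal at each
#' earlier scale, i.e. contain some earlier generator (equivalently, its
#' support must be a nonface of the earlier complex).
#'
#' @param x a `filtered_complex`, or a list of [minimal_nonfaces()] results
#'   (one per scale, ascending) to check directly.
#' @param scales ascending scales (required when `x` is a complex).
#' @return `TRUE` if the chain is descending, else `FALSE`.
#' @export
ideal_chain_check <- function(x, scales = NULL) {
  if (inherits(x, "filtered_complex")) {
    if (is.null(scales)) stop("scales must be supplied for a complex")
    if (is.unsorted(scales)) stop("scales must be ascending")
    gens <- lapply(scales, function(e) minimal_nonfaces(x, e))
  } else {
    gens <- x
  }
  if (length(gens) < 2L) return(TRUE)
  for (t in 2:length(gens)) {
    earlier <- gens[[t - 1L]]$generators
    for (g in gens[[t]]$generators) {
      divides <- any(vapply(earlier, function(e) all(e %in% g), logical(1)))
      if (!divides) return(FALSE)
    }
  }
  TRUE
}

#' Facet persistence barcode
#'
#' One record per simplex that is a facet (maximal face) of the sublevel
#' complex over a nonempty scale interval: born when the simplex enters the
#' filtration, dead when its first strict coface enters (half-open interval,
#' `Inf` if it stays maximal).  Computed on the stored complex, so a simplex
#' of dimension `max_dim` never acquires a coface.
#'
#' @param fc a `filtered_complex`.
#' @return Data frame of class `facet_barcode` with columns `dim`,
#'   `vertices` (comma-separated labels), `birth`, `death`.
#' @examples
#' fb <- facet_barcode(rips_filtration(pairwise_distances(octagon(2))))
#' subset(fb, dim == 0)   # eight vertices maximal until eps1
#' @export
facet_barcode <- function(fc) {
  stopifnot(inherits(fc, "filtered_complex"))
  m <- length(fc$simplices)
  death <- rep(Inf, m)
  for (j in seq_len(m)) {
    v <- fc$simplices[[j]]
    if (length(v) == 1L) next
    for (i in seq_along(v)) {
      pos <- fc$index[[simplex_key(v[-i])]]
      if (fc$births[j] < death[pos]) death[pos] <- fc$births[j]
    }
  }
  keep <- death > fc$births
  out <- data.frame(
    dim = fc$dims[keep],
    vertices = vapply(fc$simplices[keep],
                      function(v) paste(fc$labels[v], collapse = ","),
                      character(1)),
    birth = fc$births[keep],
    death = death[keep])
  out <- out[order(out$dim, out$birth, out$vertices), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("facet_barcode", "data.frame")
  out
}

#' Facet persistence Betti number
#'
#' The number of i-dimensional simplices that are maximal at both scales,
#' i.e. whose maximality interval `[birth, death)` contains both `eps` and
#' `eps_prime`.
#'
#' @param records a [facet_barcode()] result.
#' @param i facet dimension.
#' @param eps,eps_prime scales with `eps <= eps_prime`.
#' @return A nonnegative integer.
#' @export
facet_persistence_betti <- function(records, i, eps, eps_prime) {
  if (eps > eps_prime) stop("eps must not exceed eps_prime")
  sum(records$dim == i & records$birth <= eps & records$death > eps_prime)
}

## ---- f- and h-vectors ------------------------------------------------------

## binomial with the empty-product convention: C(a, 0) = 1 for every a,
## C(a, b) = 0 when b < 0 or 0 <= a < b
binom0 <- function(a, b) {
  if (b == 0) return(1)
  if (b < 0 || a < b) return(0)
  choose(a, b)
}

#' Face-count (f-) and h-vectors at a scale
#'
#' Counts simplices of the sublevel complex by dimension.  The f-vector is
#' `(f_-1, f_0, ..., f_(d-1))` with `f_-1 = 1` by convention and
#' `d = dim + 1`; the h-vector is its binomial transform (see [h_from_f()]).
#'
#' @param fc a `filtered_complex`.
#' @param eps scale.
#' @return Object of class `face_counts`: list with `eps`, `d`, `n` (vertex
#'   count), `f` (length `d + 1`), `h` (length `d + 1`).
#' @examples
#' f_vector(rips_filtration(pairwise_distances(stretched_octahedron())), 3)
#' @export
f_vector <- function(fc, eps) {
  stopifnot(inherits(fc, "filtered_complex"))
  present <- fc$births <= eps
  if (!any(present)) {
    out <- list(eps = eps, d = 0L, n = 0L, f = 1, h = 1)
    class(out) <- "face_counts"
    return(out)
  }
  dims <- fc$dims[present]
  d <- max(dims) + 1L
  f <- c(1, vapply(0:(d - 1L), function(k) sum(dims == k), numeric(1)))
  out <- list(eps = eps, d = d, n = as.integer(f[2L]), f = f,
              h = h_from_f(f, d))
  class(out) <- "face_counts"
  out
}

#' @export
print.face_counts <- function(x, ...) {
  cat(sprintf("<face_counts> eps = %.4g, d = %d\n", x$eps, x$d))
  cat("  f:", paste(x$f, collapse = " "), "\n")
  cat("  h:", paste(x$h, collapse = " "), "\n")
  invisible(x)
}

#' h-vector from an f-vector
#'
#' `h_m = sum_j C(d-j, m-j) (-1)^(m-j) f_(j-1)` for `m = 0..d`.
#'
#' @param f a [f_vector()] result, or the plain numeric vector
#'   `(f_-1, f_0, ..., f_(d-1))`.
#' @param d `dim + 1`; defaults to `length(f) - 1`.
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @examples
#' h_from_f(c(1, 6, 12, 8))   # octahedron boundary: 1 3 3 1
#' @export
h_from_f <- function(f, d = NULL) {
  if (inherits(f, "face_counts")) { d <- f$d; f <- f$f }
  if (is.null(d)) d <- length(f) - 1L
  vapply(0:d, function(m) {
    sum(vapply(0:m, function(j) {
      binom0(d - j, m - j) * (-1)^(m - j) * f[j + 1L]
    }, numeric(1)))
  }, numeric(1))
}

#' f-vector from an h-vector
#'
#' The inverse binomial transform:
#' `f_(m-1) = sum_i C(d-i, m-i) h_i` for `m = 0..d`.  Exact roundtrip with
#' [h_from_f()].
#'
#' @param h numeric vector `(h_0, ..., h_d)`.
#' @param d `dim + 1`; defaults to `length(h) - 1`.
#' @return Numeric vector `(f_-1, f_0, ..., f_(d-1))`.
#' @export
f_from_h <- function(h, d = NULL) {
  if (is.null(d)) d <- length(h) - 1L
  vapply(0:d, function(m) {
    sum(vapply(0:min(m, length(h) - 1L), function(i) {
      binom0(d - i, m - i) * h[i + 1L]
    }, numeric(1)))
  }, numeric(1))
}

## ---- Hochster graded Betti numbers -----------------------------------------

check_hochster_budget <- function(fc, strands, budget, subset_sizes) {
  if (any(strands < 1L)) stop("strands must be >= 1")
  if (fc$n_vertices > budget && is.null(subset_sizes))
    stop(sprintf(paste0(
      "exact Hochster enumeration over all %d-vertex subsets exceeds the ",
      "budget (%d vertices); pass subset_sizes = i+j range to restrict the ",
      "computation, or raise `budget` explicitly"),
      fc$n_vertices, budget))
  if (max(strands) > fc$max_dim)
    stop(sprintf(paste0(
      "strand %d needs homology in dimension %d, beyond the stored max_dim ",
      "%d; rebuild the filtration with a larger max_dim"),
      max(strands), max(strands) - 1L, fc$max_dim))
}

## reduced Betti number of the induced subcomplex on W at eps, in dimension
## jm1 (= strand - 1), by GF(2) boundary ranks
reduced_betti_subset <- function(fc, W, eps, jm1) {
  sub <- induced_subcomplex(fc, W, eps)
  if (length(sub$simplices) == 0L) return(0L)
  b <- betti_numbers(sub, eps)
  if (jm1 == 0L) max(b[1L] - 1L, 0L) else b[jm1 + 1L]
}

## number of connected components of the induced 1-skeleton (union-find);
## independent route for strand 1
components_subset <- function(fc, W, eps) {
  W <- sort(W)
  parent <- seq_along(W)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sel <- fc$dims == 1L & fc$births <= eps
  wmask <- vertex_mask(W)
  for (j in which(sel)) {
    if (bitwAnd(fc$masks[j], wmask) != fc$masks[j]) next
    v <- match(fc$simplices[[j]], W)
    ra <- find(v[1L]); rb <- find(v[2L])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_along(W), find, integer(1))))
}

new_gb_table <- function(entries, eps, eps_prime, n, d, strands) {
  if (length(entries) == 0L) {
    tab <- data.frame(i = integer(0), degree = integer(0),
                      strand = integer(0), value = integer(0))
  } else {
    tab <- do.call(rbind, entries)
  }
  tab <- tab[order(tab$strand, tab$i), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "eps") <- eps
  attr(tab, "eps_prime") <- eps_prime
  attr(tab, "n") <- n
  attr(tab, "d") <- d
  attr(tab, "strands") <- sort(strands)
  class(tab) <- c("graded_betti_table", "data.frame")
  tab
}

#' Graded Betti numbers via Hochster's formula
#'
#' `beta_(i,i+j)` of the Stanley-Reisner ring of the sublevel complex at
#' `eps`: for each strand `j`, the sum over all vertex subsets `W` of size
#' `i + j` of the dimension of reduced (j-1)-homology of the induced
#' subcomplex on `W`.  Strand 1 is additionally computed by connected-
#' component counting on the induced 1-skeleton and the two routes are
#' required to agree.
#'
#' Exact enumeration over all subsets is combinatorial in the vertex count;
#' complexes larger than `budget` vertices are refused unless a
#' `subset_sizes` restriction (the `i + j` values to compute) is supplied or
#' the budget is raised.
#'
#' @param fc a `filtered_complex`.
#' @param eps scale.
#' @param strands strand indices `j` to compute (default `1:3`; strand `j`
#'   needs `max_dim >= j`).
#' @param subset_sizes optional `i + j` sizes to restrict the enumeration.
#' @param budget largest vertex count for unrestricted enumeration
#'   (default 14).
#' @return A `graded_betti_table`: data frame `i`, `degree` (`= i + j`),
#'   `strand`, `value` (nonzero entries only), with attributes `eps`,
#'   `eps_prime` (equal to `eps`), `n`, `d`, `strands`.
#' @examples
#' sq <- point_cloud(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
#' graded_betti(rips_filtration(pairwise_distances(sq)), 1, strands = 1:2)
#' @export
graded_betti <- function(fc, eps, strands = 1:3, subset_sizes = NULL,
                         budget = 14L) {
  stopifnot(inherits(fc, "filtered_complex"))
  strands <- sort(unique(as.integer(strands)))
  check_hochster_budget(fc, strands, budget, subset_sizes)
  n <- fc$n_vertices
  sizes <- if (is.null(subset_sizes)) 2:n else
    intersect(subset_sizes, 2:n)
  entries <- list()
  for (s in sizes) {
    js <- strands[strands <= s]
    if (length(js) == 0L) next
    acc <- stats::setNames(integer(length(js)), js)
    cc_acc <- 0L
    subsets <- utils::combn(n, s)
    for (c_i in seq_len(ncol(subsets))) {
      W <- subsets[, c_i]
      for (j in js) {
        acc[[as.character(j)]] <- acc[[as.character(j)]] +
          reduced_betti_subset(fc, W, eps, j - 1L)
      }
      if (1L %in% js)
        cc_acc <- cc_acc + (components_subset(fc, W, eps) - 1L)
    }
    if (1L %in% js && cc_acc != acc[["1"]])
      stop("internal error: Hochster strand-1 routes disagree")
    for (j in js) {
      val <- acc[[as.character(j)]]
      if (val > 0L)
        entries[[length(entries) + 1L]] <- data.frame(
          i = s - j, degree = s, strand = j, value = val)
    }
  }
  fv <- f_vector(fc, eps)
  new_gb_table(entries, eps, eps, n, fv$d, strands)
}

#' @export
print.graded_betti_table <- function(x, ...) {
  cat(sprintf("<graded_betti_table> eps = %.4g, eps' = %.4g (n = %d, d = %d)\n",
              attr(x, "eps"), attr(x, "eps_prime"), attr(x, "n"),
              attr(x, "d")))
  if (nrow(x) == 0L) cat("  all entries zero on strands",
                         paste(attr(x, "strands"), collapse = ","), "\n")
  else print.data.frame(x)
  invisible(x)
}

#' Look up a graded Betti table entry
#'
#' @param table a `graded_betti_table`.
#' @param i homological degree.
#' @param degree internal degree `i + j`.
#' @return The entry `beta_(i,degree)` (0 when absent from the table).
#' @export
gb_entry <- function(table, i, degree) {
  hit <- table$i == i & table$degree == degree
  if (any(hit)) sum(table$value[hit]) else 0L
}

#' Persistent graded Betti numbers
#'
#' The two-scale refinement of [graded_betti()]: for each subset `W` of size
#' `i + j`, the rank of the map on reduced (j-1)-homology induced by the
#' inclusion of the induced subcomplex at `eps` into the one at `eps_prime`
#' (see [induced_rank()]).  At `eps = eps_prime` this equals the static table.
#'
#' @inheritParams graded_betti
#' @param eps_prime second scale, `>= eps`.
#' @return A `graded_betti_table`; the `n` and `d` attributes refer to the
#'   sublevel complex at `eps_prime`.
#' @export
persistent_graded_betti <- function(fc, eps, eps_prime, strands = 1:3,
                                    subset_sizes = NULL, budget = 14L) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (eps > eps_prime) stop("eps must not exceed eps_prime")
  strands <- sort(unique(as.integer(strands)))
  check_hochster_budget(fc, strands, budget, subset_sizes)
  n <- fc$n_vertices
  sizes <- if (is.null(subset_sizes)) 2:n else
    intersect(subset_sizes, 2:n)
  entries <- list()
  for (s in sizes) {
    js <- strands[strands <= s]
    if (length(js) == 0L) next
    acc <- stats::setNames(integer(length(js)), js)
    subsets <- utils::combn(n, s)
    for (c_i in seq_len(ncol(subsets))) {
      W <- subsets[, c_i]
      bc <- compute_barcode(induced_subcomplex(fc, W))
      for (j in js) {
        acc[[as.character(j)]] <- acc[[as.character(j)]] +
          induced_rank(fc, W, j - 1L, eps, eps_prime, barcode = bc)
      }
    }
    for (j in js) {
      val <- acc[[as.character(j)]]
      if (val > 0L)
        entries[[length(entries) + 1L]] <- data.frame(
          i = s - j, degree = s, strand = j, value = val)
    }
  }
  fv <- f_vector(fc, eps_prime)
  new_gb_table(entries, eps, eps_prime, n, fv$d, strands)
}

#' Persistent h-vector from a persistent graded Betti table
#'
#' `h_m = sum_(j=0..m) C(n-d+m-j-1, m-j) sum_(i=0..j) (-1)^i beta_(i,j)` for
#' `m = 0..d`, where `beta_(i,j)` is indexed by internal degree `j`, with the
#' resolution-start convention `beta_(0,0) = 1`, `beta_(i,0) = 0` for
#' `i > 0`, and `beta_(0,j) = 0` for `j >= 1`.  `n` and `d` are taken from
#' the larger complex of the pair (the table's attributes) unless overridden.
#'
#' @param table a `graded_betti_table` (its strands must cover the internal
#'   degrees up to `d`).
#' @param n ambient vertex count; defaults to the table attribute.
#' @param d `dim + 1` of the larger complex; defaults to the table attribute.
#' @return Numeric vector `(h_0, ..., h_d)`.
#' @export
persistent_h_vector <- function(table, n = attr(table, "n"),
                                d = attr(table, "d")) {
  inner <- vapply(0:d, function(deg) {
    if (deg == 0L) return(1)
    sum(vapply(seq_len(deg), function(i) {
      (-1)^i * gb_entry(table, i, deg)
    }, numeric(1)))
  }, numeric(1))
  vapply(0:d, function(m) {
    sum(vapply(0:m, function(j) {
      binom0(n - d + m - j - 1, m - j) * inner[j + 1L]
    }, numeric(1)))
  }, numeric(1))
}

#' Persistent f-vector from a persistent h-vector
#'
#' The same inverse binomial transform as [f_from_h()]; at a diagonal scale
#' pair it reproduces the ordinary f-vector.
#'
#' @param h persistent h-vector `(h_0, ..., h_d)`.
#' @param d `dim + 1`; defaults to `length(h) - 1`.
#' @return Numeric vector `(f_-1, f_0, ..., f_(d-1))`.
#' @export
persistent_f_vector <- function(h, d = NULL) f_from_h(h, d)
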