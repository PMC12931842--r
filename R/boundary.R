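## Boundary operators and rank computations.
##
## Boundary matrices are assembled sparsely (Matrix package) in the canonical
## basis order of the complex.  Over signed fields the (tau, sigma) entry is
## (-1)^i when tau omits the i-th vertex of sigma; over GF(2) the entries are
## the parities.  Ranks over GF(2) use the same column-reduction engine as the
## persistence computation; ranks over the reals use base::qr and serve as an
## independent cross-check.

#' Boundary operator of a sublevel complex
#'
#' The matrix of the k-th boundary map on the sublevel complex at `eps`, with
#' rows indexed by the (k-1)-simplices and columns by the k-simplices, both in
#' the canonical basis order (birth scale, then dimension, then lexicographic
#' vertex tuple).  For `k = 0` the codomain is the zero chain group and the
#' matrix has zero rows.
#'
#' @param fc a `filtered_complex`.
#' @param k dimension of the mapped chains, `0 <= k <= max_dim`.
#' @param eps scale (default `Inf`).
#' @param field `"GF2"` (0/1 entries), `"rational"` or `"float"` (signed
#'   entries; identical matrices, kept distinct for intent).
#' @return An object of class `boundary_operator`: list with `k`, `field`,
#'   `rows`/`cols` (lists of vertex vectors), and `matrix` (a sparse
#'   [Matrix::sparseMatrix()]).
#' @examples
#' fc <- rips_filtration(pairwise_distances(octagon(2)))
#' B1 <- boundary_matrix(fc, 1, eps = 2)
#' dim(B1$matrix)
#' @export
boundary_matrix <- function(fc, k, eps = Inf,
                            field = c("GF2", "rational", "float")) {
  stopifnot(inherits(fc, "filtered_complex"))
  field <- match.arg(field)
  k <- as.integer(k)
  if (k < 0L || k > fc$max_dim)
    stop(sprintf("k must be between 0 and max_dim = %d", fc$max_dim))
  cols <- simplices_at(fc, k, eps)
  rows <- if (k >= 1L) simplices_at(fc, k - 1L, eps) else
    list(simplices = list(), births = numeric(0), keys = character(0))
  nr <- length(rows$simplices)
  nc <- length(cols$simplices)
  if (k == 0L || nc == 0L) {
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nr, nc))
  } else {
    row_idx <- seq_len(nr)
    names(row_idx) <- rows$keys
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_len(nc)) {
      v <- cols$simplices[[j]]
      for (i in seq_along(v)) {
        face <- v[-i]
        ii <- c(ii, row_idx[[simplex_key(face)]])
        jj <- c(jj, j)
        xx <- c(xx, if (field == "GF2") 1 else (-1)^(i - 1))
      }
    }
    mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr, nc))
  }
  structure(list(k = k, field = field, rows = rows$simplices,
                 cols = cols$simplices, matrix = mat),
            class = "boundary_operator")
}

#' @export
print.boundary_operator <- function(x, ...) {
  cat(sprintf("<boundary_operator> d_%d over %s: %d x %d\n",
              x$k, x$field, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

## --- GF(2) column reduction -------------------------------------------------
## Columns are sorted integer vectors of row indices.  Standard persistence
## reduction: repeatedly add (xor) the stored column with the same lowest row
## until the low is unique or the column vanishes.

xor_cols <- function(a, b) {
  u <- c(a, b)
  u <- sort(u)
  u[!(u %in% u[duplicated(u)])]
}

## returns list(lows = integer vector, per input column (0 when reduced to 0),
##              reduced = list of reduced columns)
gf2_reduce <- function(columns, n_rows) {
  m <- length(columns)
  lows <- integer(m)
  pivot_owner <- integer(n_rows)  # row -> column that has this low, 0 if none
  reduced <- columns
  for (j in seq_len(m)) {
    col <- reduced[[j]]
    while (length(col) > 0L) {
      low <- col[length(col)]
      owner <- pivot_owner[low]
      if (owner == 0L) break
      col <- xor_cols(col, reduced[[owner]])
    }
    reduced[[j]] <- col
    if (length(col) > 0L) {
      low <- col[length(col)]
      lows[j] <- low
      pivot_owner[low] <- j
    }
  }
  list(lows = lows, reduced = reduced)
}

sparse_columns <- function(mat) {
  mat <- methods::as(Matrix::drop0(mat), "CsparseMatrix")
  p <- mat@p
  i <- mat@i + 1L
  lapply(seq_len(ncol(mat)), function(j) {
    if (p[j + 1L] == p[j]) integer(0) else sort(i[(p[j] + 1L):p[j + 1L]])
  })
}

## rank of a 0/1 sparse matrix over GF(2)
gf2_rank <- function(mat) {
  if (nrow(mat) == 0L || ncol(mat) == 0L) return(0L)
  cols <- sparse_columns(mat)
  sum(gf2_reduce(cols, nrow(mat))$lows > 0L)
}

## rank over the reals; absolute floor keeps numerically-zero matrices at
## rank 0 (a relative-only threshold is scale invariant and would not)
real_rank <- function(mat, tol = 1e-9) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) return(0L)
  sv <- svd(mat, nu = 0, nv = 0)$d
  sum(sv > max(1e-10, tol * max(sv)))
}

## field-dispatched rank of a boundary_operator
operator_rank <- function(bop, field = bop$field) {
  if (field == "GF2") gf2_rank(bop$matrix) else real_rank(bop$matrix)
}
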