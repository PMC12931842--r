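## Persistence barcodes via boundary-matrix column reduction over GF(2).
##
## The reduction processes dimensions from the top down with the clearing
## optimization: a simplex identified as a pivot (death) in dimension k+1
## necessarily has a zero reduced column in dimension k, so its column is
## skipped.  Bars follow the half-open convention [birth, death): a feature
## dying at a scale is not counted at that scale.

#' Persistence barcode of a filtered complex
#'
#' Standard persistence pairing over GF(2).  Each bar's birth and death are
#' the filtration values of its creating and destroying simplices; classes
#' alive at the end of the filtration get death `Inf`.  Zero-length bars
#' (birth equal to death) are retained in the `all_bars` component for
#' diagnostics but excluded from the reported barcode.
#'
#' @param fc a `filtered_complex`.
#' @return An object of class `rips_barcode`: list with `bars` (data frame
#'   `dim`, `birth`, `death`; positive-length bars only), `all_bars`
#'   (including zero-length pairs), `max_dim`, `n_vertices`.
#' @examples
#' bc <- compute_barcode(rips_filtration(pairwise_distances(octagon(2))))
#' subset(bc$bars, dim == 1)   # one loop on [eps1, eps3)
#' @export
compute_barcode <- function(fc) {
  stopifnot(inherits(fc, "filtered_complex"))
  m <- length(fc$simplices)
  dims <- fc$dims
  births <- fc$births
  idx <- fc$index

  cleared <- logical(m)       # positive by the clearing lemma
  destroyer <- logical(m)     # column had a nonzero reduced form
  pair_birth <- integer(0)
  pair_death <- integer(0)

  for (k in seq(fc$max_dim, 1L, by = -1L)) {
    pos <- which(dims == k)
    if (length(pos) == 0L) next
    pivot_owner <- integer(m)     # low row -> position in `pos`
    reduced <- vector("list", length(pos))
    for (jj in seq_along(pos)) {
      j <- pos[jj]
      if (cleared[j]) {
        reduced[[jj]] <- integer(0)
        next
      }
      v <- fc$simplices[[j]]
      col <- sort(vapply(seq_along(v),
                         function(i) idx[[simplex_key(v[-i])]], integer(1)))
      repeat {
        if (length(col) == 0L) break
        low <- col[length(col)]
        owner <- pivot_owner[low]
        if (owner == 0L) break
        col <- xor_cols(col, reduced[[owner]])
      }
      reduced[[jj]] <- col
      if (length(col) > 0L) {
        low <- col[length(col)]
        pivot_owner[low] <- jj
        destroyer[j] <- TRUE
        cleared[low] <- TRUE
        pair_birth <- c(pair_birth, low)
        pair_death <- c(pair_death, j)
      }
    }
  }

  all_bars <- data.frame(
    dim = c(dims[pair_birth], integer(0)),
    birth = c(births[pair_birth], numeric(0)),
    death = c(births[pair_death], numeric(0)))
  ## essential classes: positive simplices never killed
  positive <- !destroyer
  essential <- positive & !(seq_len(m) %in% pair_birth)
  if (any(essential)) {
    all_bars <- rbind(all_bars, data.frame(
      dim = dims[essential], birth = births[essential],
      death = rep(Inf, sum(essential))))
  }
  all_bars <- all_bars[order(all_bars$dim, all_bars$birth, all_bars$death), ,
                       drop = FALSE]
  rownames(all_bars) <- NULL
  bars <- all_bars[all_bars$death > all_bars$birth, , drop = FALSE]
  rownames(bars) <- NULL
  structure(list(bars = bars, all_bars = all_bars,
                 max_dim = fc$max_dim, n_vertices = fc$n_vertices),
            class = "rips_barcode")
}

#' @export
print.rips_barcode <- function(x, ...) {
  cat(sprintf("<rips_barcode> %d bars (+%d zero-length) on %d vertices\n",
              nrow(x$bars), nrow(x$all_bars) - nrow(x$bars), x$n_vertices))
  for (k in sort(unique(x$bars$dim))) {
    b <- x$bars[x$bars$dim == k, ]
    cat(sprintf("  dim %d: %d bars (%d infinite)\n",
                k, nrow(b), sum(is.infinite(b$death))))
  }
  invisible(x)
}

#' Betti numbers at a scale, by boundary ranks
#'
#' Computes `beta_k = N_k - rank d_k - rank d_(k+1)` on the sublevel complex,
#' a code path independent of the barcode reduction (the two are checked
#' against each other in the test suite).
#'
#' @param fc a `filtered_complex`.
#' @param eps finite scale.
#' @param field coefficient field passed to [boundary_matrix()].
#' @return Integer vector `beta_0, ..., beta_max_dim`.
#' @examples
#' fc <- rips_filtration(pairwise_distances(dodecahedron(1.4)), max_dim = 2)
#' betti_numbers(fc, 1.5)   # 1 component, 11 independent loops
#' @export
betti_numbers <- function(fc, eps, field = "GF2") {
  stopifnot(inherits(fc, "filtered_complex"), is.finite(eps))
  ranks <- integer(fc$max_dim + 2L)  # rank of d_k for k = 0..max_dim+1
  nk <- integer(fc$max_dim + 1L)
  for (k in 0:fc$max_dim) {
    bop <- boundary_matrix(fc, k, eps, field)
    nk[k + 1L] <- ncol(bop$matrix)
    ranks[k + 1L] <- operator_rank(bop)
  }
  ranks[fc$max_dim + 2L] <- 0L   # truncation: no (max_dim+1)-simplices stored
  vapply(0:fc$max_dim, function(k) {
    nk[k + 1L] - ranks[k + 1L] - ranks[k + 2L]
  }, integer(1))
}

#' Persistent Betti number between two scales
#'
#' The rank of the map on k-homology induced by the inclusion of the sublevel
#' complex at `eps` into the one at `eps_prime`, counted as the number of bars
#' in dimension `k` with `birth <= eps` and `death > eps_prime`.
#'
#' @param fc a `filtered_complex`.
#' @param k homology dimension.
#' @param eps,eps_prime scales with `eps <= eps_prime`.
#' @param barcode optional precomputed [compute_barcode()] result for `fc`.
#' @return A nonnegative integer.
#' @export
persistent_betti <- function(fc, k, eps, eps_prime, barcode = NULL) {
  if (eps > eps_prime) stop("eps must not exceed eps_prime")
  if (is.null(barcode)) barcode <- compute_barcode(fc)
  b <- barcode$all_bars
  sum(b$dim == k & b$birth <= eps & b$death > eps_prime)
}

#' Reduced Betti numbers at a scale
#'
#' Reduced homology differs from ordinary homology only in dimension 0, where
#' one global component is discounted.  For the empty complex the reduced
#' homology is concentrated in dimension -1 with rank 1; the returned vector
#' then carries attribute `empty_complex = TRUE` and the rank in the
#' `reduced_minus_one` attribute.
#'
#' @param fc a `filtered_complex`.
#' @param eps finite scale.
#' @return Integer vector of reduced Betti numbers for dimensions
#'   `0..max_dim`.
#' @export
reduced_betti <- function(fc, eps) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (!any(fc$births <= eps)) {
    out <- integer(fc$max_dim + 1L)
    attr(out, "empty_complex") <- TRUE
    attr(out, "reduced_minus_one") <- 1L
    return(out)
  }
  b <- betti_numbers(fc, eps)
  b[1L] <- b[1L] - 1L
  b
}

#' Rank of the map on reduced homology of an induced subcomplex pair
#'
#' For a vertex subset `W` and scales `eps <= eps_prime`, computes the rank of
#' the homomorphism on reduced homology in dimension `j` induced by the
#' inclusion of the induced subcomplex at `eps` into the one at `eps_prime` —
#' the elementary contribution of `W` to the persistent graded Betti numbers.
#'
#' @param fc a `filtered_complex`.
#' @param W nonempty vertex subset (indices or labels).
#' @param j reduced homology dimension, `>= 0`.
#' @param eps,eps_prime scales with `eps <= eps_prime`.
#' @param barcode optional precomputed barcode of `induced_subcomplex(fc, W)`.
#' @return A nonnegative integer.
#' @export
induced_rank <- function(fc, W, j, eps, eps_prime, barcode = NULL) {
  if (eps > eps_prime) stop("eps must not exceed eps_prime")
  if (j < 0L) stop("j must be nonnegative")
  if (is.null(barcode)) barcode <- compute_barcode(induced_subcomplex(fc, W))
  b <- barcode$all_bars
  r <- sum(b$dim == j & b$birth <= eps & b$death > eps_prime)
  if (j == 0L) {
    ## reduced dim 0: one global class is discounted when the complex at eps
    ## is nonempty (vertices are born at 0)
    if (eps >= 0) r <- r - 1L
    r <- max(r, 0L)
  }
  r
}

#' Export a barcode to CSV (and optionally JSON)
#'
#' CSV columns `dim,birth,death`, death empty for infinite bars; the JSON
#' mirror serializes infinite deaths as `null`.
#'
#' @param barcode a `rips_barcode`.
#' @param csv_path output CSV path, or `NULL` to skip.
#' @param json_path output JSON path, or `NULL` to skip.
#' @return Invisibly, the bar data frame written.
#' @export
write_barcode <- function(barcode, csv_path = NULL, json_path = NULL) {
  b <- barcode$bars
  if (!is.null(csv_path)) {
    out <- b
    out$death <- ifelse(is.infinite(out$death), NA_real_, out$death)
    utils::write.csv(format_float_df(out), csv_path, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    recs <- lapply(seq_len(nrow(b)), function(i) {
      list(dim = b$dim[i], birth = b$birth[i],
           death = if (is.infinite(b$death[i])) NULL else b$death[i])
    })
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(b)
}
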