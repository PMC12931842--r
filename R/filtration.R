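## Filtered simplicial complexes and Vietoris-Rips construction.
##
## A filtered_complex stores every simplex together with its birth scale in a
## single canonical order: primary key birth, then dimension, then
## lexicographic vertex tuple.  The dimension key guarantees that a face never
## follows one of its cofaces at equal birth, so the stored order is always a
## valid filtration order for matrix reduction.  Vertex indices are 1-based;
## original labels are preserved for I/O.

simplex_key <- function(v) paste(sprintf("%04d", v), collapse = "|")

simplex_keys <- function(simplices) {
  vapply(simplices, simplex_key, character(1))
}

vertex_mask <- function(v) sum(2^(v - 1))

new_filtered_complex <- function(simplices, births, n_vertices, max_dim,
                                 labels = NULL) {
  dims <- lengths(simplices) - 1L
  keys <- simplex_keys(simplices)
  ord <- order(births, dims, keys, method = "radix")
  simplices <- simplices[ord]
  births <- births[ord]
  dims <- dims[ord]
  keys <- keys[ord]
  if (is.null(labels)) labels <- paste0("v", seq_len(n_vertices))
  idx <- seq_along(keys)
  names(idx) <- keys
  structure(
    list(simplices = simplices, births = births, dims = dims, keys = keys,
         index = idx,
         masks = vapply(simplices, vertex_mask, numeric(1)),
         n_vertices = as.integer(n_vertices), max_dim = as.integer(max_dim),
         labels = labels),
    class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  tab <- table(factor(x$dims, levels = 0:max(x$dims)))
  cat(sprintf("<filtered_complex> %d simplices on %d vertices (max_dim %d)\n",
              length(x$simplices), x$n_vertices, x$max_dim))
  cat("  count by dimension:", paste(sprintf("f%s=%d", names(tab), tab),
                                     collapse = ", "), "\n")
  rng <- range(x$births)
  cat(sprintf("  birth scales in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Check face-closure and filtration monotonicity of a filtered complex
#'
#' Verifies that every face of every stored simplex is stored, and that a face
#' is never born later than any of its cofaces (so every sublevel set is a
#' simplicial complex).
#'
#' @param fc a `filtered_complex`.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_filtration <- function(fc) {
  stopifnot(inherits(fc, "filtered_complex"))
  for (i in seq_along(fc$simplices)) {
    v <- fc$simplices[[i]]
    if (is.unsorted(v, strictly = TRUE))
      stop("simplex vertices must be strictly increasing")
    if (length(v) == 1L) next
    for (j in seq_along(v)) {
      face <- v[-j]
      pos <- fc$index[simplex_key(face)]
      if (is.na(pos))
        stop(sprintf("face (%s) of simplex (%s) is missing",
                     paste(face, collapse = ","), paste(v, collapse = ",")))
      if (fc$births[pos] > fc$births[i] + 1e-12)
        stop(sprintf("face (%s) born after its coface (%s)",
                     paste(face, collapse = ","), paste(v, collapse = ",")))
    }
  }
  invisible(TRUE)
}

#' Vietoris-Rips filtration of a distance matrix
#'
#' Builds all Rips simplices up to `max_dim` whose pairwise distances do not
#' exceed `max_scale`.  Vertices are born at scale 0; a higher simplex is born
#' at the maximum pairwise distance among its vertices (closed comparison
#' `d <= scale`, so a simplex is present exactly at its printed critical
#' radius).  Construction is by incremental expansion of the neighbourhood
#' graph and is fully deterministic.
#'
#' Distances equal up to `snap_tol` (relative) are snapped to their common
#' critical-scale representative before the complex is built, so simplices
#' that are equidistant by symmetry share exactly equal birth scales instead
#' of differing in the last floating-point bits.
#'
#' @param dm symmetric distance matrix (or a [point_cloud()], from which
#'   distances are computed).
#' @param max_dim maximal simplex dimension retained (default 3, enough for
#'   homology and Laplacians in dimensions 0-2).
#' @param max_scale largest edge length admitted; default `Inf` (complete
#'   filtration up to the diameter).
#' @param snap_tol relative tolerance for merging equal distances (see
#'   [critical_scales()]); `0` disables snapping.
#' @return A `filtered_complex`.
#' @examples
#' fc <- rips_filtration(pairwise_distances(octagon(2)), max_dim = 3)
#' fc
#' @export
rips_filtration <- function(dm, max_dim = 3L, max_scale = Inf,
                            snap_tol = 1e-9) {
  if (inherits(dm, "point_cloud")) {
    labels <- dm$labels
    dm <- pairwise_distances(dm)
  } else {
    check_distance_matrix(dm)
    labels <- rownames(dm)
  }
  if (snap_tol > 0 && nrow(dm) > 1L) {
    reps <- critical_scales(dm, tol = snap_tol)
    if (length(reps)) {
      off <- dm > 0
      idx <- findInterval(dm[off], reps)
      dm[off] <- reps[pmax(idx, 1L)]
    }
  }
  max_dim <- as.integer(max_dim)
  if (is.na(max_dim) || max_dim < 0L)
    stop("max_dim must be a nonnegative integer")
  n <- nrow(dm)
  simplices <- lapply(seq_len(n), function(i) i)
  births <- rep(0, n)

  if (max_dim >= 1L && n >= 2L) {
    ## lower neighbours: nb[[v]] = vertices u > v with d(u, v) <= max_scale
    nb <- lapply(seq_len(n), function(v) {
      u <- which(dm[v, ] <= max_scale)
      u[u > v]
    })
    frontier <- list()   # simplices of current dimension
    fbirth <- numeric(0)
    for (v in seq_len(n)) {
      for (u in nb[[v]]) {
        frontier[[length(frontier) + 1L]] <- c(v, u)
        fbirth <- c(fbirth, dm[v, u])
      }
    }
    simplices <- c(simplices, frontier)
    births <- c(births, fbirth)
    k <- 1L
    while (k < max_dim && length(frontier) > 0L) {
      nxt <- list()
      nbirth <- numeric(0)
      for (s in seq_along(frontier)) {
        sigma <- frontier[[s]]
        ## candidate extensions: common upper neighbours of all vertices
        cand <- nb[[sigma[1L]]]
        for (v in sigma[-1L]) cand <- cand[cand %in% nb[[v]]]
        cand <- cand[cand > sigma[length(sigma)]]
        for (u in cand) {
          nxt[[length(nxt) + 1L]] <- c(sigma, u)
          nbirth <- c(nbirth, max(fbirth[s], max(dm[sigma, u])))
        }
      }
      simplices <- c(simplices, nxt)
      births <- c(births, nbirth)
      frontier <- nxt
      fbirth <- nbirth
      k <- k + 1L
    }
  }
  new_filtered_complex(simplices, births, n, max_dim, labels)
}

#' Sublevel complex at a scale
#'
#' Restricts a filtered complex to the simplices with birth `<= eps`.  The
#' result is itself a `filtered_complex` (face-closed by monotonicity of the
#' filtration), carrying the original vertex labels and indices.
#'
#' @param fc a `filtered_complex`.
#' @param eps finite scale in Angstrom.
#' @return A `filtered_complex` containing exactly the simplices born at or
#'   before `eps`.
#' @export
sublevel_complex <- function(fc, eps) {
  stopifnot(inherits(fc, "filtered_complex"), is.finite(eps))
  keep <- fc$births <= eps
  new_filtered_complex(fc$simplices[keep], fc$births[keep],
                       fc$n_vertices, fc$max_dim, fc$labels)
}

#' Induced subcomplex on a vertex subset
#'
#' Returns the simplices of the sublevel complex at `eps` all of whose
#' vertices lie in `W`.  Vertex indices (and labels) of the ambient complex
#' are preserved.
#'
#' @param fc a `filtered_complex`.
#' @param W vertex subset: integer indices or labels.
#' @param eps scale (default `Inf`: the whole filtration restricted to `W`).
#' @return A `filtered_complex`.
#' @export
induced_subcomplex <- function(fc, W, eps = Inf) {
  stopifnot(inherits(fc, "filtered_complex"))
  if (is.character(W)) {
    W <- match(W, fc$labels)
    if (anyNA(W)) stop("unknown vertex label in W")
  }
  W <- unique(as.integer(W))
  if (length(W) == 0L) stop("W must be nonempty")
  if (any(W < 1L | W > fc$n_vertices)) stop("unknown vertex index in W")
  wmask <- vertex_mask(W)
  keep <- fc$births <= eps &
    vapply(fc$masks, function(m) bitwAnd(m, wmask) == m, logical(1))
  new_filtered_complex(fc$simplices[keep], fc$births[keep],
                       fc$n_vertices, fc$max_dim, fc$labels)
}

## simplices of dimension k born at or before eps, in canonical order
simplices_at <- function(fc, k, eps = Inf) {
  sel <- fc$dims == k & fc$births <= eps
  list(simplices = fc$simplices[sel], births = fc$births[sel],
       keys = fc$keys[sel])
}

#' Serialize a filtered complex to JSON
#'
#' Writes the complex as a JSON array of `{"vertices": [...], "birth": x}`
#' records (vertex labels, canonical order).
#'
#' @param fc a `filtered_complex`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filtration_json <- function(fc, path) {
  recs <- lapply(seq_along(fc$simplices), function(i) {
    list(vertices = fc$labels[fc$simplices[[i]]], birth = fc$births[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
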