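#' Construct a labelled 3-D point cloud
#'
#' A point cloud is the raw input of every analysis in ripstack: a set of
#' uniquely labelled points in 3-space (coordinates in Angstrom).  Labels are
#' carried through to all exports; internally vertices are addressed by their
#' row index.
#'
#' @param coords numeric matrix with one row per point and 3 columns, or a
#'   3-column data frame.  All entries must be finite.
#' @param labels character vector of unique vertex identifiers, one per row.
#'   Defaults to `"v1", "v2", ...`.
#' @return An object of class `point_cloud`: a list with elements `coords`
#'   (n x 3 numeric matrix) and `labels` (character vector).
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(3, 4, 0)))
#' pairwise_distances(pc)
#' @export
point_cloud <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have exactly 3 columns (x, y, z)")
  if (nrow(coords) < 1L)
    stop("a point cloud needs at least one vertex")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  if (is.null(labels))
    labels <- paste0("v", seq_len(nrow(coords)))
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("labels must match the number of points")
  if (anyDuplicated(labels))
    stop("labels must be unique")
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(list(coords = coords, labels = labels), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d vertices\n", nrow(x$coords)))
  if (nrow(x$coords) <= 10L) print(round(x$coords, 4)) else {
    print(round(utils::head(x$coords, 5L), 4))
    cat(sprintf("  ... %d more\n", nrow(x$coords) - 5L))
  }
  invisible(x)
}

n_points <- function(cloud) nrow(cloud$coords)

#' Euclidean pairwise distance matrix of a point cloud
#'
#' @param cloud a [point_cloud()].
#' @return A symmetric n x n numeric matrix with zero diagonal, row/column
#'   names equal to the vertex labels.
#' @examples
#' pairwise_distances(point_cloud(rbind(c(0, 0, 0), c(3, 4, 0))))
#' @export
pairwise_distances <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  dm <- as.matrix(stats::dist(cloud$coords, method = "euclidean"))
  dimnames(dm) <- list(cloud$labels, cloud$labels)
  dm
}

check_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (!all(is.finite(dm)))
    stop("distance matrix entries must be finite")
  if (any(dm < 0))
    stop("distances must be nonnegative")
  if (any(abs(diag(dm)) > 0))
    stop("distance matrix diagonal must be zero")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  invisible(dm)
}

#' Critical scales of a Vietoris-Rips filtration
#'
#' The distinct pairwise distances of the cloud, in increasing order.  These
#' are exactly the scales at which the Rips complex changes.  Distances equal
#' up to a relative tolerance are merged into a single representative (the
#' smallest of the group), so symmetric configurations whose equal distances
#' differ only by floating-point round-off yield one critical scale.
#'
#' @param dm symmetric distance matrix, e.g. from [pairwise_distances()].
#' @param tol relative merge tolerance; default `1e-9`.
#' @return Strictly increasing numeric vector of distinct positive distances
#'   (empty for a single point).
#' @examples
#' critical_scales(pairwise_distances(octagon(2)))  # 1.53 2.83 3.70 4.00
#' @export
critical_scales <- function(dm, tol = 1e-9) {
  check_distance_matrix(dm)
  d <- sort(dm[upper.tri(dm)])
  if (length(d) == 0L) return(numeric(0))
  reps <- d[1L]
  for (x in d[-1L]) {
    last <- reps[length(reps)]
    if (x - last > tol * max(1, abs(x)))
      reps <- c(reps, x)
  }
  reps
}
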