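## Deterministic geometric fixtures.  Every generator is a pure function of
## its parameters: identical calls regenerate bit-identical point clouds.

#' Regular octagon point cloud
#'
#' Eight planar points at angles `2*pi*m/8` on a circle of circumradius `R`
#' in the z = 0 plane.  Its Rips filtration has four critical scales
#' `2 R sin(k*pi/8)`, `k = 1..4`.
#'
#' @param R circumradius in Angstrom (default 2).
#' @return A [point_cloud()] with labels `p0..p7`.
#' @examples
#' critical_scales(pairwise_distances(octagon(2)))
#' @export
octagon <- function(R = 2) {
  if (!is.finite(R) || R <= 0) stop("R must be positive")
  m <- 0:7
  theta <- 2 * pi * m / 8
  point_cloud(cbind(R * cos(theta), R * sin(theta), 0),
              labels = paste0("p", m))
}

#' Stretched octahedron point cloud
#'
#' The six vertices `(+-1, 0, 0), (0, +-1, 0), (0, 0, +-1.5)`: an octahedron
#' with the polar axis stretched, separating the four critical Rips scales
#' `sqrt(2) ~ 1.41`, `sqrt(3.25) ~ 1.80`, `2.00`, `3.00`.
#'
#' @return A [point_cloud()] with labels `e1..e4` (equator), `pN`, `pS`
#'   (poles).
#' @export
stretched_octahedron <- function() {
  point_cloud(rbind(c( 1, 0, 0), c(0,  1, 0), c(-1, 0, 0), c(0, -1, 0),
                    c(0, 0, 1.5), c(0, 0, -1.5)),
              labels = c("e1", "e2", "e3", "e4", "pN", "pS"))
}

#' Regular dodecahedron point cloud (C20 fullerene surrogate)
#'
#' The 20 vertices of a regular dodecahedron, scaled so the nearest-neighbour
#' (edge) distance equals `edge`.  At the carbon bond length 1.4 Angstrom
#' this serves as a surrogate for the C20 fullerene cage: 30 bonds, twelve
#' pentagonal faces, cycle rank 11 at the graph scale.
#'
#' @param edge nearest-neighbour distance in Angstrom (default 1.4).
#' @return A [point_cloud()] with labels `C1..C20`.
#' @export
dodecahedron <- function(edge = 1.4) {
  if (!is.finite(edge) || edge <= 0) stop("edge must be positive")
  phi <- (1 + sqrt(5)) / 2
  s <- c(-1, 1)
  cube <- as.matrix(expand.grid(x = s, y = s, z = s))
  rect <- as.matrix(expand.grid(a = s / phi, b = s * phi))
  v <- rbind(cube,
             cbind(0, rect[, 1], rect[, 2]),       # (0, +-1/phi, +-phi)
             cbind(rect[, 1], rect[, 2], 0),       # (+-1/phi, +-phi, 0)
             cbind(rect[, 2], 0, rect[, 1]))       # (+-phi, 0, +-1/phi)
  v <- v * (edge / (2 / phi))   # unit-coordinate dodecahedron has edge 2/phi
  point_cloud(v, labels = paste0("C", seq_len(nrow(v))))
}

#' Parametric helix point cloud
#'
#' Points at `(radius*cos(m*turn), radius*sin(m*turn), m*rise)` for
#' `m = 0..n-1`.  The defaults (radius 2.3, rise 1.5, turn 100 degrees)
#' emulate an alpha-helical C-alpha backbone trace with consecutive spacing
#' close to 3.8 Angstrom.
#'
#' @param n number of points.
#' @param radius helix radius, Angstrom.
#' @param rise axial rise per point, Angstrom.
#' @param turn rotation per point, degrees.
#' @return A [point_cloud()] with labels `r1..rn`.
#' @export
helix <- function(n = 20L, radius = 2.3, rise = 1.5, turn = 100) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  m <- 0:(n - 1L)
  th <- m * turn * pi / 180
  point_cloud(cbind(radius * cos(th), radius * sin(th), m * rise),
              labels = paste0("r", m + 1L))
}

#' Built-in fixture registry
#'
#' Resolves a fixture name (as used by the command-line interface, e.g.
#' `"builtin:octagon"`) to its point cloud with default parameters.
#'
#' @param name one of `"octagon"`, `"octahedron"`, `"c20"`/`"dodecahedron"`,
#'   `"helix"`, optionally prefixed `"builtin:"`.
#' @return A [point_cloud()].
#' @export
fixture_cloud <- function(name) {
  key <- sub("^builtin:", "", tolower(name))
  switch(key,
    octagon = octagon(2),
    octahedron = stretched_octahedron(),
    c20 = dodecahedron(1.4),
    dodecahedron = dodecahedron(1.4),
    helix = helix(20L),
    stop(sprintf("unknown fixture '%s'", name)))
}
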