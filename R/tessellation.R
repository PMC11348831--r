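#' Cube-bounded Voronoi tessellation
#'
#' Partitions the cube into one convex cell per generating point: the cell of
#' point i is the set of locations closer to i than to any other generating
#' point, clipped exactly by the six cube planes. Cells are built by
#' sequentially intersecting the cube with the perpendicular-bisector
#' half-spaces of neighbouring points; a security-radius bound prunes
#' bisectors that cannot touch the cell, so the construction stays fast up to
#' several hundred points.
#'
#' @param pose A [voro_pose][sample_pose()] (or a matrix of points, coerced
#'   with [as_pose()]).
#' @param cube A [bounding_cube()]; defaults to the pose's own cube.
#' @return An object of class `cell_complex`: a list with `cube`, `pose` and
#'   `cells`, where each cell holds its vertex coordinates, ordered face loops
#'   (outward-oriented), the plane id of each face (negative for the six cube
#'   planes, positive for the bisector with that neighbour), its exact volume,
#'   volume centroid, and second moment about the generating point.
#' @examples
#' cc <- bounded_voronoi(sample_pose(12, seed = 7))
#' sum(cell_volumes(cc)) # == 100^3
#' @export
bounded_voronoi <- function(pose, cube = NULL) {
  if (is.matrix(pose)) pose <- as_pose(pose, cube %||% bounding_cube())
  if (!inherits(pose, "voro_pose")) {
    abort("`pose` must be a voro_pose or a 3-column matrix.",
          class = "voroscaffold_invalid_parameter")
  }
  cube <- cube %||% pose$cube
  assert_cube(cube)
  pts <- pose$points
  check_points_inside(pts, cube)
  L <- cube$side_length

  if (nrow(pts) > 1) {
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    mind <- min(d)
    if (mind <= 1e-9 * L) {
      pair <- sort(which(d == mind, arr.ind = TRUE)[1, ])
      abort(sprintf(
        "generating points %d and %d are coincident or nearly so (distance %g).",
        pair[1], pair[2], mind),
        class = "voroscaffold_degenerate_input")
    }
  }

  cells <- cpp_bounded_voronoi(pts, L, cube$origin)
  structure(
    list(cube = cube, pose = pose, cells = cells),
    class = "cell_complex"
  )
}

#' @export
print.cell_complex <- function(x, ...) {
  cat(sprintf("<cell_complex> G = %d cells, L = %g, total volume = %g\n",
              length(x$cells), x$cube$side_length, sum(cell_volumes(x))))
  invisible(x)
}

#' Cell volumes of a complex
#' @param complex A [cell_complex][bounded_voronoi()].
#' @return Numeric vector of exact cell volumes; they sum to L^3.
#' @export
cell_volumes <- function(complex) {
  assert_complex(complex)
  vapply(complex$cells, function(c) c$volume, numeric(1))
}

#' Cell centroids of a complex
#' @param complex A [cell_complex][bounded_voronoi()].
#' @return G x 3 matrix of exact volume centroids.
#' @export
cell_centroids <- function(complex) {
  assert_complex(complex)
  t(vapply(complex$cells, function(c) c$centroid, numeric(3)))
}

assert_complex <- function(x) {
  if (!inherits(x, "cell_complex")) {
    abort("expected a `cell_complex` from `bounded_voronoi()`.",
          class = "voroscaffold_invalid_parameter")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
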