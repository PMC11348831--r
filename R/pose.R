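#' Sample a pose of generating points
#'
#' A *pose* is one concrete random arrangement of `count` generating points,
#' drawn i.i.d. uniformly over the open interior of the cube and identified by
#' its seed, so the same `(seed, count, cube)` always reproduces the same
#' points. A minimum pairwise separation of `1e-9 * L` is enforced by
#' resampling offending points (uniform sampling essentially never violates
#' it, but near-coincident generators would make the tessellation degenerate).
#'
#' @param count Number of generating points G (>= 1).
#' @param seed Integer seed identifying the pose.
#' @param cube A [bounding_cube()].
#' @param pose_id Optional integer label carried through to ensemble tables.
#' @return An object of class `voro_pose` with fields `points` (a `count` x 3
#'   matrix), `count`, `seed`, `pose_id` and `cube`.
#' @examples
#' p <- sample_pose(12, seed = 7)
#' head(p$points)
#' @export
sample_pose <- function(count, seed, cube = bounding_cube(), pose_id = 1L) {
  if (!is.numeric(count) || length(count) != 1 || count < 1 ||
      count != floor(count)) {
    abort("`count` must be a single integer >= 1.",
          class = "voroscaffold_invalid_parameter")
  }
  assert_cube(cube)
  count <- as.integer(count)
  seed <- as.integer(seed)
  L <- cube$side_length
  min_sep <- 1e-9 * L

  pts <- withr::with_seed(seed, {
    m <- matrix(stats::runif(3 * count, min = 0, max = L), ncol = 3)
    # resample points that collide (vanishingly rare for uniform draws)
    for (attempt in seq_len(50)) {
      bad <- too_close(m, min_sep)
      if (length(bad) == 0) break
      m[bad, ] <- matrix(stats::runif(3 * length(bad), min = 0, max = L),
                         ncol = 3)
    }
    m
  })
  bad <- too_close(pts, min_sep)
  if (length(bad) > 0) {
    abort("could not sample points with the required minimum separation.",
          class = "voroscaffold_degenerate_input")
  }
  pts <- sweep(pts, 2, cube$origin, "+")
  new_pose(pts, seed = seed, pose_id = pose_id, cube = cube)
}

new_pose <- function(points, seed = NA_integer_, pose_id = NA_integer_,
                     cube = bounding_cube()) {
  storage.mode(points) <- "double"
  structure(
    list(points = points, count = nrow(points), seed = seed,
         pose_id = pose_id, cube = cube),
    class = "voro_pose"
  )
}

# indices of points involved in a pair closer than min_sep
too_close <- function(m, min_sep) {
  if (nrow(m) < 2) return(integer(0))
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  which(apply(d, 1, min) < min_sep)
}

#' @export
print.voro_pose <- function(x, ...) {
  cat(sprintf("<voro_pose> G = %d, seed = %s, L = %g\n",
              x$count, x$seed, x$cube$side_length))
  invisible(x)
}

#' Coerce a matrix of points to a pose
#'
#' @param points Numeric matrix with 3 columns; every point must lie strictly
#'   inside the cube.
#' @param cube A [bounding_cube()].
#' @param pose_id Optional integer label.
#' @return A `voro_pose`.
#' @export
as_pose <- function(points, cube = bounding_cube(), pose_id = NA_integer_) {
  assert_cube(cube)
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1 || any(!is.finite(points))) {
    abort("`points` must be a finite numeric matrix with 3 columns.",
          class = "voroscaffold_invalid_parameter")
  }
  check_points_inside(points, cube)
  new_pose(points, cube = cube, pose_id = pose_id)
}

check_points_inside <- function(points, cube) {
  lo <- cube$origin
  hi <- cube$origin + cube$side_length
  inside <- points[, 1] > lo[1] & points[, 1] < hi[1] &
    points[, 2] > lo[2] & points[, 2] < hi[2] &
    points[, 3] > lo[3] & points[, 3] < hi[3]
  if (!all(inside)) {
    abort(sprintf("point(s) %s lie outside the open cube interior.",
                  paste(which(!inside), collapse = ", ")),
          class = "voroscaffold_invalid_parameter")
  }
  invisible(TRUE)
}

#' @export
as_tibble.voro_pose <- function(x, ...) {
  tibble(point = seq_len(x$count), x = x$points[, 1], y = x$points[, 2],
         z = x$points[, 3])
}
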