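#' Volume centroid of a convex polyhedron
#'
#' Computes the exact volume centroid by tetrahedral decomposition: each face
#' is fanned into triangles, each triangle forms a tetrahedron with an interior
#' apex, and the centroid is the volume-weighted mean of the tetrahedra
#' centroids.
#'
#' @param cell Either a cell from a [cell_complex][bounded_voronoi()], or a
#'   list with `vertices` (n x 3 matrix) and `faces` (list of 1-based ordered
#'   vertex loops).
#' @return Numeric 3-vector.
#' @examples
#' cube_cell <- bounded_voronoi(sample_pose(1, seed = 1))$cells[[1]]
#' polyhedron_centroid(cube_cell) # (50, 50, 50)
#' @export
polyhedron_centroid <- function(cell) {
  if (!is.list(cell) || is.null(cell$vertices) || is.null(cell$faces)) {
    abort("`cell` must have `vertices` and `faces`.",
          class = "voroscaffold_invalid_parameter")
  }
  props <- cpp_poly_props(cell$vertices, cell$faces, c(0, 0, 0))
  if (!is.finite(props$volume) || props$volume <= 0) {
    abort("degenerate polyhedron: non-positive volume.",
          class = "voroscaffold_degenerate_geometry")
  }
  as.numeric(props$centroid)
}

#' CVT energy of a tessellation
#'
#' The centroidal-Voronoi (quantisation) energy
#' `sum_i integral over cell_i of |x - p_i|^2 dx`, computed exactly from the
#' per-cell second moments about the generating points. Lloyd iteration never
#' increases this quantity, which makes it a sharp diagnostic of convergence
#' toward a CVT.
#'
#' @param complex A [cell_complex][bounded_voronoi()].
#' @return A single number (units: length^5).
#' @export
cvt_energy <- function(complex) {
  assert_complex(complex)
  sum(vapply(complex$cells, function(c) c$second_moment, numeric(1)))
}

#' Monte-Carlo CVT energy
#'
#' Independent stochastic estimate of [cvt_energy()]: uniform samples in the
#' cube are assigned to their nearest generating point and
#' `mean(|x - p|^2) * L^3` is returned. Used as a cross-check of the exact
#' moment computation; too noisy to drive convergence decisions.
#'
#' @param complex A [cell_complex][bounded_voronoi()].
#' @param n_samples Number of uniform samples.
#' @param seed Seed for the sample draw.
#' @return A single number.
#' @export
cvt_energy_mc <- function(complex, n_samples = 1e5, seed = 1) {
  assert_complex(complex)
  cube <- complex$cube
  L <- cube$side_length
  pts <- complex$pose$points
  withr::with_seed(seed, {
    x <- matrix(stats::runif(3 * n_samples, 0, L), ncol = 3)
    x <- sweep(x, 2, cube$origin, "+")
    # squared distance to nearest generating point
    d2 <- rep(Inf, n_samples)
    for (i in seq_len(nrow(pts))) {
      di <- (x[, 1] - pts[i, 1])^2 + (x[, 2] - pts[i, 2])^2 +
        (x[, 3] - pts[i, 3])^2
      d2 <- pmin(d2, di)
    }
    mean(d2) * L^3
  })
}

#' One Lloyd iteration
#'
#' Moves every generating point to the volume centroid of its Voronoi cell and
#' returns the new pose. Centroids of cube-clipped convex cells are always
#' inside the cube, so the iteration is closed.
#'
#' @param pose A [voro_pose][sample_pose()].
#' @param cube A [bounding_cube()]; defaults to the pose's cube.
#' @return The updated `voro_pose` (same count, seed and pose_id).
#' @export
lloyd_step <- function(pose, cube = NULL) {
  cube <- cube %||% pose$cube
  complex <- bounded_voronoi(pose, cube)
  cen <- cell_centroids(complex)
  out <- new_pose(cen, seed = pose$seed, pose_id = pose$pose_id, cube = cube)
  out
}

#' Lloyd relaxation toward a centroidal Voronoi tessellation
#'
#' Runs `lambda_max` Lloyd iterations, recording the structure at every step
#' (record 0 is the unrelaxed structure). Convergence to a CVT is declared
#' when the largest point displacement in a step falls below
#' `displacement_tolerance * L`; by default the full `lambda_max` iterations
#' are still carried out so that fixed-lambda ensembles are comparable, with
#' `early_stop = TRUE` available to truncate the trace at convergence.
#'
#' @param pose A [voro_pose][sample_pose()].
#' @param cube A [bounding_cube()]; defaults to the pose's cube.
#' @param lambda_max Number of Lloyd iterations (>= 0).
#' @param displacement_tolerance CVT declaration threshold, as a fraction of
#'   L (default 1e-6).
#' @param early_stop Stop iterating once converged (default `FALSE`).
#' @param record_metrics Measure every intermediate structure (default
#'   `TRUE`); with `FALSE` only poses and displacements are tracked.
#' @param record_energy Record the exact CVT energy per iteration (default
#'   `TRUE`).
#' @return An object of class `relaxation_trace`: a list with `records` (a
#'   tibble with one row per recorded iteration: `iteration`, `V`, `E`, `F`,
#'   `epsilon`, `chi`, `short_edge_count`, `min_edge_length`,
#'   `max_displacement`, `energy`), `poses` (list of `voro_pose`),
#'   `final_complex`, and `converged_at` (iteration index, or `NA`).
#' @examples
#' tr <- relax(sample_pose(8, seed = 3), lambda_max = 5)
#' tr$records
#' @export
relax <- function(pose, cube = NULL, lambda_max = 25,
                  displacement_tolerance = 1e-6, early_stop = FALSE,
                  record_metrics = TRUE, record_energy = TRUE) {
  if (lambda_max < 0 || lambda_max != floor(lambda_max)) {
    abort("`lambda_max` must be a non-negative integer.",
          class = "voroscaffold_invalid_parameter")
  }
  cube <- cube %||% pose$cube
  L <- cube$side_length
  tol <- displacement_tolerance * L

  poses <- vector("list", lambda_max + 1)
  rows <- vector("list", lambda_max + 1)
  converged_at <- NA_integer_
  complex <- bounded_voronoi(pose, cube)
  n_rec <- 0L

  for (it in 0:lambda_max) {
    n_rec <- n_rec + 1L
    poses[[n_rec]] <- pose
    disp <- if (it == 0) NA_real_ else attr(pose, "last_displacement")
    rows[[n_rec]] <- record_row(complex, it, disp, record_metrics,
                                record_energy)
    if (it == lambda_max) break
    cen <- cell_centroids(complex)
    step <- max(sqrt(rowSums((cen - pose$points)^2)))
    pose <- new_pose(cen, seed = pose$seed, pose_id = pose$pose_id,
                     cube = cube)
    attr(pose, "last_displacement") <- step
    complex <- bounded_voronoi(pose, cube)
    if (is.na(converged_at) && step < tol) converged_at <- it + 1L
    if (early_stop && !is.na(converged_at) && converged_at == it + 1L) {
      n_rec <- n_rec + 1L
      poses[[n_rec]] <- pose
      rows[[n_rec]] <- record_row(complex, it + 1L, step, record_metrics,
                                  record_energy)
      break
    }
  }

  structure(
    list(records = dplyr::bind_rows(rows[seq_len(n_rec)]),
         poses = poses[seq_len(n_rec)],
         final_complex = complex,
         converged_at = converged_at,
         displacement_tolerance = displacement_tolerance),
    class = "relaxation_trace"
  )
}

record_row <- function(complex, iteration, displacement, record_metrics,
                       record_energy) {
  if (record_metrics) {
    m <- measure(complex)
    tibble(iteration = as.integer(iteration), V = m$V, E = m$E, F = m$F,
           epsilon = m$epsilon, chi = m$chi,
           short_edge_count = m$short_edge_count,
           min_edge_length = m$min_edge_length,
           max_displacement = displacement,
           energy = if (record_energy) cvt_energy(complex) else NA_real_)
  } else {
    tibble(iteration = as.integer(iteration), V = NA_integer_,
           E = NA_integer_, F = NA_integer_, epsilon = NA_real_,
           chi = NA_integer_, short_edge_count = NA_integer_,
           min_edge_length = NA_real_, max_displacement = displacement,
           energy = if (record_energy) cvt_energy(complex) else NA_real_)
  }
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat(sprintf("<relaxation_trace> %d records, converged_at = %s\n",
              nrow(x$records),
              ifelse(is.na(x$converged_at), "not converged",
                     x$converged_at)))
  print(x$records, n = 5)
  invisible(x)
}

#' Export a relaxation trace as CSV
#'
#' Writes one row per recorded iteration with columns
#' `(iteration, V, E, F, epsilon, chi, max_displacement, short_edge_count)`.
#'
#' @param trace A [relaxation_trace][relax()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "relaxation_trace"))
  df <- trace$records[, c("iteration", "V", "E", "F", "epsilon", "chi",
                          "max_displacement", "short_edge_count")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
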