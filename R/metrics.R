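#' Extract the deduplicated wireframe of a cell complex
#'
#' Collects every face-boundary edge of every cell (including the faces on the
#' cube surface, hence the cube's own edges), merges vertices closer than
#' `merge_tolerance`, and collapses duplicate edges to unique unordered pairs.
#' The wireframe is the printable structure: shared interior faces contribute
#' their boundary once, and the 8 cube corners remain the only degree-3
#' vertices of a non-degenerate structure.
#'
#' @param complex A [cell_complex][bounded_voronoi()].
#' @param merge_tolerance Vertex merge radius in model units; default
#'   `1e-9 * L`, far below any genuine feature size so merging never alters
#'   topology.
#' @return An object of class `wireframe`: `vertices` (V x 3 matrix), `edges`
#'   (E x 2 integer matrix, `edges[,1] < edges[,2]`), `edge_lengths`,
#'   `n_dropped_edges` (edges that collapsed to a point during merging,
#'   recorded as degeneracies), `merge_tolerance`, `cube` and `g` (number of
#'   generating points).
#' @examples
#' wf <- extract_wireframe(bounded_voronoi(sample_pose(1, seed = 1)))
#' nrow(wf$vertices) # 8
#' nrow(wf$edges)    # 12
#' @export
extract_wireframe <- function(complex, merge_tolerance = NULL) {
  assert_complex(complex)
  d <- dedup_complex(complex, merge_tolerance)
  structure(
    list(vertices = d$vertices, edges = d$edges,
         edge_lengths = d$edge_lengths, n_dropped_edges = d$n_dropped_edges,
         merge_tolerance = d$merge_tolerance, cube = complex$cube,
         g = length(complex$cells)),
    class = "wireframe"
  )
}

#' @export
print.wireframe <- function(x, ...) {
  cat(sprintf("<wireframe> V = %d, E = %d (G = %d, L = %g)\n",
              nrow(x$vertices), nrow(x$edges), x$g, x$cube$side_length))
  invisible(x)
}

# Shared deduplication core: merged vertex table, unique edges with lengths,
# unique face count (interior faces counted once) and degeneracy bookkeeping.
dedup_complex <- function(complex, merge_tolerance = NULL) {
  L <- complex$cube$side_length
  merge_tolerance <- merge_tolerance %||% (1e-9 * L)
  if (merge_tolerance <= 0) {
    abort("`merge_tolerance` must be positive.",
          class = "voroscaffold_invalid_parameter")
  }

  verts <- do.call(rbind, lapply(complex$cells, function(c) c$vertices))
  offsets <- cumsum(c(0L, vapply(complex$cells,
                                 function(c) nrow(c$vertices), integer(1))))
  ids <- cpp_dedup_points(verts, merge_tolerance)
  n_unique <- max(ids)
  first <- match(seq_len(n_unique), ids)
  uverts <- verts[first, , drop = FALSE]

  edge_a <- integer(0); edge_b <- integer(0)
  face_keys <- character(0)
  n_dropped <- 0L
  for (ci in seq_along(complex$cells)) {
    cell <- complex$cells[[ci]]
    off <- offsets[ci]
    for (loop in cell$faces) {
      gl <- ids[loop + off]
      m <- length(gl)
      a <- gl
      b <- gl[c(2:m, 1)]
      keep <- a != b
      n_dropped <- n_dropped + sum(!keep)
      edge_a <- c(edge_a, pmin(a[keep], b[keep]))
      edge_b <- c(edge_b, pmax(a[keep], b[keep]))
      face_keys <- c(face_keys, paste(sort(unique(gl)), collapse = "-"))
    }
  }
  key <- edge_a * (n_unique + 1) + edge_b
  sel <- !duplicated(key)
  edges <- cbind(edge_a[sel], edge_b[sel])
  lens <- sqrt(rowSums((uverts[edges[, 1], , drop = FALSE] -
                          uverts[edges[, 2], , drop = FALSE])^2))
  list(vertices = uverts, edges = edges, edge_lengths = lens,
       n_faces = length(unique(face_keys)), n_dropped_edges = n_dropped,
       merge_tolerance = merge_tolerance)
}

#' Euler characteristic
#'
#' `chi = V - E + F`. A single convex polyhedron has chi = 2; a cube-bounded
#' Voronoi cell complex built from G generating points has chi = 1 + G.
#'
#' @param V,E,F Non-negative integer counts of vertices, edges and faces.
#' @return Integer V - E + F.
#' @examples
#' euler_characteristic(8, 12, 6)   # 2
#' euler_characteristic(60, 116, 69) # 13
#' @export
euler_characteristic <- function(V, E, F) {
  if (any(c(V, E, F) < 0) || any(c(V, E, F) != floor(c(V, E, F)))) {
    abort("V, E, F must be non-negative integers.",
          class = "voroscaffold_invalid_parameter")
  }
  as.integer(V) - as.integer(E) + as.integer(F)
}

#' Measure the structural parameters of a structure
#'
#' Deduplicates the complex into a wireframe and computes the four structural
#' parameters: vertex count V, edge count E, face count F (interior faces
#' shared by two cells counted once), mean edge length epsilon (unweighted
#' arithmetic mean over unique edges), and the Euler characteristic
#' chi = V - E + F. Also fills topology diagnostics: the vertex degree
#' histogram and a census of edges below the short-edge threshold, which in
#' practice mark structures whose topology deviates from the ideal
#' chi = 1 + G / E = 2V - 4 relations.
#'
#' @param complex A [cell_complex][bounded_voronoi()].
#' @param merge_tolerance Vertex merge radius (default `1e-9 * L`).
#' @param short_edge_threshold Diagnostic threshold; default `1.5e-4 * L`,
#'   i.e. 0.015 at L = 100.
#' @return An object of class `structure_metrics` with fields `V`, `E`, `F`,
#'   `epsilon`, `chi`, `degree_histogram` (named integer vector),
#'   `n_degree3`, `n_degree4`, `short_edge_count`, `min_edge_length`, `g`,
#'   `L`, and the tolerances used. Use [tidy()] for a one-row tibble.
#' @examples
#' measure(bounded_voronoi(sample_pose(1, seed = 1)))
#' @export
measure <- function(complex, merge_tolerance = NULL,
                    short_edge_threshold = NULL) {
  assert_complex(complex)
  L <- complex$cube$side_length
  short_edge_threshold <- short_edge_threshold %||% (1.5e-4 * L)
  d <- dedup_complex(complex, merge_tolerance)
  V <- nrow(d$vertices)
  E <- nrow(d$edges)
  F <- d$n_faces
  deg <- tabulate(c(d$edges[, 1], d$edges[, 2]), nbins = V)
  hist <- table(deg)
  degree_histogram <- stats::setNames(as.integer(hist), names(hist))
  structure(
    list(V = V, E = E, F = F,
         epsilon = mean(d$edge_lengths),
         chi = euler_characteristic(V, E, F),
         degree_histogram = degree_histogram,
         n_degree3 = sum(deg == 3L),
         n_degree4 = sum(deg == 4L),
         short_edge_count = sum(d$edge_lengths < short_edge_threshold),
         min_edge_length = min(d$edge_lengths),
         n_dropped_edges = d$n_dropped_edges,
         g = length(complex$cells), L = L,
         merge_tolerance = d$merge_tolerance,
         short_edge_threshold = short_edge_threshold),
    class = "structure_metrics"
  )
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf(
    "<structure_metrics> G = %d: V = %d, E = %d, F = %d, epsilon = %.4g, chi = %d\n",
    x$g, x$V, x$E, x$F, x$epsilon, x$chi))
  if (x$short_edge_count > 0) {
    cat(sprintf("  %d edge(s) below the short-edge threshold (%g)\n",
                x$short_edge_count, x$short_edge_threshold))
  }
  invisible(x)
}

#' @rdname measure
#' @param x A `structure_metrics` object.
#' @param ... Unused.
#' @export
tidy.structure_metrics <- function(x, ...) {
  tibble(G = x$g, L = x$L, V = x$V, E = x$E, F = x$F, epsilon = x$epsilon,
         chi = x$chi, n_degree3 = x$n_degree3, n_degree4 = x$n_degree4,
         short_edge_count = x$short_edge_count,
         min_edge_length = x$min_edge_length)
}

#' Flag short wireframe edges
#'
#' Edges shorter than the threshold are associated with degenerate topology
#' (missing faces or duplicate vertices): structures carrying them are the
#' ones that deviate from chi = 1 + G and E = 2V - 4.
#'
#' @param wireframe A [wireframe][extract_wireframe()].
#' @param threshold Length threshold in model units; default `1.5e-4 * L`.
#' @return A tibble of flagged edges sorted by increasing length, with columns
#'   `edge` (row index into `wireframe$edges`), `from`, `to`, `length`.
#' @export
detect_short_edges <- function(wireframe, threshold = NULL) {
  stopifnot(inherits(wireframe, "wireframe"))
  threshold <- threshold %||% (1.5e-4 * wireframe$cube$side_length)
  if (threshold <= 0) {
    abort("`threshold` must be positive.",
          class = "voroscaffold_invalid_parameter")
  }
  idx <- which(wireframe$edge_lengths < threshold)
  out <- tibble(edge = idx,
                from = wireframe$edges[idx, 1],
                to = wireframe$edges[idx, 2],
                length = wireframe$edge_lengths[idx])
  dplyr::arrange(out, .data$length)
}

#' Topology conformance report
#'
#' Checks a measured structure against the three ideal-topology relations of a
#' cube-bounded Voronoi structure: the Euler relation chi = 1 + G, the degree
#' identity E = 2V - 4, and the degree histogram (exactly the 8 cube corners
#' of degree 3, all other vertices of degree 4). Failures are expected only in
#' structures carrying short-edge degeneracies; because it is generally not
#' possible to attribute a failure to one specific short edge, the report
#' cross-references the short-edge census as candidates rather than asserting
#' causality.
#'
#' @param metrics A [structure_metrics][measure()].
#' @param G Number of generating points; defaults to the one recorded in
#'   `metrics`.
#' @return A tibble with one row per check: `check`, `pass`, `observed`,
#'   `expected`, `short_edge_candidates`.
#' @examples
#' check_topology(measure(bounded_voronoi(sample_pose(1, seed = 1))))
#' @export
check_topology <- function(metrics, G = NULL) {
  stopifnot(inherits(metrics, "structure_metrics"))
  G <- G %||% metrics$g
  deg_ok <- metrics$n_degree3 == 8L &&
    metrics$n_degree4 == metrics$V - 8L &&
    sum(metrics$degree_histogram) == metrics$n_degree3 + metrics$n_degree4
  tibble(
    check = c("euler_chi_1_plus_g", "edge_vertex_identity",
              "degree_histogram"),
    pass = c(metrics$chi == 1L + G,
             metrics$E == 2L * metrics$V - 4L,
             deg_ok),
    observed = c(sprintf("chi = %d", metrics$chi),
                 sprintf("E = %d", metrics$E),
                 sprintf("{3: %d, 4: %d, other: %d}", metrics$n_degree3,
                         metrics$n_degree4,
                         sum(metrics$degree_histogram) - metrics$n_degree3 -
                           metrics$n_degree4)),
    expected = c(sprintf("chi = %d", 1L + G),
                 sprintf("E = %d", 2L * metrics$V - 4L),
                 sprintf("{3: 8, 4: %d}", metrics$V - 8L)),
    short_edge_candidates = rep(metrics$short_edge_count, 3)
  )
}
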