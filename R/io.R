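STRUCTURE_FORMAT_VERSION <- "1.0"

#' Write a structure to the native JSON format
#'
#' Serialises a cell complex (cube, pose, cells with face loops and plane
#' ids) to a self-contained JSON file at full floating-point precision, so
#' that re-measuring a re-loaded structure reproduces identical parameters.
#'
#' @param complex A [cell_complex][bounded_voronoi()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_json <- function(complex, path) {
  assert_complex(complex)
  obj <- list(
    format = "voroscaffold-structure",
    version = STRUCTURE_FORMAT_VERSION,
    length_unit = "model units (cm at the reference scale)",
    point_distribution = "iid uniform over the open cube interior (assumed)",
    cube = list(side_length = complex$cube$side_length,
                origin = complex$cube$origin),
    pose = list(seed = complex$pose$seed, pose_id = complex$pose$pose_id,
                count = complex$pose$count,
                points = complex$pose$points),
    cells = lapply(complex$cells, function(c) {
      list(vertices = c$vertices, faces = c$faces, plane = c$plane,
           volume = c$volume, centroid = c$centroid,
           second_moment = c$second_moment)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a structure from the native JSON format
#'
#' @param path Path to a file written by [write_structure_json()].
#' @return A [cell_complex][bounded_voronoi()].
#' @export
read_structure_json <- function(path) {
  # no automatic simplification: cells with equal-length face loops would
  # otherwise collapse into matrices and lose their list-of-loops shape
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || !identical(obj$format, "voroscaffold-structure")) {
    abort("not a voroscaffold structure file.",
          class = "voroscaffold_invalid_parameter")
  }
  as_rows <- function(x) do.call(rbind, lapply(x, function(r)
    as.numeric(unlist(r))))
  cube <- bounding_cube(as.numeric(obj$cube$side_length),
                        as.numeric(unlist(obj$cube$origin)))
  pts <- as_rows(obj$pose$points)
  pose <- new_pose(pts, seed = obj$pose$seed %||% NA_integer_,
                   pose_id = obj$pose$pose_id %||% NA_integer_, cube = cube)
  cells <- lapply(obj$cells, function(c_in) {
    list(vertices = as_rows(c_in$vertices),
         faces = lapply(c_in$faces, function(f) as.integer(unlist(f))),
         plane = as.integer(unlist(c_in$plane)),
         volume = as.numeric(c_in$volume),
         centroid = as.numeric(unlist(c_in$centroid)),
         second_moment = as.numeric(c_in$second_moment))
  })
  structure(list(cube = cube, pose = pose, cells = cells),
            class = "cell_complex")
}

#' Export a wireframe for viewing or 3D printing
#'
#' Formats:
#' * `"obj"` - Wavefront OBJ with `v` vertex records and `l` line records;
#'   the lightest faithful representation of the wireframe graph.
#' * `"ply"` - ASCII PLY with vertex and edge elements.
#' * `"stl"` - binary STL of a printable solid: every edge becomes a closed
#'   capped prism with `beam_sides` sides and radius `beam_radius`, so each
#'   beam is individually watertight. STL carries no units; the unit label is
#'   recorded in a sidecar `<path>.meta.json`.
#' * `"json"` - native lossless round-trip of the wireframe graph.
#'
#' @param wireframe A [wireframe][extract_wireframe()].
#' @param path Output file path.
#' @param format One of `"obj"`, `"ply"`, `"stl"`, `"json"`; default guessed
#'   from the file extension.
#' @param beam_radius Beam radius for STL export (default `0.01 * L`). Radii
#'   of at least half the shortest edge are clamped with a warning.
#' @param beam_sides Number of prism sides (>= 3, default 8).
#' @param length_unit Unit label recorded in the STL sidecar (default
#'   `"cm"`).
#' @return `path`, invisibly.
#' @export
write_wireframe <- function(wireframe, path,
                            format = c("auto", "obj", "ply", "stl", "json"),
                            beam_radius = NULL, beam_sides = 8,
                            length_unit = "cm") {
  stopifnot(inherits(wireframe, "wireframe"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply", "stl", "json")) {
      abort("cannot guess the format; pass `format` explicitly.",
            class = "voroscaffold_invalid_parameter")
    }
    format <- ext
  }
  switch(format,
    obj = write_obj(wireframe, path),
    ply = write_ply(wireframe, path),
    stl = write_stl_beams(wireframe, path, beam_radius, beam_sides,
                          length_unit),
    json = write_wireframe_json(wireframe, path)
  )
  invisible(path)
}

write_obj <- function(wf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# voroscaffold wireframe", con)
  writeLines(sprintf("v %.17g %.17g %.17g", wf$vertices[, 1],
                     wf$vertices[, 2], wf$vertices[, 3]), con)
  writeLines(sprintf("l %d %d", wf$edges[, 1], wf$edges[, 2]), con)
}

write_ply <- function(wf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(wf$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element edge %d", nrow(wf$edges)),
               "property int vertex1", "property int vertex2",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", wf$vertices[, 1], wf$vertices[, 2],
                     wf$vertices[, 3]), con)
  writeLines(sprintf("%d %d", wf$edges[, 1] - 1L, wf$edges[, 2] - 1L), con)
}

write_wireframe_json <- function(wf, path) {
  obj <- list(format = "voroscaffold-wireframe",
              version = STRUCTURE_FORMAT_VERSION,
              cube = list(side_length = wf$cube$side_length,
                          origin = wf$cube$origin),
              g = wf$g, merge_tolerance = wf$merge_tolerance,
              vertices = wf$vertices, edges = wf$edges)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
}

#' Read a wireframe from the native JSON format
#' @param path Path to a file written by [write_wireframe()] with
#'   `format = "json"`.
#' @return A [wireframe][extract_wireframe()].
#' @export
read_wireframe_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  if (is.null(obj$format) || obj$format != "voroscaffold-wireframe") {
    abort("not a voroscaffold wireframe file.",
          class = "voroscaffold_invalid_parameter")
  }
  verts <- matrix(as.numeric(obj$vertices), ncol = 3)
  edges <- matrix(as.integer(obj$edges), ncol = 2)
  lens <- sqrt(rowSums((verts[edges[, 1], , drop = FALSE] -
                          verts[edges[, 2], , drop = FALSE])^2))
  structure(
    list(vertices = verts, edges = edges, edge_lengths = lens,
         n_dropped_edges = 0L, merge_tolerance = obj$merge_tolerance,
         cube = bounding_cube(obj$cube$side_length, obj$cube$origin),
         g = obj$g),
    class = "wireframe"
  )
}

# triangulated beam solid: one closed capped prism per edge
beam_triangles <- function(wf, beam_radius, beam_sides) {
  n <- beam_sides
  tri <- vector("list", nrow(wf$edges))
  for (e in seq_len(nrow(wf$edges))) {
    # per-beam phase offset: collinear beams meeting at a node would
    # otherwise generate exactly coincident cap rings, which breaks the
    # every-edge-shared-twice property of the combined mesh
    theta <- 2 * pi * (0:(n - 1)) / n + e * 1e-3
    p <- wf$vertices[wf$edges[e, 1], ]
    q <- wf$vertices[wf$edges[e, 2], ]
    a <- q - p
    a <- a / sqrt(sum(a^2))
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- c(a[2] * ref[3] - a[3] * ref[2],
           a[3] * ref[1] - a[1] * ref[3],
           a[1] * ref[2] - a[2] * ref[1])
    u <- u / sqrt(sum(u^2))
    w <- c(a[2] * u[3] - a[3] * u[2],
           a[3] * u[1] - a[1] * u[3],
           a[1] * u[2] - a[2] * u[1])
    ring <- outer(cos(theta), u) + outer(sin(theta), w)
    rp <- sweep(beam_radius * ring, 2, p, "+")
    rq <- sweep(beam_radius * ring, 2, q, "+")
    # each triangle is a 3x3 matrix (rows = corners)
    tris <- vector("list", 2 * n + 2 * (n - 2))
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      tris[[2 * k - 1]] <- rbind(rp[k, ], rq[k, ], rq[k2, ])
      tris[[2 * k]] <- rbind(rp[k, ], rq[k2, ], rp[k2, ])
    }
    for (k in 2:(n - 1)) {
      tris[[2 * n + k - 1]] <- rbind(rp[1, ], rp[k + 1, ], rp[k, ])
      tris[[2 * n + n - 2 + k - 1]] <- rbind(rq[1, ], rq[k, ], rq[k + 1, ])
    }
    tri[[e]] <- tris
  }
  do.call(c, tri)
}

write_stl_beams <- function(wf, path, beam_radius, beam_sides, length_unit) {
  L <- wf$cube$side_length
  beam_radius <- beam_radius %||% (0.01 * L)
  if (beam_sides < 3 || beam_sides != floor(beam_sides)) {
    abort("`beam_sides` must be an integer >= 3.",
          class = "voroscaffold_invalid_parameter")
  }
  min_edge <- min(wf$edge_lengths)
  if (beam_radius >= min_edge / 2) {
    warn(sprintf("beam_radius %g >= half the shortest edge (%g); clamping.",
                 beam_radius, min_edge / 2))
    beam_radius <- 0.49 * min_edge
  }
  tris <- beam_triangles(wf, beam_radius, beam_sides)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "voroscaffold beam-solid wireframe"))
  writeBin(header[1:80], con)
  writeBin(as.integer(length(tris)), con, size = 4, endian = "little")
  for (t in tris) {
    e1 <- t[2, ] - t[1, ]
    e2 <- t[3, ] - t[1, ]
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, t[1, ], t[2, ], t[3, ])), con, size = 4,
             endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  jsonlite::write_json(
    list(format = "voroscaffold-stl-sidecar", length_unit = length_unit,
         beam_radius = beam_radius, beam_sides = beam_sides,
         n_triangles = length(tris)),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
}

#' Read a binary STL file
#'
#' Minimal binary-STL reader used to validate exported beam meshes.
#'
#' @param path Path to a binary STL file.
#' @return A list of 3x3 matrices, one triangle each (rows are corners).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  tris <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    tris[[i]] <- matrix(vals[4:12], nrow = 3, byrow = TRUE)
  }
  tris
}

#' Check that a triangle soup is watertight
#'
#' Every undirected triangle edge must be shared by exactly two triangles.
#' Vertices are identified by exact coordinate equality, which holds for
#' meshes produced by [write_wireframe()] since shared corners are written
#' from the same computed values.
#'
#' @param triangles A list of 3x3 matrices as returned by [read_stl()].
#' @return `TRUE`/`FALSE`.
#' @export
is_watertight <- function(triangles) {
  if (length(triangles) == 0) return(FALSE)
  # identical float32 corners read back as identical doubles, so an exact
  # per-element representation keys shared corners reliably
  corner_key <- function(v) paste(sprintf("%.9e", v), collapse = ",")
  edges <- character(3 * length(triangles))
  k <- 0L
  for (t in triangles) {
    keys <- apply(t, 1, corner_key)
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      k <- k + 1L
      edges[k] <- paste(sort(keys[pair]), collapse = "|")
    }
  }
  all(table(edges) == 2L)
}
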