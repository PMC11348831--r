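# Shared fixtures and independent oracles.

# the deterministic two-cell case: generating points on the x axis split the
# cube into two 50 x 100 x 100 boxes sharing the plane x = 50
two_box_pose <- function() {
  as_pose(rbind(c(25, 50, 50), c(75, 50, 50)))
}

# direct half-space construction of the two-box wireframe: 12 vertices
# (the 8 cube corners plus the 4 corners of the shared face) and 20 edges
two_box_expected <- function() {
  corners <- as.matrix(expand.grid(x = c(0, 100), y = c(0, 100),
                                   z = c(0, 100)))
  mid <- as.matrix(expand.grid(x = 50, y = c(0, 100), z = c(0, 100)))
  list(vertices = rbind(corners, mid), V = 12L, E = 20L, F = 11L,
       epsilon = (8 * 50 + 12 * 100) / 20, chi = 3L)
}

# outward plane (normal, offset) of a face loop, from its first triangle
face_plane <- function(verts, loop) {
  a <- verts[loop[1], ]; b <- verts[loop[2], ]; c <- verts[loop[3], ]
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  n <- n / sqrt(sum(n^2))
  list(normal = n, offset = sum(n * a))
}

# is `p` inside the convex cell (all face planes satisfied)?
point_in_cell <- function(cell, p, tol = 1e-9) {
  for (loop in cell$faces) {
    pl <- face_plane(cell$vertices, loop)
    if (sum(pl$normal * p) - pl$offset > tol) return(FALSE)
  }
  TRUE
}

# Monte-Carlo rejection-sampling centroid of a convex cell
mc_centroid <- function(cell, n = 2e5, seed = 42) {
  withr::with_seed(seed, {
    lo <- apply(cell$vertices, 2, min)
    hi <- apply(cell$vertices, 2, max)
    pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
                 runif(n, lo[3], hi[3]))
    keep <- apply(pts, 1, function(p) point_in_cell(cell, p, tol = 1e-9))
    inside <- pts[keep, , drop = FALSE]
    list(centroid = colMeans(inside), n_inside = nrow(inside),
         se = apply(inside, 2, sd) / sqrt(nrow(inside)))
  })
}

# sorted canonical form of a vertex table, for set comparison
canon_vertices <- function(m, digits = 6) {
  m <- round(m, digits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}
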