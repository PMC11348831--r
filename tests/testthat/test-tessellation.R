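test_that("pose sampling is deterministic per seed and uniform in the cube", {
  p1 <- sample_pose(12, seed = 7)
  p2 <- sample_pose(12, seed = 7)
  expect_identical(p1$points, p2$points)
  expect_equal(nrow(p1$points), 12)
  expect_true(all(p1$points > 0 & p1$points < 100))

  pa <- sample_pose(5, seed = 1)
  pb <- sample_pose(5, seed = 2)
  expect_false(isTRUE(all.equal(pa$points, pb$points)))

  expect_error(sample_pose(0, seed = 1),
               class = "voroscaffold_invalid_parameter")
  expect_error(bounding_cube(-1), class = "voroscaffold_invalid_parameter")
})

test_that("pose sampling scales exactly with the cube side", {
  small <- sample_pose(9, seed = 4, cube = bounding_cube(10))
  big <- sample_pose(9, seed = 4, cube = bounding_cube(100))
  expect_equal(big$points, 10 * small$points, tolerance = 1e-14)
})

test_that("a single generating point owns the whole cube", {
  cc <- bounded_voronoi(sample_pose(1, seed = 3))
  expect_length(cc$cells, 1)
  cell <- cc$cells[[1]]
  expect_equal(nrow(cell$vertices), 8)
  expect_length(cell$faces, 6)
  expect_equal(cell$volume, 1e6)
  expect_equal(as.numeric(cell$centroid), c(50, 50, 50))
  expect_equal(canon_vertices(cell$vertices),
               canon_vertices(as.matrix(expand.grid(c(0, 100), c(0, 100),
                                                    c(0, 100)))),
               ignore_attr = TRUE)
})

test_that("two symmetric points split the cube into two half boxes", {
  cc <- bounded_voronoi(two_box_pose())
  vols <- cell_volumes(cc)
  expect_equal(vols, c(5e5, 5e5))
  exp <- two_box_expected()
  got <- canon_vertices(do.call(rbind, lapply(cc$cells,
                                              function(c) c$vertices)))
  # each half box has 8 corners; the 4 shared-face corners appear twice
  expect_equal(nrow(got), 16)
  expect_equal(unique(got), canon_vertices(exp$vertices),
               ignore_attr = TRUE)
  # both cells carry a face on the bisector plane x = 50
  for (cell in cc$cells) {
    planes <- lapply(cell$faces, function(l) face_plane(cell$vertices, l))
    on_bisector <- vapply(planes, function(pl) {
      abs(abs(pl$normal[1]) - 1) < 1e-12 && abs(abs(pl$offset) - 50) < 1e-9
    }, logical(1))
    expect_equal(sum(on_bisector), 1)
  }
})

test_that("cell volumes sum to the cube volume and cells contain their points", {
  for (g in c(10, 80, 300)) {
    pose <- sample_pose(g, seed = g)
    cc <- bounded_voronoi(pose)
    expect_length(cc$cells, g)
    expect_equal(sum(cell_volumes(cc)), 1e6, tolerance = 1e-8)
    inside <- vapply(seq_len(g), function(i) {
      point_in_cell(cc$cells[[i]], pose$points[i, ], tol = 1e-7)
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("cell membership matches the nearest-generating-point rule", {
  for (g in 2:6) {
    pose <- sample_pose(g, seed = 20 + g)
    cc <- bounded_voronoi(pose)
    gr <- seq(5, 95, length.out = 10)
    probes <- as.matrix(expand.grid(gr, gr, gr))
    d2 <- sapply(seq_len(g), function(i) {
      colSums((t(probes) - pose$points[i, ])^2)
    })
    nearest <- max.col(-d2)
    member <- apply(probes, 1, function(p) {
      hits <- which(vapply(cc$cells, point_in_cell, logical(1), p = p,
                           tol = 1e-7))
      hits[1]
    })
    expect_identical(member, nearest)
  }
})

test_that("interior faces are shared between exactly two cells", {
  cc <- bounded_voronoi(sample_pose(15, seed = 11))
  for (i in seq_along(cc$cells)) {
    neigh <- cc$cells[[i]]$plane
    for (j in neigh[neigh > 0]) {
      # the neighbour must reciprocally list cell i
      expect_true(i %in% cc$cells[[j]]$plane)
    }
  }
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  bad <- rbind(c(50, 50, 50), c(50, 50, 50 + 1e-11))
  expect_error(bounded_voronoi(as_pose(bad)),
               class = "voroscaffold_degenerate_input")
  expect_error(bounded_voronoi(as_pose(bad)), "points 1 and 2")
  expect_error(as_pose(rbind(c(150, 50, 50), c(25, 50, 50))),
               class = "voroscaffold_invalid_parameter")
})
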