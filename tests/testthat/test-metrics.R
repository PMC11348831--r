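test_that("the single-cell cube measures as the classical polyhedron", {
  cc <- bounded_voronoi(sample_pose(1, seed = 1))
  wf <- extract_wireframe(cc)
  expect_equal(nrow(wf$vertices), 8)
  expect_equal(nrow(wf$edges), 12)
  m <- measure(cc)
  expect_equal(m$V, 8)
  expect_equal(m$E, 12)
  expect_equal(m$F, 6)
  expect_equal(m$epsilon, 100)
  expect_equal(m$chi, 2)
  expect_equal(m$degree_histogram, c("3" = 8L))
  expect_equal(nrow(detect_short_edges(wf)), 0)
  expect_true(all(check_topology(m)$pass))
})

test_that("the two-box complex measures per the half-space construction", {
  m <- measure(bounded_voronoi(two_box_pose()))
  exp <- two_box_expected()
  expect_equal(m$V, exp$V)
  expect_equal(m$E, exp$E)
  expect_equal(m$F, exp$F)
  expect_equal(m$epsilon, exp$epsilon)
  expect_equal(m$chi, exp$chi)
})

test_that("euler_characteristic is V - E + F", {
  expect_equal(euler_characteristic(8, 12, 6), 2L)
  expect_equal(euler_characteristic(12, 20, 11), 3L)
  # 12-point structure: 60 vertices, 116 edges imply 69 faces via chi = 13
  expect_equal(euler_characteristic(60, 116, 69), 13L)
  expect_error(euler_characteristic(-1, 0, 0),
               class = "voroscaffold_invalid_parameter")
})

test_that("random structures obey the cube-bounded topology relations", {
  for (g in c(3, 7, 25, 60, 140)) {
    m <- measure(bounded_voronoi(sample_pose(g, seed = 300 + g)))
    if (m$short_edge_count > 0) next
    expect_equal(m$chi, 1L + g)
    expect_equal(m$E, 2L * m$V - 4L)
    expect_equal(m$F, 1L + g - m$V + m$E)
    expect_equal(m$n_degree3, 8L)
    expect_equal(m$n_degree4, m$V - 8L)
    expect_equal(sum(as.integer(names(m$degree_histogram)) *
                       m$degree_histogram), 2L * m$E)
    expect_true(all(check_topology(m)$pass))
  }
})

test_that("degree-3 vertices are exactly the cube corners", {
  cc <- bounded_voronoi(sample_pose(30, seed = 77))
  wf <- extract_wireframe(cc)
  deg <- tabulate(c(wf$edges[, 1], wf$edges[, 2]), nbins = nrow(wf$vertices))
  v3 <- wf$vertices[deg == 3, , drop = FALSE]
  corners <- as.matrix(expand.grid(c(0, 100), c(0, 100), c(0, 100)))
  expect_equal(canon_vertices(v3), canon_vertices(corners),
               ignore_attr = TRUE)
})

test_that("the wireframe graph is connected, with no loops or duplicates", {
  skip_if_not_installed("igraph")
  wf <- extract_wireframe(bounded_voronoi(sample_pose(40, seed = 8)))
  expect_true(all(wf$edges[, 1] < wf$edges[, 2]))
  expect_false(any(duplicated(wf$edges)))
  gr <- igraph::graph_from_edgelist(wf$edges, directed = FALSE)
  expect_true(igraph::is_connected(gr))
})

test_that("counts are scale invariant and epsilon scales with L", {
  for (Lbig in c(10, 150)) {
    m100 <- measure(bounded_voronoi(sample_pose(22, seed = 5,
                                                cube = bounding_cube(100))))
    mL <- measure(bounded_voronoi(sample_pose(22, seed = 5,
                                              cube = bounding_cube(Lbig))))
    expect_identical(mL$V, m100$V)
    expect_identical(mL$E, m100$E)
    expect_identical(mL$F, m100$F)
    expect_identical(mL$chi, m100$chi)
    expect_equal(mL$epsilon / m100$epsilon, Lbig / 100, tolerance = 1e-9)
  }
})

test_that("metrics are deterministic across repeated runs", {
  m1 <- tidy(measure(bounded_voronoi(sample_pose(50, seed = 123))))
  m2 <- tidy(measure(bounded_voronoi(sample_pose(50, seed = 123))))
  expect_identical(m1, m2)
})

test_that("short edges are detected and sorted ascending", {
  wf <- extract_wireframe(bounded_voronoi(sample_pose(1, seed = 1)))
  expect_equal(nrow(detect_short_edges(wf, threshold = 0.015)), 0)
  # every edge of the cube frame flags under an absurdly large threshold
  flagged <- detect_short_edges(wf, threshold = 200)
  expect_equal(nrow(flagged), 12)
  expect_true(!is.unsorted(flagged$length))
  expect_error(detect_short_edges(wf, threshold = -1),
               class = "voroscaffold_invalid_parameter")
})

test_that("topology report flags a doctored structure and cross-references short edges", {
  m <- measure(bounded_voronoi(sample_pose(5, seed = 2)))
  m$chi <- m$chi + 1L
  m$short_edge_count <- 2L
  rep <- check_topology(m, G = 5)
  expect_false(rep$pass[rep$check == "euler_chi_1_plus_g"])
  expect_equal(unique(rep$short_edge_candidates), 2L)
})
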