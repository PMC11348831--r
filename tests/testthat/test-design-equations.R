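test_that("the three published case-study predictions are reproduced exactly", {
  expect_equal(g_from_vertices(65)$g, 13L)
  expect_equal(g_from_edges(1388)$g, 129L)
  expect_equal(suppressWarnings(g_from_edge_length(35, L = 150))$g, 25L)
})

test_that("vertex and edge predictions follow the inverse lines", {
  # forward V for G = 10 is 5.45*10 - 8.53 = 46 after rounding
  expect_equal(g_from_vertices(46)$g, 10L)
  expect_equal(g_from_vertices(25)$g_real, (25 + 8.53) / 5.45)
  expect_equal(g_from_vertices(25)$g, 6L)
  expect_equal(g_from_edges(45)$g_real, (45 + 21.10) / 10.89)
  expect_equal(g_from_edges(45)$g, 6L)
  expect_error(g_from_vertices(7), class = "voroscaffold_invalid_parameter")
  expect_error(g_from_edges(11), class = "voroscaffold_invalid_parameter")
  expect_warning(g_from_vertices(20), "tested range")
})

test_that("edge-length predictions invert the power law in both variants", {
  # epsilon = L is the single-cell cube
  expect_equal(suppressWarnings(g_from_edge_length(100, L = 100))$g, 1L)
  p <- g_from_edge_length(7, L = 100)
  expect_equal(p$g_real, (7 / 100)^(-1 / 0.45))
  cal <- g_from_edge_length(35, L = 100, calibrated = TRUE)
  expect_equal(cal$g_real, (35 / 101.41)^(-1 / 0.45))
  # the calibrated prefactor rescales with L: identical predictions at any L
  cal150 <- suppressWarnings(
    g_from_edge_length(35 * 1.5, L = 150, calibrated = TRUE))
  expect_equal(cal150$g_real, cal$g_real, tolerance = 1e-12)
  expect_error(g_from_edge_length(0, L = 100),
               class = "voroscaffold_invalid_parameter")
  expect_error(g_from_edge_length(101, L = 100),
               class = "voroscaffold_invalid_parameter")
})

test_that("the Euler route is the exact inverse of chi = 1 + G", {
  expect_equal(g_from_euler(13)$g, 12L)
  expect_equal(g_from_euler(2)$g, 1L)
  expect_equal(g_from_euler(301)$g, 300L)
  expect_equal(g_from_euler(13)$expected_deviation, 0L)
  expect_error(g_from_euler(1), class = "voroscaffold_invalid_parameter")
})

test_that("forward expectations invert back within the tabulated deviations", {
  eq <- design_equations()
  for (g in c(5, 13, 60, 129, 300)) {
    fwd <- expected_metrics_from_g(g)
    expect_equal(fwd$chi_hat, 1 + g)
    gv <- suppressWarnings(g_from_vertices(max(round(fwd$V_hat), 8))$g)
    ge <- suppressWarnings(g_from_edges(max(round(fwd$E_hat), 12))$g)
    gl <- suppressWarnings(g_from_edge_length(fwd$epsilon_hat, L = 100)$g)
    expect_lte(abs(gv - g), 1)
    expect_lte(abs(ge - g), 1)
    expect_lte(abs(gl - g), 3)
  }
  f <- expected_metrics_from_g(13)
  expect_equal(f$V_hat, 5.45 * 13 - 8.53)
  f1 <- expected_metrics_from_g(1)
  expect_equal(f1$epsilon_hat, 100)
  expect_equal(f1$chi_hat, 2)
  f129 <- expected_metrics_from_g(129)
  expect_equal(f129$E_hat, 10.89 * 129 - 21.10)
})

test_that("vertex and edge routes agree through the degree identity", {
  for (V in c(25, 65, 300, 1700)) {
    gv <- suppressWarnings(g_from_vertices(V)$g)
    ge <- suppressWarnings(g_from_edges(2 * V - 4)$g)
    expect_lte(abs(gv - ge), 1)
  }
})

test_that("all four predictors are monotone", {
  vs <- suppressWarnings(g_from_vertices(seq(8, 1700, by = 7))$g_real)
  expect_true(all(diff(vs) > 0))
  es <- suppressWarnings(g_from_edges(seq(12, 3400, by = 13))$g_real)
  expect_true(all(diff(es) > 0))
  ls <- suppressWarnings(
    g_from_edge_length(seq(1, 100, by = 1), L = 100)$g_real)
  expect_true(all(diff(ls) < 0))
  expect_true(all(diff(g_from_euler(2:50)$g) > 0))
})

test_that("custom equation sets are validated", {
  expect_error(design_equations(v_slope = -1),
               class = "voroscaffold_invalid_parameter")
  expect_warning(design_equations(e_slope = 12), "inconsistent")
  refit <- design_equations(v_slope = 5.5, e_slope = 11, provenance = "refit")
  expect_equal(refit$provenance, "refit")
  expect_equal(g_from_vertices(65, refit)$g_real, (65 + 8.53) / 5.5)
})
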