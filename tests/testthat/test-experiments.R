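test_that("ensemble bookkeeping: one row per pose, reproducible", {
  spec <- ensemble_spec(5:7, poses_per_g = 2, lambda_max = 3, master_seed = 9)
  tab <- run_ensemble(spec)
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$G)), 5:7)
  expect_true(all(tab$lambda == 3))
  tab2 <- run_ensemble(spec)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # per-structure seeds are distinct and valid 32-bit values
  expect_false(any(duplicated(tab$seed)))
  expect_true(all(tab$seed >= 1 & tab$seed <= 2147483647))
})

test_that("recording every iteration yields lambda_max + 1 rows per pose", {
  spec <- ensemble_spec(6, poses_per_g = 2, lambda_max = 4, master_seed = 2,
                        record_every_iteration = TRUE)
  tab <- run_ensemble(spec)
  expect_equal(nrow(tab), 2 * 5)
  expect_equal(sort(unique(tab$lambda)), 0:4)
})

test_that("clean ensemble structures satisfy the Euler relation", {
  tab <- run_ensemble(ensemble_spec(c(5, 9, 14), poses_per_g = 3,
                                    lambda_max = 8, master_seed = 4))
  clean <- tab[tab$short_edge_count == 0, ]
  expect_gt(nrow(clean), 0)
  expect_true(all(clean$chi == clean$G + 1))
  expect_true(all(clean$E == 2 * clean$V - 4))
})

test_that("linear fits recover exact synthetic coefficients", {
  g <- rep(seq(5, 100, by = 5), each = 3)
  tab <- tibble::tibble(G = g, V = 5.45 * g - 8.53, E = 10.89 * g - 21.10,
                        epsilon = 100 * g^(-0.45), chi = g + 1, L = 100)
  # lm warns about "essentially perfect fit" on exact synthetic data
  fv <- suppressWarnings(fit_linear(tab, "V"))
  expect_equal(fv$slope, 5.45, tolerance = 1e-10)
  expect_equal(fv$intercept, -8.53, tolerance = 1e-8)
  expect_equal(fv$r_squared, 1, tolerance = 1e-12)
  fe <- suppressWarnings(fit_linear(tab, "E", aggregation = "per_structure"))
  expect_equal(fe$slope, 10.89, tolerance = 1e-10)
  fp <- suppressWarnings(fit_powerlaw(tab))
  expect_equal(fp$prefactor, 100, tolerance = 1e-8)
  expect_equal(fp$exponent, 0.45, tolerance = 1e-10)
  expect_equal(fp$r_squared, 1, tolerance = 1e-12)

  expect_equal(tidy(fv)$estimate, c(5.45, -8.53), tolerance = 1e-8)
  expect_equal(glance(fp)$model, "powerlaw")
  expect_error(fit_linear(tab[tab$G == 5, ], "V"),
               class = "voroscaffold_invalid_parameter")
})

test_that("refit from a generated ensemble keeps the edge/vertex slope ratio", {
  tab <- run_ensemble(ensemble_spec(c(5, 8, 12, 16, 30, 60),
                                    poses_per_g = 3, lambda_max = 10,
                                    master_seed = 6))
  fv <- fit_linear(tab, "V")
  fe <- fit_linear(tab, "E")
  expect_equal(fe$slope / fv$slope, 2, tolerance = 0.01)
  # intercepts related through E = 2V - 4
  expect_equal(fe$intercept, 2 * fv$intercept - 4, tolerance = 0.15)
  eq <- refit_design_equations(tab)
  expect_s3_class(eq, "design_equation_set")
  expect_equal(eq$provenance, "refit")
})

test_that("the power-law prefactor scales with the cube side", {
  gs <- c(6, 12, 24, 48)
  t10 <- run_ensemble(ensemble_spec(gs, poses_per_g = 3, lambda_max = 8,
                                    L = 10, master_seed = 11))
  t100 <- run_ensemble(ensemble_spec(gs, poses_per_g = 3, lambda_max = 8,
                                     L = 100, master_seed = 11))
  f10 <- fit_powerlaw(t10)
  f100 <- fit_powerlaw(t100)
  # identical seeds at both scales: exponent identical, prefactor 10x
  expect_equal(f10$exponent, f100$exponent, tolerance = 1e-6)
  expect_equal(f100$prefactor / f10$prefactor, 10, tolerance = 1e-6)
})

test_that("deviation reports are zero on exact tables and on the Euler route", {
  g <- rep(c(10, 20, 40, 80), each = 2)
  exact <- tibble::tibble(G = g, V = round(5.45 * g - 8.53),
                          E = round(10.89 * g - 21.10),
                          epsilon = 100 * g^(-0.45), chi = g + 1, L = 100)
  rep <- deviation_report(exact)
  expect_equal(rep$mean_abs_deviation[rep$equation == "eq_euler"], 0)
  expect_true(all(rep$mean_abs_deviation <= 1))
  expect_true(all(rep$mean_abs_deviation <= rep$max_abs_deviation))
  expect_error(deviation_report(exact[0, ]),
               class = "voroscaffold_invalid_parameter")
})

test_that("the Lloyd audit confirms delta E = 2 delta V on recorded traces", {
  tr <- relax(sample_pose(12, seed = 5), lambda_max = 10,
              record_energy = FALSE)
  audit <- lloyd_delta_audit(tr)
  expect_equal(audit$n_transitions, 10)
  clean <- audit$steps[!audit$steps$short_edge_flag, ]
  expect_true(all(clean$conforming))

  # constant-V stub trace conforms trivially
  stub <- structure(list(records = tibble::tibble(
    iteration = 0:3, V = 60L, E = 116L, F = 69L, epsilon = 32,
    chi = 13L, short_edge_count = 0L, min_edge_length = 1,
    max_displacement = NA, energy = NA)), class = "relaxation_trace")
  a2 <- lloyd_delta_audit(stub)
  expect_true(all(a2$steps$delta_E == 0 & a2$steps$conforming))

  # a 60 -> 58 vertex drop must shed exactly four edges over two steps
  fig3 <- structure(list(records = tibble::tibble(
    iteration = 0:2, V = c(60L, 59L, 58L), E = c(116L, 114L, 112L),
    F = c(69L, 68L, 67L), epsilon = c(32.74, 33.0, 33.26), chi = 13L,
    short_edge_count = 0L, min_edge_length = 1,
    max_displacement = NA, energy = NA)), class = "relaxation_trace")
  a3 <- lloyd_delta_audit(fig3)
  expect_true(all(a3$steps$conforming))
  expect_equal(a3$conforming_fraction, 1)
})

test_that("case studies predict the published G and separate neighbours", {
  cs <- case_study("lymph", n_structures = 25, lambda_max = 8,
                   master_seed = 3)
  expect_equal(cs$prediction$g, 13L)
  expect_equal(sort(cs$summary$G), c(12, 13, 14))
  hits <- cs$summary$n_exact[cs$summary$G == 13]
  miss <- cs$summary$n_exact[cs$summary$G != 13]
  expect_gt(hits, max(miss))

  cs_b <- case_study("bone", n_structures = 2, lambda_max = 2,
                     master_seed = 1, include_neighbors = FALSE)
  expect_equal(cs_b$prediction$g, 129L)
  cs_t <- case_study("tumour", n_structures = 3, lambda_max = 2,
                     master_seed = 1, include_neighbors = FALSE)
  expect_equal(cs_t$prediction$g, 25L)
  expect_equal(cs_t$target$L, 150)
  expect_equal(unique(cs_t$table$L), 150)
})
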