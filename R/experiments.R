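#' Specify an ensemble of structures
#'
#' An ensemble spans a grid of generating-point counts, several independent
#' poses per count, and a fixed number of Lloyd iterations. Per-structure
#' seeds are derived deterministically from the master seed (a multiplicative
#' congruential mix over (G, pose index)), so every individual structure is
#' reproducible in isolation.
#'
#' The reference study conditions are: set A with G = 5-18, 20 poses per G and
#' lambda = 40; set B with G = 30-300, 5 poses and lambda = 25. Desk-scale
#' replications shrink the pose counts but keep the G coverage.
#'
#' @param g_values Integer vector of generating-point counts (all >= 1).
#' @param poses_per_g Number of independent poses per G (>= 1).
#' @param lambda_max Lloyd iterations applied to every pose.
#' @param L Cube side length.
#' @param master_seed Master seed from which per-structure seeds derive.
#' @param record_every_iteration Keep one row per Lloyd iteration instead of
#'   final structures only.
#' @return An object of class `ensemble_spec`.
#' @examples
#' ensemble_spec(5:18, poses_per_g = 10, lambda_max = 15)
#' @export
ensemble_spec <- function(g_values, poses_per_g, lambda_max = 25, L = 100,
                          master_seed = 1, record_every_iteration = FALSE) {
  if (any(g_values < 1) || any(g_values != floor(g_values))) {
    abort("all `g_values` must be integers >= 1.",
          class = "voroscaffold_invalid_parameter")
  }
  if (poses_per_g < 1 || poses_per_g != floor(poses_per_g)) {
    abort("`poses_per_g` must be an integer >= 1.",
          class = "voroscaffold_invalid_parameter")
  }
  structure(
    list(g_values = as.integer(g_values),
         poses_per_g = as.integer(poses_per_g),
         lambda_max = as.integer(lambda_max), L = as.numeric(L),
         master_seed = as.integer(master_seed),
         record_every_iteration = isTRUE(record_every_iteration)),
    class = "ensemble_spec"
  )
}

# Deterministic per-structure seed: two rounds of the MINSTD multiplier over
# (master, G, pose), reduced mod 2^31 - 1 and kept >= 1.
child_seed <- function(master_seed, g, pose) {
  m <- 2147483647
  s <- as.numeric(master_seed) %% m
  s <- (s * 48271 + as.numeric(g)) %% m
  s <- (s * 48271 + as.numeric(pose)) %% m
  as.integer(s + 1)
}

#' Generate an ensemble table
#'
#' Runs the full pipeline (sample pose, Lloyd-relax, measure) over every
#' (G, pose) combination it describes and returns one row per final structure
#' (or per recorded iteration when `record_every_iteration` is set). Structures
#' with short-edge degeneracies are kept and flagged via `short_edge_count`,
#' never dropped: they carry the topology deviations the audit reports count.
#'
#' @param spec An [ensemble_spec()].
#' @param .progress Print a line per G level (default `FALSE`).
#' @return A tibble of class `ensemble_table` with columns `structure_id`,
#'   `G`, `pose_id`, `seed`, `lambda`, `L`, `V`, `E`, `F`, `epsilon`, `chi`,
#'   `short_edge_count`, `min_edge_length`.
#' @examples
#' tab <- run_ensemble(ensemble_spec(5:7, poses_per_g = 2, lambda_max = 2))
#' tab
#' @export
run_ensemble <- function(spec, .progress = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  cube <- bounding_cube(spec$L)
  rows <- list()
  k <- 0L
  for (g in spec$g_values) {
    if (.progress) message("G = ", g)
    for (p in seq_len(spec$poses_per_g)) {
      seed <- child_seed(spec$master_seed, g, p)
      pose <- sample_pose(g, seed = seed, cube = cube, pose_id = p)
      tr <- relax(pose, cube, lambda_max = spec$lambda_max,
                  record_metrics = spec$record_every_iteration,
                  record_energy = FALSE)
      if (spec$record_every_iteration) {
        rec <- tr$records
      } else {
        m <- measure(tr$final_complex)
        rec <- tidy(m)[, c("V", "E", "F", "epsilon", "chi",
                           "short_edge_count", "min_edge_length")]
        rec$iteration <- spec$lambda_max
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        structure_id = sprintf("G%d_p%d_l%d", g, p, rec$iteration),
        G = g, pose_id = p, seed = seed, lambda = rec$iteration,
        L = spec$L, V = rec$V, E = rec$E, F = rec$F, epsilon = rec$epsilon,
        chi = rec$chi, short_edge_count = rec$short_edge_count,
        min_edge_length = rec$min_edge_length)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ensemble_table", class(out))
  out
}

assert_table <- function(table) {
  need <- c("G", "V", "E", "epsilon", "chi")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    abort("`table` must be an ensemble table with columns G, V, E, epsilon, chi.",
          class = "voroscaffold_invalid_parameter")
  }
  invisible(table)
}

#' Linear fit of a structural parameter against G
#'
#' Ordinary least squares of the per-G mean vertex (or edge) count against the
#' number of generating points; this is the regression behind the inverse
#' design lines. Aggregation over per-G means is the default (each published
#' data point averages many structures); `aggregation = "per_structure"` fits
#' the raw rows.
#'
#' @param table An ensemble table (from [run_ensemble()] or read from CSV).
#' @param response `"V"` or `"E"`.
#' @param aggregation `"per_g_mean"` (default) or `"per_structure"`.
#' @return An object of class `voro_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_points`; see [tidy.voro_fit()] and [glance.voro_fit()].
#' @examples
#' tab <- tibble::tibble(G = rep(5:10, each = 2),
#'                       V = 5.45 * rep(5:10, each = 2) - 8.53,
#'                       E = 2 * V - 4, epsilon = 1, chi = G + 1)
#' fit_linear(tab, "V")
#' @export
fit_linear <- function(table, response = c("V", "E"),
                       aggregation = c("per_g_mean", "per_structure")) {
  assert_table(table)
  response <- match.arg(response)
  aggregation <- match.arg(aggregation)
  if (length(unique(table$G)) < 3) {
    abort("need at least 3 distinct G values to fit.",
          class = "voroscaffold_invalid_parameter")
  }
  df <- aggregate_table(table, response, aggregation)
  fit <- stats::lm(y ~ G, data = df)
  new_voro_fit(model = "linear", response = response,
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r_squared = summary(fit)$r.squared, n_points = nrow(df),
               aggregation = aggregation, fit = fit)
}

#' Power-law fit of mean edge length against G
#'
#' OLS of `log(epsilon)` on `log(G)` over per-G means (or per structure),
#' reporting the back-transformed prefactor (the fitted edge length at G = 1)
#' and the magnitude of the exponent. At L = 100 the published calibration is
#' `epsilon = 101.41 * G^-0.45`.
#'
#' @inheritParams fit_linear
#' @return A `voro_fit` with `prefactor`, `exponent` (positive magnitude),
#'   `r_squared`, `n_points`.
#' @export
fit_powerlaw <- function(table,
                         aggregation = c("per_g_mean", "per_structure")) {
  assert_table(table)
  aggregation <- match.arg(aggregation)
  if (length(unique(table$G)) < 3) {
    abort("need at least 3 distinct G values to fit.",
          class = "voroscaffold_invalid_parameter")
  }
  if (any(table$epsilon <= 0)) {
    abort("all epsilon values must be positive for a log-log fit.",
          class = "voroscaffold_invalid_parameter")
  }
  df <- aggregate_table(table, "epsilon", aggregation)
  fit <- stats::lm(log(y) ~ log(G), data = df)
  new_voro_fit(model = "powerlaw", response = "epsilon",
               prefactor = exp(unname(coef(fit)[1])),
               exponent = -unname(coef(fit)[2]),
               r_squared = summary(fit)$r.squared, n_points = nrow(df),
               aggregation = aggregation, fit = fit)
}

aggregate_table <- function(table, response, aggregation) {
  if (aggregation == "per_g_mean") {
    df <- dplyr::summarise(dplyr::group_by(as_tibble(table), .data$G),
                           y = mean(.data[[response]]), .groups = "drop")
  } else {
    df <- tibble(G = table$G, y = table[[response]])
  }
  df
}

new_voro_fit <- function(...) {
  structure(list(...), class = "voro_fit")
}

#' @export
print.voro_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("<voro_fit> %s = %.4g * G %+.4g  (R^2 = %.4f, n = %d, %s)\n",
                x$response, x$slope, x$intercept, x$r_squared, x$n_points,
                x$aggregation))
  } else {
    cat(sprintf("<voro_fit> epsilon = %.4g * G^-%.4g  (R^2 = %.4f, n = %d, %s)\n",
                x$prefactor, x$exponent, x$r_squared, x$n_points,
                x$aggregation))
  }
  invisible(x)
}

#' Tidy a structural-parameter fit
#' @param x A [voro_fit][fit_linear()].
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.voro_fit <- function(x, ...) {
  if (x$model == "linear") {
    tibble(term = c("slope", "intercept"),
           estimate = c(x$slope, x$intercept))
  } else {
    tibble(term = c("prefactor", "exponent"),
           estimate = c(x$prefactor, x$exponent))
  }
}

#' Glance at a structural-parameter fit
#' @param x A [voro_fit][fit_linear()].
#' @param ... Unused.
#' @return A one-row tibble: `model`, `response`, `r_squared`, `n_points`,
#'   `aggregation`.
#' @export
glance.voro_fit <- function(x, ...) {
  tibble(model = x$model, response = x$response, r_squared = x$r_squared,
         n_points = x$n_points, aggregation = x$aggregation)
}

#' Refit the design equation set from an ensemble
#'
#' Convenience wrapper: fits the vertex and edge lines and the edge-length
#' power law on an ensemble table and assembles a `design_equation_set` with
#' `provenance = "refit"`. The prefactor is rescaled to L = 100 for
#' comparability with the published calibration.
#'
#' @param table An ensemble table generated at a single L.
#' @return A [design_equations()] set.
#' @export
refit_design_equations <- function(table) {
  assert_table(table)
  L <- if ("L" %in% names(table)) unique(table$L) else 100
  if (length(L) != 1) {
    abort("refit requires an ensemble generated at a single cube size.",
          class = "voroscaffold_invalid_parameter")
  }
  fv <- fit_linear(table, "V")
  fe <- fit_linear(table, "E")
  fp <- fit_powerlaw(table)
  design_equations(v_slope = fv$slope, v_offset = -fv$intercept,
                   e_slope = fe$slope, e_offset = -fe$intercept,
                   eps_exponent = fp$exponent,
                   eps_prefactor = fp$prefactor * 100 / L,
                   provenance = "refit")
}

#' Prediction-deviation report
#'
#' For every structure in the table, predicts G from each of its measured
#' parameters through the four inverse equations and reports the mean and
#' maximum absolute deviation |g_hat - G| per equation. The Euler route is
#' exact on structures free of short-edge degeneracies; the published average
#' deviations are about 1 (vertex and edge lines), 3 (edge-length power law)
#' and 0 (Euler).
#'
#' Deviations are averaged per structure; `per_g` adds the alternative
#' aggregation (mean over per-G mean deviations) alongside.
#'
#' @param table An ensemble table.
#' @param eqset A [design_equations()] set.
#' @param per_g Also report the per-G-mean aggregation (default `TRUE`).
#' @return A tibble with one row per equation: `equation`,
#'   `mean_abs_deviation`, `max_abs_deviation`, `n` and (optionally)
#'   `mean_abs_deviation_per_g`.
#' @export
deviation_report <- function(table, eqset = design_equations(),
                             per_g = TRUE) {
  assert_table(table)
  if (nrow(table) == 0) {
    abort("`table` is empty.", class = "voroscaffold_invalid_parameter")
  }
  L <- if ("L" %in% names(table)) table$L else rep(100, nrow(table))
  preds <- list(
    eq_vertices = suppressWarnings(g_from_vertices(table$V, eqset)$g),
    eq_edges = suppressWarnings(g_from_edges(table$E, eqset)$g),
    eq_edge_length = suppressWarnings(
      vapply(seq_len(nrow(table)),
             function(i) g_from_edge_length(table$epsilon[i], L[i], eqset)$g,
             integer(1))),
    eq_euler = suppressWarnings(g_from_euler(table$chi)$g)
  )
  out <- purrr::map_dfr(names(preds), function(eq) {
    dev <- abs(preds[[eq]] - table$G)
    row <- tibble(equation = eq,
                  mean_abs_deviation = mean(dev),
                  max_abs_deviation = as.integer(max(dev)),
                  n = nrow(table))
    if (per_g) {
      row$mean_abs_deviation_per_g <-
        mean(tapply(dev, table$G, mean))
    }
    row
  })
  out
}

#' Audit vertex/edge deltas across Lloyd iterations
#'
#' Between consecutive Lloyd iterations of the same pose, adding or removing a
#' vertex adds or removes exactly two edges (every vertex has degree 4 except
#' the 8 degree-3 cube corners), so `delta E = 2 * delta V` whenever no
#' short-edge degeneracy is present. This audit checks that relation along a
#' relaxation trace.
#'
#' @param trace A [relaxation_trace][relax()] recorded with metrics.
#' @return A list of class `lloyd_audit`: `steps` (tibble with
#'   `iteration_from`, `iteration_to`, `delta_V`, `delta_E`, `conforming`,
#'   `short_edge_flag`), `n_transitions`, `conforming_fraction` (all
#'   transitions) and `conforming_fraction_clean` (transitions without
#'   short-edge flags; `NaN` when there are none).
#' @export
lloyd_delta_audit <- function(trace) {
  stopifnot(inherits(trace, "relaxation_trace"))
  r <- trace$records
  if (nrow(r) < 2) {
    abort("trace must contain at least 2 records.",
          class = "voroscaffold_invalid_parameter")
  }
  if (any(is.na(r$V))) {
    abort("trace was recorded without metrics; rerun relax() with record_metrics = TRUE.",
          class = "voroscaffold_invalid_parameter")
  }
  i <- seq_len(nrow(r) - 1)
  steps <- tibble(
    iteration_from = r$iteration[i],
    iteration_to = r$iteration[i + 1],
    delta_V = r$V[i + 1] - r$V[i],
    delta_E = r$E[i + 1] - r$E[i],
    short_edge_flag = r$short_edge_count[i] > 0 |
      r$short_edge_count[i + 1] > 0
  )
  steps$conforming <- steps$delta_E == 2L * steps$delta_V
  clean <- steps[!steps$short_edge_flag, ]
  structure(
    list(steps = steps, n_transitions = nrow(steps),
         conforming_fraction = mean(steps$conforming),
         conforming_fraction_clean = mean(clean$conforming)),
    class = "lloyd_audit"
  )
}

#' @export
print.lloyd_audit <- function(x, ...) {
  cat(sprintf("<lloyd_audit> %d transitions, %.1f%% conforming (delta E = 2 delta V)\n",
              x$n_transitions, 100 * x$conforming_fraction))
  invisible(x)
}

#' Biomedical case studies
#'
#' Reproduces the three worked inverse-design examples:
#'
#' * `"lymph"` - a lymph-node T-cell niche modelled on fibroblastic reticular
#'   cell networks: 65 vertices in an L = 100 micrometre cube; the vertex line
#'   predicts G = 13.
#' * `"bone"` - trabecular bone with 1388 edges in a segment of the bone
#'   microenvironment; the edge line predicts G = 129.
#' * `"tumour"` - a kidney tumour with mean cell-cell edge length 35.0 mm in
#'   an L = 150 mm design space; the power-law inverse predicts G = 25.
#'
#' For the predicted G (and optionally its published neighbours) the function
#' generates `n_structures` independent structures and summarises the achieved
#' parameter against the design target.
#'
#' @param kind `"lymph"`, `"bone"` or `"tumour"`.
#' @param n_structures Structures generated per G level (default 100).
#' @param lambda_max Lloyd iterations per structure (default 25, the
#'   large-structure ensemble convention; the original report does not state
#'   it for the case studies).
#' @param master_seed Master seed.
#' @param include_neighbors Also generate the neighbouring G levels examined
#'   in the original report (default `TRUE`).
#' @return A list of class `case_study`: `kind`, `target` (parameter name and
#'   value, and cube size), `prediction` (tibble from the inverse equation),
#'   `summary` (one row per G level: n, mean/min/max of the target parameter,
#'   `n_exact` for the lymph vertex counts), and `table` (the full per-
#'   structure ensemble table).
#' @export
case_study <- function(kind = c("lymph", "bone", "tumour"),
                       n_structures = 100, lambda_max = 25, master_seed = 1,
                       include_neighbors = TRUE) {
  kind <- match.arg(kind)
  if (n_structures < 1) {
    abort("`n_structures` must be >= 1.",
          class = "voroscaffold_invalid_parameter")
  }
  cfg <- switch(kind,
    lymph = list(parameter = "V", value = 65, L = 100,
                 predict = function() g_from_vertices(65),
                 neighbors = c(-1, 1)),
    bone = list(parameter = "E", value = 1388, L = 100,
                predict = function() g_from_edges(1388),
                neighbors = c(-1, 1, 2)),
    tumour = list(parameter = "epsilon", value = 35.0, L = 150,
                  predict = function() g_from_edge_length(35.0, L = 150),
                  neighbors = c(-2, -1, 1))
  )
  pred <- cfg$predict()
  g_hat <- pred$g
  g_levels <- if (include_neighbors) sort(g_hat + c(0, cfg$neighbors))
              else g_hat
  spec <- ensemble_spec(g_levels, poses_per_g = n_structures,
                        lambda_max = lambda_max, L = cfg$L,
                        master_seed = master_seed)
  tab <- run_ensemble(spec)
  summ <- dplyr::summarise(
    dplyr::group_by(as_tibble(tab), .data$G),
    n = dplyr::n(),
    mean = mean(.data[[cfg$parameter]]),
    min = min(.data[[cfg$parameter]]),
    max = max(.data[[cfg$parameter]]),
    n_exact = sum(.data[[cfg$parameter]] == cfg$value),
    .groups = "drop")
  structure(
    list(kind = kind,
         target = list(parameter = cfg$parameter, value = cfg$value,
                       L = cfg$L),
         prediction = pred, summary = summ, table = tab,
         lambda_max = lambda_max),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study: %s> target %s = %g (L = %g) -> predicted G = %d\n",
              x$kind, x$target$parameter, x$target$value, x$target$L,
              x$prediction$g))
  print(x$summary)
  invisible(x)
}
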