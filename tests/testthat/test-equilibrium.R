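# frozen expected values for the symmetric equilibria, confirmed against the
# brute-force grid oracle in the test below:
#   size_independent,  s = 0.1, r = 0    -> sqrt(1/5)    = 0.4472136
#   size_independent,  s = 0.1, r = 0.5  -> 1/3          = 0.3333333
#   size_proportional, s = 0.1, r = 0    -> sqrt(0.02)   = 0.1414214
#   size_scaled_cost,  s = 0.1, r = 0.25 -> 0.1*sqrt(3/19) = 0.03973597

test_that("closed-form symmetric equilibria are fixed points of the brute-force best response", {
  cases <- expand.grid(form = fitness_formulations(),
                       s = c(0.05, 0.1, 0.5, 1), r = c(0, 0.25, 0.5, 0.9),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    a_star <- symmetric_equilibrium_analytic(cases$s[i], cases$r[i],
                                             cases$form[i])
    br <- bf_best_response(cases$s[i], cases$s[i], cases$r[i], cases$form[i],
                           a_star, n = 1e5)
    expect_equal(br, a_star, tolerance = 1e-3)
  }
  expect_equal(symmetric_equilibrium_analytic(0.1, 0, "size_independent"),
               sqrt(0.2), tolerance = 1e-12)
  expect_equal(symmetric_equilibrium_analytic(0.1, 0.5, "size_independent"),
               1 / 3, tolerance = 1e-12)
  expect_equal(symmetric_equilibrium_analytic(0.1, 0, "size_proportional"),
               sqrt(0.02), tolerance = 1e-12)
  expect_equal(symmetric_equilibrium_analytic(0.1, 0.25, "size_scaled_cost"),
               0.1 * sqrt(0.75 / 4.75), tolerance = 1e-12)
  expect_warning(out <- symmetric_equilibrium_analytic(0.3, 1, "size_independent"),
                 "neutral")
  expect_equal(out, 0)
})

test_that("best response reproduces the symmetric fixed points", {
  g <- dyad_game(0.1, 0.1, 0, "size_independent")
  expect_equal(as.numeric(best_response(g, 1 / sqrt(5))), 1 / sqrt(5),
               tolerance = 1e-6)
  g <- dyad_game(0.1, 0.1, 0.5, "size_independent")
  expect_equal(as.numeric(best_response(g, 1 / 3)), 1 / 3, tolerance = 1e-6)
})

test_that("a fully costly opponent removes the kin penalty even at r = 1", {
  # with the opponent at its zero-fitness bound, v2 = 0, so the focal
  # maximises omega1 * v1 and the optimum is strictly interior
  for (form in fitness_formulations()) {
    g <- dyad_game(0.3, 0.6, 1, form)
    a2 <- max_aggressiveness(0.6, form)
    br <- best_response(g, a2)
    expect_gt(as.numeric(br), 0)
    expect_lt(as.numeric(br), max_aggressiveness(0.3, form))
    expect_equal(as.numeric(br), bf_best_response(0.3, 0.6, 1, form, a2),
                 tolerance = 1e-3)
  }
})

test_that("best response to a passive opponent is flagged as an unattained supremum", {
  g <- dyad_game(0.1, 0.1, 0, "size_independent")
  opts <- solver_options()
  br <- best_response(g, 0, opts = opts)
  expect_true(attr(br, "supremum_not_attained"))
  expect_equal(as.numeric(br), 1 / (opts$grid_points - 1))
})

test_that("symmetric Nash equilibria match the analytic solutions", {
  eq <- nash_equilibrium(dyad_game(0.1, 0.1, 0, "size_independent"))
  expect_true(eq$converged)
  expect_equal(eq$a1_star, 0.4472136, tolerance = 1e-5)
  expect_equal(eq$a1_star, eq$a2_star, tolerance = 1e-8)
  eq <- nash_equilibrium(dyad_game(0.1, 0.1, 0.25, "size_scaled_cost"))
  expect_equal(eq$a1_star, 0.03973597, tolerance = 1e-5)
  eq <- nash_equilibrium(dyad_game(0.1, 0.1, 0, "size_proportional"))
  expect_equal(eq$a1_star, 0.14142136, tolerance = 1e-5)
})

test_that("equilibria are invariant to doubling the search grid", {
  games <- list(dyad_game(0.1, 0.45, 0.25, "size_scaled_cost"),
                dyad_game(0.2, 0.9, 0.5, "size_independent"),
                dyad_game(0.1, 0.2, 0.25, "size_proportional"))
  for (g in games) {
    e1 <- nash_equilibrium(g, solver_options(grid_points = 1001))
    e2 <- nash_equilibrium(g, solver_options(grid_points = 2001))
    expect_lt(max(abs(c(e1$a1_star - e2$a1_star, e1$a2_star - e2$a2_star))),
              1e-8 * 10 + 1e-7)
  }
})

test_that("mutual-best-response verification accepts equilibria and rejects perturbations", {
  g <- dyad_game(0.1, 0.1, 0, "size_independent")
  a_star <- symmetric_equilibrium_analytic(0.1, 0, "size_independent")
  expect_true(verify_mutual_best_response(g, a_star, a_star, tol = 1e-5))
  amax <- max_aggressiveness(0.1, "size_independent")
  expect_false(verify_mutual_best_response(g, amax, amax, tol = 1e-5))
  tol <- 1e-5
  expect_false(verify_mutual_best_response(g, a_star + 50 * tol, a_star,
                                           tol = tol))
})

test_that("non-convergence is reported as a flag, never an exception", {
  g <- dyad_game(0.1, 0.45, 0.25, "size_scaled_cost")
  eq <- nash_equilibrium(g, solver_options(max_iterations = 1,
                                           br_tol = 1e-14, restarts = 2))
  expect_false(eq$converged)
  expect_s3_class(eq, "equilibrium_result")
})

test_that("the sweep has the documented shape, ordering and symmetric diagonal", {
  grid <- seq(0.1, 0.5, by = 0.1)
  sw <- equilibrium_sweep(s_small = 0.1, s_large_grid = grid)
  expect_equal(nrow(sw), 3 * 3 * length(grid))
  expect_identical(names(sw),
                   c("formulation", "r", "s_small", "s_large", "a_small",
                     "a_large", "converged", "is_corner", "iterations"))
  # deterministic ordering: formulation, then r, then s_large ascending
  expect_identical(sw$s_large, rep(grid, times = 9))
  diag_rows <- sw[sw$s_large == sw$s_small, ]
  expect_true(all(abs(diag_rows$a_small - diag_rows$a_large) < 1e-7))
  expect_true(all(sw$converged))
})

test_that("sweep CSV round-trips through the package reader", {
  sw <- equilibrium_sweep(s_large_grid = c(0.1, 0.3),
                          r_values = c(0, 0.5),
                          formulations = "size_scaled_cost")
  path <- tempfile(fileext = ".csv")
  write_sweep(sw, path, seed = 99)
  back <- read_commented_csv(path)
  expect_equal(back, sw, tolerance = 1e-12)
  expect_match(readLines(path, n = 2)[2], "seed: 99")
})

test_that("solver options validate their domains", {
  expect_error(solver_options(grid_points = 2))
  expect_error(solver_options(refine_tol = 0))
  expect_error(solver_options(restarts = 0))
  expect_error(solver_options(damping = 0))
})
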