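#' Solver options for best-response and equilibrium computation
#'
#' @param grid_points Number of points in the coarse grid over the admissible
#'   aggressiveness interval (boundaries included). At least 3.
#' @param refine_tol Absolute tolerance of the bounded local refinement around
#'   the best grid point.
#' @param br_tol Convergence tolerance on `max(|delta a|)` across
#'   best-response iterations.
#' @param max_iterations Maximum number of best-response iterations per start.
#' @param restarts Number of quasi-random initial aggressiveness pairs (the
#'   two corner pairs are always added).
#' @param damping Step factor in `(0, 1]` applied to best-response updates;
#'   1 is undamped. Lower it if oscillation is flagged.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(grid_points = 1001L, refine_tol = 1e-9,
                           br_tol = 1e-8, max_iterations = 500L,
                           restarts = 8L, damping = 1) {
  stopifnot(grid_points >= 3, refine_tol > 0, br_tol > 0,
            max_iterations >= 1, restarts >= 1,
            damping > 0, damping <= 1)
  structure(list(grid_points = as.integer(grid_points),
                 refine_tol = refine_tol, br_tol = br_tol,
                 max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts), damping = damping),
            class = "solver_options")
}

game_side <- function(game, focal) {
  if (focal == 1L) list(s = game$s1, s_opp = game$s2) else list(s = game$s2, s_opp = game$s1)
}

#' Best-response aggressiveness
#'
#' Finds the aggressiveness maximising the focal contestant's expected
#' inclusive fitness given the opponent's aggressiveness, by a coarse grid
#' over `[0, max_aggressiveness]` followed by bounded derivative-free
#' refinement around the best grid point. Both boundaries are always
#' evaluated, and ties are broken toward the smallest aggressiveness.
#'
#' When the opponent is fully passive (`opponent_a = 0`) the focal's payoff
#' jumps: any positive aggressiveness wins outright, and payoff then decreases
#' in `a`, so the supremum lies at `a -> 0+` and is not attained. The function
#' returns the smallest positive grid value, with attribute
#' `supremum_not_attained = TRUE`, rather than hiding the discontinuity.
#'
#' @param game A [dyad_game()].
#' @param opponent_a Opponent's aggressiveness (admissible for its size).
#' @param focal Which contestant responds (1 or 2).
#' @param opts A [solver_options()].
#' @return The best-response aggressiveness, with attributes
#'   `supremum_not_attained` (logical) and `f_value` (the attained expected
#'   inclusive fitness).
#' @export
best_response <- function(game, opponent_a, focal = 1L, opts = solver_options()) {
  stopifnot(inherits(game, "dyad_game"), inherits(opts, "solver_options"))
  sd <- game_side(game, focal)
  amax <- max_aggressiveness(sd$s, game$formulation)
  amax_opp <- max_aggressiveness(sd$s_opp, game$formulation)
  if (opponent_a < 0 || opponent_a > amax_opp * (1 + 1e-12))
    stop("opponent aggressiveness is outside its admissible range", call. = FALSE)

  f <- if (focal == 1L) {
    function(a) expected_inclusive_fitness(game, a, opponent_a, focal = 1L)
  } else {
    function(a) expected_inclusive_fitness(game, opponent_a, a, focal = 2L)
  }

  grid <- seq(0, amax, length.out = opts$grid_points)
  fv <- f(grid)
  if (any(!is.finite(fv)))
    stop(sprintf(
      "non-finite expected fitness (focal %d, opponent_a = %g, formulation %s)",
      focal, opponent_a, game$formulation), call. = FALSE)

  sup_flag <- FALSE
  if (opponent_a == 0) {
    # payoff is discontinuous at a = 0 and strictly decreasing for a > 0:
    # the supremum sits at a -> 0+ unless staying passive beats every attack
    a_eps <- grid[2L]
    if (f(a_eps) >= fv[1L]) {
      a_star <- a_eps
      sup_flag <- TRUE
      return(structure(a_star, supremum_not_attained = TRUE,
                       f_value = f(a_star)))
    }
    return(structure(0, supremum_not_attained = FALSE, f_value = fv[1L]))
  }

  best <- which.max(fv)  # first maximum -> smallest a on exact ties
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  cand_a <- grid[best]
  cand_f <- fv[best]
  if (hi > lo) {
    op <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                          tol = opts$refine_tol)
    if (op$objective >= cand_f) {
      cand_a <- op$maximum
      cand_f <- op$objective
    }
  }
  # boundary candidates always compete; prefer smaller a on ties within tol
  for (ab in c(0, amax)) {
    fb <- f(ab)
    if (fb > cand_f + opts$refine_tol ||
        (fb >= cand_f - opts$refine_tol && ab < cand_a)) {
      cand_a <- ab
      cand_f <- fb
    }
  }
  structure(cand_a, supremum_not_attained = sup_flag, f_value = cand_f)
}

#' Closed-form symmetric equilibrium
#'
#' For equal sizes (`s1 = s2 = s`) the stationarity condition of the expected
#' inclusive fitness at a symmetric pair \eqn{a_1 = a_2 = a^*} reduces, for
#' all three formulations, to \eqn{(1-r)(\upsilon/\kappa) = 4 a^{*2}/\kappa}
#' with the formulation's own scaling \eqn{\kappa}, giving
#' \deqn{a^* = \sqrt{\frac{1-r}{5-r}} \quad \text{(size-independent)}, \qquad
#'       a^* = \sqrt{\frac{s(1-r)}{5-r}} \quad \text{(size-proportional)}, \qquad
#'       a^* = s\sqrt{\frac{1-r}{5-r}} \quad \text{(size-scaled cost)}.}
#' At `r = 1` the contest is fitness-neutral and 0 is returned with a warning.
#'
#' These closed forms serve as analytic oracles for the numeric solver; the
#' package's tests re-check them against brute-force grid search.
#'
#' @param s Common relative size of both contestants.
#' @param r Relatedness in `[0, 1]`.
#' @param formulation One of [fitness_formulations()].
#' @return The symmetric equilibrium aggressiveness.
#' @export
symmetric_equilibrium_analytic <- function(s, r, formulation) {
  formulation <- match_formulation(formulation)
  stopifnot(s > 0, r >= 0, r <= 1)
  if (r == 1) {
    warning("r = 1 is fitness-neutral at the symmetric point; returning 0")
    return(0)
  }
  root <- sqrt((1 - r) / (5 - r))
  switch(formulation,
         size_independent  = root,
         size_proportional = sqrt(s) * root,
         size_scaled_cost  = s * root)
}

#' Check that an aggressiveness pair is a mutual best response
#'
#' Recomputes each side's best response on an independent fine grid (at least
#' `1e5` points by default) with tight local refinement, and checks both
#' `|best_response(a2) - a1| <= tol` and `|best_response(a1) - a2| <= tol`.
#'
#' A side whose opponent plays exactly 0 has no attained best response (the
#' supremum sits at `a -> 0+`); such a side passes when its candidate value is
#' itself effectively zero-plus, i.e. at most `100 * tol`.
#'
#' @param game A [dyad_game()].
#' @param a1,a2 Candidate equilibrium aggressiveness pair.
#' @param tol Acceptance tolerance on each coordinate.
#' @param grid_points Fine-grid resolution for the independent check.
#' @return `TRUE` or `FALSE`, with attribute `deviations` giving the two
#'   coordinate discrepancies.
#' @export
verify_mutual_best_response <- function(game, a1, a2, tol = 1e-5,
                                        grid_points = 100001L) {
  opts <- solver_options(grid_points = grid_points,
                         refine_tol = min(tol / 100, 1e-9))
  dev <- numeric(2)
  ok <- logical(2)
  cand <- c(a1, a2)
  opp <- c(a2, a1)
  for (i in 1:2) {
    br <- best_response(game, opp[i], focal = i, opts = opts)
    if (isTRUE(attr(br, "supremum_not_attained"))) {
      dev[i] <- cand[i]
      ok[i] <- cand[i] <= 100 * tol
    } else {
      dev[i] <- abs(as.numeric(br) - cand[i])
      ok[i] <- dev[i] <= tol
    }
  }
  structure(all(ok), deviations = dev)
}

# low-discrepancy (golden-ratio) points in [0,1]^2 for restart positions
quasi_random_pairs <- function(n) {
  phi <- (sqrt(5) - 1) / 2
  k <- seq_len(n)
  cbind((k * phi) %% 1, (k * phi^2) %% 1)
}

#' Mutual-best-response (Nash) equilibrium of a dyadic contest
#'
#' Runs iterated best response from several starting pairs (quasi-random
#' interior points plus the two corner pairs) until the largest coordinate
#' update falls below `br_tol` or `max_iterations` is reached. Distinct fixed
#' points found across restarts (separated by more than `10 * refine_tol`)
#' are recorded in `multiplicity`; the reported equilibrium is the fixed point
#' reached most often, with ties broken toward the smallest total
#' aggressiveness. Symmetric games are symmetrised to machine agreement.
#'
#' @param game A [dyad_game()].
#' @param opts A [solver_options()].
#' @return An object of class `equilibrium_result` with elements `a1_star`,
#'   `a2_star`, `converged`, `iterations`, `is_corner`,
#'   `supremum_not_attained`, `oscillation`, and `multiplicity` (a data frame
#'   of the distinct fixed points with their basin counts).
#' @export
nash_equilibrium <- function(game, opts = solver_options()) {
  stopifnot(inherits(game, "dyad_game"), inherits(opts, "solver_options"))
  amax1 <- max_aggressiveness(game$s1, game$formulation)
  amax2 <- max_aggressiveness(game$s2, game$formulation)

  qr <- quasi_random_pairs(opts$restarts)
  starts <- rbind(cbind(qr[, 1] * amax1, qr[, 2] * amax2),
                  c(0, 0), c(amax1, amax2))

  fixed <- list()
  for (k in seq_len(nrow(starts))) {
    a <- starts[k, ]
    converged <- FALSE
    sup_flag <- FALSE
    osc <- FALSE
    prev_delta <- Inf
    it <- 0L
    for (it in seq_len(opts$max_iterations)) {
      b1 <- best_response(game, a[2], focal = 1L, opts = opts)
      b2 <- best_response(game, as.numeric(b1), focal = 2L, opts = opts)
      sup_flag <- isTRUE(attr(b1, "supremum_not_attained")) ||
        isTRUE(attr(b2, "supremum_not_attained"))
      new <- a + opts$damping * (c(as.numeric(b1), as.numeric(b2)) - a)
      delta <- max(abs(new - a))
      if (delta > prev_delta * 1.5 && delta > 100 * opts$br_tol) osc <- TRUE
      prev_delta <- delta
      a <- new
      if (delta < opts$br_tol) {
        converged <- TRUE
        break
      }
    }
    fixed[[k]] <- list(a1 = a[1], a2 = a[2], converged = converged,
                       iterations = it, sup = sup_flag, osc = osc)
  }

  conv <- Filter(function(z) z$converged, fixed)
  if (length(conv) == 0L) {
    z <- fixed[[1L]]
    return(structure(list(a1_star = z$a1, a2_star = z$a2, converged = FALSE,
                          iterations = z$iterations, is_corner = NA,
                          supremum_not_attained = z$sup, oscillation = z$osc,
                          multiplicity = data.frame()),
                     class = "equilibrium_result"))
  }

  # cluster fixed points; distinct beyond 10 * refine_tol
  sep <- 10 * opts$refine_tol
  pts <- data.frame(a1 = vapply(conv, `[[`, 0, "a1"),
                    a2 = vapply(conv, `[[`, 0, "a2"),
                    sup = vapply(conv, `[[`, TRUE, "sup"),
                    iterations = vapply(conv, `[[`, 0L, "iterations"))
  cl <- integer(nrow(pts))
  reps <- list()
  for (i in seq_len(nrow(pts))) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (max(abs(c(pts$a1[i], pts$a2[i]) - reps[[j]])) <= sep) { hit <- j; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- c(pts$a1[i], pts$a2[i])
      hit <- length(reps)
    }
    cl[i] <- hit
  }
  mult <- do.call(rbind, lapply(seq_along(reps), function(j) {
    data.frame(a1_star = reps[[j]][1], a2_star = reps[[j]][2],
               basin_count = sum(cl == j))
  }))
  # report the most-visited fixed point; ties toward smallest total aggression
  ord <- order(-mult$basin_count, mult$a1_star + mult$a2_star)
  pick <- ord[1L]
  sel <- which(cl == pick)[1L]
  a1s <- mult$a1_star[pick]
  a2s <- mult$a2_star[pick]
  if (game$s1 == game$s2) {
    m <- (a1s + a2s) / 2
    a1s <- m
    a2s <- m
  }
  corner_tol <- 10 * opts$refine_tol
  is_corner <- a1s <= corner_tol || a2s <= corner_tol ||
    a1s >= amax1 - corner_tol || a2s >= amax2 - corner_tol
  structure(list(a1_star = a1s, a2_star = a2s, converged = TRUE,
                 iterations = pts$iterations[sel], is_corner = is_corner,
                 supremum_not_attained = any(pts$sup[cl == pick]),
                 oscillation = any(vapply(conv, `[[`, TRUE, "osc")),
                 multiplicity = mult),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> a1* = %.6f, a2* = %.6f (%s%s)\n",
              x$a1_star, x$a2_star,
              if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$is_corner)) ", corner" else ""))
  if (nrow(x$multiplicity) > 1L)
    cat(sprintf("  %d distinct fixed points across restarts\n",
                nrow(x$multiplicity)))
  if (isTRUE(x$supremum_not_attained))
    cat("  note: one side best-responds to a passive opponent (supremum not attained)\n")
  invisible(x)
}

#' Equilibrium sweep over size, relatedness and formulation
#'
#' Computes the Nash aggressiveness pair for every combination of
#' direct-fitness formulation, relatedness and larger-contestant size, holding
#' the smaller contestant's size fixed. The default configuration holds the
#' small size at 0.1 and sweeps the large size from 0.1 to 1.0 in steps of
#' 0.01 for relatedness 0, 0.25 and 0.5 under all three formulations —
#' the grid on which the model's qualitative predictions (smaller contestants
#' compensating under size-independent fitness; passive small relatives
#' beyond a size threshold under size-proportional fitness; consistently more
#' aggressive large contestants under size-scaled costs) are read off.
#'
#' @param s_small Fixed size of the smaller contestant.
#' @param s_large_grid Ascending sizes of the larger contestant; the first
#'   element must be at least `s_small`.
#' @param r_values Relatedness levels.
#' @param formulations Direct-fitness formulations to include.
#' @param opts A [solver_options()].
#' @return A data frame with one row per (formulation, r, s_large), columns
#'   `formulation, r, s_small, s_large, a_small, a_large, converged,
#'   is_corner, iterations`, ordered by formulation, then r, then s_large.
#'   Non-converged rows are kept, flagged, never dropped.
#' @export
equilibrium_sweep <- function(s_small = 0.1,
                              s_large_grid = seq(0.1, 1, by = 0.01),
                              r_values = c(0, 0.25, 0.5),
                              formulations = fitness_formulations(),
                              opts = solver_options()) {
  stopifnot(s_small > 0, !is.unsorted(s_large_grid),
            s_large_grid[1] >= s_small)
  formulations <- vapply(formulations, match_formulation, "")
  rows <- vector("list", length(formulations) * length(r_values) *
                   length(s_large_grid))
  i <- 0L
  for (f in formulations) {
    for (r in r_values) {
      for (sl in s_large_grid) {
        g <- dyad_game(s1 = s_small, s2 = sl, relatedness = r, formulation = f)
        eq <- nash_equilibrium(g, opts)
        i <- i + 1L
        rows[[i]] <- data.frame(
          formulation = f, r = r, s_small = s_small, s_large = sl,
          a_small = eq$a1_star, a_large = eq$a2_star,
          converged = eq$converged,
          is_corner = if (is.na(eq$is_corner)) NA else eq$is_corner,
          iterations = eq$iterations)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an equilibrium sweep to CSV
#'
#' Comma-separated, '.' decimal, with `#`-prefixed header comment lines
#' recording package version and, when supplied, the seed. Re-readable with
#' [read_commented_csv()].
#'
#' @param sweep A data frame from [equilibrium_sweep()].
#' @param path Output file path.
#' @param seed Optional integer recorded in the header.
#' @export
write_sweep <- function(sweep, path, seed = NULL) {
  write_commented_csv(sweep, path, seed = seed)
}
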