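#' Fitness formulations
#'
#' The winner's direct fitness \eqn{\upsilon} can depend on its relative size
#' \eqn{s} in three alternative ways, each with an accelerating cost of
#' aggressiveness \eqn{a}:
#'
#' * `"size_independent"`: \eqn{\upsilon = 1 - a^2} — adult reproductive
#'   success does not depend on larval size.
#' * `"size_proportional"`: \eqn{\upsilon = s - a^2} — reproductive success is
#'   proportional to size at a given aggressiveness.
#' * `"size_scaled_cost"`: \eqn{\upsilon = 1 - (a/s)^2} — aggressiveness is
#'   costlier for smaller individuals.
#'
#' @return `fitness_formulations()` returns the character vector of the three
#'   valid formulation tags.
#' @export
fitness_formulations <- function() {
  c("size_independent", "size_proportional", "size_scaled_cost")
}

match_formulation <- function(formulation) {
  match.arg(formulation, fitness_formulations())
}

#' Dyadic contest game
#'
#' Bundles the two contestants' relative sizes, their genetic relatedness and
#' a direct-fitness formulation into the unit on which best responses and
#' equilibria are computed. Only one contestant survives the contest; the
#' survivor's inclusive-fitness payoff is \eqn{\upsilon_1 - r\,\upsilon_2},
#' discounting its own success by the lost success of the relative it killed.
#'
#' Sizes are dimensionless relative quantities; nothing requires them to be
#' at most 1.
#'
#' @param s1,s2 Strictly positive relative sizes of contestants 1 and 2.
#' @param relatedness Coefficient of relatedness `r` in `[0, 1]` (0.5 full
#'   siblings, 0.25 paternal half siblings, 0 unrelated).
#' @param formulation One of [fitness_formulations()].
#' @return An object of class `dyad_game`.
#' @examples
#' dyad_game(0.1, 0.4, relatedness = 0.25, formulation = "size_scaled_cost")
#' @export
dyad_game <- function(s1, s2, relatedness = 0, formulation = "size_independent") {
  formulation <- match_formulation(formulation)
  stopifnot(is.numeric(s1), length(s1) == 1L, is.finite(s1),
            is.numeric(s2), length(s2) == 1L, is.finite(s2),
            is.numeric(relatedness), length(relatedness) == 1L,
            is.finite(relatedness))
  if (s1 <= 0 || s2 <= 0)
    stop("contestant sizes must be strictly positive", call. = FALSE)
  if (relatedness < 0 || relatedness > 1)
    stop("relatedness must lie in [0, 1]", call. = FALSE)
  structure(
    list(s1 = s1, s2 = s2, relatedness = relatedness,
         formulation = formulation),
    class = "dyad_game"
  )
}

#' @export
print.dyad_game <- function(x, ...) {
  cat(sprintf("<dyad_game> s1 = %g, s2 = %g, r = %g, formulation = %s\n",
              x$s1, x$s2, x$relatedness, x$formulation))
  invisible(x)
}

#' Competitive strength
#'
#' Competitive strength is the product \eqn{\theta = s \cdot a}: a given
#' increment in aggressiveness raises a large contestant's strength more than
#' a small one's.
#'
#' @param s Strictly positive relative size (vectorised).
#' @param a Non-negative aggressiveness (vectorised).
#' @return \eqn{s \cdot a}; zero exactly when `a = 0`.
#' @examples
#' competitive_strength(0.1, 0.5)  # 0.05
#' @export
competitive_strength <- function(s, a) {
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size must be strictly positive and finite", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0))
    stop("aggressiveness must be non-negative and finite", call. = FALSE)
  s * a
}

#' Probability that contestant 1 wins
#'
#' Contestant 1 wins with probability equal to its relative competitive
#' strength, \eqn{\omega_1 = \theta_1 / (\theta_1 + \theta_2)}. When both
#' strengths are zero (both contestants fully passive) the contest is resolved
#' by relative size alone: \eqn{\omega_1 = s_1 / (s_1 + s_2)}, the limit of
#' \eqn{\omega_1} along any path with \eqn{a_1 = a_2 \to 0^+}.
#'
#' @param theta1,theta2 Non-negative competitive strengths (vectorised).
#' @param s1,s2 Sizes, used only for the both-zero convention.
#' @return \eqn{\omega_1 \in [0, 1]}; `win_probability(theta2, theta1, s2, s1)`
#'   is its complement.
#' @export
win_probability <- function(theta1, theta2, s1, s2) {
  if (any(theta1 < 0) || any(theta2 < 0))
    stop("competitive strengths must be non-negative", call. = FALSE)
  tot <- theta1 + theta2
  out <- ifelse(tot > 0, theta1 / ifelse(tot > 0, tot, 1), s1 / (s1 + s2))
  out
}

#' Admissible upper bound on aggressiveness
#'
#' The largest aggressiveness for which the winner's direct fitness is still
#' non-negative: 1 under `size_independent`, \eqn{\sqrt{s}} under
#' `size_proportional`, and \eqn{s} under `size_scaled_cost`. Direct fitness
#' is exactly zero at the bound.
#'
#' @inheritParams competitive_strength
#' @param formulation One of [fitness_formulations()].
#' @export
max_aggressiveness <- function(s, formulation) {
  formulation <- match_formulation(formulation)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size must be strictly positive and finite", call. = FALSE)
  switch(formulation,
         size_independent  = rep_len(1, length(s)),
         size_proportional = sqrt(s),
         size_scaled_cost  = s)
}

#' Winner's direct fitness
#'
#' Evaluates the selected direct-fitness formulation (see
#' [fitness_formulations()]). Aggressiveness beyond [max_aggressiveness()]
#' would make fitness negative and is rejected rather than clamped: a negative
#' reproductive success for a surviving contestant has no meaning in the model
#' and would distort optimisation.
#'
#' @inheritParams max_aggressiveness
#' @param a Non-negative aggressiveness, at most `max_aggressiveness(s, formulation)`.
#' @return Direct fitness \eqn{\upsilon \ge 0}, strictly decreasing in `a`.
#' @examples
#' direct_fitness(0.4, 0.2, "size_proportional")  # 0.36
#' @export
direct_fitness <- function(s, a, formulation) {
  formulation <- match_formulation(formulation)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size must be strictly positive and finite", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0))
    stop("aggressiveness must be non-negative and finite", call. = FALSE)
  amax <- max_aggressiveness(s, formulation)
  # small numeric slack so boundary candidates produced by optimisers pass
  if (any(a > amax * (1 + 1e-12) + 1e-15))
    stop("aggressiveness exceeds the zero-fitness bound for this size/formulation",
         call. = FALSE)
  v <- switch(formulation,
              size_independent  = 1 - a^2,
              size_proportional = s - a^2,
              size_scaled_cost  = 1 - (a / s)^2)
  pmax(v, 0)
}

#' Expected inclusive fitness of one contestant
#'
#' The focal contestant's probability-weighted inclusive fitness,
#' \eqn{F_{focal} = \omega_{focal} (\upsilon_{focal} - r\,\upsilon_{other})}.
#' The loser's inclusive fitness is zero (it neither reproduces nor affects
#' the winner's reproduction), so the expectation is the win probability times
#' the winner's payoff.
#'
#' @param game A [dyad_game()].
#' @param a1,a2 Aggressiveness of contestants 1 and 2, each admissible for its
#'   own size under the game's formulation. Vectorised over `a1`/`a2`.
#' @param focal Which contestant's expected fitness to return (1 or 2).
#' @return \eqn{F_{focal}}; exactly 0 when the focal's aggressiveness is 0 and
#'   the opponent's is positive, and equal to
#'   \eqn{\omega_{focal}\,\upsilon_{focal}} when `relatedness = 0`.
#' @examples
#' g <- dyad_game(0.1, 0.1, relatedness = 0, formulation = "size_independent")
#' expected_inclusive_fitness(g, 0.5, 0.5)  # 0.5 * (1 - 0.25) = 0.375
#' @export
expected_inclusive_fitness <- function(game, a1, a2, focal = 1L) {
  stopifnot(inherits(game, "dyad_game"), focal %in% c(1L, 2L))
  th1 <- competitive_strength(game$s1, a1)
  th2 <- competitive_strength(game$s2, a2)
  v1 <- direct_fitness(game$s1, a1, game$formulation)
  v2 <- direct_fitness(game$s2, a2, game$formulation)
  if (focal == 1L) {
    w <- win_probability(th1, th2, game$s1, game$s2)
    w * (v1 - game$relatedness * v2)
  } else {
    w <- win_probability(th2, th1, game$s2, game$s1)
    w * (v2 - game$relatedness * v1)
  }
}
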