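# Straight-line re-implementations of the contest-game equations, kept
# deliberately independent of the package's code paths so they can serve as
# oracles: plain arithmetic, grid search only, no refinement, no shared
# helpers.

bf_direct_fitness <- function(s, a, form) {
  if (form == "size_independent") 1 - a^2
  else if (form == "size_proportional") s - a^2
  else 1 - (a / s)^2
}

bf_amax <- function(s, form) {
  if (form == "size_independent") 1
  else if (form == "size_proportional") sqrt(s)
  else s
}

bf_expected_fitness <- function(s1, s2, r, form, a1, a2) {
  th1 <- s1 * a1
  th2 <- s2 * a2
  w1 <- ifelse(th1 + th2 > 0, th1 / (th1 + th2), s1 / (s1 + s2))
  w1 * (bf_direct_fitness(s1, a1, form) - r * bf_direct_fitness(s2, a2, form))
}

# brute-force best response of contestant 1 on an n-point grid
bf_best_response <- function(s1, s2, r, form, a2, n = 1e5) {
  grid <- seq(0, bf_amax(s1, form), length.out = n)
  f <- bf_expected_fitness(s1, s2, r, form, grid, a2)
  grid[which.max(f)]
}

default_params_zero_effects <- function() {
  generating_params(
    activity_acclimation = c(intercept = 0.72),
    activity_experimental = c(intercept = -5.3),
    aggression = c(intercept = -8.03),
    latency = c(half_siblings = 0))
}
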