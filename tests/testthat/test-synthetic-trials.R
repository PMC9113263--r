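test_that("design and parameter validation reject infeasible settings", {
  expect_error(trial_design(mass_range = c(0.38, 0.04)), "increasing")
  expect_error(trial_design(mass_range = c(0.1, 0.2),
                            mass_diff_range = c(0.15, 0.3)), "infeasible")
  expect_error(generating_params(aggression = c(interecpt = -8)), "interecpt")
  expect_error(generating_params(re_variances = c(pair = 1)), "pair")
  expect_error(generating_params(dispersion = c(-1, 2)))
})

test_that("dyad sampling honours the design counts, mass constraints and pedigree", {
  d <- sample_dyads(trial_design(), seed = 101)
  expect_equal(nrow(d), 45)
  expect_true(all(table(d$relatedness_level) == 15))
  expect_true(all(d$mass_diff >= 0.03 & d$mass_diff <= 0.30))
  expect_true(all(d$mass_large > d$mass_small))
  expect_true(all(d$mass_large <= 0.38 & d$mass_small >= 0.04))
  sib <- d[d$relatedness_level == "sibling", ]
  half <- d[d$relatedness_level == "half_sibling", ]
  non <- d[d$relatedness_level == "non_sibling", ]
  expect_true(all(sib$family_large == sib$family_small))
  expect_true(all(half$sire_large == half$sire_small))
  expect_true(all(half$family_large != half$family_small))
  expect_true(all(non$sire_large != non$sire_small))
  expect_identical(unname(relatedness_r <- d$r[match(c("non_sibling",
    "half_sibling", "sibling"), d$relatedness_level)]), c(0, 0.25, 0.5))
})

test_that("identical seeds give identical datasets; different seeds differ", {
  t1 <- generate_trials(seed = 202)
  t2 <- generate_trials(seed = 202)
  t3 <- generate_trials(seed = 203)
  expect_identical(t1$tadpoles, t2$tadpoles)
  expect_identical(t1$latency, t2$latency)
  expect_false(identical(t1$tadpoles$activity_count,
                         t3$tadpoles$activity_count))
})

test_that("aggression counts match their closed-form Poisson means", {
  # one huge dyad table -> tight Monte-Carlo error on the marginal mean;
  # the scan interval is shortened so the scan-budget cap cannot bind
  d <- sample_dyads(trial_design(n_per_level = 4000), seed = 1)
  p0 <- generating_params(aggression = c(intercept = 0),
                          re_variances = c(aggression_pair = 0))
  agg <- generate_aggression(d, p0, seed = 2, duration_s = 3600,
                             scan_interval = 0.4)
  expect_lt(abs(mean(agg$count) - 3600) / 3600, 0.02)
  expect_false(any(agg$capped))

  p1 <- generating_params(aggression = c(intercept = -8.03),
                          re_variances = c(aggression_pair = 0))
  agg <- generate_aggression(d, p1, seed = 3)
  expect_lt(abs(mean(agg$count) - 3600 * exp(-8.03)) / (3600 * exp(-8.03)),
            0.03)
  agg0 <- generate_aggression(d[1:50, ], p1, seed = 4, duration_s = 0)
  expect_true(all(agg0$count == 0))
})

test_that("activity counts reproduce the generating rate ratio and Poisson limit", {
  d <- sample_dyads(trial_design(n_per_level = 4000), seed = 5)
  # large/small mean ratio at the generating size effect
  p <- generating_params(
    activity_experimental = c(intercept = log(10 / 3600),
                              size_large = log(3.46)),
    re_variances = c(activity_pair_experimental = 0,
                     activity_family_experimental = 0))
  act <- generate_activity(d, p, seed = 6, phase = "experimental")
  ratio <- mean(act$count[act$relative_size == "large"]) /
    mean(act$count[act$relative_size == "small"])
  expect_lt(abs(ratio - 3.46) / 3.46, 0.05)

  # dispersion -> infinity approaches the Poisson variance/mean of 1
  p_pois <- generating_params(
    activity_experimental = c(intercept = log(20 / 3600)),
    dispersion = c(acclimation = 1e8, experimental = 1e8),
    re_variances = c(activity_pair_experimental = 0,
                     activity_family_experimental = 0))
  act <- generate_activity(d[1:5000, ], p_pois, seed = 7)
  expect_lt(abs(var(act$count) / mean(act$count) - 1), 0.05)

  # no effects in either arm -> equal means across relatedness levels
  p_null <- generating_params(
    activity_experimental = c(intercept = log(20 / 3600)),
    re_variances = c(activity_pair_experimental = 0,
                     activity_family_experimental = 0))
  act <- generate_activity(d, p_null, seed = 8)
  means <- tapply(act$count,
                  d$relatedness_level[match(act$pair_id, d$pair_id)], mean)
  expect_lt(max(means) / min(means), 1.05)
})

test_that("no generated count exceeds the scan budget of its phase", {
  tr <- generate_trials(trial_design(n_per_level = 60), seed = 9)
  expect_true(all(tr$tadpoles$activity_count <= tr$tadpoles$n_scans))
  exp_rows <- tr$tadpoles$phase == "experimental"
  expect_true(all(tr$tadpoles$aggression_count[exp_rows] <=
                    tr$tadpoles$n_scans[exp_rows]))
  expect_true(all(is.na(tr$tadpoles$aggression_count[!exp_rows])))
})

test_that("latency times follow the exponential hazard and censoring rules", {
  d <- sample_dyads(trial_design(n_per_level = 4000), seed = 10)
  lam <- 1 / 500
  p <- generating_params(latency = c(half_siblings = 0),
                         baseline_hazard = lam,
                         re_variances = c(latency_family = 0))
  lat <- generate_latency(d, p, seed = 11, duration_s = 1e9)
  expect_lt(abs(mean(lat$time_s) - 1 / lam) / (1 / lam), 0.03)
  expect_true(all(lat$event))

  p0 <- generating_params(latency = c(half_siblings = 0), baseline_hazard = 0)
  lat0 <- generate_latency(d[1:100, ], p0, seed = 12)
  expect_true(all(!lat0$event))
  expect_true(all(lat0$time_s == 3600))
  expect_true(all(lat0$first_biter == "none"))

  # proportional-hazards structure: empirical rate ratio between sibling
  # dyads at mass_diff 0.30 vs 0.03 equals the generating hazard ratio
  p_int <- generating_params(latency = c("siblings:mass_diff" = 16.32),
                             baseline_hazard = 1e-4,
                             re_variances = c(latency_family = 0))
  dd <- d[d$relatedness_level == "sibling", ]
  dd_hi <- dd; dd_hi$mass_diff <- 0.30
  dd_lo <- dd; dd_lo$mass_diff <- 0.03
  t_hi <- generate_latency(dd_hi, p_int, seed = 13, duration_s = 1e12)
  t_lo <- generate_latency(dd_lo, p_int, seed = 14, duration_s = 1e12)
  hr <- mean(t_lo$time_s) / mean(t_hi$time_s)
  expect_lt(abs(log(hr) - 16.32 * 0.27), 0.05 * 16.32 * 0.27)
})

test_that("censoring fraction is monotone decreasing in the baseline hazard", {
  d <- sample_dyads(trial_design(n_per_level = 1500), seed = 15)
  cens <- vapply(c(1e-5, 1e-4, 1e-3), function(lam) {
    p <- generating_params(baseline_hazard = lam)
    mean(!generate_latency(d, p, seed = 16)$event)
  }, numeric(1))
  expect_true(all(diff(cens) < 0))
})

test_that("the calibrated baseline hazard hits the target event fraction", {
  lam <- calibrate_baseline_hazard(target_event_frac = 38 / 45, seed = 17)
  p <- generating_params(baseline_hazard = lam)
  d <- sample_dyads(trial_design(n_per_level = 3000), seed = 18)
  re <- draw_random_effects(d, seed = 19)
  lat <- generate_latency(d, p, re, seed = 20)
  expect_lt(abs(mean(lat$event) - 38 / 45), 0.02)
})

test_that("first-biter identity follows the per-level probabilities", {
  d <- sample_dyads(trial_design(n_per_level = 4000), seed = 21)
  p <- generating_params(baseline_hazard = 1e-2,
                         p_large_first = c(non_sibling = 11 / 12,
                                           half_sibling = 10 / 13,
                                           sibling = 8 / 13))
  lat <- generate_latency(d, p, seed = 22)
  lat <- lat[lat$event, ]
  frac <- tapply(lat$first_biter == "large", lat$relatedness_level, mean)
  expect_equal(as.numeric(frac[c("non_sibling", "half_sibling", "sibling")]),
               c(11 / 12, 10 / 13, 8 / 13), tolerance = 0.03)
})

test_that("trial tables have the documented shape and round-trip through CSV", {
  tr <- generate_trials(seed = 23)
  expect_equal(nrow(tr$latency), 45)
  expect_equal(nrow(tr$tadpoles), 180)  # 2 tadpoles x 2 phases x 45 dyads
  stem <- tempfile()
  write_trials(tr, stem)
  back <- read_trials(stem)
  expect_equal(back$tadpoles$activity_count, tr$tadpoles$activity_count)
  expect_equal(back$latency$time_s, tr$latency$time_s)
  expect_identical(as.character(back$tadpoles$relatedness_level),
                   as.character(tr$tadpoles$relatedness_level))
  empty <- tr
  empty$tadpoles <- tr$tadpoles[0, ]
  expect_error(write_trials(empty, tempfile()), "empty")
})

test_that("early termination truncates durations and exposures when enabled", {
  p <- generating_params(early_termination_prob = 3 / 45)
  tr <- generate_trials(trial_design(n_per_level = 200), p, seed = 24)
  short <- tr$tadpoles$duration_s < 3600 & tr$tadpoles$phase == "experimental"
  expect_gt(sum(short), 0)
  expect_true(all(tr$tadpoles$n_scans[short] ==
                    floor(tr$tadpoles$duration_s[short] / 15)))
  expect_true(all(tr$latency$time_s <= tr$latency$duration_s))
})
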