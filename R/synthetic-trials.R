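relatedness_levels <- function() c("non_sibling", "half_sibling", "sibling")

relatedness_r <- function(level) {
  c(non_sibling = 0, half_sibling = 0.25, sibling = 0.5)[level]
}

fixed_effect_terms <- function() {
  c("intercept", "half_siblings", "siblings", "size_large",
    "half_siblings:size_large", "siblings:size_large")
}

latency_terms <- function() {
  c("half_siblings", "siblings", "mass_diff",
    "half_siblings:mass_diff", "siblings:mass_diff")
}

named_coefs <- function(x, terms, what) {
  if (is.null(names(x))) {
    if (length(x) != length(terms))
      stop(sprintf("%s must have %d values (%s)", what, length(terms),
                   paste(terms, collapse = ", ")), call. = FALSE)
    names(x) <- terms
    return(x)
  }
  bad <- setdiff(names(x), terms)
  if (length(bad))
    stop(sprintf("unknown %s coefficient(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  out <- stats::setNames(numeric(length(terms)), terms)
  out[names(x)] <- x
  out
}

#' Dyadic trial design
#'
#' Design constants of the behavioral experiment the generator emulates:
#' dyads of visually size-mismatched tadpoles, one dyad per trial, scan
#' sampling of behavior every 15 s through a 10-min post-acclimation phase
#' (contestants separated by an opaque barrier) and a 60-min experimental
#' phase (barrier removed).
#'
#' @param n_per_level Dyads per relatedness level (non-sibling, paternal
#'   half-sibling, full sibling).
#' @param scan_interval Seconds between behavioral scans.
#' @param experimental_duration Experimental-phase length in seconds.
#' @param acclimation_scans Number of scans per tadpole in the
#'   post-acclimation phase (40 = 10 min at 15-s scans).
#' @param mass_range Admissible tadpole masses in grams.
#' @param mass_diff_range Admissible within-dyad mass differences in grams
#'   (the larger tadpole is always the heavier one).
#' @param n_sires,n_dams Size of the breeding pool from which families
#'   (breeding pairs) are drawn; families recur across dyads, giving the
#'   family random effect replication.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_level = 15L, scan_interval = 15,
                         experimental_duration = 3600,
                         acclimation_scans = 40L,
                         mass_range = c(0.04, 0.38),
                         mass_diff_range = c(0.03, 0.30),
                         n_sires = 8L, n_dams = 12L) {
  stopifnot(n_per_level >= 1, scan_interval > 0, experimental_duration > 0,
            acclimation_scans >= 1, length(mass_range) == 2L,
            length(mass_diff_range) == 2L, n_sires >= 2, n_dams >= 2)
  if (mass_range[1] <= 0 || diff(mass_range) <= 0)
    stop("mass_range must be positive and increasing", call. = FALSE)
  if (mass_diff_range[1] < 0 || diff(mass_diff_range) < 0 ||
      mass_diff_range[1] > diff(mass_range))
    stop("mass_diff_range is infeasible under mass_range", call. = FALSE)
  structure(list(n_per_level = as.integer(n_per_level),
                 scan_interval = scan_interval,
                 experimental_duration = experimental_duration,
                 acclimation_scans = as.integer(acclimation_scans),
                 mass_range = mass_range,
                 mass_diff_range = mass_diff_range,
                 n_sires = as.integer(n_sires), n_dams = as.integer(n_dams)),
            class = "trial_design")
}

#' Generating parameters for the three trial models
#'
#' Coefficient sets, random-effect variances and auxiliary rates for the
#' generative statistical models behind [generate_trials()]: a negative
#' binomial activity model per phase, a Poisson aggression model, and an
#' exponential proportional-hazards model for first-bite latency. All count
#' coefficients are on the log (link) scale with the non-sibling / small
#' reference; terms are `intercept, half_siblings, siblings, size_large,
#' half_siblings:size_large, siblings:size_large` (latency drops the
#' intercept and replaces the size factor with the continuous `mass_diff`
#' in grams).
#'
#' Defaults are the fitted coefficient sets of the corresponding published
#' models: aggression on the log scale; experimental activity converted from
#' the rate-ratio scale on which it is reported (its baseline log-intercept,
#' unrecoverable from the rounded report, is set to -5.3, i.e. about 18
#' active scans per hour for a small non-sibling); acclimation activity keeps
#' only its intercept, matching the null results of that phase. Exposure
#' offsets are log seconds for the experimental phase and log minutes for the
#' acclimation phase. Negative-binomial size parameters are mapped from the
#' reported residual variances \eqn{\sigma^2} via \eqn{k = 1/(e^{\sigma^2}-1)}
#' (lognormal tail matching — a documented approximation).
#'
#' @param activity_acclimation,activity_experimental,aggression Named (or
#'   positional) coefficient vectors over the six fixed-effect terms.
#' @param latency Named coefficient vector over the five latency terms (log
#'   hazard ratios; mass-difference terms per gram).
#' @param dispersion Negative-binomial size parameters `k` (acclimation,
#'   experimental); larger is closer to Poisson.
#' @param re_variances Random-intercept variances: activity pair/family per
#'   phase, aggression pair/family, latency family.
#' @param baseline_hazard Exponential baseline hazard of the first bite, per
#'   second, for a non-sibling dyad at mass difference 0. The default is
#'   calibrated (see [calibrate_baseline_hazard()]) so that about 38/45 of
#'   default-design dyads experience a first bite within the hour, the
#'   observed event fraction.
#' @param p_large_first Probability that the larger tadpole is the first
#'   biter given an event: a single pooled value (default 29/38, the pooled
#'   observed fraction) or one value per relatedness level.
#' @param early_termination_prob Per-trial probability that the trial is
#'   stopped early (a potential lethal attack); when it fires, the trial
#'   duration is drawn uniformly over the experimental phase and all
#'   exposures shorten accordingly. Off (0) by default.
#' @return An object of class `generating_params`.
#' @export
generating_params <- function(
    activity_acclimation = c(intercept = 0.72),
    activity_experimental = c(intercept = -5.3,
                              half_siblings = log(1.25),
                              siblings = log(1.52),
                              size_large = log(3.46),
                              "half_siblings:size_large" = log(0.81),
                              "siblings:size_large" = log(0.51)),
    aggression = c(intercept = -8.03, half_siblings = 0.42, siblings = 0.54,
                   size_large = 1.42, "half_siblings:size_large" = -0.40,
                   "siblings:size_large" = -1.12),
    latency = c(half_siblings = -1.27, siblings = -1.44, mass_diff = 0.89,
                "half_siblings:mass_diff" = 9.62,
                "siblings:mass_diff" = 16.32),
    dispersion = c(acclimation = 1 / expm1(1.68),
                   experimental = 1 / expm1(0.43)),
    re_variances = c(activity_pair_acclimation = 0.19,
                     activity_family_acclimation = 0.001,
                     activity_pair_experimental = 0.001,
                     activity_family_experimental = 0.01,
                     aggression_pair = 1.04,
                     aggression_family = 0.13,
                     latency_family = 0.25),
    baseline_hazard = 5.31e-4,
    p_large_first = 29 / 38,
    early_termination_prob = 0) {
  re_terms <- c("activity_pair_acclimation", "activity_family_acclimation",
                "activity_pair_experimental", "activity_family_experimental",
                "aggression_pair", "aggression_family", "latency_family")
  re <- stats::setNames(numeric(length(re_terms)), re_terms)
  if (!is.null(names(re_variances))) {
    bad <- setdiff(names(re_variances), re_terms)
    if (length(bad))
      stop("unknown random-effect variance(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    re[names(re_variances)] <- re_variances
  } else re[] <- re_variances
  disp <- named_coefs(dispersion, c("acclimation", "experimental"),
                      "dispersion")
  stopifnot(all(disp > 0), all(re >= 0), baseline_hazard >= 0,
            early_termination_prob >= 0, early_termination_prob <= 1)
  if (length(p_large_first) == 1L)
    p_large_first <- stats::setNames(rep(p_large_first, 3),
                                     relatedness_levels())
  p_large_first <- named_coefs(p_large_first, relatedness_levels(),
                               "p_large_first")
  stopifnot(all(p_large_first >= 0), all(p_large_first <= 1))
  structure(list(
    activity_acclimation = named_coefs(activity_acclimation,
                                       fixed_effect_terms(),
                                       "acclimation activity"),
    activity_experimental = named_coefs(activity_experimental,
                                        fixed_effect_terms(),
                                        "experimental activity"),
    aggression = named_coefs(aggression, fixed_effect_terms(), "aggression"),
    latency = named_coefs(latency, latency_terms(), "latency"),
    dispersion = disp, re_variances = re,
    baseline_hazard = baseline_hazard, p_large_first = p_large_first,
    early_termination_prob = early_termination_prob),
    class = "generating_params")
}

#' Sample synthetic dyads
#'
#' Draws `n_per_level` dyads per relatedness level. Each tadpole's mass is
#' uniform over the design's mass range, with the pair rejected and redrawn
#' until the within-dyad difference falls in the admissible difference range;
#' the heavier tadpole is labelled large. Families (breeding pairs) are drawn
#' from a finite sire x dam pool: full siblings share the breeding pair,
#' paternal half siblings share only the sire, non-siblings share neither
#' parent.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed; identical seeds give identical dyads.
#' @return A data frame with one row per dyad: `pair_id, relatedness_level,
#'   r, mass_large, mass_small, mass_diff, family_large, family_small,
#'   sire_large, sire_small`.
#' @export
sample_dyads <- function(design = trial_design(), seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(as.integer(seed))
  levels_ <- relatedness_levels()
  n <- design$n_per_level * length(levels_)
  lev <- rep(levels_, each = design$n_per_level)

  # rejection sampling, vectorised: redraw pairs until the difference fits
  m1 <- stats::runif(n, design$mass_range[1], design$mass_range[2])
  m2 <- stats::runif(n, design$mass_range[1], design$mass_range[2])
  repeat {
    d <- abs(m1 - m2)
    bad <- d < design$mass_diff_range[1] | d > design$mass_diff_range[2]
    if (!any(bad)) break
    m1[bad] <- stats::runif(sum(bad), design$mass_range[1],
                            design$mass_range[2])
    m2[bad] <- stats::runif(sum(bad), design$mass_range[1],
                            design$mass_range[2])
  }
  masses <- cbind(pmax(m1, m2), pmin(m1, m2))

  fam <- function(s, d) sprintf("S%02dxD%02d", s, d)
  shift <- function(i, k, m) ((i - 1L + k) %% m) + 1L  # a different index mod m
  sire_large <- sample.int(design$n_sires, n, replace = TRUE)
  sire_small <- sire_large
  dam_large <- sample.int(design$n_dams, n, replace = TRUE)
  dam_small <- dam_large
  is_half <- lev == "half_sibling"
  is_non <- lev == "non_sibling"
  dam_small[is_half] <- shift(dam_large[is_half],
                              sample.int(design$n_dams - 1L, sum(is_half),
                                         replace = TRUE), design$n_dams)
  sire_small[is_non] <- shift(sire_large[is_non],
                              sample.int(design$n_sires - 1L, sum(is_non),
                                         replace = TRUE), design$n_sires)
  dam_small[is_non] <- sample.int(design$n_dams, sum(is_non), replace = TRUE)
  family_large <- fam(sire_large, dam_large)
  family_small <- fam(sire_small, dam_small)
  sire_large <- sprintf("S%02d", sire_large)
  sire_small <- sprintf("S%02d", sire_small)
  data.frame(
    pair_id = sprintf("P%03d", seq_len(n)),
    relatedness_level = factor(lev, levels = levels_),
    r = unname(relatedness_r(lev)),
    mass_large = masses[, 1], mass_small = masses[, 2],
    mass_diff = masses[, 1] - masses[, 2],
    family_large = family_large, family_small = family_small,
    sire_large = sire_large, sire_small = sire_small,
    stringsAsFactors = FALSE)
}

# model matrix row for one tadpole: (1, half, sib, large, half:large, sib:large)
count_linear_predictor <- function(coefs, level, is_large) {
  half <- as.numeric(level == "half_sibling")
  sib <- as.numeric(level == "sibling")
  lg <- as.numeric(is_large)
  coefs[["intercept"]] + coefs[["half_siblings"]] * half +
    coefs[["siblings"]] * sib + coefs[["size_large"]] * lg +
    coefs[["half_siblings:size_large"]] * half * lg +
    coefs[["siblings:size_large"]] * sib * lg
}

latency_linear_predictor <- function(coefs, level, mass_diff) {
  half <- as.numeric(level == "half_sibling")
  sib <- as.numeric(level == "sibling")
  coefs[["half_siblings"]] * half + coefs[["siblings"]] * sib +
    coefs[["mass_diff"]] * mass_diff +
    coefs[["half_siblings:mass_diff"]] * half * mass_diff +
    coefs[["siblings:mass_diff"]] * sib * mass_diff
}

#' Draw shared random effects for a dyad table
#'
#' One standard-normal draw per pair and per family for each model family
#' (activity, aggression, latency); generators scale these by the applicable
#' standard deviation, so the activity phases (and the two tadpoles of a
#' pair) share draws as the fitted models assume.
#'
#' @param dyads A dyad table from [sample_dyads()].
#' @param seed Integer seed.
#' @return A list of named standard-normal vectors: `pair_activity`,
#'   `pair_aggression` (by pair id), `family_activity`, `family_aggression`,
#'   `family_latency` (by family id).
#' @export
draw_random_effects <- function(dyads, seed = 1L) {
  set.seed(as.integer(seed))
  fams <- sort(unique(c(dyads$family_large, dyads$family_small)))
  draw <- function(ids) stats::setNames(stats::rnorm(length(ids)), ids)
  list(pair_activity = draw(dyads$pair_id),
       pair_aggression = draw(dyads$pair_id),
       family_activity = draw(fams),
       family_aggression = draw(fams),
       family_latency = draw(fams))
}

# shared machinery for the two count generators; returns long per-tadpole rows
generate_counts <- function(dyads, coefs, re_pair, re_fam, sd_pair, sd_fam,
                            exposure, n_scans, nb_size = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(dyads)
  rows <- vector("list", 2L)
  for (side in 1:2) {
    is_large <- side == 1L
    fam <- if (is_large) dyads$family_large else dyads$family_small
    lp <- count_linear_predictor(coefs, as.character(dyads$relatedness_level),
                                 is_large) +
      sd_pair * re_pair[dyads$pair_id] + sd_fam * re_fam[fam]
    mu <- exp(lp) * exposure
    raw <- if (is.null(nb_size)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = nb_size, mu = mu)
    }
    rows[[side]] <- data.frame(
      pair_id = dyads$pair_id,
      relative_size = if (is_large) "large" else "small",
      family = fam, count = pmin(raw, n_scans),
      capped = raw > n_scans, stringsAsFactors = FALSE)
  }
  out <- rbind(rows[[1]], rows[[2]])
  out[order(out$pair_id, out$relative_size), , drop = FALSE]
}

#' Generate aggression counts
#'
#' Per-tadpole total aggression (bites + chases) drawn Poisson with log rate
#' = linear predictor (relatedness x relative size, plus pair and family
#' random intercepts) + log exposure, where exposure is the trial duration in
#' seconds. Counts cannot exceed the number of scans in the phase; draws
#' beyond the scan budget are capped and flagged.
#'
#' @param dyads A dyad table from [sample_dyads()].
#' @param params A [generating_params()].
#' @param re_draws Standard-normal random-effect draws from
#'   [draw_random_effects()] (or `NULL` for none).
#' @param seed Integer seed.
#' @param duration_s Trial duration(s) in seconds (scalar or per dyad).
#' @param scan_interval Seconds per scan (sets the count cap).
#' @return A data frame with one row per tadpole: `pair_id, relative_size,
#'   family, count, capped`.
#' @export
generate_aggression <- function(dyads, params, re_draws = NULL, seed = 1L,
                                duration_s = 3600, scan_interval = 15) {
  stopifnot(inherits(params, "generating_params"))
  if (is.null(re_draws))
    re_draws <- list(pair_aggression = stats::setNames(
      numeric(nrow(dyads)), dyads$pair_id),
      family_aggression = stats::setNames(
        numeric(length(unique(c(dyads$family_large, dyads$family_small)))),
        unique(c(dyads$family_large, dyads$family_small))))
  generate_counts(
    dyads, params$aggression,
    re_pair = re_draws$pair_aggression, re_fam = re_draws$family_aggression,
    sd_pair = sqrt(params$re_variances[["aggression_pair"]]),
    sd_fam = sqrt(params$re_variances[["aggression_family"]]),
    exposure = duration_s, n_scans = floor(duration_s / scan_interval),
    nb_size = NULL, seed = seed)
}

#' Generate activity counts
#'
#' Per-tadpole activity (swimming) scan counts drawn negative binomial with a
#' log-link linear predictor as in [generate_aggression()]. The phases use
#' their own coefficient sets, dispersions and random-effect variances:
#' exposure is log seconds in the experimental phase and log minutes in the
#' acclimation phase, whose default coefficient set carries no size or
#' relatedness effects.
#'
#' @inheritParams generate_aggression
#' @param phase `"acclimation"` or `"experimental"`.
#' @param design A [trial_design()] supplying scan counts and durations.
#' @return As [generate_aggression()].
#' @export
generate_activity <- function(dyads, params, re_draws = NULL, seed = 1L,
                              phase = c("experimental", "acclimation"),
                              design = trial_design(), duration_s = NULL) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "generating_params"))
  if (is.null(re_draws))
    re_draws <- list(pair_activity = stats::setNames(
      numeric(nrow(dyads)), dyads$pair_id),
      family_activity = stats::setNames(
        numeric(length(unique(c(dyads$family_large, dyads$family_small)))),
        unique(c(dyads$family_large, dyads$family_small))))
  if (phase == "experimental") {
    dur <- if (is.null(duration_s)) design$experimental_duration else duration_s
    exposure <- dur
    n_scans <- floor(dur / design$scan_interval)
    coefs <- params$activity_experimental
    sd_pair <- sqrt(params$re_variances[["activity_pair_experimental"]])
    sd_fam <- sqrt(params$re_variances[["activity_family_experimental"]])
    k <- params$dispersion[["experimental"]]
  } else {
    exposure <- design$acclimation_scans * design$scan_interval / 60  # minutes
    n_scans <- design$acclimation_scans
    coefs <- params$activity_acclimation
    sd_pair <- sqrt(params$re_variances[["activity_pair_acclimation"]])
    sd_fam <- sqrt(params$re_variances[["activity_family_acclimation"]])
    k <- params$dispersion[["acclimation"]]
  }
  generate_counts(dyads, coefs, re_pair = re_draws$pair_activity,
                  re_fam = re_draws$family_activity,
                  sd_pair = sd_pair, sd_fam = sd_fam,
                  exposure = exposure, n_scans = n_scans,
                  nb_size = k, seed = seed)
}

#' Generate censored first-bite latencies
#'
#' Event times are exponential with hazard `baseline_hazard *
#' exp(relatedness + mass_diff + interactions + family random effect)`, the
#' proportional-hazards structure of the latency analysis; the family effect
#' is the large tadpole's. Times beyond the trial duration are censored at
#' it. When an event occurs the first biter is the large tadpole with
#' probability `p_large_first` for the dyad's relatedness level,
#' independently of the time.
#'
#' @inheritParams generate_aggression
#' @return A data frame with one row per dyad: `pair_id, relatedness_level,
#'   mass_diff, family, time_s, event, first_biter`.
#' @export
generate_latency <- function(dyads, params, re_draws = NULL, seed = 1L,
                             duration_s = 3600) {
  stopifnot(inherits(params, "generating_params"))
  set.seed(as.integer(seed))
  n <- nrow(dyads)
  zf <- if (is.null(re_draws)) {
    stats::setNames(numeric(n), dyads$family_large)
  } else re_draws$family_latency
  sd_f <- sqrt(params$re_variances[["latency_family"]])
  lp <- latency_linear_predictor(params$latency,
                                 as.character(dyads$relatedness_level),
                                 dyads$mass_diff) +
    sd_f * zf[dyads$family_large]
  hazard <- params$baseline_hazard * exp(lp)
  t_event <- ifelse(hazard > 0, stats::rexp(n) / pmax(hazard, 1e-300), Inf)
  dur <- rep_len(duration_s, n)
  event <- t_event <= dur
  time_s <- pmin(t_event, dur)
  p_lg <- params$p_large_first[as.character(dyads$relatedness_level)]
  large_first <- stats::runif(n) < p_lg
  first_biter <- ifelse(event, ifelse(large_first, "large", "small"), "none")
  data.frame(pair_id = dyads$pair_id,
             relatedness_level = dyads$relatedness_level,
             mass_diff = dyads$mass_diff, family = dyads$family_large,
             time_s = time_s, event = event, first_biter = first_biter,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic trial dataset
#'
#' Samples dyads and generates both phases' activity counts, experimental
#' aggression counts and censored first-bite latencies under one master seed
#' (deterministically split per stage). Random-effect draws are shared
#' across phases and tadpoles as the fitted models assume.
#'
#' @param design A [trial_design()].
#' @param params A [generating_params()].
#' @param seed Master integer seed.
#' @return An object of class `trial_data`: a list with `dyads`, `tadpoles`
#'   (one row per tadpole x phase: activity count, aggression count on
#'   experimental rows, scan budget, duration), `latency`, and `cap_hits`
#'   (number of generated counts truncated at the scan budget).
#' @export
generate_trials <- function(design = trial_design(),
                            params = generating_params(), seed = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(params, "generating_params"))
  seeds <- split_seed(seed, 6L)
  dyads <- sample_dyads(design, seeds[1])
  re <- draw_random_effects(dyads, seeds[2])

  dur <- rep(design$experimental_duration, nrow(dyads))
  if (params$early_termination_prob > 0) {
    set.seed(seeds[6])
    hit <- stats::runif(nrow(dyads)) < params$early_termination_prob
    dur[hit] <- stats::runif(sum(hit), 0, design$experimental_duration)
  }

  acc <- generate_activity(dyads, params, re, seeds[3], phase = "acclimation",
                           design = design)
  exp_act <- generate_activity(dyads, params, re, seeds[4],
                               phase = "experimental", design = design,
                               duration_s = dur)
  agg <- generate_aggression(dyads, params, re, seeds[5],
                             duration_s = dur,
                             scan_interval = design$scan_interval)
  lat <- generate_latency(dyads, params, re, seeds[5] + 1L,
                          duration_s = dur)

  meta_cols <- c("pair_id", "relatedness_level", "r", "mass_diff")
  dyad_meta <- dyads[, meta_cols]
  dur_by_pair <- stats::setNames(dur, dyads$pair_id)

  mk_phase <- function(act, aggc, phase, n_scans, dur_s) {
    out <- merge(act, dyad_meta, by = "pair_id", sort = FALSE)
    out$phase <- phase
    out$duration_s <- dur_s[out$pair_id]
    out$n_scans <- n_scans[out$pair_id]
    names(out)[names(out) == "count"] <- "activity_count"
    names(out)[names(out) == "capped"] <- "activity_capped"
    if (is.null(aggc)) {
      out$aggression_count <- NA_integer_
      out$aggression_capped <- NA
    } else {
      key <- paste(aggc$pair_id, aggc$relative_size)
      idx <- match(paste(out$pair_id, out$relative_size), key)
      out$aggression_count <- aggc$count[idx]
      out$aggression_capped <- aggc$capped[idx]
    }
    out
  }
  acc_dur <- stats::setNames(rep(design$acclimation_scans *
                                   design$scan_interval, nrow(dyads)),
                             dyads$pair_id)
  acc_scans <- stats::setNames(rep(design$acclimation_scans, nrow(dyads)),
                               dyads$pair_id)
  exp_scans <- stats::setNames(floor(dur / design$scan_interval),
                               dyads$pair_id)
  tadpoles <- rbind(
    mk_phase(acc, NULL, "acclimation", acc_scans, acc_dur),
    mk_phase(exp_act, agg, "experimental", exp_scans, dur_by_pair))
  tadpoles <- tadpoles[order(tadpoles$pair_id, tadpoles$phase,
                             tadpoles$relative_size), ]
  rownames(tadpoles) <- NULL
  lat$duration_s <- dur_by_pair[lat$pair_id]

  cap_hits <- sum(tadpoles$activity_capped, na.rm = TRUE) +
    sum(tadpoles$aggression_capped, na.rm = TRUE)
  structure(list(dyads = dyads, tadpoles = tadpoles, latency = lat,
                 cap_hits = cap_hits, seed = as.integer(seed)),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "<trial_data> %d dyads (%s), %d tadpole-phase rows, %d latency rows\n",
    nrow(x$dyads),
    paste(table(x$dyads$relatedness_level), collapse = "/"),
    nrow(x$tadpoles), nrow(x$latency)))
  cat(sprintf("  events: %d/%d uncensored; cap hits: %d; seed %d\n",
              sum(x$latency$event), nrow(x$latency), x$cap_hits, x$seed))
  invisible(x)
}

#' Calibrate the baseline first-bite hazard
#'
#' Solves for the exponential baseline hazard at which a target fraction of
#' dyads experience an uncensored first bite under a given design and
#' coefficient set, by Monte-Carlo integration over the dyad distribution
#' (masses, relatedness mix, family effects) and root finding on the log
#' hazard.
#'
#' @param params A [generating_params()] (its `baseline_hazard` is ignored).
#' @param design A [trial_design()].
#' @param target_event_frac Desired uncensored fraction (default 38/45, the
#'   observed event fraction).
#' @param n_mc Number of Monte-Carlo dyads.
#' @param seed Integer seed for the integration sample.
#' @return The calibrated baseline hazard (per second).
#' @export
calibrate_baseline_hazard <- function(params = generating_params(),
                                      design = trial_design(),
                                      target_event_frac = 38 / 45,
                                      n_mc = 20000L, seed = 1L) {
  stopifnot(target_event_frac > 0, target_event_frac < 1)
  big <- trial_design(n_per_level = ceiling(n_mc / 3),
                      scan_interval = design$scan_interval,
                      experimental_duration = design$experimental_duration,
                      acclimation_scans = design$acclimation_scans,
                      mass_range = design$mass_range,
                      mass_diff_range = design$mass_diff_range,
                      n_sires = design$n_sires, n_dams = design$n_dams)
  dyads <- sample_dyads(big, seed)
  set.seed(as.integer(seed) + 1L)
  zf <- stats::rnorm(nrow(dyads))
  lp <- latency_linear_predictor(params$latency,
                                 as.character(dyads$relatedness_level),
                                 dyads$mass_diff) +
    sqrt(params$re_variances[["latency_family"]]) * zf
  T_ <- design$experimental_duration
  frac <- function(log_lambda)
    mean(1 - exp(-exp(log_lambda + lp) * T_)) - target_event_frac
  stats::uniroot(frac, lower = log(1e-12), upper = log(1), tol = 1e-10)$root |>
    exp()
}

#' Write a synthetic trial dataset to CSV
#'
#' Writes the tadpole-phase table and the dyad-level latency table as two
#' CSVs (`<stem>_tadpoles.csv`, `<stem>_latency.csv`) with commented headers
#' recording the seed; [read_trials()] round-trips them losslessly.
#'
#' @param trials A `trial_data` object.
#' @param stem Output path stem (without suffix).
#' @return The two paths, invisibly.
#' @export
write_trials <- function(trials, stem) {
  stopifnot(inherits(trials, "trial_data"))
  if (nrow(trials$tadpoles) == 0L)
    stop("empty trial record list", call. = FALSE)
  p1 <- paste0(stem, "_tadpoles.csv")
  p2 <- paste0(stem, "_latency.csv")
  write_commented_csv(trials$tadpoles, p1, seed = trials$seed)
  write_commented_csv(trials$latency, p2, seed = trials$seed)
  invisible(c(tadpoles = p1, latency = p2))
}

#' Read a synthetic trial dataset written by [write_trials()]
#'
#' @param stem The path stem used when writing.
#' @return A list with `tadpoles` and `latency` data frames.
#' @export
read_trials <- function(stem) {
  tad <- read_commented_csv(paste0(stem, "_tadpoles.csv"))
  lat <- read_commented_csv(paste0(stem, "_latency.csv"))
  tad$relatedness_level <- factor(tad$relatedness_level,
                                  levels = relatedness_levels())
  lat$relatedness_level <- factor(lat$relatedness_level,
                                  levels = relatedness_levels())
  list(tadpoles = tad, latency = lat)
}
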