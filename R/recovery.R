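check_levels <- function(df, min_per_level = 2L, what = "dyads") {
  tab <- table(factor(df$relatedness_level, levels = relatedness_levels()))
  if (any(tab < min_per_level))
    stop(sprintf(
      "inestimable design: need at least %d %s in every relatedness level (got %s)",
      min_per_level, what, paste(tab, collapse = "/")), call. = FALSE)
  invisible(TRUE)
}

prep_count_frame <- function(trials, phase) {
  tad <- if (inherits(trials, "trial_data")) trials$tadpoles else trials$tadpoles
  df <- tad[tad$phase == phase, , drop = FALSE]
  df$relatedness_level <- factor(df$relatedness_level,
                                 levels = relatedness_levels())
  df$relative_size <- factor(df$relative_size, levels = c("small", "large"))
  df$pair_id <- factor(df$pair_id)
  df$family <- factor(df$family)
  # acclimation exposure is in minutes, experimental in seconds, matching the
  # generator's offset convention
  df$exposure <- if (phase == "acclimation") df$duration_s / 60 else df$duration_s
  df
}

# glmmTMB term names -> the canonical table row names
canonical_count_terms <- function(terms) {
  map <- c("(Intercept)" = "intercept",
           "relatedness_levelhalf_sibling" = "half_siblings",
           "relatedness_levelsibling" = "siblings",
           "relative_sizelarge" = "size_large",
           "relatedness_levelhalf_sibling:relative_sizelarge" =
             "half_siblings:size_large",
           "relatedness_levelsibling:relative_sizelarge" =
             "siblings:size_large")
  unname(map[terms])
}

canonical_latency_terms <- function(terms) {
  map <- c("relatedness_levelhalf_sibling" = "half_siblings",
           "relatedness_levelsibling" = "siblings",
           "mass_diff" = "mass_diff",
           "relatedness_levelhalf_sibling:mass_diff" =
             "half_siblings:mass_diff",
           "relatedness_levelsibling:mass_diff" = "siblings:mass_diff")
  unname(map[terms])
}

fit_result <- function(model_tag, coefficients, converged, re_variances,
                       notes = character()) {
  structure(list(model_tag = model_tag, coefficients = coefficients,
                 converged = converged, re_variances = re_variances,
                 notes = notes),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s> %s\n", x$model_tag,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients, digits = 4)
  if (length(x$re_variances))
    cat("random-effect variances:",
        paste(sprintf("%s = %.3g", names(x$re_variances), x$re_variances),
              collapse = ", "), "\n")
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

tidy_glmmTMB <- function(fit, term_mapper) {
  co <- summary(fit)$coefficients$cond
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  data.frame(term = term_mapper(rownames(co)), estimate = unname(est),
             se = unname(se),
             conf.low = unname(est - stats::qnorm(0.975) * se),
             conf.high = unname(est + stats::qnorm(0.975) * se),
             stringsAsFactors = FALSE)
}

glmm_re_variances <- function(fit) {
  vc <- glmmTMB::VarCorr(fit)$cond
  vapply(vc, function(m) m[1, 1], numeric(1))
}

fit_count_glmm <- function(df, family, model_tag) {
  notes <- character()
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(
      count ~ relatedness_level * relative_size + offset(log(exposure)) +
        (1 | pair_id) + (1 | family),
      data = df, family = family,
      control = glmmTMB::glmmTMBControl(profile = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fit_result(model_tag,
                      data.frame(term = character(), estimate = numeric(),
                                 se = numeric(), conf.low = numeric(),
                                 conf.high = numeric()),
                      converged = FALSE, re_variances = numeric(),
                      notes = conditionMessage(fit)))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  re <- glmm_re_variances(fit)
  if (any(re < 1e-6))
    notes <- c(notes, sprintf(
      "random-intercept variance at boundary (~0) for: %s",
      paste(names(re)[re < 1e-6], collapse = ", ")))
  coefs <- tidy_glmmTMB(fit, canonical_count_terms)
  if (!conv) notes <- c(notes, "optimiser did not report clean convergence")
  fit_result(model_tag, coefs, conv, re, notes)
}

#' Fit the aggression model
#'
#' Refits the total-aggression model structure to a (synthetic) trial
#' dataset: Poisson GLMM with log link for per-tadpole aggression counts,
#' predictors relative size x relatedness (non-sibling / small reference),
#' log trial-duration offset, and random intercepts for pair and family.
#' A random-intercept variance collapsing to the boundary is recorded in
#' `notes`, not treated as failure.
#'
#' @param trials A `trial_data` object (or a list with a compatible
#'   `tadpoles` data frame).
#' @return A `fit_result` with log-scale coefficients named after the model
#'   table rows, Wald 95% intervals, convergence flag and random-effect
#'   variance estimates.
#' @export
fit_aggression_model <- function(trials) {
  df <- prep_count_frame(trials, "experimental")
  check_levels(df[df$relative_size == "large", ], 2L)
  df$count <- df$aggression_count
  fit_count_glmm(df, stats::poisson(), "aggression")
}

#' Fit the activity model
#'
#' As [fit_aggression_model()] but negative binomial (quadratic
#' mean-variance), for the scan-sampled activity counts of the selected
#' phase. The acclimation fit uses exposure in minutes and the experimental
#' fit exposure in seconds, matching the generator's offset conventions.
#'
#' @inheritParams fit_aggression_model
#' @param phase `"experimental"` or `"acclimation"`.
#' @return A `fit_result`; `dispersion` (the NB size) is appended to
#'   `re_variances` under the name `"nb_size"`.
#' @export
fit_activity_model <- function(trials, phase = c("experimental",
                                                 "acclimation")) {
  phase <- match.arg(phase)
  df <- prep_count_frame(trials, phase)
  check_levels(df[df$relative_size == "large", ], 2L)
  df$count <- df$activity_count
  res <- fit_count_glmm(df, glmmTMB::nbinom2(), paste0("activity_", phase))
  res
}

#' Fit the first-bite latency model
#'
#' Refits the latency model structure: a proportional-hazards model of
#' first-bite time with censoring indicator, predictors relatedness x
#' mass difference, and a Gaussian frailty (random intercept on the log
#' hazard) for family. The latency table has one row per dyad, so pair
#' identity needs no random term. If the frailty variance is inestimable the
#' model is refitted without it and a note recorded; `frailty = FALSE`
#' drops it up front.
#'
#' @inheritParams fit_aggression_model
#' @param frailty Include the family frailty term.
#' @return A `fit_result` with log-hazard-ratio coefficients.
#' @export
fit_latency_model <- function(trials, frailty = TRUE) {
  lat <- trials$latency
  lat$relatedness_level <- factor(lat$relatedness_level,
                                  levels = relatedness_levels())
  ev <- tapply(lat$event, lat$relatedness_level, sum)
  if (any(is.na(ev)) || any(ev < 1))
    stop("need at least one uncensored first bite per relatedness level",
         call. = FALSE)
  lat$family <- factor(lat$family)
  notes <- character()

  do_fit <- function(with_frailty) {
    fm <- if (with_frailty) {
      survival::Surv(time_s, event) ~ relatedness_level * mass_diff +
        survival::frailty(family, distribution = "gaussian")
    } else {
      survival::Surv(time_s, event) ~ relatedness_level * mass_diff
    }
    tryCatch(suppressWarnings(survival::coxph(fm, data = lat)),
             error = function(e) e)
  }
  fit <- do_fit(frailty)
  if (frailty && inherits(fit, "error")) {
    notes <- c(notes, paste("frailty term dropped:", conditionMessage(fit)))
    fit <- do_fit(FALSE)
  }
  if (inherits(fit, "error"))
    return(fit_result("latency",
                      data.frame(term = character(), estimate = numeric(),
                                 se = numeric(), conf.low = numeric(),
                                 conf.high = numeric()),
                      converged = FALSE, re_variances = numeric(),
                      notes = c(notes, conditionMessage(fit))))
  est <- stats::coef(fit)  # fixed effects only; frailty coefs live elsewhere
  se <- sqrt(diag(fit$var))[seq_along(est)]
  coefs <- data.frame(term = canonical_latency_terms(names(est)),
                      estimate = unname(est), se = unname(se),
                      conf.low = unname(est - stats::qnorm(0.975) * se),
                      conf.high = unname(est + stats::qnorm(0.975) * se),
                      stringsAsFactors = FALSE)
  re <- numeric()
  if (!is.null(fit$history) && length(fit$history))
    re <- c(latency_family = unname(fit$history[[1]]$theta))
  fit_result("latency", coefs, converged = TRUE, re_variances = re,
             notes = notes)
}

generating_values <- function(params, model_tag) {
  switch(model_tag,
         aggression = params$aggression,
         activity_experimental = params$activity_experimental,
         activity_acclimation = params$activity_acclimation,
         latency = params$latency)
}

#' Replicated parameter-recovery experiment
#'
#' Generates independent synthetic datasets (seeds deterministically split
#' from the master seed), refits the selected model structures to each, and
#' summarises recovery per coefficient: generating value, mean estimate,
#' bias, empirical SD, and 95%-interval coverage of the generating value.
#' Per-replicate fit failures are counted, never propagated.
#'
#' @param params A [generating_params()] — the generating truth.
#' @param design A [trial_design()].
#' @param n_replicates Number of independent datasets (at least 2).
#' @param seed Master integer seed.
#' @param models Any of `"aggression"`, `"activity"`, `"latency"`.
#' @param activity_phase Phase for the activity refits.
#' @param frailty Passed to [fit_latency_model()].
#' @param out_csv Optional path: write the summary as commented CSV.
#' @return A data frame of class `recovery_summary` with one row per
#'   (model, coefficient); the full replicate-level estimates are attached
#'   as attribute `"estimates"`.
#' @export
recovery_experiment <- function(params = generating_params(),
                                design = trial_design(),
                                n_replicates = 10L, seed = 1L,
                                models = c("aggression", "activity",
                                           "latency"),
                                activity_phase = "experimental",
                                frailty = TRUE, out_csv = NULL) {
  stopifnot(n_replicates >= 2)
  models <- match.arg(models, several.ok = TRUE)
  seeds <- split_seed(seed, n_replicates)
  rows <- list()
  for (i in seq_len(n_replicates)) {
    trials <- generate_trials(design, params, seeds[i])
    for (m in models) {
      res <- switch(m,
        aggression = fit_aggression_model(trials),
        activity = fit_activity_model(trials, activity_phase),
        latency = tryCatch(fit_latency_model(trials, frailty = frailty),
                           error = function(e)
                             fit_result("latency", data.frame(),
                                        FALSE, numeric(),
                                        conditionMessage(e))))
      if (nrow(res$coefficients) == 0L || !res$converged) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = i, model = res$model_tag, term = NA_character_,
          estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
          converged = FALSE, stringsAsFactors = FALSE)
      } else {
        co <- res$coefficients
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = i, model = res$model_tag, term = co$term,
          estimate = co$estimate, conf.low = co$conf.low,
          conf.high = co$conf.high, converged = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  est <- do.call(rbind, rows)

  summaries <- list()
  for (m in unique(est$model)) {
    sub <- est[est$model == m & est$converged & !is.na(est$term), ,
               drop = FALSE]
    n_fail <- length(unique(est$replicate[est$model == m & !est$converged]))
    gen <- generating_values(params, m)
    for (term in unique(sub$term)) {
      g <- if (term %in% names(gen)) gen[[term]] else NA_real_
      e <- sub[sub$term == term, , drop = FALSE]
      summaries[[length(summaries) + 1L]] <- data.frame(
        model = m, term = term, generating = g,
        mean_estimate = mean(e$estimate), bias = mean(e$estimate) - g,
        empirical_sd = stats::sd(e$estimate),
        coverage = if (is.na(g)) NA_real_ else
          mean(e$conf.low <= g & g <= e$conf.high),
        n_replicates = nrow(e), n_nonconverged = n_fail,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  class(out) <- c("recovery_summary", "data.frame")
  attr(out, "estimates") <- est
  if (!is.null(out_csv))
    write_commented_csv(as.data.frame(out), out_csv, seed = seed,
                        extra = c(n_replicates = format(n_replicates)))
  out
}
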