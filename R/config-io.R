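#' Split a master seed into per-stage seeds
#'
#' All randomness in a run flows from one integer seed; stages (dyad
#' sampling, each generator, each replicate) draw their own sub-seeds
#' deterministically from it, so a whole pipeline is reproducible from a
#' single number.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Write a data frame as CSV with a commented header
#'
#' Comma-separated, UTF-8, '.' decimal; lines starting with `#` carry
#' provenance (package version, seed, config hash) and are skipped by
#' [read_commented_csv()].
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param extra Named character vector of extra header fields.
#' @export
write_commented_csv <- function(x, path, seed = NULL, extra = NULL) {
  stopifnot(is.data.frame(x))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kincontest %s",
                     as.character(utils::packageVersion("kincontest"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", format(seed)), con)
  if (!is.null(extra))
    writeLines(sprintf("# %s: %s", names(extra), unname(extra)), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_commented_csv()]
#'
#' @param path File path.
#' @return A data frame; `#` comment lines are ignored.
#' @export
read_commented_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

config_template <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    solver = unclass(solver_options()),
    sweep = list(s_small = 0.1,
                 s_large_min = 0.1, s_large_max = 1.0, s_large_step = 0.01,
                 r_values = c(0, 0.25, 0.5),
                 formulations = fitness_formulations()),
    design = unclass(trial_design()),
    generating_params = unclass(generating_params())
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: '%s'", full), call. = FALSE)
    def <- defaults[[key]]
    val <- user[[key]]
    if (is.list(def) && !is.null(names(def))) {
      if (!is.list(val))
        stop(sprintf("configuration key '%s' must be a mapping", full),
             call. = FALSE)
      defaults[[key]] <- merge_config(def, val, full)
    } else if (is.atomic(def) && !is.null(names(def))) {
      # named vectors (coefficient sets, variances) merge element-wise
      if (is.list(val)) val <- unlist(val)
      if (is.null(names(val)) && length(val) == length(def)) {
        names(val) <- names(def)
      }
      bad <- setdiff(names(val), names(def))
      if (length(bad))
        stop(sprintf("unknown configuration key: '%s.%s'", full, bad[1]),
             call. = FALSE)
      def[names(val)] <- val
      defaults[[key]] <- def
    } else {
      if (is.list(val)) val <- unlist(val)
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Parse a run configuration
#'
#' Reads a YAML configuration file and merges it over the package defaults
#' (which reproduce the study-design defaults of every module: solver
#' settings, the sweep grid, the trial design, and the generating
#' parameters). Unknown keys are rejected by name; a missing or `NULL` path
#' returns the full defaults.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @return A named list of class `run_config`.
#' @export
parse_config <- function(path = NULL) {
  cfg <- config_template()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) stop(sprintf(
                       "malformed configuration file '%s': %s",
                       path, conditionMessage(e)), call. = FALSE))
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Serialise a run configuration to YAML
#'
#' Round-trips through [parse_config()] unchanged.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors become YAML maps so element names survive the trip
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  writeLines(yaml::as.yaml(prep(unclass(config)), precision = 15), path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' A deterministic hex digest of the canonical YAML serialisation, recorded
#' in output headers so runs can be matched to their configuration.
#'
#' @param config A `run_config` (or any list).
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(txt)
  # two interleaved polynomial hashes mod Mersenne prime 2^31-1 (exact in doubles)
  m <- 2147483647
  h1 <- 17; h2 <- 257
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% m
    h2 <- (h2 * 137 + b) %% m
  }
  sprintf("%08x%08x", h1, h2)
}

#' Run logger
#'
#' A lightweight sink that records the seed, configuration hash and package
#' version at start-up and counts warnings (generator cap hits, solver
#' non-convergence, boundary variance estimates) so they can be summarised at
#' the end of a run instead of scrolling past.
#'
#' @param config A `run_config`.
#' @param quiet Suppress the start-up banner.
#' @return An environment of class `run_log` with functions `note(tag)`,
#'   `counts()` and `summary()`.
#' @export
run_logging <- function(config = parse_config(), quiet = FALSE) {
  log <- new.env(parent = emptyenv())
  log$seed <- config$seed
  log$hash <- config_hash(config)
  log$version <- as.character(utils::packageVersion("kincontest"))
  log$counts <- integer()
  log$note <- function(tag, n = 1L) {
    cur <- if (tag %in% names(log$counts)) log$counts[[tag]] else 0L
    log$counts[[tag]] <- cur + as.integer(n)
    invisible(NULL)
  }
  log$get_counts <- function() log$counts
  log$summary <- function() {
    cat(sprintf("run: kincontest %s, seed %s, config %s\n",
                log$version, format(log$seed), log$hash))
    if (length(log$counts) == 0L) {
      cat("no warnings recorded\n")
    } else {
      for (tag in names(log$counts))
        cat(sprintf("  %s: %d\n", tag, log$counts[[tag]]))
    }
    invisible(log$counts)
  }
  if (!quiet)
    message(sprintf("kincontest %s | seed %s | config %s",
                    log$version, format(log$seed), log$hash))
  class(log) <- c("run_log", "environment")
  log
}
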