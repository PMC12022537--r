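#' Specification of one simulated test
#'
#' Defines the score model for one neurocognitive measure: group-specific
#' baselines (the post-habituation asymptote), between-subject spread,
#' decaying learning amplitudes and a per-day residual-error schedule.
#' The generated score for subject s (group g) on day d, trial t is
#' \deqn{\mu_g + b_s + sign \cdot c_g [A e^{-\lambda_g (d-1)} +
#'   a e^{-\lambda_g (d-1)} 1\{t=1\}] + \epsilon_{sdt}}
#' with \eqn{b_s \sim N(0, \sigma_s^2)},
#' \eqn{\epsilon \sim N(0, \sigma_e(d)^2)}, and `sign` chosen so that the
#' learning term makes early performance worse (higher times, lower hit
#' counts).
#'
#' @param name test label.
#' @param units score units (e.g. `"s"`, `"cm"`, `"hits"`, `"ms"`).
#' @param higher_is_better logical; `TRUE` for counts, `FALSE` for times.
#' @param baseline named numeric vector of asymptotic group means.
#' @param subject_sd between-subject SD \eqn{\sigma_s > 0}.
#' @param amp_interday day-level learning amplitude A (score units).
#' @param amp_intraday extra trial-1 amplitude a (score units), letting
#'   within-day improvement persist independently of the day-level decay.
#' @param decay exponential decay rate \eqn{\lambda \ge 0} per day.
#' @param error_sd residual SD per day: scalar or vector of length
#'   `n_days`; a nonincreasing vector emulates random error shrinking with
#'   exposure.
#' @param floor,ceiling optional physical bounds applied after all terms.
#' @param censor_value optional recorded value for scores beyond
#'   `ceiling` (e.g. 51 cm for a dropped 50-cm ruler); must be >= ceiling.
#' @return a `test_spec` object.
#' @export
test_spec <- function(name, units, higher_is_better, baseline, subject_sd,
                      amp_interday, amp_intraday, decay, error_sd,
                      floor = NULL, ceiling = NULL, censor_value = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.logical(higher_is_better),
            !is.null(names(baseline)),
            subject_sd > 0, decay >= 0, all(error_sd > 0),
            amp_interday >= 0, amp_intraday >= 0)
  if (!is.null(censor_value)) {
    if (is.null(ceiling)) stop("censor_value requires a ceiling")
    if (censor_value < ceiling) stop("censor_value must be >= ceiling")
  }
  structure(list(name = name, units = units,
                 higher_is_better = higher_is_better,
                 baseline = baseline, subject_sd = subject_sd,
                 amp_interday = amp_interday, amp_intraday = amp_intraday,
                 decay = decay, error_sd = error_sd,
                 floor = floor, ceiling = ceiling,
                 censor_value = censor_value),
            class = "test_spec")
}

#' Simulation configuration for a repeated-measures cohort
#'
#' @param groups data.frame with columns `label`, `n` and optionally
#'   `learning_scale` (multiplies both learning amplitudes; children
#'   typically > 1) and `decay_scale` (multiplies the decay rate).
#' @param tests list of [test_spec()] objects; every test's `baseline`
#'   must name every group label.
#' @param n_days number of daily sessions.
#' @param n_trials_per_day trials per session.
#' @return a `sim_config` object.
#' @export
sim_config <- function(groups, tests, n_days = 5L, n_trials_per_day = 2L) {
  stopifnot(is.data.frame(groups), all(c("label", "n") %in% names(groups)),
            all(groups$n >= 1L), n_days >= 1L, n_trials_per_day >= 1L)
  if (is.null(groups$learning_scale)) groups$learning_scale <- 1
  if (is.null(groups$decay_scale)) groups$decay_scale <- 1
  groups$label <- as.character(groups$label)
  if (anyDuplicated(groups$label)) stop("duplicate group labels")
  for (ts in tests) {
    stopifnot(inherits(ts, "test_spec"))
    missing_g <- setdiff(groups$label, names(ts$baseline))
    if (length(missing_g) > 0L) {
      stop("test '", ts$name, "' lacks baselines for group(s): ",
           paste(missing_g, collapse = ", "))
    }
    if (!length(ts$error_sd) %in% c(1L, n_days)) {
      stop("test '", ts$name, "': error_sd must have length 1 or n_days")
    }
  }
  if (anyDuplicated(vapply(tests, `[[`, "", "name"))) {
    stop("duplicate test names")
  }
  structure(list(groups = groups, tests = tests,
                 n_days = as.integer(n_days),
                 n_trials_per_day = as.integer(n_trials_per_day)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d group(s) (N = %d), %d test(s), %d days x %d trials\n",
              nrow(x$groups), sum(x$groups$n), length(x$tests),
              x$n_days, x$n_trials_per_day))
  invisible(x)
}

#' Paper-like preset cohort configuration
#'
#' A three-group cohort (22 children, 20 young adults, 23 older adults)
#' tested on five measures over 5 days with 2 trials per day: ruler drop
#' (cm, censored at 51), trail making (s), Stroop word reading (s), choice
#' reaction hits (count) and choice reaction time (ms). Baselines,
#' learning amplitudes, decay rates and shrinking error schedules are
#' chosen to qualitatively reproduce published reliability patterns for
#' these tasks (strong early learning that decays to a negligible level by
#' the fourth to fifth session, with random error shrinking alongside);
#' they are illustrative scaffolding, not a fit to any dataset.
#'
#' @return a [sim_config()].
#' @examples
#' cfg <- cohort_preset()
#' cfg$groups$n
#' @export
cohort_preset <- function() {
  groups <- data.frame(
    label = c("children", "young_adults", "older_adults"),
    n = c(22L, 20L, 23L),
    learning_scale = c(1.4, 0.8, 1.0),
    decay_scale = c(1, 1, 1))
  tests <- list(
    test_spec("ruler_drop", "cm", FALSE,
              baseline = c(children = 14, young_adults = 8, older_adults = 11),
              subject_sd = 4.5, amp_interday = 8, amp_intraday = 2,
              decay = 0.8, error_sd = c(5, 4.5, 4.2, 4, 4),
              floor = 1, ceiling = 50, censor_value = 51),
    test_spec("trail_making", "s", FALSE,
              baseline = c(children = 24, young_adults = 11, older_adults = 14),
              subject_sd = 8, amp_interday = 11, amp_intraday = 2.5,
              decay = 1.2, error_sd = c(3.5, 3, 2.5, 2, 2),
              floor = 5),
    test_spec("stroop", "s", FALSE,
              baseline = c(children = 27, young_adults = 15, older_adults = 15),
              subject_sd = 7, amp_interday = 3.5, amp_intraday = 1,
              decay = 1.2, error_sd = c(1.8, 1.4, 1.0, 0.8, 0.7),
              floor = 5),
    test_spec("choice_reaction", "hits", TRUE,
              baseline = c(children = 44, young_adults = 57, older_adults = 50),
              subject_sd = 6.5, amp_interday = 5.5, amp_intraday = 1,
              decay = 1.2, error_sd = c(1.6, 1.5, 1.3, 1.2, 1.1),
              floor = 0),
    test_spec("reaction_time", "ms", FALSE,
              baseline = c(children = 590, young_adults = 390, older_adults = 450),
              subject_sd = 110, amp_interday = 75, amp_intraday = 15,
              decay = 1.2, error_sd = c(30, 28, 24, 22, 20),
              floor = 100))
  sim_config(groups, tests, n_days = 5L, n_trials_per_day = 2L)
}

#' Simulate a cohort
#'
#' Draws a full long-format dataset from a [sim_config()]. All
#' randomness flows from one seeded generator, so equal seeds yield
#' identical datasets; the caller's RNG state is restored on exit.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return a [trial_data()] dataset.
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  n_total <- sum(cfg$groups$n)
  subj_id <- sprintf("s%03d", seq_len(n_total))
  subj_group <- rep(cfg$groups$label, cfg$groups$n)
  d_idx <- seq_len(cfg$n_days)
  t_idx <- seq_len(cfg$n_trials_per_day)
  n_cells <- cfg$n_days * cfg$n_trials_per_day

  out <- vector("list", length(cfg$tests))
  for (j in seq_along(cfg$tests)) {
    ts <- cfg$tests[[j]]
    sgn <- if (ts$higher_is_better) -1 else 1
    err_sd <- rep(ts$error_sd, length.out = cfg$n_days)
    b <- stats::rnorm(n_total, 0, ts$subject_sd)
    mu <- ts$baseline[subj_group]
    lscale <- cfg$groups$learning_scale[match(subj_group, cfg$groups$label)]
    dscale <- cfg$groups$decay_scale[match(subj_group, cfg$groups$label)]

    day <- rep(rep(d_idx, each = cfg$n_trials_per_day), times = n_total)
    trial <- rep(rep(t_idx, times = cfg$n_days), times = n_total)
    subj_i <- rep(seq_len(n_total), each = n_cells)
    decay_term <- exp(-ts$decay * dscale[subj_i] * (day - 1))
    learning <- sgn * lscale[subj_i] *
      (ts$amp_interday + ts$amp_intraday * (trial == 1L)) * decay_term
    eps <- stats::rnorm(n_total * n_cells, 0, err_sd[day])
    score <- mu[subj_i] + b[subj_i] + learning + eps

    if (!is.null(ts$censor_value)) {
      score[score > ts$ceiling] <- ts$censor_value
    } else if (!is.null(ts$ceiling)) {
      score <- pmin(score, ts$ceiling)
    }
    if (!is.null(ts$floor)) score <- pmax(score, ts$floor)

    out[[j]] <- data.frame(subject = subj_id[subj_i],
                           group = subj_group[subj_i],
                           test = ts$name, day = day, trial = trial,
                           score = score)
  }
  df <- do.call(rbind, out)
  hib <- vapply(cfg$tests, `[[`, logical(1L), "higher_is_better")
  un <- vapply(cfg$tests, `[[`, character(1L), "units")
  names(hib) <- names(un) <- vapply(cfg$tests, `[[`, character(1L), "name")
  trial_data(df, higher_is_better = hib, units = un)
}

#' Analytic ground truth implied by a simulation configuration
#'
#' Bookkeeping for parameter-recovery checks: the reliability and bias
#' values the generator's variance components imply, before sampling
#' noise and censoring.
#'
#' @param cfg a [sim_config()].
#' @param bias_threshold absolute bias (score units) below which a
#'   consecutive-day learning effect counts as undetectable when locating
#'   the first stable day.
#' @return list with one element per test: per-day true intraclass
#'   correlation at trial level (\eqn{\sigma_s^2/(\sigma_s^2+\sigma_e(d)^2)}),
#'   per-group true consecutive-day biases of the day means
#'   (earlier - later), the implied day-mean difference SDs, and
#'   `first_stable_day` (per group, relative to `bias_threshold`).
#' @export
sim_truth <- function(cfg, bias_threshold = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(stats::setNames(cfg$tests,
                         vapply(cfg$tests, `[[`, "", "name")), function(ts) {
    err_sd <- rep(ts$error_sd, length.out = cfg$n_days)
    icc_day <- ts$subject_sd^2 / (ts$subject_sd^2 + err_sd^2)
    sgn <- if (ts$higher_is_better) -1 else 1
    d <- seq_len(cfg$n_days - 1L)
    amp <- ts$amp_interday + ts$amp_intraday / cfg$n_trials_per_day
    per_group <- lapply(seq_len(nrow(cfg$groups)), function(gi) {
      lam <- ts$decay * cfg$groups$decay_scale[gi]
      bias <- sgn * cfg$groups$learning_scale[gi] * amp *
        (exp(-lam * (d - 1)) - exp(-lam * d))
      sd_diff <- sqrt((err_sd[d]^2 + err_sd[d + 1L]^2) /
                        cfg$n_trials_per_day)
      fsd <- if (is.null(bias_threshold)) NA_integer_ else {
        ok <- abs(bias) < bias_threshold
        stable <- which(rev(cumprod(rev(ok))) == 1)
        if (length(stable) == 0L) NA_integer_ else as.integer(stable[1L])
      }
      list(label = cfg$groups$label[gi], bias = bias, sd_diff = sd_diff,
           first_stable_day = fsd)
    })
    names(per_group) <- cfg$groups$label
    list(test = ts$name, icc_day = icc_day, groups = per_group)
  })
}

#' Serialize / restore a simulation configuration
#'
#' Round-trips a [sim_config()] through YAML (or JSON when the path ends
#' in `.json`) so simulation settings can live next to the data they
#' produced.
#'
#' @param cfg a [sim_config()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly for the writer; a `sim_config` for the reader.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  payload <- list(
    groups = cfg$groups,
    n_days = cfg$n_days,
    n_trials_per_day = cfg$n_trials_per_day,
    tests = lapply(cfg$tests, function(ts) {
      ts <- unclass(ts)
      ts$baseline <- as.list(ts$baseline)
      ts[!vapply(ts, is.null, logical(1L))]
    }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  payload <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  groups <- as.data.frame(payload$groups)
  tests <- lapply(payload$tests, function(ts) {
    test_spec(name = ts$name, units = ts$units,
              higher_is_better = ts$higher_is_better,
              baseline = unlist(ts$baseline),
              subject_sd = ts$subject_sd,
              amp_interday = ts$amp_interday,
              amp_intraday = ts$amp_intraday,
              decay = ts$decay,
              error_sd = unlist(ts$error_sd),
              floor = ts$floor, ceiling = ts$ceiling,
              censor_value = ts$censor_value)
  })
  sim_config(groups, tests, n_days = payload$n_days,
             n_trials_per_day = payload$n_trials_per_day)
}
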