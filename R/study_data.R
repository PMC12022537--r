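#' Construct a validated long-format trial dataset
#'
#' The canonical input for all analyses: one row per administered trial,
#' identified by subject, test, day (1-based session index) and trial
#' (1-based trial-within-day index). Each test carries a direction flag
#' stating whether larger scores mean better performance (e.g. hit counts)
#' or worse performance (e.g. completion times in seconds).
#'
#' @param df data.frame with columns `subject`, `group`, `test`, `day`,
#'   `trial`, `score`.
#' @param higher_is_better named logical vector, one entry per test label;
#'   unnamed single logical recycles to all tests. Defaults to `FALSE`
#'   (time-scored tests) for any test not named.
#' @param units optional named character vector of score units per test.
#' @return A `trial_data` object: the validated data.frame (rows with
#'   missing scores dropped and counted in `attr(, "n_dropped")`) with the
#'   per-test direction map attached.
#' @examples
#' df <- data.frame(subject = "s1", group = "g", test = "stroop",
#'                  day = rep(1:3, each = 2), trial = rep(1:2, 3),
#'                  score = c(20, 18, 17.5, 17, 16.8, 17.1))
#' ds <- trial_data(df)
#' design_of(ds)
#' @export
trial_data <- function(df, higher_is_better = NULL, units = NULL) {
  required <- c("subject", "group", "test", "day", "trial", "score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$subject <- as.character(df$subject)
  df$group <- as.character(df$group)
  df$test <- as.character(df$test)
  df$day <- as.integer(df$day)
  df$trial <- as.integer(df$trial)
  df$score <- as.numeric(df$score)

  n_dropped <- sum(is.na(df$score))
  if (n_dropped > 0L) df <- df[!is.na(df$score), , drop = FALSE]

  if (any(is.na(df$day)) || any(df$day < 1L)) stop("day must be an integer >= 1")
  if (any(is.na(df$trial)) || any(df$trial < 1L)) stop("trial must be an integer >= 1")
  if (any(!is.finite(df$score))) stop("scores must be finite")

  key <- paste(df$subject, df$test, df$day, df$trial, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate (subject, test, day, trial) key: (%s, %s, %d, %d)",
      dup$subject, dup$test, dup$day, dup$trial))
  }
  # group labels must partition subjects
  gmap <- unique(df[c("subject", "group")])
  if (anyDuplicated(gmap$subject)) {
    stop("subject(s) assigned to more than one group: ",
         paste(unique(gmap$subject[duplicated(gmap$subject)]), collapse = ", "))
  }

  tests <- sort(unique(df$test))
  dir <- stats::setNames(rep(FALSE, length(tests)), tests)
  if (!is.null(higher_is_better)) {
    if (is.null(names(higher_is_better)) && length(higher_is_better) == 1L) {
      dir[] <- higher_is_better
    } else {
      known <- intersect(names(higher_is_better), tests)
      dir[known] <- higher_is_better[known]
    }
  }
  un <- stats::setNames(rep(NA_character_, length(tests)), tests)
  if (!is.null(units)) {
    known <- intersect(names(units), tests)
    un[known] <- units[known]
  }

  df <- df[order(df$test, df$subject, df$day, df$trial), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            higher_is_better = dir,
            units = un,
            n_dropped = n_dropped,
            class = c("trial_data", "data.frame"))
}

#' Read a long-format trial CSV
#'
#' Reads a UTF-8 CSV with a header row and validates it into a
#' [trial_data()] object. Nonstandard column names are resolved through
#' `schema`, a named character vector mapping the canonical names
#' (`subject`, `group`, `test`, `day`, `trial`, `score`) to the file's
#' column names.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector, e.g.
#'   `c(subject = "id", score = "value")`; unmapped canonical names are
#'   assumed to match.
#' @inheritParams trial_data
#' @return a `trial_data` object.
#' @export
read_trials <- function(path, schema = NULL, higher_is_better = NULL,
                        units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  canonical <- c("subject", "group", "test", "day", "trial", "score")
  if (!is.null(schema)) {
    for (canon in intersect(names(schema), canonical)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop("schema maps '", canon, "' to missing column '", src, "'")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  trial_data(raw, higher_is_better = higher_is_better, units = units)
}

#' Write a trial dataset to CSV
#'
#' @param ds a `trial_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ds, path) {
  stopifnot(inherits(ds, "trial_data"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Testing design of a dataset
#'
#' @param ds a `trial_data` object.
#' @return data.frame with one row per test: number of days and maximum
#'   trials per day observed.
#' @export
design_of <- function(ds) {
  stopifnot(inherits(ds, "trial_data"))
  out <- lapply(split(ds, ds$test), function(d) {
    data.frame(test = d$test[1L],
               n_days = length(unique(d$day)),
               n_trials_per_day = max(tapply(d$trial, d$day,
                                             function(t) length(unique(t)))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Trial dataset: %d observations, %d subjects, %d group(s), %d test(s)\n",
              nrow(x), length(unique(x$subject)), length(unique(x$group)),
              length(unique(x$test))))
  if (attr(x, "n_dropped") > 0L) {
    cat(sprintf("  (%d rows with missing scores dropped at load)\n",
                attr(x, "n_dropped")))
  }
  print(design_of(x))
  invisible(x)
}

#' Per-subject day means
#'
#' Averages the available trials of each subject on each day, the
#' aggregation that interday comparisons operate on (the mean of the two
#' valid trials per session in a 2-trial design; a single surviving trial
#' stands as its own mean).
#'
#' @param ds a `trial_data` object.
#' @param test test label.
#' @return data.frame with columns `subject`, `group`, `day`, `score`
#'   (the day mean) and `n_trials`.
#' @export
day_means <- function(ds, test) {
  stopifnot(inherits(ds, "trial_data"))
  d <- ds[ds$test == test, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for test '", test, "'")
  key <- interaction(d$subject, d$day, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(d)), key), function(idx) {
    data.frame(subject = d$subject[idx[1L]],
               group = d$group[idx[1L]],
               day = d$day[idx[1L]],
               score = mean(d$score[idx]),
               n_trials = length(idx))
  }))
  agg <- agg[order(agg$subject, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

new_paired_comparison <- function(label, kind, test, x, y, subjects, units) {
  stopifnot(length(x) == length(y), length(x) == length(subjects))
  structure(list(label = label, kind = kind, test = test,
                 x = as.numeric(x), y = as.numeric(y),
                 n = length(x), subjects = subjects,
                 units = units),
            class = "paired_comparison")
}

#' Construct a paired comparison from two aligned score vectors
#'
#' Low-level constructor for a test--retest pair; `x` is always the
#' chronologically earlier measurement and serves as the reference for
#' percentage errors.
#'
#' @param x,y numeric vectors of equal length, element i of each belonging
#'   to the same subject.
#' @param label comparison label (e.g. `"stroop 1"` or `"stroop 1_2"`).
#' @param kind one of `"intraday"`, `"interday"`, `"first_vs_last"`.
#' @param test test label.
#' @param subjects optional subject identifiers.
#' @param units score units.
#' @return a `paired_comparison` object.
#' @export
paired_comparison <- function(x, y, label = "pair", kind = "intraday",
                              test = NA_character_, subjects = NULL,
                              units = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("a paired comparison needs n >= 2 subjects")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("scores must be finite")
  if (is.null(subjects)) subjects <- as.character(seq_along(x))
  new_paired_comparison(label, kind, test, x, y, subjects, units)
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison '%s' (%s): n = %d\n", x$label, x$kind, x$n))
  invisible(x)
}

#' Build test--retest pairs from a dataset
#'
#' Intraday mode pairs trial 1 against trial 2 within each day. Interday
#' mode pairs the day means of consecutive days (1_2, 2_3, ...) plus the
#' first-versus-last-day comparison (e.g. 1_5). Pairing is complete-case
#' per comparison: a subject missing one side of a pair is excluded from
#' that pair only. Comparisons with fewer than 2 complete-case subjects
#' are skipped with a warning.
#'
#' @param ds a `trial_data` object.
#' @param test test label.
#' @param mode `"intraday"`, `"interday"` or `"first_vs_last"`.
#' @return list of [paired_comparison()] objects, chronologically ordered.
#' @export
make_pairs <- function(ds, test,
                       mode = c("intraday", "interday", "first_vs_last")) {
  stopifnot(inherits(ds, "trial_data"))
  mode <- match.arg(mode)
  units <- attr(ds, "units")[[test]]
  if (is.null(units)) units <- NA_character_

  if (mode == "intraday") {
    d <- ds[ds$test == test, , drop = FALSE]
    if (nrow(d) == 0L) stop("no observations for test '", test, "'")
    days <- sort(unique(d$day))
    pairs <- list()
    for (day in days) {
      dd <- d[d$day == day & d$trial %in% c(1L, 2L), , drop = FALSE]
      t1 <- dd[dd$trial == 1L, ]
      t2 <- dd[dd$trial == 2L, ]
      subjects <- sort(intersect(t1$subject, t2$subject))
      if (length(subjects) < 2L) {
        warning(sprintf("skipping intraday comparison '%s %d': fewer than 2 complete cases",
                        test, day))
        next
      }
      x <- t1$score[match(subjects, t1$subject)]
      y <- t2$score[match(subjects, t2$subject)]
      pairs[[length(pairs) + 1L]] <- new_paired_comparison(
        paste(test, day), "intraday", test, x, y, subjects, units)
    }
    return(pairs)
  }

  dm <- day_means(ds, test)
  days <- sort(unique(dm$day))
  if (length(days) < 2L) stop("interday pairing needs at least 2 days")
  pair_days <- if (mode == "first_vs_last") {
    list(c(days[1L], days[length(days)]))
  } else {
    consec <- lapply(seq_len(length(days) - 1L),
                     function(i) c(days[i], days[i + 1L]))
    if (length(days) > 2L) {
      c(consec, list(c(days[1L], days[length(days)])))
    } else {
      consec
    }
  }
  pairs <- list()
  for (pd in pair_days) {
    e <- dm[dm$day == pd[1L], ]
    l <- dm[dm$day == pd[2L], ]
    subjects <- sort(intersect(e$subject, l$subject))
    label <- paste0(test, " ", pd[1L], "_", pd[2L])
    if (length(subjects) < 2L) {
      warning(sprintf("skipping interday comparison '%s': fewer than 2 complete cases",
                      label))
      next
    }
    kind <- if (pd[2L] - pd[1L] > 1L) "first_vs_last" else "interday"
    x <- e$score[match(subjects, e$subject)]
    y <- l$score[match(subjects, l$subject)]
    pairs[[length(pairs) + 1L]] <- new_paired_comparison(
      label, kind, test, x, y, subjects, units)
  }
  pairs
}
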