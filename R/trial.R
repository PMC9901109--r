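CENSOR_MARKERS <- c("CENSOR", "CENSORED", "LOST", "LTFU", "LOST_TO_FOLLOWUP",
                    "WITHDRAWN", "DROPOUT")

#' Assemble and validate a trial event table
#'
#' A trial table holds one row per (subject, event time, event type) for a
#' fixed-follow-up randomized trial, plus an arm label. The method requires
#' complete follow-up: every subject is observed to `followup` days or to a
#' terminal event, and no censoring of any kind is admitted. Subjects with no
#' events are carried as a roster row with `event_type = "NONE"` and
#' `time = followup`, so the sample size per arm is recoverable from the
#' table alone.
#'
#' Validation enforces: known event types only; times in `(0, followup]`;
#' at most one terminal event per subject and none after it; no duplicated
#' identical rows (simultaneous events of *different* types are legal); no
#' censoring markers; no mixing of `"NONE"` rows with event rows.
#'
#' @param data data frame with columns `subject_id`, `arm`, `time`,
#'   `event_type`.
#' @param catalog an [event_catalog()].
#' @param followup fixed follow-up length, days.
#' @return An object of class `wce_trial`: the canonicalized data frame
#'   (ordered by arm, subject, time, with terminal events last within ties)
#'   with attributes `catalog` and `followup`.
#' @export
wce_trial <- function(data, catalog, followup) {
  stopifnot(inherits(catalog, "wce_catalog"))
  if (!is.numeric(followup) || length(followup) != 1 || followup <= 0)
    stop_validation("`followup` must be a single positive number of days")
  need <- c("subject_id", "arm", "time", "event_type")
  if (!all(need %in% names(data)))
    stop_validation(sprintf("trial table must have columns %s",
                            paste(need, collapse = ", ")))
  if (any(c("status", "censored", "censor") %in% tolower(names(data))))
    stop_validation(paste(
      "censoring indicator column found: the weighted composite endpoint",
      "method excludes right censoring; every subject must be followed to",
      "the end of follow-up or to the terminal event"))
  d <- data.frame(subject_id = as.character(data$subject_id),
                  arm = as.character(data$arm),
                  time = as.numeric(data$time),
                  event_type = as.character(data$event_type),
                  stringsAsFactors = FALSE)
  row0 <- seq_len(nrow(d))
  if (nrow(d) == 0) stop_validation("trial table is empty")

  if (any(toupper(d$event_type) %in% CENSOR_MARKERS))
    stop_validation(paste0(
      "censoring marker in rows ",
      paste(head(row0[toupper(d$event_type) %in% CENSOR_MARKERS]), collapse = ", "),
      ": the weighted composite endpoint method excludes right censoring"))
  known <- c(catalog$event_type, "NONE")
  bad <- !d$event_type %in% known
  if (any(bad))
    stop_validation(sprintf("unknown event type '%s' in row %d",
                            d$event_type[bad][1], row0[bad][1]))
  bad <- !is.finite(d$time) | d$time <= 0 | d$time > followup
  if (any(bad))
    stop_validation(sprintf(
      "row %d: time %s outside (0, %g]", row0[bad][1],
      format(d$time[bad][1]), followup))
  if (anyDuplicated(d))
    stop_validation(sprintf("duplicated identical row (first at input row %d)",
                            row0[duplicated(d)][1]))

  term_type <- catalog$event_type[catalog$terminal]
  for (id in unique(d$subject_id[d$event_type == term_type])) {
    rows <- d$subject_id == id
    tt <- d$time[rows & d$event_type == term_type]
    if (length(tt) > 1)
      stop_validation(sprintf("subject '%s' has %d terminal events", id, length(tt)))
    if (any(d$time[rows] > tt))
      stop_validation(sprintf(
        "subject '%s' has an event after the terminal event at day %g", id, tt))
  }
  mixed <- intersect(d$subject_id[d$event_type == "NONE"],
                     d$subject_id[d$event_type != "NONE"])
  if (length(mixed))
    stop_validation(sprintf(
      "subject '%s' has both event rows and a 'NONE' roster row", mixed[1]))
  none <- d$event_type == "NONE"
  if (any(duplicated(d$subject_id[none])))
    stop_validation("duplicated 'NONE' roster rows for one subject")
  d$time[none] <- followup
  one_arm <- tapply(d$arm, d$subject_id, function(a) length(unique(a)) == 1)
  if (!all(one_arm))
    stop_validation(sprintf("subject '%s' appears in more than one arm",
                            names(one_arm)[!one_arm][1]))

  # canonical order: arm, subject, time; terminal sorts after ties at one time
  ord <- order(d$arm, d$subject_id, d$time, d$event_type == term_type)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  structure(d, catalog = catalog, followup = followup,
            class = c("wce_trial", "data.frame"))
}

#' Read / write a trial event table
#'
#' Trial tables are CSV files with header `subject_id,arm,time,event_type`.
#' Lines starting with `#` are treated as provenance comments and skipped on
#' read; `write_trial_table` can emit such a header (e.g. simulation seed and
#' calibration constants). Reading validates the full no-censoring contract
#' via [wce_trial()].
#'
#' @param path file path.
#' @param catalog an [event_catalog()].
#' @param followup fixed follow-up length, days.
#' @return `read_trial_table` returns a `wce_trial`; `write_trial_table`
#'   returns `path` invisibly.
#' @export
read_trial_table <- function(path, catalog, followup) {
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  wce_trial(d, catalog, followup)
}

#' @rdname read_trial_table
#' @param trial a `wce_trial`.
#' @param provenance optional named character vector written as `# key: value`
#'   comment lines above the header.
#' @export
write_trial_table <- function(trial, path, provenance = NULL) {
  stopifnot(inherits(trial, "wce_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  write.csv(as.data.frame(trial), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.wce_trial <- function(x, ...) {
  n <- table(tapply(x$arm, x$subject_id, `[`, 1))
  cat("Trial event table:", length(unique(x$subject_id)), "subjects,",
      sum(x$event_type != "NONE"), "events,", attr(x, "followup"),
      "days follow-up\n")
  cat("  subjects per arm:",
      paste(sprintf("%s=%d", names(n), as.integer(n)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-arm subject rosters
#'
#' @param trial a `wce_trial`.
#' @return Named list (one element per arm) of character vectors of subject ids.
#' @export
trial_subjects <- function(trial) {
  stopifnot(inherits(trial, "wce_trial"))
  arm_of <- tapply(trial$arm, trial$subject_id, `[`, 1)
  split(names(arm_of), as.character(arm_of))
}

# events of one arm mapped to 1..n subject indices and catalog weights
arm_events <- function(trial, arm) {
  catalog <- attr(trial, "catalog")
  ids <- trial_subjects(trial)[[arm]]
  rows <- trial$arm == arm & trial$event_type != "NONE"
  ev <- trial[rows, , drop = FALSE]
  k <- match(ev$event_type, catalog$event_type)
  list(
    i = match(ev$subject_id, ids),
    time = ev$time,
    k = k,
    w = catalog$weight[k],
    term = catalog$terminal[k],
    n = length(ids),
    ids = ids
  )
}
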