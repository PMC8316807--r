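## CSV dialect shared by all observational tables: header row, UTF-8,
## "." decimal separator, 0/1 integer flags, blank = missing.  Times are
## numeric seconds from an arbitrary per-study epoch (only differences are
## used); focal session durations are hours.

.read_raw <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[required_cols]
}

.row_fail <- function(table, row, field, msg) {
  stop(sprintf("%s row %d, field '%s': %s", table, row, field, msg),
       call. = FALSE)
}

.check_numeric <- function(df, table, field, min = -Inf, allow_na = FALSE) {
  x <- df[[field]]
  if (length(x) == 0L) return(invisible(numeric(0)))
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))[1]
    .row_fail(table, if (is.na(bad)) 1L else bad, field, "not numeric")
  }
  if (!allow_na && anyNA(x)) .row_fail(table, which(is.na(x))[1], field, "missing value")
  bad <- which(!is.na(x) & x < min)
  if (length(bad) > 0L) {
    .row_fail(table, bad[1], field, sprintf("value %s below minimum %s", x[bad[1]], min))
  }
  invisible(x)
}

.check_flag <- function(df, table, field) {
  x <- df[[field]]
  if (length(x) == 0L) return(invisible(integer(0)))
  bad <- which(is.na(x) | !(x %in% c(0L, 1L)))
  if (length(bad) > 0L) .row_fail(table, bad[1], field, "flag must be 0 or 1")
  invisible(as.integer(x))
}

.check_id <- function(df, table, field) {
  x <- df[[field]]
  if (length(x) == 0L) return(invisible(character(0)))
  bad <- which(is.na(x) | !nzchar(as.character(x)))
  if (length(bad) > 0L) .row_fail(table, bad[1], field, "empty identifier")
  invisible(as.character(x))
}

#' Validate a table of directed aggression bouts
#'
#' Checks one row per directed agonistic interaction: aggressor and victim
#' differ, times are non-negative, flags are 0/1, and a winner is present
#' if and only if the bout is decided (the victim fled or submitted), in
#' which case the winner must be one of the two participants.
#'
#' @param bouts data frame with columns `group_id`, `bout_id`, `time`
#'   (seconds), `aggressor_id`, `victim_id`, `contact`, `counter`,
#'   `decided` (0/1 flags) and `winner_id` (`NA` on undecided bouts).
#' @return the validated data frame, invisibly coerced column types.
#' @export
validate_bouts <- function(bouts) {
  tb <- "bouts"
  for (f in c("group_id", "bout_id", "aggressor_id", "victim_id")) {
    bouts[[f]] <- .check_id(bouts, tb, f)
  }
  bouts$time <- .check_numeric(bouts, tb, "time", min = 0)
  for (f in c("contact", "counter", "decided")) bouts[[f]] <- .check_flag(bouts, tb, f)
  bouts$winner_id <- as.character(bouts$winner_id)
  bad <- which(bouts$aggressor_id == bouts$victim_id)
  if (length(bad) > 0L) .row_fail(tb, bad[1], "victim_id", "aggressor_id equals victim_id")
  bad <- which(bouts$decided == 1L & is.na(bouts$winner_id))
  if (length(bad) > 0L) .row_fail(tb, bad[1], "winner_id", "decided bout without winner")
  bad <- which(bouts$decided == 0L & !is.na(bouts$winner_id))
  if (length(bad) > 0L) .row_fail(tb, bad[1], "winner_id", "winner given on undecided bout")
  bad <- which(bouts$decided == 1L &
                 !(bouts$winner_id == bouts$aggressor_id |
                     bouts$winner_id == bouts$victim_id))
  if (length(bad) > 0L) {
    .row_fail(tb, bad[1], "winner_id", "winner is neither aggressor nor victim")
  }
  invisible(bouts)
}

#' @rdname validate_bouts
#' @param scans data frame with columns `group_id`, `focal_id`, `time`,
#'   `feeding`, `neighbor_within_1m`.
#' @export
validate_scans <- function(scans) {
  tb <- "scans"
  for (f in c("group_id", "focal_id")) scans[[f]] <- .check_id(scans, tb, f)
  scans$time <- .check_numeric(scans, tb, "time", min = 0)
  for (f in c("feeding", "neighbor_within_1m")) scans[[f]] <- .check_flag(scans, tb, f)
  invisible(scans)
}

#' @rdname validate_bouts
#' @param sessions data frame with columns `group_id`, `focal_id`, `start`
#'   (seconds) and `duration` (hours, > 0); sessions of one focal may not
#'   overlap.
#' @export
validate_sessions <- function(sessions) {
  tb <- "sessions"
  for (f in c("group_id", "focal_id")) sessions[[f]] <- .check_id(sessions, tb, f)
  sessions$start <- .check_numeric(sessions, tb, "start", min = 0)
  sessions$duration <- .check_numeric(sessions, tb, "duration")
  bad <- which(sessions$duration <= 0)
  if (length(bad) > 0L) .row_fail(tb, bad[1], "duration", "duration must be > 0")
  for (id in unique(sessions$focal_id)) {
    rows <- which(sessions$focal_id == id)
    o <- rows[order(sessions$start[rows])]
    if (length(o) > 1L) {
      ends <- sessions$start[o] + sessions$duration[o] * 3600
      ov <- which(ends[-length(o)] > sessions$start[o][-1])
      if (length(ov) > 0L) {
        .row_fail(tb, o[ov[1] + 1L], "start",
                  sprintf("session overlaps previous session of focal '%s'", id))
      }
    }
  }
  invisible(sessions)
}

#' @rdname validate_bouts
#' @param events data frame with columns `group_id`, `focal_id`, `time`
#'   (vocalization onset, seconds).
#' @param sessions_for_events optional validated session table; when given,
#'   every event must fall inside one of its focal's sessions.
#' @export
validate_vocal_events <- function(events, sessions_for_events = NULL) {
  tb <- "vocal_events"
  for (f in c("group_id", "focal_id")) events[[f]] <- .check_id(events, tb, f)
  events$time <- .check_numeric(events, tb, "time", min = 0)
  if (!is.null(sessions_for_events)) {
    for (i in seq_len(nrow(events))) {
      s <- sessions_for_events[sessions_for_events$focal_id == events$focal_id[i], ]
      inside <- nrow(s) > 0L &&
        any(events$time[i] >= s$start & events$time[i] <= s$start + s$duration * 3600)
      if (!inside) {
        .row_fail(tb, i, "time",
                  sprintf("event of focal '%s' at t=%s outside all focal sessions",
                          events$focal_id[i], format(events$time[i])))
      }
    }
  }
  invisible(events)
}

#' @rdname validate_bouts
#' @param groups data frame with columns `group_id`, `species_id`,
#'   `group_size` (>= 2); group identifiers must be unique.
#' @export
validate_group_meta <- function(groups) {
  tb <- "groups"
  for (f in c("group_id", "species_id")) groups[[f]] <- .check_id(groups, tb, f)
  groups$group_size <- .check_numeric(groups, tb, "group_size", min = 2)
  dup <- which(duplicated(groups$group_id))
  if (length(dup) > 0L) .row_fail(tb, dup[1], "group_id", "duplicate group identifier")
  invisible(groups)
}

#' @rdname validate_bouts
#' @param repertoires data frame with columns `species_id`, `total_calls`
#'   and `hierarchy_calls` (a subset of the total, so
#'   `0 <= hierarchy_calls <= total_calls`).
#' @export
validate_repertoires <- function(repertoires) {
  tb <- "repertoires"
  repertoires$species_id <- .check_id(repertoires, tb, "species_id")
  repertoires$total_calls <- .check_numeric(repertoires, tb, "total_calls", min = 0)
  repertoires$hierarchy_calls <- .check_numeric(repertoires, tb, "hierarchy_calls", min = 0)
  bad <- which(repertoires$hierarchy_calls > repertoires$total_calls)
  if (length(bad) > 0L) {
    .row_fail(tb, bad[1], "hierarchy_calls", "hierarchy_calls exceeds total_calls")
  }
  dup <- which(duplicated(repertoires$species_id))
  if (length(dup) > 0L) .row_fail(tb, dup[1], "species_id", "duplicate species")
  invisible(repertoires)
}

#' Read and validate the observational CSV tables
#'
#' Each reader loads one CSV schema, validates every row against the
#' table's invariants and either returns the full table (row order
#' preserved) or raises an error naming the first offending row and field.
#'
#' @param path path to a CSV file in the documented dialect.
#' @return a validated data frame (zero rows for a header-only file).
#' @seealso [validate_bouts()] for the per-table invariants.
#' @export
read_bouts <- function(path) {
  df <- .read_raw(path, c("group_id", "bout_id", "time", "aggressor_id",
                          "victim_id", "contact", "counter", "decided",
                          "winner_id"))
  validate_bouts(df)
  df
}

#' @rdname read_bouts
#' @export
read_scans <- function(path) {
  df <- .read_raw(path, c("group_id", "focal_id", "time", "feeding",
                          "neighbor_within_1m"))
  validate_scans(df)
  df
}

#' @rdname read_bouts
#' @export
read_sessions <- function(path) {
  df <- .read_raw(path, c("group_id", "focal_id", "start", "duration"))
  validate_sessions(df)
  df
}

#' @rdname read_bouts
#' @param sessions optional validated session table used to cross-check
#'   that every vocal event falls inside one of its focal's sessions.
#' @export
read_vocal_events <- function(path, sessions = NULL) {
  df <- .read_raw(path, c("group_id", "focal_id", "time"))
  validate_vocal_events(df, sessions)
  df
}

#' @rdname read_bouts
#' @export
read_group_meta <- function(path) {
  df <- .read_raw(path, c("group_id", "species_id", "group_size"))
  validate_group_meta(df)
  df
}

#' @rdname read_bouts
#' @export
read_repertoires <- function(path) {
  df <- .read_raw(path, c("species_id", "total_calls", "hierarchy_calls"))
  validate_repertoires(df)
  df
}

#' Write a study bundle to a directory of CSV files
#'
#' Writes the five observational tables and, when present, the phylogeny
#' (Newick) and the ground truth (JSON) of a simulated study.  The files
#' round-trip through the corresponding readers field-for-field.
#'
#' @param study a list with elements `bouts`, `scans`, `sessions`,
#'   `vocal_events`, `groups`, `repertoires` and optionally `tree`
#'   (an `ape::phylo`) and `truth`.
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("bouts", "scans", "sessions", "vocal_events", "groups", "repertoires")
  for (tb in tabs) {
    write.csv(study[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE, na = "", quote = FALSE)
  }
  if (!is.null(study$tree)) {
    ape::write.tree(study$tree, file.path(dir, "phylogeny.nwk"))
  }
  if (!is.null(study$truth)) {
    truth <- study$truth
    truth$tree <- NULL
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Load a study bundle written by [write_study()]
#'
#' @param dir directory containing the CSV tables (and optionally
#'   `phylogeny.nwk`).
#' @return a list with the validated tables and, if present, the tree.
#' @export
load_study <- function(dir) {
  sessions <- read_sessions(file.path(dir, "sessions.csv"))
  study <- list(
    bouts = read_bouts(file.path(dir, "bouts.csv")),
    scans = read_scans(file.path(dir, "scans.csv")),
    sessions = sessions,
    vocal_events = read_vocal_events(file.path(dir, "vocal_events.csv"), sessions),
    groups = read_group_meta(file.path(dir, "groups.csv")),
    repertoires = read_repertoires(file.path(dir, "repertoires.csv"))
  )
  nwk <- file.path(dir, "phylogeny.nwk")
  if (file.exists(nwk)) study$tree <- read_newick(nwk)
  study
}
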