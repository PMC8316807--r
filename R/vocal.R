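#' Segment vocalization times into bouts
#'
#' Chains consecutive vocalizations into one bout while successive events
#' are within `ibi` seconds of one another (single linkage between
#' consecutive events; a gap exactly equal to `ibi` stays in the bout).
#' A new bout starts at each event whose gap from the previous event
#' exceeds `ibi`.
#'
#' @param times numeric vocalization onsets in seconds, sorted ascending.
#' @param ibi inter-bout interval in seconds (default 30).
#' @return the number of bouts (0 for an empty input).
#' @export
segment_bouts <- function(times, ibi = 30) {
  if (ibi <= 0) stop("ibi must be > 0", call. = FALSE)
  if (length(times) == 0L) return(0L)
  if (is.unsorted(times)) stop("segment_bouts: times must be sorted ascending",
                               call. = FALSE)
  1L + sum(diff(times) > ibi)
}

#' Hourly vocal-bout rates per focal individual
#'
#' Events are segmented into bouts within each focal session independently
#' (a bout cannot span unobserved time between sessions, so chaining never
#' crosses session boundaries).  The rate is bouts per hour of focal
#' observation; individuals with less than `min_hours` of observation are
#' flagged as not included.
#'
#' @param events validated vocal event table.
#' @param sessions validated focal session table.
#' @param focal_id optionally restrict to one focal; by default every
#'   focal with at least one session is reported.
#' @param ibi inter-bout interval in seconds (default 30).
#' @param min_hours minimum focal observation time for inclusion
#'   (default 2 h).
#' @return data frame with columns `focal_id`, `group_id`, `n_bouts`,
#'   `obs_hours`, `rate` and `included`.
#' @export
vocal_rate <- function(events, sessions, focal_id = NULL, ibi = 30, min_hours = 2) {
  ids <- if (is.null(focal_id)) sort(unique(sessions$focal_id)) else focal_id
  missing <- setdiff(unique(events$focal_id), sessions$focal_id)
  if (length(missing) > 0L) {
    stop("vocal_rate: events for focal(s) without sessions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    s <- sessions[sessions$focal_id == id, , drop = FALSE]
    if (nrow(s) == 0L) stop("vocal_rate: no sessions for focal ", id, call. = FALSE)
    tt <- sort(events$time[events$focal_id == id])
    nb <- 0L
    for (k in seq_len(nrow(s))) {
      inside <- tt[tt >= s$start[k] & tt <= s$start[k] + s$duration[k] * 3600]
      nb <- nb + segment_bouts(inside, ibi)
    }
    hours <- sum(s$duration)
    data.frame(focal_id = id, group_id = s$group_id[1], n_bouts = nb,
               obs_hours = hours, rate = nb / hours,
               included = hours >= min_hours, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
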