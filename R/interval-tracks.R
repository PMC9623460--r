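# Interval tracks: the time-dependent state "period of interest" — a set of
# half-open valued intervals per statistical unit. A collection is one tibble
# (class "interval_tracks") holding every unit's records; the per-unit track
# is the subset of rows sharing a unit_id.
#
# Half-open convention: a record [start, end) contains instant t iff
# start <= t < end. start == end denotes a point event with zero duration.

INTERVAL_COLS <- c("unit_id", "person_id", "track_concept", "start", "end",
                   "value_num", "value_concept", "source_value",
                   "visit_occurrence_id")

#' Build an interval-track collection
#'
#' An interval track is the time-dependent state of one statistical unit: a
#' set of half-open `[start, end)` intervals, each carrying either a numeric
#' value or a categorical concept (default numeric 1, an on/off state).
#' `start == end` encodes a point event. A collection holds the tracks of
#' many units in one tibble.
#'
#' @param unit_id statistical-unit identifier per record.
#' @param start,end interval bounds (anything [as_timepoint()] accepts);
#'   half-open semantics, `end < start` is an error.
#' @param track_concept concept naming the type of track (e.g.
#'   `"hospital_stay"`).
#' @param value_num numeric value per record; defaults to 1 where no
#'   categorical value is given.
#' @param value_concept categorical concept per record (e.g. a drug code);
#'   exactly one of `value_num`/`value_concept` is populated per record.
#' @param person_id person each unit belongs to; defaults to `unit_id`.
#' @param source_value optional free-text provenance.
#' @param visit_occurrence_id optional anchoring visit.
#' @return tibble of class `interval_tracks` with one row per record.
#' @examples
#' interval_tracks("u1", "2021-03-10", "2021-03-15", "hospital_stay")
#' @export
interval_tracks <- function(unit_id = character(), start = NULL, end = NULL,
                            track_concept = "track",
                            value_num = NULL, value_concept = NULL,
                            person_id = NULL, source_value = NULL,
                            visit_occurrence_id = NULL) {
  n <- length(unit_id)
  start <- if (is.null(start)) tp_from_num(numeric(0)) else as_timepoint(start)
  end <- if (is.null(end)) tp_from_num(numeric(0)) else as_timepoint(end)
  df <- tibble::tibble(
    unit_id = as.character(unit_id),
    person_id = as.character(if (is.null(person_id)) unit_id else person_id),
    track_concept = rep_len(as.character(track_concept), n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    value_num = if (is.null(value_num)) rep(NA_real_, n) else rep_len(as.numeric(value_num), n),
    value_concept = if (is.null(value_concept)) rep(NA_character_, n) else rep_len(as.character(value_concept), n),
    source_value = if (is.null(source_value)) rep(NA_character_, n) else rep_len(as.character(source_value), n),
    visit_occurrence_id = if (is.null(visit_occurrence_id)) rep(NA_character_, n) else rep_len(as.character(visit_occurrence_id), n)
  )
  new_interval_tracks(df)
}

# low-level constructor + invariant checks
new_interval_tracks <- function(df, exclusions = NULL) {
  for (col in INTERVAL_COLS) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(col,
        value_num = NA_real_,
        start = , end = tp_from_num(NA_real_),
        NA_character_
      )
    }
  }
  df <- df[INTERVAL_COLS]
  df$unit_id <- as.character(df$unit_id)
  df$person_id <- as.character(df$person_id)
  df$track_concept <- as.character(df$track_concept)
  df$value_concept <- as.character(df$value_concept)
  df$value_num <- as.numeric(df$value_num)
  bad <- !is.na(df$end) & !is.na(df$start) & df$end < df$start
  if (any(bad)) {
    stop("malformed track: end precedes start in ", sum(bad), " record(s)",
         call. = FALSE)
  }
  # default on/off value
  none <- is.na(df$value_num) & is.na(df$value_concept)
  df$value_num[none] <- 1
  both <- !is.na(df$value_num) & !is.na(df$value_concept)
  if (any(both)) {
    stop("record(s) with both numeric and categorical values", call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  class(df) <- c("interval_tracks", class(tibble::tibble()))
  attr(df, "exclusions") <- exclusions %||% empty_exclusions()
  df
}

#' @export
print.interval_tracks <- function(x, ...) {
  cat("<interval_tracks> ", nrow(x), " record(s), ",
      length(unique(x$unit_id)), " unit(s)\n", sep = "")
  NextMethod()
}

# one key per distinct track value, used for coalescing and count_distinct
vkey <- function(x) {
  ifelse(!is.na(x$value_concept),
         paste0("c:", x$value_concept),
         paste0("n:", format(x$value_num, digits = 15, scientific = FALSE)))
}

# merge possibly overlapping/abutting [s, e) pairs into disjoint maximal ones
merge_spans <- function(s, e) {
  if (length(s) == 0) return(cbind(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  em <- cummax(e)
  new_grp <- c(TRUE, s[-1] > em[-length(em)])
  g <- cumsum(new_grp)
  cbind(s = s[!duplicated(g)], e = tapply(e, g, max))
}

#' Coalesce an interval track
#'
#' Normal form for the interval algebra: within each unit and track concept,
#' overlapping or abutting records carrying the same value are merged (under
#' half-open semantics `[0,5)` and `[5,8)` abut and merge). Distinct values
#' never merge. Idempotent; total covered duration per value is preserved.
#'
#' @param x an `interval_tracks` collection.
#' @return coalesced collection, ordered by (unit, concept, start).
#' @export
coalesce_tracks <- function(x) {
  stopifnot(inherits(x, "interval_tracks"))
  if (nrow(x) == 0) return(x)
  key <- paste(x$unit_id, x$track_concept, vkey(x), sep = "\r")
  parts <- split(seq_len(nrow(x)), key)
  out <- lapply(parts, function(idx) {
    rows <- x[idx, ]
    sp <- merge_spans(tp_num(rows$start), tp_num(rows$end))
    tpl <- rows[1, ]
    res <- tpl[rep(1, nrow(sp)), ]
    res$start <- tp_from_num(sp[, "s"])
    res$end <- tp_from_num(sp[, "e"])
    res
  })
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$unit_id, .data$track_concept, .data$start, .data$end)
  new_interval_tracks(res, exclusions = exclusions(x))
}

#' Total covered duration of interval tracks
#'
#' Duration of the union of a unit's intervals in seconds, regardless of how
#' many values cover an instant (overlap between distinct values is not
#' double counted).
#'
#' @param x an `interval_tracks` collection.
#' @param units optional character vector of unit ids to report (defaults to
#'   units present in `x`); units with no records report 0.
#' @return tibble (unit_id, duration_s).
#' @export
total_duration <- function(x, units = NULL) {
  stopifnot(inherits(x, "interval_tracks"))
  units <- units %||% unique(x$unit_id)
  dur <- vapply(units, function(u) {
    rows <- x[x$unit_id == u, ]
    sp <- merge_spans(tp_num(rows$start), tp_num(rows$end))
    sum(sp[, "e"] - sp[, "s"])
  }, numeric(1))
  tibble::tibble(unit_id = as.character(units), duration_s = unname(dur))
}

# clip one unit's payload records to a set of disjoint mask spans.
# Positive-length records are cut to the overlap; point events survive iff
# they lie inside a mask span (half-open membership).
clip_rows_to_spans <- function(rows, spans) {
  if (nrow(rows) == 0 || nrow(spans) == 0) return(rows[0, ])
  s0 <- tp_num(rows$start); e0 <- tp_num(rows$end)
  is_point <- s0 == e0
  out <- vector("list", nrow(spans))
  for (j in seq_len(nrow(spans))) {
    ms <- spans[j, "s"]; me <- spans[j, "e"]
    ns <- pmax(s0, ms); ne <- pmin(e0, me)
    keep <- (!is_point & ns < ne) | (is_point & s0 >= ms & s0 < me)
    if (!any(keep)) next
    part <- rows[keep, ]
    part$start <- tp_from_num(ns[keep])
    part$end <- tp_from_num(ifelse(is_point[keep], s0[keep], ne[keep]))
    out[[j]] <- part
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) rows[0, ] else res
}

#' Intersect two interval-track collections
#'
#' Per unit, the covered time of the result is the set intersection of the
#' two tracks' covered time. Value semantics follow the payload/mask idiom:
#' the result carries the left operand's values (e.g. a drug concept
#' surviving masking by a 90-day window, so a later count-distinct still
#' sees the drug).
#'
#' @param a payload track collection (values kept).
#' @param b mask track collection (only its covered time matters).
#' @param concept optional concept for the derived track; default keeps
#'   `a`'s concepts.
#' @return `interval_tracks`, coalesced.
#' @export
intersect_tracks <- function(a, b, concept = NULL) {
  stopifnot(inherits(a, "interval_tracks"), inherits(b, "interval_tracks"))
  units <- unique(a$unit_id)
  out <- lapply(units, function(u) {
    rows <- a[a$unit_id == u, ]
    mk <- b[b$unit_id == u, ]
    spans <- merge_spans(tp_num(mk$start), tp_num(mk$end))
    spans <- spans[spans[, "e"] > spans[, "s"], , drop = FALSE]
    clip_rows_to_spans(rows, spans)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) res <- a[0, ]
  if (!is.null(concept)) res$track_concept <- concept
  coalesce_tracks(new_interval_tracks(res))
}

#' Union of two interval-track collections
#'
#' Per unit, all records of both operands are retained — distinct values
#' stay distinct records (so a later count-distinct still distinguishes
#' them) — and records of equal value are coalesced. Covered time is the
#' set union.
#'
#' @inheritParams intersect_tracks
#' @param concept optional concept for the derived track; default keeps each
#'   record's own concept.
#' @return `interval_tracks`, coalesced.
#' @export
union_tracks <- function(a, b, concept = NULL) {
  stopifnot(inherits(a, "interval_tracks"), inherits(b, "interval_tracks"))
  res <- dplyr::bind_rows(a, b)
  res <- new_interval_tracks(res)
  if (!is.null(concept)) res$track_concept <- concept
  coalesce_tracks(res)
}

#' Shift or widen intervals into derived windows
#'
#' Builds an artificial period from each record by anchoring at its start or
#' end and applying signed offsets: the 90 days before a hospital stay is
#' `shift_window(stay, "start", -90 * DAY_S, 0)`; the 10 minutes after a
#' drug administration is `shift_window(events, "start", 0, 600)`.
#'
#' @param x an `interval_tracks` collection.
#' @param anchor `"start"` or `"end"`: the record endpoint offsets apply to.
#' @param offset_start,offset_end signed offsets in seconds added to the
#'   anchor to give the new interval `[anchor + offset_start,
#'   anchor + offset_end)`.
#' @param concept optional concept for the derived track.
#' @return `interval_tracks` with one window per input record.
#' @export
shift_window <- function(x, anchor = c("start", "end"),
                         offset_start = 0, offset_end = 0, concept = NULL) {
  stopifnot(inherits(x, "interval_tracks"))
  anchor <- match.arg(anchor)
  if (offset_end < offset_start) {
    stop("window offsets invert the interval (offset_end < offset_start)",
         call. = FALSE)
  }
  a <- tp_num(if (anchor == "start") x$start else x$end)
  res <- x
  res$start <- tp_from_num(a + offset_start)
  res$end <- tp_from_num(a + offset_end)
  if (!is.null(concept)) res$track_concept <- concept
  new_interval_tracks(res, exclusions = exclusions(x))
}

#' Observation periods for a drug-drug interaction
#'
#' For every maximal episode `[s, e)` where both exposures overlap, emits
#' the window starting the day after the two drugs were first administered
#' together and ending 4 days after the first of the two was discontinued:
#' `[s + 1 day, e + 4 days)`. Applied per overlap episode so re-exposure
#' yields one window per episode.
#'
#' @param a,b coalesced exposure track collections.
#' @param concept concept for the derived track.
#' @return `interval_tracks` with one record per overlap episode.
#' @export
ddi_observation_period <- function(a, b, concept = "ddi_observation") {
  stopifnot(inherits(a, "interval_tracks"), inherits(b, "interval_tracks"))
  units <- intersect(unique(a$unit_id), unique(b$unit_id))
  out <- lapply(units, function(u) {
    ra <- a[a$unit_id == u, ]; rb <- b[b$unit_id == u, ]
    sa <- merge_spans(tp_num(ra$start), tp_num(ra$end))
    sb <- merge_spans(tp_num(rb$start), tp_num(rb$end))
    ov <- span_intersection(sa, sb)
    ov <- ov[ov[, "e"] > ov[, "s"], , drop = FALSE]
    if (nrow(ov) == 0) return(NULL)
    s <- ov[, "s"] + DAY_S
    e <- ov[, "e"] + 4 * DAY_S
    keep <- s < e
    if (!any(keep)) return(NULL)
    interval_tracks(rep(u, sum(keep)), tp_from_num(s[keep]), tp_from_num(e[keep]),
                    track_concept = concept, person_id = ra$person_id[1])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(interval_tracks(track_concept = concept))
  }
  new_interval_tracks(res)
}

# intersection of two disjoint sorted span sets
span_intersection <- function(sa, sb) {
  if (nrow(sa) == 0 || nrow(sb) == 0) return(cbind(s = numeric(0), e = numeric(0)))
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(sa))) {
    s <- pmax(sa[i, "s"], sb[, "s"])
    e <- pmin(sa[i, "e"], sb[, "e"])
    keep <- s < e
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  o <- order(out_s)
  cbind(s = out_s[o], e = out_e[o])
}

#' Unit-level boolean track from an event count
#'
#' Emits, per unit, one record spanning `window` with value 1 when at least
#' `min_count` point events fall inside the window (half-open: an event at
#' the window end is excluded), and nothing otherwise. Encodes rules such as
#' "at least 3 antibiotic therapies".
#'
#' @param events point-event `interval_tracks`.
#' @param min_count minimum number of events required (>= 1).
#' @param window a `periods` tibble (unit_id, start, end) giving the
#'   counting window per unit, or a length-2 vector applied to every unit.
#' @param concept concept for the derived track.
#' @return `interval_tracks` with 0 or 1 record per unit.
#' @export
count_condition_track <- function(events, min_count, window,
                                  concept = "condition_met") {
  stopifnot(inherits(events, "interval_tracks"), min_count >= 1)
  if (!is.data.frame(window)) {
    window <- tibble::tibble(unit_id = unique(events$unit_id),
                             start = as_timepoint(window[[1]]),
                             end = as_timepoint(window[[2]]))
  }
  out <- lapply(seq_len(nrow(window)), function(i) {
    u <- window$unit_id[i]
    ws <- tp_num(as_timepoint(window$start[i])); we <- tp_num(as_timepoint(window$end[i]))
    rows <- events[events$unit_id == u, ]
    t <- tp_num(rows$start)
    n <- sum(t >= ws & t < we)
    if (n < min_count) return(NULL)
    interval_tracks(u, tp_from_num(ws), tp_from_num(we), track_concept = concept,
                    person_id = rows$person_id[1] %||% u)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(interval_tracks(track_concept = concept))
  new_interval_tracks(res)
}

#' Keep the period records that contain enough events
#'
#' Generalizes [count_condition_track()] from one window per unit to a track
#' of candidate windows: each record of `periods_track` is kept iff at least
#' `min_count` point events fall inside it (half-open). Used e.g. to flag
#' the drug-interaction observation windows in which an INR excursion
#' occurred.
#'
#' @param periods_track `interval_tracks` of candidate windows.
#' @param events point-event `interval_tracks` on the same units.
#' @param min_count minimum events required inside a window (>= 1).
#' @return the qualifying subset of `periods_track` records.
#' @export
mark_periods_containing <- function(periods_track, events, min_count = 1) {
  stopifnot(inherits(periods_track, "interval_tracks"),
            inherits(events, "interval_tracks"), min_count >= 1)
  if (nrow(periods_track) == 0) return(periods_track)
  keep <- vapply(seq_len(nrow(periods_track)), function(i) {
    u <- periods_track$unit_id[i]
    s <- tp_num(periods_track$start[i]); e <- tp_num(periods_track$end[i])
    t <- tp_num(events$start[events$unit_id == u])
    sum(t >= s & t < e) >= min_count
  }, logical(1))
  new_interval_tracks(periods_track[keep, ], exclusions = exclusions(periods_track))
}

#' Per-unit exclusion log
#'
#' Operations that drop a statistical unit (missing milestone, undefined
#' reference, inverted period) record the unit and reason; downstream code
#' can always reconcile `count(input units) == count(output units) +
#' count(excluded units)`.
#'
#' @param x an object produced by a track or aggregation operation.
#' @return tibble (unit_id, reason).
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||% empty_exclusions()
}

empty_exclusions <- function() {
  tibble::tibble(unit_id = character(), reason = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
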