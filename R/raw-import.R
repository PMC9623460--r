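# From raw OMOP-style event tables to tracks: concept-set selection, stay
# and exposure intervals, milestone selection and period-of-interest
# construction. Raw tables are plain data frames with OMOP-convention column
# names (person_id, drug_concept_id, drug_exposure_start_date, ...).

#' Define a concept set
#'
#' A flat list of (vocabulary, code) pairs selecting clinical events, with
#' optional prefix matching (dot-stripped ICD10 dialect: member `I95`
#' flagged `is_prefix` matches `I95.1`) and an optional mapping target per
#' member (e.g. raw ATC codes mapped to the wider category "VKA").
#'
#' @param set_id identifier of the set (becomes the track concept).
#' @param vocabulary,code character vectors defining the members.
#' @param is_prefix logical per member: match codes by prefix after
#'   removing dots.
#' @param target_concept optional mapped concept substituted for matching
#'   records; `NA` keeps the raw code.
#' @return tibble of class `concept_set`.
#' @export
concept_set <- function(set_id, vocabulary = character(), code = character(),
                        is_prefix = FALSE, target_concept = NA_character_) {
  n <- length(code)
  df <- tibble::tibble(
    set_id = rep_len(as.character(set_id), max(n, 0)),
    vocabulary = rep_len(as.character(vocabulary), n),
    code = as.character(code),
    is_prefix = rep_len(as.logical(is_prefix), n),
    target_concept = rep_len(as.character(target_concept), n)
  )
  if (anyDuplicated(df[c("vocabulary", "code")])) {
    stop("duplicate codes in concept set ", set_id, call. = FALSE)
  }
  attr(df, "set_id") <- as.character(set_id)
  class(df) <- c("concept_set", class(tibble::tibble()))
  df
}

#' Read a concept set from a delimited file
#'
#' Expects columns `set_id, vocabulary, code, is_prefix, target_concept`.
#' @param path CSV file path.
#' @return `concept_set`.
#' @export
read_concept_set <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  concept_set(df$set_id[1], df$vocabulary, df$code,
              is_prefix = tolower(df$is_prefix) %in% c("true", "1", "t", "yes"),
              target_concept = ifelse(df$target_concept == "", NA, df$target_concept))
}

strip_dots <- function(x) gsub(".", "", x, fixed = TRUE)

# map raw codes against a set; returns target concept per row (NA = no match)
match_concept_set <- function(code, set, vocabulary = NULL) {
  members <- set
  if (!is.null(vocabulary)) {
    if (!all(vocabulary %in% set$vocabulary)) {
      stop("unknown vocabulary label: ",
           paste(setdiff(vocabulary, set$vocabulary), collapse = ", "), call. = FALSE)
    }
    members <- set[set$vocabulary %in% vocabulary, ]
  }
  code_n <- strip_dots(as.character(code))
  out <- rep(NA_character_, length(code))
  for (i in seq_len(nrow(members))) {
    m <- strip_dots(members$code[i])
    hit <- if (isTRUE(members$is_prefix[i])) startsWith(code_n, m) else code_n == m
    hit[is.na(hit)] <- FALSE
    fill <- hit & is.na(out)
    out[fill] <- if (is.na(members$target_concept[i])) as.character(code)[fill] else members$target_concept[i]
  }
  out
}

# resolve raw rows to statistical units via a unit map (tibble with unit_id
# + one join column). NULL map: person is the unit. The join may be
# one-to-many (a person with two hospital stays contributes every exposure
# row to both stay units): the result gives, per output record, the source
# row index `idx` and its `unit_id`.
resolve_units <- function(raw, unit_map, on_unresolved = c("drop", "error")) {
  on_unresolved <- match.arg(on_unresolved)
  if (is.null(unit_map)) {
    return(list(idx = seq_len(nrow(raw)), unit_id = as.character(raw$person_id)))
  }
  keys <- intersect(c("visit_occurrence_id", "procedure_occurrence_id",
                      "anchor_id", "person_id"),
                    intersect(names(unit_map), names(raw)))
  if (length(keys) == 0) stop("unit map shares no join column with the raw table", call. = FALSE)
  key <- keys[1]
  um <- split(as.character(unit_map$unit_id), as.character(unit_map[[key]]))
  matches <- um[as.character(raw[[key]])]
  counts <- lengths(matches)
  unresolved <- counts == 0
  if (any(unresolved)) {
    if (on_unresolved == "error") {
      stop(sum(unresolved), " matched row(s) with unresolvable statistical unit", call. = FALSE)
    }
    warning(sum(unresolved), " row(s) dropped: unresolvable statistical unit", call. = FALSE)
  }
  list(idx = rep(seq_len(nrow(raw)), counts),
       unit_id = as.character(unlist(matches, use.names = FALSE)))
}

# first present column name
pick_col <- function(df, candidates, what) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit) == 0) stop("no ", what, " column found (looked for ",
                             paste(candidates, collapse = ", "), ")", call. = FALSE)
  hit[1]
}

#' Select raw events matching a concept set as a point-event track
#'
#' One zero-length record per matching row; rows whose code is outside the
#' set are dropped; when the set defines a mapping target the record's
#' value carries the mapped concept (otherwise the raw code).
#'
#' @param raw event table (drug_exposure, procedure_occurrence, ...).
#' @param concepts a [concept_set()].
#' @param unit_map optional tibble mapping a raw join column
#'   (`person_id`/`visit_occurrence_id`/...) to `unit_id`; default person is
#'   the unit.
#' @param code_col,time_col column holding the code / event time; guessed
#'   from OMOP conventions when omitted.
#' @param vocabulary restrict matching to these vocabulary labels (must
#'   exist in the set).
#' @param on_unresolved what to do with matched rows whose unit cannot be
#'   resolved: drop with a warning (default) or error.
#' @param concept track concept of the output; defaults to the set id.
#' @return point-event `interval_tracks`.
#' @export
select_events <- function(raw, concepts, unit_map = NULL, code_col = NULL,
                          time_col = NULL, vocabulary = NULL,
                          on_unresolved = c("drop", "error"), concept = NULL) {
  stopifnot(inherits(concepts, "concept_set"))
  raw <- tibble::as_tibble(raw)
  code_col <- code_col %||% pick_col(raw, c("drug_concept_id", "procedure_concept_id",
                                            "condition_concept_id", "measurement_concept_id",
                                            "concept_code", "code"), "concept code")
  time_col <- time_col %||% pick_col(raw, c("drug_exposure_start_datetime",
                                            "drug_exposure_start_date",
                                            "procedure_datetime", "procedure_date",
                                            "condition_start_datetime", "condition_start_date",
                                            "measurement_datetime", "event_datetime",
                                            "datetime", "date"), "event time")
  concept <- concept %||% attr(concepts, "set_id")
  mapped <- match_concept_set(raw[[code_col]], concepts, vocabulary)
  raw <- raw[!is.na(mapped), ]
  mapped <- mapped[!is.na(mapped)]
  if (nrow(raw) == 0) return(interval_tracks(track_concept = concept))
  res <- resolve_units(raw, unit_map, match.arg(on_unresolved))
  raw <- raw[res$idx, ]; mapped <- mapped[res$idx]
  t <- as_timepoint(raw[[time_col]])
  interval_tracks(res$unit_id, t, t, track_concept = concept,
                  value_concept = mapped,
                  person_id = as.character(raw$person_id),
                  source_value = as.character(raw[[code_col]]),
                  visit_occurrence_id = if ("visit_occurrence_id" %in% names(raw))
                    as.character(raw$visit_occurrence_id) else NULL)
}

#' Build stay intervals from start/end date fields
#'
#' One record per row with value 1. When both fields are day-granular dates
#' the interval is `[start, end + 1 day)` — the discharge day is occupied,
#' and a same-day stay is a real 1-day stay. Datetime fields are taken as
#' exact bounds. Rows with `end < start` are rejected (see
#' `attr(, "rejects")`); a missing end is censored at `censor_end` when
#' given, otherwise rejected.
#'
#' @param raw visit-style table.
#' @param start_field,end_field column names, e.g. `"visit_start_date"`.
#' @param unit_map optional unit resolution (see [select_events()]); default
#'   one unit per row keyed by `visit_occurrence_id` (or person).
#' @param concept track concept of the output.
#' @param censor_end optional study-end instant closing open-ended stays.
#' @return `interval_tracks`; rejected rows in `attr(, "rejects")`.
#' @export
interval_from_fields <- function(raw, start_field = "visit_start_date",
                                 end_field = "visit_end_date", unit_map = NULL,
                                 concept = "stay", censor_end = NULL) {
  raw <- tibble::as_tibble(raw)
  sv <- as.character(raw[[start_field]]); ev <- as.character(raw[[end_field]])
  day_granular <- !grepl("[T ]", sv)
  start <- as_timepoint(sv)
  end <- as_timepoint(ev)
  rejects <- tibble::tibble(row = integer(), reason = character())
  open_ended <- is.na(end) | ev == ""
  if (any(open_ended)) {
    if (!is.null(censor_end)) {
      end[open_ended] <- as_timepoint(censor_end)
      day_granular[open_ended] <- FALSE  # censor instant is exact
    } else {
      rejects <- dplyr::bind_rows(rejects,
        tibble::tibble(row = which(open_ended), reason = "missing end date"))
    }
  }
  # day-inclusive convention for day-level data
  end_adj <- tp_from_num(tp_num(end) + ifelse(day_granular, DAY_S, 0))
  inverted <- !is.na(end) & !open_ended & tp_num(end) < tp_num(start)
  rejects <- dplyr::bind_rows(rejects,
    tibble::tibble(row = which(inverted), reason = "end precedes start"))
  keep <- !inverted & !(open_ended & is.null(censor_end))
  keep[is.na(keep)] <- FALSE
  raw2 <- raw[keep, ]
  start <- start[keep]; end_adj <- end_adj[keep]
  if (is.null(unit_map) && "visit_occurrence_id" %in% names(raw2)) {
    uid <- as.character(raw2$visit_occurrence_id)
  } else if (is.null(unit_map)) {
    uid <- as.character(raw2$person_id)
  } else {
    res <- resolve_units(raw2, unit_map)
    raw2 <- raw2[res$idx, ]
    start <- start[res$idx]; end_adj <- end_adj[res$idx]
    uid <- res$unit_id
  }
  out <- interval_tracks(uid, start, end_adj, track_concept = concept,
                         person_id = as.character(raw2$person_id),
                         visit_occurrence_id = if ("visit_occurrence_id" %in% names(raw2))
                           as.character(raw2$visit_occurrence_id) else NULL)
  attr(out, "rejects") <- rejects
  out
}

#' Build drug-exposure intervals from start date + days of supply
#'
#' One record `[start, start + days)` per row, carrying the drug concept as
#' its value. A zero days-supply still evidences exposure on the dispensing
#' day and becomes a 1-day exposure; a negative duration rejects the row.
#' Overlapping refills of the same drug coalesce via [coalesce_tracks()].
#'
#' @param raw drug_exposure-style table.
#' @param unit_map optional unit resolution (see [select_events()]).
#' @param start_col,duration_col,code_col column names (OMOP defaults).
#' @param concept track concept of the output.
#' @return `interval_tracks`; rejected rows in `attr(, "rejects")`.
#' @export
exposure_intervals <- function(raw, unit_map = NULL,
                               start_col = "drug_exposure_start_date",
                               duration_col = "days_supply",
                               code_col = "drug_concept_id",
                               concept = "drug_exposure") {
  raw <- tibble::as_tibble(raw)
  days <- as.numeric(raw[[duration_col]])
  days[is.na(days)] <- 0
  rejects <- tibble::tibble(row = which(days < 0), reason = rep("negative duration", sum(days < 0)))
  keep <- days >= 0
  raw2 <- raw[keep, ]; days <- pmax(days[keep], 1)
  res <- resolve_units(raw2, unit_map)
  raw2 <- raw2[res$idx, ]; days <- days[res$idx]
  start <- as_timepoint(raw2[[start_col]])
  out <- interval_tracks(res$unit_id, start,
                         tp_from_num(tp_num(start) + days * DAY_S),
                         track_concept = concept,
                         value_concept = as.character(raw2[[code_col]]),
                         person_id = as.character(raw2$person_id),
                         visit_occurrence_id = if ("visit_occurrence_id" %in% names(raw2))
                           as.character(raw2$visit_occurrence_id) else NULL)
  attr(out, "rejects") <- rejects
  out
}

#' Filter and map a track's values through a concept set
#'
#' Keeps the records whose value matches the set (exact or prefix,
#' dot-stripped) and substitutes the member's target concept where one is
#' defined — e.g. collapsing raw ATC codes onto the wider category "VKA"
#' before interval algebra.
#'
#' @param x an `interval_tracks` collection with categorical values.
#' @param concepts a [concept_set()].
#' @param vocabulary optional restriction to these vocabulary labels.
#' @param concept optional new track concept for the result.
#' @return filtered, remapped `interval_tracks`.
#' @export
map_track_values <- function(x, concepts, vocabulary = NULL, concept = NULL) {
  stopifnot(inherits(x, "interval_tracks"), inherits(concepts, "concept_set"))
  mapped <- match_concept_set(x$value_concept, concepts, vocabulary)
  out <- x[!is.na(mapped), ]
  out$value_concept <- mapped[!is.na(mapped)]
  if (!is.null(concept)) out$track_concept <- concept
  new_interval_tracks(out, exclusions = exclusions(x))
}

#' Point-event track from measurement values passing a condition
#'
#' Selects measurement instants — optionally only those whose value passes
#' a comparison, encoding rules like "at least one INR >= 5" as an episode
#' track of the excursion instants.
#'
#' @param measurement OMOP-style measurement table.
#' @param concept_id filter on `measurement_concept_id`.
#' @param comparator,threshold optional value condition (`">="`, 5).
#' @param unit_map optional unit resolution (see [select_events()]).
#' @param concept track concept of the output.
#' @return point-event `interval_tracks` whose records carry the measured
#'   value.
#' @export
measurement_events <- function(measurement, concept_id, comparator = NULL,
                               threshold = NULL, unit_map = NULL,
                               concept = concept_id) {
  s <- measurement_samples(measurement, unit_map = unit_map, concept_id = concept_id)
  if (!is.null(comparator)) {
    cmp_fun <- switch(match.arg(comparator, c("<", "<=", ">", ">=")),
                      "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`)
    s <- s[cmp_fun(s$value, threshold), ]
  }
  interval_tracks(s$unit_id, s$time, s$time, track_concept = concept,
                  value_num = s$value, person_id = s$person_id)
}

#' Milestone selection rule
#'
#' The start (or end) of a procedure may be documented by several distinct
#' events — e.g. induction, hypnotic administration, intubation, mechanical
#' ventilation — and a priority rule selects the main one.
#'
#' @param candidates concept identifiers, highest priority first.
#' @param fallback when no candidate concept is present for a unit:
#'   `"first"`/`"last"` take the earliest/latest event of any concept,
#'   `"error"` excludes the unit.
#' @param tie within the selected concept, take the `"first"` (earliest,
#'   default) or `"last"` event.
#' @return list of class `milestone_rule`.
#' @export
milestone_rule <- function(candidates, fallback = c("first", "last", "error"),
                           tie = c("first", "last")) {
  stopifnot(length(candidates) >= 1)
  structure(list(candidates = as.character(candidates),
                 fallback = match.arg(fallback), tie = match.arg(tie)),
            class = "milestone_rule")
}

#' Select one milestone instant per unit
#'
#' Applies a [milestone_rule()] to a point-event track: the tie-selected
#' event of the highest-priority concept present; if no candidate concept is
#' present, the fallback; units with no usable event are excluded and
#' logged.
#'
#' @param events point-event `interval_tracks` whose values identify the
#'   event concepts.
#' @param rule a [milestone_rule()].
#' @param units unit ids to resolve (defaults to units present in
#'   `events`); listed units with no events are reported as excluded.
#' @return tibble (unit_id, milestone); exclusions via [exclusions()].
#' @export
select_milestone <- function(events, rule, units = NULL) {
  stopifnot(inherits(events, "interval_tracks"), inherits(rule, "milestone_rule"))
  units <- as.character(units %||% unique(events$unit_id))
  excl <- empty_exclusions()
  pickt <- function(t) if (rule$tie == "first") min(t) else max(t)
  rows <- lapply(units, function(u) {
    ev <- events[events$unit_id == u, ]
    for (cand in rule$candidates) {
      hit <- ev[!is.na(ev$value_concept) & ev$value_concept == cand, ]
      if (nrow(hit) > 0) {
        return(tibble::tibble(unit_id = u, milestone = tp_from_num(pickt(tp_num(hit$start)))))
      }
    }
    if (rule$fallback == "error" || nrow(ev) == 0) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "missing milestone"))
      return(NULL)
    }
    t <- tp_num(ev$start)
    m <- if (rule$fallback == "first") min(t) else max(t)
    tibble::tibble(unit_id = u, milestone = tp_from_num(m))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) res <- tibble::tibble(unit_id = character(), milestone = tp_from_num(numeric(0)))
  attr(res, "exclusions") <- excl
  res
}

#' Build periods of interest from start and end milestones
#'
#' One half-open window per unit: `[start + offset_start,
#' end + offset_end)`. Units missing either milestone, or whose period
#' inverts after offsets, are excluded with a logged reason. A zero-length
#' period is legal (aggregations over it return empty-period results).
#'
#' @param start_milestones,end_milestones tibbles (unit_id, milestone) as
#'   returned by [select_milestone()].
#' @param offset_start,offset_end signed offsets in seconds.
#' @return tibble (unit_id, start, end); exclusions via [exclusions()]
#'   (including those carried by the milestone inputs).
#' @export
build_period <- function(start_milestones, end_milestones,
                         offset_start = 0, offset_end = 0) {
  excl <- dplyr::bind_rows(exclusions(start_milestones), exclusions(end_milestones))
  units <- union(start_milestones$unit_id, end_milestones$unit_id)
  rows <- lapply(units, function(u) {
    s <- start_milestones$milestone[start_milestones$unit_id == u]
    e <- end_milestones$milestone[end_milestones$unit_id == u]
    if (length(s) == 0 || length(e) == 0) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(
        unit_id = u,
        reason = if (length(s) == 0) "missing start milestone" else "missing end milestone"))
      return(NULL)
    }
    ps <- tp_num(s[1]) + offset_start; pe <- tp_num(e[1]) + offset_end
    if (pe < ps) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "inverted period"))
      return(NULL)
    }
    tibble::tibble(unit_id = u, start = tp_from_num(ps), end = tp_from_num(pe))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble::tibble(unit_id = character(),
                          start = tp_from_num(numeric(0)), end = tp_from_num(numeric(0)))
  }
  attr(res, "exclusions") <- dplyr::distinct(excl)
  res
}

#' Periods of interest from a one-record-per-unit track
#'
#' @param x coalesced `interval_tracks` with at most one record per unit.
#' @return tibble (unit_id, start, end).
#' @export
periods_from_track <- function(x) {
  stopifnot(inherits(x, "interval_tracks"))
  if (anyDuplicated(x$unit_id)) {
    stop("track has multiple records for one unit; coalesce or aggregate first",
         call. = FALSE)
  }
  tibble::tibble(unit_id = x$unit_id, person_id = x$person_id,
                 start = x$start, end = x$end)
}
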