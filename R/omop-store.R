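# Flat-file persistence of tracks and features in OMOP-convention TRACK and
# FEATURE tables. UTF-8, comma-delimited, ISO-8601 timestamps, empty string
# = absent, one header row. Date columns hold the date part of the paired
# datetime columns (OMOP's date/datetime convention; the in-memory model is
# second-granular).

TRACK_TABLE_COLS <- c("track_id", "person_id", "track_concept_id",
                      "track_type_concept_id", "track_start_date",
                      "track_start_datetime", "track_end_date",
                      "track_end_datetime", "value_as_number",
                      "value_as_concept_id", "visit_occurrence_id",
                      "visit_detail_id", "track_source_value")

FEATURE_TABLE_COLS <- c("feature_id", "person_id", "feature_concept_id",
                        "feature_type_concept_id", "value_as_number",
                        "value_as_concept_id", "visit_occurrence_id",
                        "visit_detail_id", "episode_id", "feature_source_value")

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

# rows of the TRACK table for one collection (interval records, or the
# defined constant pieces of a signal)
track_rows <- function(x) {
  if (inherits(x, "interval_tracks")) {
    visit <- as.character(ifelse(!is.na(x$visit_occurrence_id), x$visit_occurrence_id,
                                 ifelse(x$unit_id != x$person_id, x$unit_id,
                                        NA_character_)))
    tibble::tibble(person_id = x$person_id, track_concept_id = x$track_concept,
                   s = tp_num(x$start), e = tp_num(x$end),
                   value_as_number = x$value_num, value_as_concept_id = x$value_concept,
                   visit_occurrence_id = visit, track_source_value = x$source_value)
  } else if (inherits(x, "signal_tracks")) {
    parts <- lapply(unique(x$unit_id), function(u) {
      rows <- x[x$unit_id == u, ]
      segs <- unit_segments(rows)
      if (nrow(segs) == 0) return(NULL)
      tibble::tibble(person_id = rows$person_id[1], track_concept_id = rows$track_concept[1],
                     s = segs$s, e = segs$e, value_as_number = segs$value,
                     value_as_concept_id = NA_character_,
                     visit_occurrence_id = if (rows$unit_id[1] != rows$person_id[1]) u else NA_character_,
                     track_source_value = NA_character_)
    })
    dplyr::bind_rows(parts)
  } else {
    stop("not a track collection", call. = FALSE)
  }
}

#' Write track collections to a TRACK table
#'
#' One row per interval record and one per defined constant piece of a
#' signal (storing segments rather than samples keeps voluminous signal
#' tracks compact). Rows are ordered by (person, concept, start) and ids
#' assigned sequentially from 1, so identical collections produce
#' byte-identical files.
#'
#' @param tracks one collection or a (possibly named) list of
#'   `interval_tracks` / `signal_tracks`.
#' @param path destination CSV.
#' @param track_type value of `track_type_concept_id` for every row.
#' @return number of rows written, invisibly.
#' @export
write_tracks <- function(tracks, path, track_type = "feature_extraction_derived") {
  if (!is.list(tracks) || inherits(tracks, c("interval_tracks", "signal_tracks"))) {
    tracks <- list(tracks)
  }
  rows <- dplyr::bind_rows(lapply(tracks, track_rows))
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(person_id = character(), track_concept_id = character(),
                           s = numeric(), e = numeric(), value_as_number = numeric(),
                           value_as_concept_id = character(),
                           visit_occurrence_id = character(), track_source_value = character())
  }
  rows <- rows[order(rows$person_id, rows$track_concept_id, rows$s, rows$e,
                     fmt_num(rows$value_as_number), rows$value_as_concept_id,
                     method = "radix"), ]
  out <- tibble::tibble(
    track_id = as.character(seq_len(nrow(rows))),
    person_id = rows$person_id,
    track_concept_id = rows$track_concept_id,
    track_type_concept_id = rep(track_type, nrow(rows)),
    track_start_date = fmt_date(tp_from_num(rows$s)),
    track_start_datetime = fmt_datetime(tp_from_num(rows$s)),
    track_end_date = fmt_date(tp_from_num(rows$e)),
    track_end_datetime = fmt_datetime(tp_from_num(rows$e)),
    value_as_number = fmt_num(rows$value_as_number),
    value_as_concept_id = rows$value_as_concept_id,
    visit_occurrence_id = rows$visit_occurrence_id,
    visit_detail_id = NA_character_,
    track_source_value = rows$track_source_value
  )
  readr::write_csv(out, path, na = "")
  invisible(nrow(out))
}

read_table_checked <- function(path, required) {
  df <- tibble::as_tibble(utils::read.csv(path, colClasses = "character"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    warning("ignoring extra column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df[df == ""] <- NA
  df
}

#' Read a TRACK table back into track collections
#'
#' Rows are grouped by (unit, concept); concepts listed in
#' `signal_concepts` are rebuilt as `signal_tracks` (abutting numeric
#' segment rows become breakpoints, non-abutting rows leave undefined
#' gaps), all others as `interval_tracks`. The statistical unit is the
#' visit when `visit_occurrence_id` is populated, otherwise the person.
#' Malformed rows (both value slots empty, end before start) are collected
#' in `attr(, "rejects")` with their line numbers.
#'
#' @param path TRACK CSV path.
#' @param signal_concepts concepts to rebuild as signals.
#' @return named list of collections, one per track concept.
#' @export
read_tracks <- function(path, signal_concepts = character()) {
  df <- read_table_checked(path, TRACK_TABLE_COLS)
  if (anyDuplicated(df$track_id[!is.na(df$track_id)])) {
    stop("duplicate track_id on read", call. = FALSE)
  }
  rejects <- tibble::tibble(line = integer(), reason = character())
  no_value <- is.na(df$value_as_number) & is.na(df$value_as_concept_id)
  s <- as_timepoint(df$track_start_datetime)
  e <- as_timepoint(df$track_end_datetime)
  inverted <- !is.na(s) & !is.na(e) & tp_num(e) < tp_num(s)
  bad <- no_value | inverted
  if (any(bad)) {
    rejects <- tibble::tibble(
      line = which(bad) + 1L,  # header is line 1
      reason = ifelse(no_value[bad], "no value slot populated", "end precedes start"))
  }
  df <- df[!bad, ]; s <- s[!bad]; e <- e[!bad]
  unit_id <- ifelse(!is.na(df$visit_occurrence_id), df$visit_occurrence_id, df$person_id)
  out <- lapply(split(seq_len(nrow(df)), df$track_concept_id), function(idx) {
    sub <- df[idx, ]
    if (sub$track_concept_id[1] %in% signal_concepts) {
      parts <- lapply(split(idx, unit_id[idx]), function(j) {
        o <- j[order(tp_num(s[j]))]
        segs <- data.frame(s = tp_num(s[o]), e = tp_num(e[o]),
                           value = as.numeric(df$value_as_number[o]))
        tpl <- tibble::tibble(unit_id = unit_id[o[1]], person_id = df$person_id[o[1]],
                              track_concept = df$track_concept_id[o[1]],
                              time = tp_from_num(0), value = NA_real_,
                              domain_start = tp_from_num(0), domain_end = tp_from_num(0))
        segments_to_rows(segs, tpl, segs$s[1], segs$e[nrow(segs)])
      })
      new_signal_tracks(dplyr::bind_rows(parts))
    } else {
      new_interval_tracks(tibble::tibble(
        unit_id = unit_id[idx], person_id = sub$person_id,
        track_concept = sub$track_concept_id,
        start = s[idx], end = e[idx],
        value_num = as.numeric(sub$value_as_number),
        value_concept = sub$value_as_concept_id,
        source_value = sub$track_source_value,
        visit_occurrence_id = sub$visit_occurrence_id))
    }
  })
  attr(out, "rejects") <- rejects
  out
}

#' Write features to a FEATURE table
#'
#' Exactly one value slot per row; `episode_id` carries the occurrence
#' discriminator when one unit yields several occurrences of a feature;
#' `feature_source_value` carries the producing definition id (provenance
#' is never dropped). Deterministic ordering and sequential ids as in
#' [write_tracks()].
#'
#' @param features a `features` tibble (or list of them).
#' @param path destination CSV.
#' @param feature_type value of `feature_type_concept_id` for every row.
#' @return number of rows written, invisibly.
#' @export
write_features <- function(features, path, feature_type = "feature_extraction_derived") {
  if (is.list(features) && !is.data.frame(features)) {
    features <- dplyr::bind_rows(features)
  }
  x <- new_features(features)
  visit <- ifelse(x$unit_id != x$person_id, x$unit_id, NA_character_)
  rows <- tibble::tibble(
    person_id = x$person_id, feature_concept_id = x$feature_concept,
    value_as_number = x$value_num, value_as_concept_id = x$value_concept,
    visit_occurrence_id = visit, episode_id = x$occurrence_id,
    feature_source_value = x$definition_id)
  rows <- rows[order(rows$person_id, rows$feature_concept_id,
                     rows$visit_occurrence_id, rows$episode_id,
                     fmt_num(rows$value_as_number), rows$value_as_concept_id,
                     method = "radix"), ]
  out <- tibble::tibble(
    feature_id = as.character(seq_len(nrow(rows))),
    person_id = rows$person_id,
    feature_concept_id = rows$feature_concept_id,
    feature_type_concept_id = rep(feature_type, nrow(rows)),
    value_as_number = fmt_num(rows$value_as_number),
    value_as_concept_id = rows$value_as_concept_id,
    visit_occurrence_id = rows$visit_occurrence_id,
    visit_detail_id = NA_character_,
    episode_id = rows$episode_id,
    feature_source_value = rows$feature_source_value
  )
  readr::write_csv(out, path, na = "")
  invisible(nrow(out))
}

#' Read a FEATURE table
#'
#' @param path FEATURE CSV path.
#' @return `features` tibble; the unit is the visit when
#'   `visit_occurrence_id` is populated, otherwise the person. Rows
#'   violating the one-value-slot invariant are collected in
#'   `attr(, "rejects")`; a duplicate `feature_id` is a validation error.
#' @export
read_features <- function(path) {
  df <- read_table_checked(path, FEATURE_TABLE_COLS)
  if (anyDuplicated(df$feature_id[!is.na(df$feature_id)])) {
    stop("duplicate feature_id on read", call. = FALSE)
  }
  no_value <- is.na(df$value_as_number) & is.na(df$value_as_concept_id)
  both <- !is.na(df$value_as_number) & !is.na(df$value_as_concept_id)
  bad <- no_value | both
  rejects <- tibble::tibble(line = which(bad) + 1L,
                            reason = ifelse(no_value[bad], "no value slot populated",
                                            "both value slots populated"))
  df <- df[!bad, ]
  out <- new_features(tibble::tibble(
    unit_id = ifelse(!is.na(df$visit_occurrence_id), df$visit_occurrence_id, df$person_id),
    person_id = df$person_id,
    feature_concept = df$feature_concept_id,
    value_num = as.numeric(df$value_as_number),
    value_concept = df$value_as_concept_id,
    definition_id = df$feature_source_value,
    occurrence_id = df$episode_id))
  attr(out, "rejects") <- rejects
  out
}

#' Validate TRACK/FEATURE files against each other and raw tables
#'
#' Report-based referential-integrity and invariant checking: orphan
#' `person_id`/`visit_occurrence_id` references, date-order violations and
#' value-slot violations. An empty report means the files are consistent.
#'
#' @param track_file,feature_file paths (either may be `NULL`).
#' @param person_file,visit_file optional raw person / visit_occurrence
#'   CSVs used for foreign-key checks.
#' @return tibble (severity, table, row_id, rule, message); zero rows when
#'   everything checks out.
#' @export
validate_tables <- function(track_file = NULL, feature_file = NULL,
                            person_file = NULL, visit_file = NULL) {
  findings <- list()
  note <- function(severity, table, row_id, rule, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      severity = severity, table = table, row_id = as.character(row_id),
      rule = rule, message = message)
  }
  persons <- if (!is.null(person_file)) {
    as.character(utils::read.csv(person_file, colClasses = "character")$person_id)
  } else NULL
  visits <- if (!is.null(visit_file)) {
    as.character(utils::read.csv(visit_file, colClasses = "character")$visit_occurrence_id)
  } else NULL
  check_common <- function(df, table, id_col) {
    no_value <- is.na(df$value_as_number) & is.na(df$value_as_concept_id)
    for (i in which(no_value)) {
      note("error", table, df[[id_col]][i], "value-slot", "no value slot populated")
    }
    both <- !is.na(df$value_as_number) & !is.na(df$value_as_concept_id)
    for (i in which(both)) {
      note("error", table, df[[id_col]][i], "value-slot", "both value slots populated")
    }
    if (!is.null(persons)) {
      for (i in which(!is.na(df$person_id) & !df$person_id %in% persons)) {
        note("error", table, df[[id_col]][i], "orphan-fk",
             paste0("unknown person_id ", df$person_id[i]))
      }
    }
    if (!is.null(visits)) {
      for (i in which(!is.na(df$visit_occurrence_id) & !df$visit_occurrence_id %in% visits)) {
        note("error", table, df[[id_col]][i], "orphan-fk",
             paste0("unknown visit_occurrence_id ", df$visit_occurrence_id[i]))
      }
    }
    dup <- df[[id_col]][duplicated(df[[id_col]])]
    for (d in unique(dup)) note("error", table, d, "duplicate-id", paste0("duplicate ", id_col))
  }
  if (!is.null(track_file)) {
    tr <- read_table_checked(track_file, TRACK_TABLE_COLS)
    check_common(tr, "track", "track_id")
    s <- suppressWarnings(as_timepoint(tr$track_start_datetime))
    e <- suppressWarnings(as_timepoint(tr$track_end_datetime))
    for (i in which(!is.na(s) & !is.na(e) & tp_num(e) < tp_num(s))) {
      note("error", "track", tr$track_id[i], "date-order", "track end precedes start")
    }
    mism <- which(!is.na(s) & !is.na(tr$track_start_date) &
                    fmt_date(s) != tr$track_start_date)
    for (i in mism) note("warning", "track", tr$track_id[i], "date-consistency",
                         "start date differs from datetime's date part")
  }
  if (!is.null(feature_file)) {
    fe <- read_table_checked(feature_file, FEATURE_TABLE_COLS)
    check_common(fe, "feature", "feature_id")
  }
  if (length(findings) == 0) {
    return(tibble::tibble(severity = character(), table = character(),
                          row_id = character(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(findings)
}
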