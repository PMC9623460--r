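# Track aggregation: reducing a track over a period of interest to one
# time-independent feature per statistical unit, with a closed catalogue of
# extraction methods. Features carry no time column — time is implicit in
# the label (e.g. mean_map_before_induction) or in the value (a duration).

SIGNAL_METHODS <- c("min", "max", "mean", "median", "weighted_average")
INTERVAL_METHODS <- c("sum_duration", "count", "count_distinct", "exists",
                      "delay", "first", "last")

FEATURE_COLS <- c("unit_id", "person_id", "feature_concept", "value_num",
                  "value_concept", "definition_id", "occurrence_id")

new_features <- function(df = NULL, exclusions = NULL) {
  if (is.null(df)) {
    df <- tibble::tibble(unit_id = character(), person_id = character(),
                         feature_concept = character(), value_num = numeric(),
                         value_concept = character(), definition_id = character(),
                         occurrence_id = character())
  }
  for (col in FEATURE_COLS) {
    if (!col %in% names(df)) df[[col]] <- if (col == "value_num") NA_real_ else NA_character_
  }
  df <- tibble::as_tibble(df[FEATURE_COLS])
  class(df) <- c("features", class(tibble::tibble()))
  attr(df, "exclusions") <- exclusions %||% empty_exclusions()
  df
}

#' @export
print.features <- function(x, ...) {
  cat("<features> ", nrow(x), " value(s), ",
      length(unique(x$unit_id)), " unit(s)\n", sep = "")
  NextMethod()
}

# weighted median of values with integer-second weights: the median of the
# per-second multiset, matching stats::median on the expanded vector
weighted_median <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  n <- sum(w)
  cum <- cumsum(w)
  if (n %% 2 == 1) {
    v[which(cum >= (n + 1) / 2)[1]]
  } else {
    lo <- v[which(cum >= n / 2)[1]]
    hi <- v[which(cum >= n / 2 + 1)[1]]
    (lo + hi) / 2
  }
}

#' Aggregate a signal track over periods of interest
#'
#' Reduces each unit's signal, restricted to its period, to one value.
#' `mean` and `weighted_average` are the same operation — the time-weighted
#' mean over defined segments (with 1 s resampling this equals the plain
#' mean of per-second values). `min`/`max` range over values attained in the
#' period; `median` is the value-at-time median on the 1 s grid. Undefined
#' time carries no weight. Units whose signal is entirely undefined within
#' the period yield no feature and are reported as excluded.
#'
#' @param x a `signal_tracks` collection.
#' @param periods tibble (unit_id, start, end), optionally `occurrence_id`
#'   when one unit has several periods.
#' @param method one of `min, max, mean, median, weighted_average`.
#' @param feature_concept label of the resulting feature.
#' @return `features` tibble; exclusions via [exclusions()].
#' @export
aggregate_signal <- function(x, periods, method, feature_concept = method) {
  stopifnot(inherits(x, "signal_tracks"))
  if (!method %in% SIGNAL_METHODS) {
    stop("unknown signal extraction method: ", method, call. = FALSE)
  }
  excl <- empty_exclusions()
  has_occ <- "occurrence_id" %in% names(periods)
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    u <- as.character(periods$unit_id[i])
    ps <- tp_num(as_timepoint(periods$start[i])); pe <- tp_num(as_timepoint(periods$end[i]))
    occ <- if (has_occ) as.character(periods$occurrence_id[i]) else NA_character_
    urows <- x[x$unit_id == u, ]
    segs <- unit_segments(urows)
    s <- pmax(segs$s, ps); e <- pmin(segs$e, pe)
    keep <- s < e
    if (!any(keep)) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(
        unit_id = u,
        reason = if (pe <= ps) "empty period" else "signal undefined in period"))
      return(NULL)
    }
    pid <- if ("person_id" %in% names(periods)) as.character(periods$person_id[i]) else urows$person_id[1]
    if (length(pid) == 0 || is.na(pid)) pid <- urows$person_id[1]
    if (length(pid) == 0 || is.na(pid)) pid <- u
    v <- segs$value[keep]; w <- (e - s)[keep]
    val <- switch(method,
      min = min(v),
      max = max(v),
      mean = , weighted_average = sum(v * w) / sum(w),
      median = weighted_median(v, w))
    tibble::tibble(unit_id = u, person_id = pid,
                   feature_concept = feature_concept, value_num = val,
                   value_concept = NA_character_, definition_id = NA_character_,
                   occurrence_id = occ)
  })
  new_features(dplyr::bind_rows(rows), exclusions = excl)
}

#' Aggregate an interval track over periods of interest
#'
#' Records are clipped to each unit's period first (half-open: a point
#' event at the period end is outside). Then: `sum_duration` — total
#' covered time in seconds; `count` — number of clipped records;
#' `count_distinct` — number of distinct values among them; `exists` — 1/0;
#' `delay` — seconds from period start to the earliest clipped record;
#' `first`/`last` — the value of the earliest/latest clipped record (ties
#' broken by stable sort on start then value). An empty clip yields 0 for
#' the count-like methods (the mathematically forced value) but an absent
#' value plus an exclusion record for `delay`/`first`/`last`.
#'
#' @param x an `interval_tracks` collection.
#' @param periods tibble (unit_id, start, end), optionally `occurrence_id`.
#' @param method one of `sum_duration, count, count_distinct, exists,
#'   delay, first, last`.
#' @param feature_concept label of the resulting feature.
#' @return `features` tibble; exclusions via [exclusions()].
#' @export
aggregate_intervals <- function(x, periods, method, feature_concept = method) {
  stopifnot(inherits(x, "interval_tracks"))
  if (!method %in% INTERVAL_METHODS) {
    stop("unknown interval extraction method: ", method, call. = FALSE)
  }
  excl <- empty_exclusions()
  has_occ <- "occurrence_id" %in% names(periods)
  rows <- lapply(seq_len(nrow(periods)), function(i) {
    u <- as.character(periods$unit_id[i])
    ps <- tp_num(as_timepoint(periods$start[i])); pe <- tp_num(as_timepoint(periods$end[i]))
    occ <- if (has_occ) as.character(periods$occurrence_id[i]) else NA_character_
    urows <- x[x$unit_id == u, ]
    clipped <- clip_rows_to_spans(urows, cbind(s = ps, e = pe))
    pid <- if ("person_id" %in% names(periods)) as.character(periods$person_id[i]) else urows$person_id[1]
    if (length(pid) == 0 || is.na(pid)) pid <- urows$person_id[1]
    if (length(pid) == 0 || is.na(pid)) pid <- u
    feat <- function(num = NA_real_, conc = NA_character_) {
      tibble::tibble(unit_id = u, person_id = pid, feature_concept = feature_concept,
                     value_num = num, value_concept = conc,
                     definition_id = NA_character_, occurrence_id = occ)
    }
    if (nrow(clipped) == 0) {
      if (method %in% c("sum_duration", "count", "count_distinct", "exists")) {
        return(feat(num = 0))
      }
      excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "no records in period"))
      return(NULL)
    }
    if (method %in% c("first", "last", "delay")) {
      o <- order(tp_num(clipped$start), vkey(clipped))
      clipped <- clipped[o, ]
      pick <- if (method == "last") clipped[nrow(clipped), ] else clipped[1, ]
      if (method == "delay") return(feat(num = tp_num(pick$start) - ps))
      if (!is.na(pick$value_concept)) return(feat(conc = pick$value_concept))
      return(feat(num = pick$value_num))
    }
    switch(method,
      sum_duration = {
        sp <- merge_spans(tp_num(clipped$start), tp_num(clipped$end))
        feat(num = sum(sp[, "e"] - sp[, "s"]))
      },
      count = feat(num = nrow(clipped)),
      count_distinct = feat(num = length(unique(vkey(clipped)))),
      exists = feat(num = 1))
  })
  new_features(dplyr::bind_rows(rows), exclusions = excl)
}

#' Derive a binary indicator feature from a numeric feature
#'
#' Generic feature post-processing: compares each numeric feature value to a
#' threshold and emits 1/0, e.g. turning a mean mL/kg tidal volume into a
#' guideline-noncompliance flag.
#'
#' @param features a `features` tibble with numeric values.
#' @param comparator one of `"<", "<=", ">", ">="`.
#' @param threshold numeric cut-off.
#' @param feature_concept label of the derived indicator.
#' @return `features` tibble of 0/1 values on the same units.
#' @export
threshold_feature <- function(features, comparator, threshold, feature_concept) {
  cmp_fun <- switch(match.arg(comparator, c("<", "<=", ">", ">=")),
                    "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`)
  out <- features
  out$value_num <- as.numeric(cmp_fun(features$value_num, threshold))
  out$feature_concept <- rep(feature_concept, nrow(out))
  new_features(out, exclusions = exclusions(features))
}

#' Declare a feature definition (the 7-item reproducibility contract)
#'
#' A feature is fully documented by 7 items: the raw source, the
#' statistical unit, the type of track, the value rule that built the
#' track, the final track to aggregate, the period of interest and the
#' extraction method. Serializing these with the feature removes ambiguity
#' about what was computed.
#'
#' @param definition_id unique identifier.
#' @param label human-readable feature name.
#' @param feature_concept concept stamped on produced features.
#' @param source item 1 — the raw signal/table selector (free text).
#' @param statistical_unit item 2 — unit kind (`person`, `visit`,
#'   `procedure_occurrence`, ...).
#' @param track_type item 3 — concept of the track being aggregated.
#' @param value_rule item 4 — how track values were computed (free text
#'   plus parameters).
#' @param final_track item 5 — name of the track (in the track list passed
#'   to [run_definition()]) that is aggregated.
#' @param period item 6 — name of the period-of-interest set.
#' @param method item 7 — extraction method name from the closed catalogue.
#' @param method_params optional named list of method parameters.
#' @return list of class `feature_definition`.
#' @export
feature_definition <- function(definition_id, label, feature_concept,
                               source, statistical_unit, track_type,
                               value_rule, final_track, period, method,
                               method_params = list()) {
  items <- list(definition_id = definition_id, label = label,
                feature_concept = feature_concept, source = source,
                statistical_unit = statistical_unit, track_type = track_type,
                value_rule = value_rule, final_track = final_track,
                period = period, method = method, method_params = method_params)
  missing <- names(items)[vapply(items[1:10], function(v) is.null(v) || !nzchar(as.character(v)[1]), logical(1))]
  if (length(missing) > 0) {
    stop("feature definition incomplete, missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!method %in% c(SIGNAL_METHODS, INTERVAL_METHODS)) {
    stop("unknown extraction method: ", method, call. = FALSE)
  }
  structure(items, class = "feature_definition")
}

#' @export
print.feature_definition <- function(x, ...) {
  cat(format_definition(x), sep = "\n")
  invisible(x)
}

#' Human-readable account of a definition's 7 items
#' @param x a `feature_definition`.
#' @return character vector, one line per item.
#' @export
format_definition <- function(x) {
  c(sprintf("Feature definition %s: %s", x$definition_id, x$label),
    sprintf("  feature concept : %s", x$feature_concept),
    sprintf("  1. source            : %s", x$source),
    sprintf("  2. statistical unit  : %s", x$statistical_unit),
    sprintf("  3. type of track     : %s", x$track_type),
    sprintf("  4. value rule        : %s", x$value_rule),
    sprintf("  5. final track       : %s", x$final_track),
    sprintf("  6. period of interest: %s", x$period),
    sprintf("  7. extraction method : %s%s", x$method,
            if (length(x$method_params) > 0)
              paste0(" (", jsonlite::toJSON(x$method_params, auto_unbox = TRUE), ")")
            else ""))
}

#' Run one feature definition against named track and period collections
#'
#' Resolves the definition's `final_track` and `period` references (a
#' dangling reference is a configuration error raised before any
#' computation), dispatches to [aggregate_signal()] or
#' [aggregate_intervals()] by track kind, and stamps every feature with the
#' definition id. Deterministic: re-running yields identical output.
#'
#' @param defn a [feature_definition()].
#' @param tracks named list of track collections.
#' @param periods named list of period tibbles.
#' @return `features` tibble with `definition_id` populated; excluded units
#'   via [exclusions()].
#' @export
run_definition <- function(defn, tracks, periods) {
  stopifnot(inherits(defn, "feature_definition"))
  if (!defn$final_track %in% names(tracks)) {
    stop("definition ", defn$definition_id, " references unknown track '",
         defn$final_track, "'", call. = FALSE)
  }
  if (!defn$period %in% names(periods)) {
    stop("definition ", defn$definition_id, " references unknown period '",
         defn$period, "'", call. = FALSE)
  }
  trk <- tracks[[defn$final_track]]
  per <- periods[[defn$period]]
  out <- if (inherits(trk, "signal_tracks")) {
    aggregate_signal(trk, per, defn$method, feature_concept = defn$feature_concept)
  } else {
    aggregate_intervals(trk, per, defn$method, feature_concept = defn$feature_concept)
  }
  out$definition_id <- rep(defn$definition_id, nrow(out))
  out
}

#' Write/read feature definitions as DCF blocks
#'
#' One Debian-control-format block per definition, blank-line separated;
#' field names are exactly the 7 items plus identifiers, method parameters
#' serialized as JSON. Reading back is lossless.
#'
#' @param defns list of [feature_definition()]s.
#' @param path file path.
#' @return `write_definitions()` the path invisibly; `read_definitions()` a
#'   named list of definitions.
#' @export
write_definitions <- function(defns, path) {
  if (inherits(defns, "feature_definition")) defns <- list(defns)
  mat <- do.call(rbind, lapply(defns, function(d) {
    c(definition_id = d$definition_id, label = d$label,
      feature_concept = d$feature_concept, source = d$source,
      statistical_unit = d$statistical_unit, track_type = d$track_type,
      value_rule = d$value_rule, final_track = d$final_track,
      period = d$period, method = d$method,
      method_params = as.character(jsonlite::toJSON(d$method_params, auto_unbox = TRUE)))
  }))
  write.dcf(mat, path)
  invisible(path)
}

#' @rdname write_definitions
#' @export
read_definitions <- function(path) {
  mat <- read.dcf(path)
  defns <- lapply(seq_len(nrow(mat)), function(i) {
    r <- as.list(mat[i, ])
    mp <- if (is.na(r$method_params %||% NA)) list() else jsonlite::fromJSON(r$method_params)
    feature_definition(r$definition_id, r$label, r$feature_concept, r$source,
                       r$statistical_unit, r$track_type, r$value_rule,
                       r$final_track, r$period, r$method,
                       method_params = as.list(mp))
  })
  stats::setNames(defns, vapply(defns, `[[`, character(1), "definition_id"))
}
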