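# Signal tracks: per-unit piecewise-constant numeric functions of time, the
# representation of irregularly sampled vitals after reconstruction. A
# breakpoint (t, v) means the signal holds value v on [t, next breakpoint);
# v = NA marks an explicitly undefined (gap) segment. The last breakpoint's
# value holds to the end of the unit's domain; time before the first
# breakpoint is undefined.

SIGNAL_COLS <- c("unit_id", "person_id", "track_concept", "time", "value",
                 "domain_start", "domain_end")

#' Build a signal-track collection
#'
#' @param unit_id unit identifier per breakpoint.
#' @param time breakpoint instants, strictly increasing within a unit.
#' @param value numeric value holding from each breakpoint to the next;
#'   `NA` marks an undefined segment (gap).
#' @param domain_start,domain_end per-unit interval within which the step
#'   function is defined at all.
#' @param track_concept concept naming the signal (e.g. `"map_mmhg"`).
#' @param person_id person of each unit; defaults to `unit_id`.
#' @return tibble of class `signal_tracks`, one row per breakpoint.
#' @export
signal_tracks <- function(unit_id = character(), time = NULL, value = numeric(),
                          domain_start = NULL, domain_end = NULL,
                          track_concept = "signal", person_id = NULL) {
  n <- length(unit_id)
  time <- if (is.null(time)) tp_from_num(numeric(0)) else as_timepoint(time)
  df <- tibble::tibble(
    unit_id = as.character(unit_id),
    person_id = as.character(if (is.null(person_id)) unit_id else person_id),
    track_concept = rep_len(as.character(track_concept), n),
    time = rep_len(time, n),
    value = rep_len(as.numeric(value), n),
    domain_start = rep_len(if (is.null(domain_start)) tp_from_num(numeric(0)) else as_timepoint(domain_start), n),
    domain_end = rep_len(if (is.null(domain_end)) tp_from_num(numeric(0)) else as_timepoint(domain_end), n)
  )
  new_signal_tracks(df)
}

new_signal_tracks <- function(df, exclusions = NULL) {
  df <- tibble::as_tibble(df[SIGNAL_COLS])
  df <- dplyr::arrange(df, .data$unit_id, .data$track_concept, .data$time)
  for (u in unique(df$unit_id)) {
    t <- tp_num(df$time[df$unit_id == u])
    if (any(diff(t) <= 0)) {
      stop("signal breakpoints not strictly increasing for unit ", u, call. = FALSE)
    }
  }
  class(df) <- c("signal_tracks", class(tibble::tibble()))
  attr(df, "exclusions") <- exclusions %||% empty_exclusions()
  df
}

#' @export
print.signal_tracks <- function(x, ...) {
  cat("<signal_tracks> ", nrow(x), " breakpoint(s), ",
      length(unique(x$unit_id)), " unit(s)\n", sep = "")
  NextMethod()
}

# defined segments of one unit as a data.frame (s, e, value) in numeric
# seconds, clipped to the domain; NA segments omitted
unit_segments <- function(rows) {
  if (nrow(rows) == 0) return(data.frame(s = numeric(0), e = numeric(0), value = numeric(0)))
  t <- tp_num(rows$time)
  ds <- tp_num(rows$domain_start[1]); de <- tp_num(rows$domain_end[1])
  e <- c(t[-1], de)
  s <- pmax(t, ds); e <- pmin(e, de)
  keep <- !is.na(rows$value) & s < e
  data.frame(s = s[keep], e = e[keep], value = rows$value[keep])
}

# all units' defined segments
signal_segments <- function(x) {
  stopifnot(inherits(x, "signal_tracks"))
  parts <- split(seq_len(nrow(x)), x$unit_id)
  out <- lapply(names(parts), function(u) {
    segs <- unit_segments(x[parts[[u]], ])
    if (nrow(segs) == 0) return(NULL)
    cbind(unit_id = u, segs)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- data.frame(unit_id = character(0), s = numeric(0), e = numeric(0),
                      value = numeric(0))
  }
  res
}

# rebuild a unit's breakpoint rows from disjoint sorted defined segments
segments_to_rows <- function(segs, template, ds, de) {
  if (nrow(segs) == 0) {
    row <- template[1, ]
    row$time <- tp_from_num(ds); row$value <- NA_real_
    row$domain_start <- tp_from_num(ds); row$domain_end <- tp_from_num(de)
    return(row)
  }
  times <- numeric(0); values <- numeric(0)
  if (segs$s[1] > ds) { times <- ds; values <- NA_real_ }
  for (i in seq_len(nrow(segs))) {
    times <- c(times, segs$s[i]); values <- c(values, segs$value[i])
    nxt <- if (i < nrow(segs)) segs$s[i + 1] else de
    if (segs$e[i] < nxt) { times <- c(times, segs$e[i]); values <- c(values, NA_real_) }
  }
  out <- template[rep(1, length(times)), ]
  out$time <- tp_from_num(times)
  out$value <- values
  out$domain_start <- tp_from_num(ds)
  out$domain_end <- tp_from_num(de)
  out
}

# resolve a per-unit window argument (periods tibble, interval_tracks, or a
# length-2 start/end) into a lookup: unit_id -> c(s, e)
resolve_windows <- function(window, units) {
  if (inherits(window, "interval_tracks") || is.data.frame(window)) {
    tibble::tibble(unit_id = as.character(window$unit_id),
                   s = tp_num(as_timepoint(window$start)),
                   e = tp_num(as_timepoint(window$end)))
  } else {
    tibble::tibble(unit_id = units,
                   s = tp_num(as_timepoint(window[[1]])),
                   e = tp_num(as_timepoint(window[[2]])))
  }
}

#' Reconstruct a regular step signal from irregular samples
#'
#' Last-observation-carried-forward on a regular grid: at each grid point
#' the value of the most recent sample at or before it is carried forward,
#' unless that sample is more than `max_gap` seconds old, in which case the
#' point is undefined. Time before the first sample is undefined. The
#' default 600 s validity horizon reflects typical monitor-archiving gaps.
#'
#' @param samples tibble with columns `unit_id`, `time`, `value` (see
#'   [measurement_samples()] for OMOP measurement tables), optionally
#'   `person_id`.
#' @param domain per-unit reconstruction window: a `periods` tibble
#'   (unit_id, start, end) or a length-2 start/end applied to all units.
#' @param step grid step in seconds (>= 1); signals are reconstructed at
#'   one measurement per `step` seconds.
#' @param max_gap seconds a sample stays valid; grid points further than
#'   this after the last sample are undefined.
#' @param track_concept concept for the reconstructed signal.
#' @param method `"locf"` (default) or `"linear"` — linear interpolation
#'   between samples (gaps wider than `max_gap` still undefined).
#' @return `signal_tracks` with breakpoints on the grid (runs of equal
#'   values compressed).
#' @export
resample <- function(samples, domain, step = 1, max_gap = 600,
                     track_concept = "signal", method = c("locf", "linear")) {
  method <- match.arg(method)
  stopifnot(step >= 1)
  samples$unit_id <- as.character(samples$unit_id)
  if (!"person_id" %in% names(samples)) samples$person_id <- samples$unit_id
  win <- resolve_windows(domain, unique(samples$unit_id))
  out <- lapply(seq_len(nrow(win)), function(i) {
    u <- win$unit_id[i]; ds <- win$s[i]; de <- win$e[i]
    rows <- samples[samples$unit_id == u, ]
    rows <- rows[order(as_timepoint(rows$time)), ]
    st <- tp_num(as_timepoint(rows$time)); sv <- as.numeric(rows$value)
    inside <- st < de  # samples after the domain never influence it
    st <- st[inside]; sv <- sv[inside]
    if (de <= ds) return(NULL)
    grid <- seq(ds, de - 1e-9, by = step)
    if (length(st) == 0) {
      gv <- rep(NA_real_, length(grid))
    } else if (method == "locf") {
      idx <- findInterval(grid, st)
      gv <- ifelse(idx > 0 & (grid - st[pmax(idx, 1)]) <= max_gap, sv[pmax(idx, 1)], NA_real_)
    } else {
      idx <- findInterval(grid, st)
      gv <- rep(NA_real_, length(grid))
      ok <- idx > 0
      # interpolate within max_gap-bounded sample pairs; after last sample LOCF up to max_gap
      for (k in which(ok)) {
        i0 <- idx[k]
        if (i0 < length(st) && (st[i0 + 1] - st[i0]) <= max_gap) {
          w <- (grid[k] - st[i0]) / (st[i0 + 1] - st[i0])
          gv[k] <- sv[i0] * (1 - w) + sv[i0 + 1] * w
        } else if ((grid[k] - st[i0]) <= max_gap) {
          gv[k] <- sv[i0]
        }
      }
    }
    # compress runs of identical values (NA a state of its own)
    n <- length(gv)
    if (n > 1) {
      a <- gv[-1]; b <- gv[-n]
      same <- (a == b & !is.na(a) & !is.na(b)) | (is.na(a) & is.na(b))
      keep <- c(TRUE, !same)
    } else keep <- TRUE
    tibble::tibble(
      unit_id = u,
      person_id = rows$person_id[1] %||% u,
      track_concept = track_concept,
      time = tp_from_num(grid[keep]),
      value = gv[keep],
      domain_start = tp_from_num(ds),
      domain_end = tp_from_num(de)
    )
  })
  new_signal_tracks(dplyr::bind_rows(out))
}

#' Convert an OMOP measurement table to resampling input
#'
#' @param measurement data frame with OMOP-convention columns
#'   `measurement_datetime` and `value_as_number`, plus a unit resolution.
#' @param unit_map tibble mapping `person_id` (or `visit_occurrence_id`) to
#'   `unit_id`; defaults to person-as-unit.
#' @param concept_id optional filter on `measurement_concept_id`.
#' @return tibble (unit_id, person_id, time, value).
#' @export
measurement_samples <- function(measurement, unit_map = NULL, concept_id = NULL) {
  m <- tibble::as_tibble(measurement)
  if (!is.null(concept_id)) {
    m <- m[as.character(m$measurement_concept_id) %in% as.character(concept_id), ]
  }
  m$person_id <- as.character(m$person_id)
  res <- resolve_units(m, unit_map)  # may be one-to-many (person -> several units)
  m <- m[res$idx, ]
  tibble::tibble(unit_id = res$unit_id, person_id = m$person_id,
                 time = as_timepoint(m$measurement_datetime),
                 value = as.numeric(m$value_as_number))
}

#' Restrict a signal to a mask
#'
#' The signal becomes undefined outside the mask and is unchanged inside;
#' used to aggregate a vital sign "during the procedure" only.
#'
#' @param x a `signal_tracks` collection.
#' @param mask an `interval_tracks` collection, a `periods` tibble, or a
#'   length-2 start/end applied to all units.
#' @return `signal_tracks` over the same domains.
#' @export
restrict_signal <- function(x, mask) {
  stopifnot(inherits(x, "signal_tracks"))
  units <- unique(x$unit_id)
  if (inherits(mask, "interval_tracks")) {
    mk <- mask
    spans_of <- function(u) {
      rows <- mk[mk$unit_id == u, ]
      sp <- merge_spans(tp_num(rows$start), tp_num(rows$end))
      sp[sp[, "e"] > sp[, "s"], , drop = FALSE]
    }
  } else {
    win <- resolve_windows(mask, units)
    spans_of <- function(u) {
      w <- win[win$unit_id == u, ]
      if (nrow(w) == 0) return(cbind(s = numeric(0), e = numeric(0)))
      merge_spans(w$s, w$e)
    }
  }
  out <- lapply(units, function(u) {
    rows <- x[x$unit_id == u, ]
    ds <- tp_num(rows$domain_start[1]); de <- tp_num(rows$domain_end[1])
    segs <- unit_segments(rows)
    sp <- spans_of(u)
    clipped <- lapply(seq_len(nrow(sp)), function(j) {
      s <- pmax(segs$s, sp[j, "s"]); e <- pmin(segs$e, sp[j, "e"])
      keep <- s < e
      data.frame(s = s[keep], e = e[keep], value = segs$value[keep])
    })
    segs2 <- dplyr::bind_rows(clipped)
    if (nrow(segs2) > 0) segs2 <- segs2[order(segs2$s), ]
    else segs2 <- data.frame(s = numeric(0), e = numeric(0), value = numeric(0))
    segments_to_rows(segs2, rows[1, ], ds, de)
  })
  new_signal_tracks(dplyr::bind_rows(out), exclusions = exclusions(x))
}

#' Transform a signal by a per-unit scalar
#'
#' Value-wise arithmetic against a per-unit constant, e.g. dividing tidal
#' volume by ideal body weight to obtain mL/kg. Undefined segments stay
#' undefined. Units with a missing scalar — or a zero divisor — are excluded
#' and logged.
#'
#' @param x a `signal_tracks` collection.
#' @param scalar per-unit constant: named numeric vector or tibble
#'   (unit_id, value).
#' @param op one of `"divide"`, `"multiply"`, `"subtract"`.
#' @return `signal_tracks`; excluded units reported via [exclusions()].
#' @export
transform_signal <- function(x, scalar, op = c("divide", "multiply", "subtract")) {
  stopifnot(inherits(x, "signal_tracks"))
  op <- match.arg(op)
  if (is.data.frame(scalar)) {
    sc <- stats::setNames(as.numeric(scalar$value), as.character(scalar$unit_id))
  } else {
    sc <- scalar
  }
  excl <- empty_exclusions()
  keep_units <- character(0)
  out <- x
  for (u in unique(x$unit_id)) {
    v <- unname(sc[u])
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "missing scalar"))
    } else if (op == "divide" && v == 0) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "zero divisor"))
    } else {
      keep_units <- c(keep_units, u)
      idx <- out$unit_id == u
      out$value[idx] <- switch(op,
        divide = out$value[idx] / v,
        multiply = out$value[idx] * v,
        subtract = out$value[idx] - v)
    }
  }
  res <- out[out$unit_id %in% keep_units, ]
  new_signal_tracks(res, exclusions = dplyr::bind_rows(exclusions(x), excl))
}

#' Reference constant of a signal over a baseline period
#'
#' Time-weighted mean of the signal restricted to a per-unit reference
#' period — e.g. the mean systolic pressure between arrival in the operating
#' room and induction, used later as the denominator of a relative
#' hypotension threshold. Units whose signal is entirely undefined in the
#' period are excluded and logged.
#'
#' @param x a `signal_tracks` collection.
#' @param reference_period per-unit window (periods tibble or length-2).
#' @param statistic only `"mean"` (time-weighted) is defined.
#' @return tibble (unit_id, value); exclusions via [exclusions()].
#' @export
reference_constant <- function(x, reference_period, statistic = "mean") {
  stopifnot(inherits(x, "signal_tracks"), identical(statistic, "mean"))
  units <- unique(x$unit_id)
  win <- resolve_windows(reference_period, units)
  excl <- empty_exclusions()
  vals <- lapply(units, function(u) {
    w <- win[win$unit_id == u, ]
    segs <- unit_segments(x[x$unit_id == u, ])
    if (nrow(w) == 0) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "no reference period"))
      return(NULL)
    }
    s <- pmax(segs$s, w$s[1]); e <- pmin(segs$e, w$e[1])
    keep <- s < e
    if (!any(keep)) {
      excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "signal undefined in reference period"))
      return(NULL)
    }
    wgt <- (e - s)[keep]
    tibble::tibble(unit_id = u, value = sum(segs$value[keep] * wgt) / sum(wgt))
  })
  res <- dplyr::bind_rows(vals)
  if (nrow(res) == 0) res <- tibble::tibble(unit_id = character(), value = numeric())
  attr(res, "exclusions") <- excl
  res
}

#' Detect threshold episodes in a signal
#'
#' Finds the maximal defined spans where `signal <comparator> threshold`
#' holds, then merges episodes separated by gaps of at most `merge_gap`
#' seconds, then drops episodes shorter than `min_duration` seconds. The
#' threshold is either absolute or a fraction of a per-unit reference value
#' (`relative = TRUE`), encoding rules such as "a drop of 20% from the
#' reference value" as `comparator = "<", threshold = 0.8, relative = TRUE`.
#'
#' @param x a `signal_tracks` collection.
#' @param comparator one of `"<", "<=", ">", ">="`.
#' @param threshold numeric threshold, absolute or a fraction of the
#'   reference.
#' @param relative if `TRUE`, the effective threshold per unit is
#'   `threshold * reference`.
#' @param reference per-unit reference values (tibble (unit_id, value) as
#'   returned by [reference_constant()], or a named vector); required when
#'   `relative = TRUE`.
#' @param min_duration drop episodes shorter than this many seconds.
#' @param merge_gap merge consecutive episodes separated by at most this
#'   many seconds.
#' @param concept concept for the derived episode track.
#' @return `interval_tracks` of episodes (value 1); units lacking a
#'   required reference are excluded and logged.
#' @export
threshold_episodes <- function(x, comparator, threshold, relative = FALSE,
                               reference = NULL, min_duration = 0,
                               merge_gap = 0, concept = "episode") {
  stopifnot(inherits(x, "signal_tracks"))
  cmp <- match.arg(comparator, c("<", "<=", ">", ">="))
  if (relative && is.null(reference)) {
    stop("fractional threshold requires a reference value", call. = FALSE)
  }
  if (is.data.frame(reference)) {
    reference <- stats::setNames(as.numeric(reference$value), as.character(reference$unit_id))
  }
  cmp_fun <- switch(cmp, "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`)
  excl <- empty_exclusions()
  out <- lapply(unique(x$unit_id), function(u) {
    thr <- threshold
    if (relative) {
      r <- unname(reference[u])
      if (length(r) == 0 || is.na(r)) {
        excl <<- dplyr::bind_rows(excl, tibble::tibble(unit_id = u, reason = "missing reference value"))
        return(NULL)
      }
      thr <- threshold * r
    }
    rows <- x[x$unit_id == u, ]
    segs <- unit_segments(rows)
    hit <- segs[cmp_fun(segs$value, thr), , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    sp <- merge_spans(hit$s, hit$e)
    if (merge_gap > 0 && nrow(sp) > 1) {
      # widen by merge_gap/2-free trick is wrong for asymmetric gaps; do a pass
      s <- sp[, "s"]; e <- sp[, "e"]
      grp <- cumsum(c(TRUE, s[-1] - e[-length(e)] > merge_gap))
      sp <- cbind(s = s[!duplicated(grp)], e = tapply(e, grp, max))
    }
    keep <- (sp[, "e"] - sp[, "s"]) >= min_duration & (sp[, "e"] > sp[, "s"])
    if (min_duration > 0) keep <- keep & (sp[, "e"] - sp[, "s"]) >= min_duration
    sp <- sp[keep, , drop = FALSE]
    if (nrow(sp) == 0) return(NULL)
    interval_tracks(rep(u, nrow(sp)), tp_from_num(sp[, "s"]), tp_from_num(sp[, "e"]),
                    track_concept = concept, person_id = rows$person_id[1])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) res <- interval_tracks(track_concept = concept)
  new_interval_tracks(res, exclusions = dplyr::bind_rows(exclusions(x), excl))
}

#' Canonical form of a signal collection
#'
#' Trims leading/trailing undefined time (the domain shrinks to the defined
#' support), merges abutting equal-value segments and collapses undefined
#' runs; units with no defined time are dropped. Round-tripping through the
#' TRACK table is the identity on canonical collections.
#'
#' @param x a `signal_tracks` collection.
#' @return canonical `signal_tracks`.
#' @export
canonical_signal <- function(x) {
  stopifnot(inherits(x, "signal_tracks"))
  out <- lapply(unique(x$unit_id), function(u) {
    rows <- x[x$unit_id == u, ]
    segs <- unit_segments(rows)
    if (nrow(segs) == 0) return(NULL)
    segs <- segs[order(segs$s), ]
    # merge abutting equal values
    if (nrow(segs) > 1) {
      same <- c(FALSE, segs$s[-1] == segs$e[-nrow(segs)] &
                  segs$value[-1] == segs$value[-nrow(segs)])
      grp <- cumsum(!same)
      segs <- data.frame(s = segs$s[!duplicated(grp)],
                         e = as.numeric(tapply(segs$e, grp, max)),
                         value = segs$value[!duplicated(grp)])
    }
    segments_to_rows(segs, rows[1, ], segs$s[1], segs$e[nrow(segs)])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(signal_tracks())
  new_signal_tracks(res)
}
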