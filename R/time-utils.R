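# Time conventions: one study-wide UTC-naive clock, second resolution.
# Internally every instant is a POSIXct in tz "UTC"; durations are numeric
# seconds. Day-level claims data and second-level monitor data share this
# representation (dates promote to midnight).

#' Seconds in one day
#'
#' Duration constants used throughout: all duration arithmetic is in integer
#' seconds, the package's finest time resolution.
#' @export
DAY_S <- 86400

#' @rdname DAY_S
#' @export
MINUTE_S <- 60

#' @rdname DAY_S
#' @export
HOUR_S <- 3600

#' Coerce an instant to the study clock
#'
#' Accepts POSIXct, Date, ISO-8601 character (date or datetime, `T` or space
#' separator) or numeric seconds since the epoch. Date-only inputs are
#' promoted to midnight (00:00:00). Times are truncated to whole seconds.
#'
#' @param x vector to coerce.
#' @return POSIXct vector in tz "UTC".
#' @examples
#' as_timepoint("2021-03-10")            # midnight
#' as_timepoint("2021-03-10T14:30:05")
#' @export
as_timepoint <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- as.POSIXct(floor(as.numeric(x)), origin = "1970-01-01", tz = "UTC")
  } else if (inherits(x, "Date")) {
    out <- as.POSIXct(as.numeric(x) * DAY_S, origin = "1970-01-01", tz = "UTC")
  } else if (is.numeric(x)) {
    out <- as.POSIXct(floor(x), origin = "1970-01-01", tz = "UTC")
  } else if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
    blank <- is.na(x) | x == ""
    has_time <- grepl("[T ]", x) & !blank
    if (any(has_time)) {
      v <- as.POSIXct(sub("T", " ", x[has_time]), tz = "UTC",
                      format = "%Y-%m-%d %H:%M:%S")
      bad <- is.na(v)
      if (any(bad)) {
        stop("unparseable datetime: ", paste(unique(x[has_time][bad]), collapse = ", "),
             call. = FALSE)
      }
      out[has_time] <- v
    }
    date_only <- !has_time & !blank
    if (any(date_only)) {
      out[date_only] <- promote_date(x[date_only])
    }
    out
  } else {
    stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
         " as a time point", call. = FALSE)
  }
  out
}

#' Promote a calendar date to a time point at midnight
#'
#' OMOP claims tables carry day-level dates while monitor signals carry
#' datetimes; promoting dates to midnight lets the interval algebra mix them.
#' Invalid calendar dates (e.g. "2021-02-30") are an error, not silently
#' rolled over.
#'
#' @param d Date vector or ISO-8601 `YYYY-MM-DD` character.
#' @return POSIXct at 00:00:00 UTC of each date.
#' @export
promote_date <- function(d) {
  if (inherits(d, "Date")) {
    return(as.POSIXct(as.numeric(d) * DAY_S, origin = "1970-01-01", tz = "UTC"))
  }
  d <- as.character(d)
  if (!all(grepl("^\\d{4}-\\d{2}-\\d{2}$", d[!is.na(d)]))) {
    bad <- d[!is.na(d) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", d)]
    stop("unparseable date: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  dt <- as.Date(d, format = "%Y-%m-%d")
  # as.Date() accepts impossible days by NA, catch those explicitly
  bad <- !is.na(d) & is.na(dt)
  # strptime-based parsing also normalizes e.g. 2021-02-30 -> NA on most
  # platforms, but double-check by formatting back
  rt <- !is.na(dt) & format(dt, "%Y-%m-%d") != d
  if (any(bad | rt)) {
    stop("invalid calendar date: ", paste(unique(d[bad | rt]), collapse = ", "),
         call. = FALSE)
  }
  as.POSIXct(as.numeric(dt) * DAY_S, origin = "1970-01-01", tz = "UTC")
}

#' Format instants for storage
#'
#' @param x POSIXct vector.
#' @return `fmt_datetime()`: ISO-8601 `YYYY-MM-DDTHH:MM:SS` character;
#'   `fmt_date()`: the date part `YYYY-MM-DD`.
#' @keywords internal
fmt_datetime <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

#' @rdname fmt_datetime
#' @keywords internal
fmt_date <- function(x) {
  out <- format(x, "%Y-%m-%d", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

# numeric seconds since epoch (exact for whole-second POSIXct)
tp_num <- function(x) as.numeric(x)

tp_from_num <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
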