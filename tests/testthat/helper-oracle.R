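# Brute-force per-second oracles and random-instance generators. The
# oracles enumerate membership second by second and stay independent of
# the interval-algebra implementation they check.

EPOCH0 <- as.POSIXct(0, origin = "1970-01-01", tz = "UTC")

tp <- function(s) as.POSIXct(s, origin = "1970-01-01", tz = "UTC")
num <- function(t) as.numeric(t)

# logical membership vector over seconds [lo, hi) for a set of [s, e) pairs
oracle_cover <- function(s, e, lo, hi) {
  out <- rep(FALSE, hi - lo)
  for (i in seq_along(s)) {
    a <- max(s[i], lo); b <- min(e[i], hi)
    if (a < b) out[(a - lo + 1):(b - lo)] <- TRUE
  }
  out
}

oracle_track_cover <- function(track, lo, hi, unit = NULL) {
  rows <- if (is.null(unit)) track else track[track$unit_id == unit, ]
  oracle_cover(num(rows$start), num(rows$end), lo, hi)
}

# per-second LOCF value of irregular samples (NA where stale / before first)
oracle_locf <- function(st, sv, grid, max_gap = 600) {
  vapply(grid, function(t) {
    i <- which(st <= t)
    if (length(i) == 0) return(NA_real_)
    i <- max(i)
    if (t - st[i] > max_gap) NA_real_ else sv[i]
  }, numeric(1))
}

# per-second values of a signal_tracks unit (NA = undefined)
oracle_signal_values <- function(sig, unit, grid) {
  rows <- sig[sig$unit_id == unit, ]
  t <- num(rows$time); v <- rows$value
  ds <- num(rows$domain_start[1]); de <- num(rows$domain_end[1])
  vapply(grid, function(g) {
    if (g < ds || g >= de) return(NA_real_)
    i <- which(t <= g)
    if (length(i) == 0) return(NA_real_)
    v[max(i)]
  }, numeric(1))
}

# random interval track over [0, span) seconds with values from an alphabet
rand_track <- function(n_rec = 6, span = 600, values = c("A", "B"),
                       unit = "u1", concept = "t") {
  s <- sort(sample.int(span, n_rec, replace = TRUE)) - 1
  len <- sample.int(span %/% 4, n_rec, replace = TRUE)
  e <- pmin(s + len, span)
  interval_tracks(rep(unit, n_rec), tp(s), tp(e), track_concept = concept,
                  value_concept = sample(values, n_rec, replace = TRUE))
}

# random step signal over [0, span) with occasional undefined gaps
rand_signal <- function(span = 600, n_bp = 8, p_gap = 0.2, unit = "u1",
                        concept = "s") {
  t <- sort(sample.int(span - 1, n_bp)) - 1
  t[1] <- 0
  t <- unique(t)
  v <- round(stats::runif(length(t), 50, 150), 3)
  v[stats::runif(length(t)) < p_gap] <- NA
  signal_tracks(rep(unit, length(t)), tp(t), v, domain_start = tp(0),
                domain_end = tp(span), track_concept = concept, person_id = unit)
}

# ISO date for "day n" of the epoch calendar
fmt_d <- function(day) format(as.Date("1970-01-01") + day)

expect_same_records <- function(a, b) {
  key <- function(x) paste(x$unit_id, num(x$start), num(x$end),
                           x$value_num, x$value_concept)
  expect_setequal(key(a), key(b))
}
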