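# Track definition: selection, mapping, interval construction, windows,
# milestones, resampling, thresholding and the interval algebra.

test_that("select_events keeps matching rows as point records and maps codes", {
  raw <- tibble::tibble(
    person_id = "p1",
    drug_concept_id = c("B01AA03", "X1", "B01AA04", "X2", "X3"),
    drug_exposure_start_date = sprintf("2021-01-%02d", 1:5))
  cs <- concept_set("vka", "ATC", c("B01AA03", "B01AA04"), target_concept = "VKA")
  trk <- select_events(raw, cs)
  expect_equal(nrow(trk), 2)
  expect_true(all(trk$value_concept == "VKA"))      # mapped to wider category
  expect_true(all(trk$start == trk$end))            # zero-length point events
  expect_equal(trk$source_value, c("B01AA03", "B01AA04"))

  empty <- select_events(raw, concept_set("none", "ATC", character()))
  expect_equal(nrow(empty), 0)
})

test_that("prefix members match dot-stripped codes, exact members do not", {
  cs <- concept_set("hypo", "ICD10", "I95", is_prefix = TRUE)
  raw <- tibble::tibble(person_id = "p1",
                        condition_concept_id = c("I95.1", "I95", "I9", "E95.1"),
                        condition_start_date = rep("2021-01-01", 4))
  expect_equal(nrow(select_events(raw, cs)), 2)
  cs2 <- concept_set("hypo", "ICD10", "I95", is_prefix = FALSE)
  expect_equal(select_events(raw, cs2)$source_value, "I95")
  expect_error(select_events(raw, cs, vocabulary = "ATC"), "unknown vocabulary")
})

test_that("stay intervals are day-inclusive; same-day stays last one day", {
  raw <- tibble::tibble(person_id = "p1", visit_occurrence_id = c("v1", "v2"),
                        visit_start_date = c("2021-03-10", "2021-03-12"),
                        visit_end_date = c("2021-03-15", "2021-03-12"))
  trk <- interval_from_fields(raw)
  expect_equal(trk$start[1], as_timepoint("2021-03-10"))
  expect_equal(trk$end[1], as_timepoint("2021-03-16"))  # discharge day occupied
  expect_equal(num(trk$end[2]) - num(trk$start[2]), DAY_S)
})

test_that("inverted and open-ended stays are rejected or censored", {
  raw <- tibble::tibble(person_id = "p1", visit_occurrence_id = c("v1", "v2"),
                        visit_start_date = c("2021-03-10", "2021-03-12"),
                        visit_end_date = c("2021-03-01", ""))
  trk <- interval_from_fields(raw)
  expect_equal(nrow(trk), 0)
  rej <- attr(trk, "rejects")
  expect_setequal(rej$reason, c("end precedes start", "missing end date"))
  cens <- interval_from_fields(raw[2, ], censor_end = "2021-12-31T00:00:00")
  expect_equal(cens$end, as_timepoint("2021-12-31"))
})

test_that("exposures span start + days_supply; zero supply is a 1-day exposure", {
  raw <- tibble::tibble(person_id = "p1", drug_concept_id = "A",
                        drug_exposure_start_date = c("2021-01-01", "2021-01-01"),
                        days_supply = c(5, 0))
  trk <- exposure_intervals(raw)
  expect_equal(num(trk$end) - num(trk$start), c(5, 1) * DAY_S)
  neg <- exposure_intervals(tibble::tibble(
    person_id = "p1", drug_concept_id = "A",
    drug_exposure_start_date = "2021-01-01", days_supply = -2))
  expect_equal(nrow(neg), 0)
  expect_equal(attr(neg, "rejects")$reason, "negative duration")
})

test_that("overlapping refills coalesce to the per-day oracle coverage", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:5, 1)
    start_day <- sample(0:40, n, replace = TRUE)
    supply <- sample(1:10, n, replace = TRUE)
    raw <- tibble::tibble(person_id = "p1", drug_concept_id = "A",
                          drug_exposure_start_date = fmt_d(start_day),
                          days_supply = supply)
    trk <- coalesce_tracks(exposure_intervals(raw))
    oracle_days <- sum(oracle_cover(start_day, start_day + supply, 0, 60))
    expect_equal(total_duration(trk)$duration_s, oracle_days * DAY_S)
  }
})

test_that("shift_window builds the calendar windows of the study cases", {
  stay <- interval_tracks("u", as_timepoint("2021-03-10"), as_timepoint("2021-03-16"), "stay")
  before90 <- shift_window(stay, "start", -90 * DAY_S, 0)
  expect_equal(before90$start, as_timepoint("2020-12-10"))
  expect_equal(before90$end, as_timepoint("2021-03-10"))
  after90 <- shift_window(stay, "end", 0, 90 * DAY_S)   # 90 days following
  expect_equal(after90$start, as_timepoint("2021-03-16"))
  expect_equal(after90$end, as_timepoint("2021-06-14"))

  t <- as_timepoint("2021-05-01T10:00:00")
  atro <- interval_tracks("u", t, t, "atropine")
  expect_equal(num(shift_window(atro, "start", -600, 0)$start), num(t) - 600)
  # zero offsets are the identity on the anchored endpoint
  expect_identical(shift_window(stay, "start", 0, 0)$start, stay$start)
  expect_error(shift_window(stay, "start", 0, -1), "invert")
})

test_that("milestone priority beats recency; fallback and ties behave", {
  ev <- interval_tracks(rep("u", 2), tp(c(300, 100)), tp(c(300, 100)), "ev",
                        value_concept = c("induction", "intubation"))
  rule <- milestone_rule(c("induction", "hypnotic", "intubation", "ventilation"))
  expect_equal(num(select_milestone(ev, rule)$milestone), 300)  # priority wins

  only_vent <- interval_tracks("u", tp(400), tp(400), "ev",
                               value_concept = "ventilation")
  expect_equal(num(select_milestone(only_vent, rule)$milestone), 400)

  two <- interval_tracks(rep("u", 2), tp(c(200, 100)), tp(c(200, 100)), "ev",
                         value_concept = "induction")
  expect_equal(num(select_milestone(two, rule)$milestone), 100)  # earliest tie-break
  expect_equal(num(select_milestone(
    two, milestone_rule("induction", tie = "last"))$milestone), 200)

  none <- interval_tracks("u", tp(50), tp(50), "ev", value_concept = "other")
  res <- select_milestone(none, milestone_rule("induction", fallback = "error"))
  expect_equal(nrow(res), 0)
  expect_equal(exclusions(res)$reason, "missing milestone")
  expect_equal(num(select_milestone(
    none, milestone_rule("induction", fallback = "first"))$milestone), 50)
})

test_that("build_period applies offsets, legal zero length, logs exclusions", {
  ms <- function(u, t) structure(tibble::tibble(unit_id = u, milestone = tp(t)))
  p <- build_period(ms("u1", 100), ms("u1", 100))
  expect_equal(num(p$end) - num(p$start), 0)       # zero-length period is legal
  p2 <- build_period(ms("u1", 100), ms("u1", 200), offset_start = -50, offset_end = 30)
  expect_equal(num(p2$start), 50); expect_equal(num(p2$end), 230)
  # unit accounting: inputs == outputs + exclusions
  s <- ms(c("u1", "u2"), c(100, 100)); e <- ms("u1", 200)
  p3 <- build_period(s, e)
  expect_equal(nrow(p3) + nrow(exclusions(p3)), 2)
  expect_equal(exclusions(p3)$reason, "missing end milestone")
  inv <- build_period(ms("u1", 500), ms("u1", 100))
  expect_equal(exclusions(inv)$reason, "inverted period")
})

test_that("resample is LOCF on the grid with a validity horizon", {
  smp <- tibble::tibble(unit_id = "u", time = tp(c(0, 5)), value = c(100, 90))
  sig <- resample(smp, domain = c(tp(0), tp(8)), step = 1, max_gap = 600)
  expect_equal(oracle_signal_values(sig, "u", 0:7),
               c(100, 100, 100, 100, 100, 90, 90, 90))

  # 120 s between samples with a 60 s horizon: defined 61 s, stale 59 s
  smp2 <- tibble::tibble(unit_id = "u", time = tp(c(0, 120)), value = c(1, 2))
  sig2 <- resample(smp2, domain = c(tp(0), tp(180)), step = 1, max_gap = 60)
  vals <- oracle_signal_values(sig2, "u", 0:179)
  expect_equal(vals, oracle_locf(c(0, 120), c(1, 2), 0:179, max_gap = 60))
  expect_true(all(is.na(vals[62:120])))

  # single sample at domain start: constant signal
  one <- resample(tibble::tibble(unit_id = "u", time = tp(0), value = 7),
                  domain = c(tp(0), tp(100)), max_gap = 600)
  expect_equal(unique(oracle_signal_values(one, "u", 0:99)), 7)

  # before the first sample: undefined; no samples at all: fully undefined
  late <- resample(tibble::tibble(unit_id = "u", time = tp(50), value = 3),
                   domain = c(tp(0), tp(100)), max_gap = 600)
  expect_true(all(is.na(oracle_signal_values(late, "u", 0:49))))
  nosmp <- resample(tibble::tibble(unit_id = "u", time = tp(500), value = 3),
                    domain = c(tp(0), tp(100)), max_gap = 600)
  expect_true(all(is.na(oracle_signal_values(nosmp, "u", 0:99))))
})

test_that("resampling a step signal at its own breakpoints reproduces it", {
  set.seed(12)
  for (i in 1:20) {
    t <- sort(sample(0:99, 5)); v <- round(runif(5, 1, 9), 2)
    smp <- tibble::tibble(unit_id = "u", time = tp(t), value = v)
    sig <- resample(smp, domain = c(tp(min(t)), tp(120)), step = 1, max_gap = 1e6)
    expect_equal(oracle_signal_values(sig, "u", min(t):119),
                 oracle_locf(t, v, min(t):119, max_gap = 1e6))
  }
})

test_that("reference_constant is the time-weighted mean over the period", {
  sig <- signal_tracks(rep("u", 2), tp(c(0, 60)), c(100, 80),
                       domain_start = tp(0), domain_end = tp(90))
  ref <- reference_constant(sig, c(tp(0), tp(90)))
  expect_equal(ref$value, (100 * 60 + 80 * 30) / 90)  # 93.333...
  const <- signal_tracks("u", tp(0), 120, domain_start = tp(0), domain_end = tp(50))
  expect_equal(reference_constant(const, c(tp(0), tp(50)))$value, 120)
  # undefined everywhere in the period -> excluded with reason
  gap <- signal_tracks("u", tp(0), NA_real_, domain_start = tp(0), domain_end = tp(50))
  r <- reference_constant(gap, c(tp(0), tp(50)))
  expect_equal(nrow(r), 0)
  expect_match(exclusions(r)$reason, "undefined")
})

test_that("threshold_episodes finds maximal spans, merges gaps, drops shorts", {
  sig <- signal_tracks(rep("u", 3), tp(c(0, 60, 120)), c(100, 85, 95),
                       domain_start = tp(0), domain_end = tp(180))
  ep <- threshold_episodes(sig, "<", 90)
  expect_equal(num(ep$start), 60); expect_equal(num(ep$end), 120)

  const <- signal_tracks("u", tp(0), 100, domain_start = tp(0), domain_end = tp(100))
  expect_equal(nrow(threshold_episodes(const, "<", 0.9, relative = TRUE,
                                       reference = c(u = 100))), 0)
  expect_error(threshold_episodes(const, "<", 0.9, relative = TRUE),
               "reference")

  # two dips 30 s apart merge with merge_gap 30; min_duration drops the rest
  sig2 <- signal_tracks(rep("u", 5), tp(c(0, 100, 160, 190, 220)),
                        c(100, 80, 100, 80, 100),
                        domain_start = tp(0), domain_end = tp(400))
  ep2 <- threshold_episodes(sig2, "<", 90, merge_gap = 30)
  expect_equal(num(ep2$start), 100); expect_equal(num(ep2$end), 220)
  ep3 <- threshold_episodes(sig2, "<", 90, min_duration = 40)
  expect_equal(nrow(ep3), 1)   # only the 60 s dip survives
  expect_equal(num(ep3$start), 100)
})

test_that("threshold episodes match the per-second comparator oracle", {
  set.seed(13)
  for (i in 1:40) {
    sig <- rand_signal(span = 300)
    thr <- runif(1, 60, 140)
    ep <- threshold_episodes(sig, "<", thr)
    vals <- oracle_signal_values(sig, "u1", 0:299)
    expect_equal(total_duration(ep, units = "u1")$duration_s,
                 sum(!is.na(vals) & vals < thr))
  }
})

test_that("intersect keeps the payload value over the mask's covered time", {
  a <- interval_tracks("u", tp(0), tp(10), "a", value_concept = "drugA")
  b <- interval_tracks("u", tp(5), tp(15), "b")
  ab <- intersect_tracks(a, b)
  expect_equal(num(ab$start), 5); expect_equal(num(ab$end), 10)
  expect_equal(ab$value_concept, "drugA")
  # half-open: [0,5) and [5,10) share no instant
  expect_equal(nrow(intersect_tracks(
    interval_tracks("u", tp(0), tp(5), "a"),
    interval_tracks("u", tp(5), tp(10), "b"))), 0)
})

test_that("union keeps distinct values and the algebra laws hold", {
  a <- interval_tracks("u", tp(0), tp(5), "x", value_concept = "A")
  b <- interval_tracks("u", tp(3), tp(8), "x", value_concept = "A")
  expect_equal(nrow(union_tracks(a, b)), 1)        # same value coalesces
  b2 <- interval_tracks("u", tp(3), tp(8), "x", value_concept = "B")
  u2 <- union_tracks(a, b2)
  expect_setequal(u2$value_concept, c("A", "B"))   # distinct concepts survive

  set.seed(14)
  for (i in 1:60) {
    ta <- rand_track(); tb <- rand_track()
    dur1 <- function(x) total_duration(x, units = "u1")$duration_s
    dA <- dur1(ta); dB <- dur1(tb)
    dU <- dur1(union_tracks(ta, tb))
    dI <- dur1(intersect_tracks(ta, tb))
    expect_equal(dA + dB, dU + dI)                 # inclusion-exclusion
    # commutativity on covered time
    expect_equal(dI, dur1(intersect_tracks(tb, ta)))
    expect_equal(dU, dur1(union_tracks(tb, ta)))
    # T ∩ T and T ∪ T cover coalesce(T)
    expect_equal(dur1(intersect_tracks(ta, ta)), dA)
    expect_equal(dur1(union_tracks(ta, ta)), dA)
  }
})

test_that("restrict_signal masks definedness only", {
  sig <- signal_tracks("u", tp(0), 5, domain_start = tp(0), domain_end = tp(30))
  r <- restrict_signal(sig, interval_tracks("u", tp(10), tp(20), "m"))
  vals <- oracle_signal_values(r, "u", 0:29)
  expect_true(all(is.na(vals[c(1:10, 21:30)])))
  expect_true(all(vals[11:20] == 5))
  empty_mask <- restrict_signal(sig, interval_tracks(track_concept = "m"))
  expect_true(all(is.na(oracle_signal_values(empty_mask, "u", 0:29))))
})

test_that("transform_signal divides by per-unit scalars; zero divisor excluded", {
  sig <- signal_tracks("u", tp(0), 480, domain_start = tp(0), domain_end = tp(60))
  d <- transform_signal(sig, c(u = 60), "divide")
  expect_equal(d$value, 8)                          # 480 mL / 60 kg = 8 mL/kg
  expect_equal(transform_signal(sig, c(u = 1), "multiply")$value, 480)
  z <- transform_signal(sig, c(u = 0), "divide")
  expect_equal(nrow(z), 0)
  expect_equal(exclusions(z)$reason, "zero divisor")
  # divide-then-threshold == threshold-times-scalar on the raw signal
  set.seed(15)
  for (i in 1:20) {
    s <- rand_signal(span = 200, p_gap = 0)
    k <- runif(1, 2, 5)
    thr <- runif(1, 15, 60)
    e1 <- threshold_episodes(transform_signal(s, c(u1 = k), "divide"), "<", thr)
    e2 <- threshold_episodes(s, "<", thr * k)
    expect_equal(total_duration(e1, units = "u1")$duration_s,
                 total_duration(e2, units = "u1")$duration_s)
  }
})

test_that("count_condition_track enforces min_count with half-open windows", {
  ev <- interval_tracks(rep("u", 3), tp(c(10, 20, 30)), tp(c(10, 20, 30)), "abx")
  win <- tibble::tibble(unit_id = "u", start = tp(0), end = tp(100))
  expect_equal(nrow(count_condition_track(ev, 3, win)), 1)
  expect_equal(nrow(count_condition_track(ev, 4, win)), 0)
  # event exactly at the window end is excluded
  edge <- interval_tracks("u", tp(100), tp(100), "abx")
  expect_equal(nrow(count_condition_track(edge, 1, win)), 0)
})

test_that("ddi observation periods follow the day-after / 4-days-after rule", {
  d <- function(n) tp(n * DAY_S)
  a <- interval_tracks("u", d(1), d(10), "vka")
  b <- interval_tracks("u", d(5), d(20), "x")
  obs <- ddi_observation_period(a, b)
  expect_equal(num(obs$start), 6 * DAY_S)   # overlap [d5,d10) -> [d6,d14)
  expect_equal(num(obs$end), 14 * DAY_S)
  expect_equal(nrow(ddi_observation_period(
    a, interval_tracks("u", d(30), d(40), "x"))), 0)

  # several exposure episodes: one window per overlap, verified per day
  set.seed(16)
  for (i in 1:20) {
    sa <- sort(sample(0:60, 2)); sb <- sort(sample(0:60, 2))
    ta <- interval_tracks(rep("u", 2), d(sa), d(sa + sample(3:10, 2, TRUE)), "a")
    tb <- interval_tracks(rep("u", 2), d(sb), d(sb + sample(3:10, 2, TRUE)), "b")
    obs <- ddi_observation_period(coalesce_tracks(ta), coalesce_tracks(tb))
    ov <- oracle_track_cover(ta, 0, 100 * DAY_S) & oracle_track_cover(tb, 0, 100 * DAY_S)
    r <- rle(ov)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    exp_sp <- cbind(s = starts[r$values] - 1 + DAY_S,
                    e = ends[r$values] + 4 * DAY_S)
    expect_equal(cbind(s = num(obs$start), e = num(obs$end)),
                 exp_sp, ignore_attr = TRUE)
  }
})

test_that("mark_periods_containing keeps qualifying windows only", {
  per <- interval_tracks(rep("u", 2), tp(c(0, 100)), tp(c(50, 150)), "w")
  ev <- interval_tracks("u", tp(120), tp(120), "e")
  kept <- mark_periods_containing(per, ev)
  expect_equal(num(kept$start), 100)
  expect_equal(nrow(mark_periods_containing(per, ev, min_count = 2)), 0)
})

test_that("map_track_values filters and substitutes target concepts", {
  trk <- interval_tracks(rep("u", 3), tp(c(0, 10, 20)), tp(c(5, 15, 25)), "d",
                         value_concept = c("B01AA03", "Z9", "B01AA04"))
  cs <- concept_set("vka", "ATC", c("B01AA03", "B01AA04"), target_concept = "VKA")
  out <- map_track_values(trk, cs)
  expect_equal(nrow(out), 2)
  expect_true(all(out$value_concept == "VKA"))
})
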