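# Track aggregation: the closed extraction-method catalogue, feature
# definitions (the 7-item contract) and run_definition.

per <- function(u = "u", s = 0, e = 90) tibble::tibble(unit_id = u, start = tp(s), end = tp(e))

test_that("signal aggregation: forced arithmetic on a two-segment signal", {
  sig <- signal_tracks(rep("u", 2), tp(c(0, 60)), c(100, 80),
                       domain_start = tp(0), domain_end = tp(90))
  p <- per()
  expect_equal(aggregate_signal(sig, p, "weighted_average")$value_num, 280 / 3)
  expect_equal(aggregate_signal(sig, p, "mean")$value_num, 280 / 3)  # same op
  expect_equal(aggregate_signal(sig, p, "median")$value_num, 100)    # 60 s of 100 vs 30 s of 80
  expect_equal(aggregate_signal(sig, p, "min")$value_num, 80)
  expect_equal(aggregate_signal(sig, p, "max")$value_num, 100)

  const <- signal_tracks("u", tp(0), 97, domain_start = tp(0), domain_end = tp(90))
  for (m in c("min", "max", "mean", "median", "weighted_average")) {
    expect_equal(aggregate_signal(const, p, m)$value_num, 97)
  }
  expect_error(aggregate_signal(const, p, "variance"), "unknown signal")
})

test_that("signal aggregation equals the 1 s-grid brute force (random)", {
  set.seed(21)
  for (i in 1:40) {
    sig <- rand_signal(span = 400)
    ps <- sample(0:100, 1); pe <- ps + sample(50:250, 1)
    p <- per(u = "u1", s = ps, e = pe)
    vals <- oracle_signal_values(sig, "u1", ps:(pe - 1))
    def <- vals[!is.na(vals)]
    if (length(def) == 0) {
      r <- aggregate_signal(sig, p, "mean")
      expect_equal(nrow(r), 0)
      expect_equal(nrow(exclusions(r)), 1)
      next
    }
    expect_equal(aggregate_signal(sig, p, "mean")$value_num, mean(def), tolerance = 1e-12)
    expect_equal(aggregate_signal(sig, p, "min")$value_num, min(def))
    expect_equal(aggregate_signal(sig, p, "max")$value_num, max(def))
    expect_equal(aggregate_signal(sig, p, "median")$value_num, stats::median(def))
    # ordering invariant
    expect_true(min(def) <= aggregate_signal(sig, p, "median")$value_num)
    expect_true(aggregate_signal(sig, p, "mean")$value_num <= max(def))
  }
})

test_that("time-weighted mean is invariant under breakpoint refinement", {
  set.seed(22)
  for (i in 1:20) {
    sig <- rand_signal(span = 300, p_gap = 0)
    # split one segment without changing values
    j <- sample(nrow(sig), 1)
    tj <- num(sig$time[j])
    nxt <- if (j < nrow(sig)) num(sig$time[j + 1]) else num(sig$domain_end[1])
    if (nxt - tj < 2) next
    refined <- tibble::add_row(sig[, ], sig[j, ] |>
                                 dplyr::mutate(time = tp(tj + 1)))
    refined <- signal_tracks(refined$unit_id, refined$time, refined$value,
                             refined$domain_start, refined$domain_end,
                             track_concept = refined$track_concept[1])
    p <- per(u = "u1", s = 0, e = 300)
    expect_equal(aggregate_signal(refined, p, "mean")$value_num,
                 aggregate_signal(sig, p, "mean")$value_num, tolerance = 1e-12)
  }
})

test_that("interval aggregation: clipping, counts, delay, first/last", {
  trk <- interval_tracks(rep("u", 2), tp(c(0, 120)), tp(c(60, 150)), "ep")
  p <- per(e = 180)
  expect_equal(aggregate_intervals(trk, p, "sum_duration")$value_num, 90)
  expect_equal(aggregate_intervals(trk, p, "count")$value_num, 2)
  expect_equal(aggregate_intervals(trk, p, "exists")$value_num, 1)

  drugs <- interval_tracks(rep("u", 3), tp(c(0, 10, 20)), tp(c(5, 15, 25)), "d",
                           value_concept = c("A", "A", "B"))
  expect_equal(aggregate_intervals(drugs, per(e = 100), "count_distinct")$value_num, 2)

  # delay: period starts at midnight, first episode 10 minutes later
  p0 <- tibble::tibble(unit_id = "u", start = as_timepoint("2021-03-10"),
                       end = as_timepoint("2021-03-11"))
  ep <- interval_tracks("u", as_timepoint("2021-03-10T00:10:00"),
                        as_timepoint("2021-03-10T00:40:00"), "ep")
  expect_equal(aggregate_intervals(ep, p0, "delay")$value_num, 600)

  expect_equal(aggregate_intervals(drugs, per(e = 100), "first")$value_concept, "A")
  expect_equal(aggregate_intervals(drugs, per(e = 100), "last")$value_concept, "B")

  # sum_duration never exceeds the period; equality iff full coverage
  full <- interval_tracks("u", tp(0), tp(90), "ep")
  expect_equal(aggregate_intervals(full, per(), "sum_duration")$value_num, 90)
})

test_that("empty clips: zero for count-like methods, absent for the rest", {
  empty <- interval_tracks(track_concept = "ep")
  p <- per()
  for (m in c("sum_duration", "count", "count_distinct", "exists")) {
    expect_equal(aggregate_intervals(empty, p, m)$value_num, 0)
  }
  for (m in c("delay", "first", "last")) {
    r <- aggregate_intervals(empty, p, m)
    expect_equal(nrow(r), 0)
    expect_equal(exclusions(r)$reason, "no records in period")
  }
  # record at the period end is outside (half-open)
  edge <- interval_tracks("u", tp(90), tp(90), "ep")
  expect_equal(aggregate_intervals(edge, p, "count")$value_num, 0)
})

test_that("clip-then-aggregate commutes with pre-restricting the track", {
  set.seed(23)
  for (i in 1:30) {
    trk <- rand_track(n_rec = 5)
    ps <- sample(0:200, 1); pe <- ps + sample(100:300, 1)
    p <- per(s = ps, e = pe)
    mask <- interval_tracks("u1", tp(ps), tp(pe), "m")
    pre <- intersect_tracks(trk, mask)
    expect_equal(aggregate_intervals(trk, p, "sum_duration")$value_num,
                 aggregate_intervals(pre, p, "sum_duration")$value_num)
    expect_true(aggregate_intervals(trk, p, "count_distinct")$value_num <=
                  aggregate_intervals(trk, p, "count")$value_num)
    expect_true(aggregate_intervals(trk, p, "sum_duration")$value_num <= pe - ps)
  }
})

test_that("feature definitions demand all 7 items and round-trip via DCF", {
  d <- feature_definition("d1", "Mean MAP before induction", "mean_map_before_induction",
                          "measurement: map", "procedure_occurrence", "map_resampled",
                          "LOCF 1 s resampling", "map_resampled", "before_induction",
                          "mean", method_params = list(step = 1))
  expect_error(feature_definition("d2", "", "x", "s", "u", "t", "r", "f", "p", "mean"),
               "incomplete")
  expect_error(feature_definition("d2", "l", "x", "s", "u", "t", "r", "f", "p",
                                  "quantile"), "unknown extraction method")
  path <- tempfile(fileext = ".dcf")
  on.exit(unlink(path))
  write_definitions(list(d), path)
  back <- read_definitions(path)[["d1"]]
  expect_equal(back[setdiff(names(back), "method_params")],
               d[setdiff(names(d), "method_params")])
  expect_equal(back$method_params$step, 1)
  txt <- format_definition(d)
  expect_length(grep("^  [1-7]\\.", txt), 7)   # all 7 items printed
})

test_that("run_definition stamps provenance, is deterministic, checks refs", {
  trk <- interval_tracks(rep("u", 2), tp(c(0, 120)), tp(c(60, 150)), "ep")
  d <- feature_definition("sc2x", "hypotension duration", "hypo_s",
                          "measurement: map", "procedure_occurrence", "ep",
                          "below 90% of reference", "ep", "proc", "sum_duration")
  f1 <- run_definition(d, list(ep = trk), list(proc = per(e = 180)))
  f2 <- run_definition(d, list(ep = trk), list(proc = per(e = 180)))
  expect_identical(f1, f2)
  expect_equal(f1$definition_id, "sc2x")
  expect_equal(f1$value_num, 90)
  expect_error(run_definition(d, list(other = trk), list(proc = per())),
               "unknown track")
  expect_error(run_definition(d, list(ep = trk), list(other = per())),
               "unknown period")
  # zero units: empty output, empty exclusions
  f0 <- run_definition(d, list(ep = trk), list(proc = per()[0, ]))
  expect_equal(nrow(f0), 0)
  expect_equal(nrow(exclusions(f0)), 0)
})

test_that("threshold_feature derives binary indicators", {
  f <- run_definition(
    feature_definition("d", "mean mL/kg", "vtkg", "s", "u", "t", "r", "tk", "p", "mean"),
    list(tk = signal_tracks("u", tp(0), 9, domain_start = tp(0), domain_end = tp(60))),
    list(p = per(e = 60)))
  flag <- threshold_feature(f, ">", 8, "noncompliant")
  expect_equal(flag$value_num, 1)
  expect_equal(flag$feature_concept, "noncompliant")
})
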