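# Casebook pipelines and the command-line layer.

test_that("the worked 90-day medication fixture reproduces all 8 steps", {
  fx <- generate_worked_sc6_fixture()
  b <- fx$bundle; ex <- fx$expected
  vt <- b$tables$visit_occurrence

  stays <- interval_from_fields(vt, concept = "hospital_stay")        # step 1
  expect_equal(stays$start, as_timepoint(ex$step1_stay["start"]), ignore_attr = TRUE)
  expect_equal(stays$end, as_timepoint(ex$step1_stay["end"]), ignore_attr = TRUE)

  window <- shift_window(stays, "start", -90 * DAY_S, 0)              # step 2
  expect_equal(window$start, as_timepoint(ex$step2_window["start"]), ignore_attr = TRUE)
  expect_equal(window$end, as_timepoint(ex$step2_window["end"]), ignore_attr = TRUE)

  um <- tibble::tibble(person_id = vt$person_id, unit_id = vt$visit_occurrence_id)
  expo <- map_track_values(exposure_intervals(b$tables$drug_exposure, unit_map = um),
                           laroche_list_set())
  a <- expo[expo$value_concept == ex$drug_a, ]                        # step 3
  expect_equal(a$start, as_timepoint(ex$step3_drug_a["start"]), ignore_attr = TRUE)
  expect_equal(a$end, as_timepoint(ex$step3_drug_a["end"]), ignore_attr = TRUE)
  btr <- expo[expo$value_concept == ex$drug_b, ]                      # step 4
  expect_equal(btr$start, as_timepoint(ex$step4_drug_b["start"]), ignore_attr = TRUE)
  expect_equal(btr$end, as_timepoint(ex$step4_drug_b["end"]), ignore_attr = TRUE)
  expect_false("X99ZZ99" %in% expo$value_concept)   # non-listed drug filtered

  a_in <- intersect_tracks(trackfeat:::new_interval_tracks(a), window)  # step 5
  expect_equal(a_in$start, as_timepoint(ex$step5_a_masked["start"]), ignore_attr = TRUE)
  expect_equal(a_in$end, as_timepoint(ex$step5_a_masked["end"]), ignore_attr = TRUE)
  b_in <- intersect_tracks(trackfeat:::new_interval_tracks(btr), window) # step 6
  expect_equal(b_in$start, as_timepoint(ex$step6_b_masked["start"]), ignore_attr = TRUE)
  expect_equal(b_in$end, as_timepoint(ex$step6_b_masked["end"]), ignore_attr = TRUE)

  u <- union_tracks(a_in, b_in)                                       # step 7
  expect_equal(nrow(u), 2)
  got <- lapply(seq_len(nrow(u)), function(i) c(start = format(u$start[i], "%Y-%m-%dT%H:%M:%S"),
                                                end = format(u$end[i], "%Y-%m-%dT%H:%M:%S")))
  expect_setequal(vapply(got, paste, collapse = "|", FUN.VALUE = ""),
                  vapply(ex$step7_union, paste, collapse = "|", FUN.VALUE = ""))

  feat <- aggregate_intervals(u, periods_from_track(window), "count_distinct")
  expect_equal(feat$value_num, ex$step8_count_distinct)               # step 8

  # and the full pipeline agrees with the fixture's answer key
  res <- run_case("sc6", b)
  f <- res$features
  for (i in seq_len(nrow(b$answer_key))) {
    k <- b$answer_key[i, ]
    expect_equal(f$value_num[f$unit_id == k$unit_id &
                               f$feature_concept == k$feature_concept],
                 k$true_value)
  }
})

test_that("run_case reproduces planted truths on small bundles (sc3, sc7)", {
  for (sc in c("sc3", "sc7")) {
    b <- simulate_bundle(sc, n_units = 4, seed = 17)
    res <- run_case(sc, b)
    f <- res$features
    f$k <- ifelse(is.na(f$occurrence_id), f$unit_id, f$occurrence_id)
    for (i in seq_len(nrow(b$answer_key))) {
      k <- b$answer_key[i, ]
      expect_equal(f$value_num[f$k == k$unit_id & f$feature_concept == k$feature_concept],
                   k$true_value, tolerance = 1e-9, label = paste(sc, k$feature_concept))
    }
    expect_equal(nrow(res$exclusions), 0)
  }
})

test_that("run_case persists tracks, features, definitions and exclusions", {
  d <- tempfile(); on.exit(unlink(d, recursive = TRUE))
  b <- simulate_bundle("sc6", n_units = 2, seed = 3)
  res <- run_case("sc6", b, out_dir = d)
  expect_setequal(list.files(d),
                  c("TRACK.csv", "FEATURE.csv", "definitions.dcf", "exclusions.csv"))
  feats <- read_features(file.path(d, "FEATURE.csv"))
  expect_setequal(unique(feats$definition_id),
                  c("sc6_laroche_before", "sc6_laroche_after"))
  defs <- read_definitions(file.path(d, "definitions.dcf"))
  expect_setequal(names(defs), c("sc6_laroche_before", "sc6_laroche_after"))
  # re-running the case writes byte-identical outputs
  d2 <- tempfile(); on.exit(unlink(d2, recursive = TRUE), add = TRUE)
  run_case("sc6", b, out_dir = d2)
  for (f in c("TRACK.csv", "FEATURE.csv")) {
    expect_identical(readBin(file.path(d, f), "raw", file.size(file.path(d, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("run_case on an empty bundle produces empty outputs, no crash", {
  b <- simulate_bundle("sc6", n_units = 1, seed = 1)
  b$tables$visit_occurrence <- b$tables$visit_occurrence[0, ]
  b$tables$drug_exposure <- b$tables$drug_exposure[0, ]
  res <- run_case("sc6", b)
  expect_equal(nrow(res$features), 0)
  b$tables$drug_exposure <- NULL
  expect_error(run_case("sc6", b), "requires missing input table")
})

test_that("the CLI wires simulate, run-case, describe and validate together", {
  d <- tempfile(); out <- tempfile()
  on.exit(unlink(c(d, out), recursive = TRUE))
  expect_equal(trackfeat_cli(c("simulate", "--scenario", "sc6", "--n", "3",
                               "--seed", "8", "--out", d)), 0L)
  expect_true(file.exists(file.path(d, "drug_exposure.csv")))
  expect_equal(trackfeat_cli(c("run-case", "--case", "sc6", "--bundle", d,
                               "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "FEATURE.csv")))

  msgs <- capture.output(
    code <- trackfeat_cli(c("describe", "--definitions",
                            file.path(out, "definitions.dcf"))))
  expect_equal(code, 0L)
  expect_length(grep("^  [1-7]\\.", msgs), 14)   # 7 items x 2 definitions

  expect_equal(trackfeat_cli(c("validate", "--track", file.path(out, "TRACK.csv"),
                               "--feature", file.path(out, "FEATURE.csv"))), 0L)
  # corrupted FEATURE.csv -> findings -> exit 1
  fdf <- utils::read.csv(file.path(out, "FEATURE.csv"), colClasses = "character")
  fdf$value_as_number[1] <- ""; fdf$value_as_concept_id[1] <- ""
  readr::write_csv(fdf, file.path(out, "FEATURE.csv"), na = "")
  expect_equal(suppressMessages(
    trackfeat_cli(c("validate", "--feature", file.path(out, "FEATURE.csv")))), 1L)
  invisible(capture.output({
    code_unknown <- suppressMessages(trackfeat_cli(c("frobnicate")))
    code_empty <- trackfeat_cli(character())
  }))
  expect_equal(code_unknown, 2L)
  expect_equal(code_empty, 2L)
})
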