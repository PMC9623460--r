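# Hand-written (not sampled) miniature for the potentially-inappropriate-
# medication case: one hospital stay, two listed drugs whose exposures
# partially overlap the 90-day pre-admission window, and the expected
# intermediate track after each of the 8 pipeline steps. Every expected
# value below is forced by the fixture's construction, making the full
# chain -- stay, window, exposures, intersections, union, count distinct --
# checkable end to end with exact interval endpoints.

#' Worked fixture for the 90-day inappropriate-medication chain
#'
#' One person, one hospital stay 2021-06-01 -> 2021-06-10 (day-inclusive,
#' so the stay occupies `[2021-06-01, 2021-06-11)`), and two listed drugs:
#' drug A exposed `[2021-02-25, 2021-03-07)` (10 days, crossing into the
#' window), drug B exposed `[2021-05-20, 2021-06-09)` (20 days, crossing
#' out of it), plus one non-listed drug inside the window that must be
#' filtered out. The 90-day pre-admission window is
#' `[2021-03-03, 2021-06-01)`.
#'
#' @return list with `bundle` (raw tables + answer key) and `expected`,
#'   the forced intermediate results of the 8 steps: `step1` stay
#'   interval, `step2` window, `step3`/`step4` drug A/B exposure
#'   intervals, `step5`/`step6` the masked exposures, `step7` the union
#'   records, `step8` the final distinct count.
#' @export
generate_worked_sc6_fixture <- function() {
  pid <- "fxp1"; vid <- "fxv1"
  drug_a <- LAROCHE_CODES[1]; drug_b <- LAROCHE_CODES[2]
  person <- dplyr::bind_rows(empty_person(),
                             tibble::tibble(person_id = pid, age = 82, ibw_kg = NA_real_))
  visit <- dplyr::bind_rows(empty_visit(), tibble::tibble(
    visit_occurrence_id = vid, person_id = pid, visit_concept_id = "hospital_stay",
    visit_start_date = "2021-06-01", visit_end_date = "2021-06-10",
    visit_start_datetime = NA_character_, visit_end_datetime = NA_character_,
    septic_shock_ventilated = NA_real_))
  drug <- dplyr::bind_rows(empty_drug(), tibble::tibble(
    drug_exposure_id = c("fxd1", "fxd2", "fxd3"),
    person_id = pid, visit_occurrence_id = NA_character_,
    drug_concept_id = c(drug_a, drug_b, "X99ZZ99"),
    drug_exposure_start_date = c("2021-02-25", "2021-05-20", "2021-04-15"),
    drug_exposure_start_datetime = NA_character_,
    days_supply = c(10, 20, 5)))
  bundle <- list(
    tables = list(person = person, visit_occurrence = visit,
                  drug_exposure = drug, measurement = empty_meas(),
                  procedure_occurrence = empty_proc()),
    answer_key = dplyr::bind_rows(
      akey(vid, "laroche_distinct_before", 2),
      akey(vid, "laroche_distinct_after", 0)),
    scenario = "sc6_fixture", seed = NA_integer_)
  iso <- function(s, e) c(start = s, end = e)
  expected <- list(
    step1_stay = iso("2021-06-01T00:00:00", "2021-06-11T00:00:00"),
    step2_window = iso("2021-03-03T00:00:00", "2021-06-01T00:00:00"),
    step3_drug_a = iso("2021-02-25T00:00:00", "2021-03-07T00:00:00"),
    step4_drug_b = iso("2021-05-20T00:00:00", "2021-06-09T00:00:00"),
    step5_a_masked = iso("2021-03-03T00:00:00", "2021-03-07T00:00:00"),
    step6_b_masked = iso("2021-05-20T00:00:00", "2021-06-01T00:00:00"),
    step7_union = list(
      iso("2021-03-03T00:00:00", "2021-03-07T00:00:00"),
      iso("2021-05-20T00:00:00", "2021-06-01T00:00:00")),
    step8_count_distinct = 2,
    drug_a = drug_a, drug_b = drug_b)
  list(bundle = bundle, expected = expected)
}
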