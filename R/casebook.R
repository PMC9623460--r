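# Reference pipelines for the eight study cases, each expressed purely as
# compositions of track-definition and track-aggregation operations; the
# final value of every feature is produced by run_definition() so that
# provenance (the 7-item definition) travels with it.

#' Concept sets used by the study-case pipelines
#'
#' Flat concept sets for the synthetic vocabulary of the simulator:
#' potentially inappropriate medications (Laroche-style list), vitamin K
#' antagonists and their interacting drugs (raw ATC codes mapped to the
#' wider categories "VKA" / "DDI_PARTNER"), COPD-related drug classes,
#' atropine, and the anesthesia milestone events.
#'
#' @return a [concept_set()].
#' @export
laroche_list_set <- function() {
  concept_set("laroche_list", "ATC", LAROCHE_CODES)
}

#' @rdname laroche_list_set
#' @export
vka_set <- function() {
  concept_set("vka", "ATC", VKA_CODES, target_concept = "VKA")
}

#' @rdname laroche_list_set
#' @export
ddi_partner_set <- function() {
  concept_set("ddi_partner", "ATC", DDI_PARTNER_CODES, target_concept = "DDI_PARTNER")
}

#' @rdname laroche_list_set
#' @export
copd_drug_sets <- function() {
  list(bronchodilator = concept_set("bronchodilator", "ATC", BRONCHODILATOR_CODES),
       resp_antibiotic = concept_set("resp_antibiotic", "ATC", RESP_ANTIBIOTIC_CODES),
       nicotine_substitute = concept_set("nicotine_substitute", "ATC", NICOTINE_CODES),
       all = concept_set("copd_drugs", "ATC",
                         c(BRONCHODILATOR_CODES, RESP_ANTIBIOTIC_CODES, NICOTINE_CODES)))
}

#' @rdname laroche_list_set
#' @export
atropine_set <- function() concept_set("atropine", "ATC", ATROPINE_CODE)

event_set <- function(id, codes) concept_set(id, "local", codes)

require_tables <- function(bundle, needed, case_id) {
  missing <- setdiff(needed, names(bundle$tables))
  empty <- needed[vapply(needed, function(nm) {
    !is.null(bundle$tables[[nm]]) && nrow(bundle$tables[[nm]]) == 0
  }, logical(1))]
  if (length(missing) > 0) {
    stop("case ", case_id, " requires missing input table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(empty)
}

collect_excl <- function(...) {
  dplyr::distinct(dplyr::bind_rows(lapply(list(...), exclusions)))
}

defn7 <- function(id, label, concept, source, unit, track_type, rule,
                  final_track, period, method) {
  feature_definition(id, label, concept, source, unit, track_type, rule,
                     final_track, period, method)
}

# ---- per-case pipelines --------------------------------------------------

case_sc1 <- function(bundle) {
  require_tables(bundle, c("visit_occurrence", "measurement"), "sc1")
  vt <- bundle$tables$visit_occurrence
  vt <- vt[vt$visit_concept_id == "icu_stay" & !is.na(vt$septic_shock_ventilated) &
             vt$septic_shock_ventilated == 1, ]
  stays <- interval_from_fields(vt, "visit_start_datetime", "visit_end_datetime",
                                concept = "icu_stay")
  first24 <- shift_window(stays, "start", 0, 24 * HOUR_S, concept = "icu_first_24h")
  periods <- periods_from_track(first24)
  meas <- bundle$tables$measurement
  meas <- meas[meas$visit_occurrence_id %in% vt$visit_occurrence_id, ]
  um <- tibble::tibble(visit_occurrence_id = vt$visit_occurrence_id,
                       unit_id = vt$visit_occurrence_id)
  samples <- measurement_samples(meas, unit_map = um, concept_id = "pao2")
  pao2 <- resample(samples, domain = periods, step = 1, max_gap = 600,
                   track_concept = "pao2_resampled")
  defn <- defn7("sc1_pao2_wmean", "Weighted average PaO2, first 24 h of ICU stay",
                "pao2_wmean_24h", "measurement: pao2 (irregular samples)",
                "visit (ICU stay)", "pao2_resampled",
                "LOCF resampling at 1 s, validity horizon 600 s",
                "pao2_resampled", "icu_first_24h", "weighted_average")
  feats <- run_definition(defn, list(pao2_resampled = pao2),
                          list(icu_first_24h = periods))
  list(features = feats,
       tracks = list(icu_stay = stays, icu_first_24h = first24, pao2_resampled = pao2),
       periods = list(icu_first_24h = periods),
       definitions = list(defn),
       exclusions = collect_excl(feats))
}

# shared engine for the two relative-hypotension cases
case_hypotension <- function(bundle, case_id, sig_concept, resampled_concept,
                             start_rule, ref_end_rule, end_rule, frac,
                             episode_concept, feat_concept, label) {
  require_tables(bundle, c("visit_occurrence", "measurement", "procedure_occurrence"),
                 case_id)
  pr <- bundle$tables$procedure_occurrence
  ev_set <- event_set(paste0(case_id, "_events"),
                      unique(c(start_rule$candidates, ref_end_rule$candidates,
                               end_rule$candidates)))
  events <- select_events(pr, ev_set, code_col = "procedure_concept_id",
                          time_col = "procedure_datetime",
                          unit_map = tibble::tibble(
                            visit_occurrence_id = unique(pr$visit_occurrence_id),
                            unit_id = unique(pr$visit_occurrence_id)),
                          concept = "procedure_events")
  ms_start <- select_milestone(events, start_rule)
  ms_ref_end <- select_milestone(events, ref_end_rule)
  ms_end <- select_milestone(events, end_rule)
  ref_period <- build_period(ms_start, ms_ref_end)
  full_period <- build_period(ms_start, ms_end)
  poi <- build_period(ms_ref_end, ms_end)   # induction/incision -> end
  meas <- bundle$tables$measurement
  um <- tibble::tibble(visit_occurrence_id = full_period$unit_id,
                       unit_id = full_period$unit_id)
  meas <- meas[meas$visit_occurrence_id %in% um$visit_occurrence_id, ]
  samples <- measurement_samples(meas, unit_map = um, concept_id = sig_concept)
  sig <- resample(samples, domain = full_period, step = 1, max_gap = 600,
                  track_concept = resampled_concept)
  ref <- reference_constant(sig, ref_period)
  episodes <- threshold_episodes(sig, "<", frac, relative = TRUE, reference = ref,
                                 concept = episode_concept)
  defn <- defn7(paste0(case_id, "_hypotension_duration"), label, feat_concept,
                paste0("measurement: ", sig_concept, " (irregular samples)"),
                "procedure (via visit)", episode_concept,
                sprintf("episodes with signal < %d%% of the reference value (time-weighted mean over the reference period)",
                        round(frac * 100)),
                episode_concept, "procedure_period", "sum_duration")
  feats <- run_definition(defn, stats::setNames(list(episodes), episode_concept),
                          list(procedure_period = full_period))
  list(features = feats,
       tracks = stats::setNames(
         list(events, episodes, sig),
         c("procedure_events", episode_concept, resampled_concept)),
       periods = list(reference_period = ref_period, procedure_period = full_period,
                      exposure_period = poi),
       definitions = list(defn),
       exclusions = collect_excl(ms_start, ms_ref_end, ms_end, ref_period,
                                 full_period, ref, episodes, feats))
}

case_sc2 <- function(bundle) {
  case_hypotension(bundle, "sc2", "map", "map_resampled",
                   milestone_rule("anesthesia_start"),
                   milestone_rule("incision"),
                   milestone_rule("anesthesia_end"),
                   frac = 0.90, episode_concept = "map_below90_episode",
                   feat_concept = "map_below90_duration_s",
                   label = "Duration of MAP > 10% below reference, during anesthesia")
}

case_sc3 <- function(bundle) {
  case_hypotension(bundle, "sc3", "sap", "sap_resampled",
                   milestone_rule("arrival_or"),
                   milestone_rule(c("induction", "hypnotic", "intubation", "ventilation")),
                   milestone_rule("birth"),
                   frac = 0.80, episode_concept = "sap_below80_episode",
                   feat_concept = "sap_below80_duration_s",
                   label = "Duration of SAP > 20% below reference, induction to birth")
}

case_sc4 <- function(bundle) {
  require_tables(bundle, c("drug_exposure", "measurement"), "sc4")
  dr <- bundle$tables$drug_exposure
  dr <- dr[dr$drug_concept_id == ATROPINE_CODE, ]
  # person-level tracks; each administration is one occurrence (episode)
  adm <- select_events(dr, atropine_set(),
                       time_col = "drug_exposure_start_datetime",
                       concept = "atropine_administration")
  before <- shift_window(adm, "start", -10 * MINUTE_S, 0, concept = "10min_before")
  after <- shift_window(adm, "start", 0, 10 * MINUTE_S, concept = "10min_after")
  occ_periods <- function(w) {
    tibble::tibble(unit_id = w$unit_id, person_id = w$person_id,
                   start = w$start, end = w$end,
                   occurrence_id = dr$drug_exposure_id)
  }
  adm_t <- tp_num(as_timepoint(dr$drug_exposure_start_datetime))
  hull <- tibble::tibble(unit_id = unique(as.character(dr$person_id)))
  hull$start <- tp_from_num(vapply(hull$unit_id, function(p)
    min(adm_t[dr$person_id == p]) - 10 * MINUTE_S, numeric(1)))
  hull$end <- tp_from_num(vapply(hull$unit_id, function(p)
    max(adm_t[dr$person_id == p]) + 10 * MINUTE_S, numeric(1)))
  samples <- measurement_samples(bundle$tables$measurement, concept_id = "hr")
  samples <- samples[samples$unit_id %in% hull$unit_id, ]
  hr <- resample(samples, domain = hull, step = 1, max_gap = 600,
                 track_concept = "hr_resampled")
  specs <- expand.grid(stat = c("median", "min", "max"),
                       win = c("before", "after"), stringsAsFactors = FALSE)
  defns <- list(); feats <- list()
  for (i in seq_len(nrow(specs))) {
    st <- specs$stat[i]; wn <- specs$win[i]
    fc <- sprintf("hr_%s_%s", st, wn)
    defns[[i]] <- defn7(paste0("sc4_", fc),
                        sprintf("Heart rate %s, 10 min %s atropine", st, wn),
                        fc, "measurement: hr (irregular samples)",
                        "event occurrence (atropine administration)",
                        "hr_resampled", "LOCF resampling at 1 s",
                        "hr_resampled", paste0("10min_", wn), st)
    feats[[i]] <- run_definition(defns[[i]], list(hr_resampled = hr),
                                 stats::setNames(list(occ_periods(
                                   if (wn == "before") before else after)),
                                   paste0("10min_", wn)))
  }
  all_feats <- new_features(dplyr::bind_rows(feats),
                            exclusions = do.call(collect_excl, feats))
  list(features = all_feats,
       tracks = list(atropine_administration = adm, `10min_before` = before,
                     `10min_after` = after, hr_resampled = hr),
       periods = list(`10min_before` = occ_periods(before),
                      `10min_after` = occ_periods(after)),
       definitions = defns,
       exclusions = do.call(collect_excl, feats))
}

case_sc5 <- function(bundle) {
  require_tables(bundle, c("person", "visit_occurrence", "measurement",
                           "procedure_occurrence"), "sc5")
  pr <- bundle$tables$procedure_occurrence
  events <- select_events(pr, event_set("sc5_events", c("surgery_start", "surgery_end")),
                          code_col = "procedure_concept_id",
                          time_col = "procedure_datetime",
                          unit_map = tibble::tibble(
                            visit_occurrence_id = unique(pr$visit_occurrence_id),
                            unit_id = unique(pr$visit_occurrence_id)),
                          concept = "procedure_events")
  period <- build_period(select_milestone(events, milestone_rule("surgery_start")),
                         select_milestone(events, milestone_rule("surgery_end")))
  meas <- bundle$tables$measurement
  um <- tibble::tibble(visit_occurrence_id = period$unit_id, unit_id = period$unit_id)
  meas <- meas[meas$visit_occurrence_id %in% um$visit_occurrence_id, ]
  samples <- measurement_samples(meas, unit_map = um, concept_id = "tidal_volume_ml")
  vt_sig <- resample(samples, domain = period, step = 1, max_gap = 600,
                     track_concept = "vt_resampled")
  # ideal body weight is a per-unit input column (person table)
  per <- bundle$tables$person
  vis <- bundle$tables$visit_occurrence
  ibw <- tibble::tibble(unit_id = vis$visit_occurrence_id,
                        value = per$ibw_kg[match(vis$person_id, per$person_id)])
  vt_kg <- transform_signal(vt_sig, ibw, "divide")
  vt_kg$track_concept <- rep("vt_per_kg", nrow(vt_kg))
  defn <- defn7("sc5_vt_per_kg_mean", "Mean end-tidal volume per kg IBW during surgery",
                "vt_ml_per_kg_mean", "measurement: tidal_volume_ml + person.ibw_kg",
                "procedure (via visit)", "vt_per_kg",
                "tidal volume divided by ideal body weight (mL/kg)",
                "vt_per_kg", "surgery_period", "mean")
  mean_feat <- run_definition(defn, list(vt_per_kg = vt_kg),
                              list(surgery_period = period))
  flag <- threshold_feature(mean_feat, ">", 8, "vt_noncompliant")
  flag$definition_id <- rep("sc5_vt_noncompliant", nrow(flag))
  defn2 <- defn7("sc5_vt_noncompliant", "Mean tidal volume above 8 mL/kg IBW",
                 "vt_noncompliant", "measurement: tidal_volume_ml + person.ibw_kg",
                 "procedure (via visit)", "vt_per_kg",
                 "indicator: mean mL/kg > 8", "vt_per_kg", "surgery_period", "mean")
  feats <- new_features(dplyr::bind_rows(mean_feat, flag),
                        exclusions = collect_excl(period, vt_kg, mean_feat))
  list(features = feats,
       tracks = list(procedure_events = events, vt_resampled = vt_sig,
                     vt_per_kg = vt_kg),
       periods = list(surgery_period = period),
       definitions = list(defn, defn2),
       exclusions = collect_excl(period, vt_kg, mean_feat))
}

case_sc6 <- function(bundle) {
  require_tables(bundle, c("visit_occurrence", "drug_exposure"), "sc6")
  vt <- bundle$tables$visit_occurrence
  vt <- vt[vt$visit_concept_id == "hospital_stay", ]
  stays <- interval_from_fields(vt, "visit_start_date", "visit_end_date",
                                concept = "hospital_stay")
  before <- shift_window(stays, "start", -90 * DAY_S, 0, concept = "90d_before_stay")
  after <- shift_window(stays, "end", 0, 90 * DAY_S, concept = "90d_after_stay")
  um <- tibble::tibble(person_id = vt$person_id, unit_id = vt$visit_occurrence_id)
  expo <- exposure_intervals(bundle$tables$drug_exposure, unit_map = um,
                             concept = "drug_exposure")
  laroche <- map_track_values(expo, laroche_list_set(), concept = "laroche_exposure")
  laroche <- coalesce_tracks(laroche)
  in_before <- intersect_tracks(laroche, before, concept = "laroche_in_90d_before")
  in_after <- intersect_tracks(laroche, after, concept = "laroche_in_90d_after")
  defn_b <- defn7("sc6_laroche_before",
                  "Distinct Laroche-list drugs in the 90 days before the stay",
                  "laroche_distinct_before", "drug_exposure (ATC codes)",
                  "visit (hospital stay)", "laroche_in_90d_before",
                  "exposures [start, start + days_supply) filtered to the Laroche list, masked by the 90-day pre-admission window",
                  "laroche_in_90d_before", "90d_before_stay", "count_distinct")
  defn_a <- defn7("sc6_laroche_after",
                  "Distinct Laroche-list drugs in the 90 days after the stay",
                  "laroche_distinct_after", "drug_exposure (ATC codes)",
                  "visit (hospital stay)", "laroche_in_90d_after",
                  "exposures filtered to the Laroche list, masked by the 90-day post-discharge window",
                  "laroche_in_90d_after", "90d_after_stay", "count_distinct")
  fb <- run_definition(defn_b, list(laroche_in_90d_before = in_before),
                       list(`90d_before_stay` = periods_from_track(before)))
  fa <- run_definition(defn_a, list(laroche_in_90d_after = in_after),
                       list(`90d_after_stay` = periods_from_track(after)))
  feats <- new_features(dplyr::bind_rows(fb, fa), exclusions = collect_excl(fb, fa))
  list(features = feats,
       tracks = list(hospital_stay = stays, `90d_before_stay` = before,
                     `90d_after_stay` = after, laroche_exposure = laroche,
                     laroche_in_90d_before = in_before,
                     laroche_in_90d_after = in_after),
       periods = list(`90d_before_stay` = periods_from_track(before),
                      `90d_after_stay` = periods_from_track(after)),
       definitions = list(defn_b, defn_a),
       exclusions = collect_excl(fb, fa))
}

case_sc7 <- function(bundle) {
  require_tables(bundle, c("person", "drug_exposure", "measurement"), "sc7")
  expo <- exposure_intervals(bundle$tables$drug_exposure, concept = "drug_exposure")
  vka <- coalesce_tracks(map_track_values(expo, vka_set(), concept = "vka_exposure"))
  partner <- coalesce_tracks(map_track_values(expo, ddi_partner_set(),
                                              concept = "ddi_partner_exposure"))
  obs <- ddi_observation_period(vka, partner, concept = "ddi_observation")
  meas <- bundle$tables$measurement
  high <- measurement_events(meas, "inr", ">=", 5, concept = "inr_ge_5")
  low <- measurement_events(meas, "inr", "<=", 1.5, concept = "inr_le_1_5")
  pot <- mark_periods_containing(obs, high)
  pot$track_concept <- rep("vka_potentiation", nrow(pot))
  inh <- mark_periods_containing(obs, low)
  inh$track_concept <- rep("vka_inhibition", nrow(inh))
  # study period per patient: the whole simulated span
  persons <- as.character(bundle$tables$person$person_id)
  span <- study_span(bundle)
  study <- tibble::tibble(unit_id = persons, start = span[1], end = span[2])
  defn_p <- defn7("sc7_potentiation", "Count of VKA potentiation episodes",
                  "vka_potentiation_count", "drug_exposure (ATC) + measurement: inr",
                  "person", "vka_potentiation",
                  "DDI observation windows (overlap + 1 day to overlap end + 4 days) containing at least one INR >= 5",
                  "vka_potentiation", "study_period", "count")
  defn_i <- defn7("sc7_inhibition", "Count of VKA inhibition episodes",
                  "vka_inhibition_count", "drug_exposure (ATC) + measurement: inr",
                  "person", "vka_inhibition",
                  "DDI observation windows containing at least one INR <= 1.5",
                  "vka_inhibition", "study_period", "count")
  fp <- run_definition(defn_p, list(vka_potentiation = pot), list(study_period = study))
  fi <- run_definition(defn_i, list(vka_inhibition = inh), list(study_period = study))
  feats <- new_features(dplyr::bind_rows(fp, fi), exclusions = collect_excl(fp, fi))
  list(features = feats,
       tracks = list(vka_exposure = vka, ddi_partner_exposure = partner,
                     ddi_observation = obs, inr_ge_5 = high, inr_le_1_5 = low,
                     vka_potentiation = pot, vka_inhibition = inh),
       periods = list(study_period = study),
       definitions = list(defn_p, defn_i),
       exclusions = collect_excl(fp, fi))
}

case_sc8 <- function(bundle) {
  require_tables(bundle, c("person", "drug_exposure", "procedure_occurrence"), "sc8")
  per <- bundle$tables$person
  eligible <- as.character(per$person_id[!is.na(per$age) & per$age > 40])
  dr <- bundle$tables$drug_exposure
  dr_eleg <- dr[dr$person_id %in% eligible, ]
  sets <- copd_drug_sets()
  span <- study_span(bundle)
  persons <- as.character(per$person_id)
  study <- tibble::tibble(unit_id = persons, start = span[1], end = span[2])
  window <- tibble::tibble(unit_id = eligible, start = span[1], end = span[2])
  sel <- function(set) {
    if (nrow(dr_eleg) == 0) return(interval_tracks(track_concept = attr(set, "set_id")))
    select_events(dr_eleg, set, time_col = "drug_exposure_start_date")
  }
  cond <- union_tracks(
    union_tracks(count_condition_track(sel(sets$bronchodilator), 1, window,
                                       concept = "copd_criterion"),
                 count_condition_track(sel(sets$resp_antibiotic), 3, window,
                                       concept = "copd_criterion")),
    count_condition_track(sel(sets$nicotine_substitute), 1, window,
                          concept = "copd_criterion"))
  defn_s <- defn7("sc8_suspect", "Suspect COPD patient (age > 40 + drug criteria)",
                  "copd_suspect", "drug_exposure (ATC) + person.age",
                  "person", "copd_criterion",
                  "age > 40 and (>= 1 bronchodilator, or >= 3 respiratory antibiotics, or >= 1 nicotine substitute)",
                  "copd_criterion", "study_period", "exists")
  fs <- run_definition(defn_s, list(copd_criterion = cond), list(study_period = study))
  suspects <- fs$unit_id[fs$value_num == 1]
  all_copd <- sel(sets$all)
  suspect_events <- new_interval_tracks(all_copd[all_copd$unit_id %in% suspects, ])
  # anchor: first COPD-drug exposure of the suspect (fallback rule: first event)
  anchor <- select_milestone(suspect_events,
                             milestone_rule("first_copd_exposure", fallback = "first"),
                             units = suspects)
  year <- build_period(anchor, anchor, 0, 365 * DAY_S)
  spiro <- select_events(bundle$tables$procedure_occurrence,
                         event_set("spirometry_set", "spirometry"),
                         code_col = "procedure_concept_id",
                         time_col = "procedure_datetime", concept = "spirometry")
  defn_c <- defn7("sc8_admin_count", "COPD-drug administrations in the year after first exposure",
                  "copd_admin_count_1y", "drug_exposure (ATC)", "person",
                  "copd_drugs", "administrations of COPD-specific drugs",
                  "copd_drugs", "year_after_first_exposure", "count")
  defn_f <- defn7("sc8_fre", "Functional respiratory exploration within the year",
                  "fre_done_1y", "procedure_occurrence: spirometry", "person",
                  "spirometry", "spirometry / FRE procedure instants",
                  "spirometry", "year_after_first_exposure", "exists")
  fc <- run_definition(defn_c, list(copd_drugs = suspect_events),
                       list(year_after_first_exposure = year))
  ff <- run_definition(defn_f, list(spirometry = spiro),
                       list(year_after_first_exposure = year))
  feats <- new_features(dplyr::bind_rows(fs, fc, ff),
                        exclusions = collect_excl(fs, anchor, year, fc, ff))
  list(features = feats,
       tracks = list(copd_criterion = cond, copd_drugs = all_copd, spirometry = spiro),
       periods = list(study_period = study, year_after_first_exposure = year),
       definitions = list(defn_s, defn_c, defn_f),
       exclusions = collect_excl(fs, anchor, year, fc, ff))
}

# overall time span covered by a bundle (loose bounds are fine: it only has
# to contain every event)
study_span <- function(bundle) {
  ts <- c()
  grab <- function(x) suppressWarnings(tp_num(as_timepoint(x[!is.na(x) & x != ""])))
  tb <- bundle$tables
  if (!is.null(tb$visit_occurrence) && nrow(tb$visit_occurrence) > 0) {
    ts <- c(ts, grab(tb$visit_occurrence$visit_start_date),
            grab(tb$visit_occurrence$visit_end_date))
  }
  if (!is.null(tb$drug_exposure) && nrow(tb$drug_exposure) > 0) {
    ts <- c(ts, grab(tb$drug_exposure$drug_exposure_start_date))
  }
  if (!is.null(tb$measurement) && nrow(tb$measurement) > 0) {
    ts <- c(ts, range(grab(tb$measurement$measurement_datetime)))
  }
  if (!is.null(tb$procedure_occurrence) && nrow(tb$procedure_occurrence) > 0) {
    ts <- c(ts, grab(tb$procedure_occurrence$procedure_datetime))
  }
  if (length(ts) == 0) ts <- SIM_BASE
  tp_from_num(c(min(ts) - 400 * DAY_S, max(ts) + 400 * DAY_S))
}

#' Run one study-case pipeline on a raw-table bundle
#'
#' Executes the case's track-definition and track-aggregation steps in
#' order. When `out_dir` is given, persists every intermediate track to
#' `TRACK.csv`, the features to `FEATURE.csv`, the feature definitions to
#' `definitions.dcf` and the per-unit exclusions to `exclusions.csv`
#' (intermediates can be suppressed with `write_intermediates = FALSE`).
#'
#' @param case_id one of `"sc1"`..`"sc8"`.
#' @param bundle a bundle as produced by [simulate_bundle()] /
#'   [read_bundle()] (list with a `tables` element).
#' @param out_dir optional output directory.
#' @param write_intermediates persist intermediate tracks too (default) or
#'   only the final ones.
#' @return list with `features`, `tracks`, `periods`, `definitions`,
#'   `exclusions`.
#' @export
run_case <- function(case_id, bundle, out_dir = NULL, write_intermediates = TRUE) {
  case_id <- match.arg(case_id, paste0("sc", 1:8))
  fun <- switch(case_id, sc1 = case_sc1, sc2 = case_sc2, sc3 = case_sc3,
                sc4 = case_sc4, sc5 = case_sc5, sc6 = case_sc6,
                sc7 = case_sc7, sc8 = case_sc8)
  res <- fun(bundle)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tracks <- if (write_intermediates) res$tracks else utils::tail(res$tracks, 1)
    write_tracks(tracks, file.path(out_dir, "TRACK.csv"))
    write_features(res$features, file.path(out_dir, "FEATURE.csv"))
    write_definitions(res$definitions, file.path(out_dir, "definitions.dcf"))
    readr::write_csv(res$exclusions, file.path(out_dir, "exclusions.csv"), na = "")
  }
  res
}
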