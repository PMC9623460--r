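# Seeded generator of OMOP-style raw tables with planted ground truth for
# the eight study cases. Signals are built as ground-truth step functions
# whose value changes occur exactly at sample instants (every timestamp a
# whole second), so last-observation-carried-forward reconstruction at 1 s
# is exact and every planted truth can be computed analytically from the
# samples. Additive noise beyond the per-sample draws is off by design:
# truths live on the generated step function, not on an unobservable ideal.

# ---- shared code pools (also used by the casebook's concept sets) --------
LAROCHE_CODES <- c("N05BA01", "N05CD06", "N02AX02", "A03AB05", "C01BA01",
                   "N06AA04", "M01AB05", "R06AD02", "C04AD03", "G04BD07")
VKA_CODES <- c("B01AA03", "B01AA04")
DDI_PARTNER_CODES <- c("J01CA04", "M01AE01", "C03DA01")
BRONCHODILATOR_CODES <- c("R03AC02", "R03AL02", "R03BB04")
RESP_ANTIBIOTIC_CODES <- c("J01CA04", "J01FA09", "J01AA02")
NICOTINE_CODES <- c("N07BA01", "N07BA03")
ATROPINE_CODE <- "A03BA01"

SIM_BASE <- 1609459200  # 2021-01-01T00:00:00 UTC, the simulated study epoch

SCENARIOS <- c(paste0("sc", 1:8), "mixed")

# uniform integers on [lo, hi], driven by the single runif stream
rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
rint1 <- function(lo, hi) rint(1, lo, hi)

# run code under a seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- table scaffolds -----------------------------------------------------
empty_person <- function() tibble::tibble(person_id = character(), age = numeric(),
                                          ibw_kg = numeric())
empty_visit <- function() tibble::tibble(
  visit_occurrence_id = character(), person_id = character(),
  visit_concept_id = character(), visit_start_date = character(),
  visit_end_date = character(), visit_start_datetime = character(),
  visit_end_datetime = character(), septic_shock_ventilated = numeric())
empty_drug <- function() tibble::tibble(
  drug_exposure_id = character(), person_id = character(),
  visit_occurrence_id = character(), drug_concept_id = character(),
  drug_exposure_start_date = character(), drug_exposure_start_datetime = character(),
  days_supply = numeric())
empty_meas <- function() tibble::tibble(
  measurement_id = character(), person_id = character(),
  visit_occurrence_id = character(), measurement_concept_id = character(),
  measurement_datetime = character(), value_as_number = numeric())
empty_proc <- function() tibble::tibble(
  procedure_occurrence_id = character(), person_id = character(),
  visit_occurrence_id = character(), procedure_concept_id = character(),
  procedure_datetime = character())

akey <- function(unit_id, feature_concept, true_value) {
  tibble::tibble(unit_id = as.character(unit_id),
                 feature_concept = as.character(feature_concept),
                 true_value = as.numeric(true_value))
}

# ---- step-function machinery ---------------------------------------------
# irregular sample instants over [ds, de) with gaps uniform on gap_range,
# forced to include `force` instants (dip boundaries, window edges)
irregular_times <- function(ds, de, gap_range, force = numeric()) {
  n_est <- ceiling((de - ds) / gap_range[1]) + 2
  gaps <- rint(n_est, gap_range[1], gap_range[2])
  t <- ds + c(0, cumsum(gaps))
  t <- t[t < de]
  sort(unique(c(t, force[force >= ds & force < de])))
}

# step function segments (s, e, value) implied by samples over [ds, de)
step_segments <- function(times, values, de) {
  data.frame(s = times, e = c(times[-1], de), value = values)
}

clip_segments <- function(segs, ws, we) {
  s <- pmax(segs$s, ws); e <- pmin(segs$e, we)
  keep <- s < e
  data.frame(s = s[keep], e = e[keep], value = segs$value[keep])
}

seg_twmean <- function(segs) sum(segs$value * (segs$e - segs$s)) / sum(segs$e - segs$s)
seg_stats <- function(segs) {
  list(mean = seg_twmean(segs), min = min(segs$value), max = max(segs$value),
       median = weighted_median(segs$value, segs$e - segs$s))
}

# place k non-overlapping dip windows inside [ws, we); returns (s, e)
plant_dips <- function(ws, we, k, min_len = 60, max_len = 600) {
  if (k == 0) return(data.frame(s = numeric(0), e = numeric(0)))
  block <- floor((we - ws) / k)
  stopifnot(block >= min_len + 120)
  s <- e <- numeric(k)
  for (j in seq_len(k)) {
    bs <- ws + (j - 1) * block
    len <- rint1(min_len, min(max_len, block - 120))
    off <- rint1(1, block - len - 60)
    s[j] <- bs + off; e[j] <- s[j] + len
  }
  data.frame(s = s, e = e)
}

# samples for a signal with planted dips: value drawn from dip_range inside
# a dip, normal_range outside; boundaries are sample instants by force
dip_signal_samples <- function(ds, de, dips, normal_range, dip_range, gap_range) {
  times <- irregular_times(ds, de, gap_range,
                           force = c(dips$s, dips$e))
  in_dip <- vapply(times, function(t) any(t >= dips$s & t < dips$e), logical(1))
  v_norm <- stats::runif(length(times), normal_range[1], normal_range[2])
  v_dip <- stats::runif(length(times), dip_range[1], dip_range[2])
  data.frame(t = times, v = ifelse(in_dip, v_dip, v_norm))
}

meas_rows <- function(pid, vid, concept, t, v, id_prefix) {
  tibble::tibble(measurement_id = paste0(id_prefix, seq_along(t)),
                 person_id = pid, visit_occurrence_id = vid,
                 measurement_concept_id = concept,
                 measurement_datetime = fmt_datetime(tp_from_num(t)),
                 value_as_number = v)
}
proc_row <- function(pid, vid, concept, t, id) {
  tibble::tibble(procedure_occurrence_id = id, person_id = pid,
                 visit_occurrence_id = vid, procedure_concept_id = concept,
                 procedure_datetime = fmt_datetime(tp_from_num(t)))
}
drug_row_day <- function(id, pid, code, start_day_num, supply, vid = NA_character_) {
  tibble::tibble(drug_exposure_id = id, person_id = pid,
                 visit_occurrence_id = vid, drug_concept_id = code,
                 drug_exposure_start_date = fmt_date(tp_from_num(start_day_num)),
                 drug_exposure_start_datetime = NA_character_,
                 days_supply = supply)
}

# ---- per-scenario generators ---------------------------------------------

gen_sc1 <- function(n, gap_range) {
  person <- visit <- meas <- key <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("sc1p%03d", i); vid <- sprintf("sc1v%03d", i)
    t0 <- SIM_BASE + rint1(0, 364) * DAY_S + rint1(0, DAY_S - 1)
    stay_end <- t0 + rint1(2, 5) * DAY_S
    flag <- as.numeric(stats::runif(1) >= 0.1)  # ~10% not ventilated/septic
    person[[i]] <- tibble::tibble(person_id = pid, age = rint1(30, 85), ibw_kg = NA_real_)
    visit[[i]] <- tibble::tibble(
      visit_occurrence_id = vid, person_id = pid, visit_concept_id = "icu_stay",
      visit_start_date = fmt_date(tp_from_num(t0)), visit_end_date = fmt_date(tp_from_num(stay_end)),
      visit_start_datetime = fmt_datetime(tp_from_num(t0)),
      visit_end_datetime = fmt_datetime(tp_from_num(stay_end)),
      septic_shock_ventilated = flag)
    base <- stats::runif(1, 80, 110)
    times <- irregular_times(t0, t0 + DAY_S, gap_range)
    vals <- stats::runif(length(times), base - 15, base + 15)
    meas[[i]] <- meas_rows(pid, vid, "pao2", times, vals, sprintf("sc1m%03d_", i))
    if (flag == 1) {
      truth <- seg_twmean(step_segments(times, vals, t0 + DAY_S))
      key[[i]] <- akey(vid, "pao2_wmean_24h", truth)
    }
  }
  list(person = dplyr::bind_rows(person), visit = dplyr::bind_rows(visit),
       meas = dplyr::bind_rows(meas), key = dplyr::bind_rows(key))
}

gen_hypotension <- function(n, gap_range, prefix, events_fun, frac, dip_frac,
                            sig_concept, feat_concept) {
  # common engine for sc2/sc3: constant reference window then planted dips
  person <- visit <- meas <- proc <- key <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("%sp%03d", prefix, i); vid <- sprintf("%sv%03d", prefix, i)
    t0 <- SIM_BASE + rint1(0, 364) * DAY_S + rint1(0, DAY_S - 1)
    ev <- events_fun(i, pid, vid, t0)   # list(proc rows, ref window, dip window)
    person[[i]] <- tibble::tibble(person_id = pid, age = rint1(18, 90), ibw_kg = NA_real_)
    visit[[i]] <- tibble::tibble(
      visit_occurrence_id = vid, person_id = pid, visit_concept_id = "surgery",
      visit_start_date = fmt_date(tp_from_num(t0)),
      visit_end_date = fmt_date(tp_from_num(ev$de)),
      visit_start_datetime = fmt_datetime(tp_from_num(t0)),
      visit_end_datetime = fmt_datetime(tp_from_num(ev$de)),
      septic_shock_ventilated = NA_real_)
    proc[[i]] <- ev$proc
    B <- stats::runif(1, 75, 110)
    k <- rint1(1, ev$max_dips)
    dips <- plant_dips(ev$dip_ws, ev$dip_we, k,
                       min_len = 60, max_len = min(600, floor((ev$dip_we - ev$dip_ws) / k) - 120))
    # reference window: exactly constant B so the reference value is B
    ref_times <- irregular_times(ev$ref_ws, ev$ref_we, gap_range)
    ref_rows <- data.frame(t = ref_times, v = rep(B, length(ref_times)))
    dip_rows <- dip_signal_samples(ev$dip_ws, ev$dip_we, dips,
                                   normal_range = c((frac + 0.05) * B, 1.10 * B),
                                   dip_range = c(dip_frac[1] * B, dip_frac[2] * B),
                                   gap_range = gap_range)
    rows <- rbind(ref_rows, dip_rows)
    meas[[i]] <- meas_rows(pid, vid, sig_concept, rows$t, rows$v, sprintf("%sm%03d_", prefix, i))
    key[[i]] <- akey(vid, feat_concept, sum(dips$e - dips$s))
  }
  list(person = dplyr::bind_rows(person), visit = dplyr::bind_rows(visit),
       meas = dplyr::bind_rows(meas), proc = dplyr::bind_rows(proc),
       key = dplyr::bind_rows(key))
}

gen_sc2 <- function(n, gap_range) {
  gen_hypotension(n, gap_range, "sc2", function(i, pid, vid, t0) {
    incision <- t0 + 600
    de <- incision + rint1(3600, 7200)
    list(proc = dplyr::bind_rows(
           proc_row(pid, vid, "anesthesia_start", t0, sprintf("sc2e%03da", i)),
           proc_row(pid, vid, "incision", incision, sprintf("sc2e%03db", i)),
           proc_row(pid, vid, "anesthesia_end", de, sprintf("sc2e%03dc", i))),
         ref_ws = t0, ref_we = incision, dip_ws = incision, dip_we = de,
         de = de, max_dips = 3)
  }, frac = 0.90, dip_frac = c(0.78, 0.88),
  sig_concept = "map", feat_concept = "map_below90_duration_s")
}

gen_sc3 <- function(n, gap_range) {
  gen_hypotension(n, gap_range, "sc3", function(i, pid, vid, t0) {
    induction <- t0 + rint1(300, 900)
    birth <- induction + rint1(1500, 3600)
    # the procedure start may be documented by several events; the priority
    # rule must pick induction/hypnotic over later-priority documentation
    main <- if (stats::runif(1) < 0.7) "induction" else "hypnotic"
    pr <- dplyr::bind_rows(
      proc_row(pid, vid, "arrival_or", t0, sprintf("sc3e%03da", i)),
      proc_row(pid, vid, main, induction, sprintf("sc3e%03db", i)),
      proc_row(pid, vid, "birth", birth, sprintf("sc3e%03dc", i)))
    if (stats::runif(1) < 0.5) {  # distractor documented before the main event
      pr <- dplyr::bind_rows(pr,
        proc_row(pid, vid, "intubation", induction - rint1(30, 120), sprintf("sc3e%03dd", i)))
    }
    if (stats::runif(1) < 0.5) {
      pr <- dplyr::bind_rows(pr,
        proc_row(pid, vid, "ventilation", induction + rint1(30, 120), sprintf("sc3e%03de", i)))
    }
    list(proc = pr, ref_ws = t0, ref_we = induction,
         dip_ws = induction, dip_we = birth, de = birth, max_dips = 2)
  }, frac = 0.80, dip_frac = c(0.62, 0.78),
  sig_concept = "sap", feat_concept = "sap_below80_duration_s")
}

gen_sc4 <- function(n, gap_range) {
  person <- meas <- drug <- key <- list()
  made <- 0; ip <- 0
  while (made < n) {
    ip <- ip + 1
    pid <- sprintf("sc4p%03d", ip)
    n_adm <- min(rint1(1, 2), n - made)
    t0 <- SIM_BASE + rint1(0, 364) * DAY_S + rint1(0, DAY_S - 1)
    adm_t <- t0 + 700 + (seq_len(n_adm) - 1) * 4000
    ds <- t0; de <- max(adm_t) + 700
    times <- irregular_times(ds, de, gap_range, force = numeric())
    vals <- stats::runif(length(times), 45, 110)
    segs <- step_segments(times, vals, de)
    person[[ip]] <- tibble::tibble(person_id = pid, age = rint1(18, 90), ibw_kg = NA_real_)
    meas[[ip]] <- meas_rows(pid, NA_character_, "hr", times, vals, sprintf("sc4m%03d_", ip))
    dr <- list(); kk <- list()
    for (j in seq_len(n_adm)) {
      made <- made + 1
      aid <- sprintf("sc4adm%03d", made)
      dr[[j]] <- tibble::tibble(
        drug_exposure_id = aid, person_id = pid, visit_occurrence_id = NA_character_,
        drug_concept_id = ATROPINE_CODE,
        drug_exposure_start_date = fmt_date(tp_from_num(adm_t[j])),
        drug_exposure_start_datetime = fmt_datetime(tp_from_num(adm_t[j])),
        days_supply = 0)
      before <- seg_stats(clip_segments(segs, adm_t[j] - 600, adm_t[j]))
      after <- seg_stats(clip_segments(segs, adm_t[j], adm_t[j] + 600))
      kk[[j]] <- akey(rep(aid, 6),
                      c("hr_median_before", "hr_min_before", "hr_max_before",
                        "hr_median_after", "hr_min_after", "hr_max_after"),
                      c(before$median, before$min, before$max,
                        after$median, after$min, after$max))
    }
    drug[[ip]] <- dplyr::bind_rows(dr); key[[ip]] <- dplyr::bind_rows(kk)
  }
  list(person = dplyr::bind_rows(person), meas = dplyr::bind_rows(meas),
       drug = dplyr::bind_rows(drug), key = dplyr::bind_rows(key))
}

gen_sc5 <- function(n, gap_range) {
  person <- visit <- meas <- proc <- key <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("sc5p%03d", i); vid <- sprintf("sc5v%03d", i)
    t0 <- SIM_BASE + rint1(0, 364) * DAY_S + rint1(0, DAY_S - 1)
    de <- t0 + rint1(3600, 7200)
    ibw <- round(stats::runif(1, 50, 85), 1)
    compliant <- stats::runif(1) < 0.5
    r <- if (compliant) stats::runif(1, 6.2, 7.4) else stats::runif(1, 8.6, 9.8)
    times <- irregular_times(t0, de, gap_range)
    rates <- stats::runif(length(times), r - 0.5, r + 0.5)
    vt <- round(rates * ibw, 6)
    person[[i]] <- tibble::tibble(person_id = pid, age = rint1(18, 90), ibw_kg = ibw)
    visit[[i]] <- tibble::tibble(
      visit_occurrence_id = vid, person_id = pid, visit_concept_id = "surgery",
      visit_start_date = fmt_date(tp_from_num(t0)), visit_end_date = fmt_date(tp_from_num(de)),
      visit_start_datetime = fmt_datetime(tp_from_num(t0)),
      visit_end_datetime = fmt_datetime(tp_from_num(de)),
      septic_shock_ventilated = NA_real_)
    proc[[i]] <- dplyr::bind_rows(
      proc_row(pid, vid, "surgery_start", t0, sprintf("sc5e%03da", i)),
      proc_row(pid, vid, "surgery_end", de, sprintf("sc5e%03db", i)))
    meas[[i]] <- meas_rows(pid, vid, "tidal_volume_ml", times, vt, sprintf("sc5m%03d_", i))
    mean_rate <- seg_twmean(step_segments(times, vt / ibw, de))
    key[[i]] <- dplyr::bind_rows(
      akey(vid, "vt_ml_per_kg_mean", mean_rate),
      akey(vid, "vt_noncompliant", as.numeric(mean_rate > 8)))
  }
  list(person = dplyr::bind_rows(person), visit = dplyr::bind_rows(visit),
       meas = dplyr::bind_rows(meas), proc = dplyr::bind_rows(proc),
       key = dplyr::bind_rows(key))
}

gen_sc6 <- function(n, gap_range) {
  n_pers <- max(1, ceiling(n * 0.8))
  stays_per <- rep(1, n_pers)
  extra <- n - n_pers
  if (extra > 0) stays_per[seq_len(extra)] <- 2
  person <- visit <- drug <- key <- list()
  sv <- 0; sd <- 0
  for (ip in seq_len(n_pers)) {
    pid <- sprintf("sc6p%03d", ip)
    person[[ip]] <- tibble::tibble(person_id = pid, age = rint1(65, 95), ibw_kg = NA_real_)
    adm_prev_end <- SIM_BASE + 220 * DAY_S
    vv <- dd <- kk <- list()
    for (j in seq_len(stays_per[ip])) {
      sv <- sv + 1
      vid <- sprintf("sc6v%03d", sv)
      adm <- adm_prev_end + rint1(200, 260) * DAY_S
      len <- rint1(1, 14)
      disch <- adm + (len - 1) * DAY_S        # discharge date (day-level)
      stay_end <- disch + DAY_S               # occupied through discharge day
      adm_prev_end <- stay_end
      vv[[j]] <- tibble::tibble(
        visit_occurrence_id = vid, person_id = pid, visit_concept_id = "hospital_stay",
        visit_start_date = fmt_date(tp_from_num(adm)),
        visit_end_date = fmt_date(tp_from_num(disch)),
        visit_start_datetime = NA_character_, visit_end_datetime = NA_character_,
        septic_shock_ventilated = NA_real_)
      d_before <- rint1(0, 5)
      d_after <- rint1(0, 4)
      in_drugs <- sample(LAROCHE_CODES, d_before)
      aft_drugs <- sample(LAROCHE_CODES, d_after)
      rows <- list()
      for (code in in_drugs) {
        for (rr in seq_len(rint1(1, 2))) {
          sd <- sd + 1
          rows[[length(rows) + 1]] <- drug_row_day(
            sprintf("sc6d%04d", sd), pid, code,
            adm - rint1(6, 85) * DAY_S, rint1(1, 5))
        }
      }
      for (code in aft_drugs) {
        sd <- sd + 1
        rows[[length(rows) + 1]] <- drug_row_day(
          sprintf("sc6d%04d", sd), pid, code,
          stay_end + rint1(0, 84) * DAY_S, rint1(1, 5))
      }
      for (o in seq_len(rint1(0, 3) + 1) - 1) {  # 0..3 clearly-outside rows
        if (o == 0) next
        sd <- sd + 1
        # 100-110 d before admission: ends before the 90-day window opens and,
        # for a second stay, starts after the previous stay's 90-day
        # post-discharge window closed (stays are >= 200 days apart)
        rows[[length(rows) + 1]] <- drug_row_day(
          sprintf("sc6d%04d", sd), pid, sample(LAROCHE_CODES, 1),
          adm - rint1(100, 110) * DAY_S, rint1(1, 5))
      }
      sd <- sd + 1  # one non-Laroche drug inside the window
      rows[[length(rows) + 1]] <- drug_row_day(
        sprintf("sc6d%04d", sd), pid, "X99ZZ99", adm - rint1(6, 85) * DAY_S, rint1(1, 5))
      dd[[j]] <- dplyr::bind_rows(rows)
      kk[[j]] <- dplyr::bind_rows(
        akey(vid, "laroche_distinct_before", d_before),
        akey(vid, "laroche_distinct_after", d_after))
    }
    visit[[ip]] <- dplyr::bind_rows(vv)
    drug[[ip]] <- dplyr::bind_rows(dd)
    key[[ip]] <- dplyr::bind_rows(kk)
  }
  list(person = dplyr::bind_rows(person), visit = dplyr::bind_rows(visit),
       drug = dplyr::bind_rows(drug), key = dplyr::bind_rows(key))
}

gen_sc7 <- function(n, gap_range) {
  person <- drug <- meas <- key <- list()
  sd <- 0; sm <- 0
  for (ip in seq_len(n)) {
    pid <- sprintf("sc7p%03d", ip)
    person[[ip]] <- tibble::tibble(person_id = pid, age = rint1(40, 90), ibw_kg = NA_real_)
    m <- rint1(0, 2)
    pot <- 0; inh <- 0
    dd <- mm <- list()
    for (j in seq_len(m)) {
      a_day <- SIM_BASE + ((j - 1) * 200 + rint1(0, 50)) * DAY_S
      len_a <- rint1(10, 30)
      b_off <- rint1(1, len_a - 2)
      len_b <- rint1(5, 25)
      b_day <- a_day + b_off * DAY_S
      ov_s <- b_day
      ov_e <- min(a_day + len_a * DAY_S, b_day + len_b * DAY_S)
      obs_s <- ov_s + DAY_S; obs_e <- ov_e + 4 * DAY_S
      sd <- sd + 1
      dd[[length(dd) + 1]] <- drug_row_day(sprintf("sc7d%04d", sd), pid,
                                           sample(VKA_CODES, 1), a_day, len_a)
      sd <- sd + 1
      dd[[length(dd) + 1]] <- drug_row_day(sprintf("sc7d%04d", sd), pid,
                                           sample(DDI_PARTNER_CODES, 1), b_day, len_b)
      # daily INR at 08:00 around the episode, baseline safely in (1.5, 5)
      days <- seq(a_day - 5 * DAY_S, ov_e + 40 * DAY_S, by = DAY_S)
      inr <- stats::runif(length(days), 1.8, 3.4)
      typ <- sample(c("none", "pot", "inh"), 1, prob = c(0.4, 0.3, 0.3))
      if (typ != "none") {
        pick_day <- rint1(0, (obs_e - obs_s) / DAY_S - 1)
        idx <- which(days == obs_s + pick_day * DAY_S)
        inr[idx] <- if (typ == "pot") stats::runif(1, 5.2, 8) else stats::runif(1, 1.0, 1.4)
        if (typ == "pot") pot <- pot + 1 else inh <- inh + 1
      }
      sm <- sm + 1
      mm[[length(mm) + 1]] <- meas_rows(pid, NA_character_, "inr",
                                        days + 8 * HOUR_S, inr, sprintf("sc7m%03d_%d_", ip, j))
    }
    if (m == 0) {  # VKA alone, no interacting exposure, no observation period
      sd <- sd + 1
      dd[[1]] <- drug_row_day(sprintf("sc7d%04d", sd), pid, sample(VKA_CODES, 1),
                              SIM_BASE + rint1(0, 100) * DAY_S, rint1(10, 30))
    }
    drug[[ip]] <- dplyr::bind_rows(dd)
    meas[[ip]] <- if (length(mm) > 0) dplyr::bind_rows(mm) else empty_meas()
    key[[ip]] <- dplyr::bind_rows(
      akey(pid, "vka_potentiation_count", pot),
      akey(pid, "vka_inhibition_count", inh))
  }
  list(person = dplyr::bind_rows(person), drug = dplyr::bind_rows(drug),
       meas = dplyr::bind_rows(meas), key = dplyr::bind_rows(key))
}

gen_sc8 <- function(n, gap_range) {
  person <- drug <- proc <- key <- list()
  sd <- 0; sp <- 0
  for (ip in seq_len(n)) {
    pid <- sprintf("sc8p%03d", ip)
    age <- rint1(20, 80)
    person[[ip]] <- tibble::tibble(person_id = pid, age = age, ibw_kg = NA_real_)
    nb <- rint1(0, 2); na_ <- rint1(0, 4); nk <- rint1(0, 1)
    ev_days <- numeric(0); ev_codes <- character(0)
    add_ev <- function(k, pool) {
      for (q in seq_len(k)) {
        ev_days <<- c(ev_days, SIM_BASE + rint1(0, 300) * DAY_S)
        ev_codes <<- c(ev_codes, sample(pool, 1))
      }
    }
    add_ev(nb, BRONCHODILATOR_CODES)
    add_ev(na_, RESP_ANTIBIOTIC_CODES)
    add_ev(nk, NICOTINE_CODES)
    suspect <- age > 40 && (nb >= 1 || na_ >= 3 || nk >= 1)
    # extra administration beyond the 1-year window: only for already-suspect
    # patients (for others it would itself satisfy the drug criterion)
    late <- suspect && stats::runif(1) < 0.3 && length(ev_days) > 0
    anchor <- if (length(ev_days) > 0) min(ev_days) else NA
    if (late) {  # an administration beyond the 1-year window
      ev_days <- c(ev_days, anchor + rint1(400, 500) * DAY_S)
      ev_codes <- c(ev_codes, sample(BRONCHODILATOR_CODES, 1))
    }
    dd <- list()
    for (q in seq_along(ev_days)) {
      sd <- sd + 1
      dd[[q]] <- drug_row_day(sprintf("sc8d%04d", sd), pid, ev_codes[q],
                              ev_days[q], rint1(1, 30))
    }
    drug[[ip]] <- if (length(dd) > 0) dplyr::bind_rows(dd) else empty_drug()
    kk <- akey(pid, "copd_suspect", as.numeric(suspect))
    if (suspect) {
      in_window <- ev_days >= anchor & ev_days < anchor + 365 * DAY_S
      fre <- 0
      u <- stats::runif(1)
      if (u < 0.6) {
        sp <- sp + 1; fre <- 1
        proc[[length(proc) + 1]] <- proc_row(pid, NA_character_, "spirometry",
                                             anchor + rint1(10, 350) * DAY_S,
                                             sprintf("sc8e%03d", sp))
      } else if (u < 0.8) {  # spirometry outside the year window
        sp <- sp + 1
        proc[[length(proc) + 1]] <- proc_row(pid, NA_character_, "spirometry",
                                             anchor + rint1(380, 480) * DAY_S,
                                             sprintf("sc8e%03d", sp))
      }
      kk <- dplyr::bind_rows(kk,
        akey(pid, "copd_admin_count_1y", sum(in_window)),
        akey(pid, "fre_done_1y", fre))
    }
    key[[ip]] <- kk
  }
  list(person = dplyr::bind_rows(person), drug = dplyr::bind_rows(drug),
       proc = if (length(proc) > 0) dplyr::bind_rows(proc) else empty_proc(),
       key = dplyr::bind_rows(key))
}

# ---- public surface ------------------------------------------------------

#' Declare a simulation scenario
#'
#' The stated world of the generator: each scenario emulates the raw data
#' one study case needs (irregular intraoperative vitals, anesthesia
#' milestone events, day-level drug exposures, INR series, hospital stays)
#' with planted, exactly-known truths per unit.
#'
#' @param scenario one of `"sc1"`..`"sc8"` or `"mixed"`.
#' @param n_units number of statistical units to generate (>= 1).
#' @param seed integer seed; identical seeds give byte-identical bundles.
#' @param gap_range inter-sample gap range (seconds, uniform) for vital
#'   signs; the default 15–120 s reflects typical monitor archiving.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, n_units = 50, seed = 42,
                          gap_range = c(15, 120)) {
  scenario <- match.arg(scenario, SCENARIOS)
  stopifnot(n_units >= 1, length(gap_range) == 2, gap_range[1] >= 1,
            gap_range[2] >= gap_range[1])
  structure(list(scenario = scenario, n_units = n_units, seed = as.integer(seed),
                 gap_range = gap_range), class = "scenario_spec")
}

#' Generate a raw-table bundle with planted ground truth
#'
#' Writes nothing; returns in-memory OMOP-style tables (person,
#' visit_occurrence, drug_exposure, measurement, procedure_occurrence) plus
#' an answer key of the planted true feature values per unit. Same seed,
#' same bundle; the truths are defined on the generated step functions and
#' are unaffected by the irregular sampling.
#'
#' @param spec a [scenario_spec()], or a scenario name (with `...` passed
#'   to [scenario_spec()]).
#' @param ... used when `spec` is a scenario name.
#' @return list with elements `tables` (named list of tibbles),
#'   `answer_key` (tibble unit_id, feature_concept, true_value),
#'   `scenario`, `seed`.
#' @export
simulate_bundle <- function(spec, ...) {
  if (is.character(spec)) spec <- scenario_spec(spec, ...)
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    if (spec$scenario == "mixed") {
      per_sc <- max(1, ceiling(spec$n_units / 8))
      parts <- lapply(paste0("sc", 1:8), function(sc) {
        gen_one(sc, per_sc, spec$gap_range)
      })
      raw <- list(
        person = dplyr::bind_rows(lapply(parts, `[[`, "person")),
        visit = dplyr::bind_rows(lapply(parts, `[[`, "visit")),
        drug = dplyr::bind_rows(lapply(parts, `[[`, "drug")),
        meas = dplyr::bind_rows(lapply(parts, `[[`, "meas")),
        proc = dplyr::bind_rows(lapply(parts, `[[`, "proc")),
        key = dplyr::bind_rows(lapply(parts, `[[`, "key")))
    } else {
      raw <- gen_one(spec$scenario, spec$n_units, spec$gap_range)
    }
    tables <- list(
      person = dplyr::bind_rows(empty_person(), raw$person),
      visit_occurrence = dplyr::bind_rows(empty_visit(), raw$visit),
      drug_exposure = dplyr::bind_rows(empty_drug(), raw$drug),
      measurement = dplyr::bind_rows(empty_meas(), raw$meas),
      procedure_occurrence = dplyr::bind_rows(empty_proc(), raw$proc))
    list(tables = tables, answer_key = raw$key, scenario = spec$scenario,
         seed = spec$seed)
  })
}

gen_one <- function(scenario, n, gap_range) {
  out <- switch(scenario,
    sc1 = gen_sc1(n, gap_range), sc2 = gen_sc2(n, gap_range),
    sc3 = gen_sc3(n, gap_range), sc4 = gen_sc4(n, gap_range),
    sc5 = gen_sc5(n, gap_range), sc6 = gen_sc6(n, gap_range),
    sc7 = gen_sc7(n, gap_range), sc8 = gen_sc8(n, gap_range))
  for (nm in c("person", "visit", "drug", "meas", "proc", "key")) {
    if (is.null(out[[nm]])) {
      out[[nm]] <- switch(nm, person = empty_person(), visit = empty_visit(),
                          drug = empty_drug(), meas = empty_meas(),
                          proc = empty_proc(),
                          key = akey(character(0), character(0), numeric(0)))
    }
  }
  out
}

#' Write / read a bundle as delimited files
#'
#' One CSV per raw table plus `answer_key.csv` and a small `bundle.json`
#' with the scenario and seed; byte-deterministic for a given bundle.
#'
#' @param bundle result of [simulate_bundle()].
#' @param dir destination / source directory.
#' @return `write_bundle()` the directory invisibly; `read_bundle()` a
#'   bundle list.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    readr::write_csv(bundle$tables[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  readr::write_csv(bundle$answer_key, file.path(dir, "answer_key.csv"), na = "")
  jsonlite::write_json(list(scenario = bundle$scenario, seed = bundle$seed),
                       file.path(dir, "bundle.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bundle.json"))
  tables <- lapply(c(person = "person", visit_occurrence = "visit_occurrence",
                     drug_exposure = "drug_exposure", measurement = "measurement",
                     procedure_occurrence = "procedure_occurrence"),
                   function(nm) {
    tibble::as_tibble(utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                      colClasses = "character"))
  })
  # restore numeric columns
  num_cols <- list(person = c("age", "ibw_kg"), visit_occurrence = "septic_shock_ventilated",
                   drug_exposure = "days_supply", measurement = "value_as_number")
  for (nm in names(num_cols)) {
    for (cc in num_cols[[nm]]) {
      if (cc %in% names(tables[[nm]])) {
        tables[[nm]][[cc]] <- suppressWarnings(as.numeric(tables[[nm]][[cc]]))
      }
    }
  }
  key <- tibble::as_tibble(utils::read.csv(file.path(dir, "answer_key.csv"),
                                           colClasses = "character"))
  key$true_value <- as.numeric(key$true_value)
  list(tables = tables, answer_key = key, scenario = meta$scenario, seed = meta$seed)
}
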