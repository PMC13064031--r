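# Synthetic-exercise generator: vignettes, waved arrivals, triage decisions
# with a clustered misclassification model, service times, roster and
# questionnaires. Track rendering lives in tracks.R; everything here is
# driven by named RNG substreams of the master seed so identical configs
# produce identical exercises.

#' Default triage rule list
#'
#' Ordered feature-predicate rules (first match wins, default category III)
#' approximating an in-hospital triage algorithm in cABCDE order:
#' catastrophic haemorrhage, airway, breathing, circulation, disability
#' criteria map to category I (including the peri-arrest and
#' obstructed-airway criteria), serious-but-not-immediate injuries to
#' category II. Only the category-I criteria are fixed by the benchmark
#' algorithm; the remainder is an explicitly configurable placeholder list.
#'
#' @return data.frame `feature, category` in priority order.
#' @export
default_triage_rules <- function() {
  data.frame(
    feature = c("massive_hemorrhage",          # c
                "airway_obstructed",           # A
                "peri_arrest",                 # A/B
                "respiratory_distress",        # B
                "shock",                       # C
                "unresponsive",                # D
                "blast_trauma",                # II
                "open_fracture", "fracture", "deep_burn", "major_laceration"),
    category = c(rep("I", 6), rep("II", 5)),
    stringsAsFactors = FALSE)
}

#' Apply the triage rule list to one vignette
#'
#' @param features character vector of feature flags.
#' @param rules rule data.frame ([default_triage_rules()]); an empty list
#'   yields the default category III.
#' @return assigned category (`"I"`, `"II"` or `"III"`).
#' @export
triage_rule_engine <- function(features, rules = default_triage_rules()) {
  if (NROW(rules)) {
    for (i in seq_len(nrow(rules))) {
      if (rules$feature[i] %in% features) return(rules$category[i])
    }
  }
  "III"
}

#' Sample patient vignettes
#'
#' Expected categories are multinomial with the configured 30/30/40 mix.
#' Category-I vignettes get one leading injury among abdominal, thoracic,
#' amputation, burn and TBI/other at 20% each, plus a category-I severity
#' flag (peri-arrest, obstructed airway, massive haemorrhage or shock) so
#' the rule engine reproduces the expected category. A configurable
#' fraction of category-II vignettes carries `blast_trauma` (deafness and
#' bleeding from the ear); the rest get another category-II flag.
#'
#' @param config `mci_sim_config`.
#' @param n number of vignettes (default `config$n_patients`).
#' @return vignette data.frame (`patient_id, expected_category, features,
#'   tag_id`); the first `n_tracked_patients` get tag ids.
#' @export
sample_vignettes <- function(config, n = config$n_patients) {
  with_substream(config$seed, "vignettes", {
    if (n == 0) {
      return(data.frame(patient_id = character(),
                        expected_category = character(),
                        features = character(), tag_id = character(),
                        stringsAsFactors = FALSE))
    }
    cat <- sample(TRIAGE_LEVELS, n, replace = TRUE, prob = config$category_mix)
    sev_I <- c("peri_arrest", "airway_obstructed", "massive_hemorrhage",
               "shock")
    inj_I <- c("abdominal", "thoracic", "amputation", "burn", "tbi")
    flag_II <- c("open_fracture", "fracture", "deep_burn", "major_laceration")
    flag_III <- c("abrasion", "sprain", "minor_laceration")
    features <- character(n)
    for (i in seq_len(n)) {
      features[i] <- switch(cat[i],
        I = paste(c(sample(sev_I, 1), sample(inj_I, 1, prob = rep(0.2, 5))),
                  collapse = ";"),
        II = if (stats::runif(1) < config$blast_fraction) "blast_trauma"
             else sample(flag_II, 1),
        III = sample(flag_III, 1))
    }
    ntr <- min(config$n_tracked_patients, n)
    tags <- c(sprintf("PT%03d", seq_len(ntr)), rep(NA_character_, n - ntr))
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               expected_category = cat, features = features,
               tag_id = tags, stringsAsFactors = FALSE)
  })
}

#' Sample waved arrival times
#'
#' A cluster process: wave centers uniform over
#' `[first_arrival_min, arrival_last_min]`, patients assigned to waves
#' uniformly, Gaussian within-wave jitter, all arrivals clamped to the
#' window, so no arrival precedes `first_arrival_min`.
#'
#' @param config `mci_sim_config`.
#' @param n number of patients.
#' @return numeric vector of arrival times in minutes since the alarm.
#' @export
sample_arrivals <- function(config, n = config$n_patients) {
  with_substream(config$seed, "arrivals", {
    if (n == 0) return(numeric())
    lo <- config$first_arrival_min
    hi <- config$arrival_last_min
    centers <- sort(stats::runif(config$n_waves, lo, hi))
    wave <- sample.int(config$n_waves, n, replace = TRUE)
    t <- centers[wave] + stats::rnorm(n, 0, config$wave_sd_min)
    pmin(pmax(t, lo), hi)
  })
}

#' Sample per-patient triage service times
#'
#' Lognormal, moment-matched to the configured per-category mean and SD and
#' truncated below at `service_min_s` (resampling): positive, right-skewed
#' durations.
#'
#' @param config `mci_sim_config`.
#' @param categories character vector of (assigned) categories.
#' @return numeric vector of service times in seconds.
#' @export
sample_service_times <- function(config, categories) {
  with_substream(config$seed, "service", {
    ts <- config$triage_service
    out <- numeric(length(categories))
    for (k in seq_len(nrow(ts))) {
      idx <- which(categories == ts$category[k])
      if (!length(idx)) next
      m <- ts$mean_s[k]; s <- ts$sd_s[k]
      sig2 <- log(1 + (s / m)^2)
      mu <- log(m) - sig2 / 2
      x <- stats::rlnorm(length(idx), mu, sqrt(sig2))
      while (any(x < config$service_min_s)) {
        bad <- x < config$service_min_s
        x[bad] <- stats::rlnorm(sum(bad), mu, sqrt(sig2))
      }
      out[idx] <- x
    }
    out
  })
}

#' @keywords internal
#' @noRd
draw_assigned <- function(expected, blast, m, bias) {
  n <- length(expected)
  out <- character(n)
  for (i in seq_len(n)) {
    row <- m[expected[i], ]
    a <- sample(TRIAGE_LEVELS, 1, prob = row)
    # masked serious injury: blast-trauma II kept at II may still read green
    if (a == "II" && expected[i] == "II" && blast[i] &&
        stats::runif(1) < bias) {
      a <- "III"
    }
    out[i] <- a
  }
  out
}

#' Sample stage-1 and stage-2 triage decisions
#'
#' Stage-2 categories are drawn from the stage-2 misclassification matrix
#' given the expected category; blast-trauma expected-II vignettes whose
#' draw kept them at II are downgraded to III with probability
#' `blast_trauma_green_bias`. The stage-1 decision copies stage 2 with
#' probability `stage_correlation` and is otherwise drawn independently
#' from the stage-1 matrix (the benchmark implies similar but not identical
#' error sets at the two triage points).
#'
#' @param vignettes vignette data.frame.
#' @param config `mci_sim_config`.
#' @param arrivals_min optional arrival times (minutes) used for
#'   `t_assign_ms`; stage 1 is stamped at arrival, stage 2 at arrival +
#'   2 min.
#' @return triage record data.frame (`patient_id, stage, assigned_category,
#'   t_assign_ms`).
#' @export
sample_triage_decisions <- function(vignettes, config, arrivals_min = NULL) {
  with_substream(config$seed, "decisions", {
    n <- nrow(vignettes)
    if (!n) {
      return(data.frame(patient_id = character(), stage = integer(),
                        assigned_category = character(),
                        t_assign_ms = numeric(), stringsAsFactors = FALSE))
    }
    blast <- vapply(vignette_features(vignettes$features),
                    function(f) "blast_trauma" %in% f, TRUE)
    s2 <- draw_assigned(vignettes$expected_category, blast,
                        config$misclassification_stage2,
                        config$blast_trauma_green_bias)
    s1 <- draw_assigned(vignettes$expected_category, blast,
                        config$misclassification_stage1,
                        config$blast_trauma_green_bias)
    copy <- stats::runif(n) < config$stage_correlation
    s1[copy] <- s2[copy]
    if (is.null(arrivals_min)) arrivals_min <- rep(NA_real_, n)
    data.frame(patient_id = rep(vignettes$patient_id, 2),
               stage = rep(c(1L, 2L), each = n),
               assigned_category = c(s1, s2),
               t_assign_ms = c(arrivals_min * 60000,
                               (arrivals_min + 2) * 60000),
               stringsAsFactors = FALSE)
  })
}

#' Sample the participant roster
#'
#' Group sizes, gender ratios, age and experience distributions follow the
#' benchmark demographics: 46 physicians (27 residents, 19 specialists),
#' 41 nurses, 6 nursing trainees, 5 others; 75 participants carry tags.
#' Ages and experience are drawn from per-group normal distributions
#' clamped to the reported ranges.
#'
#' @param config `mci_sim_config`.
#' @return roster data.frame.
#' @export
sample_roster <- function(config) {
  with_substream(config$seed, "roster", {
    grp <- c(rep("physician", 46), rep("nurse", 41), rep("nurse_trainee", 6),
             rep("other", 5))
    n <- length(grp)
    specialist <- rep(NA, n)
    specialist[grp == "physician"] <- rep(c(FALSE, TRUE), c(27, 19))
    # per-group (age mean, sd, min, max), (exp mean, sd, min, max), P(female)
    pars <- list(
      physician_res = list(age = c(31, 3, 26, 40), exp = c(3.5, 2.5, 0, 10), pf = 0.35),
      physician_spec = list(age = c(39, 5, 30, 49), exp = c(12, 5, 5, 22), pf = 0.35),
      nurse = list(age = c(37.5, 12.2, 21, 66), exp = c(14.9, 13.3, 0.5, 44), pf = 0.75),
      nurse_trainee = list(age = c(22, 2.2, 20, 25), exp = c(2.3, 1.1, 0, 3), pf = 0.67),
      other = list(age = c(51, 10.4, 32, 61), exp = c(24.8, 10.5, 7, 34), pf = 0.40))
    key <- ifelse(grp == "physician",
                  ifelse(specialist, "physician_spec", "physician_res"), grp)
    draw <- function(p, k) {
      v <- stats::rnorm(sum(key == k), p[1], p[2])
      pmin(pmax(v, p[3]), p[4])
    }
    age <- experience <- numeric(n); gender <- character(n)
    for (k in unique(key)) {
      idx <- key == k
      age[idx] <- round(draw(pars[[k]]$age, k))
      experience[idx] <- round(draw(pars[[k]]$exp, k), 1)
      gender[idx] <- ifelse(stats::runif(sum(idx)) < pars[[k]]$pf,
                            "female", "male")
    }
    tagged <- sample.int(n, min(config$n_staff_tagged, n))
    tag <- rep(NA_character_, n)
    tag[tagged] <- sprintf("ST%03d", seq_along(tagged))
    data.frame(code = sprintf("C%03d", sample.int(n)), group = grp,
               specialist = specialist, experience_years = experience,
               age_years = age, gender = gender, tag_id = tag,
               stringsAsFactors = FALSE)
  })
}

#' Sample NASA-TLX and TEAM questionnaire responses
#'
#' Raw-TLX totals are drawn per participant from the configured group
#' mean/SD (residents vs specialists vs nurses vs trainees vs others); the
#' six items are the configured subscale means shifted by the respondent's
#' total deviation split evenly, plus unit-SD item noise, rounded and
#' clamped to 1-20. TEAM items are discretized normals on 0-4 with the
#' leader items lowest and team morale highest. Nonresponse is Bernoulli
#' per respondent at `1 - response_rate`; missing respondents are simply
#' absent (never imputed).
#'
#' @param roster roster data.frame ([sample_roster()]).
#' @param config `mci_sim_config`.
#' @return list with `tlx` and `team` data.frames.
#' @export
sample_questionnaires <- function(roster, config) {
  with_substream(config$seed, "questionnaires", {
    n <- nrow(roster)
    key <- ifelse(roster$group == "physician",
                  ifelse(roster$specialist, "specialist", "resident"),
                  ifelse(roster$group == "nurse", "nurse",
                         ifelse(roster$group == "nurse_trainee",
                                "nurse_trainee", "other")))
    gp <- config$tlx_groups
    mu_t <- gp$mean[match(key, gp$key)]
    sd_t <- gp$sd[match(key, gp$key)]
    total <- stats::rnorm(n, mu_t, sd_t)
    mus <- config$tlx_item_means
    items <- sapply(seq_along(mus), function(j) {
      v <- mus[j] + (total - sum(mus)) / 6 + stats::rnorm(n, 0, 1)
      pmin(pmax(round(v), 1), 20)
    })
    colnames(items) <- TLX_ITEMS
    tlx <- data.frame(code = roster$code, items, stringsAsFactors = FALSE)
    respond <- stats::runif(n) < config$response_rate
    tlx <- tlx[respond, , drop = FALSE]

    tm <- sapply(seq_along(config$team_item_means), function(j) {
      v <- stats::rnorm(n, config$team_item_means[j], config$team_item_sds[j])
      pmin(pmax(round(v), 0), 4)
    })
    colnames(tm) <- paste0("item", 1:11)
    team <- data.frame(code = roster$code, tm,
                       global = pmin(pmax(round(stats::rnorm(n, 7.9, 1.2)), 1), 10),
                       rater_role = "self", stringsAsFactors = FALSE)
    respond_team <- stats::runif(n) < config$response_rate
    team <- team[respond_team, , drop = FALSE]
    rownames(tlx) <- rownames(team) <- NULL
    list(tlx = tlx, team = team)
  })
}

#' Generate a complete synthetic exercise
#'
#' Runs every generator component and returns all observable tables plus
#' the latent ground truth (true categories, sampled service times, the
#' contact plan). With `tracks = TRUE` a full RTLS position stream is
#' rendered (see [generate_tracks()]) and the zone-episode/contact tables
#' are what the spatiotemporal pipeline measures; with `tracks = FALSE`
#' (the cheap mode used for large replicate studies) zone episodes and
#' contacts are emitted directly from the ground truth.
#'
#' @param config `mci_sim_config`.
#' @param tracks render RTLS position samples (default `FALSE`).
#' @return object of class `mci_exercise`: list of tables (`vignettes`,
#'   `roster`, `triage`, `tlx`, `team`, `zones`, `episodes`, `contacts`,
#'   optionally `positions`) plus `ground_truth` and `config`.
#' @export
simulate_exercise <- function(config = mci_sim_config(), tracks = FALSE) {
  vg <- sample_vignettes(config)
  arr <- sample_arrivals(config, nrow(vg))
  tri <- sample_triage_decisions(vg, config, arrivals_min = arr)
  s2 <- tri[tri$stage == 2L, ]
  assigned2 <- s2$assigned_category[match(vg$patient_id, s2$patient_id)]
  service_s <- sample_service_times(config, assigned2)
  roster <- sample_roster(config)
  qn <- sample_questionnaires(roster, config)
  zones <- default_zones()
  plan <- plan_exercise(vg, arr, tri, service_s, roster, config, zones)
  ex <- list(vignettes = vg, roster = roster, triage = tri,
             tlx = qn$tlx, team = qn$team, zones = zones,
             episodes = plan$episodes, contacts = plan$contacts,
             positions = NULL,
             ground_truth = list(arrival_min = arr, service_s = service_s,
                                 assigned2 = assigned2,
                                 itinerary = plan$itinerary,
                                 contact_plan = plan$contact_plan),
             config = config)
  class(ex) <- "mci_exercise"
  if (tracks) {
    ex$positions <- generate_tracks(ex, config)
  }
  ex
}

#' @export
print.mci_exercise <- function(x, ...) {
  cat("Synthetic MCI exercise\n")
  cat(sprintf("  %d patients (%d tracked), %d roster entries (%d tagged)\n",
              nrow(x$vignettes),
              sum(!is.na(x$vignettes$tag_id)),
              nrow(x$roster), sum(!is.na(x$roster$tag_id))))
  cat(sprintf("  %d triage records, %d zone episodes, %d contact episodes\n",
              nrow(x$triage), nrow(x$episodes), nrow(x$contacts)))
  if (!is.null(x$positions)) {
    cat(sprintf("  %d position samples\n", nrow(x$positions)))
  }
  invisible(x)
}

# Build the timed exercise plan: per-patient zone itinerary (triage2 dwell =
# sampled service time, category-appropriate treatment zone, transport) and
# the staff-patient contact plan, plus the episode/contact tables implied by
# it. Tracked patients only appear in RTLS-derived tables.
#' @keywords internal
#' @noRd
plan_exercise <- function(vg, arr, tri, service_s, roster, config,
                          zones = default_zones()) {
  with_substream(config$seed, "plan", {
    n <- nrow(vg)
    if (!n) {
      empty_ep <- data.frame(tag_id = character(), zone_id = character(),
                             t_enter_ms = numeric(), t_exit_ms = numeric(),
                             stringsAsFactors = FALSE)
      empty_ct <- data.frame(staff_tag = character(),
                             patient_tag = character(),
                             t_start_ms = numeric(), t_end_ms = numeric(),
                             min_distance_m = numeric(),
                             stringsAsFactors = FALSE)
      return(list(episodes = empty_ep, contacts = empty_ct,
                  contact_plan = empty_ct[, 1:4], itinerary = NULL))
    }
    s1 <- tri[tri$stage == 1L, ]; s2 <- tri[tri$stage == 2L, ]
    a1 <- s1$assigned_category[match(vg$patient_id, s1$patient_id)]
    a2 <- s2$assigned_category[match(vg$patient_id, s2$patient_id)]
    # itinerary times in ms
    t_arr <- arr * 60000
    t1_dwell <- stats::runif(n, 15, 30) * 1000          # first-look
    walk1 <- stats::runif(n, 20, 40) * 1000             # to triage2
    t2_enter <- t_arr + t1_dwell + walk1
    t2_exit <- t2_enter + service_s * 1000
    walk2 <- stats::runif(n, 30, 60) * 1000             # to treatment
    treat_enter <- t2_exit + walk2
    treat_dwell <- pmin(10 + stats::rexp(n, 1 / 8), 30) * 60000
    treat_exit <- treat_enter + treat_dwell
    trans_enter <- treat_exit + stats::runif(n, 20, 40) * 1000
    trans_exit <- trans_enter + stats::runif(n, 40, 90) * 1000
    triage2_zone <- ifelse(a1 == "III", "triage2_green", "triage2_main")
    treat_zone <- unname(c(I = "treatment_red", II = "treatment_yellow",
                           III = "treatment_green")[a2])
    trans_zone <- ifelse(a2 == "III", "transport_f0", "transport_f1")
    tracked <- !is.na(vg$tag_id)
    grid <- function(t) round(t / 500) * 500
    # align planned crossings to the grid so rendered tracks reproduce them
    t_arr <- grid(t_arr); t1_exit <- grid(t_arr + t1_dwell)
    t2_enter <- grid(t2_enter); t2_exit <- grid(t2_exit)
    treat_enter <- grid(treat_enter); treat_exit <- grid(treat_exit)
    trans_enter <- grid(trans_enter); trans_exit <- grid(trans_exit)
    # bed: a fixed interior point of the treatment zone, margin 1.5 m
    zb <- lapply(zones, function(z) {
      c(range(z$polygon[, 1]), range(z$polygon[, 2]))
    })
    names(zb) <- vapply(zones, `[[`, "", "zone_id")
    bed_x <- bed_y <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      b <- zb[[treat_zone[i]]]
      bed_x[i] <- stats::runif(1, b[1] + 1.5, b[2] - 1.5)
      bed_y[i] <- stats::runif(1, b[3] + 1.5, b[4] - 1.5)
    }
    itinerary <- data.frame(
      patient_id = vg$patient_id, tag_id = vg$tag_id,
      t_arr = t_arr, t1_exit = t1_exit,
      t2_enter = t2_enter, t2_exit = t2_exit,
      treat_enter = treat_enter, treat_exit = treat_exit,
      trans_enter = trans_enter, trans_exit = trans_exit,
      triage1_zone = "triage1", triage2_zone = triage2_zone,
      treat_zone = treat_zone, trans_zone = trans_zone,
      bed_x = bed_x, bed_y = bed_y, stringsAsFactors = FALSE)
    episodes <- rbind(
      data.frame(tag_id = vg$tag_id, zone_id = "triage1",
                 t_enter_ms = t_arr, t_exit_ms = t1_exit),
      data.frame(tag_id = vg$tag_id, zone_id = triage2_zone,
                 t_enter_ms = t2_enter, t_exit_ms = t2_exit),
      data.frame(tag_id = vg$tag_id, zone_id = treat_zone,
                 t_enter_ms = treat_enter, t_exit_ms = treat_exit),
      data.frame(tag_id = vg$tag_id, zone_id = trans_zone,
                 t_enter_ms = trans_enter, t_exit_ms = trans_exit))
    episodes <- episodes[!is.na(episodes$tag_id), , drop = FALSE]
    episodes <- episodes[order(episodes$tag_id, episodes$t_enter_ms), ]
    rownames(episodes) <- NULL

    # contact plan: staff visits during treatment windows
    staff <- roster[!is.na(roster$tag_id), , drop = FALSE]
    w <- stats::rgamma(nrow(staff), shape = config$staff_weight_shape,
                       rate = config$staff_weight_shape)
    plan_rows <- list()
    for (i in which(tracked)) {
      k <- stats::rpois(1, config$contacts_per_patient_mean)
      if (k == 0) next
      k <- min(k, nrow(staff))
      who <- sample.int(nrow(staff), k, prob = w)
      # schedule visits inside the treatment window
      win <- c(treat_enter[i], treat_exit[i])
      dur <- stats::runif(k, 60, 240) * 1000
      start <- stats::runif(k, win[1], pmax(win[1], win[2] - dur))
      end <- pmin(start + dur, win[2])
      keep <- end - start >= 1000
      if (!any(keep)) next
      plan_rows[[length(plan_rows) + 1L]] <- data.frame(
        staff_tag = staff$tag_id[who[keep]], patient_tag = vg$tag_id[i],
        zone_id = treat_zone[i],
        t_start_ms = grid(start[keep]), t_end_ms = grid(end[keep]),
        win_end_ms = treat_exit[i], stringsAsFactors = FALSE)
    }
    contact_plan <- do.call(rbind, c(plan_rows, list(make.row.names = FALSE)))
    if (is.null(contact_plan)) {
      contact_plan <- data.frame(staff_tag = character(),
                                 patient_tag = character(),
                                 zone_id = character(),
                                 t_start_ms = numeric(), t_end_ms = numeric(),
                                 stringsAsFactors = FALSE)
    }
    # a staff member is one place at a time: visits overlapping a previously
    # scheduled visit of the same person (10 s walking buffer) are shifted
    # later within the patient's treatment window, and dropped only when
    # they no longer fit
    if (nrow(contact_plan)) {
      contact_plan <- contact_plan[order(contact_plan$staff_tag,
                                         contact_plan$t_start_ms), ]
      keep <- rep(TRUE, nrow(contact_plan))
      last_end <- -Inf; last_tag <- ""
      for (j in seq_len(nrow(contact_plan))) {
        if (contact_plan$staff_tag[j] != last_tag) last_end <- -Inf
        if (contact_plan$t_start_ms[j] < last_end + 10000) {
          dur <- contact_plan$t_end_ms[j] - contact_plan$t_start_ms[j]
          new_start <- last_end + 10000
          new_end <- min(new_start + dur, contact_plan$win_end_ms[j])
          if (new_end - new_start >= 30000) {
            contact_plan$t_start_ms[j] <- new_start
            contact_plan$t_end_ms[j] <- new_end
          } else {
            keep[j] <- FALSE
          }
        }
        if (keep[j]) last_end <- contact_plan$t_end_ms[j]
        last_tag <- contact_plan$staff_tag[j]
      }
      contact_plan <- contact_plan[keep, , drop = FALSE]
      contact_plan$win_end_ms <- NULL
      rownames(contact_plan) <- NULL
    }
    contacts <- data.frame(staff_tag = contact_plan$staff_tag,
                           patient_tag = contact_plan$patient_tag,
                           t_start_ms = contact_plan$t_start_ms,
                           t_end_ms = contact_plan$t_end_ms,
                           min_distance_m = stats::runif(nrow(contact_plan),
                                                         0.2, 0.7),
                           stringsAsFactors = FALSE)
    list(episodes = episodes, contacts = contacts,
         contact_plan = contact_plan, itinerary = itinerary)
  })
}

#' Write a synthetic exercise to disk
#'
#' Emits every analyzer input (`positions.csv` if rendered, `zones.json`,
#' `roster.csv`, `vignettes.csv`, `triage.csv`, `tlx.csv`, `team.csv`,
#' `episodes.csv`, `contacts.csv`) plus a `ground_truth.json` sidecar.
#'
#' @param exercise `mci_exercise`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_exercise <- function(exercise, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(exercise$positions)) {
    write_positions(exercise$positions, p("positions.csv"))
  }
  write_zones(exercise$zones, p("zones.json"))
  write_table(exercise$roster, p("roster.csv"))
  write_table(exercise$vignettes, p("vignettes.csv"))
  write_table(exercise$triage, p("triage.csv"))
  write_table(exercise$tlx, p("tlx.csv"))
  write_table(exercise$team, p("team.csv"))
  write_table(exercise$episodes, p("episodes.csv"))
  write_table(exercise$contacts, p("contacts.csv"))
  jsonlite::write_json(exercise$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read an exercise dataset from disk
#'
#' Counterpart of [write_exercise()]; missing optional files yield `NULL`
#' entries.
#'
#' @param dir dataset directory.
#' @return list of tables usable by [mci_analyze()].
#' @export
read_exercise <- function(dir) {
  p <- function(f) file.path(dir, f)
  opt <- function(f, reader, ...) {
    if (file.exists(p(f))) reader(p(f), ...) else NULL
  }
  list(positions = opt("positions.csv", read_positions),
       zones = opt("zones.json", read_zones),
       roster = opt("roster.csv", read_roster),
       vignettes = opt("vignettes.csv", read_vignettes),
       triage = opt("triage.csv", read_triage),
       tlx = opt("tlx.csv", read_questionnaires, instrument = "tlx"),
       team = opt("team.csv", read_questionnaires, instrument = "team"),
       episodes = opt("episodes.csv", utils::read.csv,
                      stringsAsFactors = FALSE),
       contacts = opt("contacts.csv", utils::read.csv,
                      stringsAsFactors = FALSE))
}
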