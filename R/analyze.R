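# Full exercise analysis: a pure function of the input tables (no hidden
# state, no clock) producing a report bundle shaped like the benchmark
# tables - two-stage triage accuracy, triage timing by category, contacts
# per participant group, demographics, NASA-TLX and TEAM summaries with the
# stars convention.

#' Analyze an exercise dataset
#'
#' Accepts either an `mci_exercise`, a directory written by
#' [write_exercise()]/[cmd_simulate()], or a plain list of tables
#' (`vignettes`, `triage`, `roster`, and optionally `positions`, `zones`,
#' `episodes`, `contacts`, `tlx`, `team`). When raw positions are present
#' the spatiotemporal pipeline (regularization, zone episodes, contact
#' detection) is run; otherwise precomputed `episodes`/`contacts` tables
#' are used. Sections whose inputs are missing are omitted with a notice.
#'
#' @param x exercise data (see above).
#' @param experience_split split questionnaire contrasts at the median
#'   experience (ties go to the more experienced half), default `TRUE`.
#' @return object of class `mci_analysis`.
#' @export
mci_analyze <- function(x, experience_split = TRUE) {
  if (is.character(x)) x <- read_exercise(x)
  notes <- character()
  res <- list()

  zones <- x$zones
  episodes <- x$episodes
  contacts <- x$contacts
  patient_tags <- if (!is.null(x$vignettes)) {
    x$vignettes$tag_id[!is.na(x$vignettes$tag_id)]
  } else character()
  staff_tags <- if (!is.null(x$roster)) {
    x$roster$tag_id[!is.na(x$roster$tag_id)]
  } else character()

  if (!is.null(x$positions) && nrow(x$positions) && !is.null(zones)) {
    tracks <- regularize_all(x$positions)
    episodes <- zone_episodes_all(tracks, zones)
    contacts <- detect_contacts_all(tracks, staff_tags, patient_tags)
  }

  # triage accuracy ---------------------------------------------------
  if (!is.null(x$vignettes) && !is.null(x$triage)) {
    tracked_vg <- x$vignettes[!is.na(x$vignettes$tag_id), , drop = FALSE]
    res$confusion <- lapply(c(1, 2), function(s) {
      cm <- build_confusion(tracked_vg, x$triage, s)
      list(confusion = cm,
           metrics = if (cm$n_total > 0) accuracy_metrics(cm) else NULL)
    })
    names(res$confusion) <- c("stage1", "stage2")
  } else {
    notes <- c(notes, "triage accuracy omitted: vignettes or triage missing")
  }

  # triage timing ------------------------------------------------------
  if (!is.null(episodes) && nrow(episodes) && !is.null(zones) &&
      !is.null(x$vignettes) && !is.null(x$triage)) {
    tt <- triage_times(patient_tags, episodes, zones)
    vg <- x$vignettes
    tt$patient_id <- vg$patient_id[match(tt$tag_id, vg$tag_id)]
    s2 <- x$triage[x$triage$stage == 2, ]
    tt$category <- s2$assigned_category[match(tt$patient_id, s2$patient_id)]
    res$timing <- list(
      table = tt,
      n_missing = sum(tt$missing),
      overall = list(n = sum(!tt$missing),
                     mean_s = mean(tt$duration_s, na.rm = TRUE),
                     sd_s = stats::sd(tt$duration_s, na.rm = TRUE)),
      by_category = timing_by_category(tt[, c("category", "duration_s")]),
      undertriage_contrast = undertriage_timing_contrast(
        tt[, c("patient_id", "duration_s")], vg, x$triage, stage = 2))
  } else {
    notes <- c(notes, "triage timing omitted: episodes/zones/triage missing")
  }

  # contacts ------------------------------------------------------------
  if (!is.null(contacts) && !is.null(x$roster)) {
    res$contacts <- contact_group_analysis(contacts, x$roster)
  } else {
    notes <- c(notes, "contact analysis omitted: contacts or roster missing")
  }

  # demographics ---------------------------------------------------------
  if (!is.null(x$roster)) res$demographics <- demographics_table(x$roster)

  # questionnaires -------------------------------------------------------
  if (!is.null(x$tlx) && nrow(x$tlx) && !is.null(x$roster)) {
    res$tlx <- tlx_analysis(x$tlx, x$roster, experience_split)
  } else {
    notes <- c(notes, "NASA-TLX section omitted: no responses")
  }
  if (!is.null(x$team) && nrow(x$team) && !is.null(x$roster)) {
    res$team <- team_analysis(x$team, x$roster)
  } else {
    notes <- c(notes, "TEAM section omitted: no responses")
  }

  res$notes <- notes
  class(res) <- "mci_analysis"
  res
}

#' @keywords internal
#' @noRd
contact_group_analysis <- function(contacts, roster) {
  cp <- contacts_per_person(contacts, roster)
  per <- merge(cp$per_person, roster, by = "code")
  grp_stats <- function(idx, label) {
    x <- per$n_contacts[idx]
    data.frame(group = label, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }
  summary <- rbind(
    grp_stats(rep(TRUE, nrow(per)), "all_tracked_staff"),
    grp_stats(per$group == "physician", "physicians"),
    grp_stats(per$group == "nurse", "nursing_staff"),
    grp_stats(per$group == "nurse_trainee", "nursing_trainees"))
  cmp <- function(a, b, label) {
    if (length(a) < 2 || length(b) < 2) return(NULL)
    r <- compare_two(a, b)
    data.frame(contrast = label, test = r$test_name, p_value = r$p_value,
               stars = r$stars, stringsAsFactors = FALSE)
  }
  nc <- per$n_contacts
  exp_med <- stats::median(per$experience_years, na.rm = TRUE)
  age_med <- stats::median(per$age_years, na.rm = TRUE)
  tests <- rbind(
    cmp(nc[per$group == "physician"],
        nc[per$group %in% c("nurse", "nurse_trainee")],
        "physicians_vs_nursing_incl_trainees"),
    cmp(nc[per$group == "physician" & per$specialist %in% FALSE],
        nc[per$group == "physician" & per$specialist %in% TRUE],
        "resident_vs_specialist"),
    cmp(nc[per$group == "nurse"], nc[per$group == "nurse_trainee"],
        "nursing_staff_vs_trainees"),
    cmp(nc[per$gender == "female"], nc[per$gender == "male"],
        "female_vs_male"),
    cmp(nc[per$age_years < age_med], nc[per$age_years >= age_med],
        "young_vs_old"),
    cmp(nc[per$experience_years < exp_med],
        nc[per$experience_years >= exp_med], "professional_experience"))
  list(n_contacts = cp$n_contacts, n_staff = cp$n_staff,
       mean = cp$mean, sd = cp$sd, per_person = cp$per_person,
       summary = summary, tests = tests)
}

#' @keywords internal
#' @noRd
demographics_table <- function(roster) {
  n <- nrow(roster)
  grp_row <- function(idx, label) {
    data.frame(group = label, n = sum(idx),
               ratio_pct = round_half_up(100 * sum(idx) / n, 1),
               age_mean = round_half_up(mean(roster$age_years[idx]), 1),
               age_sd = round_half_up(stats::sd(roster$age_years[idx]), 1),
               age_median = stats::median(roster$age_years[idx]),
               exp_mean = round_half_up(mean(roster$experience_years[idx]), 1),
               exp_sd = round_half_up(stats::sd(roster$experience_years[idx]), 1),
               exp_median = stats::median(roster$experience_years[idx]),
               n_female = sum(roster$gender[idx] == "female"),
               stringsAsFactors = FALSE)
  }
  rbind(grp_row(rep(TRUE, n), "all_participants"),
        grp_row(roster$group == "physician", "physicians"),
        grp_row(roster$group == "physician" & roster$specialist %in% FALSE,
                "residents"),
        grp_row(roster$group == "physician" & roster$specialist %in% TRUE,
                "specialists"),
        grp_row(roster$group == "nurse", "nursing_staff"),
        grp_row(roster$group == "nurse_trainee", "nursing_trainees"),
        grp_row(roster$group == "other", "others"))
}

# Median split on experience; ties at the median go to the "more
# experienced" half (deterministic, near-equal halves).
#' @keywords internal
#' @noRd
experience_halves <- function(df) {
  med <- stats::median(df$experience_years, na.rm = TRUE)
  list(less = df$experience_years < med,
       more = df$experience_years >= med)
}

#' @keywords internal
#' @noRd
tlx_analysis <- function(tlx, roster, experience_split = TRUE) {
  scored <- score_tlx(tlx)
  m <- merge_by_code(roster, scored)
  tot <- m$raw_total
  out <- list(
    n = sum(!is.na(tot)),
    overall = list(mean = mean(tot, na.rm = TRUE),
                   sd = stats::sd(tot, na.rm = TRUE)),
    items = tlx_item_summary(m),
    contrasts = list())
  add_contrast <- function(name, a, b, labels) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return()
    out$contrasts[[name]] <<- list(
      labels = labels,
      mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
      n = c(length(a), length(b)),
      test = compare_two(a, b),
      effect = hedges_g_samples(a, b, labels = labels))
  }
  spec <- m$group == "physician" & m$specialist %in% TRUE
  resd <- m$group == "physician" & m$specialist %in% FALSE
  add_contrast("specialist_vs_resident", tot[spec], tot[resd],
               c("specialist", "resident"))
  add_contrast("physician_vs_nurse", tot[m$group == "physician"],
               tot[m$group == "nurse"], c("physician", "nurse"))
  add_contrast("female_vs_male", tot[m$gender == "female"],
               tot[m$gender == "male"], c("female", "male"))
  if (experience_split) {
    h <- experience_halves(m)
    add_contrast("more_vs_less_experienced", tot[h$more], tot[h$less],
                 c("more_experienced", "less_experienced"))
  }
  groups <- split(tot, m$group)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 0L) >= 2]
  if (length(groups) >= 3) out$group_test <- compare_k(groups)
  out
}

#' @keywords internal
#' @noRd
team_analysis <- function(team, roster) {
  scored <- score_team(team)
  m <- merge_by_code(roster, scored)
  out <- list(summary = team_summary(m))
  by_grp <- split(m$total, m$group)
  by_grp <- lapply(by_grp, function(g) g[!is.na(g)])
  by_grp <- by_grp[vapply(by_grp, length, 0L) >= 2]
  out$group_means <- vapply(by_grp, mean, 0)
  if (length(by_grp) >= 3) out$group_test <- compare_k(by_grp)
  out
}

#' @export
print.mci_analysis <- function(x, ...) {
  cat("MCI exercise analysis\n")
  if (!is.null(x$confusion)) {
    for (s in names(x$confusion)) {
      m <- x$confusion[[s]]$metrics
      if (is.null(m)) next
      cat(sprintf("  %s: accuracy %.1f%%, undertriage %.1f%%, overtriage %.1f%% (n = %d)\n",
                  s, m$overall_pct, m$undertriage_pct, m$overtriage_pct,
                  m$n_total))
    }
  }
  if (!is.null(x$timing)) {
    s <- x$timing$by_category$summary
    cat("  triage time by category:",
        paste(sprintf("%s %.0f+-%.0f s (n=%d)", s$category, s$mean_s, s$sd_s,
                      s$n), collapse = ", "), "\n")
  }
  if (!is.null(x$contacts)) {
    cat(sprintf("  contacts: %d episodes, %d tracked staff, mean %.1f +- %.1f per person\n",
                x$contacts$n_contacts, x$contacts$n_staff,
                round_half_up(x$contacts$mean, 1),
                round_half_up(x$contacts$sd, 1)))
  }
  if (!is.null(x$tlx)) {
    cat(sprintf("  NASA-TLX: n = %d, overall %.1f +- %.1f\n", x$tlx$n,
                x$tlx$overall$mean, x$tlx$overall$sd))
  }
  if (!is.null(x$team)) {
    cat(sprintf("  TEAM: n = %d, mean item %.1f, total %.1f%%\n",
                x$team$summary$n, x$team$summary$mean_item,
                x$team$summary$percent))
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
summary.mci_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$tlx) && length(object$tlx$contrasts)) {
    cat("NASA-TLX contrasts:\n")
    for (nm in names(object$tlx$contrasts)) {
      ct <- object$tlx$contrasts[[nm]]
      cat(sprintf("  %s: %.1f +- %.1f (n=%d) vs %.1f +- %.1f (n=%d), p = %.4f %s, ",
                  nm, ct$mean[1], ct$sd[1], ct$n[1], ct$mean[2], ct$sd[2],
                  ct$n[2], ct$test$p_value, ct$test$stars))
      print(ct$effect)
    }
  }
  invisible(object)
}
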