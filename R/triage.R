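# Two-stage triage evaluation: per-patient triage durations measured from
# geofence episodes, and the expected-vs-assigned category confusion
# analysis (overall accuracy, under-/overtriage).

#' Triage duration of one patient from zone episodes
#'
#' Triage time is defined as the time from arrival at the second (algorithm
#' based) triage area until transport out of it: the span from the first
#' entry into any `triage2` zone to the final exit, in seconds. Re-entries
#' in between are counted inside the span and flagged for review. Patients
#' with no `triage2` episode get `NA` and are flagged missing.
#'
#' @param patient_tag tag id of the patient.
#' @param episodes zone episode data.frame ([zone_episodes()]).
#' @param zones `mci_zones` list (used to find `role == "triage2"` zones).
#' @return list `duration_s`, `n_episodes`, `multi_visit`, `missing`.
#' @export
triage_time <- function(patient_tag, episodes, zones) {
  t2 <- vapply(zones, function(z) z$role == "triage2", TRUE)
  t2_ids <- vapply(zones[t2], `[[`, "", "zone_id")
  ep <- episodes[episodes$tag_id == patient_tag &
                 episodes$zone_id %in% t2_ids, , drop = FALSE]
  if (!nrow(ep)) {
    return(list(duration_s = NA_real_, n_episodes = 0L,
                multi_visit = FALSE, missing = TRUE))
  }
  list(duration_s = (max(ep$t_exit_ms) - min(ep$t_enter_ms)) / 1000,
       n_episodes = nrow(ep), multi_visit = nrow(ep) > 1L, missing = FALSE)
}

#' Triage durations for a set of patients
#' @param patient_tags character vector of patient tag ids.
#' @inheritParams triage_time
#' @return data.frame `tag_id, duration_s, n_episodes, multi_visit, missing`.
#' @export
triage_times <- function(patient_tags, episodes, zones) {
  rows <- lapply(patient_tags, triage_time, episodes = episodes, zones = zones)
  data.frame(tag_id = patient_tags,
             duration_s = vapply(rows, `[[`, 0, "duration_s"),
             n_episodes = vapply(rows, `[[`, 0L, "n_episodes"),
             multi_visit = vapply(rows, `[[`, TRUE, "multi_visit"),
             missing = vapply(rows, `[[`, TRUE, "missing"),
             stringsAsFactors = FALSE)
}

#' Build the expected-vs-assigned triage confusion matrix
#'
#' Counts patients over the 3x3 grid of expected (vignette) by assigned
#' category for one triage stage. Only patients with both an expected
#' category and a stage assignment are counted; the excluded patient ids are
#' attached as attribute `excluded`. Rows: expected, columns: assigned.
#'
#' @param vignettes vignette data.frame (`patient_id, expected_category`).
#' @param triage_records triage data.frame (`patient_id, stage,
#'   assigned_category`).
#' @param stage triage stage, 1 or 2.
#' @return object of class `mci_confusion`: list with `counts` (3x3 integer
#'   matrix), `n_total`, `stage`.
#' @export
build_confusion <- function(vignettes, triage_records, stage) {
  stopifnot(stage %in% c(1, 2))
  tr <- triage_records[triage_records$stage == stage, , drop = FALSE]
  m <- merge(vignettes[, c("patient_id", "expected_category")],
             tr[, c("patient_id", "assigned_category")], by = "patient_id")
  m <- m[!is.na(m$expected_category) & !is.na(m$assigned_category), ]
  counts <- table(expected = as_category(m$expected_category, "expected"),
                  assigned = as_category(m$assigned_category, "assigned"))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(expected = TRIAGE_LEVELS,
                                   assigned = TRIAGE_LEVELS))
  structure(list(counts = counts, n_total = sum(counts), stage = stage),
            class = "mci_confusion",
            excluded = setdiff(vignettes$patient_id, m$patient_id))
}

#' @export
print.mci_confusion <- function(x, ...) {
  cat(sprintf("Triage confusion matrix, stage %d (n = %d)\n", x$stage,
              x$n_total))
  print(x$counts)
  if (x$n_total > 0) {
    m <- accuracy_metrics(x)
    cat(sprintf("overall %.1f%%  undertriage %.1f%%  overtriage %.1f%%\n",
                m$overall_pct, m$undertriage_pct, m$overtriage_pct))
  }
  invisible(x)
}

#' Accuracy, undertriage and overtriage rates from a confusion matrix
#'
#' With urgency ordered I > II > III, undertriage means a less urgent
#' assignment than expected (cells above the diagonal in the I,II,III
#' layout) and overtriage a more urgent one (below the diagonal).
#' `missed_I` is expected I assigned II or III; `missed_II` expected II
#' assigned III; `false_I` expected II or III assigned I. All rates are
#' 100 * count / n_total, reported half-up-rounded to one decimal; exact
#' fractions are returned alongside under `raw`.
#'
#' @param cm `mci_confusion` object (or plain 3x3 matrix, rows expected).
#' @return list of percentages (`overall_pct`, `undertriage_pct`,
#'   `overtriage_pct`, `missed_I_pct`, `missed_II_pct`, `false_I_pct`),
#'   counts, `n_total`, and exact proportions in `raw`.
#' @export
accuracy_metrics <- function(cm) {
  counts <- if (inherits(cm, "mci_confusion")) cm$counts else as.matrix(cm)
  n <- sum(counts)
  if (n == 0) stop("accuracy undefined for an empty confusion matrix",
                   call. = FALSE)
  correct <- sum(diag(counts))
  under <- counts[1, 2] + counts[1, 3] + counts[2, 3]
  over <- counts[2, 1] + counts[3, 1] + counts[3, 2]
  missed_I <- counts[1, 2] + counts[1, 3]
  missed_II <- counts[2, 3]
  false_I <- counts[2, 1] + counts[3, 1]
  raw <- c(overall = correct, undertriage = under, overtriage = over,
           missed_I = missed_I, missed_II = missed_II, false_I = false_I) / n
  pct <- round_half_up(100 * raw, 1)
  list(overall_pct = pct[["overall"]], undertriage_pct = pct[["undertriage"]],
       overtriage_pct = pct[["overtriage"]], missed_I_pct = pct[["missed_I"]],
       missed_II_pct = pct[["missed_II"]], false_I_pct = pct[["false_I"]],
       counts = c(overall = correct, undertriage = under, overtriage = over,
                  missed_I = missed_I, missed_II = missed_II,
                  false_I = false_I),
       n_total = n, raw = raw)
}

#' Triage-duration summary and pairwise comparisons by assigned category
#'
#' Summarizes durations per assigned category (n, mean, SD, median) and runs
#' the two-group comparison ([compare_two()], which gates on normality and
#' falls back to Mann-Whitney) for every category pair with at least two
#' observations each. Categories with no observations are excluded.
#'
#' @param timings data.frame with columns `category` (I/II/III) and
#'   `duration_s`.
#' @return list with `summary` data.frame and `pairwise` data.frame
#'   (`group1, group2, test, p_value, stars`).
#' @export
timing_by_category <- function(timings) {
  timings <- timings[!is.na(timings$duration_s) & !is.na(timings$category), ]
  timings$category <- as_category(timings$category)
  by_cat <- split(timings$duration_s, timings$category, drop = FALSE)
  by_cat <- by_cat[vapply(by_cat, length, 0L) > 0]
  summ <- data.frame(
    category = names(by_cat),
    n = vapply(by_cat, length, 0L),
    mean_s = vapply(by_cat, mean, 0),
    sd_s = vapply(by_cat, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 0),
    median_s = vapply(by_cat, stats::median, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  pairs <- if (length(by_cat) >= 2) {
    utils::combn(names(by_cat), 2, simplify = FALSE)
  } else list()
  pw <- lapply(pairs, function(p) {
    a <- by_cat[[p[1]]]; b <- by_cat[[p[2]]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    r <- compare_two(a, b)
    data.frame(group1 = p[1], group2 = p[2], test = r$test_name,
               p_value = r$p_value, stars = r$stars, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  if (is.null(pw)) {
    pw <- data.frame(group1 = character(), group2 = character(),
                     test = character(), p_value = numeric(),
                     stars = character(), stringsAsFactors = FALSE)
  }
  list(summary = summ, pairwise = pw)
}

#' Compare triage durations: correctly triaged category I vs undertriaged
#'
#' Contrasts the durations of patients whose expected category I was
#' assigned correctly against those of undertriaged patients (any expected
#' category assigned less urgently). Skipped with a notice when either group
#' has fewer than two observations.
#'
#' @param timings data.frame `patient_id, duration_s`.
#' @param vignettes vignette data.frame.
#' @param triage_records triage data.frame.
#' @param stage triage stage, default 2.
#' @return list with group summaries and a `test` (`mci_test` or `NULL`).
#' @export
undertriage_timing_contrast <- function(timings, vignettes, triage_records,
                                        stage = 2) {
  tr <- triage_records[triage_records$stage == stage, ]
  m <- merge(merge(vignettes[, c("patient_id", "expected_category")],
                   tr[, c("patient_id", "assigned_category")],
                   by = "patient_id"),
             timings[, c("patient_id", "duration_s")], by = "patient_id")
  m <- m[!is.na(m$duration_s), ]
  exp_i <- match(m$expected_category, TRIAGE_LEVELS)
  asg_i <- match(m$assigned_category, TRIAGE_LEVELS)
  correct_I <- m$duration_s[exp_i == 1 & asg_i == 1]
  undertriaged <- m$duration_s[asg_i > exp_i]
  summ <- function(x) list(n = length(x), mean_s = mean(x),
                           sd_s = if (length(x) > 1) stats::sd(x) else NA_real_)
  out <- list(correct_I = summ(correct_I), undertriaged = summ(undertriaged),
              test = NULL, note = NULL)
  if (length(correct_I) < 2 || length(undertriaged) < 2) {
    out$note <- "comparison skipped: a group has fewer than 2 observations"
  } else {
    out$test <- compare_two(correct_I, undertriaged)
  }
  out
}
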