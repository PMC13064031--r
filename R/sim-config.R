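# Simulation configuration for a synthetic MCI exercise, with defaults
# matching the benchmark study conditions: 91 casualties (69 of them
# tracked), 75 tagged staff, a 30/30/40 category I/II/III mix, first
# arrival 40 min after the alarm, a 207 min exercise, category-dependent
# triage service times (means 59/173/205 s, SDs 25/74/100 s), a
# misclassification model whose marginal error rates reproduce the
# benchmark confusion (overall accuracy 75.4% at n = 69) with
# yellow-to-green errors clustered on blast-trauma vignettes, and
# questionnaire distributions carrying the printed group effects.

#' Default misclassification matrices
#'
#' Row-stochastic 3x3 matrices P(assigned | expected), derived from the
#' benchmark error counts over the expected category-mix at n = 69
#' (expected ~20.7 patients each in I and II): stage 2 has P(I->II) = 8/20.7
#' and for expected II a marginal P(II->III) = 7/20.7 and P(II->I) = 2/20.7.
#' Because part of the II->III mass is produced by the blast-trauma
#' downgrade (see [mci_sim_config()]), the matrix carries only the residual
#' base rate q solving q + (1 - p21 - q) * f * b = 7/20.7 for blast fraction
#' f and downgrade probability b. Expected overall accuracy is then
#' 0.3 * (1 - 8/20.7) + 0.3 * (1 - 9/20.7) + 0.4 = 75.4%, independent of the
#' realized category counts.
#'
#' @param stage 1 or 2.
#' @param blast_fraction fraction of expected-II vignettes with blast trauma.
#' @param blast_bias downgrade probability for those vignettes.
#' @return 3x3 row-stochastic matrix.
#' @export
default_misclassification <- function(stage = 2, blast_fraction = 0.35,
                                      blast_bias = 0.85) {
  e <- 69 * 0.3  # expected patients per minority category
  p12 <- if (stage == 2) 8 / e else 7 / e
  p21 <- 2 / e
  p23_marginal <- 7 / e
  fb <- blast_fraction * blast_bias
  q <- (p23_marginal - (1 - p21) * fb) / (1 - fb)
  stopifnot(q >= 0, q + p21 < 1)
  m <- rbind(c(1 - p12, p12, 0),
             c(p21, 1 - p21 - q, q),
             c(0, 0, 1))
  dimnames(m) <- list(expected = TRIAGE_LEVELS, assigned = TRIAGE_LEVELS)
  m
}

#' Default NASA-TLX group parameters
#'
#' Per-group mean and SD of the raw TLX total (sum of six items), set to the
#' benchmark group summaries: residents 71.1 +- 11.0, specialists
#' 63.7 +- 13.0, nursing trainees 75.2 +- 16.9; nurse and other means are
#' chosen so the cohort-weighted mean matches the overall 66.7 +- 16.
#' @return data.frame `key, mean, sd`.
#' @export
default_tlx_groups <- function() {
  data.frame(key = c("resident", "specialist", "nurse", "nurse_trainee",
                     "other"),
             mean = c(71.1, 63.7, 62.9, 75.2, 66.0),
             sd = c(11.0, 13.0, 16.0, 16.9, 16.0),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic exercise, with defaults equal to
#' the benchmark study conditions. The misclassification matrices apply per
#' expected category; blast-trauma expected-II vignettes whose matrix draw
#' kept them at II are additionally downgraded to III with probability
#' `blast_trauma_green_bias` (masked serious injury), which concentrates
#' II->III errors on blast cases (~6 of 7) while preserving the marginal
#' error rates.
#'
#' @param n_patients total casualties (91).
#' @param n_tracked_patients casualties with a working tag (69).
#' @param n_staff_tagged tagged staff (75).
#' @param category_mix probabilities for I/II/III (0.30/0.30/0.40).
#' @param first_arrival_min no patient arrives earlier (40 min post alarm).
#' @param exercise_duration_min exercise length (207 min).
#' @param arrival_last_min latest arrival (default 180 min).
#' @param n_waves,wave_sd_min arrival wave count and within-wave jitter SD.
#' @param triage_service data.frame `category, mean_s, sd_s` of lognormal
#'   service-time targets (59/173/205 s means, 25/74/100 s SDs).
#' @param service_min_s lower truncation of service times (10 s).
#' @param misclassification_stage1,misclassification_stage2 3x3
#'   row-stochastic matrices.
#' @param blast_fraction fraction of expected-II vignettes with blast trauma.
#' @param blast_trauma_green_bias downgrade probability (see above).
#' @param stage_correlation probability that the stage-1 decision simply
#'   copies the stage-2 decision (0.5).
#' @param tlx_groups data.frame `key, mean, sd` of raw-TLX totals per group.
#' @param tlx_item_means six subscale means (sum = overall total mean).
#' @param team_item_means,team_item_sds 11 TEAM item means/SDs (leader items
#'   lowest at 2.8, morale highest at 3.6; cohort mean item 3.2).
#' @param response_rate questionnaire response probability (0.99 TLX).
#' @param dropout probability of losing a single position sample (0.02).
#' @param speed_m_s walking speed used in track rendering.
#' @param contacts_per_patient_mean mean distinct staff contacts per treated
#'   patient (536/69 in the benchmark).
#' @param staff_weight_shape gamma shape for staff contact-load
#'   heterogeneity (smaller = more overdispersed contact counts).
#' @param seed integer master seed; every component derives a named
#'   substream from it.
#' @return object of class `mci_sim_config`.
#' @export
mci_sim_config <- function(n_patients = 91,
                           n_tracked_patients = 69,
                           n_staff_tagged = 75,
                           category_mix = c(I = 0.30, II = 0.30, III = 0.40),
                           first_arrival_min = 40,
                           exercise_duration_min = 207,
                           arrival_last_min = 180,
                           n_waves = 6,
                           wave_sd_min = 4,
                           triage_service = data.frame(
                             category = c("I", "II", "III"),
                             mean_s = c(59, 173, 205),
                             sd_s = c(25, 74, 100)),
                           service_min_s = 10,
                           misclassification_stage1 = NULL,
                           misclassification_stage2 = NULL,
                           blast_fraction = 0.35,
                           blast_trauma_green_bias = 0.85,
                           stage_correlation = 0.5,
                           tlx_groups = default_tlx_groups(),
                           tlx_item_means = c(mental = 12.0, physical = 9.2,
                                              temporal = 13.0,
                                              performance = 13.9,
                                              effort = 11.4,
                                              frustration = 7.2),
                           team_item_means = c(2.8, 2.8, 3.2, 3.3, 3.2, 3.3,
                                               3.2, 3.5, 3.6, 3.1, 3.1),
                           team_item_sds = c(1.2, 1.3, 0.8, 0.8, 0.8, 0.8,
                                             0.8, 0.7, 0.7, 0.8, 0.8),
                           response_rate = 0.99,
                           dropout = 0.02,
                           speed_m_s = 1.3,
                           contacts_per_patient_mean = 536 / 69,
                           staff_weight_shape = 1.6,
                           seed = 1L) {
  if (is.null(misclassification_stage1)) {
    misclassification_stage1 <- default_misclassification(1, blast_fraction,
                                                          blast_trauma_green_bias)
  }
  if (is.null(misclassification_stage2)) {
    misclassification_stage2 <- default_misclassification(2, blast_fraction,
                                                          blast_trauma_green_bias)
  }
  cfg <- list(n_patients = n_patients,
              n_tracked_patients = min(n_tracked_patients, n_patients),
              n_staff_tagged = n_staff_tagged,
              category_mix = category_mix,
              first_arrival_min = first_arrival_min,
              exercise_duration_min = exercise_duration_min,
              arrival_last_min = arrival_last_min,
              n_waves = n_waves, wave_sd_min = wave_sd_min,
              triage_service = triage_service,
              service_min_s = service_min_s,
              misclassification_stage1 = misclassification_stage1,
              misclassification_stage2 = misclassification_stage2,
              blast_fraction = blast_fraction,
              blast_trauma_green_bias = blast_trauma_green_bias,
              stage_correlation = stage_correlation,
              tlx_groups = tlx_groups,
              tlx_item_means = tlx_item_means,
              team_item_means = team_item_means,
              team_item_sds = team_item_sds,
              response_rate = response_rate,
              dropout = dropout,
              speed_m_s = speed_m_s,
              contacts_per_patient_mean = contacts_per_patient_mean,
              staff_weight_shape = staff_weight_shape,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "mci_sim_config")
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0, cfg$n_staff_tagged >= 0,
            cfg$first_arrival_min >= 0,
            cfg$arrival_last_min <= cfg$exercise_duration_min,
            cfg$blast_trauma_green_bias >= 0, cfg$blast_trauma_green_bias <= 1,
            cfg$stage_correlation >= 0, cfg$stage_correlation <= 1)
  if (abs(sum(cfg$category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  for (m in list(cfg$misclassification_stage1, cfg$misclassification_stage2)) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
      stop("misclassification matrices must be row-stochastic", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.mci_sim_config <- function(x, ...) {
  cat("MCI exercise simulation config\n")
  cat(sprintf("  patients: %d (%d tracked), tagged staff: %d\n",
              x$n_patients, x$n_tracked_patients, x$n_staff_tagged))
  cat(sprintf("  category mix I/II/III: %s\n",
              paste(x$category_mix, collapse = "/")))
  cat(sprintf("  arrivals: first %g min, last %g min, %d waves; exercise %g min\n",
              x$first_arrival_min, x$arrival_last_min, x$n_waves,
              x$exercise_duration_min))
  cat(sprintf("  triage service means (s): %s\n",
              paste(x$triage_service$mean_s, collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Named RNG substreams: each component of the generator draws from its own
# seed derived deterministically from the master seed, so adding draws to
# one component never shifts another component's stream.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1e6
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' @keywords internal
#' @noRd
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Default zone layout
#'
#' A packaged synthetic two-floor layout standing in for the (unpublished)
#' hospital geometry: ground floor `F0` with the first-look triage zone, the
#' green-stream algorithm triage zone, the category-III treatment area and a
#' transport zone; emergency-department floor `F1` with the main algorithm
#' triage zone, category-I and category-II treatment areas and a transport
#' zone. Rectangles in a per-floor metric frame.
#'
#' @return `mci_zones` list.
#' @export
default_zones <- function() {
  rect <- function(x0, y0, x1, y1) {
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  structure(list(
    zone("triage1", "F0", "triage1", rect(2, 20, 8, 26)),
    zone("triage2_green", "F0", "triage2", rect(12, 2, 20, 10)),
    zone("treatment_green", "F0", "treatment_green", rect(24, 2, 34, 12)),
    zone("transport_f0", "F0", "transport", rect(38, 2, 44, 10)),
    zone("triage2_main", "F1", "triage2", rect(2, 2, 10, 10)),
    zone("treatment_red", "F1", "treatment_red", rect(14, 2, 24, 12)),
    zone("treatment_yellow", "F1", "treatment_yellow", rect(14, 16, 24, 26)),
    zone("transport_f1", "F1", "transport", rect(28, 2, 36, 10))),
    class = "mci_zones")
}
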