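# NASA-TLX and TEAM questionnaire scoring.
#
# NASA-TLX here is the "Raw TLX": six subscales (mental, physical, temporal
# demand, performance, effort, frustration) each rated 1-20 with high values
# meaning high workload, summed without the weighted pairwise-comparison
# step. TEAM is the Team Emergency Assessment Measure: 11 items rated 0-4,
# summed to a total out of 44, plus a global rating 1-10. In this exercise
# the TEAM was self-rated by the participants (rather than by an external
# observer); a `rater_role` field records that provenance.

TLX_ITEMS <- c("mental", "physical", "temporal", "performance", "effort",
               "frustration")

#' Score NASA-TLX (Raw TLX) responses
#'
#' Validates the six items against the 1-20 range and computes
#' `raw_total` as their plain sum (range 6-120). A respondent with any
#' missing item gets a missing `raw_total`; items are never imputed.
#'
#' @param tlx data.frame with columns `mental, physical, temporal,
#'   performance, effort, frustration` (and optionally `code`).
#' @return the input with a `raw_total` column appended.
#' @export
score_tlx <- function(tlx) {
  check_cols(tlx, TLX_ITEMS, "tlx")
  items <- as.matrix(tlx[, TLX_ITEMS])
  bad <- !is.na(items) & (items < 1 | items > 20 | items != floor(items))
  if (any(bad)) {
    stop("NASA-TLX items must be integers in [1, 20]; offending rows: ",
         paste(unique(which(bad, arr.ind = TRUE)[, 1]), collapse = ", "),
         call. = FALSE)
  }
  tlx$raw_total <- rowSums(items)  # NA whenever any item missing
  tlx
}

#' Per-item NASA-TLX means
#'
#' Means per subscale over non-missing responses (respondents with a
#' missing item contribute their remaining items).
#'
#' @param tlx scored or raw TLX data.frame.
#' @return data.frame `item, mean, n`.
#' @export
tlx_item_summary <- function(tlx) {
  check_cols(tlx, TLX_ITEMS, "tlx")
  data.frame(item = TLX_ITEMS,
             mean = vapply(TLX_ITEMS, function(i) mean(tlx[[i]], na.rm = TRUE), 0),
             n = vapply(TLX_ITEMS, function(i) sum(!is.na(tlx[[i]])), 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score TEAM responses
#'
#' Validates the 11 section items (0-4) and the global rating (1-10),
#' computes `total` (sum of the 11 items, max 44), `percent`
#' (100 * total / 44) and `mean_item` (total / 11). Missing items propagate
#' to a missing total.
#'
#' @param team data.frame with columns `item1..item11`, `global` (and
#'   optionally `code`, `rater_role`).
#' @return the input with `total`, `percent`, `mean_item` appended.
#' @export
score_team <- function(team) {
  item_cols <- paste0("item", 1:11)
  check_cols(team, c(item_cols, "global"), "team")
  items <- as.matrix(team[, item_cols])
  bad <- !is.na(items) & (items < 0 | items > 4 | items != floor(items))
  if (any(bad)) stop("TEAM items must be integers in [0, 4]", call. = FALSE)
  g <- team$global
  if (any(!is.na(g) & (g < 1 | g > 10))) {
    stop("TEAM global rating must be in [1, 10]", call. = FALSE)
  }
  if (is.null(team$rater_role)) team$rater_role <- "self"
  team$total <- rowSums(items)
  team$percent <- 100 * team$total / 44
  team$mean_item <- team$total / 11
  team
}

#' Cohort-level TEAM summary
#'
#' The cohort percentage is computed from the summed raw totals
#' (`100 * mean(total) / 44`), not from the rounded mean item score: a mean
#' item score printed as 3.2 corresponds to 80.0% when re-expanded, whereas
#' the raw totals may give e.g. 79.8% - the two are deliberately kept
#' distinct.
#'
#' @param team scored TEAM data.frame ([score_team()]).
#' @return list with `n`, `mean_total`, `percent` (from raw totals),
#'   `mean_item`, `percent_from_mean_item` (from the 1-decimal mean item
#'   score), `item_means`, `global_mean`.
#' @export
team_summary <- function(team) {
  ok <- !is.na(team$total)
  item_cols <- paste0("item", 1:11)
  list(n = sum(ok),
       mean_total = mean(team$total[ok]),
       percent = 100 * mean(team$total[ok]) / 44,
       mean_item = mean(team$total[ok]) / 11,
       percent_from_mean_item =
         100 * round_half_up(mean(team$total[ok]) / 11, 1) / 4,
       item_means = vapply(item_cols,
                           function(i) mean(team[[i]], na.rm = TRUE), 0),
       item_sds = vapply(item_cols,
                         function(i) stats::sd(team[[i]], na.rm = TRUE), 0),
       global_mean = mean(team$global, na.rm = TRUE))
}
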