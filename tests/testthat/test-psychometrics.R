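test_that("raw TLX total is the plain item sum with hard bounds", {
  mk <- function(v) as.data.frame(as.list(setNames(v, c("mental", "physical",
    "temporal", "performance", "effort", "frustration"))))
  expect_equal(score_tlx(mk(rep(1, 6)))$raw_total, 6)
  expect_equal(score_tlx(mk(rep(20, 6)))$raw_total, 120)
  expect_equal(score_tlx(mk(c(14, 9, 13, 14, 10, 7)))$raw_total, 67)
  expect_error(score_tlx(mk(c(0, 9, 13, 14, 10, 7))), "1, 20")
  expect_error(score_tlx(mk(c(21, 9, 13, 14, 10, 7))), "1, 20")
  # missing item -> missing total, no imputation
  x <- mk(c(14, 9, 13, 14, 10, 7)); x$effort <- NA
  expect_true(is.na(score_tlx(x)$raw_total))
})

test_that("per-item TLX means average over non-missing responses", {
  tlx <- data.frame(code = c("a", "b"), mental = c(10, 12), physical = c(8, 10),
                    temporal = c(12, 14), performance = c(13, 15),
                    effort = c(10, 12), frustration = c(6, NA))
  s <- tlx_item_summary(tlx)
  expect_equal(s$mean[s$item == "mental"], 11)
  expect_equal(s$mean[s$item == "frustration"], 6)
  expect_equal(s$n[s$item == "frustration"], 1L)

  single <- tlx_item_summary(tlx[1, ])
  expect_equal(single$mean, c(10, 8, 12, 13, 10, 6), ignore_attr = TRUE)
})

test_that("synthetic cohort recovers configured TLX item means within 2 SEM", {
  cfg <- mci_sim_config(seed = 21)
  roster <- sample_roster(cfg)
  qn <- sample_questionnaires(roster, cfg)
  s <- tlx_item_summary(qn$tlx)
  for (i in seq_len(nrow(s))) {
    target <- unname(cfg$tlx_item_means[s$item[i]])
    sem <- sd(qn$tlx[[s$item[i]]]) / sqrt(s$n[i])
    expect_lt(abs(s$mean[i] - target), max(2 * sem, 0.8),
              label = sprintf("item %s: mean %.2f vs target %.2f",
                              s$item[i], s$mean[i], target))
  }
})

test_that("TEAM scoring: totals, percent, bounds and validation", {
  mk <- function(items, global = 8) {
    df <- as.data.frame(as.list(setNames(items, paste0("item", 1:11))))
    df$global <- global
    df
  }
  allmax <- score_team(mk(rep(4, 11)))
  expect_equal(allmax$total, 44)
  expect_equal(allmax$percent, 100)
  allmin <- score_team(mk(rep(0, 11)))
  expect_equal(allmin$total, 0)
  expect_equal(allmin$percent, 0)
  expect_error(score_team(mk(rep(5, 11))), "0, 4")
  expect_error(score_team(mk(rep(4, 11), global = 11)), "1, 10")
})

test_that("cohort percent comes from raw sums, not the rounded item mean", {
  # cohort mean total 35.1/44 = 79.77...% -> 79.8, while the 1-decimal mean
  # item score 3.2 re-expands to 80.0: both views are reported distinctly
  items <- matrix(3, nrow = 10, ncol = 11)
  extra <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 3)  # per-respondent bonus points
  for (i in 1:10) items[i, seq_len(extra[i])] <- 4
  team <- as.data.frame(items)
  names(team) <- paste0("item", 1:11)
  team$code <- sprintf("c%02d", 1:10)
  team$global <- 8
  scored <- score_team(team)
  expect_equal(mean(scored$total), 35.1)
  s <- team_summary(scored)
  expect_equal(round_half_up(s$percent, 1), 79.8)
  expect_equal(round_half_up(s$mean_item, 1), 3.2)
  expect_equal(s$percent_from_mean_item, 80.0)
})

test_that("scoring is deterministic and permutation-invariant", {
  cfg <- mci_sim_config(seed = 4)
  qn <- sample_questionnaires(sample_roster(cfg), cfg)
  a <- score_team(qn$team)
  b <- score_team(qn$team[sample.int(nrow(qn$team)), ])
  expect_equal(sort(a$total), sort(b$total))
  expect_true(all(a$percent >= 0 & a$percent <= 100))
  tl <- score_tlx(qn$tlx)
  expect_true(all(tl$raw_total >= 6 & tl$raw_total <= 120, na.rm = TRUE))
})
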