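test_that("triage time spans first entry to final exit of the triage2 zone", {
  zs <- structure(list(square_zone("t2", role = "triage2"),
                       square_zone("tx", 20, 0, 5, role = "transport")),
                  class = "mci_zones")
  ep <- data.frame(tag_id = "PT1", zone_id = "t2",
                   t_enter_ms = 100000, t_exit_ms = 159000)
  expect_equal(triage_time("PT1", ep, zs)$duration_s, 59)

  # two episodes 0-30 s and 40-100 s -> 100 s, flagged multi-visit
  ep2 <- data.frame(tag_id = "PT1", zone_id = "t2",
                    t_enter_ms = c(0, 40000), t_exit_ms = c(30000, 100000))
  r <- triage_time("PT1", ep2, zs)
  expect_equal(r$duration_s, 100)
  expect_true(r$multi_visit)

  # no triage2 episode -> missing + flagged
  r2 <- triage_time("PT1", ep2[0, ], zs)
  expect_true(r2$missing)
  expect_true(is.na(r2$duration_s))

  # episodes in non-triage2 zones don't count
  ep3 <- data.frame(tag_id = "PT1", zone_id = "tx",
                    t_enter_ms = 0, t_exit_ms = 50000)
  expect_true(triage_time("PT1", ep3, zs)$missing)
})

test_that("confusion matrix reproduces the benchmark two-stage error pattern", {
  fx <- table2_fixture()
  cm2 <- build_confusion(fx$vignettes, fx$triage, stage = 2)
  expect_equal(cm2$n_total, 69)
  expect_equal(cm2$counts["I", "II"], 8L)
  expect_equal(cm2$counts["II", "III"], 7L)
  expect_equal(cm2$counts["II", "I"], 2L)
  expect_equal(sum(diag(cm2$counts)), 52L)

  m <- accuracy_metrics(cm2)
  expect_equal(m$overall_pct, 75.4)
  expect_equal(m$undertriage_pct, 21.7)
  expect_equal(m$missed_I_pct, 11.6)
  expect_equal(m$missed_II_pct, 10.1)
  expect_equal(m$overtriage_pct, 2.9)
  expect_equal(m$false_I_pct, 2.9)

  cm1 <- build_confusion(fx$vignettes, fx$triage, stage = 1)
  m1 <- accuracy_metrics(cm1)
  expect_equal(m1$overall_pct, 76.8)
  expect_equal(m1$undertriage_pct, 20.3)
})

test_that("accuracy metrics handle the identity and empty cases", {
  vg <- data.frame(patient_id = c("a", "b"), expected_category = c("I", "III"),
                   features = "", tag_id = NA)
  tri <- data.frame(patient_id = c("a", "b"), stage = 2L,
                    assigned_category = c("I", "III"), t_assign_ms = NA_real_)
  m <- accuracy_metrics(build_confusion(vg, tri, 2))
  expect_equal(m$overall_pct, 100.0)
  expect_equal(m$undertriage_pct, 0.0)
  expect_equal(m$overtriage_pct, 0.0)

  empty <- build_confusion(vg[0, ], tri[0, ], 2)
  expect_equal(empty$n_total, 0)
  expect_equal(sum(empty$counts), 0)
  expect_error(accuracy_metrics(empty), "empty")
})

test_that("confusion invariants: sums, row totals, order invariance", {
  fx <- table2_fixture()
  cm <- build_confusion(fx$vignettes, fx$triage, 2)
  m <- accuracy_metrics(cm)
  # overall + under + over = 100 up to report rounding
  expect_lt(abs(m$overall_pct + m$undertriage_pct + m$overtriage_pct - 100),
            0.15)
  expect_equal(sum(m$raw[c("overall", "undertriage", "overtriage")]), 1)
  # row sums = expected-category counts
  expect_equal(unname(rowSums(cm$counts)),
               unname(table(fx$vignettes$expected_category)[c("I", "II", "III")]),
               ignore_attr = TRUE)
  # permuting patients changes nothing
  perm <- sample.int(nrow(fx$vignettes))
  cm_p <- build_confusion(fx$vignettes[perm, ],
                          fx$triage[sample.int(nrow(fx$triage)), ], 2)
  expect_equal(cm_p$counts, cm$counts)
})

test_that("patients lacking an assignment are excluded and reported", {
  fx <- table2_fixture()
  tri <- fx$triage[fx$triage$patient_id != "P01", ]
  cm <- build_confusion(fx$vignettes, tri, 2)
  expect_equal(cm$n_total, 68)
  expect_equal(attr(cm, "excluded"), "P01")
})

test_that("timing summary separates categories and tests pairs", {
  set.seed(1)
  timings <- data.frame(
    category = rep(c("I", "II", "III"), times = c(15, 25, 30)),
    duration_s = c(rnorm(15, 59, 25), rnorm(25, 173, 74), rnorm(30, 205, 100)))
  timings$duration_s <- pmax(timings$duration_s, 10)
  r <- timing_by_category(timings)
  expect_equal(r$summary$category, c("I", "II", "III"))
  expect_equal(nrow(r$pairwise), 3)
  i_row <- r$summary[r$summary$category == "I", ]
  expect_true(all(i_row$mean_s < r$summary$mean_s[r$summary$category != "I"]))
  p_i <- r$pairwise[r$pairwise$group1 == "I", "p_value"]
  expect_true(all(p_i < 0.01))

  # single category present: summary only
  r2 <- timing_by_category(timings[timings$category == "I", ])
  expect_equal(nrow(r2$summary), 1)
  expect_equal(nrow(r2$pairwise), 0)
})

test_that("undertriaged patients take longer than correct category I", {
  set.seed(2)
  fx <- table2_fixture()
  # durations: correct I ~59 s, undertriaged ~192 s
  tri2 <- fx$triage[fx$triage$stage == 2, ]
  m <- merge(fx$vignettes, tri2, by = "patient_id")
  exp_i <- match(m$expected_category, c("I", "II", "III"))
  asg_i <- match(m$assigned_category, c("I", "II", "III"))
  dur <- rep(120, nrow(m))
  dur[exp_i == 1 & asg_i == 1] <- rnorm(sum(exp_i == 1 & asg_i == 1), 59, 25)
  dur[asg_i > exp_i] <- rnorm(sum(asg_i > exp_i), 192, 104)
  timings <- data.frame(patient_id = m$patient_id, duration_s = pmax(dur, 10))
  r <- undertriage_timing_contrast(timings, fx$vignettes, fx$triage, 2)
  expect_equal(r$correct_I$n, 13)
  expect_equal(r$undertriaged$n, 15)
  expect_lt(r$correct_I$mean_s, r$undertriaged$mean_s)
  expect_lt(r$test$p_value, 0.05)

  # one group too small: skipped with a notice
  few <- timings[timings$patient_id %in% m$patient_id[exp_i == 1 & asg_i == 1][1], ]
  r2 <- undertriage_timing_contrast(few, fx$vignettes, fx$triage, 2)
  expect_null(r2$test)
  expect_match(r2$note, "skipped")
})
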