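test_that("vignette categories follow the configured mix", {
  cfg <- mci_sim_config(seed = 41)
  vg <- sample_vignettes(cfg)
  expect_equal(nrow(vg), 91)
  expect_equal(sum(!is.na(vg$tag_id)), 69)
  counts <- table(factor(vg$expected_category, c("I", "II", "III")))
  # multinomial 95% envelope around (27.3, 27.3, 36.4)
  p <- c(0.3, 0.3, 0.4)
  for (k in 1:3) {
    se <- sqrt(91 * p[k] * (1 - p[k]))
    expect_lt(abs(counts[k] - 91 * p[k]), 2.5 * se)
  }
  # degenerate mix and empty input
  all_I <- sample_vignettes(mci_sim_config(category_mix = c(I = 1, II = 0,
                                                            III = 0),
                                           seed = 1))
  expect_true(all(all_I$expected_category == "I"))
  expect_equal(nrow(sample_vignettes(cfg, n = 0)), 0)
})

test_that("generated vignettes are consistent with the triage rule engine", {
  vg <- sample_vignettes(mci_sim_config(seed = 42))
  derived <- vapply(vignette_features(vg$features), triage_rule_engine, "")
  expect_equal(derived, vg$expected_category)
})

test_that("rule engine applies first-match category-I criteria", {
  expect_equal(triage_rule_engine("peri_arrest"), "I")
  expect_equal(triage_rule_engine("airway_obstructed"), "I")
  expect_equal(triage_rule_engine(c("abrasion", "blast_trauma")), "II")
  expect_equal(triage_rule_engine(character()), "III")
  expect_equal(triage_rule_engine("anything", rules = NULL), "III")
})

test_that("arrivals respect the first-arrival bound and cluster in waves", {
  cfg <- mci_sim_config(seed = 43)
  for (s in 1:20) {
    a <- sample_arrivals(mci_sim_config(seed = s))
    expect_gte(min(a), 40)
    expect_lte(max(a), cfg$arrival_last_min)
  }
  # one wave, zero jitter: all arrivals at the wave center
  one <- sample_arrivals(mci_sim_config(n_waves = 1, wave_sd_min = 0,
                                        seed = 44))
  expect_equal(length(unique(one)), 1)
  # clustering: variance-to-mean ratio of 10-min bin counts > 1 mostly
  vmr_hits <- mean(sapply(1:40, function(s) {
    a <- sample_arrivals(mci_sim_config(seed = s))
    cnt <- table(cut(a, breaks = seq(40, 180, by = 10)))
    var(as.numeric(cnt)) / mean(as.numeric(cnt)) > 1
  }))
  expect_gte(vmr_hits, 0.9)
})

test_that("triage decisions follow the misclassification model", {
  cfg <- mci_sim_config(seed = 45)
  vg <- sample_vignettes(cfg)
  # identity matrices + zero bias: all correct at both stages
  ident <- diag(3); dimnames(ident) <- dimnames(cfg$misclassification_stage2)
  cfg0 <- mci_sim_config(misclassification_stage1 = ident,
                         misclassification_stage2 = ident,
                         blast_trauma_green_bias = 0, seed = 45)
  tri0 <- sample_triage_decisions(vg, cfg0)
  m0 <- merge(vg, tri0[tri0$stage == 2, ], by = "patient_id")
  expect_true(all(m0$assigned_category == m0$expected_category))

  # bias 1: every blast-trauma II vignette assigned III at stage 2
  cfg1 <- mci_sim_config(misclassification_stage1 = ident,
                         misclassification_stage2 = ident,
                         blast_trauma_green_bias = 1, seed = 45)
  tri1 <- sample_triage_decisions(vg, cfg1)
  m1 <- merge(vg, tri1[tri1$stage == 2, ], by = "patient_id")
  blast <- grepl("blast_trauma", m1$features)
  expect_true(all(m1$assigned_category[blast] == "III"))
  expect_true(all(m1$assigned_category[!blast] == m1$expected_category[!blast]))
})

test_that("service times match the configured moments and truncation", {
  cfg <- mci_sim_config(seed = 46)
  cats <- rep(c("I", "II", "III"), each = 4000)
  sv <- sample_service_times(cfg, cats)
  expect_true(all(sv >= cfg$service_min_s))
  for (k in 1:3) {
    ts <- cfg$triage_service
    x <- sv[cats == ts$category[k]]
    expect_lt(abs(mean(x) - ts$mean_s[k]), 3 * ts$sd_s[k] / sqrt(length(x)))
    expect_lt(abs(sd(x) - ts$sd_s[k]) / ts$sd_s[k], 0.1)
  }
})

test_that("questionnaire generator hits boundary configurations", {
  roster <- sample_roster(mci_sim_config(seed = 47))
  # all-max config: every item clamps to 20, raw_total 120
  gx <- default_tlx_groups(); gx$mean <- 600; gx$sd <- 0
  cfg <- mci_sim_config(tlx_groups = gx, response_rate = 1, seed = 47)
  qn <- sample_questionnaires(roster, cfg)
  expect_true(all(score_tlx(qn$tlx)$raw_total == 120))

  # zero group effect: specialist-resident g centred near 0
  g0 <- default_tlx_groups(); g0$mean <- 66.7; g0$sd <- 14
  cfg0 <- mci_sim_config(tlx_groups = g0, response_rate = 1, seed = 48)
  gs <- sapply(1:40, function(s) {
    cfg_s <- mci_sim_config(tlx_groups = g0, response_rate = 1, seed = s)
    r <- sample_roster(cfg_s)
    q <- score_tlx(sample_questionnaires(r, cfg_s)$tlx)
    m <- merge_by_code(r, q)
    spec <- m$group == "physician" & m$specialist %in% TRUE
    resd <- m$group == "physician" & m$specialist %in% FALSE
    (mean(m$raw_total[spec]) - mean(m$raw_total[resd]))
  })
  expect_lt(abs(mean(gs)), 2 * sd(gs) / sqrt(length(gs)) + 1)
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- mci_sim_config(n_patients = 12, n_tracked_patients = 10,
                        n_staff_tagged = 8, seed = 49)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_exercise(simulate_exercise(cfg, tracks = TRUE), d1)
  write_exercise(simulate_exercise(cfg, tracks = TRUE), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("emitted files pass the readers' validation round-trip", {
  cfg <- mci_sim_config(n_patients = 15, n_tracked_patients = 12,
                        n_staff_tagged = 10, seed = 50)
  ex <- simulate_exercise(cfg, tracks = FALSE)
  d <- withr::local_tempdir()
  write_exercise(ex, d)
  back <- read_exercise(d)
  expect_equal(back$vignettes$expected_category, ex$vignettes$expected_category)
  expect_equal(back$roster$code, ex$roster$code)
  expect_equal(back$triage$assigned_category, ex$triage$assigned_category)
  expect_equal(back$episodes$t_enter_ms, ex$episodes$t_enter_ms)
  expect_equal(back$tlx$mental, ex$tlx$mental)
  expect_equal(back$team$item1, ex$team$item1)
})

test_that("n_patients = 0 still yields a valid (empty) dataset", {
  cfg <- mci_sim_config(n_patients = 0, n_tracked_patients = 0, seed = 51)
  ex <- simulate_exercise(cfg)
  expect_equal(nrow(ex$vignettes), 0)
  expect_equal(nrow(ex$triage), 0)
  d <- withr::local_tempdir()
  write_exercise(ex, d)
  expect_silent(read_exercise(d))
})
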