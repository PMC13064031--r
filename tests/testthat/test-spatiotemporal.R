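test_that("regularize_track interpolates onto the grid and splits on gaps", {
  s <- data.frame(tag_id = "A", t_ms = c(0, 1000), x_m = c(0, 2),
                  y_m = c(0, 0), floor_id = "F0")
  g <- regularize_track(s)
  expect_equal(g$t_ms, c(0, 500, 1000))
  expect_equal(g$x_m, c(0, 1, 2))

  # 10 s gap: two segments, no interpolation across
  s2 <- data.frame(tag_id = "A", t_ms = c(0, 500, 10500, 11000),
                   x_m = c(0, 1, 100, 101), y_m = 0, floor_id = "F0")
  g2 <- regularize_track(s2)
  expect_equal(unique(g2$segment), c(1L, 2L))
  expect_equal(nrow(g2), 4)

  # already-gridded track returned unchanged
  s3 <- make_track("A", seq(0, 2000, 500), x = 1:5, y = 5:1)
  g3 <- regularize_track(s3[, -6])
  expect_equal(g3$t_ms, s3$t_ms)
  expect_equal(g3$x_m, s3$x_m)
  expect_equal(g3$y_m, s3$y_m)

  # single-sample track: one-point segment
  g4 <- regularize_track(data.frame(tag_id = "A", t_ms = 500, x_m = 1,
                                    y_m = 2, floor_id = "F0"))
  expect_equal(nrow(g4), 1)
})

test_that("boundary points count as inside the polygon", {
  z <- square_zone(x0 = 0, y0 = 0, side = 10)
  expect_true(point_in_polygon(0, 5, z$polygon))    # edge
  expect_true(point_in_polygon(0, 0, z$polygon))    # vertex
  expect_true(point_in_polygon(5, 5, z$polygon))
  expect_false(point_in_polygon(10.01, 5, z$polygon))
})

test_that("zone episode debounce opens/closes per the confirm rules", {
  z <- square_zone()
  inside <- c(5, 5); outside <- c(50, 50)
  mk <- function(xy_seq) {
    make_track("A", seq(0, by = 500, length.out = length(xy_seq)),
               x = vapply(xy_seq, `[[`, 0, 1), y = vapply(xy_seq, `[[`, 0, 2))
  }
  # 10 consecutive in-zone samples -> one episode spanning them
  ep <- zone_episodes(mk(rep(list(inside), 10)), z)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_enter_ms, 0)
  expect_equal(ep$t_exit_ms, 4500 + 500)

  # single in-zone sample flanked by out-of-zone -> no episode
  ep2 <- zone_episodes(mk(c(list(outside), list(inside), list(outside),
                            list(outside))), z)
  expect_equal(nrow(ep2), 0)

  # two in-zone runs separated by 5 out-of-zone samples -> two episodes
  seq3 <- c(rep(list(inside), 4), rep(list(outside), 5), rep(list(inside), 4))
  tr3 <- mk(seq3)
  ep3 <- zone_episodes(tr3, z)
  expect_equal(nrow(ep3), 2)
  # agrees with the independent rectangle + state machine oracle
  oracle <- brute_rect_episodes(tr3, 0, 0, 10, 10)
  expect_equal(ep3$t_enter_ms, oracle$t_enter_ms)
  expect_equal(ep3$t_exit_ms, oracle$t_exit_ms)
})

test_that("dwell_time sums episode durations per tag", {
  ep <- data.frame(tag_id = c("A", "A", "B"), zone_id = "Z",
                   t_enter_ms = c(100000, 200000, 0),
                   t_exit_ms = c(159000, 220000, 10000))
  expect_equal(unname(dwell_time(ep, "Z")["A"]), 59 + 20)
  expect_equal(unname(dwell_time(ep, "Z", tags = c("A", "C"))["C"]), 0)
  expect_equal(unname(dwell_time(ep[0, ], "Z", tags = "A")["A"]), 0)
})

test_that("contact rule: <1 m sustained >=1 s, with gap merging", {
  tt <- seq(0, by = 500, length.out = 4)
  still <- make_track("P", tt, x = rep(0, 4), y = rep(0, 4))
  near <- make_track("S", tt, x = rep(0.5, 4), y = rep(0, 4))
  far <- make_track("S", tt, x = rep(1.5, 4), y = rep(0, 4))

  ep <- detect_contacts(near, still)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_end_ms - ep$t_start_ms, 2000)  # 4 instants x 500 ms
  expect_equal(ep$min_distance_m, 0.5)

  expect_equal(nrow(detect_contacts(far, still)), 0)

  # exactly one proximal instant: duration 0.5 s < 1 s
  one <- make_track("S", tt, x = c(0.5, 1.5, 1.5, 1.5), y = rep(0, 4))
  expect_equal(nrow(detect_contacts(one, still)), 0)

  # 0.5/0.5/1.5/0.5 pattern merges into a single episode
  pat <- make_track("S", tt, x = c(0.5, 0.5, 1.5, 0.5), y = rep(0, 4))
  ep2 <- detect_contacts(pat, still)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$t_start_ms, 0)
  expect_equal(ep2$t_end_ms, 2000)
  orc <- brute_contacts(pat, still)
  expect_equal(ep2$t_start_ms, orc$t_start_ms)
  expect_equal(ep2$t_end_ms, orc$t_end_ms)

  # different floors are never proximal
  otherfloor <- make_track("S", tt, x = rep(0.1, 4), y = rep(0, 4),
                           floor = "F1")
  expect_equal(nrow(detect_contacts(otherfloor, still)), 0)
})

test_that("detect_contacts matches the brute-force oracle on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    a <- random_track("S", n, p_drop = runif(1, 0, 0.3),
                      two_floors = i %% 3 == 0)
    b <- random_track("P", n, p_drop = runif(1, 0, 0.3),
                      two_floors = i %% 3 == 0)
    got <- detect_contacts(a, b)
    want <- brute_contacts(a, b)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want)) {
      expect_equal(got$t_start_ms, want$t_start_ms, info = paste("case", i))
      expect_equal(got$t_end_ms, want$t_end_ms, info = paste("case", i))
      expect_equal(got$min_distance_m, want$min_distance_m,
                   info = paste("case", i))
    }
  }
})

test_that("detect_contacts is symmetric under role swap", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_track("S", 80); b <- random_track("P", 80)
    ab <- detect_contacts(a, b); ba <- detect_contacts(b, a)
    expect_equal(ab$t_start_ms, ba$t_start_ms)
    expect_equal(ab$t_end_ms, ba$t_end_ms)
    expect_equal(ab$min_distance_m, ba$min_distance_m)
  }
})

test_that("episode count/coverage respond monotonically to thresholds", {
  set.seed(11)
  cover <- function(ep) if (nrow(ep)) sum(ep$t_end_ms - ep$t_start_ms) else 0
  for (i in 1:20) {
    a <- random_track("S", 100); b <- random_track("P", 100)
    base <- detect_contacts(a, b, d_max_m = 1, t_min_ms = 1000,
                            merge_gap_ms = 1000)
    wider <- detect_contacts(a, b, d_max_m = 2, t_min_ms = 1000,
                             merge_gap_ms = 1000)
    expect_gte(cover(wider), cover(base))
    merged <- detect_contacts(a, b, d_max_m = 1, t_min_ms = 1000,
                              merge_gap_ms = 3000)
    expect_gte(cover(merged), cover(base))
    stricter <- detect_contacts(a, b, d_max_m = 1, t_min_ms = 5000,
                                merge_gap_ms = 1000)
    expect_lte(nrow(stricter), nrow(base))
  }
})

test_that("total dwell across disjoint zones never exceeds the track span", {
  set.seed(5)
  zs <- structure(list(square_zone("z1", 0, 0, 8),
                       square_zone("z2", 9, 0, 8, role = "other"),
                       square_zone("z3", 0, 9, 8, role = "transport")),
                  class = "mci_zones")
  for (i in 1:10) {
    tr <- random_track("A", 150, p_drop = 0.1)
    ep <- zone_episodes(tr, zs)
    total <- sum(dwell_time(ep))
    span <- (max(tr$t_ms) - min(tr$t_ms) + 500) / 1000
    expect_lte(total, span + 1e-9)
  }
})

test_that("contacts_per_person counts zeros and reports the cohort mean", {
  roster <- mini_roster(4, tagged = 3)
  contacts <- data.frame(staff_tag = c("ST01", "ST01", "ST01"),
                         patient_tag = "PT01",
                         t_start_ms = c(0, 5000, 10000),
                         t_end_ms = c(2000, 7000, 12000),
                         min_distance_m = 0.5)
  cp <- contacts_per_person(contacts, roster)
  expect_equal(cp$n_staff, 3)  # only tagged staff count
  expect_equal(cp$n_contacts, 3)
  expect_equal(cp$mean, 1)     # 3 episodes over 3 tracked staff
  expect_equal(sort(cp$per_person$n_contacts), c(0, 0, 3))

  # 1 staff with 3 episodes, 1 with 0 -> mean 1.5
  cp2 <- contacts_per_person(contacts, mini_roster(2, tagged = 2))
  expect_equal(cp2$mean, 1.5)

  # unknown staff tag excluded with warning
  bad <- contacts; bad$staff_tag <- "NOPE"
  expect_warning(cp3 <- contacts_per_person(bad, roster), "unknown staff tag")
  expect_equal(cp3$n_contacts, 0)
  expect_equal(cp3$mean, 0)
})
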