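# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately re-derive the definitions with plain per-instant
# loops (and, for rectangles, direct coordinate comparison instead of the
# package's point-in-polygon), so they share no code path with the
# implementation they check.

# a gridded track from explicit instants/positions
make_track <- function(tag, t_ms, x, y, floor = "F0") {
  data.frame(tag_id = tag, t_ms = t_ms, x_m = x, y_m = y,
             floor_id = rep_len(floor, length(t_ms)),
             segment = 1L, stringsAsFactors = FALSE)
}

square_zone <- function(id = "Z", x0 = 0, y0 = 0, side = 10, floor = "F0",
                        role = "triage2") {
  zone(id, floor, role,
       cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side)))
}

# random gridded track: random walk with dropout and occasional floor hops
random_track <- function(tag, n_instants, period = 500, p_drop = 0.15,
                         two_floors = FALSE) {
  t <- seq(0, by = period, length.out = n_instants)
  keep <- runif(n_instants) >= p_drop
  if (!any(keep)) keep[1] <- TRUE
  x <- cumsum(rnorm(n_instants, 0, 0.6))
  y <- cumsum(rnorm(n_instants, 0, 0.6))
  fl <- if (two_floors) {
    ifelse(cumsum(runif(n_instants) < 0.02) %% 2 == 0, "F0", "F1")
  } else "F0"
  make_track(tag, t[keep], x[keep], y[keep],
             if (length(fl) > 1) fl[keep] else fl)
}

# Oracle 1: contact detection by explicit per-instant labelling + run merge
brute_contacts <- function(a, b, d_max = 1, t_min = 1000, merge_gap = 1000,
                           period = 500) {
  ts <- sort(intersect(a$t_ms, b$t_ms))
  eps <- list()
  cur <- NULL
  for (t in ts) {
    ia <- which(a$t_ms == t); ib <- which(b$t_ms == t)
    d <- sqrt((a$x_m[ia] - b$x_m[ib])^2 + (a$y_m[ia] - b$y_m[ib])^2)
    prox <- (a$floor_id[ia] == b$floor_id[ib]) && (d < d_max)
    if (prox) {
      if (is.null(cur)) {
        cur <- list(start = t, last = t, mind = d)
      } else if (t - cur$last - period <= merge_gap) {
        cur$last <- t; cur$mind <- min(cur$mind, d)
      } else {
        eps[[length(eps) + 1L]] <- cur
        cur <- list(start = t, last = t, mind = d)
      }
    }
  }
  if (!is.null(cur)) eps[[length(eps) + 1L]] <- cur
  eps <- Filter(function(e) e$last - e$start + period >= t_min, eps)
  data.frame(t_start_ms = vapply(eps, `[[`, 0, "start"),
             t_end_ms = vapply(eps, `[[`, 0, "last") + period,
             min_distance_m = vapply(eps, `[[`, 0, "mind"))
}

# Oracle 2: zone episodes for an axis-aligned rectangle by direct
# coordinate membership + explicit debounce state machine
brute_rect_episodes <- function(track, x0, y0, x1, y1, floor = "F0",
                                enter_confirm = 2, exit_confirm = 2,
                                period = 500) {
  out <- data.frame(t_enter_ms = numeric(), t_exit_ms = numeric())
  for (seg in unique(track$segment)) {
    s <- track[track$segment == seg & track$floor_id == floor, , drop = FALSE]
    if (!nrow(s)) next
    inz <- s$x_m >= x0 & s$x_m <= x1 & s$y_m >= y0 & s$y_m <= y1
    state <- FALSE; nin <- 0; nout <- 0; t_enter <- NA; t_last_in <- NA
    for (i in seq_along(inz)) {
      if (inz[i]) {
        nin <- nin + 1; nout <- 0
        if (!state && nin >= enter_confirm) {
          state <- TRUE
          t_enter <- s$t_ms[i - enter_confirm + 1]
        }
        if (state) t_last_in <- s$t_ms[i]
      } else {
        nout <- nout + 1; nin <- 0
        if (state && nout >= exit_confirm) {
          state <- FALSE
          out <- rbind(out, data.frame(t_enter_ms = t_enter,
                                       t_exit_ms = t_last_in + period))
        }
      }
    }
    if (state) {
      out <- rbind(out, data.frame(t_enter_ms = t_enter,
                                   t_exit_ms = t_last_in + period))
    }
  }
  out[order(out$t_enter_ms), , drop = FALSE]
}

# Table-2-shaped fixtures: 69 tracked patients with expected categories and
# stage assignments reproducing the benchmark confusion counts.
# stage 2: 52 correct, 8 I->II, 7 II->III, 2 II->I
# stage 1: 53 correct, 7 I->II, 7 II->III, 2 II->I
table2_fixture <- function() {
  n_I <- 21; n_II <- 21; n_III <- 27  # 69 total, ~30/30/40
  expected <- c(rep("I", n_I), rep("II", n_II), rep("III", n_III))
  pid <- sprintf("P%02d", seq_along(expected))
  assign_stage <- function(n_i_to_ii) {
    a <- expected
    a[seq_len(n_i_to_ii)] <- "II"                 # I -> II
    a[n_I + 1:7] <- "III"                         # II -> III
    a[n_I + 8:9] <- "I"                           # II -> I
    a
  }
  vg <- data.frame(patient_id = pid, expected_category = expected,
                   features = "", tag_id = sprintf("PT%02d", seq_along(pid)),
                   stringsAsFactors = FALSE)
  tri <- rbind(
    data.frame(patient_id = pid, stage = 1L,
               assigned_category = assign_stage(7), t_assign_ms = NA_real_),
    data.frame(patient_id = pid, stage = 2L,
               assigned_category = assign_stage(8), t_assign_ms = NA_real_))
  list(vignettes = vg, triage = tri)
}

# tiny roster for contact / merge tests
mini_roster <- function(n = 4, tagged = n) {
  data.frame(code = sprintf("C%02d", seq_len(n)),
             group = rep_len(c("physician", "nurse"), n),
             specialist = rep_len(c(TRUE, NA), n),
             experience_years = seq_len(n),
             age_years = 30 + seq_len(n),
             gender = rep_len(c("female", "male"), n),
             tag_id = c(sprintf("ST%02d", seq_len(tagged)),
                        rep(NA_character_, n - tagged)),
             stringsAsFactors = FALSE)
}
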