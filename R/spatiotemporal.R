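# Zone-occupancy and proximity-contact analytics on gridded tag tracks.
#
# All operations work on the common RTLS sampling grid: instants at integer
# multiples of the 500 ms sampling period, in ms since the exercise alarm.
# A run of k consecutive grid instants has duration k * period, so that two
# consecutive proximity instants already satisfy the "at least 1 s" contact
# rule.

#' Regularize a raw tag track onto the sampling grid
#'
#' Positions are linearly interpolated onto the common grid (multiples of
#' `period_ms` in absolute exercise time) within runs whose inter-sample gap
#' is at most `max_gap_ms`; larger gaps (signal dropout, out-of-coverage,
#' floor changes) split the track into segments, and nothing is interpolated
#' across a split. A track already on the grid is returned unchanged (up to
#' segment labelling).
#'
#' @param samples data.frame `t_ms, x_m, y_m, floor_id` for one tag, sorted
#'   by `t_ms` (a `tag_id` column is carried through if present).
#' @param period_ms sampling period, default 500.
#' @param max_gap_ms largest gap bridged by interpolation, default 2000.
#' @return data.frame `t_ms, x_m, y_m, floor_id, segment` on the grid.
#' @export
regularize_track <- function(samples, period_ms = 500, max_gap_ms = 2000) {
  stopifnot(!is.unsorted(samples$t_ms))
  n <- nrow(samples)
  tag <- if ("tag_id" %in% names(samples) && n) samples$tag_id[1] else NA_character_
  empty <- data.frame(tag_id = character(), t_ms = numeric(), x_m = numeric(),
                      y_m = numeric(), floor_id = character(),
                      segment = integer(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  brk <- c(TRUE, diff(samples$t_ms) > max_gap_ms |
                 samples$floor_id[-1] != samples$floor_id[-n])
  seg_id <- cumsum(brk)
  out <- lapply(split(seq_len(n), seg_id), function(idx) {
    s <- samples[idx, , drop = FALSE]
    t0 <- ceiling(s$t_ms[1] / period_ms) * period_ms
    t1 <- floor(s$t_ms[nrow(s)] / period_ms) * period_ms
    if (t1 < t0) {  # segment shorter than one grid cell: keep nearest instant
      tg <- round(s$t_ms[1] / period_ms) * period_ms
      return(data.frame(t_ms = tg, x_m = s$x_m[1], y_m = s$y_m[1],
                        floor_id = s$floor_id[1], stringsAsFactors = FALSE))
    }
    tg <- seq(t0, t1, by = period_ms)
    if (nrow(s) == 1) {
      xg <- rep(s$x_m, length(tg)); yg <- rep(s$y_m, length(tg))
    } else {
      xg <- stats::approx(s$t_ms, s$x_m, xout = tg, ties = "ordered")$y
      yg <- stats::approx(s$t_ms, s$y_m, xout = tg, ties = "ordered")$y
    }
    data.frame(t_ms = tg, x_m = xg, y_m = yg, floor_id = s$floor_id[1],
               stringsAsFactors = FALSE)
  })
  seg_len <- vapply(out, nrow, 0L)
  out <- do.call(rbind, out)
  out$segment <- rep(seq_along(seg_len), seg_len)
  out <- out[!duplicated(out$t_ms), , drop = FALSE]  # segments may abut
  out$tag_id <- tag
  rownames(out) <- NULL
  out[, c("tag_id", "t_ms", "x_m", "y_m", "floor_id", "segment")]
}

#' Regularize all tags in a position table
#' @param positions data.frame as from [read_positions()].
#' @inheritParams regularize_track
#' @return data.frame of gridded tracks for all tags.
#' @export
regularize_all <- function(positions, period_ms = 500, max_gap_ms = 2000) {
  parts <- lapply(split(positions, positions$tag_id), regularize_track,
                  period_ms = period_ms, max_gap_ms = max_gap_ms)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- regularize_track(positions[0, ])
  out
}

#' Detect zone-occupancy episodes of one gridded track
#'
#' Point-in-polygon membership (boundary inclusive) is evaluated per grid
#' instant for every zone on the track's floor. An episode opens once
#' `enter_confirm` consecutive in-zone instants are seen (`t_enter` = the
#' first of them) and closes once `exit_confirm` consecutive out-of-zone
#' instants follow (`t_exit` = the first of them); the debounce suppresses
#' single-sample jitter across a geofence border. Track segments are
#' processed independently; an episode still open when a segment ends closes
#' at the last in-zone instant plus one period (which coincides with the
#' usual `t_exit` rule on the grid).
#'
#' @param track gridded track from [regularize_track()].
#' @param zones `mci_zones` list (or a single `mci_zone`).
#' @param enter_confirm,exit_confirm debounce lengths in samples, default 2.
#' @param period_ms sampling period, default 500.
#' @return data.frame `tag_id, zone_id, t_enter_ms, t_exit_ms`.
#' @export
zone_episodes <- function(track, zones, enter_confirm = 2, exit_confirm = 2,
                          period_ms = 500) {
  if (inherits(zones, "mci_zone")) zones <- list(zones)
  out <- list()
  for (z in zones) {
    on_floor <- track$floor_id == z$floor_id
    if (!any(on_floor)) next
    for (seg in unique(track$segment[on_floor])) {
      s <- track[on_floor & track$segment == seg, , drop = FALSE]
      inz <- point_in_polygon(s$x_m, s$y_m, z$polygon)
      ep <- debounce_runs(inz, enter_confirm, exit_confirm)
      if (!nrow(ep)) next
      out[[length(out) + 1L]] <- data.frame(
        tag_id = s$tag_id[1], zone_id = z$zone_id,
        t_enter_ms = s$t_ms[ep$first],
        t_exit_ms = s$t_ms[ep$last] + period_ms,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(tag_id = character(), zone_id = character(),
                      t_enter_ms = numeric(), t_exit_ms = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$zone_id, out$t_enter_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Debounced run detection on a logical vector: a run opens after
# `enter_confirm` consecutive TRUE and closes after `exit_confirm`
# consecutive FALSE (or at end of vector). Returns first/last index of the
# in-state stretch (from the first confirming TRUE to the last TRUE before
# close).
#' @keywords internal
#' @noRd
debounce_runs <- function(inz, enter_confirm, exit_confirm) {
  n <- length(inz)
  first <- integer(); last <- integer()
  state <- FALSE; run_in <- 0L; run_out <- 0L; start <- NA_integer_; last_in <- NA_integer_
  for (i in seq_len(n)) {
    if (inz[i]) {
      run_in <- run_in + 1L; run_out <- 0L
      if (!state && run_in >= enter_confirm) {
        state <- TRUE
        start <- i - enter_confirm + 1L
      }
      if (state) last_in <- i
    } else {
      run_out <- run_out + 1L; run_in <- 0L
      if (state && run_out >= exit_confirm) {
        state <- FALSE
        first <- c(first, start); last <- c(last, last_in)
      }
    }
  }
  if (state) { first <- c(first, start); last <- c(last, last_in) }
  data.frame(first = first, last = last)
}

#' Zone episodes for every tag in a gridded position table
#' @param tracks output of [regularize_all()].
#' @inheritParams zone_episodes
#' @return combined episode data.frame.
#' @export
zone_episodes_all <- function(tracks, zones, enter_confirm = 2,
                              exit_confirm = 2, period_ms = 500) {
  parts <- lapply(split(tracks, tracks$tag_id), zone_episodes, zones = zones,
                  enter_confirm = enter_confirm, exit_confirm = exit_confirm,
                  period_ms = period_ms)
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Total dwell time per tag in a zone
#'
#' @param episodes data.frame from [zone_episodes()].
#' @param zone_id zone to sum over (or `NULL` for all zones together).
#' @param tags optional character vector of tags to report (tags with no
#'   episode get 0).
#' @return named numeric vector, seconds per tag.
#' @export
dwell_time <- function(episodes, zone_id = NULL, tags = NULL) {
  if (!is.null(zone_id)) episodes <- episodes[episodes$zone_id %in% zone_id, ]
  secs <- vapply(split((episodes$t_exit_ms - episodes$t_enter_ms) / 1000,
                       episodes$tag_id), sum, 0)
  if (!is.null(tags)) {
    out <- stats::setNames(numeric(length(tags)), tags)
    out[names(secs)[names(secs) %in% tags]] <-
      secs[names(secs) %in% tags]
    return(out)
  }
  secs
}

#' Detect staff-patient proximity contacts
#'
#' Implements the contact rule: proximity at a grid instant holds iff both
#' tags are on the same floor and their Euclidean distance is below `d_max_m`
#' (1 m). Maximal runs of proximity instants separated by at most
#' `merge_gap_ms` of non-proximity are merged; merged runs lasting at least
#' `t_min_ms` (1 s) become contact episodes. A run covering instants
#' `t_first..t_last` has duration `t_last - t_first + period_ms`, so two
#' consecutive instants meet the 1 s minimum. Instants present in only one
#' track (dropout, no temporal overlap) count as non-proximity.
#'
#' @param staff_track,patient_track gridded tracks ([regularize_track()]).
#' @param d_max_m proximity distance threshold, default 1.0.
#' @param t_min_ms minimum episode duration, default 1000.
#' @param merge_gap_ms longest non-proximity gap merged over, default 1000.
#' @param period_ms sampling period, default 500.
#' @return data.frame `staff_tag, patient_tag, t_start_ms, t_end_ms,
#'   min_distance_m`; `t_end_ms` is the last proximity instant plus one
#'   period, so `t_end_ms - t_start_ms` is the episode duration.
#' @export
detect_contacts <- function(staff_track, patient_track, d_max_m = 1.0,
                            t_min_ms = 1000, merge_gap_ms = 1000,
                            period_ms = 500) {
  empty <- data.frame(staff_tag = character(), patient_tag = character(),
                      t_start_ms = numeric(), t_end_ms = numeric(),
                      min_distance_m = numeric(), stringsAsFactors = FALSE)
  ts <- intersect(staff_track$t_ms, patient_track$t_ms)
  if (!length(ts)) return(empty)
  ts <- sort(ts)
  a <- staff_track[match(ts, staff_track$t_ms), ]
  b <- patient_track[match(ts, patient_track$t_ms), ]
  dist <- sqrt((a$x_m - b$x_m)^2 + (a$y_m - b$y_m)^2)
  prox <- (a$floor_id == b$floor_id) & (dist < d_max_m)
  if (!any(prox)) return(empty)
  pt <- ts[prox]
  pd <- dist[prox]
  # merge proximity instants whose spacing allows <= merge_gap_ms of
  # non-proximity between them
  newrun <- c(TRUE, diff(pt) > merge_gap_ms + period_ms)
  run <- cumsum(newrun)
  t_start <- tapply(pt, run, min)
  t_last <- tapply(pt, run, max)
  mind <- tapply(pd, run, min)
  dur <- t_last - t_start + period_ms
  keep <- dur >= t_min_ms
  if (!any(keep)) return(empty)
  data.frame(staff_tag = staff_track$tag_id[1],
             patient_tag = patient_track$tag_id[1],
             t_start_ms = as.numeric(t_start[keep]),
             t_end_ms = as.numeric(t_last[keep]) + period_ms,
             min_distance_m = as.numeric(mind[keep]),
             stringsAsFactors = FALSE)
}

#' Detect contacts for all staff-patient tag pairs
#'
#' @param tracks gridded tracks for all tags ([regularize_all()]).
#' @param staff_tags,patient_tags tag id vectors defining the two roles.
#' @inheritParams detect_contacts
#' @return combined contact episode data.frame.
#' @export
detect_contacts_all <- function(tracks, staff_tags, patient_tags,
                                d_max_m = 1.0, t_min_ms = 1000,
                                merge_gap_ms = 1000, period_ms = 500) {
  bytag <- split(tracks, tracks$tag_id)
  out <- list()
  for (s in intersect(staff_tags, names(bytag))) {
    for (p in intersect(patient_tags, names(bytag))) {
      ep <- detect_contacts(bytag[[s]], bytag[[p]], d_max_m, t_min_ms,
                            merge_gap_ms, period_ms)
      if (nrow(ep)) out[[length(out) + 1L]] <- ep
    }
  }
  if (!length(out)) {
    return(detect_contacts(regularize_track(empty_positions()),
                           regularize_track(empty_positions())))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Patient contacts per staff member
#'
#' Maps each contact episode to the staff member's anonymized code and
#' counts episodes per person. Staff who carry a tag but logged no contact
#' count as zero; episodes whose staff tag is not on the roster are dropped
#' with a warning.
#'
#' @param contacts contact episodes ([detect_contacts()] output).
#' @param roster roster data.frame with `code` and `tag_id`.
#' @return list with `per_person` (data.frame `code, n_contacts`), `n_staff`,
#'   `n_contacts`, `mean`, `sd`.
#' @export
contacts_per_person <- function(contacts, roster) {
  tagged <- roster[!is.na(roster$tag_id) & nzchar(roster$tag_id), ]
  known <- contacts$staff_tag %in% tagged$tag_id
  if (any(!known)) {
    warning(sum(!known), " contact episode(s) with unknown staff tag excluded",
            call. = FALSE)
    contacts <- contacts[known, , drop = FALSE]
  }
  code <- tagged$code[match(contacts$staff_tag, tagged$tag_id)]
  counts <- table(factor(code, levels = tagged$code))
  per <- data.frame(code = names(counts), n_contacts = as.integer(counts),
                    stringsAsFactors = FALSE)
  list(per_person = per,
       n_staff = nrow(tagged),
       n_contacts = sum(per$n_contacts),
       mean = mean(per$n_contacts),
       sd = stats::sd(per$n_contacts))
}
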