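# RTLS position rendering for the synthetic exercise. Each tracked patient
# follows the planned itinerary arrival -> first-look triage -> algorithm
# triage (dwell = sampled service time) -> category-appropriate treatment
# area -> transport; staff tags are rendered during their planned patient
# visits, standing 0.3-0.7 m from the patient (locators only cover the
# equipped areas, so idle staff produce no samples). Zone boundary
# crossings are aligned to the planned enter/exit instants by placing
# keyframes 0.25 m outside and inside the geofence edge 250 ms around the
# crossing, so the measured dwell recovers the planned one to within about
# one sampling period.

#' @keywords internal
#' @noRd
zone_anchor <- function(zones) {
  out <- list()
  for (z in zones) {
    xs <- z$polygon[, 1]; ys <- z$polygon[, 2]
    cx <- mean(range(xs)); cy <- mean(range(ys))
    out[[z$zone_id]] <- list(
      floor = z$floor_id,
      center = c(cx, cy),
      entry_out = c(min(xs) - 0.25, cy), entry_in = c(min(xs) + 0.25, cy),
      exit_in = c(max(xs) - 0.25, cy), exit_out = c(max(xs) + 0.25, cy),
      bbox = c(min(xs), min(ys), max(xs), max(ys)))
  }
  out
}

# keyframes for one zone visit: approach/entry pair, interior anchor(s),
# exit pair. `hold` optionally pins an interior position over [h0, h1].
#' @keywords internal
#' @noRd
visit_keyframes <- function(anchor, t_enter, t_exit, hold_pos = NULL) {
  ctr <- if (is.null(hold_pos)) anchor$center else hold_pos
  k <- data.frame(
    t = c(t_enter - 250, t_enter + 250),
    x = c(anchor$entry_out[1], anchor$entry_in[1]),
    y = c(anchor$entry_out[2], anchor$entry_in[2]),
    floor = anchor$floor, stringsAsFactors = FALSE)
  mid0 <- t_enter + min(5000, (t_exit - t_enter) / 3)
  mid1 <- t_exit - min(5000, (t_exit - t_enter) / 3)
  if (mid1 > mid0) {
    k <- rbind(k, data.frame(t = c(mid0, mid1), x = ctr[1], y = ctr[2],
                             floor = anchor$floor))
  }
  rbind(k, data.frame(
    t = c(t_exit - 250, t_exit + 250),
    x = c(anchor$exit_in[1], anchor$exit_out[1]),
    y = c(anchor$exit_in[2], anchor$exit_out[2]),
    floor = anchor$floor))
}

# sample keyframes onto the 500 ms grid; consecutive keyframes on different
# floors produce a gap (no samples in between)
#' @keywords internal
#' @noRd
render_keyframes <- function(tag, keys, period_ms = 500) {
  keys <- keys[order(keys$t), , drop = FALSE]
  blk <- cumsum(c(TRUE, keys$floor[-1] != keys$floor[-nrow(keys)]))
  out <- lapply(split(keys, blk), function(k) {
    t0 <- ceiling(min(k$t) / period_ms) * period_ms
    t1 <- floor(max(k$t) / period_ms) * period_ms
    if (t1 < t0) return(NULL)
    tg <- seq(t0, t1, by = period_ms)
    data.frame(tag_id = tag, t_ms = tg,
               x_m = stats::approx(k$t, k$x, xout = tg, ties = "ordered")$y,
               y_m = stats::approx(k$t, k$y, xout = tg, ties = "ordered")$y,
               floor_id = k$floor[1], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Render RTLS position samples for a synthetic exercise
#'
#' Builds 500 ms position streams for all tracked patients and all staff
#' visits from the exercise plan, applies per-sample dropout, and returns a
#' position table in reading order.
#'
#' @param exercise `mci_exercise` from [simulate_exercise()].
#' @param config `mci_sim_config` (defaults to the exercise's own).
#' @return positions data.frame (`tag_id, t_ms, x_m, y_m, floor_id`).
#' @export
generate_tracks <- function(exercise, config = exercise$config) {
  itin <- exercise$ground_truth$itinerary
  plan <- exercise$ground_truth$contact_plan
  anchors <- zone_anchor(exercise$zones)
  with_substream(config$seed, "tracks", {
    parts <- list()
    for (i in seq_len(NROW(itin))) {
      r <- itin[i, ]
      if (is.na(r$tag_id)) next
      ent <- anchors[[r$triage1_zone]]
      keys <- rbind(
        data.frame(t = r$t_arr - 15000, x = ent$entry_out[1] - 3,
                   y = ent$entry_out[2] + 3, floor = ent$floor),
        visit_keyframes(anchors[[r$triage1_zone]], r$t_arr, r$t1_exit),
        visit_keyframes(anchors[[r$triage2_zone]], r$t2_enter, r$t2_exit),
        visit_keyframes(anchors[[r$treat_zone]], r$treat_enter, r$treat_exit,
                        hold_pos = c(r$bed_x, r$bed_y)),
        visit_keyframes(anchors[[r$trans_zone]], r$trans_enter, r$trans_exit))
      parts[[length(parts) + 1L]] <- render_keyframes(r$tag_id, keys)
    }
    # staff: static at patient bed + offset during each visit
    if (NROW(plan)) {
      bed <- itin[match(plan$patient_tag, itin$tag_id), c("bed_x", "bed_y")]
      ang <- stats::runif(nrow(plan), 0, 2 * pi)
      rad <- stats::runif(nrow(plan), 0.3, 0.7)
      for (j in seq_len(nrow(plan))) {
        anchor <- anchors[[plan$zone_id[j]]]
        tg <- seq(ceiling(plan$t_start_ms[j] / 500) * 500,
                  floor(plan$t_end_ms[j] / 500) * 500, by = 500)
        parts[[length(parts) + 1L]] <- data.frame(
          tag_id = plan$staff_tag[j], t_ms = tg,
          x_m = bed$bed_x[j] + rad[j] * cos(ang[j]),
          y_m = bed$bed_y[j] + rad[j] * sin(ang[j]),
          floor_id = anchor$floor, stringsAsFactors = FALSE)
      }
    }
    pos <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
    if (is.null(pos)) return(empty_positions())
    if (config$dropout > 0) {
      pos <- pos[stats::runif(nrow(pos)) >= config$dropout, , drop = FALSE]
    }
    pos <- pos[order(pos$tag_id, pos$t_ms), , drop = FALSE]
    rownames(pos) <- NULL
    pos
  })
}
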