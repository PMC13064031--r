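# Report rendering and CLI-facing commands. All report rounding is
# centralized here: one decimal for percentages and means, integers for
# counts, two decimals for effect sizes. Rendering is deterministic: a
# rerun on the same bundle is byte-identical.

#' @keywords internal
#' @noRd
fmt1 <- function(x) sprintf("%.1f", round_half_up(x, 1))

#' @keywords internal
#' @noRd
fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' @keywords internal
#' @noRd
md_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col) && !all(col == floor(col) | is.na(col))) fmt1(col)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(cells) | cells == "NA"] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Render a human-readable markdown report
#'
#' @param analysis `mci_analysis` object.
#' @return character vector of markdown lines.
#' @export
render_report <- function(analysis) {
  out <- c("# MCI exercise report", "")
  if (!is.null(analysis$demographics)) {
    out <- c(out, "## Participants", "", md_table(analysis$demographics), "")
  }
  if (!is.null(analysis$confusion)) {
    out <- c(out, "## Triage accuracy", "")
    for (s in names(analysis$confusion)) {
      blk <- analysis$confusion[[s]]
      m <- blk$metrics
      if (is.null(m)) next
      out <- c(out, sprintf("### %s (n = %d)", s, m$n_total), "",
               sprintf("- overall accuracy: %d (%s%%)",
                       m$counts[["overall"]], fmt1(m$overall_pct)),
               sprintf("- undertriage: %d (%s%%); missed category I: %d (%s%%); missed category II: %d (%s%%)",
                       m$counts[["undertriage"]], fmt1(m$undertriage_pct),
                       m$counts[["missed_I"]], fmt1(m$missed_I_pct),
                       m$counts[["missed_II"]], fmt1(m$missed_II_pct)),
               sprintf("- overtriage: %d (%s%%); false category I: %d (%s%%)",
                       m$counts[["overtriage"]], fmt1(m$overtriage_pct),
                       m$counts[["false_I"]], fmt1(m$false_I_pct)), "")
    }
  }
  if (!is.null(analysis$timing)) {
    out <- c(out, "## Triage duration by assigned category", "",
             md_table(analysis$timing$by_category$summary), "")
    if (nrow(analysis$timing$by_category$pairwise)) {
      out <- c(out, md_table(analysis$timing$by_category$pairwise), "")
    }
    uc <- analysis$timing$undertriage_contrast
    if (!is.null(uc$test)) {
      out <- c(out, sprintf(
        "Correctly triaged category I (%s +- %s s, n = %d) vs undertriaged (%s +- %s s, n = %d): %s, p = %.4g %s",
        fmt1(uc$correct_I$mean_s), fmt1(uc$correct_I$sd_s), uc$correct_I$n,
        fmt1(uc$undertriaged$mean_s), fmt1(uc$undertriaged$sd_s),
        uc$undertriaged$n, uc$test$test_name, uc$test$p_value,
        uc$test$stars), "")
    }
  }
  if (!is.null(analysis$contacts)) {
    out <- c(out, "## Patient contacts per participant", "",
             md_table(analysis$contacts$summary), "")
    if (!is.null(analysis$contacts$tests) && nrow(analysis$contacts$tests)) {
      out <- c(out, md_table(analysis$contacts$tests), "")
    }
  }
  if (!is.null(analysis$tlx)) {
    out <- c(out, "## NASA-TLX workload", "",
             sprintf("Overall raw TLX: %s +- %s (n = %d)",
                     fmt1(analysis$tlx$overall$mean),
                     fmt1(analysis$tlx$overall$sd), analysis$tlx$n), "",
             md_table(analysis$tlx$items), "")
    for (nm in names(analysis$tlx$contrasts)) {
      ct <- analysis$tlx$contrasts[[nm]]
      out <- c(out, sprintf(
        "- %s: %s +- %s (n = %d) vs %s +- %s (n = %d); %s p = %.4g %s; Hedges' g = %s [%s, %s]",
        nm, fmt1(ct$mean[1]), fmt1(ct$sd[1]), ct$n[1], fmt1(ct$mean[2]),
        fmt1(ct$sd[2]), ct$n[2], ct$test$test_name, ct$test$p_value,
        ct$test$stars, fmt2(ct$effect$g), fmt2(ct$effect$ci_low),
        fmt2(ct$effect$ci_high)))
    }
    out <- c(out, "")
  }
  if (!is.null(analysis$team)) {
    s <- analysis$team$summary
    out <- c(out, "## TEAM teamwork", "",
             sprintf("Mean item score %s, total %s%% of 44 (n = %d); global rating mean %s",
                     fmt1(s$mean_item), fmt1(s$percent), s$n,
                     fmt1(s$global_mean)), "")
  }
  if (length(analysis$notes)) {
    out <- c(out, "## Warnings", "", paste0("- ", analysis$notes), "")
  }
  out
}

#' Simulate an exercise and write the dataset (CLI command)
#'
#' @param out_dir output directory.
#' @param config `mci_sim_config` (or `NULL` for defaults).
#' @param tracks render RTLS positions (default `TRUE`).
#' @param seed optional seed override.
#' @return output directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = NULL, tracks = TRUE, seed = NULL) {
  if (is.null(config)) config <- mci_sim_config()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  ex <- simulate_exercise(config, tracks = tracks)
  write_exercise(ex, out_dir)
  jsonlite::write_json(list(seed = config$seed,
                            n_patients = config$n_patients,
                            n_staff_tagged = config$n_staff_tagged),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Analyze a dataset directory and write the report bundle (CLI command)
#'
#' @param in_dir dataset directory ([cmd_simulate()] output or equivalent).
#' @param out_dir bundle directory.
#' @return the `mci_analysis`, invisibly.
#' @export
cmd_analyze <- function(in_dir, out_dir) {
  analysis <- mci_analyze(in_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- analysis_bundle(analysis)
  jsonlite::write_json(bundle, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  if (!is.null(analysis$demographics)) {
    write_table(analysis$demographics, file.path(out_dir, "demographics.csv"))
  }
  if (!is.null(analysis$timing)) {
    write_table(analysis$timing$by_category$summary,
                file.path(out_dir, "timing_by_category.csv"))
  }
  if (!is.null(analysis$contacts)) {
    write_table(analysis$contacts$summary,
                file.path(out_dir, "contacts_summary.csv"))
  }
  invisible(analysis)
}

#' @keywords internal
#' @noRd
analysis_bundle <- function(analysis) {
  strip <- function(x) {
    if (inherits(x, c("mci_test", "mci_effect", "mci_confusion"))) {
      unclass(x)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, strip)
    } else x
  }
  strip(unclass(analysis))
}

#' Render the report bundle to markdown (CLI command)
#'
#' @param analysis `mci_analysis` (or a dataset/bundle directory: a dataset
#'   is re-analyzed).
#' @param out_path markdown output path.
#' @return `out_path`, invisibly.
#' @export
cmd_report <- function(analysis, out_path) {
  if (is.character(analysis)) analysis <- mci_analyze(analysis)
  writeLines(render_report(analysis), out_path)
  invisible(out_path)
}
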