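# Readers/writers for all exercise input files. Timestamps are integer
# milliseconds since the exercise alarm (t = 0); coordinates are metres in a
# per-floor planar frame. CSV is UTF-8 with header and "." decimal
# separator; positions may alternatively be JSON lines. All readers validate
# invariants and report (not silently drop) malformed input.

ZONE_ROLES <- c("triage1", "triage2", "treatment_red", "treatment_yellow",
                "treatment_green", "transport", "other")
STAFF_GROUPS <- c("physician", "nurse", "nurse_trainee", "other")

#' Read RTLS tag position samples
#'
#' Expects columns `tag_id, t_ms, x_m, y_m, floor_id` (CSV) or one JSON
#' object per line with those keys (JSONL). Rows with missing/non-finite
#' coordinates or timestamps are rejected and counted; the rejection count is
#' attached as attribute `n_rejected`. Samples are returned grouped per tag
#' and stably sorted by time; non-monotone input timestamps within a tag
#' trigger a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return data.frame `tag_id, t_ms, x_m, y_m, floor_id`, sorted by
#'   `(tag_id, t_ms)`, with attribute `n_rejected`.
#' @export
read_positions <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    if (file.size(path) == 0) {
      df <- empty_positions()
    } else {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (nrow(df)) {
        df$tag_id <- as.character(df$tag_id)
        df$floor_id <- as.character(df$floor_id)
      }
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      df <- empty_positions()
    } else {
      rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
      df <- do.call(rbind, rows)
    }
  }
  if (!nrow(df)) {
    out <- empty_positions()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  check_cols(df, c("tag_id", "t_ms", "x_m", "y_m", "floor_id"), "positions")
  df$t_ms <- suppressWarnings(as.numeric(df$t_ms))
  df$x_m <- suppressWarnings(as.numeric(df$x_m))
  df$y_m <- suppressWarnings(as.numeric(df$y_m))
  ok <- is.finite(df$t_ms) & is.finite(df$x_m) & is.finite(df$y_m) &
        !is.na(df$tag_id) & nzchar(df$tag_id)
  n_rejected <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  # stable sort per tag; warn on non-monotone raw order
  nonmono <- vapply(split(df$t_ms, df$tag_id), function(t) is.unsorted(t),
                    logical(1))
  if (any(nonmono)) {
    warning("non-monotone timestamps within tag(s): ",
            paste(names(nonmono)[nonmono], collapse = ", "),
            "; applying stable sort", call. = FALSE)
  }
  df <- df[order(df$tag_id, df$t_ms, method = "radix"),
           c("tag_id", "t_ms", "x_m", "y_m", "floor_id"), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rejected
  df
}

#' @keywords internal
#' @noRd
empty_positions <- function() {
  data.frame(tag_id = character(), t_ms = numeric(), x_m = numeric(),
             y_m = numeric(), floor_id = character(),
             stringsAsFactors = FALSE)
}

#' Write position samples
#' @param positions data.frame as returned by [read_positions()].
#' @param path destination; `format` as in [read_positions()].
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(positions, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(positions))) {
      writeLines(jsonlite::toJSON(as.list(positions[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
  }
  invisible(path)
}

#' Construct a zone (geofence)
#'
#' @param zone_id unique identifier.
#' @param floor_id floor the polygon lives on.
#' @param role one of `triage1, triage2, treatment_red, treatment_yellow,
#'   treatment_green, transport, other`.
#' @param polygon numeric matrix (columns x,y, metres), at least 3 vertices,
#'   simple (non-self-intersecting).
#' @return object of class `mci_zone`.
#' @export
zone <- function(zone_id, floor_id, role, polygon) {
  role <- match.arg(role, ZONE_ROLES)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) {
    stop("zone '", zone_id, "': polygon needs >= 3 vertices", call. = FALSE)
  }
  if (!polygon_is_simple(polygon)) {
    stop("zone '", zone_id, "': polygon is self-intersecting", call. = FALSE)
  }
  structure(list(zone_id = as.character(zone_id),
                 floor_id = as.character(floor_id),
                 role = role,
                 polygon = unname(polygon[, 1:2, drop = FALSE])),
            class = "mci_zone")
}

#' Read zone geofences from JSON
#'
#' Schema: an array of objects `{"id": ..., "floor": ..., "role": ...,
#' "polygon": [[x, y], ...]}`.
#'
#' @param path JSON file.
#' @return list of `mci_zone` objects (class `mci_zones`).
#' @export
read_zones <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  zones <- lapply(raw, function(z) {
    poly <- if (is.matrix(z$polygon)) z$polygon
            else do.call(rbind, lapply(z$polygon, unlist))
    zone(z$id, z$floor, z$role, poly)
  })
  check_unique(vapply(zones, `[[`, "", "zone_id"), "zone_id")
  structure(zones, class = "mci_zones")
}

#' Write zones to JSON
#' @param zones `mci_zones` list.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zones, path) {
  out <- lapply(zones, function(z) {
    list(id = z$zone_id, floor = z$floor_id, role = z$role,
         polygon = lapply(seq_len(nrow(z$polygon)),
                          function(i) as.numeric(z$polygon[i, ])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the participant roster
#'
#' Columns: `code, group, specialist, experience_years, age_years, gender,
#' tag_id` (tag_id may be blank for untagged staff). `specialist` is only
#' meaningful for physicians and is stored `NA` otherwise.
#'
#' @param path CSV file.
#' @return data.frame of participants.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_cols(df, c("code", "group", "specialist", "experience_years",
                   "age_years", "gender"), "roster")
  check_unique(df$code, "roster code")
  bad <- !df$group %in% STAFF_GROUPS
  if (any(bad)) stop("roster: invalid group(s): ",
                     paste(unique(df$group[bad]), collapse = ", "),
                     call. = FALSE)
  df$specialist <- as.logical(df$specialist)
  df$specialist[df$group != "physician"] <- NA
  if (is.null(df$tag_id)) df$tag_id <- NA_character_
  df$tag_id <- as.character(df$tag_id)
  if (any(df$experience_years < 0, na.rm = TRUE)) {
    stop("roster: negative experience_years", call. = FALSE)
  }
  df
}

#' Read patient vignettes
#'
#' Columns: `patient_id, expected_category, features, tag_id`; `features` is
#' a `;`-separated list of flags (e.g. `peri_arrest;burn`).
#'
#' @param path CSV file.
#' @return data.frame of vignettes; `features` kept as the raw string,
#'   parse with [vignette_features()].
#' @export
read_vignettes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  check_cols(df, c("patient_id", "expected_category"), "vignettes")
  check_unique(df$patient_id, "patient_id")
  df$expected_category <- as.character(as_category(df$expected_category,
                                                   "expected_category"))
  if (is.null(df$features)) df$features <- ""
  df$features[is.na(df$features)] <- ""
  if (is.null(df$tag_id)) df$tag_id <- NA_character_
  df$tag_id <- as.character(df$tag_id)
  df
}

#' Split a vignette feature string into flags
#' @param features character vector of `;`-separated flags.
#' @return list of character vectors.
#' @export
vignette_features <- function(features) {
  lapply(strsplit(as.character(features), ";", fixed = TRUE),
         function(f) f[nzchar(f)])
}

#' Read triage assignment records
#'
#' Columns: `patient_id, stage, assigned_category, t_assign_ms`. At most one
#' record per (patient, stage).
#'
#' @param path CSV file.
#' @return data.frame of triage records.
#' @export
read_triage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("patient_id", "stage", "assigned_category"), "triage")
  if (!all(df$stage %in% c(1L, 2L))) {
    stop("triage: stage must be 1 or 2", call. = FALSE)
  }
  check_unique(paste(df$patient_id, df$stage), "(patient_id, stage) pair")
  df$assigned_category <- as.character(as_category(df$assigned_category,
                                                   "assigned_category"))
  if (is.null(df$t_assign_ms)) df$t_assign_ms <- NA_real_
  df
}

#' Read questionnaire response tables
#'
#' NASA-TLX: `code, mental, physical, temporal, performance, effort,
#' frustration` (each 1-20). TEAM: `code, item1..item11` (each 0-4) plus
#' `global` (1-10). Missing items stay `NA`; no imputation is ever applied.
#'
#' @param path CSV file.
#' @param instrument `"tlx"` or `"team"`.
#' @return data.frame of raw responses.
#' @export
read_questionnaires <- function(path, instrument = c("tlx", "team")) {
  instrument <- match.arg(instrument)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (instrument == "tlx") {
    check_cols(df, c("code", TLX_ITEMS), "tlx")
  } else {
    check_cols(df, c("code", paste0("item", 1:11), "global"), "team")
  }
  df
}

#' Merge roster and questionnaire responses by anonymized code
#'
#' Inner join on `code`; codes present on only one side are reported via the
#' `unmatched` attribute (a list with `roster_only` and `responses_only`),
#' never imputed.
#'
#' @param roster roster data.frame.
#' @param responses questionnaire data.frame with a `code` column.
#' @return merged data.frame with attribute `unmatched`.
#' @export
merge_by_code <- function(roster, responses) {
  check_cols(roster, "code", "roster"); check_cols(responses, "code", "responses")
  merged <- merge(roster, responses, by = "code", sort = TRUE)
  attr(merged, "unmatched") <- list(
    roster_only = setdiff(roster$code, responses$code),
    responses_only = setdiff(responses$code, roster$code))
  merged
}

#' Write a generic table as CSV (and optionally JSON)
#' @param df data.frame.
#' @param path destination CSV path.
#' @param json also write a `.json` sibling.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, json = FALSE) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (json) {
    jsonlite::write_json(df, sub("\\.csv$", ".json", path), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
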