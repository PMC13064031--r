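#' Round half away from zero
#'
#' Reported percentages and summary statistics use commercial rounding
#' (half-up), not the IEC 60559 half-to-even rule of [base::round()], so that
#' e.g. 2/69 prints as 2.9 and 76.85 as 76.9. Applied only at report time;
#' internal values stay exact.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Triage category helpers: urgency order I > II > III.
TRIAGE_LEVELS <- c("I", "II", "III")

#' @keywords internal
#' @noRd
as_category <- function(x, what = "category") {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% TRIAGE_LEVELS)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (must be one of I, II, III)",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  factor(x, levels = TRIAGE_LEVELS)
}

#' @keywords internal
#' @noRd
check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s: %s", what, paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @keywords internal
#' @noRd
check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
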