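# The statistical decision tree used throughout the reports: a joint
# normality gate (Shapiro-Wilk AND Lilliefors-corrected Kolmogorov-Smirnov,
# both at the 5% level) routes each comparison to a parametric test
# (t / Welch t / one-way ANOVA) or its rank-based counterpart
# (Mann-Whitney / Kruskal-Wallis). Effect sizes for two-group contrasts are
# Hedges' g (bias-corrected standardized mean difference) with a
# normal-approximation 95% confidence interval.

#' Significance stars
#'
#' `*`, `**`, `***`, `****` for p < 0.05, 0.01, 0.001, 0.0001; `ns`
#' otherwise.
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Joint normality gate
#'
#' A sample is treated as normal iff both the Shapiro-Wilk test and the
#' Kolmogorov-Smirnov test with Lilliefors adaptation have p >= 0.05.
#' Degenerate samples (constant values) and samples with n < 5 (below the
#' Lilliefors minimum) are non-normal by convention.
#'
#' @param x numeric sample (NAs dropped).
#' @return list `normal` (logical), `shapiro_p`, `lilliefors_p`, `n`.
#' @export
normality_gate <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5 || stats::sd(x) == 0) {
    return(list(normal = FALSE, shapiro_p = NA_real_,
                lilliefors_p = NA_real_, n = n))
  }
  sw <- stats::shapiro.test(x)$p.value
  lf <- nortest::lillie.test(x)$p.value
  list(normal = sw >= 0.05 && lf >= 0.05, shapiro_p = sw, lilliefors_p = lf,
       n = n)
}

#' @keywords internal
#' @noRd
new_test_result <- function(test_name, statistic, p_value, ns, note = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = ns,
                 stars = if (is.na(p_value)) "ns" else p_stars(p_value),
                 note = note),
            class = "mci_test")
}

#' @export
print.mci_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s (n = %s)\n", x$test_name,
              x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = "/")))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Two-group comparison with normality gate
#'
#' If both samples pass [normality_gate()], an F test on the variances
#' decides between the pooled two-sample t test (F test p >= 0.05) and
#' Welch's t test; otherwise the two-tailed Mann-Whitney test is used
#' (exact enumeration when both n <= 8 and there are no ties, tie-corrected
#' normal approximation otherwise). With a single observation in a group
#' the Mann-Whitney test is attempted directly.
#'
#' @param a,b numeric samples (NAs dropped).
#' @return `mci_test` object.
#' @export
compare_two <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be nonempty",
                                     call. = FALSE)
  ns <- c(length(a), length(b))
  if (min(ns) == 1) {
    r <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
    return(new_test_result("Mann-Whitney", r$statistic, r$p.value, ns,
                           note = "n = 1 in a group"))
  }
  if (all(a[1] == c(a, b))) {  # fully degenerate: no variation anywhere
    return(new_test_result("none", NA_real_, NA_real_, ns,
                           note = "degenerate: all values equal"))
  }
  if (normality_gate(a)$normal && normality_gate(b)$normal) {
    f <- stats::var.test(a, b)
    welch <- f$p.value < 0.05
    r <- stats::t.test(a, b, var.equal = !welch)
    return(new_test_result(if (welch) "Welch t" else "t", r$statistic,
                           r$p.value, ns))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- all(ns <= 8) && !ties
  r <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE))
  new_test_result("Mann-Whitney", r$statistic, r$p.value, ns)
}

#' k-group comparison with normality gate
#'
#' For three or more groups: one-way ANOVA when every group passes the
#' normality gate, the Kruskal-Wallis test otherwise. Fully degenerate
#' input (all values identical) is flagged rather than tested.
#'
#' @param groups named list of numeric samples (>= 3 groups).
#' @return `mci_test` object.
#' @export
compare_k <- function(groups) {
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (length(groups) < 3) stop("compare_k needs >= 3 groups", call. = FALSE)
  if (any(!vapply(groups, length, 0L))) stop("empty group", call. = FALSE)
  ns <- vapply(groups, length, 0L)
  vals <- unlist(groups, use.names = FALSE)
  if (all(vals == vals[1])) {
    return(new_test_result("none", NA_real_, NA_real_, ns,
                           note = "degenerate: all values equal"))
  }
  fac <- factor(rep(seq_along(groups), ns))
  if (all(vapply(groups, function(g) normality_gate(g)$normal, TRUE))) {
    fit <- stats::aov(vals ~ fac)
    tab <- summary(fit)[[1]]
    return(new_test_result("one-way ANOVA", tab[["F value"]][1],
                           tab[["Pr(>F)"]][1], ns))
  }
  r <- stats::kruskal.test(vals, fac)
  new_test_result("Kruskal-Wallis", r$statistic, r$p.value, ns)
}

#' Hedges' g with 95% confidence interval from summary statistics
#'
#' Bias-corrected standardized mean difference:
#' `s_p = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`,
#' `d = |m1 - m2| / s_p`, `J = 1 - 3 / (4 (n1+n2-2) - 1)`, `g = J d`.
#' The confidence interval uses the normal approximation
#' `SE = sqrt((n1+n2)/(n1 n2) + g^2 / (2 (n1+n2-2)))`, `g +- 1.96 SE`.
#' The absolute-difference convention makes g symmetric under group swap;
#' the direction is carried by the group labels, not the sign.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param labels optional character(2) group labels.
#' @return object of class `mci_effect`: list `g, ci_low, ci_high, se, n1,
#'   n2, labels`.
#' @export
hedges_g <- function(m1, sd1, n1, m2, sd2, n2, labels = c("group1", "group2")) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (sp == 0) stop("pooled SD is zero: effect size undefined", call. = FALSE)
  d <- abs(m1 - m2) / sp
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
  structure(list(g = g, ci_low = g - 1.96 * se, ci_high = g + 1.96 * se,
                 se = se, n1 = n1, n2 = n2, labels = labels),
            class = "mci_effect")
}

#' Hedges' g from two samples
#' @param a,b numeric samples (NAs dropped).
#' @inheritParams hedges_g
#' @return `mci_effect` object.
#' @export
hedges_g_samples <- function(a, b, labels = c("group1", "group2")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  hedges_g(mean(a), stats::sd(a), length(a), mean(b), stats::sd(b), length(b),
           labels = labels)
}

#' @export
print.mci_effect <- function(x, ...) {
  cat(sprintf("Hedges' g = %.2f, 95%% CI [%.2f, %.2f] (%s n = %d vs %s n = %d)\n",
              round_half_up(x$g, 2), round_half_up(x$ci_low, 2),
              round_half_up(x$ci_high, 2), x$labels[1], x$n1, x$labels[2],
              x$n2))
  invisible(x)
}
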