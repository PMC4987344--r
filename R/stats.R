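#' Describe a group-comparison design
#'
#' Collects the facts the test-selection policy needs: number of groups,
#' pairing, per-group sizes, and a variance-homogeneity indicator (Levene's
#' test at alpha = 0.05 on absolute deviations from the group medians).
#'
#' @param values numeric vector of observations.
#' @param groups factor/vector of group membership, same length.
#' @param paired logical; meaningful for two groups of equal size.
#' @return A `comparison_design`: list with `n_groups`, `paired`, `sizes`,
#'   `equal_variance`, `equal_sizes` and `levene_p`.
#' @export
comparison_design <- function(values, groups, paired = FALSE) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least two groups are required")
  sizes <- as.integer(table(g))
  lev <- tryCatch(car::leveneTest(values ~ g, center = stats::median),
                  error = function(e) NULL)
  lp <- if (is.null(lev)) NA_real_ else lev[["Pr(>F)"]][1]
  structure(list(n_groups = nlevels(g), paired = paired, sizes = sizes,
                 equal_variance = is.na(lp) || lp >= 0.05,
                 equal_sizes = length(unique(sizes)) == 1,
                 levene_p = lp),
            class = "comparison_design")
}

#' Select the statistical test for a comparison design
#'
#' Deterministic policy: for two groups with any sample size below 10, the
#' nonparametric Mann-Whitney U test (unpaired) or Wilcoxon signed-rank
#' test (paired); for two larger groups, Student's t-test (paired or
#' unpaired). For more than two groups: ANOVA with post-hoc Tukey when
#' variances are equal; Welch's ANOVA for unequal variances with equal
#' sizes; the Kruskal-Wallis test for unequal variances and unequal sizes.
#'
#' @param design a `comparison_design` (or a list with the same fields).
#' @return Test name: one of `"MWU"`, `"WSR"`, `"t-test"`,
#'   `"paired t-test"`, `"ANOVA-Tukey"`, `"ANOVA-Welch"`, `"KW"`.
#' @export
select_test <- function(design) {
  need <- c("n_groups", "paired", "sizes", "equal_variance", "equal_sizes")
  if (!all(need %in% names(design))) stop("incomplete design")
  if (design$n_groups < 2) stop("contradictory design: fewer than 2 groups")
  if (design$paired && design$n_groups != 2)
    stop("contradictory design: pairing requires exactly 2 groups")
  if (design$n_groups == 2) {
    if (min(design$sizes) < 10)
      return(if (design$paired) "WSR" else "MWU")
    return(if (design$paired) "paired t-test" else "t-test")
  }
  if (design$equal_variance) return("ANOVA-Tukey")
  if (design$equal_sizes) return("ANOVA-Welch")
  "KW"
}

#' Run a named statistical test
#'
#' Wraps the standard implementations (exact small-sample distributions
#' where available). Ties and zero-variance degeneracies are reported in
#' the result's `note`, never silently dropped.
#'
#' @param name test name as returned by [select_test()], plus `"ANOVA"`
#'   and `"Pearson"`.
#' @param data for two-group tests a list with `x` and `y`; for k-group
#'   tests a list with `values` and `groups`; for `"Pearson"` a list with
#'   `x` and `y` of equal length.
#' @param alternative sidedness, default two-sided.
#' @return A `test_result`: list with `test`, `statistic`, `p_value`,
#'   `summary` (per-group [summarize_group()] output), and `note`.
#' @export
run_test <- function(name, data, alternative = "two.sided") {
  note <- NULL
  res <- switch(
    name,
    "MWU" = {
      if (any(duplicated(c(data$x, data$y))))
        note <- "ties present; exact p-value unavailable"
      suppressWarnings(stats::wilcox.test(data$x, data$y, paired = FALSE,
                                          alternative = alternative))
    },
    "WSR" = {
      d <- data$x - data$y
      if (all(d == 0))
        return(test_result("WSR", NA_real_, 1,
                           list(x = summarize_group(data$x),
                                y = summarize_group(data$y)),
                           note = "all paired differences are zero"))
      if (any(d == 0)) note <- "zero differences present"
      if (any(duplicated(abs(d[d != 0]))))
        note <- paste(c(note, "tied differences"), collapse = "; ")
      suppressWarnings(stats::wilcox.test(data$x, data$y, paired = TRUE,
                                          alternative = alternative))
    },
    "t-test" = stats::t.test(data$x, data$y, alternative = alternative),
    "paired t-test" = stats::t.test(data$x, data$y, paired = TRUE,
                                    alternative = alternative),
    "ANOVA" = ,
    "ANOVA-Tukey" = {
      g <- factor(data$groups)
      fit <- stats::aov(data$values ~ g)
      sm <- summary(fit)[[1]]
      out <- list(statistic = sm[["F value"]][1],
                  p.value = sm[["Pr(>F)"]][1])
      if (name == "ANOVA-Tukey")
        out$tukey <- stats::TukeyHSD(fit)$g
      out
    },
    "ANOVA-Welch" = stats::oneway.test(data$values ~ factor(data$groups),
                                       var.equal = FALSE),
    "KW" = stats::kruskal.test(data$values, factor(data$groups)),
    "Pearson" = stats::cor.test(data$x, data$y, method = "pearson",
                                alternative = alternative),
    stop("unknown test '", name, "'")
  )
  grp_summary <- if (!is.null(data$values)) {
    lapply(split(data$values, factor(data$groups)), summarize_group)
  } else {
    lapply(Filter(Negate(is.null), list(x = data$x, y = data$y)),
           summarize_group)
  }
  stat <- if (!is.null(res$statistic)) unname(res$statistic[1]) else
    res$statistic
  tr <- test_result(name, stat, unname(res$p.value), grp_summary, note)
  if (name == "Pearson") tr$estimate <- unname(res$estimate)
  if (!is.null(res$tukey)) tr$tukey <- res$tukey
  tr
}

test_result <- function(test, statistic, p_value, summary, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 summary = summary, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %s, p = %s\n", x$test,
              format(x$statistic), format(x$p_value)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Summary statistics of one group
#'
#' Median and quartiles (linear-interpolation convention, R type 7), mean,
#' and standard error. The standard error of a single value is flagged
#' `NA`.
#'
#' @param values numeric vector, n >= 1.
#' @return list with `n`, `median`, `q1`, `q3`, `mean`, `se`.
#' @export
summarize_group <- function(values) {
  if (!length(values)) stop("empty group")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       mean = mean(values),
       se = if (length(values) > 1)
         stats::sd(values) / sqrt(length(values)) else NA_real_)
}
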