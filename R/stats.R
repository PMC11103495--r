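#' Relative values against the cohort maximum
#'
#' Divides each tissue-level mean (fluorescence or DTA) by the largest mean
#' in the set, so the maximum maps to 1 and everything else is a fraction of
#' it.
#'
#' @param means nonnegative values, at least one positive.
#' @return Values divided by their maximum.
#' @export
relative_values <- function(means) {
  if (any(means < 0)) stop("values must be nonnegative", call. = FALSE)
  m <- max(means)
  if (m <= 0) stop("all values are zero; relative values undefined",
                   call. = FALSE)
  means / m
}

#' Pearson correlation with significance and trend line
#'
#' Pearson's r with a two-sided p-value from the t-distribution on n - 2
#' degrees of freedom, plus the least-squares trend line for scatter export.
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param alpha significance level recorded in the result.
#' @return A list of class `stat_result`: `test`, `statistic` (r), `df`,
#'   `p_value`, `slope`, `intercept`, `n`, `alpha`, `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(test = "Pearson correlation",
                 statistic = unname(ct$estimate),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x), alpha = alpha,
                 significant = ct$p.value < alpha),
            class = "stat_result")
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' One-way ANOVA with Fisher's LSD post-hoc comparisons
#'
#' Omnibus one-way ANOVA (F from the between/within sums-of-squares
#' decomposition) followed by Fisher's least-significant-difference pairwise
#' t-tests: each pair is compared with the pooled within-group mean square
#' and its residual degrees of freedom, with no further multiplicity
#' adjustment (that is what LSD means). By default the pairwise tests are
#' run regardless of the omnibus result (unprotected LSD); `protected =
#' TRUE` runs them only when the omnibus F is significant at `alpha`.
#' Significance stars follow the \*p < 0.05, \*\*p < 0.01, \*\*\*p < 0.001,
#' \*\*\*\*p < 0.0001 convention.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with >= 2
#'   values), or a data frame with `value` and `group` columns.
#' @param alpha significance level.
#' @param protected gate pairwise tests on omnibus significance?
#' @return A list of class `stat_result`: `statistic` (F), `df`, `p_value`,
#'   `ms_error`, `ss` (between/within/total), `pairwise` (data frame of
#'   group pair, mean difference, SE, t, p, stars), `alpha`.
#' @export
anova_lsd <- function(groups, alpha = 0.05, protected = FALSE) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  all_v <- unlist(groups, use.names = FALSE)
  n <- length(all_v); k <- length(groups)
  gm <- vapply(groups, mean, 0)
  grand <- mean(all_v)
  ss_between <- sum(sizes * (gm - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  ss_total <- sum((all_v - grand)^2)
  df_b <- k - 1L; df_w <- n - k
  ms_b <- ss_between / df_b; ms_w <- ss_within / df_w
  f_stat <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / ms_w
  p <- if (is.infinite(f_stat)) 0 else stats::pf(f_stat, df_b, df_w,
                                                 lower.tail = FALSE)

  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   mean_diff = NA_real_, se = NA_real_, t = NA_real_,
                   p = NA_real_, stars = NA_character_,
                   stringsAsFactors = FALSE)
  run_pairs <- !protected || p < alpha
  if (run_pairs) {
    for (i in seq_len(ncol(pairs))) {
      a <- pairs[1, i]; b <- pairs[2, i]
      d <- gm[[a]] - gm[[b]]
      se <- sqrt(ms_w * (1 / sizes[[a]] + 1 / sizes[[b]]))
      tt <- if (se == 0) { if (d == 0) 0 else Inf * sign(d) } else d / se
      pp <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df_w)
      pw$mean_diff[i] <- d; pw$se[i] <- se; pw$t[i] <- tt; pw$p[i] <- pp
      pw$stars[i] <- significance_stars(pp)
    }
  }
  structure(list(test = if (protected) "one-way ANOVA + protected Fisher LSD"
                        else "one-way ANOVA + Fisher LSD",
                 statistic = f_stat, df = c(between = df_b, within = df_w),
                 p_value = p, ms_error = ms_w,
                 ss = c(between = ss_between, within = ss_within,
                        total = ss_total),
                 group_means = gm, group_n = sizes,
                 pairwise = pw, alpha = alpha,
                 significant = p < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  if (startsWith(x$test, "one-way ANOVA")) {
    cat(sprintf("<stat_result> %s: F(%d, %d) = %.4g, p = %.4g\n", x$test,
                x$df[["between"]], x$df[["within"]], x$statistic, x$p_value))
    if (!all(is.na(x$pairwise$p))) {
      cat("  pairwise (LSD):\n")
      for (i in seq_len(nrow(x$pairwise)))
        cat(sprintf("    %s vs %s: diff %.4g, p = %.4g %s\n",
                    x$pairwise$group1[i], x$pairwise$group2[i],
                    x$pairwise$mean_diff[i], x$pairwise$p[i],
                    x$pairwise$stars[i]))
    }
  } else {
    cat(sprintf("<stat_result> %s: r = %.4f (n = %d), p = %.4g\n", x$test,
                x$statistic, x$n, x$p_value))
  }
  invisible(x)
}

#' Cohort summary with quartiles and Tukey whiskers
#'
#' @param values numeric vector.
#' @param label group label.
#' @return A list of class `cohort_summary`: `label`, `n`, `mean`,
#'   `median`, `q25`, `q75`, and Tukey whisker positions (the most extreme
#'   values within 1.5 IQR of the quartiles).
#' @export
cohort_summary <- function(values, label = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values", call. = FALSE)
  qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo <- min(values[values >= qs[1] - 1.5 * iqr])
  hi <- max(values[values <= qs[3] + 1.5 * iqr])
  structure(list(label = label, n = length(values), mean = mean(values),
                 median = qs[2], q25 = qs[1], q75 = qs[3],
                 whisker_low = lo, whisker_high = hi),
            class = "cohort_summary")
}
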