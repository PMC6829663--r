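#' Condition-level summary of per-cell values
#'
#' @param values numeric per-cell values.
#' @param label condition label.
#' @return object of class \code{condition_summary}: list(label, values,
#'   mean, sem, n).
#' @export
condition_summary <- function(values, label = "condition") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one finite value", call. = FALSE)
  structure(list(label = label, values = values, mean = mean(values),
                 sem = stats::sd(values) / sqrt(n), n = n),
            class = "condition_summary")
}

#' Compare two conditions with a Student's t test
#'
#' Two-tailed paired or unpaired t test between per-cell values, plus the
#' percent change of means, (mean_a - mean_b) / mean_a x 100, with its
#' SEM propagated from the group SEMs.
#'
#' @param a,b \code{\link{condition_summary}} objects (or numeric vectors).
#' @param design "unpaired" (default) or "paired".
#' @return list(t, df, p, mean_a, mean_b, percent_change,
#'   percent_change_sem, significant) — significance at the 0.05 level.
#' @export
compare_conditions <- function(a, b, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  if (!inherits(a, "condition_summary")) a <- condition_summary(a, "a")
  if (!inherits(b, "condition_summary")) b <- condition_summary(b, "b")
  if (a$n < 2L || b$n < 2L) stop("need n >= 2 per group", call. = FALSE)
  tt <- tryCatch(
    stats::t.test(a$values, b$values, paired = design == "paired",
                  var.equal = design == "unpaired"),
    error = function(e) {
      # degenerate data (zero-variance groups or differences): identical
      # means are trivially non-significant, distinct constant means are
      # trivially significant
      if (!grepl("constant", conditionMessage(e))) stop(e)
      df <- if (design == "paired") a$n - 1 else a$n + b$n - 2
      if (a$mean == b$mean)
        list(statistic = c(t = 0), parameter = c(df = df), p.value = 1)
      else
        list(statistic = c(t = sign(a$mean - b$mean) * Inf),
             parameter = c(df = df), p.value = 0)
    })
  pc <- (a$mean - b$mean) / a$mean * 100
  pc_sem <- sqrt(a$sem^2 + b$sem^2) / abs(a$mean) * 100
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = a$mean, mean_b = b$mean,
       percent_change = pc, percent_change_sem = pc_sem,
       significant = tt$p.value < 0.05)
}

#' Ordinary least-squares linear trend
#'
#' @param x covariate (e.g. expression level).
#' @param y response.
#' @return list(slope, intercept, r_squared, p_slope) with the two-sided
#'   p value for a nonzero slope.
#' @export
fit_linear_trend <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_slope = p)
}

#' Two-way ANOVA with Tukey's post hoc test
#'
#' Thin wrapper around \code{aov} + \code{TukeyHSD} for multi-group
#' comparisons (two crossed factors); no bespoke implementation.
#'
#' @param value numeric response.
#' @param f1,f2 factors.
#' @return list(anova = the aov summary table, tukey = TukeyHSD result).
#' @export
anova_tukey <- function(value, f1, f2) {
  d <- data.frame(value = value, f1 = factor(f1), f2 = factor(f2))
  fit <- stats::aov(value ~ f1 * f2, data = d)
  list(anova = summary(fit), tukey = stats::TukeyHSD(fit))
}
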