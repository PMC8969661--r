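## Cohort-arm statistics: Livak relative quantification, normality-gated
## two-group comparison, Pearson correlation, and the sample-size critical
## correlation threshold.

#' Livak 2^-ddCt relative expression
#'
#' Relative quantification of a target gene against a reference gene using
#' the Livak method: per subject, \eqn{\Delta Ct = Ct_{target} -
#' Ct_{reference}}; the calibrator is the arithmetic mean \eqn{\Delta Ct}
#' of the control group; \eqn{\Delta\Delta Ct = \Delta Ct - calibrator};
#' fold change = \eqn{2^{-\Delta\Delta Ct}}. By construction the geometric
#' mean of control-group fold changes is 1.
#'
#' @param table Cohort data.frame with columns `subject_id`, `group`, and
#'   the two Ct columns.
#' @param gene Target gene name; its Ct column is `paste0("Ct_", gene)`
#'   unless `target_col` is given.
#' @param control_group Group label of the calibrator group (default
#'   `"control"`).
#' @param target_col,reference_col Ct column names (defaults `Ct_<gene>`
#'   and `Ct_ref`).
#' @return data.frame with one row per subject (subjects with missing Ct
#'   are dropped with a warning): `subject_id`, `group`, `dct`, `ddct`,
#'   `fold`, plus the calibrator as attribute `"calibrator"`.
#' @examples
#' tab <- data.frame(subject_id = c("c1", "c2", "a1"),
#'                   group = c("control", "control", "case"),
#'                   Ct_TJP1 = c(25, 26, 24.5), Ct_ref = c(20, 20, 20))
#' relative_expression_ddct(tab, "TJP1")  # case fold = 2
#' @export
relative_expression_ddct <- function(table, gene, control_group = "control",
                                     target_col = paste0("Ct_", gene),
                                     reference_col = "Ct_ref") {
  for (col in c("subject_id", "group", target_col, reference_col))
    if (!col %in% names(table)) stop("cohort table lacks column '", col, "'")
  if (anyDuplicated(table$subject_id)) stop("duplicate subject ids")
  ok <- is.finite(table[[target_col]]) & is.finite(table[[reference_col]])
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) dropped for missing Ct values: ",
            paste(table$subject_id[!ok], collapse = ", "))
    table <- table[ok, , drop = FALSE]
  }
  dct <- table[[target_col]] - table[[reference_col]]
  ctrl <- table$group == control_group
  if (!any(ctrl)) stop("no subjects in control group '", control_group, "'")
  calibrator <- mean(dct[ctrl])
  ddct <- dct - calibrator
  out <- data.frame(subject_id = table$subject_id, group = table$group,
                    dct = dct, ddct = ddct, fold = 2^(-ddct),
                    stringsAsFactors = FALSE)
  attr(out, "calibrator") <- calibrator
  out
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality is assessed in each group at `alpha_normality`;
#' if both groups look normal the comparison uses a two-sample t-test
#' (Welch by default), otherwise the Mann-Whitney U test (exact when sample
#' sizes permit and there are no ties, normal approximation with continuity
#' correction otherwise). A constant group leaves the Shapiro-Wilk gate
#' undefined and falls through to Mann-Whitney with a warning. All p-values
#' are two-tailed.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 3.
#' @param alpha_normality Gate level for the Shapiro-Wilk test (default 0.05).
#' @param var_equal Use the pooled-variance Student t-test instead of Welch
#'   (default `FALSE`).
#' @return List of class `GatedTestResult`: `method` (`"t_test"` or
#'   `"mann_whitney"`), `statistic`, `p`, `shapiro_p` (length-2), and
#'   per-group summaries (`n`, `mean`, `median`).
#' @export
compare_groups <- function(values_a, values_b, alpha_normality = 0.05,
                           var_equal = FALSE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 non-missing values")
  sw <- function(x) {
    if (length(unique(x)) == 1) return(NA_real_)
    shapiro.test(x)$p.value
  }
  sw_p <- c(a = sw(values_a), b = sw(values_b))
  if (anyNA(sw_p))
    warning("constant group: normality gate undefined, using Mann-Whitney")
  normal <- !anyNA(sw_p) && all(sw_p >= alpha_normality)
  if (normal) {
    ht <- t.test(values_a, values_b, var.equal = var_equal)
    method <- "t_test"
  } else {
    ht <- suppressWarnings(wilcox.test(values_a, values_b, correct = TRUE))
    method <- "mann_whitney"
  }
  structure(list(method = method,
                 statistic = unname(ht$statistic),
                 p = ht$p.value,
                 shapiro_p = sw_p,
                 group_a = list(n = length(values_a), mean = mean(values_a),
                                median = median(values_a)),
                 group_b = list(n = length(values_b), mean = mean(values_b),
                                median = median(values_b))),
            class = "GatedTestResult")
}

#' @export
print.GatedTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-tailed p = %.4g\n",
              x$method, x$statistic, x$p))
  cat(sprintf("Shapiro-Wilk p: group a %.3g, group b %.3g\n",
              x$shapiro_p[1], x$shapiro_p[2]))
  invisible(x)
}

#' Pearson correlation with two-tailed p-value
#'
#' Sample Pearson r with the usual two-tailed p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against a Student-t distribution with
#' n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return List of class `CorrelationStat`: `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "CorrelationStat")
}

#' @export
print.CorrelationStat <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, two-tailed p = %.4g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Critical Pearson correlation for a given sample size
#'
#' The smallest |r| that reaches two-tailed significance `alpha` at sample
#' size `n`: \eqn{r^* = t^*/\sqrt{t^{*2} + (n-2)}} with \eqn{t^*} the
#' two-tailed Student-t critical value on n - 2 degrees of freedom.
#' Monotonically decreasing in `n`. For n = 6 at alpha = 0.05 this gives
#' 0.811; for n = 12, 0.576.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-tailed significance level in (0, 1), default 0.05.
#' @return Threshold in (0, 1).
#' @examples
#' critical_r(6)   # 0.8114
#' critical_r(12)  # 0.5760
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("n must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n - 2
  tstar <- qt(1 - alpha / 2, df)
  tstar / sqrt(tstar^2 + df)
}

#' Percentages of a count vector
#'
#' Convenience for descriptive proportions (e.g. allergen-sensitization
#' breakdowns): each count as a percentage of the total.
#'
#' @param counts Non-negative numeric vector (optionally named).
#' @return Numeric vector of percentages summing to 100.
#' @examples
#' percent_of_total(c(mono = 3, dual = 7, triple = 20))
#' @export
percent_of_total <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  100 * counts / total
}
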