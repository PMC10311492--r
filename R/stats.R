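new_stat_result <- function(variable, groups, test_name, statistic, df, p_value, trace) {
  stopifnot(length(trace) >= 1)
  structure(list(variable = variable, groups = groups, test_name = test_name,
                 statistic = unname(statistic), df = unname(df),
                 p_value = min(1, max(0, p_value)), selection_trace = trace),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s, statistic %.4g%s, p = %.4g\n", x$variable, x$test_name,
              x$statistic, if (!is.na(x$df)) sprintf(" (df %.4g)", x$df) else "",
              x$p_value))
  for (tr in x$selection_trace)
    cat(sprintf("  - %s: %s -> %s\n", tr$check, format(tr$value), tr$decision))
  invisible(x)
}

trace_entry <- function(check, value, decision)
  list(check = check, value = value, decision = decision)

shapiro_p <- function(x) {
  if (length(unique(x)) == 1L) return(NA_real_)  # Shapiro-Wilk undefined for constants
  shapiro.test(x)$p.value
}

#' Compare a quantitative variable between two groups
#'
#' The normality- and variance-driven decision tree used in cohort
#' comparisons: Shapiro-Wilk on each sample (both p > alpha means normal),
#' then Levene's test (mean-centered) to choose the pooled versus Welch
#' two-sample t-test; non-normal data go to the Mann-Whitney U test
#' (exact when both n <= 10 without ties, otherwise the continuity- and
#' tie-corrected normal approximation). Constant samples, for which
#' Shapiro-Wilk is undefined, are routed to Mann-Whitney with a trace note.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha gate level for the normality and variance checks (0.05).
#' @param variable label carried into the result.
#' @return A \code{stat_result} with the full \code{selection_trace}.
#' @export
compare_quantitative <- function(x, y, alpha = 0.05, variable = "x") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) stop("each sample needs n >= 3")
  trace <- list()
  px <- shapiro_p(x); py <- shapiro_p(y)
  trace[[1]] <- trace_entry("shapiro_x", px,
                            if (is.na(px)) "constant sample: normality undefined"
                            else if (px > alpha) "normal" else "non-normal")
  trace[[2]] <- trace_entry("shapiro_y", py,
                            if (is.na(py)) "constant sample: normality undefined"
                            else if (py > alpha) "normal" else "non-normal")
  normal <- !is.na(px) && !is.na(py) && px > alpha && py > alpha
  if (normal) {
    lev <- levene_test(x, y)
    equal <- lev$p.value > alpha
    trace[[3]] <- trace_entry("levene", lev$p.value,
                              if (equal) "equal variances: pooled t" else "unequal variances: Welch t")
    tt <- t.test(x, y, var.equal = equal)
    new_stat_result(variable, c(length(x), length(y)),
                    if (equal) "pooled-t" else "welch-t",
                    tt$statistic, tt$parameter, tt$p.value, trace)
  } else {
    trace[[3]] <- trace_entry("branch", NA, "Mann-Whitney U")
    exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    new_stat_result(variable, c(length(x), length(y)), "mann-whitney",
                    wt$statistic, NA_real_, wt$p.value, trace)
  }
}

# Levene's test with mean-centered absolute deviations (classic form)
levene_test <- function(x, y) {
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  a <- stats::anova(stats::lm(z ~ g))
  list(statistic = a[1, "F value"], p.value = a[1, "Pr(>F)"])
}

#' Two-sample t-test from printed summary statistics
#'
#' Closed-form two-sided test from group means, SDs and sizes — the route
#' by which published table rows can be re-tested without raw data.
#'
#' @param m1,s1,n1,m2,s2,n2 group means, SDs, sizes.
#' @param variant "pooled" (df = n1 + n2 - 2) or "welch"
#'   (Welch-Satterthwaite df).
#' @param variable label carried into the result.
#' @return A \code{stat_result}.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("pooled", "welch"), variable = "summary") {
  variant <- match.arg(variant)
  if (s1 < 0 || s2 < 0) stop("standard deviations must be >= 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  trace <- list(trace_entry("variant", variant, "t from summary statistics"))
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      trace[[2]] <- trace_entry("degenerate", 0, "zero variance, equal means: p = 1")
      return(new_stat_result(variable, c(n1, n2), paste0(variant, "-t"),
                             0, n1 + n2 - 2, 1, trace))
    }
    stop("both SDs are zero with unequal means: t undefined")
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df)
  new_stat_result(variable, c(n1, n2), paste0(variant, "-t"), tstat, df, p, trace)
}

#' Compare a categorical variable between groups
#'
#' Pearson chi-square without continuity correction, unless more than 20%
#' of cells have expected frequency below 5, in which case Fisher's exact
#' test is used (two-sided: sum of probabilities of tables no more probable
#' than the observed, conditional on the margins).
#'
#' @param tab r x c contingency table of counts (>= 2 rows and columns,
#'   positive margins).
#' @param variable label carried into the result.
#' @return A \code{stat_result}.
#' @export
compare_categorical <- function(tab, variable = "table") {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) stop("zero margin in row ", which(rs == 0)[1])
  if (any(cs == 0)) stop("zero margin in column ", which(cs == 0)[1])
  expected <- outer(rs, cs) / sum(tab)
  frac_small <- mean(expected < 5)
  trace <- list(trace_entry("expected_cells_below_5", frac_small,
                            if (frac_small > 0.2) "Fisher exact" else "Pearson chi-square"))
  if (frac_small > 0.2) {
    ft <- fisher.test(tab, workspace = 2e6)
    new_stat_result(variable, dim(tab), "fisher-exact", NA_real_, NA_real_,
                    ft$p.value, trace)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    new_stat_result(variable, dim(tab), "chi-square", ct$statistic,
                    ct$parameter, ct$p.value, trace)
  }
}

#' Summarize a sample the way cohort tables report it
#'
#' Shapiro-Wilk gates the display mode: normal samples as mean and SD,
#' otherwise median and IQR (Q3 - Q1, linear-interpolation quantiles).
#'
#' @param x numeric sample (n >= 1).
#' @param alpha normality gate level.
#' @return An object of class \code{summary_cell} with \code{mode}
#'   ("mean_sd" or "median_iqr") and \code{values}.
#' @export
summarize_sample <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty sample")
  note <- NULL
  if (length(x) < 3) {
    mode <- "median_iqr"
    note <- "n < 3: normality not assessable, reporting median (IQR)"
  } else {
    p <- shapiro_p(x)
    if (is.na(p)) {
      mode <- "median_iqr"
      note <- "constant sample: normality undefined, reporting median (IQR)"
    } else mode <- if (p > alpha) "mean_sd" else "median_iqr"
  }
  values <- if (mode == "mean_sd") c(mean = mean(x), sd = sd(x))
            else c(median = median(x), iqr = unname(diff(quantile(x, c(0.25, 0.75)))))
  structure(list(mode = mode, values = values, n = length(x), note = note),
            class = "summary_cell")
}

#' @export
print.summary_cell <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.summary_cell <- function(x, digits = 3, ...) {
  v <- signif(x$values, digits)
  if (x$mode == "mean_sd") sprintf("%s ± %s", v[1], v[2])
  else sprintf("%s (%s)", v[1], v[2])
}

#' Cohort comparison report (demographics and fracture characteristics)
#'
#' Builds the two-group summary-and-test report: quantitative variables go
#' through \code{\link{compare_quantitative}} and are displayed per the
#' \code{\link{summarize_sample}} rule; categorical variables through
#' \code{\link{compare_categorical}}. Significance is flagged at
#' p < \code{alpha}.
#'
#' @param cohort data.frame with an \code{ao_class} column (both classes
#'   present) plus the variables to compare.
#' @param quantitative,categorical variable names; defaults cover the
#'   demographic and morphometric columns produced by the simulator.
#' @param alpha significance level (0.05).
#' @return data.frame of class \code{cohort_report}: one row per variable
#'   with group summary cells, test name, statistic, p-value and
#'   significance flag. Full \code{stat_result}s are in attribute
#'   \code{"results"}.
#' @export
cohort_report <- function(cohort,
                          quantitative = intersect(c("age", "height", "weight", "bmi",
                                                     "n_fragments", "n_comminuted",
                                                     "mean_comminuted_volume"),
                                                   names(cohort)),
                          categorical = intersect(c("sex", "side", "mechanism",
                                                    "has_comminution"),
                                                  names(cohort)),
                          alpha = 0.05) {
  if (!nrow(cohort)) stop("empty cohort")
  if (!"ao_class" %in% names(cohort)) stop("cohort needs an ao_class column")
  groups <- sort(unique(cohort$ao_class))
  if (length(groups) != 2)
    stop("cohort must contain both fracture classes, found: ",
         paste(groups, collapse = ", "))
  ga <- cohort[cohort$ao_class == groups[1], , drop = FALSE]
  gb <- cohort[cohort$ao_class == groups[2], , drop = FALSE]
  rows <- list(); results <- list()
  for (v in quantitative) {
    res <- compare_quantitative(ga[[v]], gb[[v]], alpha = alpha, variable = v)
    rows[[v]] <- data.frame(variable = v,
                            group1 = format(summarize_sample(ga[[v]], alpha)),
                            group2 = format(summarize_sample(gb[[v]], alpha)),
                            test = res$test_name,
                            statistic = res$statistic, p_value = res$p_value,
                            significant = res$p_value < alpha)
    results[[v]] <- res
  }
  for (v in categorical) {
    tab <- table(factor(cohort[[v]]), factor(cohort$ao_class, levels = groups))
    res <- compare_categorical(tab, variable = v)
    cellfmt <- function(g) paste(sprintf("%s:%d", rownames(tab), tab[, g]), collapse = " ")
    rows[[v]] <- data.frame(variable = v, group1 = cellfmt(groups[1]),
                            group2 = cellfmt(groups[2]), test = res$test_name,
                            statistic = res$statistic, p_value = res$p_value,
                            significant = res$p_value < alpha)
    results[[v]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[2:3] <- paste0(groups, " (n=", c(nrow(ga), nrow(gb)), ")")
  attr(out, "results") <- results
  attr(out, "alpha") <- alpha
  class(out) <- c("cohort_report", "data.frame")
  out
}
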