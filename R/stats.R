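#' Group summary: n, mean, SEM
#'
#' @param values Numeric vector of per-unit measurements.
#' @param label Group label.
#' @return One-row `data.frame` with `group`, `n`, `mean`, `sem`
#'   (sample SD / sqrt(n); `NA` for n = 1).
#' @export
group_summary <- function(values, label = "group") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("group '", label, "' has no finite values")
  data.frame(group = label, n = n, mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
             stringsAsFactors = FALSE)
}

as_group_stats <- function(g) {
  if (is.numeric(g)) {
    n <- length(g)
    if (n < 2) stop("each group needs at least 2 values")
    list(mean = mean(g), var = stats::var(g), n = n)
  } else if (is.list(g) && all(c("mean", "sem", "n") %in% names(g))) {
    if (g$n < 2) stop("each group needs n >= 2")
    # sem = sd/sqrt(n)  =>  var = n * sem^2
    list(mean = g$mean, var = g$n * g$sem^2, n = g$n)
  } else stop("group must be a numeric vector or list(mean, sem, n)")
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Accepts either raw measurement vectors or `(mean, sem, n)` summaries for
#' each group; both entry points give identical results because the t
#' statistic depends on the data only through these summaries. The Welch
#' variant (default) does not assume equal variances and uses Satterthwaite
#' degrees of freedom; the Student variant pools the variance.
#'
#' @param group_a,group_b Numeric vectors, or lists with elements `mean`,
#'   `sem`, `n`.
#' @param variant `"welch"` (default) or `"student"`.
#' @return List of class `test_result`: `test`, `statistic`, `df`,
#'   `p_two_sided`, `mean_difference`.
#' @export
two_sample_t <- function(group_a, group_b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as_group_stats(group_a)
  b <- as_group_stats(group_b)
  d <- a$mean - b$mean
  if (a$var == 0 && b$var == 0) {
    if (d == 0)
      return(structure(list(test = paste0(variant, "_t"), statistic = 0,
                            df = a$n + b$n - 2, p_two_sided = 1,
                            mean_difference = 0), class = "test_result"))
    stop("zero variance in both groups with unequal means")
  }
  if (variant == "welch") {
    se2a <- a$var / a$n; se2b <- b$var / b$n
    stat <- d / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2)
    if (sp2 == 0) stop("zero pooled variance with unequal means")
    stat <- d / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  structure(list(test = paste0(variant, "_t"), statistic = stat, df = df,
                 p_two_sided = 2 * stats::pt(-abs(stat), df),
                 mean_difference = d),
            class = "test_result")
}

#' One-way ANOVA with Tukey's post-hoc test
#'
#' Omnibus F test across all groups followed by all-pairs Tukey HSD adjusted
#' p-values (the studentized-range adjustment needs the within-group spread,
#' so raw values are required). Unadjusted pairwise p-values computed from the
#' pooled mean square are included for reference; Tukey-adjusted p-values are
#' never smaller. Pairs involving `reference` can be filtered with the
#' `reference` argument, for designs where every condition is compared back to
#' a control group.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param reference Optional group name; the `pairwise` table is then
#'   restricted to comparisons against it.
#' @return List of class `test_result`: `test = "anova_tukey"`, `statistic`
#'   (F), `df` (numerator, denominator), `p_two_sided` (omnibus), `pairwise`
#'   (`data.frame` with `comparison`, `diff`, `p_adj`, `p_unadj`).
#' @export
anova_tukey <- function(groups, reference = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$group

  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  ns <- lengths(groups)
  cmp <- rownames(tuk)
  parts <- strsplit(cmp, "-", fixed = TRUE)
  p_unadj <- vapply(seq_along(cmp), function(i) {
    g1 <- parts[[i]][1]; g2 <- parts[[i]][2]
    se <- sqrt(mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    2 * stats::pt(-abs(tuk[i, "diff"] / se), dfe)
  }, numeric(1))
  pw <- data.frame(comparison = cmp, diff = unname(tuk[, "diff"]),
                   p_adj = unname(tuk[, "p adj"]), p_unadj = p_unadj,
                   stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% names(groups)) stop("unknown reference group")
    keep <- vapply(parts, function(p) reference %in% p, logical(1))
    pw <- pw[keep, , drop = FALSE]
  }
  rownames(pw) <- NULL
  structure(list(test = "anova_tukey",
                 statistic = an["group", "F value"],
                 df = c(an["group", "Df"], dfe),
                 p_two_sided = an["group", "Pr(>F)"],
                 pairwise = pw),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_two_sided))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey-adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}
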