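#' Test of equal proportions
#'
#' Chi-square test of homogeneity of success proportions across groups, the
#' classic `prop.test`. By default Yates' continuity correction is applied
#' only for the two-group case.
#'
#' @param successes Integer vector of success counts, one per group.
#' @param totals Integer vector of trial counts, one per group.
#' @param correct Apply the continuity correction; default: only when there
#'   are exactly two groups.
#' @return A list with `statistic`, `df`, `p_value` and `proportions`.
#' @export
equal_proportions_test <- function(successes, totals, correct = NULL) {
  stopifnot(length(successes) == length(totals), length(totals) >= 2)
  if (any(totals <= 0)) stop("all group totals must be positive")
  if (any(successes < 0 | successes > totals))
    stop("successes must lie in [0, totals]")
  if (is.null(correct)) correct <- length(totals) == 2
  res <- suppressWarnings(
    stats::prop.test(successes, totals, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, proportions = unname(res$estimate))
}

#' Dunn-Sidak correction for multiple comparisons
#'
#' Adjusts a p-value for `m` independent comparisons:
#' `p_adj = 1 - (1 - p)^m`, clipped to 1.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param m Number of comparisons in the family (>= 1); recycled against
#'   `p`.
#' @return Adjusted p-values.
#' @examples
#' dunn_sidak(0.01, 3)  # 0.029701
#' @export
dunn_sidak <- function(p, m) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (length(m) < 1 || anyNA(m) || any(m < 1 | m != round(m)))
    stop("m must be integer(s) >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Kruskal-Wallis omnibus test with Dunn's post-test against a control
#'
#' Runs the rank-based Kruskal-Wallis one-way analysis of variance across
#' all groups (via [stats::kruskal.test()]), then Dunn's z post-test
#' comparing each non-control group to the designated control, using the
#' tie-corrected pooled-rank variance. Post-test p-values are adjusted for
#' the family of control comparisons with the Dunn-Sidak correction by
#' default (Bonferroni available).
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, parallel to `values`.
#' @param control Label of the control group; default the first level.
#' @param adjust `"sidak"` (default), `"bonferroni"` or `"none"`.
#' @return A list with `omnibus` (`statistic`, `df`, `p_value`) and
#'   `comparisons`, a data frame of Dunn z statistics with raw and adjusted
#'   p-values for each group vs the control.
#' @export
kruskal_wallis_dunn <- function(values, groups, control = NULL,
                                adjust = c("sidak", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(values) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (is.null(control)) control <- levels(groups)[1]
  if (!control %in% levels(groups)) stop("control group not found")

  kw <- stats::kruskal.test(values, groups)
  omnibus <- list(statistic = unname(kw$statistic),
                  df = unname(kw$parameter),
                  p_value = kw$p.value)

  n <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, groups, mean)
  sizes <- tabulate(groups)
  names(sizes) <- levels(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  others <- setdiff(levels(groups), control)
  m <- length(others)
  comparisons <- do.call(rbind, lapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[g]] + 1 / sizes[[control]]))
    z <- (mean_ranks[[g]] - mean_ranks[[control]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group = g, control = control, z = z, p_value = p)
  }))
  comparisons$p_adjusted <- switch(
    adjust,
    sidak = dunn_sidak(comparisons$p_value, m),
    bonferroni = pmin(1, comparisons$p_value * m),
    none = comparisons$p_value
  )
  list(omnibus = omnibus, comparisons = comparisons)
}

#' Rank and linear correlation between two measures
#'
#' Returns Spearman's rank-order correlation and the Pearson linear
#' correlation together with the R-squared of the linear fit, so both the
#' monotone and the linear association are always reported side by side.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `spearman_rho`, `spearman_p`, `pearson_r`,
#'   `pearson_p` and `r_squared`. If either input has zero variance all
#'   coefficients are `NA` and a warning is raised.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in x or y; correlation undefined")
    return(list(spearman_rho = NA_real_, spearman_p = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_,
                r_squared = NA_real_))
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       r_squared = unname(pe$estimate)^2)
}
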