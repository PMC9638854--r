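# Supporting statistics for region comparisons: rank-based tests on fit
# parameters and the estimation-plot mean difference. These delegate to the
# standard R routines; all tests are two-sided.

as_groups <- function(groups, min_n = 1L, min_groups = 2L) {
  stopifnot(is.list(groups), length(groups) >= min_groups)
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  if (any(vapply(groups, length, 1L) < min_n)) {
    stop(sprintf("each group needs at least %d values", min_n), call. = FALSE)
  }
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value. When every value is
#' identical the test is degenerate; `H = 0`, `p = 1` is returned with a
#' warning.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 3).
#' @return List: `statistic` (H), `p_value`, `df`, `n`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_groups(groups, min_n = 3L)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L) {
    warning("all values identical; Kruskal-Wallis is degenerate", call. = FALSE)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                n = length(x), method = "Kruskal-Wallis"))
  }
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(x), method = "Kruskal-Wallis")
}

#' Mann-Whitney (Wilcoxon rank-sum) test, two-sided
#'
#' Exact on small tie-free samples, normal approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List: `statistic` (U), `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  g <- as_groups(list(group_a, group_b), min_n = 1L)
  wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]],
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "Mann-Whitney")
}

#' Welch two-sample t test, two-sided
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @return List: `statistic`, `p_value`, `df`, `method`.
#' @export
welch_t <- function(group_a, group_b) {
  g <- as_groups(list(group_a, group_b), min_n = 2L)
  tt <- stats::t.test(g[[1]], g[[2]], var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = "Welch t")
}

#' Paired t test, two-sided
#'
#' Groups are aligned by position (same disc). Constant differences have no
#' variance and are rejected as degenerate.
#'
#' @param group_a,group_b Numeric vectors of equal length (n >= 2).
#' @return List: `statistic`, `p_value`, `df`, `method`.
#' @export
paired_t <- function(group_a, group_b) {
  stopifnot(length(group_a) == length(group_b))
  d <- as.numeric(group_a) - as.numeric(group_b)
  d <- d[is.finite(d)]
  if (length(d) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("paired differences are constant; variance undefined", call. = FALSE)
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = "paired t")
}

#' Estimation-plot statistic: unpaired mean difference with Welch 95% CI
#'
#' Returns `mean(group_b) - mean(group_a)` with its Welch-Satterthwaite
#' confidence interval, the quantity plotted on the difference axis of an
#' estimation plot. Two zero-variance groups give a CI of width zero.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `difference`, `ci_lower`, `ci_upper`, `conf_level`,
#'   `mean_a`, `mean_b`.
#' @export
estimation_difference <- function(group_a, group_b, conf_level = 0.95) {
  g <- as_groups(list(group_a, group_b), min_n = 2L)
  a <- g[[1]]; b <- g[[2]]
  diff <- mean(b) - mean(a)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(difference = diff, ci_lower = diff, ci_upper = diff,
                conf_level = conf_level, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(b, a, var.equal = FALSE, conf.level = conf_level)
  list(difference = diff, ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
       conf_level = conf_level, mean_a = mean(a), mean_b = mean(b))
}

#' Compare a fitted parameter between regions across discs
#'
#' Pulls one parameter (`t_half`, `hill` or `max_eta`) from a
#' [fit_cohort()] table, aligns the regions by disc, and runs the requested
#' test. Only converged per-disc fits enter the comparison.
#'
#' @param fits A [fit_cohort()] data frame.
#' @param regions Character vector of regions to compare (2 for
#'   `mann_whitney`/`welch_t`/`paired_t`/`estimation`; >= 2 for `kruskal`).
#' @param param One of `"t_half"`, `"hill"`, `"max_eta"`.
#' @param test One of `"kruskal"`, `"mann_whitney"`, `"welch_t"`,
#'   `"paired_t"`, `"estimation"`.
#' @return List with the test result plus `param`, `regions`, `n_per_group`
#'   and the group medians.
#' @export
compare_fits <- function(fits, regions, param = c("t_half", "hill", "max_eta"),
                         test = c("kruskal", "mann_whitney", "welch_t",
                                  "paired_t", "estimation")) {
  param <- match.arg(param)
  test <- match.arg(test)
  col <- switch(param, t_half = "t_half_min", hill = "hill", max_eta = "max_eta")
  use <- fits[fits$level == "disc" & fits$converged & fits$region %in% regions, ]
  if (test == "paired_t") {
    wide <- stats::reshape(use[, c("disc_id", "region", col)],
                           idvar = "disc_id", timevar = "region",
                           direction = "wide")
    vals <- lapply(regions, function(r) wide[[paste0(col, ".", r)]])
    vals <- lapply(vals, function(v) v[stats::complete.cases(do.call(cbind, vals))])
  } else {
    vals <- lapply(regions, function(r) use[[col]][use$region == r])
  }
  names(vals) <- regions
  res <- switch(test,
    kruskal = kruskal_wallis(vals),
    mann_whitney = mann_whitney(vals[[1]], vals[[2]]),
    welch_t = welch_t(vals[[1]], vals[[2]]),
    paired_t = paired_t(vals[[1]], vals[[2]]),
    estimation = estimation_difference(vals[[1]], vals[[2]]))
  c(res, list(param = param, regions = regions,
              n_per_group = vapply(vals, length, 1L),
              medians = vapply(vals, stats::median, 1)))
}
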