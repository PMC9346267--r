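#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation — i.e.
#' `cor.test(..., method = "spearman", exact = FALSE)`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE, alternative = "two.sided")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Compare group locations (Kruskal-Wallis or one-way ANOVA)
#'
#' @param groups List of numeric vectors (one per group, each n >= 2), or a
#'   data frame with `value` and `group` columns.
#' @param method `"kruskal"` (rank-based H test with tie correction,
#'   chi-square p) or `"anova"` (classical one-way F test, equal variances).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
group_location_test <- function(groups, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (method == "kruskal") {
    ht <- kruskal.test(values, g)
    tibble(
      method = "kruskal", statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value
    )
  } else {
    ht <- oneway.test(values ~ g, var.equal = TRUE)
    tibble(
      method = "anova", statistic = unname(ht$statistic),
      df = unname(ht$parameter[1]), p_value = ht$p.value
    )
  }
}
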