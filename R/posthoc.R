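#' Tukey HSD all-pairs comparison
#'
#' Studentized-range adjusted p-values for all group pairs, using the pooled
#' within-group mean square; unequal group sizes are handled by the
#' Tukey-Kramer standard error. Built on `stats::aov()`/`stats::TukeyHSD()`.
#' With zero pooled variance the p-value is 1 when all group means are equal
#' and 0 (with a warning) otherwise.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return Data.frame with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of group2 minus group1), `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(values) - k < 1) stop("pooled within-group df must be >= 1", call. = FALSE)
  means <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  pairs <- utils::combn(levels(groups), 2)
  if (ssw <= 0) {
    d <- means[pairs[2, ]] - means[pairs[1, ]]
    p <- ifelse(abs(d) <= 1e-12 * max(1, max(abs(means))), 1, 0)
    if (any(p == 0))
      warning("zero pooled variance with unequal means; reporting p = 0",
              call. = FALSE)
    return(data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      diff = unname(d), p_adj = unname(p),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(values = values, groups = groups)
  tk <- stats::TukeyHSD(stats::aov(values ~ groups, data = df))$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(nm, `[`, "", 2),
             group2 = vapply(nm, `[`, "", 1),
             diff = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t statistic with Welch-Satterthwaite degrees of freedom
#' (via `stats::t.test`). When both groups have zero variance and equal
#' means the statistic is defined as 0 with p = 1.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return A list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("t-test failed on degenerate input with unequal means", call. = FALSE)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_a = mean(a), mean_b = mean(b))
}
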