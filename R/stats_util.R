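#' One-way analysis of variance
#'
#' Classical pooled-variance one-way ANOVA over labelled groups.  When both
#' the between- and within-group sums of squares are zero (all values
#' identical) the F statistic is defined as 0 with p = 1.
#'
#' @param groups a named list of numeric vectors, one per group.
#' @return list with `f_statistic`, `df_num`, `df_den`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 nonempty groups")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(v) <= length(groups)) stop("total n must exceed the group count")
  df1 <- length(groups) - 1L
  df2 <- length(v) - length(groups)
  if (var(v) == 0)
    return(list(f_statistic = 0, df_num = df1, df_den = df2, p_value = 1))
  fit <- anova(lm(v ~ g))
  list(f_statistic = fit[["F value"]][1], df_num = df1, df_den = df2,
       p_value = fit[["Pr(>F)"]][1])
}

#' Tukey's honestly-significant-difference test
#'
#' Pairwise group comparisons based on the studentized range distribution
#' at the pooled within-group variance, as the post-hoc companion to
#' [one_way_anova()].
#'
#' @param groups a named list of numeric vectors.
#' @return data.frame with columns `group_1`, `group_2`, `diff`,
#'   `p_adjusted`.
#' @export
tukey_hsd <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 nonempty groups")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (var(v) == 0) {
    cmb <- utils::combn(levels(g), 2)
    return(data.frame(group_1 = cmb[1, ], group_2 = cmb[2, ],
                      diff = 0, p_adjusted = 1))
  }
  tk <- TukeyHSD(aov(v ~ g))$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_1 = vapply(nm, `[`, "", 1L),
             group_2 = vapply(nm, `[`, "", 2L),
             diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
             row.names = NULL)
}

#' Pearson correlation with t-test
#'
#' @param x,y numeric vectors of equal length (n >= 3), nonzero variance.
#' @return list with `r`, `t`, `df` (= n - 2), `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need n >= 3 paired values")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), in input order.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Simple linear regression with slope F-test
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list with `slope`, `intercept`, `f_statistic`, `df_num`,
#'   `df_den` (= n - 2), `p_value`, `r_squared`.
#' @export
ols_f <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need n >= 3 points")
  if (var(x) == 0) stop("degenerate design: x has zero variance")
  fit <- lm(y ~ x)
  # summary.lm warns on zero-residual fits; exact lines are a designed input
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       f_statistic = unname(fs[1]), df_num = unname(fs[2]),
       df_den = unname(fs[3]),
       p_value = pf(fs[1], fs[2], fs[3], lower.tail = FALSE)[[1]],
       r_squared = sm$r.squared)
}

#' ANCOVA slope-interaction test
#'
#' Fits `y ~ x * group` over two groups and returns the F-test of the
#' slope-by-group interaction term.
#'
#' @param xA,yA,xB,yB numeric vectors for groups A and B.
#' @return list with `f_statistic`, `df_num`, `df_den`, `p_value`.
#' @export
ancova_interaction <- function(xA, yA, xB, yB) {
  if (var(xA) == 0 || var(xB) == 0)
    stop("degenerate design: zero x variance in a group")
  x <- c(xA, xB)
  y <- c(yA, yB)
  g <- factor(rep(c("A", "B"), c(length(xA), length(xB))))
  tab <- anova(lm(y ~ x * g))
  list(f_statistic = tab["x:g", "F value"],
       df_num = tab["x:g", "Df"], df_den = tab["Residuals", "Df"],
       p_value = tab["x:g", "Pr(>F)"])
}
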