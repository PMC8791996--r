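#' Reciprocal pathway pairs
#'
#' Collects every unordered area pair whose two directed pathways are both
#' observed, returning the (logit) ODR of the upper-matrix direction as `x`
#' and of the lower-matrix direction as `y`.  "Upper" and "lower" refer to
#' the triangular halves of the source-by-target ODR matrix under the
#' catalog's area order, matching the convention that makes the fitted
#' intercept reproducible.
#'
#' @param m an `odr_matrix` (see [build_odr_matrix()]).
#' @param subset `"all"` (default) or `"intra_stream"` (keep only pairs
#'   whose two areas share a stream label).
#' @param transform `"logit"` (default) or `"raw"`.
#' @param eps clipping bound passed to [logit()].
#' @return A data.frame with columns `area_i`, `area_j` (catalog order,
#'   i before j), `x`, `y`.
#' @export
pair_reciprocals <- function(m, subset = c("all", "intra_stream"),
                             transform = c("logit", "raw"), eps = 1e-3) {
  subset <- match.arg(subset)
  transform <- match.arg(transform)
  nm <- m$catalog$names
  tf <- if (transform == "logit") function(p) logit(p, eps) else identity
  out <- list()
  for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1L):length(nm)) {
    up <- m$values[nm[i], nm[j]]
    lo <- m$values[nm[j], nm[i]]
    if (is.na(up) || is.na(lo)) next
    if (subset == "intra_stream" &&
        m$catalog$streams[nm[i]] != m$catalog$streams[nm[j]]) next
    out[[length(out) + 1L]] <- data.frame(
      area_i = nm[i], area_j = nm[j], x = tf(up), y = tf(lo))
  }
  if (length(out) == 0L)
    return(data.frame(area_i = character(), area_j = character(),
                      x = numeric(), y = numeric()))
  do.call(rbind, out)
}

#' Reciprocity regression
#'
#' Ordinary least squares of the lower-matrix (logit) ODR on its reciprocal
#' upper-matrix value, with the F-test of a zero slope.  Under a
#' hierarchical organisation the slope is negative: the more feedforward a
#' pathway, the more feedback its reciprocal.  On noise-free data generated
#' from exact level differences the slope is exactly -1.
#'
#' @param pairs data.frame from [pair_reciprocals()].
#' @return A list of class `slope_fit`: `slope`, `intercept`, `f_statistic`,
#'   `df_num`, `df_den`, `p_value`, `n_pairs`, `n_pathways`.
#' @export
fit_reciprocity <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 reciprocal pairs")
  fit <- ols_f(pairs$x, pairs$y)
  structure(c(fit, list(n_pairs = nrow(pairs),
                        n_pathways = 2L * nrow(pairs))),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Reciprocity fit: slope = %.3f, F(%d, %d) = %.3f, p = %.4g (n = %d pairs, %d pathways)\n",
              x$slope, x$df_num, x$df_den, x$f_statistic, x$p_value,
              x$n_pairs, x$n_pathways))
  invisible(x)
}

#' Compare reciprocity slopes between two pathway subsets
#'
#' Analysis of covariance: fits `y ~ x * group` over the pooled pairs and
#' tests the slope-by-group interaction (used, e.g., to compare all
#' pathways against intra-stream pathways).
#'
#' @param pairsA,pairsB data.frames from [pair_reciprocals()].
#' @return list with `f_statistic`, `df_num`, `df_den`, `p_value`,
#'   `slope_A`, `slope_B`.
#' @export
compare_slopes <- function(pairsA, pairsB) {
  if (nrow(pairsA) < 3L || nrow(pairsB) < 3L)
    stop("need at least 3 pairs in each group")
  res <- ancova_interaction(pairsA$x, pairsA$y, pairsB$x, pairsB$y)
  res$slope_A <- ols_f(pairsA$x, pairsA$y)$slope
  res$slope_B <- ols_f(pairsB$x, pairsB$y)$slope
  res
}
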