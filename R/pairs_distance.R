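#' Logit ODRs of two areas toward their common third areas
#'
#' For injected areas `a` and `b`, collects one point per shared third
#' area: in `"targets"` mode, `x` is the logit ODR of `a -> t` and `y` of
#' `b -> t` over all targets `t` reached by both; in `"sources"` mode, `x`
#' is the logit ODR of `s -> a` and `y` of `s -> b` over all sources `s`
#' projecting to both.  Third areas with either pathway missing are
#' excluded.
#'
#' @param m an `odr_matrix`.
#' @param a,b distinct area ids.
#' @param mode `"targets"` (default) or `"sources"`.
#' @param eps clipping bound passed to [logit()].
#' @return A data.frame with columns `third`, `x`, `y` (possibly 0 rows).
#' @export
collect_common <- function(m, a, b, mode = c("targets", "sources"),
                           eps = 1e-3) {
  mode <- match.arg(mode)
  if (a == b) stop("a and b must be distinct")
  nm <- m$catalog$names
  if (!all(c(a, b) %in% nm)) stop("a and b must be catalog areas")
  thirds <- setdiff(nm, c(a, b))
  if (mode == "targets") {
    xa <- m$values[a, thirds]; xb <- m$values[b, thirds]
  } else {
    xa <- m$values[thirds, a]; xb <- m$values[thirds, b]
  }
  ok <- !is.na(xa) & !is.na(xb)
  data.frame(third = thirds[ok], x = logit(xa[ok], eps), y = logit(xb[ok], eps),
             row.names = NULL)
}

#' Intercept of the best-fitting unit-slope line
#'
#' Least squares with the slope fixed at 1: the intercept is the mean of
#' `y - x`.  When `x` and `y` are logit ODRs of two injected areas to
#' common targets, the expected logit ODRs are `h_t - h_a` and `h_t - h_b`,
#' so the intercept estimates the level difference `h_a - h_b` — a
#' model-free hierarchical distance (up to sign).
#'
#' @param points data.frame with columns `x`, `y` (see [collect_common()]).
#' @return The signed intercept.
#' @examples
#' unit_slope_intercept(data.frame(x = c(0, 2), y = c(1, 3)))  # 1
#' @export
unit_slope_intercept <- function(points) {
  if (nrow(points) == 0L) stop("no common points")
  mean(points$y - points$x)
}

#' Pairwise hierarchical distances from unit-slope intercepts
#'
#' Computes the unit-slope intercept for every unordered area pair with at
#' least `min_common` shared third areas; the absolute intercept is the
#' hierarchical distance.  In `"targets"` mode the signed intercept for the
#' ordered pair (a, b) estimates `h_a - h_b`; in `"sources"` mode it
#' estimates `h_b - h_a`.
#'
#' @param m an `odr_matrix` over at least 3 areas.
#' @param mode `"targets"` (default) or `"sources"`.
#' @param min_common minimum number of shared third areas required to
#'   report a pair (default 1).
#' @param eps clipping bound passed to [logit()].
#' @return A list of class `distance_matrix`: `intercepts` (antisymmetric
#'   area x area matrix; entry (a, b) is the intercept with `a` on the x
#'   axis), `distances` (symmetric `|intercept|`), `n_common`, `mode`.
#' @export
distance_matrix <- function(m, mode = c("targets", "sources"),
                            min_common = 1L, eps = 1e-3) {
  mode <- match.arg(mode)
  nm <- m$catalog$names
  if (length(nm) < 3L) stop("need at least 3 areas")
  k <- length(nm)
  inter <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  ncom <- matrix(0L, k, k, dimnames = list(nm, nm))
  diag(inter) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pts <- collect_common(m, nm[i], nm[j], mode, eps)
    ncom[i, j] <- ncom[j, i] <- nrow(pts)
    if (nrow(pts) < min_common) next
    b <- unit_slope_intercept(pts)
    inter[i, j] <- b      # x from area i, y from area j
    inter[j, i] <- -b
  }
  structure(list(intercepts = inter, distances = abs(inter),
                 n_common = ncom, mode = mode),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Unit-slope hierarchical distances (mode:", x$mode, ")\n")
  print(round(x$distances, 3))
  invisible(x)
}
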