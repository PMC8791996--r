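#' Fit an elliptical 2D Gaussian to a spatial response map
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `rate = baseline + amplitude * exp(-q(dx, dy))`, where `q` is the
#' quadratic form of an oriented ellipse with axes `sigma_x`, `sigma_y`
#' and orientation `theta`, over mean firing rates recorded at stimulus
#' positions in visual degrees.  Initialisation is deterministic: centre
#' at the peak-response position, sigmas from the second moments of the
#' baseline-subtracted rates, baseline at the 10th-percentile rate.
#'
#' @param map data.frame with columns `azimuth`, `elevation` (degrees) and
#'   `rate` (spikes/s); at least 6 distinct positions.
#' @param include_theta fit the orientation parameter (default `TRUE`).
#' @param include_baseline fit a baseline term (default `TRUE`).
#' @return list of class `gaussian_rf`: `amplitude`, `center` (deg),
#'   `sigma_x`, `sigma_y` (deg), `theta` (rad), `baseline`,
#'   `diameter_deg`, `converged`, `rss`.
#' @export
fit_gaussian_rf <- function(map, include_theta = TRUE,
                            include_baseline = TRUE) {
  need <- c("azimuth", "elevation", "rate")
  if (!all(need %in% names(map))) stop("map needs columns azimuth, elevation, rate")
  if (nrow(unique(map[c("azimuth", "elevation")])) < 6L)
    stop("need at least 6 distinct stimulus positions")
  if (any(map$rate < 0)) stop("rates must be nonnegative")
  if (var(map$rate) == 0) stop("constant response map: no response structure")
  x <- map$azimuth; y <- map$elevation; r <- map$rate
  b0 <- if (include_baseline) quantile(r, 0.10, names = FALSE) else 0
  w <- pmax(r - b0, 0)
  if (sum(w) == 0) stop("no above-baseline response")
  pk <- which.max(r)
  x0 <- x[pk]; y0 <- y[pk]
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sx0 <- sqrt(max(sum(w * (x - mx)^2) / sum(w), 1e-2))
  sy0 <- sqrt(max(sum(w * (y - my)^2) / sum(w), 1e-2))
  a0 <- max(r) - b0
  par0 <- c(baseline = b0, amplitude = a0, x0 = x0, y0 = y0,
            lsx = log(sx0), lsy = log(sy0), theta = 0)
  if (!include_theta) par0 <- par0[names(par0) != "theta"]
  if (!include_baseline) par0 <- par0[names(par0) != "baseline"]
  model <- function(p) {
    th <- if (include_theta) p[["theta"]] else 0
    bl <- if (include_baseline) p[["baseline"]] else 0
    sx <- exp(p[["lsx"]]); sy <- exp(p[["lsy"]])
    dx <- x - p[["x0"]]; dy <- y - p[["y0"]]
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    bl + p[["amplitude"]] * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  }
  # nls.lm warns at the iteration cap; convergence is reported via the flag
  nls <- suppressWarnings(
    minpack.lm::nls.lm(par = par0, fn = function(p) r - model(p),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, maxfev = 10000,
                         ftol = 1e-10, ptol = 1e-10)))
  p <- nls$par
  sx <- exp(p[["lsx"]]); sy <- exp(p[["lsy"]])
  converged <- nls$info %in% 1:4 && is.finite(sx) && is.finite(sy) &&
    sx > 1e-3 && sy > 1e-3 && sx < 1e3 && sy < 1e3
  structure(list(
    amplitude = p[["amplitude"]],
    center = c(azimuth = p[["x0"]], elevation = p[["y0"]]),
    sigma_x = sx, sigma_y = sy,
    theta = if (include_theta) p[["theta"]] %% pi else 0,
    baseline = if (include_baseline) p[["baseline"]] else 0,
    diameter_deg = 4 * sqrt(sx * sy),
    converged = converged, rss = sum(nls$fvec^2)),
    class = "gaussian_rf")
}

#' @export
print.gaussian_rf <- function(x, ...) {
  cat(sprintf("Gaussian RF: center (%.1f, %.1f) deg, sigma (%.2f, %.2f) deg, diameter %.2f deg%s\n",
              x$center[1], x$center[2], x$sigma_x, x$sigma_y, x$diameter_deg,
              if (!x$converged) " [fit flagged]" else ""))
  invisible(x)
}

#' Equal-area receptive-field diameter
#'
#' The 2-SD contour of the fitted Gaussian is an ellipse with semi-axes
#' `2 sigma_x` and `2 sigma_y`; transforming it into the circle of equal
#' area gives diameter `2 sqrt((2 sigma_x)(2 sigma_y)) =
#' 4 sqrt(sigma_x sigma_y)` degrees.  Invariant to orientation and to
#' swapping the axes.
#'
#' @param fit a `gaussian_rf` (or a list with `sigma_x`, `sigma_y`).
#' @return Diameter in degrees.
#' @examples
#' rf_diameter(list(sigma_x = 5, sigma_y = 5))  # 20
#' @export
rf_diameter <- function(fit) 4 * sqrt(fit$sigma_x * fit$sigma_y)

#' Consistency of receptive-field sizes with the hierarchy
#'
#' Summarises per-unit RF diameters by area and tests whether they track
#' the fitted hierarchical levels: one-way ANOVA of diameter across areas
#' within each stream, all-pairs Tukey comparisons, and the Pearson
#' correlation of area-mean diameter with area level.
#'
#' @param levels named numeric vector of per-area hierarchical levels.
#' @param diameters data.frame with columns `area` and `diameter_deg`.
#' @param catalog optional [area_catalog()] supplying stream labels for
#'   the per-stream ANOVAs.
#' @return list with `per_area` (area, n, mean, sem, level),
#'   `anova_by_stream`, `tukey`, `pearson`.
#' @export
hierarchy_rf_consistency <- function(levels, diameters, catalog = NULL) {
  grp <- split(diameters$diameter_deg, diameters$area)
  grp <- grp[lengths(grp) >= 2L]
  if (length(grp) < 3L) stop("need at least 3 areas with >= 2 units each")
  per_area <- data.frame(
    area = names(grp), n = lengths(grp),
    mean = vapply(grp, mean, 0),
    sem = vapply(grp, function(v) sd(v) / sqrt(length(v)), 0),
    level = levels[names(grp)], row.names = NULL)
  anova_by_stream <- NULL
  if (!is.null(catalog)) {
    anova_by_stream <- lapply(c(dorsal = "dorsal", ventral = "ventral"),
      function(s) {
        in_s <- names(grp)[catalog$streams[names(grp)] %in% c(s, "root")]
        if (length(in_s) < 2L) return(NULL)
        one_way_anova(grp[in_s])
      })
  }
  list(per_area = per_area,
       anova_by_stream = anova_by_stream,
       tukey = tukey_hsd(grp),
       pearson = pearson(per_area$level, per_area$mean))
}
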