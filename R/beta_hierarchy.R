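#' Level partitions
#'
#' A level partition groups areas that are constrained to share one
#' hierarchical level; the incidence-design columns of the grouped areas
#' are summed.  `singleton_partition()` puts every area at its own level.
#'
#' @param groups list of character vectors of area ids; disjoint, jointly
#'   covering the catalog.
#' @param catalog an [area_catalog()].
#' @return A list of class `level_partition` with elements `groups` (each
#'   sorted by catalog order, groups ordered by their lowest member),
#'   `labels`, and `reference_group` (index of the group holding the
#'   reference area).
#' @export
level_partition <- function(groups, catalog) {
  groups <- lapply(groups, as.character)
  all_areas <- unlist(groups)
  if (anyDuplicated(all_areas) || !setequal(all_areas, catalog$names))
    stop("groups must be disjoint and cover the catalog exactly")
  groups <- lapply(groups, function(g) g[order(match(g, catalog$names))])
  groups <- groups[order(vapply(groups, function(g) match(g[1], catalog$names), 0L))]
  labels <- vapply(groups, paste, "", collapse = "/")
  ref <- which(vapply(groups, function(g) catalog$reference %in% g, TRUE))
  structure(list(groups = groups, labels = labels, reference_group = ref),
            class = "level_partition")
}

#' @rdname level_partition
#' @export
singleton_partition <- function(catalog) {
  level_partition(as.list(catalog$names), catalog)
}

partition_signature <- function(partition) {
  paste(partition$labels, collapse = "|")
}

#' Incidence design for a graph regression
#'
#' Builds the edge-by-group design matrix: one row per observed directed
#' pathway, +1 in the target's group column and -1 in the source's, with
#' the reference group's column dropped so its level is fixed at 0.
#' Within-group pathways yield all-zero rows (their expected ODR is 0.5;
#' they inform only the precision).
#'
#' @param m an `odr_matrix`.
#' @param partition a [level_partition()] (default: all singletons).
#' @return list of class `incidence_design`: `X` (rows x non-reference
#'   groups), `edges` (data.frame `source`, `target`, `odr`), `partition`,
#'   `catalog`.
#' @export
build_incidence <- function(m, partition = singleton_partition(m$catalog)) {
  nm <- m$catalog$names
  idx <- which(!is.na(m$values), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no observed pathways")
  edges <- data.frame(source = nm[idx[, 1]], target = nm[idx[, 2]],
                      odr = m$values[idx])
  group_of <- setNames(rep(seq_along(partition$groups),
                           lengths(partition$groups)),
                       unlist(partition$groups))
  keep <- setdiff(seq_along(partition$groups), partition$reference_group)
  X <- matrix(0, nrow(edges), length(keep),
              dimnames = list(NULL, partition$labels[keep]))
  col_of <- setNames(match(seq_along(partition$groups), keep),
                     seq_along(partition$groups))
  for (r in seq_len(nrow(edges))) {
    gs <- group_of[[edges$source[r]]]
    gt <- group_of[[edges$target[r]]]
    cs <- col_of[[as.character(gs)]]
    ct <- col_of[[as.character(gt)]]
    if (!is.na(ct)) X[r, ct] <- X[r, ct] + 1
    if (!is.na(cs)) X[r, cs] <- X[r, cs] - 1
  }
  structure(list(X = X, edges = edges, partition = partition,
                 catalog = m$catalog),
            class = "incidence_design")
}

#' Log-density of the beta distribution in mean/precision form
#'
#' The beta density reparameterised by its mean `mu = alpha / (alpha +
#' beta)` and precision `phi = alpha + beta`:
#' `f(x; mu, phi) = Gamma(phi) / (Gamma(mu phi) Gamma((1 - mu) phi)) *
#' x^(mu phi - 1) (1 - x)^((1 - mu) phi - 1)`.
#'
#' @param x value(s) in (0, 1).
#' @param mu mean in (0, 1).
#' @param phi precision > 0.
#' @return log density, finite for x in (0, 1).
#' @export
beta_log_density <- function(x, mu, phi) {
  if (any(x <= 0 | x >= 1)) stop("x must be in (0, 1)")
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0)) stop("need 0 < mu < 1, phi > 0")
  lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
    (mu * phi - 1) * log(x) + ((1 - mu) * phi - 1) * log1p(-x)
}

# Log-likelihood and analytic gradient in theta = (delta, log phi).
.beta_loglik <- function(theta, X, y) {
  p <- ncol(X)
  eta <- if (p > 0L) drop(X %*% theta[seq_len(p)]) else rep(0, length(y))
  mu <- plogis(eta)
  phi <- exp(theta[p + 1L])
  sum(beta_log_density(y, mu, phi))
}

.beta_grad <- function(theta, X, y) {
  p <- ncol(X)
  eta <- if (p > 0L) drop(X %*% theta[seq_len(p)]) else rep(0, length(y))
  mu <- plogis(eta)
  phi <- exp(theta[p + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gd <- if (p > 0L) drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
        else numeric(0)
  glp <- phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                   (1 - mu) * digamma((1 - mu) * phi) +
                   mu * log(y) + (1 - mu) * log1p(-y))
  c(gd, glp)
}

#' Maximum-likelihood beta regression on an incidence design
#'
#' The core hierarchy estimator.  Observed pathway ODRs `y_k` are modelled
#' as beta-distributed with common precision `phi` and mean
#' `mu_k = inv_logit(x_k' delta)`, so that the expected logit ODR of a
#' pathway equals the level difference between its target and source
#' groups (`logit(E ODR) = X delta`).  The reference group's level is
#' fixed at 0 by the dropped design column.  Optimisation is quasi-Newton
#' (L-BFGS-B) on `(delta, log phi)` with an analytic gradient,
#' deterministically initialised from the ordinary least squares of
#' `logit(y)` on the design and a method-of-moments precision.  `log phi`
#' is bounded above (default `log(1e8)`); a fit on noise-free data pushes
#' `phi` to that bound and is flagged.
#'
#' @param design an [build_incidence()] object.
#' @param eps clipping applied to the ODRs before the likelihood (beta
#'   support is open); default 1e-3.
#' @param init optional numeric start `(delta, log phi)`.
#' @param max_log_phi upper bound on `log phi`.
#' @param maxit iteration cap (default 500).
#' @param drop_within if `TRUE`, within-group pathways (all-zero rows) are
#'   dropped from the likelihood instead of retained with `mu = 0.5`.
#' @return An object of class `hierarchy_fit`: `delta` (named estimates per
#'   non-reference group), `levels` (per area, reference at 0 exactly),
#'   `phi`, `covariance` (over `(delta, phi)`), `se`, `log_likelihood`,
#'   `aic`, `n_obs`, `n_params`, `converged`, `phi_at_bound`, `partition`,
#'   `gof` (Pearson r of fitted level differences vs observed logit ODRs,
#'   with t and df), plus the per-edge fitted means.
#' @export
fit_beta_regression <- function(design, eps = 1e-3, init = NULL,
                                max_log_phi = log(1e8), maxit = 500L,
                                drop_within = FALSE) {
  X <- design$X
  y <- pmin(pmax(design$edges$odr, eps), 1 - eps)
  if (drop_within) {
    keep <- rowSums(abs(X)) > 0
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  p <- ncol(X)
  if (p > 0L) {
    qrX <- qr(X)
    if (qrX$rank < p)
      stop("singular design: the observed graph does not identify every ",
           "group level (disconnected component among groups: ",
           paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):p]], collapse = ", "), ")")
  }
  if (is.null(init)) {
    z <- logit(y, eps = 1e-6)
    d0 <- if (p > 0L) qr.coef(qr(X), z) else numeric(0)
    mu0 <- plogis(if (p > 0L) drop(X %*% d0) else rep(0, length(y)))
    s2 <- max(var(y - mu0), 1e-8)
    phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 1)
    init <- c(d0, min(log(phi0), max_log_phi))
  }
  run <- function(start, factr) {
    optim(start, fn = .beta_loglik, gr = .beta_grad, X = X, y = y,
          method = "L-BFGS-B",
          lower = c(rep(-Inf, p), log(1e-4)),
          upper = c(rep(Inf, p), max_log_phi),
          control = list(fnscale = -1, maxit = maxit,
                         factr = factr, pgtol = 0))
  }
  # coarse pass, then a tight restart to polish the gradient
  opt <- run(init, 1e7)
  opt2 <- run(opt$par, 10)
  if (opt2$value >= opt$value) opt <- opt2
  theta <- unname(opt$par)
  phi <- exp(theta[p + 1L])
  # zero-residual data push the precision toward its cap
  phi_at_bound <- theta[p + 1L] >= max_log_phi - log(100)
  ll <- opt$value
  grad <- .beta_grad(theta, X, y)
  grad_ok <- max(abs(grad[seq_len(p)]), 0) < 1e-6 * max(1, abs(ll)) &&
    (phi_at_bound || abs(grad[p + 1L]) < 1e-6 * max(1, abs(ll)))
  converged <- opt$convergence == 0L || grad_ok
  # observed-information covariance on (delta, log phi), delta-method to phi
  covm <- matrix(NA_real_, p + 1L, p + 1L)
  if (!phi_at_bound) {
    H <- tryCatch(optimHess(theta, .beta_loglik, .beta_grad, X = X, y = y),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Vt <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(Vt)) {
        J <- diag(p + 1L)
        J[p + 1L, p + 1L] <- phi   # d phi / d log phi
        covm <- J %*% Vt %*% t(J)
      }
    }
  }
  dimnames(covm) <- list(c(colnames(X), "phi"), c(colnames(X), "phi"))
  delta <- setNames(theta[seq_len(p)], colnames(X))
  part <- design$partition
  lv <- numeric(length(design$catalog$names))
  names(lv) <- design$catalog$names
  for (gi in seq_along(part$groups)) {
    val <- if (gi == part$reference_group) 0 else delta[[part$labels[gi]]]
    lv[part$groups[[gi]]] <- val
  }
  eta <- if (p > 0L) drop(design$X %*% theta[seq_len(p)]) else rep(0, nrow(design$X))
  zobs <- logit(design$edges$odr, eps)
  gof <- if (length(zobs) >= 3L && var(eta) > 0 && var(zobs) > 0)
    pearson(eta, zobs) else NULL
  structure(list(
    delta = delta, levels = lv, phi = phi,
    covariance = covm,
    se = sqrt(pmax(diag(covm), 0)),
    log_likelihood = ll, aic = -2 * ll + 2 * (p + 1L),
    n_obs = length(y), n_params = p + 1L,
    converged = converged, phi_at_bound = phi_at_bound,
    partition = part, catalog = design$catalog,
    fitted = data.frame(design$edges, eta = eta,
                        mu = plogis(eta)),
    gof = gof), class = "hierarchy_fit")
}

#' Fit a hierarchy directly from an ODR matrix
#'
#' Convenience wrapper: [build_incidence()] then [fit_beta_regression()].
#'
#' @param m an `odr_matrix`.
#' @param partition a [level_partition()] (default singletons).
#' @param ... passed to [fit_beta_regression()].
#' @return A `hierarchy_fit`.
#' @export
fit_hierarchy <- function(m, partition = singleton_partition(m$catalog), ...) {
  fit_beta_regression(build_incidence(m, partition), ...)
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat("Beta-regression hierarchy fit\n")
  cat(sprintf("  %d pathways, %d levels, phi = %.2f%s\n", x$n_obs,
              length(x$partition$groups), x$phi,
              if (x$phi_at_bound) " (at bound)" else ""))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$log_likelihood, x$aic))
  lv <- sort(x$levels)
  cat("  levels:", paste(sprintf("%s=%.2f", names(lv), lv), collapse = ", "), "\n")
  if (!is.null(x$gof))
    cat(sprintf("  goodness of fit: r = %.3f, t(%d) = %.2f\n",
                x$gof$r, x$gof$df, x$gof$t))
  invisible(x)
}

# map an area or group label to its group index in the fit's partition
.group_index <- function(fit, g) {
  part <- fit$partition
  if (g %in% part$labels) return(match(g, part$labels))
  hit <- which(vapply(part$groups, function(gr) g %in% gr, TRUE))
  if (length(hit) != 1L) stop("unknown group or area: ", g)
  hit
}

#' Wald test for the level difference of two groups
#'
#' Contrast `c` with +1 on `g1`'s coefficient and -1 on `g2`'s (0 for the
#' reference group, whose level is fixed):
#' `z = c' delta / sqrt(c' V c)`, two-sided normal p-value.
#'
#' @param fit a `hierarchy_fit`.
#' @param g1,g2 group labels or member area ids.
#' @return list with `z`, `p_value`, `difference` (level of g1 minus g2).
#' @export
wald_pairwise <- function(fit, g1, g2) {
  i1 <- .group_index(fit, g1)
  i2 <- .group_index(fit, g2)
  if (i1 == i2) return(list(z = 0, p_value = 1, difference = 0))
  p <- length(fit$delta)
  cvec <- numeric(p)
  lab <- fit$partition$labels
  ref <- fit$partition$reference_group
  if (i1 != ref) cvec[match(lab[i1], names(fit$delta))] <- 1
  if (i2 != ref) cvec[match(lab[i2], names(fit$delta))] <- -1
  diff <- sum(cvec * fit$delta)
  V <- fit$covariance[seq_len(p), seq_len(p), drop = FALSE]
  v <- drop(t(cvec) %*% V %*% cvec)
  if (!is.finite(v) || v <= 0) stop("degenerate contrast variance")
  z <- diff / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), difference = diff)
}

#' Rescale fitted levels to a target range
#'
#' Affine map sending the lowest level to `lo` and the highest to `hi`
#' (e.g. 1 to 10 for display); order preserved.
#'
#' @param fit a `hierarchy_fit` (or a named numeric vector of levels).
#' @param lo,hi target endpoints.
#' @return Named numeric vector of scaled per-area levels.
#' @export
scale_levels <- function(fit, lo = 1, hi = 10) {
  lv <- if (inherits(fit, "hierarchy_fit")) fit$levels else fit
  rng <- range(lv)
  if (diff(rng) == 0) stop("all levels equal; cannot scale")
  lo + (lv - rng[1]) / diff(rng) * (hi - lo)
}

#' Classify pathways as feedforward, lateral, or feedback
#'
#' Every observed directed pathway is labelled by the Wald test on its
#' endpoint groups: `FF` when the target sits significantly above the
#' source, `FB` when significantly below, `LAT` otherwise (including
#' within-group pathways, whose contrast is identically zero).
#'
#' @param fit a `hierarchy_fit`.
#' @param m the `odr_matrix` the fit was computed from.
#' @param alpha significance level (default 0.05, uncorrected).
#' @return data.frame of class `edge_classification`: `source`, `target`,
#'   `odr`, `level_difference` (target minus source), `wald_z`, `wald_p`,
#'   `label`.
#' @export
classify_edges <- function(fit, m, alpha = 0.05) {
  idx <- which(!is.na(m$values), arr.ind = TRUE)
  nm <- m$catalog$names
  out <- data.frame(source = nm[idx[, 1]], target = nm[idx[, 2]],
                    odr = m$values[idx])
  res <- mapply(function(s, t) {
    w <- wald_pairwise(fit, t, s)   # difference = level(target) - level(source)
    c(w$difference, w$z, w$p_value)
  }, out$source, out$target)
  out$level_difference <- res[1, ]
  out$wald_z <- res[2, ]
  out$wald_p <- res[3, ]
  out$label <- ifelse(out$wald_p < alpha & out$level_difference > 0, "FF",
                ifelse(out$wald_p < alpha & out$level_difference < 0, "FB",
                       "LAT"))
  class(out) <- c("edge_classification", class(out))
  out
}

#' Per-class ODR summary with omnibus and post-hoc tests
#'
#' Descriptive statistics for the FF / LAT / FB ODR distributions plus a
#' one-way ANOVA and Tukey's range test across the nonempty classes.
#'
#' @param classes an [classify_edges()] result, or a named list of ODR
#'   vectors keyed by class.
#' @return list with `summary` (data.frame: class, n, mean, sd, sem),
#'   `anova`, `tukey`.
#' @export
class_odr_summary <- function(classes) {
  groups <- if (inherits(classes, "edge_classification"))
    split(classes$odr, factor(classes$label, levels = c("FF", "LAT", "FB")))
  else classes
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty) > 0L)
    warning("empty class(es) omitted: ", paste(empty, collapse = ", "))
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 nonempty classes")
  summ <- data.frame(
    class = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, sd, 0),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), 0),
    row.names = NULL)
  list(summary = summ, anova = one_way_anova(groups), tukey = tukey_hsd(groups))
}

# ---- model search over level partitions ------------------------------------

# Areas ordered by their singleton-fit levels, lowest first.
.level_order <- function(m, eps = 1e-3) {
  f <- fit_hierarchy(m, eps = eps)
  names(sort(f$levels))
}

# staged candidate ladder over the rank-ordered areas: the eight-model family
# spanning 2 levels to all-singleton, with intermediate models that keep the
# lowest and highest areas apart and coarsen the middle ranks.
.ladder_partitions <- function(ordered_areas) {
  k <- length(ordered_areas)
  if (k < 5L) return(list(c(list(ordered_areas[1]),
                            list(ordered_areas[2:k])),
                          as.list(ordered_areas)))
  r <- ordered_areas
  list(
    c(list(r[1]), list(r[2:k])),                                   # 2 levels
    c(list(r[1]), list(r[2]), list(r[3:k])),                       # 3 levels
    c(list(r[1]), list(r[2:(k - 1L)]), list(r[k])),                # 3 levels
    c(list(r[1]), list(r[2]), list(r[3:(k - 1L)]), list(r[k])),    # 4 levels
    c(list(r[1]), list(r[2:3]), list(r[4:(k - 1L)]), list(r[k])),  # 4 levels
    c(list(r[1]), list(r[2:3]), list(r[4:(k - 3L)]),               # 5 levels
      list(r[(k - 2L):(k - 1L)]), list(r[k])),
    c(list(r[1]), list(r[2]), list(r[3]), list(r[4:(k - 3L)]),     # 6 levels
      list(r[(k - 2L):(k - 1L)]), list(r[k])),
    as.list(r))                                                    # k levels
}

# contiguous-block partitions of a rank-ordered area vector; first and last
# ranks stay singleton ("bracketed": combinations strictly between the
# second-lowest and the highest level).
.bracketed_partitions <- function(ordered_areas) {
  k <- length(ordered_areas)
  mid <- ordered_areas[2:(k - 1L)]
  mlen <- length(mid)
  parts <- list()
  for (cut_mask in 0:(2^(mlen - 1L) - 1L)) {
    cuts <- which(bitwAnd(cut_mask, 2^(seq_len(mlen - 1L) - 1L)) > 0L)
    bounds <- c(0L, cuts, mlen)
    blocks <- lapply(seq_len(length(bounds) - 1L),
                     function(i) mid[(bounds[i] + 1L):bounds[i + 1L]])
    parts[[length(parts) + 1L]] <-
      c(list(ordered_areas[1]), blocks, list(ordered_areas[k]))
  }
  parts
}

#' AIC-driven search over same-level partitions
#'
#' Fits a beta-regression hierarchy for each candidate partition and ranks
#' the models by AIC (ascending; ties broken by fewer parameters, then by
#' the lexicographic partition signature).  Candidate strategies, all
#' driven by the area ordering of the all-singleton fit:
#' \describe{
#'   \item{`cumulative_top`}{for n = 1..K-1, the highest n areas merged
#'     into one level, all others singleton (a nested family).}
#'   \item{`lm_upward`}{the second-lowest area merged with an increasing
#'     number of the areas above it (excluding the topmost).}
#'   \item{`bracketed`}{lowest and highest areas kept singleton; all
#'     contiguous-block groupings of the areas in between.}
#'   \item{`ladder`}{a staged eight-model family from 2 levels to
#'     all-singleton: the coarse end merges everything above the lowest
#'     area, intermediate models keep the lowest and highest areas apart
#'     while coarsening the middle ranks, mirroring a stepwise
#'     same-level-constraint comparison.}
#'   \item{`explicit`}{a user-supplied list of partitions (each a list of
#'     character vectors).}
#' }
#'
#' @param m an `odr_matrix`.
#' @param strategy one of `"cumulative_top"`, `"lm_upward"`, `"bracketed"`,
#'   `"explicit"`.
#' @param partitions for `strategy = "explicit"`: list of partitions.
#' @param eps clipping bound for the likelihood.
#' @param ... further arguments to [fit_beta_regression()].
#' @return list of class `model_search`: `fits` (ranked list of
#'   `hierarchy_fit`s), `table` (data.frame: signature, n_levels,
#'   n_params, logLik, AIC), `best` (the top fit).
#' @export
model_search <- function(m, strategy = c("ladder", "bracketed",
                                         "cumulative_top",
                                         "lm_upward", "explicit"),
                         partitions = NULL, eps = 1e-3, ...) {
  strategy <- match.arg(strategy)
  cat10 <- m$catalog
  if (strategy == "explicit") {
    if (is.null(partitions)) stop("strategy 'explicit' needs `partitions`")
    cand <- lapply(partitions, level_partition, catalog = cat10)
  } else {
    ord <- .level_order(m, eps)
    k <- length(ord)
    raw <- switch(strategy,
      cumulative_top = lapply(seq_len(k - 1L), function(n) {
        top <- ord[(k - n + 1L):k]
        c(as.list(ord[seq_len(k - n)]), list(top))
      }),
      lm_upward = lapply(seq_len(k - 2L), function(n) {
        block <- ord[2:(1L + n)]
        c(list(ord[1]), list(block),
          if (n < k - 1L) as.list(ord[(2L + n):k]))
      }),
      bracketed = .bracketed_partitions(ord),
      ladder = .ladder_partitions(ord))
    cand <- lapply(raw, level_partition, catalog = cat10)
  }
  fits <- lapply(cand, function(p) fit_hierarchy(m, p, eps = eps, ...))
  tab <- data.frame(
    signature = vapply(cand, partition_signature, ""),
    n_levels = vapply(cand, function(p) length(p$groups), 0L),
    n_params = vapply(fits, function(f) f$n_params, 0L),
    logLik = vapply(fits, function(f) f$log_likelihood, 0),
    AIC = vapply(fits, function(f) f$aic, 0))
  o <- order(tab$AIC, tab$n_params, tab$signature)
  structure(list(fits = fits[o], table = tab[o, , drop = FALSE],
                 best = fits[[o[1]]], strategy = strategy),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("AIC model search (strategy:", x$strategy, ")\n")
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}
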