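#' Run the full hierarchy analysis
#'
#' Orchestrates every stage over an edge table (per-section ODRs):
#' pathway averaging into the directed ODR matrix, reciprocity regression
#' (all pathways and intra-stream), unit-slope pairs distances (common
#' targets and common sources), the all-singleton beta-regression
#' hierarchy fit, the AIC partition search, FF/LAT/FB edge classification
#' with the per-class ODR summary, and (optionally) RF consistency when
#' response maps are supplied.
#'
#' @param observations edge-table data.frame (see [read_edge_table()]).
#' @param catalog an [area_catalog()].
#' @param eps logit/likelihood clipping bound (default 1e-3).
#' @param alpha significance level for edge classification (default 0.05).
#' @param search_strategy strategy for [model_search()] (default
#'   `"ladder"`).
#' @param rf_maps optional RF response-map data.frame (`unit_id`, `area`,
#'   `azimuth`, `elevation`, `rate`).
#' @param seed integer recorded in the report (the analysis itself is
#'   deterministic).
#' @return list of class `analysis_report` with one element per stage plus
#'   `config`; serialisable with [write_report()].
#' @export
run_full_analysis <- function(observations, catalog = area_catalog(),
                              eps = 1e-3, alpha = 0.05,
                              search_strategy = "ladder",
                              rf_maps = NULL, seed = NA_integer_) {
  m <- build_odr_matrix(observations, catalog)
  recip_all <- pair_reciprocals(m, "all", eps = eps)
  recip_intra <- pair_reciprocals(m, "intra_stream", eps = eps)
  recip <- list(all = fit_reciprocity(recip_all))
  if (nrow(recip_intra) >= 3L) {
    recip$intra_stream <- fit_reciprocity(recip_intra)
    recip$slope_comparison <- compare_slopes(recip_all, recip_intra)
  }
  dist <- list(targets = distance_matrix(m, "targets", eps = eps),
               sources = distance_matrix(m, "sources", eps = eps))
  fit <- fit_hierarchy(m, eps = eps)
  search <- model_search(m, search_strategy, eps = eps)
  classes <- classify_edges(search$best, m, alpha = alpha)
  class_summary <- class_odr_summary(classes)
  rf <- NULL
  if (!is.null(rf_maps)) {
    fits <- lapply(split(rf_maps, rf_maps$unit_id), function(mp) {
      f <- tryCatch(fit_gaussian_rf(mp), error = function(e) NULL)
      if (is.null(f) || !f$converged) return(NULL)
      data.frame(unit_id = mp$unit_id[1], area = mp$area[1],
                 diameter_deg = f$diameter_deg)
    })
    diam <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
    rf <- list(diameters = diam,
               consistency = hierarchy_rf_consistency(
                 search$best$levels, diam, catalog))
  }
  structure(list(
    config = list(eps = eps, alpha = alpha,
                  search_strategy = search_strategy, seed = seed,
                  n_observations = nrow(observations),
                  package_version = as.character(utils::packageVersion("hierODR"))),
    odr_matrix = m,
    reciprocity = recip,
    distances = dist,
    hierarchy = fit,
    search = search,
    classification = classes,
    class_summary = class_summary,
    rf = rf), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Hierarchy analysis report ==\n")
  k <- length(x$odr_matrix$catalog$names)
  cat(sprintf("%d areas, %d observed pathways\n", k,
              sum(!is.na(x$odr_matrix$values))))
  print(x$reciprocity$all)
  print(x$hierarchy)
  cat(sprintf("AIC winner: %s (%d levels, AIC %.2f)\n",
              partition_signature(x$search$best$partition),
              length(x$search$best$partition$groups), x$search$best$aic))
  print(x$class_summary$summary, row.names = FALSE)
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Writes the machine-readable parts of the report (configuration, matrix,
#' reciprocity fits, distances, levels, model-search table, edge classes,
#' class summary, RF consistency) with 12 significant digits.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  best <- report$search$best
  out <- list(
    config = report$config,
    odr_matrix = as.data.frame(report$odr_matrix$values),
    reciprocity = lapply(report$reciprocity, unclass),
    distances = lapply(report$distances, function(d)
      list(mode = d$mode, intercepts = as.data.frame(d$intercepts))),
    levels = as.list(report$hierarchy$levels),
    levels_scaled_1_10 = as.list(scale_levels(best, 1, 10)),
    phi = report$hierarchy$phi,
    model_search = report$search$table,
    best_partition = best$partition$labels,
    best_aic = best$aic,
    edge_classes = as.data.frame(report$classification),
    class_summary = report$class_summary$summary,
    rf = if (!is.null(report$rf)) list(
      per_area = report$rf$consistency$per_area,
      pearson = report$rf$consistency$pearson) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 12,
                       na = "null", pretty = TRUE)
  invisible(path)
}
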