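#' Area catalog
#'
#' Defines the set of cortical areas under study, their processing-stream
#' membership, and the reference area whose hierarchical level is pinned at
#' zero.  The default catalog holds the ten areas of mouse visual cortex
#' (V1 plus nine higher visual areas) split into dorsal and ventral streams.
#'
#' @param names character vector of unique area identifiers.
#' @param streams named character vector mapping every area to one of
#'   `"dorsal"`, `"ventral"`, `"root"`.
#' @param reference the reference area (level fixed at 0); must be in `names`.
#' @return An object of class `area_catalog`: a list with elements `names`,
#'   `streams`, `reference`.
#' @examples
#' cat10 <- area_catalog()
#' cat10$reference
#' @export
area_catalog <- function(names = .default_area_names,
                         streams = .default_streams,
                         reference = "V1") {
  names <- as.character(names)
  if (length(names) == 0L || anyDuplicated(names) || any(!nzchar(names)))
    stop("area names must be unique and non-empty")
  if (!reference %in% names)
    stop("reference area '", reference, "' is not in the catalog")
  streams <- streams[names]
  if (any(is.na(streams)))
    stop("every area needs a stream label; missing: ",
         paste(names[is.na(streams)], collapse = ", "))
  if (!all(streams %in% c("dorsal", "ventral", "root")))
    stop("stream labels must be 'dorsal', 'ventral' or 'root'")
  structure(list(names = names, streams = setNames(as.character(streams), names),
                 reference = reference),
            class = "area_catalog")
}

#' @export
print.area_catalog <- function(x, ...) {
  cat("Area catalog:", length(x$names), "areas; reference =", x$reference, "\n")
  cat(paste0(x$names, " (", x$streams, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Read an area catalog from JSON
#'
#' Expects keys `areas` (ordered list), `streams` (map area -> stream) and
#' `reference` (string).
#'
#' @param path path to a JSON file.
#' @return An [area_catalog()].
#' @export
read_area_catalog <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  area_catalog(names = j$areas, streams = unlist(j$streams), reference = j$reference)
}

#' Write an area catalog to JSON
#'
#' @param catalog an [area_catalog()].
#' @param path output path.
#' @export
write_area_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(areas = catalog$names, streams = as.list(catalog$streams),
         reference = catalog$reference),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a per-section edge table
#'
#' Reads a TSV/CSV with columns `source`, `target`, `section_id`, `odr`
#' holding one optical density ratio per coronal section per directed
#' pathway, and validates it against the catalog.
#'
#' @param path path to a tab- or comma-separated file with a header.
#' @param catalog an [area_catalog()] used for validation.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return A `data.frame` with columns `source`, `target`, `section_id`,
#'   `odr`, row order preserved.
#' @export
read_edge_table <- function(path, catalog, sep = "\t") {
  if (!file.exists(path)) stop("edge table not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_edge_table(df, catalog)
}

#' Validate an in-memory edge table
#'
#' @param df data.frame with columns `source`, `target`, `section_id`, `odr`.
#' @param catalog an [area_catalog()].
#' @return The validated data.frame.
#' @export
validate_edge_table <- function(df, catalog) {
  need <- c("source", "target", "section_id", "odr")
  if (!all(need %in% names(df)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  bad <- !(df$source %in% catalog$names) | !(df$target %in% catalog$names)
  if (any(bad)) {
    unknown <- setdiff(unique(c(df$source[bad], df$target[bad])), catalog$names)
    stop("row ", which(bad)[1], ": unknown area id(s): ",
         paste(unknown, collapse = ", "))
  }
  self <- df$source == df$target
  if (any(self))
    stop("row ", which(self)[1], ": self-loop ", df$source[which(self)[1]],
         " -> ", df$target[which(self)[1]], " is not allowed")
  if (any(df$odr < 0 | df$odr > 1 | is.na(df$odr)))
    stop("row ", which(df$odr < 0 | df$odr > 1 | is.na(df$odr))[1],
         ": odr outside [0, 1]")
  df
}

#' Write an edge table
#'
#' @param df edge-table data.frame.
#' @param path output path (TSV).
#' @export
write_edge_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the directed ODR matrix from per-section observations
#'
#' For every directed pathway the section ODRs are averaged on the ODR scale
#' (the per-pathway mean of 3-5 coronal sections in the original design).
#' Pathways with no observation are left missing (`NA`), mirroring pathways
#' whose axonal projections are too weak to analyse.  Pathways with fewer
#' than `min_sections` observations are kept with a warning.
#'
#' @param obs edge-table data.frame (see [read_edge_table()]).
#' @param catalog an [area_catalog()].
#' @param min_sections minimum section count below which a warning is issued
#'   (default 3).
#' @return An object of class `odr_matrix`: list with `values` (area x area
#'   numeric matrix, `NA` = missing, rows = source, cols = target),
#'   `n_sections` (integer matrix) and `catalog`.
#' @examples
#' obs <- data.frame(source = "V1", target = "LM",
#'                   section_id = 1:3, odr = c(0.6, 0.6, 0.6))
#' m <- suppressWarnings(build_odr_matrix(obs, area_catalog()))
#' m$values["V1", "LM"]
#' @export
build_odr_matrix <- function(obs, catalog, min_sections = 3L) {
  obs <- validate_edge_table(obs, catalog)
  if (nrow(obs) == 0L) stop("no observations")
  k <- length(catalog$names)
  values <- matrix(NA_real_, k, k, dimnames = list(catalog$names, catalog$names))
  nsec <- matrix(0L, k, k, dimnames = list(catalog$names, catalog$names))
  agg <- aggregate(odr ~ source + target, data = obs, FUN = mean)
  cnt <- aggregate(odr ~ source + target, data = obs, FUN = length)
  for (r in seq_len(nrow(agg))) {
    values[agg$source[r], agg$target[r]] <- agg$odr[r]
    nsec[cnt$source[r], cnt$target[r]] <- cnt$odr[r]
  }
  few <- which(nsec > 0L & nsec < min_sections, arr.ind = TRUE)
  if (nrow(few) > 0L)
    warning(nrow(few), " pathway(s) have fewer than ", min_sections,
            " sections; retained")
  structure(list(values = values, n_sections = nsec, catalog = catalog),
            class = "odr_matrix")
}

#' @export
print.odr_matrix <- function(x, ...) {
  k <- length(x$catalog$names)
  off <- k * (k - 1L)
  present <- sum(!is.na(x$values)) # diagonal is always NA
  cat("ODR matrix:", k, "areas;", present, "of", off, "directed pathways observed\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Write / read an ODR matrix as labelled TSV
#'
#' Missing pathways are written as `NA`.
#'
#' @param m an `odr_matrix`.
#' @param path output path.
#' @rdname odr_matrix_io
#' @export
write_odr_matrix <- function(m, path) {
  write.table(m$values, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @param catalog an [area_catalog()]; row/column labels must match it.
#' @rdname odr_matrix_io
#' @export
read_odr_matrix <- function(path, catalog) {
  v <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (!identical(sort(rownames(v)), sort(catalog$names)))
    stop("matrix labels do not match the catalog")
  v <- v[catalog$names, catalog$names]
  diag(v) <- NA_real_
  nsec <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  structure(list(values = v, n_sections = nsec, catalog = catalog),
            class = "odr_matrix")
}

#' Logit transform with clipping
#'
#' Maps a proportion from (0, 1) to the real line: `log(p / (1 - p))`.
#' A logit ODR of 0 corresponds to an ODR of 0.5 (equal axon density in
#' L2-4 and L1).  Values at or beyond the clipping bound `eps` are clamped
#' to `[eps, 1 - eps]` so the transform stays finite.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param eps clipping bound in (0, 0.5); default `1e-3`.
#' @return `log(p' / (1 - p'))` with `p' = pmin(pmax(p, eps), 1 - eps)`.
#' @examples
#' logit(0.5)   # 0
#' logit(0.88)  # about 1.99
#' @export
logit <- function(p, eps = 1e-3) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Inverse logit
#'
#' @param x real value(s).
#' @return `1 / (1 + exp(-x))`, in (0, 1).
#' @export
inv_logit <- function(x) plogis(x)
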