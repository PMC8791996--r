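# Shared fixtures: small catalogs and noise-free networks built in code.

toy_catalog <- function(k = 3L, streams = NULL) {
  nm <- LETTERS[seq_len(k)]
  if (is.null(streams)) streams <- setNames(rep("dorsal", k), nm)
  area_catalog(names = nm, streams = streams, reference = nm[1])
}

# ODR matrix whose every entry is exactly inv_logit(h_target - h_source);
# `missing` is an optional 2-column matrix of (source, target) to blank out.
noise_free_matrix <- function(levels, catalog, missing = NULL) {
  nm <- catalog$names
  grid <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  if (!is.null(missing)) {
    key <- paste(missing[, 1], missing[, 2])
    grid <- grid[!(paste(grid$source, grid$target) %in% key), ]
  }
  grid$section_id <- 1L
  grid$odr <- plogis(levels[grid$target] - levels[grid$source])
  suppressWarnings(build_odr_matrix(grid, catalog, min_sections = 1L))
}
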