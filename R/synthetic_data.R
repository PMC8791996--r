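#' Simulation configuration
#'
#' Bundles the ground truth and sampling parameters for the synthetic
#' tracing/recording data generator.  The default preset mirrors the study
#' conditions of the mouse visual network: ten areas in
#' five true levels — V1 | LM,RL | A,AL,PM,P | LI,AM | POR — spread over
#' [0, 2], a common beta precision of 30, 4 coronal sections per pathway,
#' and 10 of the 90 directed pathways missing.
#'
#' @param catalog an [area_catalog()].
#' @param true_levels named numeric vector of per-area levels (reference
#'   need not be 0; only differences matter).
#' @param phi beta precision (> 0).
#' @param n_sections sections drawn per observed pathway.
#' @param n_missing number of randomly placed missing directed pathways
#'   (ignored when `missing_edges` is given).
#' @param missing_edges optional explicit 2-column matrix/data.frame of
#'   (source, target) pairs to omit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(catalog = area_catalog(),
                       true_levels = c(V1 = 0, LM = 0.5, RL = 0.5,
                                       A = 1, AL = 1, PM = 1, P = 1,
                                       LI = 1.5, AM = 1.5, POR = 2),
                       phi = 30, n_sections = 4L, n_missing = 10L,
                       missing_edges = NULL) {
  if (!setequal(names(true_levels), catalog$names))
    stop("true_levels must name every catalog area")
  if (phi <= 0) stop("phi must be > 0")
  structure(list(catalog = catalog, true_levels = true_levels[catalog$names],
                 phi = phi, n_sections = as.integer(n_sections),
                 n_missing = as.integer(n_missing),
                 missing_edges = missing_edges),
            class = "sim_config")
}

#' Simulate per-section ODR observations
#'
#' Inverts the analysis model: for a directed pathway `i -> j`, section
#' ODRs are drawn from `Beta(mu * phi, (1 - mu) * phi)` with
#' `mu = inv_logit(h_j - h_i)` — the expected logit ODR equals the level
#' difference of target and source.  A set of directed pathways is left
#' unobserved (randomly placed unless given explicitly).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is fully reproducible.
#' @return list with `observations` (edge-table data.frame), `truth`
#'   (list: `levels`, `phi`, `missing` data.frame, `seed`).
#' @export
simulate_odr <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  nm <- config$catalog$names
  pairs <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  if (!is.null(config$missing_edges)) {
    me <- as.data.frame(config$missing_edges)
    miss_key <- paste(me[[1]], me[[2]])
  } else if (config$n_missing > 0L) {
    miss_key <- paste(pairs$source, pairs$target)[
      sample.int(nrow(pairs), config$n_missing)]
  } else miss_key <- character(0)
  obs_pairs <- pairs[!(paste(pairs$source, pairs$target) %in% miss_key), ]
  h <- config$true_levels
  rows <- lapply(seq_len(nrow(obs_pairs)), function(r) {
    s <- obs_pairs$source[r]; t <- obs_pairs$target[r]
    mu <- plogis(h[[t]] - h[[s]])
    data.frame(source = s, target = t,
               section_id = seq_len(config$n_sections),
               odr = rbeta(config$n_sections, mu * config$phi,
                           (1 - mu) * config$phi))
  })
  miss <- pairs[paste(pairs$source, pairs$target) %in% miss_key, ]
  list(observations = do.call(rbind, rows),
       truth = list(levels = h, phi = config$phi,
                    missing = miss, seed = seed))
}

#' Render a two-band laminar image realising a target ODR
#'
#' Builds a synthetic dark-field section: an upper L1 band and a lower
#' L2-4 band over a uniform background, with band intensities chosen so
#' that the background-subtracted band means give
#' `m24 / (m1 + m24) = target_odr` exactly, plus optional truncated-normal
#' pixel noise.  Background strips within each band and all masks are
#' included, so the image can be pushed through the full
#' [compute_odr()] pipeline.
#'
#' @param target_odr target ratio in (0, 1).
#' @param band_px band height in pixels (default 40).
#' @param width_px image width (default 80).
#' @param background background intensity level (default 10).
#' @param signal total band signal above background shared by the two
#'   bands (default 100).
#' @param noise_sd additive Gaussian noise SD (truncated at 0); default 0.
#' @param um_per_pixel physical scale (default 1).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return list with `image` (a [laminar_image()]) and `analytic_odr`.
#' @export
render_laminar_image <- function(target_odr, band_px = 40L, width_px = 80L,
                                 background = 10, signal = 100,
                                 noise_sd = 0, um_per_pixel = 1, seed = 1L) {
  if (target_odr <= 0 || target_odr >= 1) stop("target_odr must be in (0, 1)")
  m1 <- signal * (1 - target_odr)
  m24 <- signal * target_odr
  nr <- 2L * band_px + 10L       # 10-row background strip between bands
  nc <- width_px
  px <- matrix(background, nr, nc)
  rows_L1 <- seq_len(band_px)
  rows_L24 <- (band_px + 11L):nr
  # left 3/4 of each band carries label; right quarter is clean background
  lab_cols <- seq_len(floor(nc * 0.75))
  bg_cols <- (floor(nc * 0.75) + 1L):nc
  px[rows_L1, lab_cols] <- background + m1
  px[rows_L24, lab_cols] <- background + m24
  if (noise_sd > 0) {
    set.seed(seed)
    px <- pmax(px + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
  }
  mk <- function(rows, cols) {
    m <- matrix(FALSE, nr, nc); m[rows, cols] <- TRUE; m
  }
  img <- laminar_image(px, um_per_pixel,
                       mask_L1 = mk(rows_L1, lab_cols),
                       mask_L24 = mk(rows_L24, lab_cols),
                       bg_L1 = mk(rows_L1, bg_cols),
                       bg_L24 = mk(rows_L24, bg_cols))
  list(image = img, analytic_odr = m24 / (m1 + m24))
}

#' Write a rendered laminar image to PNG + mask JSON
#'
#' Serialises a synthetic section in the on-disk format the imaging reader
#' expects: an 8-bit grayscale PNG plus a JSON annotation with rectangular
#' regions and the pixel scale.
#'
#' @param img a [laminar_image()] (intensities are rescaled to `[0, 1]`
#'   by the maximum for PNG encoding; the ODR is scale-invariant).
#' @param image_path,masks_path output paths (`.png`, `.json`).
#' @export
write_laminar_image <- function(img, image_path, masks_path) {
  mx <- max(img$pixels)
  png::writePNG(img$pixels / ifelse(mx > 0, mx, 1), image_path)
  rect_of <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    list(list(type = "rect",
              x0 = min(idx[, 2]) - 1L, x1 = max(idx[, 2]),
              y0 = min(idx[, 1]) - 1L, y1 = max(idx[, 1])))
  }
  jsonlite::write_json(
    list(um_per_pixel = img$um_per_pixel,
         L1 = rect_of(img$mask_L1), L24 = rect_of(img$mask_L24),
         bg_L1 = rect_of(img$bg_L1), bg_L24 = rect_of(img$bg_L24)),
    masks_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Simulate receptive-field response maps
#'
#' Draws per-unit elliptical Gaussian response fields on a square stimulus
#' grid with additive rate noise (clamped at 0), with per-area mean RF
#' diameters supplied by the caller (typically increasing with
#' hierarchical level).
#'
#' @param area_diameters named numeric vector: target mean RF diameter
#'   (deg) per area.
#' @param units_per_area units drawn per area (default 8).
#' @param diameter_sd between-unit SD of the diameter (default 0.1 of the
#'   mean).
#' @param grid_deg stimulus positions along each axis (default
#'   `seq(-30, 30, by = 5)`, 5-degree patch spacing).
#' @param amplitude,baseline response amplitude and baseline (spikes/s).
#' @param noise_sd additive rate noise SD (default 0).
#' @param aspect ellipse aspect ratio sigma_x / sigma_y (default 1.5).
#' @param seed integer seed.
#' @return list with `maps` (data.frame `unit_id`, `area`, `azimuth`,
#'   `elevation`, `rate`) and `truth` (per-unit data.frame of generative
#'   parameters).
#' @export
simulate_rf_maps <- function(area_diameters, units_per_area = 8L,
                             diameter_sd = NULL,
                             grid_deg = seq(-30, 30, by = 5),
                             amplitude = 20, baseline = 2, noise_sd = 0,
                             aspect = 1.5, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(azimuth = grid_deg, elevation = grid_deg)
  maps <- list(); truth <- list()
  uid <- 0L
  for (a in names(area_diameters)) {
    dm <- area_diameters[[a]]
    dsd <- if (is.null(diameter_sd)) 0.1 * dm else diameter_sd
    for (u in seq_len(units_per_area)) {
      uid <- uid + 1L
      d <- max(rnorm(1, dm, dsd), 1)
      sgm <- d / 4                       # geometric-mean sigma: 4 sqrt(sx sy) = d
      sx <- sgm * sqrt(aspect); sy <- sgm / sqrt(aspect)
      th <- runif(1, 0, pi)
      cx <- runif(1, -5, 5); cy <- runif(1, -5, 5)
      dx <- grid$azimuth - cx; dy <- grid$elevation - cy
      uu <- cos(th) * dx + sin(th) * dy
      vv <- -sin(th) * dx + cos(th) * dy
      rate <- baseline + amplitude * exp(-(uu^2 / (2 * sx^2) + vv^2 / (2 * sy^2)))
      if (noise_sd > 0) rate <- pmax(rate + rnorm(length(rate), 0, noise_sd), 0)
      maps[[uid]] <- data.frame(unit_id = uid, area = a,
                                azimuth = grid$azimuth,
                                elevation = grid$elevation, rate = rate)
      truth[[uid]] <- data.frame(unit_id = uid, area = a, amplitude = amplitude,
                                 baseline = baseline, center_x = cx,
                                 center_y = cy, sigma_x = sx, sigma_y = sy,
                                 theta = th, diameter_deg = 4 * sqrt(sx * sy))
    }
  }
  list(maps = do.call(rbind, maps), truth = do.call(rbind, truth))
}
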