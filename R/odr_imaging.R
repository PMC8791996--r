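#' Laminar section image
#'
#' A dark-field grayscale image of a coronal section together with the pixel
#' masks needed to compute an optical density ratio: the layer-1 band
#' (`mask_L1`), the layers-2-to-4 band (`mask_L24`), and background regions
#' within each band that carry no labeled axons (`bg_L1`, `bg_L24`).
#'
#' @param pixels numeric matrix of nonnegative intensities (rows = image
#'   rows, columns = image columns).
#' @param um_per_pixel physical scale, micrometres per pixel (> 0).
#' @param mask_L1,mask_L24,bg_L1,bg_L24 logical matrices of the same
#'   dimension as `pixels` marking the four pixel sets.
#' @return An object of class `laminar_image`.
#' @export
laminar_image <- function(pixels, um_per_pixel, mask_L1, mask_L24,
                          bg_L1, bg_L24) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
  if (um_per_pixel <= 0) stop("um_per_pixel must be > 0")
  masks <- list(mask_L1 = mask_L1, mask_L24 = mask_L24,
                bg_L1 = bg_L1, bg_L24 = bg_L24)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dim(pixels)))
      stop(nm, " does not match the image dimensions")
    storage.mode(masks[[nm]]) <- "logical"
  }
  if (any(masks$mask_L1 & masks$mask_L24))
    stop("L1 and L2-4 masks overlap")
  if (any((masks$bg_L1 | masks$bg_L24) & (masks$mask_L1 | masks$mask_L24)))
    stop("background regions overlap the label masks")
  structure(c(list(pixels = pixels, um_per_pixel = um_per_pixel), masks),
            class = "laminar_image")
}

#' @export
print.laminar_image <- function(x, ...) {
  cat("Laminar image:", nrow(x$pixels), "x", ncol(x$pixels), "px at",
      x$um_per_pixel, "um/px;",
      sum(x$mask_L1), "L1 px,", sum(x$mask_L24), "L2-4 px\n")
  invisible(x)
}

# Rasterise one region spec (rect or polygon, 0-based pixel coordinates,
# x = column, y = row, half-open extents for rects) into a logical matrix.
rasterize_region <- function(region, nrow_px, ncol_px) {
  m <- matrix(FALSE, nrow_px, ncol_px)
  type <- if (is.null(region$type)) "rect" else region$type
  if (type == "rect") {
    rows <- seq.int(region$y0 + 1L, region$y1)  # half-open [y0, y1)
    cols <- seq.int(region$x0 + 1L, region$x1)
    rows <- rows[rows >= 1L & rows <= nrow_px]
    cols <- cols[cols >= 1L & cols <= ncol_px]
    m[rows, cols] <- TRUE
  } else if (type == "polygon") {
    idx <- which(!m, arr.ind = TRUE)  # all pixels
    inside <- pracma::inpolygon(idx[, 2] - 1, idx[, 1] - 1,
                                unlist(region$x), unlist(region$y),
                                boundary = TRUE)
    m[idx[inside, , drop = FALSE]] <- TRUE
  } else stop("unknown region type: ", type)
  m
}

#' Read a laminar image with its mask annotations
#'
#' Reads a single-channel PNG or TIFF image (8/16-bit) plus a JSON
#' annotation file with region lists under the keys `L1`, `L24`, `bg_L1`,
#' `bg_L24` (each region a rectangle `x0,y0,x1,y1` with 0-based, half-open
#' pixel extents, or a polygon with `x`, `y` vertex arrays) and a
#' `um_per_pixel` scale.
#'
#' @param image_path path to a `.png` or `.tif`/`.tiff` file.
#' @param masks_path path to the JSON annotation file.
#' @return A [laminar_image()].
#' @export
read_laminar_image <- function(image_path, masks_path) {
  ext <- tolower(tools::file_ext(image_path))
  px <- if (ext == "png") {
    png::readPNG(image_path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    tiff::readTIFF(image_path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(px)) == 3L) px <- px[, , 1]  # first channel of gray-saved RGB
  ann <- jsonlite::read_json(masks_path, simplifyVector = FALSE)
  get_mask <- function(key) {
    regs <- ann[[key]]
    if (is.null(regs) || length(regs) == 0L)
      return(matrix(FALSE, nrow(px), ncol(px)))
    Reduce(`|`, lapply(regs, rasterize_region, nrow_px = nrow(px),
                       ncol_px = ncol(px)))
  }
  laminar_image(px, um_per_pixel = ann$um_per_pixel,
                mask_L1 = get_mask("L1"), mask_L24 = get_mask("L24"),
                bg_L1 = get_mask("bg_L1"), bg_L24 = get_mask("bg_L24"))
}

#' Subtract per-layer background intensity
#'
#' The mean intensity over the unlabeled background region of each band is
#' subtracted from every pixel of that band's label mask; negative results
#' are clamped to zero.  Pixels outside the two label masks are left
#' untouched.
#'
#' @param img a [laminar_image()].
#' @return A `laminar_image` with background-corrected band pixels.
#' @export
subtract_background <- function(img) {
  if (!any(img$bg_L1) || !any(img$bg_L24))
    stop("empty background region; both bg_L1 and bg_L24 must be nonempty")
  px <- img$pixels
  px[img$mask_L1] <- pmax(px[img$mask_L1] - mean(img$pixels[img$bg_L1]), 0)
  px[img$mask_L24] <- pmax(px[img$mask_L24] - mean(img$pixels[img$bg_L24]), 0)
  img$pixels <- px
  img
}

#' Disk-mean smoothing
#'
#' Replaces each pixel by the mean over a flat disk of physical radius
#' `radius_um`, converted to pixels as `ceiling(radius_um / um_per_pixel)`.
#' Near image borders the mean is taken over the in-bounds part of the
#' disk.  Radius 0 is the identity.  Used to damp outlier and saturated
#' pixels before averaging.
#'
#' @param img a [laminar_image()].
#' @param radius_um smoothing radius in micrometres (>= 0); default 1.
#' @return A smoothed `laminar_image` (masks unchanged).
#' @export
smooth_disk <- function(img, radius_um = 1) {
  if (radius_um < 0) stop("radius_um must be >= 0")
  r <- ceiling(radius_um / img$um_per_pixel)
  if (radius_um == 0 || r == 0L) return(img)
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx > r * r) next
    sr <- max(1L, 1L - dy):min(nr, nr - dy)    # destination rows
    sc <- max(1L, 1L - dx):min(nc, nc - dx)
    acc[sr, sc] <- acc[sr, sc] + px[sr + dy, sc + dx]
    cnt[sr, sc] <- cnt[sr, sc] + 1
  }
  img$pixels <- acc / cnt
  img
}

#' Intensity-based pixel selection
#'
#' Implements the "pixels within the top fraction of the highest intensity
#' value" rule and its robustness variants.  Mode `"range"` keeps values
#' `v >= (1 - fraction) * max(values)` (e.g. fraction 0.7 keeps everything
#' within 70% of the peak).  Mode `"rank"` keeps the top `fraction` of
#' values by rank.  `exclude_top` first removes values above
#' `(1 - exclude_top) * max` (used to drop the brightest projection core).
#'
#' @param values numeric vector of nonnegative intensities.
#' @param fraction proportion in (0, 1]; default 0.7.
#' @param mode `"range"` (default) or `"rank"`.
#' @param exclude_top proportion in `[0, 1)`; default 0.
#' @return The selected values (possibly empty when all values are zero).
#' @examples
#' select_pixels(c(10, 50, 100), fraction = 0.7)  # threshold 30 -> 50, 100
#' @export
select_pixels <- function(values, fraction = 0.7,
                          mode = c("range", "rank"), exclude_top = 0) {
  mode <- match.arg(mode)
  if (length(values) == 0L) stop("values is empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (exclude_top < 0 || exclude_top >= 1) stop("exclude_top must be in [0, 1)")
  mx <- max(values)
  if (mx == 0) return(numeric(0))
  if (exclude_top > 0) {
    values <- values[values <= (1 - exclude_top) * mx]
    if (length(values) == 0L) return(numeric(0))
    mx <- max(values)
  }
  if (mode == "range") {
    values[values >= (1 - fraction) * mx]
  } else {
    keep <- max(1L, ceiling(fraction * length(values)))
    sort(values, decreasing = TRUE)[seq_len(keep)]
  }
}

#' Optical density ratio of a laminar image
#'
#' The full per-section ODR pipeline: background subtraction, disk
#' smoothing, intensity-based pixel selection within each layer band, and
#' the ratio `mean(L2-4) / (mean(L1) + mean(L2-4))`.  High ODRs mark
#' feedforward-like (middle-layer-rich) termination; low ODRs mark
#' feedback-like (L1-biased) termination.
#'
#' @param img a [laminar_image()].
#' @param fraction,mode,exclude_top selection policy; see [select_pixels()].
#' @param radius_um smoothing radius in micrometres; default 1.
#' @param per_section_max if `TRUE`, the selection threshold uses the
#'   maximum over both bands jointly instead of per band (default `FALSE`:
#'   each band is thresholded against its own peak).
#' @return The ODR, a proportion in `[0, 1]`.
#' @export
compute_odr <- function(img, fraction = 0.7, mode = c("range", "rank"),
                        exclude_top = 0, radius_um = 1,
                        per_section_max = FALSE) {
  mode <- match.arg(mode)
  if (!any(img$mask_L1) || !any(img$mask_L24))
    stop("both layer masks must be nonempty")
  img <- smooth_disk(subtract_background(img), radius_um)
  v1 <- img$pixels[img$mask_L1]
  v24 <- img$pixels[img$mask_L24]
  if (per_section_max) {
    mx <- max(c(v1, v24))
    sel <- function(v) {
      if (mx == 0) return(numeric(0))
      v <- if (exclude_top > 0) v[v <= (1 - exclude_top) * mx] else v
      if (mode == "range") v[v >= (1 - fraction) * mx]
      else sort(v, decreasing = TRUE)[seq_len(max(1L, ceiling(fraction * length(v))))]
    }
    s1 <- sel(v1); s24 <- sel(v24)
  } else {
    s1 <- select_pixels(v1, fraction, mode, exclude_top)
    s24 <- select_pixels(v24, fraction, mode, exclude_top)
  }
  if (length(s1) == 0L && length(s24) == 0L)
    stop("no pixels selected in either band; ODR undefined")
  if (length(s24) == 0L) {
    warning("no L2-4 pixels selected; ODR forced to 0")
    return(0)
  }
  if (length(s1) == 0L) {
    warning("no L1 pixels selected; ODR forced to 1")
    return(1)
  }
  m1 <- mean(s1); m24 <- mean(s24)
  m24 / (m1 + m24)
}
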