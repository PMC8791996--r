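test_that("background subtraction uses per-band background means and clamps at zero", {
  px <- matrix(10, 20, 10)
  mk <- function(rows) { m <- matrix(FALSE, 20, 10); m[rows, 1:8] <- TRUE; m }
  bg <- function(rows) { m <- matrix(FALSE, 20, 10); m[rows, 9:10] <- TRUE; m }
  img <- laminar_image(px, 1, mk(1:8), mk(11:20), bg(1:8), bg(11:20))
  expect_equal(unique(as.vector(subtract_background(img)$pixels[img$mask_L1])), 0)

  px2 <- px; px2[1:8, 1:8] <- 50
  img2 <- laminar_image(px2, 1, mk(1:8), mk(11:20), bg(1:8), bg(11:20))
  expect_equal(unique(as.vector(subtract_background(img2)$pixels[img2$mask_L1])), 40)

  px3 <- px; px3[11, 1] <- 4   # below background mean 10 -> clamped
  img3 <- laminar_image(px3, 1, mk(1:8), mk(11:20), bg(1:8), bg(11:20))
  expect_equal(subtract_background(img3)$pixels[11, 1], 0)

  img_nobg <- laminar_image(px, 1, mk(1:8), mk(11:20),
                            matrix(FALSE, 20, 10), bg(11:20))
  expect_error(subtract_background(img_nobg), "background")
})

test_that("disk smoothing is an identity at radius 0 and a local disk mean otherwise", {
  px <- matrix(0, 11, 11)
  px[6, 6] <- 100
  mk <- matrix(TRUE, 11, 11)
  f <- matrix(FALSE, 11, 11)
  img <- laminar_image(px, 1, mk, f, f, f)
  expect_identical(smooth_disk(img, 0)$pixels, px)
  # constant image unchanged for any radius
  imgc <- laminar_image(matrix(7, 11, 11), 1, mk, f, f, f)
  expect_equal(smooth_disk(imgc, 3)$pixels, matrix(7, 11, 11))
  # 1-px disk holds 5 pixels: the bright pixel spreads to 100/5 at the centre
  sm <- smooth_disk(img, 1)
  expect_equal(sm$pixels[6, 6], 20)
  expect_equal(sm$pixels[5, 6], 20)
  expect_equal(sm$pixels[5, 5], 0)
})

test_that("range- and rank-based pixel selection follow the threshold rules", {
  expect_setequal(select_pixels(c(10, 50, 100), fraction = 0.7), c(50, 100))
  expect_setequal(select_pixels(c(10, 50, 100), fraction = 1), c(10, 50, 100))
  # threshold (1 - 0.1) * 100 = 90, inclusive
  expect_setequal(select_pixels(1:100, fraction = 0.1), 90:100)
  expect_setequal(select_pixels(1:100, fraction = 0.1, mode = "rank"), 91:100)
  # exclude_top removes the brightest core first
  expect_setequal(select_pixels(1:100, fraction = 1, exclude_top = 0.1), 1:90)
  expect_length(select_pixels(c(0, 0, 0), fraction = 0.7), 0)
  expect_error(select_pixels(numeric(0)), "empty")
})

test_that("the ODR of rendered two-band sections equals the analytic ratio", {
  r <- render_laminar_image(0.6)
  expect_equal(compute_odr(r$image, fraction = 1, radius_um = 0),
               0.6, tolerance = 1e-9)
  # default pipeline smooths across band edges: agreement to ~1e-3
  expect_equal(compute_odr(r$image), 0.6, tolerance = 1e-3)
  # symmetric bands at target 0.5
  r5 <- render_laminar_image(0.5)
  expect_equal(compute_odr(r5$image), 0.5, tolerance = 1e-3)
  # feedforward-band fixture lands in the (0.61, 0.88) range
  rff <- render_laminar_image(0.75, noise_sd = 2, seed = 4)
  odr_ff <- compute_odr(rff$image)
  expect_gt(odr_ff, 0.61); expect_lt(odr_ff, 0.88)
})

test_that("the ODR is scale invariant and mask swap maps p to 1 - p", {
  r <- render_laminar_image(0.7)
  img <- r$image
  img2 <- img; img2$pixels <- img$pixels * 3.7
  expect_equal(compute_odr(img2), compute_odr(img), tolerance = 1e-12)
  swapped <- img
  swapped$mask_L1 <- img$mask_L24; swapped$mask_L24 <- img$mask_L1
  swapped$bg_L1 <- img$bg_L24; swapped$bg_L24 <- img$bg_L1
  expect_equal(compute_odr(swapped), 1 - compute_odr(img), tolerance = 1e-9)
})

test_that("selection thresholds preserve the ordering of a monotone fixture series", {
  targets <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  for (fr in c(0.1, 0.7, 0.9)) {
    odrs <- vapply(seq_along(targets), function(i)
      compute_odr(render_laminar_image(targets[i], noise_sd = 1,
                                       seed = i)$image, fraction = fr), 0)
    expect_true(all(diff(odrs) > 0))
  }
})

test_that("label only in one band forces the ODR to the boundary with a warning", {
  r <- render_laminar_image(0.5)
  img <- r$image
  img$pixels[img$mask_L24] <- mean(img$pixels[img$bg_L24])  # L2-4 at background
  expect_warning(v <- compute_odr(img, radius_um = 0), "forced to 0")
  expect_equal(v, 0)
})

test_that("images and rectangle/polygon masks round-trip through PNG + JSON", {
  r <- render_laminar_image(0.64)
  ip <- tempfile(fileext = ".png"); mp <- tempfile(fileext = ".json")
  write_laminar_image(r$image, ip, mp)
  img <- read_laminar_image(ip, mp)
  expect_identical(img$mask_L1, r$image$mask_L1)
  expect_identical(img$mask_L24, r$image$mask_L24)
  expect_equal(compute_odr(img), 0.64, tolerance = 5e-3)  # 8-bit quantisation

  # polygon region covering the same rectangle selects the same pixels
  ann <- jsonlite::read_json(mp, simplifyVector = FALSE)
  rect <- ann$L1[[1]]
  ann$L1 <- list(list(type = "polygon",
                      x = c(rect$x0, rect$x1 - 1, rect$x1 - 1, rect$x0),
                      y = c(rect$y0, rect$y0, rect$y1 - 1, rect$y1 - 1)))
  mp2 <- tempfile(fileext = ".json")
  jsonlite::write_json(ann, mp2, auto_unbox = TRUE, digits = NA)
  img2 <- read_laminar_image(ip, mp2)
  expect_identical(img2$mask_L1, img$mask_L1)
})
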