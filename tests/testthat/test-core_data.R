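test_that("logit and inverse logit behave as the clipped transform pair", {
  expect_identical(logit(0.5), 0)
  expect_equal(logit(0.88), 1.9924, tolerance = 1e-3)
  expect_equal(logit(0), log(1e-3 / (1 - 1e-3)))
  expect_equal(logit(1, eps = 0.01), log(0.99 / 0.01))
  expect_error(logit(1.2), "outside")
  expect_error(logit(0.5, eps = 0.7), "eps")
  # odd about p = 0.5
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(logit(p), -logit(1 - p), tolerance = 1e-12)
  # monotone
  expect_true(all(diff(logit(p)) > 0))
  # round trips
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(logit(0.7)), 0.7, tolerance = 1e-12)
  expect_gt(inv_logit(20), 0.999999)
})

test_that("edge tables are validated row by row against the catalog", {
  cat3 <- toy_catalog(3)
  tab <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                    section_id = 1:3, odr = c(0.6, 0.5, 0.4))
  f <- tempfile(fileext = ".tsv")
  write_edge_table(tab, f)
  got <- read_edge_table(f, cat3)
  expect_equal(got, tab)

  bad_area <- tab; bad_area$source[2] <- "XX"
  expect_error(validate_edge_table(bad_area, cat3), "XX")
  self <- tab; self$target[1] <- "A"
  expect_error(validate_edge_table(self, cat3), "self-loop")
  oob <- tab; oob$odr[3] <- 1.4
  expect_error(validate_edge_table(oob, cat3), "\\[0, 1\\]")
})

test_that("pathway averaging builds the directed matrix with explicit missingness", {
  cat3 <- toy_catalog(3)
  obs <- data.frame(source = c("A", "A", "A", "B"), target = c("B", "B", "B", "A"),
                    section_id = c(1:3, 1), odr = c(0.6, 0.6, 0.6, 0.3))
  m <- suppressWarnings(build_odr_matrix(obs, cat3))
  expect_equal(m$values["A", "B"], 0.6)
  expect_equal(m$values["B", "A"], 0.3)
  expect_true(is.na(m$values["A", "C"]))   # unobserved pathway
  expect_true(all(is.na(diag(m$values))))
  expect_equal(m$n_sections["A", "B"], 3L)
  expect_warning(build_odr_matrix(obs, cat3), "fewer than 3")

  # invariant to row order of the edge table
  m2 <- suppressWarnings(build_odr_matrix(obs[sample.int(nrow(obs)), ], cat3))
  expect_identical(m2$values, m$values)
})

test_that("the default synthetic network fills 80 cells and leaves 10 missing", {
  sim <- simulate_odr(sim_config(), seed = 11)
  m <- build_odr_matrix(sim$observations, area_catalog())
  expect_equal(sum(!is.na(m$values)), 80L)
  off_diag <- sum(upper.tri(m$values) | lower.tri(m$values))
  expect_equal(off_diag - sum(!is.na(m$values)), 10L)
})

test_that("catalog and matrix round-trip through their file formats", {
  cat10 <- area_catalog()
  f <- tempfile(fileext = ".json")
  write_area_catalog(cat10, f)
  got <- read_area_catalog(f)
  expect_equal(got$names, cat10$names)
  expect_equal(got$streams, cat10$streams)
  expect_equal(got$reference, cat10$reference)

  sim <- simulate_odr(sim_config(), seed = 2)
  m <- build_odr_matrix(sim$observations, cat10)
  g <- tempfile(fileext = ".tsv")
  write_odr_matrix(m, g)
  m2 <- read_odr_matrix(g, cat10)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
})

test_that("catalog construction enforces its invariants", {
  expect_error(area_catalog(names = c("A", "A"),
                            streams = c(A = "dorsal"), reference = "A"))
  expect_error(area_catalog(names = c("A", "B"),
                            streams = c(A = "dorsal", B = "dorsal"),
                            reference = "Z"), "reference")
  expect_error(area_catalog(names = c("A", "B"),
                            streams = c(A = "dorsal"), reference = "A"),
               "stream")
})
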