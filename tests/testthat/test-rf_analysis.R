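test_that("noiseless Gaussian maps are recovered to high precision", {
  sim <- simulate_rf_maps(c(V1 = 12), units_per_area = 3, seed = 5)
  for (u in unique(sim$maps$unit_id)) {
    fit <- fit_gaussian_rf(sim$maps[sim$maps$unit_id == u, ])
    tru <- sim$truth[sim$truth$unit_id == u, ]
    expect_true(fit$converged)
    expect_equal(unname(fit$center["azimuth"]), tru$center_x, tolerance = 1e-6)
    expect_equal(unname(fit$center["elevation"]), tru$center_y, tolerance = 1e-6)
    # axis-swap ambiguity: compare the sorted sigmas and the diameter
    expect_equal(sort(c(fit$sigma_x, fit$sigma_y)),
                 sort(c(tru$sigma_x, tru$sigma_y)), tolerance = 1e-6)
    expect_equal(fit$diameter_deg, tru$diameter_deg, tolerance = 1e-6)
    expect_equal(fit$amplitude, tru$amplitude, tolerance = 1e-6)
    expect_equal(fit$baseline, tru$baseline, tolerance = 1e-6)
  }
})

test_that("degenerate maps are rejected", {
  grid <- expand.grid(azimuth = seq(-10, 10, 5), elevation = seq(-10, 10, 5))
  flat <- data.frame(grid, rate = 3)
  expect_error(fit_gaussian_rf(flat), "constant")
  expect_error(fit_gaussian_rf(flat[1:4, ]), "6 distinct")
})

test_that("the equal-area 2-SD diameter has its defining geometry", {
  expect_equal(rf_diameter(list(sigma_x = 5, sigma_y = 5)), 20)
  expect_equal(rf_diameter(list(sigma_x = 4, sigma_y = 9)), 24)
  # homogeneity and axis-swap/orientation invariance
  expect_equal(rf_diameter(list(sigma_x = 3 * 4, sigma_y = 3 * 9)), 3 * 24)
  expect_equal(rf_diameter(list(sigma_x = 9, sigma_y = 4)), 24)
  # area of the 2-SD ellipse equals the area of the equal-diameter circle
  sx <- 2.3; sy <- 7.1
  d <- rf_diameter(list(sigma_x = sx, sigma_y = sy))
  expect_equal(pi * (2 * sx) * (2 * sy), pi * (d / 2)^2, tolerance = 1e-12)
})

test_that("the fit is translation equivariant", {
  sim <- simulate_rf_maps(c(V1 = 15), units_per_area = 1, seed = 9)
  map <- sim$maps
  f0 <- fit_gaussian_rf(map)
  map2 <- map
  map2$azimuth <- map2$azimuth + 7
  map2$elevation <- map2$elevation - 3
  f1 <- fit_gaussian_rf(map2)
  expect_equal(unname(f1$center["azimuth"] - f0$center["azimuth"]), 7,
               tolerance = 1e-6)
  expect_equal(unname(f1$center["elevation"] - f0$center["elevation"]), -3,
               tolerance = 1e-6)
  expect_equal(f1$diameter_deg, f0$diameter_deg, tolerance = 1e-6)
})

test_that("RF sizes exactly linear in level give a perfect correlation", {
  lv <- c(V1 = 0, LM = 0.5, LI = 1.5, POR = 2)
  diam <- data.frame(
    area = rep(names(lv), each = 3),
    diameter_deg = rep(10 + 10 * lv, each = 3) + rep(c(-0.5, 0, 0.5), 4))
  rep_ <- hierarchy_rf_consistency(lv, diam)
  expect_equal(rep_$pearson$r, 1, tolerance = 1e-9)
  expect_equal(rep_$per_area$n, rep(3L, 4), ignore_attr = TRUE)
})

test_that("level-diameter correlation p-values are calibrated under the null", {
  set.seed(17)
  lv <- setNames(seq(0, 2, length.out = 8), letters[1:8])
  p <- replicate(400, {
    dm <- setNames(rnorm(8, 20, 4), names(lv))
    pearson(lv, dm)$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
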