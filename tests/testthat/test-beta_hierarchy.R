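test_that("the incidence design encodes source/target polarity and group merges", {
  cat10 <- area_catalog()
  lv <- setNames(seq(0, 2, length.out = 10), cat10$names)
  m <- noise_free_matrix(lv, cat10)
  des <- build_incidence(m)
  expect_equal(dim(des$X), c(90L, 9L))
  r_v1lm <- which(des$edges$source == "V1" & des$edges$target == "LM")
  expect_equal(unname(des$X[r_v1lm, "LM"]), 1)         # target +1
  expect_equal(sum(des$X[r_v1lm, ] != 0), 1L)          # V1 column dropped
  r_lmal <- which(des$edges$source == "LM" & des$edges$target == "AL")
  expect_equal(sum(des$X[r_lmal, ]), 0)                # -1 and +1 cancel

  sim <- simulate_odr(sim_config(), seed = 1)
  m80 <- build_odr_matrix(sim$observations, cat10)
  expect_equal(dim(build_incidence(m80)$X), c(80L, 9L))

  # merging LM and RL sums their columns; within-group edges become all-zero
  part <- level_partition(list("V1", c("LM", "RL"), "AL", "P", "LI", "PM",
                               "AM", "A", "POR"), cat10)
  desm <- build_incidence(m, part)
  expect_equal(ncol(desm$X), 8L)
  r_lm_rl <- which(desm$edges$source == "LM" & desm$edges$target == "RL")
  expect_true(all(desm$X[r_lm_rl, ] == 0))
  r_v1_rl <- which(desm$edges$source == "V1" & desm$edges$target == "RL")
  expect_equal(unname(desm$X[r_v1_rl, "LM/RL"]), 1)
})

test_that("level partitions must cover the catalog exactly", {
  cat3 <- toy_catalog(3)
  expect_error(level_partition(list("A", "B"), cat3), "cover")
  expect_error(level_partition(list(c("A", "B"), c("B", "C")), cat3), "cover")
  p <- level_partition(list(c("C", "B"), "A"), cat3)
  expect_equal(p$labels, c("A", "B/C"))   # canonical order
  expect_equal(p$reference_group, 1L)
})

test_that("the beta log-density matches closed forms and normalises", {
  expect_equal(beta_log_density(0.37, mu = 0.5, phi = 2), 0)  # Beta(1,1)
  expect_equal(beta_log_density(0.5, mu = 0.5, phi = 4), log(1.5))
  expect_equal(beta_log_density(0.3, 0.6, 11), dbeta(0.3, 0.6 * 11, 0.4 * 11,
                                                     log = TRUE))
  z <- integrate(function(x) exp(beta_log_density(x, 0.27, 8.5)), 0, 1)
  expect_equal(z$value, 1, tolerance = 1e-6)
  expect_error(beta_log_density(1.2, 0.5, 2), "\\(0, 1\\)")
})

test_that("noise-free data are recovered exactly with the precision at its bound", {
  cat10 <- area_catalog()
  lv <- setNames(seq(0, 2, length.out = 10), cat10$names)
  m <- noise_free_matrix(lv, cat10)
  fit <- fit_hierarchy(m)
  expect_identical(fit$levels[["V1"]], 0)   # reference pinned exactly
  expect_equal(fit$levels, lv, tolerance = 1e-6)
  expect_true(fit$phi_at_bound)
})

test_that("the reported log-likelihood equals the summed log-density at the optimum", {
  sim <- simulate_odr(sim_config(), seed = 13)
  m <- build_odr_matrix(sim$observations, area_catalog())
  fit <- fit_hierarchy(m)
  des <- build_incidence(m)
  y <- pmin(pmax(des$edges$odr, 1e-3), 1 - 1e-3)
  mu <- plogis(drop(des$X %*% fit$delta))
  expect_equal(fit$log_likelihood, sum(beta_log_density(y, mu, fit$phi)),
               tolerance = 1e-10)
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$n_params)
  expect_true(fit$converged)
  # goodness-of-fit report on n - 2 df
  expect_equal(fit$gof$df, fit$n_obs - 2L)
  expect_gt(fit$gof$r, 0.8)
})

test_that("adding a constant to all true levels leaves the fit unchanged", {
  cat5 <- toy_catalog(5)
  lv <- c(A = 0, B = 0.4, C = 0.9, D = 1.3, E = 1.8)
  f1 <- fit_hierarchy(noise_free_matrix(lv, cat5))
  f2 <- fit_hierarchy(noise_free_matrix(lv + 5, cat5))
  expect_equal(f1$delta, f2$delta, tolerance = 1e-6)
})

test_that("finer nested partitions never lose log-likelihood", {
  sim <- simulate_odr(sim_config(), seed = 23)
  m <- build_odr_matrix(sim$observations, area_catalog())
  coarse <- level_partition(list("V1", c("LM", "RL"),
                                 c("A", "AL", "PM", "P"),
                                 c("LI", "AM"), "POR"), area_catalog())
  f_fine <- fit_hierarchy(m)
  f_coarse <- fit_hierarchy(m, coarse)
  expect_gte(f_fine$log_likelihood, f_coarse$log_likelihood - 1e-8)
})

test_that("a disconnected group graph raises an identifiability error", {
  cat4 <- toy_catalog(4)
  obs <- data.frame(source = c("A", "B", "C", "D"),
                    target = c("B", "A", "D", "C"),
                    section_id = 1L, odr = c(0.6, 0.4, 0.7, 0.3))
  m <- suppressWarnings(build_odr_matrix(obs, cat4, 1L))
  expect_error(fit_hierarchy(m), "singular design")
})

test_that("Wald contrasts reduce correctly and classify separated levels", {
  cat4 <- toy_catalog(4)
  lv <- c(A = 0, B = 0, C = 3, D = 3)
  sim_obs <- local({
    set.seed(77)
    grid <- expand.grid(source = cat4$names, target = cat4$names,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target, ]
    grid$section_id <- 1L
    mu <- plogis(lv[grid$target] - lv[grid$source])
    grid$odr <- rbeta(nrow(grid), mu * 50, (1 - mu) * 50)
    grid
  })
  m <- suppressWarnings(build_odr_matrix(sim_obs, cat4, 1L))
  part <- level_partition(list(c("A", "B"), c("C", "D")), cat4)
  fit <- fit_hierarchy(m, part)
  same <- wald_pairwise(fit, "A/B", "A/B")
  expect_equal(same$z, 0); expect_equal(same$p_value, 1)
  # contrast vs the reference group reduces to delta / se
  w <- wald_pairwise(fit, "C/D", "A/B")
  expect_equal(w$z, fit$delta[["C/D"]] / fit$se[["C/D"]], tolerance = 1e-10)

  cls <- classify_edges(fit, m)
  expect_true(all(cls$label[cls$source %in% c("A", "B") &
                            cls$target %in% c("C", "D")] == "FF"))
  expect_true(all(cls$label[cls$source %in% c("C", "D") &
                            cls$target %in% c("A", "B")] == "FB"))
  expect_true(all(cls$label[cls$source == "A" & cls$target == "B"] == "LAT"))

  summ <- class_odr_summary(cls)
  expect_setequal(summ$summary$class, c("FF", "LAT", "FB"))
  expect_gt(summ$summary$mean[summ$summary$class == "FF"],
            summ$summary$mean[summ$summary$class == "FB"])
})

test_that("identical class distributions give a zero ANOVA F", {
  summ <- class_odr_summary(list(FF = rep(0.5, 5), LAT = rep(0.5, 5),
                                 FB = rep(0.5, 5)))
  expect_equal(summ$anova$f_statistic, 0)
})

test_that("level scaling maps endpoints linearly and idempotently", {
  expect_equal(scale_levels(c(a = 0, b = 1), 1, 10), c(a = 1, b = 10))
  expect_equal(scale_levels(c(a = 0, b = 0.5, c = 1), 1, 10),
               c(a = 1, b = 5.5, c = 10))
  once <- scale_levels(c(a = 0, b = 0.3, c = 2), 1, 10)
  expect_equal(scale_levels(once, 1, 10), once)
  expect_error(scale_levels(c(a = 1, b = 1)), "equal")
})

test_that("model search ranks by AIC with the documented strategies", {
  sim <- simulate_odr(sim_config(), seed = 31)
  m <- build_odr_matrix(sim$observations, area_catalog())
  # explicit list with one partition -> single fit
  one <- model_search(m, "explicit",
                      partitions = list(as.list(area_catalog()$names)))
  expect_length(one$fits, 1L)
  s <- model_search(m, "ladder")
  expect_equal(nrow(s$table), 8L)
  expect_true(!is.unsorted(s$table$AIC))
  expect_equal(s$best$aic, min(s$table$AIC))
  s_cum <- model_search(m, "cumulative_top")
  expect_equal(nrow(s_cum$table), 9L)
  # the all-singleton model appears in every strategy
  expect_true(any(s_cum$table$n_levels == 10L))
})
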