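test_that("noiseless cell means give back the generative shifts exactly", {
  cm <- generate_noiseless_cell_means(experiment_design(), recovery_params(1))
  fit <- grid_fit(cm, "two_shift", k_grid = 12:36, h_grid = -4:20)
  expect_equal(fit$k, 24)
  expect_equal(fit$h, 8)
  expect_gt(fit$r_squared, 1 - 1e-8)
  expect_equal(fit$logistic$inflection, 30, tolerance = 1e-2)
})

test_that("zero generative shifts are recovered as the parsimonious optimum", {
  cm <- generate_noiseless_cell_means(experiment_design(),
                                      recovery_params(1, true_k = 0, true_h = 0))
  fit <- grid_fit(cm, "two_shift", k_grid = -6:6, h_grid = -6:6)
  expect_equal(fit$k, 0)
  expect_equal(fit$h, 0)
})

test_that("the returned optimum certifies itself against the whole grid", {
  tr <- generate_choices(experiment_design(n_participants = 24),
                         recovery_params(seed = 61, participant_sd = 2))
  fit <- grid_fit(aggregate_choices(tr), "two_shift",
                  k_grid = 14:34, h_grid = -2:18)
  expect_gte(fit$r_squared, max(fit$grid$r_squared) - 1e-12)
  # the stored surface contains every evaluated grid point
  expect_equal(nrow(fit$grid), 21 * 21)
  expect_true(all(c(14, 34) %in% fit$grid$k))
  # winner appears in the surface at its reported R^2
  i <- which(fit$grid$k == fit$k & fit$grid$h == fit$h)
  expect_equal(fit$grid$r_squared[i], fit$r_squared, tolerance = 1e-12)
})

test_that("predictions are non-decreasing in Phi", {
  tr <- generate_choices(experiment_design(n_participants = 16),
                         recovery_params(seed = 62, participant_sd = 3))
  fit <- grid_fit(aggregate_choices(tr), "two_shift",
                  k_grid = 16:32, h_grid = 0:16)
  pts <- fit$fitted_points
  expect_true(all(diff(pts$predicted[order(pts$phi)]) >= -1e-12))
})

test_that("one-shift fits keep both difficulty-paired points", {
  cm <- generate_noiseless_cell_means(experiment_design(),
                                      recovery_params(1, true_k = 0, true_h = 7))
  fit <- grid_fit(cm, "one_shift", h_grid = -6:20)
  expect_equal(fit$h, 7)
  expect_true(is.na(fit$k))
  expect_equal(nrow(fit$fitted_points), 12)   # paired cells both retained
  expect_equal(length(unique(fit$fitted_points$phi)), 6)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("transfer fit frozen at the free optimum reproduces it", {
  tr <- generate_choices(experiment_design(n_participants = 24),
                         recovery_params(seed = 63, participant_sd = 1))
  ct <- aggregate_choices(tr)
  free <- grid_fit(ct, "two_shift", k_grid = 16:32, h_grid = 0:16)
  frozen <- transfer_fit(ct, fixed_h = free$h, variant = "two_shift",
                         k_grid = 16:32)
  expect_equal(frozen$h, free$h)
  expect_equal(frozen$k, free$k)
  expect_equal(frozen$r_squared, free$r_squared, tolerance = 1e-7)
  expect_true(frozen$fixed_h)
})

test_that("transfer fit far from the optimum degrades the noiseless fit", {
  cm <- generate_noiseless_cell_means(experiment_design(), recovery_params(1))
  frozen <- transfer_fit(cm, fixed_h = 24, variant = "two_shift",
                         k_grid = 12:36)
  expect_lt(frozen$r_squared, 1 - 1e-3)
})

test_that("degenerate inputs are rejected", {
  cm <- generate_noiseless_cell_means(experiment_design(), recovery_params(1))
  expect_error(grid_fit(cm[-3, ], "two_shift", k_grid = 0:1, h_grid = 0:1),
               "missing cell")
  expect_error(grid_fit(rbind(cm, cm[1, ]), "two_shift",
                        k_grid = 0:1, h_grid = 0:1), "duplicated")
  flat <- cm; flat$p_bucket <- 0.5
  expect_error(grid_fit(flat, "two_shift", k_grid = 0:1, h_grid = 0:1),
               "identical")
  expect_error(phifit(cm, "two_shift", k_grid = integer(0)), "k_grid")
})

test_that("phifit accepts trials, choice tables, and bare cell means", {
  tr <- generate_choices(experiment_design(n_participants = 12),
                         recovery_params(seed = 64))
  ct <- aggregate_choices(tr)
  f1 <- phifit(tr, "two_shift", k_grid = 20:28, h_grid = 4:12)
  f2 <- phifit(ct, "two_shift", k_grid = 20:28, h_grid = 4:12)
  f3 <- phifit(ct$group, "two_shift", k_grid = 20:28, h_grid = 4:12)
  expect_equal(f1$k, f2$k)
  expect_equal(f2$k, f3$k)
  expect_equal(f1$r_squared, f3$r_squared, tolerance = 1e-12)
})

test_that("phifit methods expose the fit coherently", {
  cm <- generate_noiseless_cell_means(experiment_design(), recovery_params(1))
  fit <- grid_fit(cm, "two_shift", k_grid = 20:28, h_grid = 4:12)
  cf <- coef(fit)
  expect_named(cf, c("k", "h", "lower", "upper", "inflection", "steepness"))
  expect_equal(unname(cf["k"]), 24)
  expect_equal(residuals(fit), fit$fitted_points$observed - fitted(fit))
  expect_equal(predict(fit, phi = fit$logistic$inflection),
               (fit$logistic$lower + fit$logistic$upper) / 2)
  # predict on new cells matches the mapping + curve composition
  nd <- data.frame(bucket_weight_kg = 0, difficulty = "hard", duration_s = 27)
  expect_equal(predict(fit, nd),
               logistic_value(27 + fit$k + fit$h, fit$logistic))
  expect_output(print(fit), "k \\(harder cognitive task\\)")
  expect_output(print(summary(fit)), "Fitted points")
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 48 * 24)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("the fitted R^2 recomputes from the reported points", {
  tr <- generate_choices(experiment_design(n_participants = 20),
                         recovery_params(seed = 65, participant_sd = 2))
  fit <- grid_fit(aggregate_choices(tr), "two_shift",
                  k_grid = 16:32, h_grid = 0:16)
  expect_equal(r_squared(fit$fitted_points$observed, fit$fitted_points$predicted),
               fit$r_squared, tolerance = 1e-10)
})
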