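# The recovery grids here sit in the dose field's identifiable regime (gate
# edge mid-well, pronounced two-step plateau); see the methods vignette for
# how the validation design was chosen.

test_that("noiseless on-grid data is recovered exactly", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  ds <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0, seed = 1)
  fit <- fit_thresholds(ds, pip$field, pip$mesh,
                        pth_grid = seq(2000, 3000, by = 250),
                        wth_grid = seq(8, 12, by = 1))
  expect_identical(fit$best$pth, 2500)
  expect_identical(fit$best$wth, 10)
  expect_identical(fit$best$objective_mm2, 0)
  expect_false(fit$best$degenerate)
})

test_that("fitting is deterministic and order-invariant", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  ds <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0.02, seed = 5)
  grids <- list(pth_grid = seq(2000, 3000, by = 250), wth_grid = seq(8, 12, by = 1))
  f1 <- do.call(fit_thresholds, c(list(ds, pip$field, pip$mesh), grids))
  f2 <- do.call(fit_thresholds, c(list(ds, pip$field, pip$mesh), grids))
  expect_identical(f1$best, f2$best)
  expect_identical(f1$grid, f2$grid)
  shuffled <- plasma_experiment(ds[sample(nrow(ds)), ])
  f3 <- do.call(fit_thresholds, c(list(shuffled, pip$field, pip$mesh), grids))
  expect_identical(f1$best, f3$best)
  # averaging replicates beforehand leaves the objective unchanged
  pre <- dataset_summary(ds) |>
    dplyr::transmute(duration_ms, replicate = 1L, radius_mm = mean_radius_mm) |>
    plasma_experiment()
  f4 <- do.call(fit_thresholds, c(list(pre, pip$field, pip$mesh), grids))
  expect_identical(f1$best, f4$best)
})

test_that("ill-posed and degenerate inputs are flagged", {
  pip <- pd_pipeline()
  one <- plasma_experiment(tibble::tibble(duration_ms = 10, replicate = 1:4,
                                          radius_mm = c(1, 1.1, 0.9, 1)))
  expect_error(fit_thresholds(one, pip$field, pip$mesh), "2 distinct")
  zero <- plasma_experiment(tibble::tibble(
    duration_ms = rep(c(2, 10, 50), each = 2), replicate = rep(1:2, 3),
    radius_mm = 0))
  fit <- fit_thresholds(zero, pip$field, pip$mesh,
                        pth_grid = seq(0, 20, 5), wth_grid = c(0.1, 1e5, 2e5),
                        refine = FALSE)
  expect_true(fit$best$degenerate)
  expect_identical(fit$best$wth, 2e5)  # boundary of the zero-death ridge
})

test_that("tidy and glance summarise the objective surface", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  ds <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0, seed = 2)
  fit <- fit_thresholds(ds, pip$field, pip$mesh,
                        pth_grid = c(2000, 2500), wth_grid = c(9, 10),
                        refine = FALSE)
  td <- tidy(fit)
  expect_identical(nrow(td), 4L)
  expect_true(all(td$objective_mm2 >= 0))
  gl <- glance(fit)
  expect_identical(gl$pth, 2500)
  expect_equal(gl$rmse_mm, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$best_Pth_uW_mm3, 2500)
})

test_that("effective pth recovers the generating gate on unsuppressed data", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  ds <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0, seed = 3)
  prof <- effective_pth(ds, pip$field, pip$mesh, wth = 10,
                        bracket = c(0, 30000))
  expect_true(all(prof$converged))
  # flat at the truth within the bisection tolerance (0.5% of the bracket)
  expect_true(all(abs(prof$effective_pth - 2500) <= 0.005 * 30000 + 1e-9))
})

test_that("a shrunken radius maps to a raised effective pth", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  base <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0, seed = 3)
  shrunk <- plasma_experiment(dplyr::mutate(base, radius_mm = radius_mm * 0.85))
  prof <- effective_pth(shrunk, pip$field, pip$mesh, wth = 10,
                        bracket = c(0, 30000))
  expect_true(all(prof$effective_pth > 2500))
})

test_that("bisection agrees with a dense grid-scan oracle", {
  pip <- pd_pipeline()
  truth <- death_model(pth = 2500, wth = 10)
  ds <- generate_dataset(pip$field, pip$mesh, truth, noise_sd_mm = 0, seed = 3,
                         short_suppression = 0.25)
  prof <- effective_pth(ds, pip$field, pip$mesh, wth = 10, bracket = c(0, 30000))
  smry <- dataset_summary(ds)
  wth_si <- convert_energy_density(10, "uJ/mm3", "J/m3")
  for (d in c(2, 8)) {
    r_obs <- smry$mean_radius_mm[smry$duration_ms == d]
    grid <- seq(0, 20000, length.out = 401)
    resid <- vapply(grid, function(p) {
      prm <- death_model(pth = p, wth = 10)
      abs(death_radius(pip$field, pip$mesh, prm, d / 1e3)$radius * 1e3 - r_obs)
    }, numeric(1))
    p_oracle <- grid[which.min(resid)]
    p_bis <- prof$effective_pth[prof$duration_ms == d]
    expect_lt(abs(p_bis - p_oracle), 0.01 * 30000)
  }
})

test_that("unattainable radii are flagged non-convergent", {
  pip <- pd_pipeline()
  ds <- plasma_experiment(tibble::tibble(duration_ms = c(2, 2, 4, 4),
                                         replicate = c(1, 2, 1, 2),
                                         radius_mm = c(3, 3, 3.1, 3.1)))
  prof <- effective_pth(ds, pip$field, pip$mesh, wth = 10, bracket = c(0, 30000))
  expect_true(all(!prof$converged))
  expect_true(all(is.na(prof$effective_pth)))
})
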