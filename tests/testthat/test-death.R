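# thresholds here are in reporting units: pth in uW/mm3, wth in uJ/mm3

test_that("time to death has the exact closed form on a constant-power field", {
  # quadrature components give p(t) = 1000 W/m3 constant
  fc <- synthetic_field(Jr = sqrt(1000), Jz = sqrt(1000) * 1i)
  # one-step: T* = Wth / p = 300 / 1000 = 0.3 s
  prm <- death_model(wth = 0.3, model = "one_step")
  expect_equal(time_to_death(fc, 1, prm, tp_max = 1), 0.3, tolerance = 1e-9)
  # Heaviside gate with H(0) = 1: a gate exactly at p still accumulates
  at <- death_model(pth = 1 - 1e-9, wth = 0.3)  # 1 uW/mm3 = 1000 W/m3
  expect_equal(time_to_death(fc, 1, at, tp_max = 1), 0.3, tolerance = 1e-6)
  # gate strictly above the peak never opens: censored
  over <- death_model(pth = 1.001, wth = 0.3)
  expect_true(is.na(time_to_death(fc, 1, over, tp_max = 1)))
  # not reached within tp_max is censored too
  expect_true(is.na(time_to_death(fc, 1, prm, tp_max = 0.2)))
})

test_that("gated accumulation matches the closed form for a sine-squared gate", {
  # p(t) = p0 sin^2(wt); gate at p0/2 admits |sin| >= sqrt(1/2), and the
  # gated integral per cycle is p0 T (1/4 + 1/(2 pi))
  p0 <- 2000
  f <- synthetic_field(Jr = 0, Jz = sqrt(p0))
  period <- 1 / 20e3
  rate <- p0 * (1 / 4 + 1 / (2 * pi))  # gated energy per unit time
  wth_si <- 300
  prm <- death_model(pth = convert_power_density(p0 / 2, "W/m3", "uW/mm3"),
                     wth = convert_energy_density(wth_si, "J/m3", "uJ/mm3"))
  got <- time_to_death(f, 1, prm, tp_max = 10, samples_per_cycle = 8192L)
  # crossing lands mid-cycle; agreement to the cycle-sampling resolution
  expect_equal(got, wth_si / rate, tolerance = 1e-3)
})

test_that("two-step with pth = 0 reduces exactly to one-step", {
  pip <- pd_pipeline()
  two <- death_curve(pip$field, pip$mesh, death_model(pth = 0, wth = 0.3))
  one <- death_curve(pip$field, pip$mesh, death_model(wth = 0.3, model = "one_step"))
  expect_identical(two$radius_mm, one$radius_mm)
  expect_identical(two$saturated, one$saturated)
})

test_that("time to death is monotone in both thresholds", {
  pip <- pd_pipeline()
  # regions whose peak power clears the largest gate used below
  regions <- c(1, 10, 15, 20)
  for (n in regions) {
    t_w <- vapply(c(1, 5, 20), function(w) {
      time_to_death(pip$field, n, death_model(pth = 100, wth = w), tp_max = 1e3)
    }, numeric(1))
    expect_true(all(diff(t_w) > 0))
    t_p <- vapply(c(0, 500, 2000), function(p) {
      time_to_death(pip$field, n, death_model(pth = p, wth = 5), tp_max = 1e3)
    }, numeric(1))
    expect_true(all(diff(t_p) >= 0))
  }
})

test_that("death radius handles censoring, saturation and interpolation", {
  pip <- pd_pipeline()
  # enormous threshold: no death anywhere
  none <- death_radius(pip$field, pip$mesh, death_model(wth = 1e6, model = "one_step"),
                       tp = 0.02)
  expect_identical(none$radius, 0)
  expect_true(none$censored)
  # tiny threshold: the whole well dies
  all_dead <- death_radius(pip$field, pip$mesh,
                           death_model(wth = 0.001, model = "one_step"), tp = 0.02)
  expect_identical(all_dead$radius, attr(pip$mesh, "well_radius"))
  expect_true(all_dead$saturated)
  # nearest mode snaps onto a region centre
  nr <- death_radius(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3),
                     tp = 0.01, interpolation = "nearest")
  expect_true(nr$radius %in% pip$field$center_radius)
  # monotone in duration
  r1 <- death_radius(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3), tp = 0.002)
  r2 <- death_radius(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3), tp = 0.05)
  expect_gte(r2$radius, r1$radius)
})

test_that("a surviving core is refused as a non-disc prediction", {
  pip <- pd_pipeline()
  # large wth at short tp: the first annulus (weakest dose in the core)
  # outlives regions further out
  expect_error(
    death_radius(pip$field, pip$mesh, death_model(wth = 30, model = "one_step"),
                 tp = 0.002),
    "disc")
})

test_that("death radius agrees with the brute-force oracle within a mesh width", {
  pip <- pd_pipeline()
  set.seed(42)
  cases <- tibble::tibble(pth = runif(5, 0, 4000), wth = runif(5, 0.5, 15),
                          tp = sample(c(0.005, 0.02), 5, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    prm <- death_model(pth = cases$pth[i], wth = cases$wth[i])
    r_pkg <- death_radius(pip$field, pip$mesh, prm, cases$tp[i])$radius
    r_orc <- oracle_death_radius(pip$field, prm$pth_si, prm$wth_si,
                                 cases$tp[i], spc = 256)
    k <- region_at_radius(pip$mesh, max(r_orc, 1e-9))
    expect_lt(abs(r_pkg - r_orc),
              pip$mesh$width[min(k + 1L, 40L)] + pip$mesh$width[k])
  }
})

test_that("death curves are monotone and respect the gate's reach", {
  pip <- pd_pipeline()
  cv <- death_curve(pip$field, pip$mesh, death_model(pth = 2500, wth = 10))
  expect_identical(nrow(cv), 11L)
  expect_true(all(diff(cv$radius_mm) >= 0))
  # the curve can never pass the outermost region whose peak power reaches pth
  pk <- convert_power_density(pip$field$p_peak, "W/m3", "uW/mm3")
  r_gate <- pip$field$center_radius[max(which(pk >= 2500))] * 1e3
  expect_true(all(cv$radius_mm <= r_gate + 1e-12))
})

test_that("sensitivity sweeps order curves by threshold", {
  pip <- pd_pipeline()
  sw_w <- sensitivity_sweep(pip$field, pip$mesh, pth_values = 0,
                            wth_values = c(1, 2, 4),
                            durations_ms = c(2, 10, 50))
  by_w <- tidyr::pivot_wider(sw_w[, c("wth", "duration_ms", "radius_mm")],
                             names_from = "wth", values_from = "radius_mm")
  expect_true(all(by_w$`2` <= by_w$`1` & by_w$`4` <= by_w$`2`))
  sw_p <- sensitivity_sweep(pip$field, pip$mesh,
                            pth_values = c(1500, 2500, 3500), wth_values = 10,
                            durations_ms = c(10, 50, 100))
  by_p <- tidyr::pivot_wider(sw_p[, c("pth", "duration_ms", "radius_mm")],
                             names_from = "pth", values_from = "radius_mm")
  expect_true(all(by_p$`2500` <= by_p$`1500` & by_p$`3500` <= by_p$`2500`))
  empty <- sensitivity_sweep(pip$field, pip$mesh, numeric(0), numeric(0))
  expect_identical(nrow(empty), 0L)
})

test_that("death-curve CSV carries the threshold columns", {
  pip <- pd_pipeline()
  cv <- death_curve(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3),
                    durations_ms = c(2, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_death_curve_csv(cv, path)
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(c("duration_ms", "radius_mm", "Pth_uW_mm3", "Wth_uJ_mm3")
                  %in% names(got)))
  expect_identical(got$Pth_uW_mm3, rep(7, 2))
})
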