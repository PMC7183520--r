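test_that("the NEMA FWHM estimator is exact on triangles and calibrated on Gaussians", {
  # symmetric triangle of base 2a has FWHM = a; linear sides make the
  # interpolated crossings exact
  a <- 3
  mids <- seq(-4, 4, by = 0.1)
  counts <- pmax(0, 1 - abs(mids) / a) * 1e4
  f <- hist_fwhm(counts, mids)
  expect_equal(f$fwhm, a, tolerance = 1e-9)
  # Gaussian samples: FWHM = 2.3548 sigma within 2%
  set.seed(501)
  for (sigma in c(0.5, 2, 40)) {
    x <- rnorm(1e6, 5, sigma)
    f <- sample_fwhm(x, bin = 0.1 * sigma)
    expect_equal(f$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.02)
  }
  expect_error(hist_fwhm(c(1, 2, 1), c(-1, 0, 1)), "5 bins")
  expect_error(hist_fwhm(rep(5, 11), seq(-5, 5)), "crossing")
})

test_that("tails background subtraction leaves the FWHM of a peaked signal unchanged", {
  set.seed(502)
  x <- rnorm(2e5, 0, 1)
  clean <- sample_fwhm(x, 0.1)$fwhm
  h <- hist(x, breaks = seq(-12, 12, 0.1), plot = FALSE)
  pedestal <- h$counts + 150
  dirty <- hist_fwhm(pedestal, h$mids, background = "tails")
  expect_equal(dirty$fwhm, clean, tolerance = 0.02)
  expect_equal(dirty$background, 150, tolerance = 0.05)
})

test_that("the estimator agrees with a dense-grid half-max search within one bin", {
  set.seed(503)
  for (k in 1:100) {
    sigma <- runif(1, 0.5, 3)
    mids <- seq(-12, 12, by = 0.25)
    counts <- 1e4 * (dnorm(mids, 0, sigma) +
                       runif(1, 0, 0.4) * dnorm(mids, 0, sigma * runif(1, 1.5, 3)))
    f <- hist_fwhm(counts, mids)
    # oracle: linear interpolation on a dense grid, direct half-max scan
    grid <- seq(min(mids), max(mids), length.out = 2e4)
    y <- approx(mids, counts, grid)$y
    half <- max(y) / 2
    above <- which(y >= half)
    w_oracle <- grid[max(above)] - grid[min(above)]
    expect_lt(abs(f$fwhm - w_oracle), 0.25)
  }
})

test_that("timing offsets correct for off-centre sources along each LOR", {
  g <- geom_fixture()
  per_mod <- g$n_tang_module * g$n_axial
  # crystal at angle 0 and its antipode: a transverse LOR along x
  c1 <- 0L
  c2 <- 9L * per_mod
  p1 <- crystal_position(g, c1); p2 <- crystal_position(g, c2)
  rec <- data.table(t1_ps = 0, t2_ps = 0, crystal1 = c1, crystal2 = c2,
                    e1_kev = 511, e2_kev = 511, dt_ps = 0,
                    window = "prompt", class = "true")
  ds <- listmode_dataset(rec)
  # source at the LOR midpoint: geometric offset 0, residual = measured dt
  src0 <- source_spec("point", c(0, 0, p1$z))
  expect_equal(timing_residuals(ds, g, src0), 0)
  # source 45 mm toward crystal 1: offset 2*45/c = 300.2 ps
  src45 <- source_spec("point", c(45, 0, p1$z))
  res <- timing_residuals(ds, g, src45)
  d1 <- sqrt(sum((unlist(p1) - c(45, 0, p1$z))^2))
  d2 <- sqrt(sum((unlist(p2) - c(45, 0, p1$z))^2))
  expect_equal(res, -(d2 - d1) / 0.299792458, tolerance = 1e-9)
  expect_equal(abs(res), 2 * 45 / 0.299792458, tolerance = 1e-6)
  expect_equal(abs(res), 300.2, tolerance = 1e-3)
  # far-away LORs are excluded
  expect_identical(length(timing_residuals(ds, g,
                     source_spec("point", c(0, 300, 0)))), 0L)
})

test_that("unblurred trues give sub-50-ps TOF limited only by crystal discretization", {
  g <- geom_fixture()
  cfg <- generator_config(seed = 511, positron_range_fwhm = 0,
                          acollinearity_fwhm_deg = 0)
  vx <- virtual_experiment("point_source",
        list(activity_bq = 8e5, duration_s = 1, position_mm = c(0, 0, 0)), cfg, g)
  det <- run_chain(vx$singles,
                   digitizer_config(noise_rate_cps = 0, time_fwhm_ps = 0,
                                    energy_resolution_511 = 0), 1, g, seed = 512)
  ds <- listmode_dataset(sort_prompts(det, g), duration_s = 1)
  tr <- tof_resolution(ds, g, source_spec("point", c(0, 0, 0)),
                       bin_ps = 1, background = "none")
  expect_lt(tr$fwhm_ps, 50)
})

test_that("default blurs reproduce the 311 ps coincidence timing and 11.2% energy resolution", {
  pt <- point_fixture()
  src <- source_spec("point", pt$pos)
  g <- geom_fixture()
  tr <- tof_resolution(pt$ds, g, src, background = "none")
  expect_gt(tr$n, 1e5)
  expect_equal(tr$fwhm_ps, sqrt(2) * 220, tolerance = 0.02)
  er <- energy_resolution(pt$ds)
  expect_equal(er$fwhm_percent, 11.2, tolerance = 0.02)
})

test_that("TOF and energy resolutions are stable across activity when pile-up losses are small", {
  g <- geom_fixture()
  src <- source_spec("point", c(0, 10, 0))
  vals <- sapply(c(1e6, 3e6), function(a) {
    vx <- virtual_experiment("point_source",
          list(activity_bq = a, duration_s = 0.6, position_mm = c(0, 10, 0)),
          generator_config(seed = 521), g)
    det <- run_chain(vx$singles, digitizer_config(noise_rate_cps = 0),
                     0.6, g, seed = 522)
    ds <- listmode_dataset(sort_prompts(det, g), duration_s = 0.6)
    c(tof = tof_resolution(ds, g, src, background = "none")$fwhm_ps,
      en = energy_resolution(ds)$fwhm_percent)
  })
  expect_lt(abs(vals["tof", 2] / vals["tof", 1] - 1), 0.04)
  expect_lt(abs(vals["en", 2] / vals["en", 1] - 1), 0.04)
})
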