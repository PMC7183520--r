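test_that("noise injection delivers the configured Poisson rate uniformly over crystals", {
  g <- geom_fixture()
  cfg <- digitizer_config()
  set.seed(211)
  s <- inject_noise(empty_singles(), cfg, duration = 2, geom = g)
  expect_lt(abs(nrow(s) - 2 * 461e3), 3 * sqrt(2 * 461e3))
  expect_false(is.unsorted(s$time_ps))
  expect_true(all(s$label == "noise"))
  # uniformity over the 23 040 crystals
  tab <- tabulate(s$crystal + 1L, nbins = g$n_crystals)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
  # zero rate leaves the stream unchanged
  cfg0 <- digitizer_config(noise_rate_cps = 0)
  base <- poisson_stream(1e3, 0.1, g)
  out0 <- inject_noise(base, cfg0, 0.1, g)
  expect_equal(out0$time_ps, base$time_ps)
  expect_identical(out0$crystal, base$crystal)
})

test_that("energy blur reproduces the crystal resolution and its inverse-sqrt scaling", {
  cfg <- digitizer_config()
  set.seed(221)
  s <- data.table(time_ps = seq_len(1e6), crystal = 0L, energy_kev = 511,
                  label = "true", ann_id = NA_integer_)
  b <- blur_energy(s, cfg)
  fwhm <- 2 * sqrt(2 * log(2)) * sd(b$energy_kev)
  expect_equal(fwhm, 0.112 * 511, tolerance = 0.01)     # 57.23 keV
  expect_equal(mean(b$energy_kev), 511, tolerance = 0.001)
  # at 255.5 keV the fractional FWHM grows by sqrt(2)
  s2 <- data.table(time_ps = seq_len(2e5), crystal = 0L, energy_kev = 255.5,
                   label = "true", ann_id = NA_integer_)
  b2 <- blur_energy(s2, cfg)
  frac <- 2 * sqrt(2 * log(2)) * sd(b2$energy_kev) / 255.5
  expect_equal(frac, 0.112 * sqrt(2), tolerance = 0.01)
  # zero resolution is the identity
  cfg0 <- digitizer_config(energy_resolution_511 = 0)
  expect_identical(blur_energy(s, cfg0)$energy_kev, s$energy_kev)
})

test_that("timing blur applies a 220 ps FWHM Gaussian and re-sorts the stream", {
  cfg <- digitizer_config()
  set.seed(231)
  t0 <- sort(runif(1e6, 0, 1e12))
  s <- data.table(time_ps = t0, crystal = 0L, energy_kev = 511,
                  label = "true", ann_id = seq_len(1e6))
  b <- blur_time(s, cfg)
  expect_false(is.unsorted(b$time_ps))
  shifts <- b[order(ann_id), time_ps] - t0
  expect_equal(sd(shifts), 220 / (2 * sqrt(2 * log(2))), tolerance = 0.01)
  cfg0 <- digitizer_config(time_fwhm_ps = 0)
  expect_identical(blur_time(s, cfg0)$time_ps, s$time_ps)
})

test_that("efficiency thinning keeps 86.5% of signal singles and spares noise", {
  cfg <- digitizer_config()
  set.seed(241)
  s <- data.table(time_ps = seq_len(1e6),
                  crystal = 0L, energy_kev = 511,
                  label = rep(c("true", "scatter"), 5e5),
                  ann_id = NA_integer_)
  k <- thin_efficiency(s, cfg)
  expect_lt(abs(nrow(k) - 865e3), 3 * sqrt(1e6 * 0.865 * 0.135))
  # thinning is label-blind for signal
  f_true <- nrow(k[label == "true"]) / 5e5
  f_sc <- nrow(k[label == "scatter"]) / 5e5
  expect_lt(abs(f_true - f_sc), 4 * sqrt(2 * 0.865 * 0.135 / 5e5))
  # noise exempt
  s[, label := "noise"]
  expect_identical(nrow(thin_efficiency(s, cfg)), nrow(s))
  s[, label := "true"]
  expect_identical(nrow(thin_efficiency(s, digitizer_config(efficiency = 1))),
                   nrow(s))
})

test_that("pile-up merges in-window deposits per crystal with summed energies", {
  g <- geom_fixture()
  cfg <- digitizer_config()      # 5.9 ns window, crystal scope
  mk <- function(t_ns, crystal, e) data.table(
    time_ps = t_ns * 1e3, crystal = as.integer(crystal), energy_kev = e,
    label = "true", ann_id = seq_along(t_ns), pileup = 0L)
  # hand trace: 0 and 3 ns in one crystal merge at t = 0 with 550 keV
  m <- apply_pileup(mk(c(0, 3), c(7, 7), c(300, 250)), cfg, g)
  expect_identical(nrow(m), 1L)
  expect_equal(m$time_ps, 0)
  expect_equal(m$energy_kev, 550)
  expect_identical(m$pileup, 1L)
  # outside the window: untouched
  m2 <- apply_pileup(mk(c(0, 7), c(7, 7), c(300, 250)), cfg, g)
  expect_identical(nrow(m2), 2L)
  expect_equal(m2$energy_kev, c(300, 250))
  # different crystals: untouched
  m3 <- apply_pileup(mk(c(0, 1), c(7, 8), c(300, 250)), cfg, g)
  expect_identical(nrow(m3), 2L)
  # anchored window: 0, 5, 11 ns -> {0+5} then {11}
  m4 <- apply_pileup(mk(c(0, 5, 11), c(7, 7, 7), c(100, 100, 100)), cfg, g)
  expect_equal(m4$time_ps, c(0, 11e3))
  expect_equal(m4$energy_kev, c(200, 100))
  expect_error(apply_pileup(mk(c(3, 0), c(7, 7), c(1, 1)), cfg, g), "sorted")
})

test_that("paralyzable deadtime discards re-paralyzed arrivals and obeys the rate law", {
  g <- geom_fixture()
  cfg <- digitizer_config()
  mk <- function(t_ns, crystal = 7L) data.table(
    time_ps = t_ns * 1e3, crystal = crystal, energy_kev = 511,
    label = "true", ann_id = seq_along(t_ns), pileup = 0L)
  # 0, 3, 7 ns: the 3 ns arrival is dead AND re-paralyzes, killing 7 ns
  d <- apply_deadtime(mk(c(0, 3, 7)), cfg, g)
  expect_equal(d$time_ps, 0)
  expect_identical(nrow(apply_deadtime(mk(5), cfg, g)), 1L)
  # system-wide closed form S_out = S_in exp(-S_in tau) at 1 MHz
  set.seed(261)
  cfg_sys <- digitizer_config(scope = "system")
  s <- poisson_stream(1e6, 1, g)
  out <- apply_deadtime(s, cfg_sys, g)
  s_in <- nrow(s)
  expect_equal(nrow(out) / (s_in * exp(-s_in * 5.9e-9)), 1, tolerance = 0.01)
  # monotone: larger tau never yields more counts
  taus <- c(0, 2, 5.9, 20, 100)
  counts <- vapply(taus, function(tau) {
    nrow(apply_deadtime(s, digitizer_config(deadtime_ns = tau,
                                            scope = "system"), g))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the energy window is inclusive and idempotent", {
  cfg <- digitizer_config()
  s <- data.table(time_ps = 1:4, crystal = 0L,
                  energy_kev = c(500, 449.68, 613.20, 449.0),
                  label = "true", ann_id = NA_integer_, pileup = 0L)
  w <- energy_window(s, cfg)
  expect_equal(w$energy_kev, c(500, 449.68, 613.20))
  expect_identical(energy_window(w, cfg), w)
})

test_that("the full chain is order-fixed, reproducible, and reduces to identity when disabled", {
  g <- geom_fixture()
  set.seed(271)
  raw <- poisson_stream(5e4, 0.2, g)
  raw[, label := "true"]
  raw[, ann_id := .I]
  off <- digitizer_config(noise_rate_cps = 0, energy_resolution_511 = 0,
                          efficiency = 1, time_fwhm_ps = 0,
                          pileup_window_ns = 0, deadtime_ns = 0,
                          energy_window_kev = c(0, Inf))
  out <- run_chain(raw, off, 0.2, g, seed = 1)
  expect_equal(out$time_ps, raw$time_ps)
  expect_equal(out$energy_kev, raw$energy_kev)
  expect_identical(out$crystal, raw$crystal)

  cfg <- digitizer_config()
  a <- run_chain(raw, cfg, 0.2, g, seed = 99)
  b <- run_chain(raw, cfg, 0.2, g, seed = 99)
  expect_identical(a, b)                      # bit-for-bit reproducible
  counts <- attr(a, "stage_counts")
  post_noise <- counts[c("inject_noise", "thin_efficiency", "blur_time",
                         "apply_pileup", "apply_deadtime", "energy_window")]
  expect_true(all(diff(post_noise) <= 0))
})

test_that("with zero activity the chain output is the in-window background-noise rate", {
  g <- geom_fixture()
  cfg <- digitizer_config()
  out <- run_chain(empty_singles(), cfg, duration = 1, geom = g, seed = 281)
  # oracle: noise rate times the Gaussian mass of the noise energy
  # distribution inside the window (deadtime/pile-up losses are O(1e-5)
  # at 20 cps per crystal)
  sig <- cfg$noise_energy_fwhm_kev / (2 * sqrt(2 * log(2)))
  in_win <- diff(pnorm(cfg$energy_window_kev, 511, sig))
  expected <- 461e3 * in_win
  expect_lt(abs(nrow(out) - expected), 4 * sqrt(461e3))
})
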