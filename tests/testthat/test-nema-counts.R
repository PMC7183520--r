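test_that("NECR and scatter fraction follow their defining ratios", {
  r <- count_rates(fake_dataset(C_t = 3, C_sc = 1, C_r = 1, duration_s = 1))
  expect_equal(necr(r), 9 / 5)
  expect_equal(scatter_fraction(r), 0.25)
  # noise-free limit: NECR equals the true rate
  r2 <- count_rates(fake_dataset(C_t = 50, C_sc = 0, C_r = 0, duration_s = 2))
  expect_equal(necr(r2), r2$true_rate)
  expect_equal(scatter_fraction(r2), 0)
  # NECR never exceeds the true rate
  set.seed(401)
  for (k in 1:20) {
    r3 <- count_rates(fake_dataset(sample(1:50, 1), sample(0:20, 1),
                                   sample(0:20, 1)))
    expect_lte(necr(r3), r3$true_rate + 1e-12)
  }
  expect_error(necr(count_rates(fake_dataset(0, 0, 0))), "no prompts")
  expect_error(scatter_fraction(count_rates(fake_dataset(0, 0, 5))),
               "undefined")
})

test_that("the NECR curve locates its peak on the activity grid and supports delayed randoms", {
  set.seed(402)
  # synthetic schedule with a known interior NECR maximum
  act <- c(1, 2, 4, 8, 16)
  dss <- lapply(act, function(a)
    fake_dataset(C_t = round(3e3 * a / (1 + a / 8)),
                 C_sc = round(1e3 * a),
                 C_r = round(40 * a^2),
                 n_delayed = round(40 * a^2)))
  cv <- build_necr_curve(dss, act)
  expect_identical(nrow(cv$points), 5L)
  expect_true(cv$peak$activity %in% act)
  ip <- which(cv$points$activity == cv$peak$activity)
  expect_true(ip > 1 && ip < 5)                      # interior maximum
  # delayed-window mode replaces the random count
  cvd <- build_necr_curve(dss, act, randoms = "delayed")
  expect_equal(cvd$points$random_rate, cv$points$random_rate)
  expect_error(build_necr_curve(dss[1], act[1]), "at least 2")
})

test_that("random rates grow quadratically with singles rate", {
  g <- geom_fixture()
  set.seed(403)
  rates <- c(2e5, 4e5, 8e5, 1.6e6)
  randoms <- vapply(rates, function(r) {
    s <- poisson_stream(r, 2, g)
    nrow(sort_prompts(s, g)) / 2
  }, 0)
  fit <- lm(log(randoms) ~ log(rates))
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.2)
})

test_that("low-activity regression recovers the background-noise level", {
  # exact line: intercept comes back exactly
  act <- c(0.5, 1, 1.5, 2, 2.5)
  rate <- 461000 + 12345 * act
  est <- estimate_noise_level(act, rate)
  expect_equal(est$intercept, 461000, tolerance = 1e-9)
  expect_error(estimate_noise_level(c(1, 2, 4), 461000 + c(1, 2, 4)),
               "at least 3")
  # unbiased over noisy replicates
  set.seed(404)
  ints <- replicate(100, {
    r <- 461000 + 12345 * act + rnorm(5, 0, 500)
    estimate_noise_level(act, r)$intercept
  })
  expect_equal(mean(ints), 461000, tolerance = 0.01)
})

test_that("the paralyzable inversion formula recovers the deadtime exactly", {
  s_in <- 1e6
  s_out <- s_in * exp(-s_in * 5.9e-9)
  expect_equal(estimate_deadtime(s_in, s_out), 5.9e-9, tolerance = 1e-12)
  expect_equal(estimate_deadtime(1e6, 1e6), 0)
  expect_error(estimate_deadtime(1e6, 1.1e6), "unphysical")
  expect_error(estimate_deadtime(1e6, 0), "positive")
})

test_that("the efficiency ratio estimator returns the mean ratio and flags drift", {
  sim <- c(1, 2, 3, 4, 5) * 1e5 * 0.865
  ref <- c(1, 2, 3, 4, 5) * 1e5
  est <- estimate_efficiency(sim, ref)
  expect_equal(est$efficiency, 0.865)
  expect_equal(est$cv, 0)
  expect_equal(estimate_efficiency(ref, ref)$efficiency, 1)
  expect_error(estimate_efficiency(sim[1:3], ref), "grid")
  expect_warning(estimate_efficiency(c(0.5, 0.9) * ref[1:2], ref[1:2]),
                 "varies")
})

test_that("simulated NECR peaks interiorly under deadtime losses and is monotone without them", {
  g <- geom_fixture()
  acts <- c(1e6, 2e6, 4e6, 8e6, 1.6e7)
  durs <- c(0.3, 0.3, 0.2, 0.1, 0.05)
  # deadtime amplified to a per-crystal 10 ms so that losses become
  # material within a desk-scale sweep (the Table-1 value saturates only
  # at per-crystal rates ~1e7 cps); the curve morphology is what is under
  # test, not the constant
  cfg_dt <- digitizer_config(noise_rate_cps = 0, deadtime_ns = 1e7,
                             pileup_window_ns = 0, scope = "crystal")
  cfg_off <- digitizer_config(noise_rate_cps = 0, deadtime_ns = 0,
                              pileup_window_ns = 0)
  with_dt <- list(); no_dt <- list()
  for (k in seq_along(acts)) {
    vx <- virtual_experiment("scatter_phantom",
          list(activity_bq = acts[k], duration_s = durs[k], p_sc = 0.3),
          generator_config(seed = 910 + k), g)
    d1 <- run_chain(vx$singles, cfg_dt, durs[k], g, seed = 920 + k)
    d2 <- run_chain(vx$singles, cfg_off, durs[k], g, seed = 930 + k)
    with_dt[[k]] <- listmode_dataset(sort_prompts(d1, g), duration_s = durs[k])
    no_dt[[k]] <- listmode_dataset(sort_prompts(d2, g), duration_s = durs[k])
  }
  cv <- build_necr_curve(with_dt, acts)
  ip <- which(cv$points$activity == cv$peak$activity)
  expect_true(ip > 1 && ip < length(acts))       # interior maximum
  cv0 <- build_necr_curve(no_dt, acts)
  expect_true(all(diff(cv0$points$necr) > 0))    # monotone without losses
  # true rate grows with activity below saturation
  expect_true(all(diff(cv0$points$true_rate) > 0))
})
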