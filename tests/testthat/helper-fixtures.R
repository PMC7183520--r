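library(data.table)

# shared scanner geometry (cheap to build, but one instance keeps tests tidy)
.fixture_env <- new.env(parent = emptyenv())

geom_fixture <- function() {
  if (is.null(.fixture_env$geom)) .fixture_env$geom <- scanner_geometry()
  .fixture_env$geom
}

# memoized high-statistics point-source acquisition (default generator
# settings, no background noise), reused by the TOF/energy/resolution tests
point_fixture <- function() {
  if (is.null(.fixture_env$point)) {
    g <- geom_fixture()
    vx <- virtual_experiment(
      "point_source",
      list(activity_bq = 3e6, duration_s = 1, position_mm = c(0, 10, 0)),
      generator_config(seed = 401), g)
    det <- run_chain(vx$singles, digitizer_config(noise_rate_cps = 0),
                     1, g, seed = 402)
    ds <- listmode_dataset(sort_prompts(det, g), duration_s = 1)
    .fixture_env$point <- list(ds = ds, pos = c(0, 10, 0))
  }
  .fixture_env$point
}

# memoized scatter-phantom acquisition with the full default chain
scatter_fixture <- function() {
  if (is.null(.fixture_env$scatter)) {
    g <- geom_fixture()
    vx <- virtual_experiment(
      "scatter_phantom",
      list(activity_bq = 2e6, duration_s = 0.5, p_sc = 0.3),
      generator_config(seed = 403), g)
    det <- run_chain(vx$singles, digitizer_config(), 0.5, g, seed = 404)
    ds <- listmode_dataset(sort_prompts(det, g), sort_delayed(det, g),
                           duration_s = 0.5, activity_bq = 2e6,
                           preset = "scatter_phantom")
    .fixture_env$scatter <- list(ds = ds, singles = vx$singles)
  }
  .fixture_env$scatter
}

# O(n^2) coincidence oracle: every unordered pair within the (offset)
# window that passes the circular module-sector constraint
brute_pairs <- function(time_ps, crystal, geom, window_ps,
                        min_sector_diff = 2L, offset_ps = 0) {
  per_mod <- geom$n_tang_module * geom$n_axial
  out <- list()
  n <- length(time_ps)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dt <- time_ps[j] - time_ps[i]
      if (dt < offset_ps || dt > offset_ps + window_ps) next
      d <- abs(crystal[i] %/% per_mod - crystal[j] %/% per_mod)
      d <- min(d, geom$n_modules - d)
      if (d < min_sector_diff) next
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) matrix(integer(), ncol = 2)
  else do.call(rbind, out)
}

# synthetic listmode dataset with prescribed class counts
fake_dataset <- function(C_t, C_sc, C_r, duration_s = 1, n_delayed = 0) {
  n <- C_t + C_sc + C_r
  mk <- function(n, cls, win) {
    if (n == 0) return(empty_rec())
    data.table(t1_ps = sort(runif(n, 0, duration_s * 1e12)),
               t2_ps = 0, crystal1 = 0L, crystal2 = 11520L,
               e1_kev = 511, e2_kev = 511, dt_ps = 0,
               window = win, class = cls)
  }
  empty_rec <- function() data.table(
    t1_ps = numeric(), t2_ps = numeric(), crystal1 = integer(),
    crystal2 = integer(), e1_kev = numeric(), e2_kev = numeric(),
    dt_ps = numeric(), window = character(), class = character())
  rec <- rbind(mk(C_t, "true", "prompt"), mk(C_sc, "scatter", "prompt"),
               mk(C_r, "random", "prompt"), mk(n_delayed, "random", "delayed"))
  listmode_dataset(rec[window == "prompt"], rec[window == "delayed"],
                   duration_s = duration_s)
}

# Poisson singles stream over random crystals (noise-like); times drawn
# with the package's high-resolution sampler (plain runif quantises at
# the coincidence-window scale over multi-second spans)
poisson_stream <- function(rate_cps, duration_s, geom, energy = 511) {
  n <- rpois(1, rate_cps * duration_s)
  data.table(time_ps = sort(petlm:::runif_hi(n, duration_s * 1e12)),
             crystal = sample.int(geom$n_crystals, n, TRUE) - 1L,
             energy_kev = energy, label = "noise", ann_id = NA_integer_)
}
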