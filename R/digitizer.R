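#' Digitizer configuration
#'
#' Parameters of the singles-processing chain, defaulting to the fitted
#' values of the scanner model: 461 kcps background noise, 11.2% FWHM energy
#' resolution at 511 keV, 86.5% detection efficiency, 220 ps FWHM timing
#' resolution, 5.9 ns pile-up and (paralyzable) deadtime windows, and a
#' 449.68-613.20 keV energy discriminator.
#'
#' @param noise_rate_cps System-wide background-noise singles rate (cps).
#' @param noise_energy_mean_kev Mean of the Gaussian noise energy (keV).
#' @param noise_energy_fwhm_kev FWHM of the noise energy distribution (keV);
#'   defaults to the crystal resolution at the noise mean.
#' @param energy_resolution_511 Fractional FWHM at 511 keV.
#' @param energy_scaling `"inv_sqrt"` (fractional FWHM scales as
#'   `1/sqrt(E)`, anchored at 511 keV) or `"constant"`.
#' @param efficiency Detection efficiency applied as binomial thinning to
#'   non-noise singles.
#' @param time_fwhm_ps Singles timing resolution (ps FWHM).
#' @param pileup_window_ns Pile-up integration window (ns).
#' @param deadtime_ns Paralyzable deadtime (ns).
#' @param energy_window_kev Two-sided inclusive energy window (keV).
#' @param scope Depth at which pile-up and deadtime act: `"crystal"`
#'   (1:1 SiPM coupling), `"die"`, or `"system"`.
#' @return A `digitizer_config` object.
#' @export
digitizer_config <- function(noise_rate_cps = 461e3,
                             noise_energy_mean_kev = 511,
                             noise_energy_fwhm_kev = NULL,
                             energy_resolution_511 = 0.112,
                             energy_scaling = c("inv_sqrt", "constant"),
                             efficiency = 0.865,
                             time_fwhm_ps = 220,
                             pileup_window_ns = 5.9,
                             deadtime_ns = 5.9,
                             energy_window_kev = c(449.68, 613.20),
                             scope = c("crystal", "die", "system")) {
  energy_scaling <- match.arg(energy_scaling)
  scope <- match.arg(scope)
  stopifnot(noise_rate_cps >= 0, efficiency > 0, efficiency <= 1,
            time_fwhm_ps >= 0, pileup_window_ns >= 0, deadtime_ns >= 0,
            length(energy_window_kev) == 2,
            energy_window_kev[1] < energy_window_kev[2])
  if (is.null(noise_energy_fwhm_kev))
    noise_energy_fwhm_kev <- energy_resolution_511 * noise_energy_mean_kev
  structure(list(noise_rate_cps = noise_rate_cps,
                 noise_energy_mean_kev = noise_energy_mean_kev,
                 noise_energy_fwhm_kev = noise_energy_fwhm_kev,
                 energy_resolution_511 = energy_resolution_511,
                 energy_scaling = energy_scaling,
                 efficiency = efficiency,
                 time_fwhm_ps = time_fwhm_ps,
                 pileup_window_ns = pileup_window_ns,
                 deadtime_ns = deadtime_ns,
                 energy_window_kev = energy_window_kev,
                 scope = scope),
            class = "digitizer_config")
}

empty_singles <- function() {
  data.table::data.table(time_ps = numeric(), crystal = integer(),
                         energy_kev = numeric(), label = character(),
                         ann_id = integer(), pileup = integer())
}

as_singles <- function(stream) {
  s <- data.table::as.data.table(stream)
  if (!"pileup" %in% names(s)) s[, pileup := 0L]
  if (!"ann_id" %in% names(s)) s[, ann_id := NA_integer_]
  s
}

#' Inject background-noise singles
#'
#' Adds system-wide noise singles: a homogeneous Poisson process at the
#' configured rate, uniform over the crystals, with Gaussian energies. The
#' merged stream is returned time-sorted with label `"noise"`.
#'
#' @param stream Singles `data.table` (may be empty).
#' @param cfg A [digitizer_config()].
#' @param duration Acquisition duration (seconds).
#' @param geom A [scanner_geometry()] supplying the crystal count.
#' @return The merged, time-sorted stream.
#' @export
inject_noise <- function(stream, cfg, duration, geom) {
  stopifnot(duration > 0)
  s <- as_singles(stream)
  if (cfg$noise_rate_cps <= 0) return(s)
  n <- stats::rpois(1, cfg$noise_rate_cps * duration)
  if (n == 0) return(s)
  sig <- cfg$noise_energy_fwhm_kev * FWHM_TO_SIGMA
  en <- stats::rnorm(n, cfg$noise_energy_mean_kev, sig)
  while (any(bad <- en <= 0))
    en[bad] <- stats::rnorm(sum(bad), cfg$noise_energy_mean_kev, sig)
  noise <- data.table::data.table(
    time_ps = runif_hi(n, duration * 1e12),
    crystal = sample.int(geom$n_crystals, n, replace = TRUE) - 1L,
    energy_kev = en,
    label = "noise",
    ann_id = NA_integer_,
    pileup = 0L)
  out <- rbind(s, noise, fill = TRUE)
  data.table::setorder(out, time_ps)
  out[]
}

#' Blur single energies with the crystal resolution
#'
#' Gaussian energy blur with FWHM `r(E) * E`, where the fractional
#' resolution `r(E)` either scales as `1/sqrt(E)` anchored at 11.2% @ 511 keV
#' (scintillator photon statistics) or is constant. Non-positive draws are
#' redrawn.
#'
#' @inheritParams inject_noise
#' @return The stream with blurred `energy_kev`.
#' @export
blur_energy <- function(stream, cfg) {
  s <- as_singles(stream)
  if (cfg$energy_resolution_511 <= 0 || nrow(s) == 0) return(s)
  frac <- if (cfg$energy_scaling == "inv_sqrt")
    cfg$energy_resolution_511 * sqrt(511 / s$energy_kev)
  else cfg$energy_resolution_511
  sig <- frac * s$energy_kev * FWHM_TO_SIGMA
  e <- stats::rnorm(nrow(s), s$energy_kev, sig)
  while (any(bad <- e <= 0))
    e[bad] <- stats::rnorm(sum(bad), s$energy_kev[bad], sig[bad])
  s[, energy_kev := e]
  s[]
}

#' Blur single timestamps with the timing resolution
#'
#' Adds an independent Gaussian shift of the configured FWHM to every
#' timestamp and re-sorts the stream. Two coincident singles blurred this
#' way acquire a time-difference FWHM of `sqrt(2)` times the singles value
#' (220 ps yields 311 ps).
#'
#' @inheritParams inject_noise
#' @return The re-sorted stream.
#' @export
blur_time <- function(stream, cfg) {
  s <- as_singles(stream)
  if (cfg$time_fwhm_ps <= 0 || nrow(s) == 0) return(s)
  s[, time_ps := time_ps + stats::rnorm(.N, 0, cfg$time_fwhm_ps * FWHM_TO_SIGMA)]
  data.table::setorder(s, time_ps)
  s[]
}

#' Thin non-noise singles by the detection efficiency
#'
#' Each non-noise single is kept independently with probability
#' `cfg$efficiency`. Noise singles are exempt: the configured noise rate is
#' already a detected-singles level.
#'
#' @inheritParams inject_noise
#' @return The thinned stream.
#' @export
thin_efficiency <- function(stream, cfg) {
  s <- as_singles(stream)
  if (cfg$efficiency >= 1 || nrow(s) == 0) return(s)
  keep <- s$label == "noise" | stats::runif(nrow(s)) < cfg$efficiency
  s[keep]
}

scope_key <- function(s, cfg, geom) {
  switch(cfg$scope,
         crystal = s$crystal,
         die = {
           idx <- crystal_index(geom, s$crystal)
           dt <- idx$tang %/% geom$crystals_per_die[1]
           da <- idx$ax %/% geom$crystals_per_die[2]
           (idx$module * (geom$n_tang_module %/% geom$crystals_per_die[1]) + dt) *
             (geom$n_axial %/% geom$crystals_per_die[2]) + da
         },
         system = rep(0L, nrow(s)))
}

# anchored grouping: within each key, events within `w` of the first event
# of the current group merge into it; the first event past the window opens
# a new group. Returns a group id per row (rows assumed ordered key, time).
anchored_groups <- function(time, key, w) {
  n <- length(time)
  if (n == 0) return(integer(0))
  # a group can never span a gap > w, so first partition into maximal runs
  # of consecutive <=w gaps and only scan inside those (rare at realistic
  # rates), re-anchoring whenever an event exceeds anchor + w
  gap_break <- c(TRUE, diff(time) > w | key[-1] != key[-n])
  run <- cumsum(gap_break)
  sub_break <- logical(n)
  idx <- which(!gap_break)
  if (length(idx)) {
    anchors <- time[gap_break]        # per-run current anchor
    for (j in idx) {
      r <- run[j]
      if (time[j] - anchors[r] > w) {
        sub_break[j] <- TRUE
        anchors[r] <- time[j]
      }
    }
  }
  cumsum(gap_break | sub_break)
}

#' Merge pile-up events
#'
#' Within the configured scope (crystal, die, or system), events arriving
#' within the pile-up window of the first event of the current accumulation
#' are merged into one single: energies are summed, the timestamp is the
#' first event's, and `pileup` counts the extra merged events. The merged
#' event anchors a new window.
#'
#' @inheritParams inject_noise
#' @return The merged stream.
#' @export
apply_pileup <- function(stream, cfg, geom) {
  s <- as_singles(stream)
  if (cfg$pileup_window_ns <= 0 || nrow(s) < 2) return(s)
  if (is.unsorted(s$time_ps)) stop("stream must be time-sorted")
  key <- scope_key(s, cfg, geom)
  ord <- order(key, s$time_ps)
  so <- s[ord]
  grp <- anchored_groups(so$time_ps, key[ord], cfg$pileup_window_ns * 1e3)
  merged <- so[, .(
    time_ps = time_ps[1], crystal = crystal[1],
    energy_kev = sum(energy_kev),
    label = label[1], ann_id = ann_id[1],
    pileup = pileup[1] + .N - 1L), by = .(.grp = grp)][, .grp := NULL]
  data.table::setorder(merged, time_ps)
  merged[]
}

#' Apply paralyzable deadtime
#'
#' Within the configured scope, every arrival -- recorded or not -- extends
#' the dead interval to its own time plus the deadtime; an event arriving
#' inside a dead interval is discarded. Equivalently, an event is recorded
#' iff it arrives more than one deadtime after the previous arrival in its
#' scope.
#'
#' @inheritParams inject_noise
#' @return The filtered stream.
#' @export
apply_deadtime <- function(stream, cfg, geom) {
  s <- as_singles(stream)
  if (cfg$deadtime_ns <= 0 || nrow(s) < 2) return(s)
  if (is.unsorted(s$time_ps)) stop("stream must be time-sorted")
  key <- scope_key(s, cfg, geom)
  ord <- order(key, s$time_ps)
  t <- s$time_ps[ord]
  k <- key[ord]
  n <- length(t)
  keep <- c(TRUE, diff(t) > cfg$deadtime_ns * 1e3 | k[-1] != k[-n])
  out <- s[ord][keep]
  data.table::setorder(out, time_ps)
  out[]
}

#' Apply the energy window discriminator
#'
#' Keeps events with energy inside the inclusive window.
#'
#' @inheritParams inject_noise
#' @return The filtered stream.
#' @export
energy_window <- function(stream, cfg) {
  s <- as_singles(stream)
  s[energy_kev >= cfg$energy_window_kev[1] &
      energy_kev <= cfg$energy_window_kev[2]]
}

#' Run the full digitizer chain
#'
#' Fixed stage order: energy blur, noise injection, efficiency thinning,
#' timing blur, pile-up, paralyzable deadtime, energy window -- pile-up and
#' deadtime deliberately precede the energy window. Per-stage event counts
#' are recorded in the `"stage_counts"` attribute of the result.
#'
#' @param stream Raw singles `data.table` (time-sorted).
#' @param cfg A [digitizer_config()].
#' @param duration Acquisition duration (seconds), for noise injection.
#' @param geom A [scanner_geometry()].
#' @param seed Optional integer; when given, seeds the RNG for bit-for-bit
#'   reproducibility.
#' @return The detected singles stream with attribute `stage_counts`.
#' @export
run_chain <- function(stream, cfg, duration, geom, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- as_singles(stream)
  if (nrow(s) && is.unsorted(s$time_ps)) stop("raw stream must be time-sorted")
  counts <- c(input = nrow(s))
  s <- blur_energy(s, cfg);            counts["blur_energy"] <- nrow(s)
  s <- inject_noise(s, cfg, duration, geom); counts["inject_noise"] <- nrow(s)
  s <- thin_efficiency(s, cfg);        counts["thin_efficiency"] <- nrow(s)
  s <- blur_time(s, cfg);              counts["blur_time"] <- nrow(s)
  s <- apply_pileup(s, cfg, geom);     counts["apply_pileup"] <- nrow(s)
  s <- apply_deadtime(s, cfg, geom);   counts["apply_deadtime"] <- nrow(s)
  s <- energy_window(s, cfg);          counts["energy_window"] <- nrow(s)
  data.table::setattr(s, "stage_counts", counts)
  s
}
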