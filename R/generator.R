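#' Source specification for a virtual acquisition
#'
#' @param kind `"point"` or `"line"`.
#' @param position Centre of the source (mm, length-3).
#' @param axis Unit axis of a line source (ignored for points).
#' @param length Line-source length (mm).
#' @param radius Line-source radius (mm); points are ideal.
#' @param activity_bq Activity at acquisition start (Bq).
#' @param half_life_s Half-life driving the decay of the emission rate
#'   (seconds); default is 18F. Use `decay = FALSE` for a constant rate.
#' @param decay Logical; apply radioactive decay over the acquisition.
#' @return A `source_spec` object.
#' @export
source_spec <- function(kind = c("point", "line"),
                        position = c(0, 0, 0),
                        axis = c(0, 0, 1),
                        length = 0,
                        radius = 0,
                        activity_bq = 1e6,
                        half_life_s = 6586.2,
                        decay = TRUE) {
  kind <- match.arg(kind)
  stopifnot(activity_bq >= 0, length >= 0, radius >= 0, half_life_s > 0)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(kind = kind, position = as.numeric(position), axis = axis,
                 length = length, radius = radius, activity_bq = activity_bq,
                 half_life_s = half_life_s, decay = decay),
            class = "source_spec")
}

#' Phantom specification
#'
#' A cylindrical attenuating/scattering phantom centred on the scanner axis,
#' described phenomenologically: photons traverse it with transmission
#' `exp(-mu * chord)` and interacted photons are re-emitted as single-Compton
#' scatters at a branching rate calibrated so that a fraction `p_sc` of the
#' emitted photons carries the scatter label.
#'
#' @param kind `"none"` or `"cylinder"`.
#' @param radius,length Cylinder dimensions (mm).
#' @param mu Linear attenuation coefficient at 511 keV (1/mm); default is
#'   polyethylene.
#' @param p_sc Target scattered fraction among emitted photons, in `[0, 1)`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind = c("none", "cylinder"),
                         radius = 102, length = 700,
                         mu = 0.00922, p_sc = 0.30) {
  kind <- match.arg(kind)
  stopifnot(mu >= 0, p_sc >= 0, p_sc < 1)
  structure(list(kind = kind, radius = radius, length = length,
                 mu = mu, p_sc = p_sc), class = "phantom_spec")
}

#' Generator configuration
#'
#' @param seed Integer seed controlling every stochastic draw of a virtual
#'   experiment.
#' @param positron_range_fwhm Isotropic 3D Gaussian blur applied to each
#'   annihilation point (mm FWHM); default 0.54 mm, an 18F literature value.
#' @param acollinearity_fwhm_deg FWHM of the Gaussian angular deviation
#'   between the two annihilation photons (degrees).
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             positron_range_fwhm = 0.54,
                             acollinearity_fwhm_deg = 0.5) {
  stopifnot(positron_range_fwhm >= 0, acollinearity_fwhm_deg >= 0)
  structure(list(seed = as.integer(seed),
                 positron_range_fwhm = positron_range_fwhm,
                 acollinearity_fwhm_deg = acollinearity_fwhm_deg),
            class = "generator_config")
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))   # 1/2.3548
C_MM_PER_PS <- 0.299792458

# uniform draws with ~53-bit resolution: base R's unif_rand() has 32-bit
# granularity, which at picosecond scale over seconds-long acquisitions
# quantises event times at ~2000 ps -- the coincidence-window scale
runif_hi <- function(n, max = 1) {
  ((stats::runif(n) + stats::runif(n) * 2^-32) %% 1) * max
}

#' Draw annihilation times and positions
#'
#' Event times follow a Poisson process whose rate decays with the source
#' half-life (or stays constant when `decay = FALSE`); positions are uniform
#' on the source support, then displaced by the isotropic positron-range
#' blur. Draws from the current RNG state.
#'
#' @param src A [source_spec()].
#' @param duration Acquisition duration (seconds).
#' @param cfg A [generator_config()].
#' @return A `data.table` with `time_ps`, `x`, `y`, `z` sorted by time.
#' @export
generate_annihilations <- function(src, duration, cfg = generator_config()) {
  stopifnot(duration > 0)
  k <- log(2) / src$half_life_s
  mean_n <- if (src$decay) src$activity_bq / k * (1 - exp(-k * duration))
            else src$activity_bq * duration
  n <- stats::rpois(1, mean_n)
  if (n == 0)
    return(data.table::data.table(time_ps = numeric(), x = numeric(),
                                  y = numeric(), z = numeric()))
  u <- runif_hi(n)
  t_s <- if (src$decay) -log(1 - u * (1 - exp(-k * duration))) / k
         else u * duration
  t_s <- sort(t_s)
  if (src$kind == "point") {
    p <- matrix(src$position, n, 3, byrow = TRUE)
  } else {
    along <- stats::runif(n, -src$length / 2, src$length / 2)
    p <- matrix(src$position, n, 3, byrow = TRUE) + outer(along, src$axis)
    if (src$radius > 0) {
      # uniform disc offset perpendicular to the axis
      e1 <- perp_unit(src$axis)
      e2 <- cross3(src$axis, e1)
      r <- src$radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      p <- p + outer(r * cos(th), e1) + outer(r * sin(th), e2)
    }
  }
  sig <- cfg$positron_range_fwhm * FWHM_TO_SIGMA
  if (sig > 0) p <- p + matrix(stats::rnorm(3 * n, 0, sig), n, 3)
  data.table::data.table(time_ps = t_s * 1e12, x = p[, 1], y = p[, 2], z = p[, 3])
}

perp_unit <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(v, a)
  w / sqrt(sum(w^2))
}

# rowwise unit vectors perpendicular to the rows of m (n x 3)
perp_unit_rows <- function(m) {
  use_x <- abs(m[, 1]) < 0.9
  ax <- ifelse(use_x, 1, 0)
  ay <- ifelse(use_x, 0, 1)
  # w = m x a
  wx <- m[, 2] * 0 - m[, 3] * ay
  wy <- m[, 3] * ax - m[, 1] * 0
  wz <- m[, 1] * ay - m[, 2] * ax
  w <- cbind(wx, wy, wz)
  w / sqrt(rowSums(w^2))
}
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Klein-Nishina cos(theta) sampling at 511 keV (k = E/mec2 = 1), by rejection
sample_kn_costheta <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    ct <- stats::runif(m, -1, 1)
    r <- 1 / (2 - ct)                      # E'/E for k = 1
    w <- r^2 * (r + 1 / r - 1 + ct^2)      # unnormalised KN density
    keep <- stats::runif(m) < w / 2        # bound: w <= 2 on [-1, 1]
    out <- c(out, ct[keep])
  }
  out[seq_len(n)]
}

# chord length from interior point p along unit direction d inside a
# finite cylinder (axis z, radius R, |z| <= L/2); 0 when p is outside
cylinder_exit_dist <- function(px, py, pz, dx, dy, dz, R, L) {
  inside <- (px^2 + py^2 <= R^2) & (abs(pz) <= L / 2)
  a <- dx^2 + dy^2
  b <- px * dx + py * dy
  cc <- px^2 + py^2 - R^2
  disc <- pmax(b^2 - a * cc, 0)
  t_side <- ifelse(a > 0, (-b + sqrt(disc)) / a, Inf)
  t_cap <- ifelse(dz > 0, (L / 2 - pz) / dz,
                  ifelse(dz < 0, (-L / 2 - pz) / dz, Inf))
  t <- pmin(t_side, t_cap)
  ifelse(inside, pmax(t, 0), 0)
}

#' Emit annihilation photon pairs and detect them on the ring
#'
#' For each annihilation point, two back-to-back 511 keV photons are emitted
#' with a Gaussian acollinearity deviation. Each photon traverses the
#' phantom: it survives unscattered with probability `exp(-mu * chord)`;
#' an interacted photon is re-emitted from a random point on its chord with
#' a Klein-Nishina deflection and Compton energy `E' = 511/(2 - cos(theta))`
#' keV (label `"scatter"`) at a branching rate calibrated to the phantom's
#' `p_sc`, and is otherwise absorbed. Surviving photons are propagated to
#' the detector cylinder and assigned the nearest crystal; photons missing
#' the ring are dropped. Arrival times include the time of flight.
#'
#' @param ann A `data.table` from [generate_annihilations()].
#' @param cfg A [generator_config()].
#' @param geom A [scanner_geometry()].
#' @param phantom A [phantom_spec()].
#' @param transmission Extra per-photon survival probability (scalar), e.g.
#'   attenuation by sensitivity sleeves.
#' @return A `data.table` of raw singles: `time_ps`, `crystal`, `energy_kev`,
#'   `label` (`"true"`/`"scatter"`), `ann_id`, sorted by time.
#' @export
emit_pairs <- function(ann, cfg, geom, phantom = phantom_spec("none"),
                       transmission = 1) {
  n <- nrow(ann)
  empty <- data.table::data.table(
    time_ps = numeric(), crystal = integer(), energy_kev = numeric(),
    label = character(), ann_id = integer())
  if (n == 0) return(empty)

  # photon 1 isotropic; photon 2 back-to-back with small Gaussian tilt
  cz <- stats::runif(n, -1, 1)
  az <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - cz^2)
  d1 <- cbind(st * cos(az), st * sin(az), cz)
  sig_a <- cfg$acollinearity_fwhm_deg * pi / 180 * FWHM_TO_SIGMA
  if (sig_a > 0) {
    # tilt -d1 by two transverse Gaussian components
    t1 <- stats::rnorm(n, 0, sig_a)
    t2 <- stats::rnorm(n, 0, sig_a)
    e1 <- perp_unit_rows(d1)
    e2 <- cross_rows(d1, e1)
    d2 <- -d1 + t1 * e1 + t2 * e2
    d2 <- d2 / sqrt(rowSums(d2^2))
  } else {
    d2 <- -d1
  }

  one_photon <- function(dirs) {
    px <- ann$x; py <- ann$y; pz <- ann$z
    dx <- dirs[, 1]; dy <- dirs[, 2]; dz <- dirs[, 3]
    en <- rep(511, n)
    lab <- rep("true", n)
    path0 <- numeric(n)                 # path travelled before re-emission
    alive <- rep(TRUE, n)
    if (phantom$kind == "cylinder" && phantom$mu > 0) {
      L <- cylinder_exit_dist(px, py, pz, dx, dy, dz,
                              phantom$radius, phantom$length)
      pT <- exp(-phantom$mu * L)
      u <- stats::runif(n)
      unscat <- u < pT
      q <- if (phantom$p_sc > 0)
        pmin(1, phantom$p_sc / (1 - phantom$p_sc) * pT / pmax(1 - pT, 1e-300))
      else 0
      scat <- !unscat & (stats::runif(n) < q)
      alive <- unscat | scat
      if (any(scat)) {
        i <- which(scat)
        frac <- stats::runif(length(i))
        path0[i] <- frac * L[i]
        px[i] <- px[i] + path0[i] * dx[i]
        py[i] <- py[i] + path0[i] * dy[i]
        pz[i] <- pz[i] + path0[i] * dz[i]
        ct <- sample_kn_costheta(length(i))
        en[i] <- 511 / (2 - ct)
        lab[i] <- "scatter"
        # deflect by theta around the incoming direction
        phi2 <- stats::runif(length(i), 0, 2 * pi)
        stheta <- sqrt(pmax(1 - ct^2, 0))
        d <- cbind(dx[i], dy[i], dz[i])
        b1 <- perp_unit_rows(d)
        b2 <- cross_rows(d, b1)
        nd <- ct * d + stheta * (cos(phi2) * b1 + sin(phi2) * b2)
        dx[i] <- nd[, 1]; dy[i] <- nd[, 2]; dz[i] <- nd[, 3]
      }
    }
    if (transmission < 1)
      alive <- alive & (stats::runif(n) < transmission)

    # propagate to the detector cylinder
    a <- dx^2 + dy^2
    b <- px * dx + py * dy
    cc <- px^2 + py^2 - geom$radius^2
    disc <- b^2 - a * cc
    hit <- alive & (a > 0) & (disc >= 0) & (cc < 0)
    tt <- rep(NA_real_, n)
    tt[hit] <- (-b[hit] + sqrt(disc[hit])) / a[hit]
    hx <- px + tt * dx; hy <- py + tt * dy; hz <- pz + tt * dz
    crystal <- rep(NA_integer_, n)
    crystal[hit] <- nearest_crystal(geom, atan2(hy[hit], hx[hit]), hz[hit])
    det <- hit & !is.na(crystal)
    flight <- (path0 + tt) / C_MM_PER_PS
    data.table::data.table(
      time_ps = ann$time_ps[det] + flight[det],
      crystal = crystal[det],
      energy_kev = en[det],
      label = lab[det],
      ann_id = which(det))
  }

  s1 <- one_photon(d1)
  s2 <- one_photon(d2)
  out <- rbind(s1, s2)
  if (nrow(out) == 0) return(empty)
  data.table::setorder(out, time_ps)
  out[]
}

MU_AL_511 <- 0.0227   # aluminium linear attenuation at 511 keV, 1/mm

#' Run a NEMA-style virtual experiment
#'
#' Presets mirror the NEMA NU 2-2018 acquisitions used to validate the
#' scanner model:
#' * `scatter_phantom` -- line source (700 mm, 1.6 mm radius) at 45 mm radial
#'   offset inside a 102 mm x 700 mm polyethylene cylinder;
#' * `sensitivity` -- centred 700 mm line source in `n_sleeves` concentric
#'   aluminium sleeves of 1.25 mm wall each, modelled as a per-photon
#'   transmission `exp(-mu_al * thickness)`;
#' * `point_source` -- an ideal point source at a given position.
#'
#' @param preset One of `"scatter_phantom"`, `"sensitivity"`, `"point_source"`.
#' @param params Named list of preset parameters: `activity_bq`, `duration_s`,
#'   and per preset `n_sleeves`/`mu_al` (sensitivity), `position_mm`
#'   (point_source), `offset_mm`/`p_sc`/`mu` (scatter_phantom), `decay`.
#' @param cfg A [generator_config()]; its seed initialises the RNG for the
#'   whole experiment.
#' @param geom A [scanner_geometry()].
#' @return A list with `singles` (raw singles stream), `truth` (annihilation
#'   table keyed by `ann_id`), and `meta`.
#' @export
virtual_experiment <- function(preset = c("scatter_phantom", "sensitivity",
                                          "point_source"),
                               params = list(),
                               cfg = generator_config(),
                               geom = scanner_geometry()) {
  preset <- match.arg(preset)
  p <- params
  act <- p$activity_bq %||% 1e6
  dur <- p$duration_s %||% 1
  decay <- p$decay %||% FALSE
  set.seed(cfg$seed)
  if (preset == "scatter_phantom") {
    src <- source_spec("line", position = c(p$offset_mm %||% 45, 0, 0),
                       axis = c(0, 0, 1), length = 700, radius = 1.6,
                       activity_bq = act, decay = decay)
    ph <- phantom_spec("cylinder", radius = 102, length = 700,
                       mu = p$mu %||% 0.00922, p_sc = p$p_sc %||% 0.30)
    trans <- 1
  } else if (preset == "sensitivity") {
    ns <- p$n_sleeves %||% 1
    stopifnot(ns >= 1, ns <= 5)
    src <- source_spec("line", position = c(0, 0, 0), axis = c(0, 0, 1),
                       length = 700, radius = 0.5,
                       activity_bq = act, decay = decay)
    ph <- phantom_spec("none")
    thickness <- 1.25 * ns
    trans <- exp(-(p$mu_al %||% MU_AL_511) * thickness)
  } else {
    pos <- p$position_mm %||% c(0, 10, 0)
    src <- source_spec("point", position = pos, activity_bq = act,
                       decay = decay)
    ph <- phantom_spec("none")
    trans <- 1
  }
  ann <- generate_annihilations(src, dur, cfg)
  ann[, ann_id := seq_len(.N)]
  singles <- emit_pairs(ann, cfg, geom, ph, transmission = trans)
  list(singles = singles,
       truth = ann,
       meta = list(preset = preset, duration_s = dur, activity_bq = act,
                   params = p, seed = cfg$seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
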