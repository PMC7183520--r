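#' Count rates of a listmode dataset
#'
#' Tallies true, scatter, and random coincidences and converts them to
#' rates over the acquisition (or truncated) duration. In simulated mode
#' (`randoms = "truth"`) the ground-truth class labels are used; in
#' experiment-like mode (`randoms = "delayed"`) the random count is taken
#' from the delayed window instead (scatter still requires labels).
#'
#' @param dataset A [listmode_dataset()].
#' @param randoms `"truth"` or `"delayed"`.
#' @return A `count_rates` object: counts `C_tot`, `C_t`, `C_sc`, `C_r`,
#'   the corresponding rates (cps), and the duration.
#' @export
count_rates <- function(dataset, randoms = c("truth", "delayed")) {
  randoms <- match.arg(randoms)
  rec <- dataset$records
  dur <- dataset$meta$duration_s
  pr <- rec[rec$window == "prompt"]
  C_tot <- nrow(pr)
  C_t <- sum(pr$class == "true")
  C_sc <- sum(pr$class == "scatter")
  C_r <- if (randoms == "truth") sum(pr$class == "random")
         else sum(rec$window == "delayed")
  structure(list(C_tot = C_tot, C_t = C_t, C_sc = C_sc, C_r = C_r,
                 duration_s = dur,
                 prompt_rate = C_tot / dur, true_rate = C_t / dur,
                 scatter_rate = C_sc / dur, random_rate = C_r / dur),
            class = "count_rates")
}

#' Noise equivalent count rate
#'
#' `NECR = C_t^2 / C_tot / duration`, the standard summary of useful
#' counting performance.
#'
#' @param rates A `count_rates` object.
#' @return NECR in cps.
#' @export
necr <- function(rates) {
  if (rates$C_tot <= 0) stop("NECR undefined: no prompts")
  rates$C_t^2 / rates$C_tot / rates$duration_s
}

#' Scatter fraction
#'
#' `SF = C_sc / (C_t + C_sc)`.
#'
#' @param rates A `count_rates` object.
#' @return Dimensionless scatter fraction.
#' @export
scatter_fraction <- function(rates) {
  if (rates$C_t + rates$C_sc <= 0) stop("scatter fraction undefined")
  rates$C_sc / (rates$C_t + rates$C_sc)
}

#' Build an NECR curve over an activity schedule
#'
#' Computes per-point count rates, NECR and scatter fraction, and locates
#' the peak NECR on the sampled activity grid (no interpolation).
#'
#' @param datasets List of [listmode_dataset()]s, one per activity point.
#' @param activity Numeric vector of activity concentrations (or
#'   activities) matching `datasets`.
#' @param randoms Passed to [count_rates()].
#' @return A `necr_curve`: `points` (data.table with one row per activity)
#'   and `peak` (list with `necr`, `activity`, `sf`).
#' @export
build_necr_curve <- function(datasets, activity, randoms = "truth") {
  if (length(datasets) < 2) stop("an NECR curve needs at least 2 points")
  stopifnot(length(datasets) == length(activity))
  pts <- data.table::rbindlist(lapply(seq_along(datasets), function(k) {
    r <- count_rates(datasets[[k]], randoms)
    data.table::data.table(
      activity = activity[k],
      prompt_rate = r$prompt_rate, true_rate = r$true_rate,
      scatter_rate = r$scatter_rate, random_rate = r$random_rate,
      necr = necr(r), sf = scatter_fraction(r))
  }))
  data.table::setorder(pts, activity)
  ipk <- which.max(pts$necr)
  structure(list(points = pts,
                 peak = list(necr = pts$necr[ipk],
                             activity = pts$activity[ipk],
                             sf = pts$sf[ipk])),
            class = "necr_curve")
}

#' Estimate the background-noise level by low-activity regression
#'
#' Ordinary least-squares fit of singles rate against activity
#' concentration restricted to points below the cutoff, extrapolated to
#' zero activity: at low activity deadtime and pile-up losses vanish and
#' the intercept is the background-noise singles rate.
#'
#' @param activity Activity concentrations (e.g. kBq/mL).
#' @param singles_rate Detected singles rates (cps).
#' @param cutoff Only points with `activity < cutoff` enter the fit
#'   (default 3, same units as `activity`).
#' @return List with `intercept` (cps), `slope`, and the `lm` fit.
#' @export
estimate_noise_level <- function(activity, singles_rate, cutoff = 3) {
  use <- activity < cutoff
  if (sum(use) < 3) stop("need at least 3 points below the cutoff")
  fit <- stats::lm(singles_rate[use] ~ activity[use])
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       fit = fit)
}

#' Invert the paralyzable deadtime model
#'
#' Recovers the deadtime constant from input and output singles rates of a
#' paralyzable stage: `tau = -(1/S_in) * ln(S_out/S_in)`.
#'
#' @param s_in Singles rate without deadtime losses (cps).
#' @param s_out Measured singles rate (cps).
#' @return Deadtime in seconds.
#' @export
estimate_deadtime <- function(s_in, s_out) {
  if (s_out <= 0 || s_in <= 0) stop("rates must be positive")
  if (s_out > s_in) stop("S_out > S_in is unphysical for a deadtime stage")
  -log(s_out / s_in) / s_in
}

#' Estimate the detection efficiency from matched rate curves
#'
#' The ratio of simulated to reference singles rates should be constant
#' over the activity range; its mean is the detection efficiency.
#'
#' @param sim_rate,ref_rate Singles rates on a matched activity grid.
#' @return List with `efficiency` (mean ratio), `cv` (coefficient of
#'   variation of the per-point ratios), and the `ratios`.
#' @export
estimate_efficiency <- function(sim_rate, ref_rate) {
  if (length(sim_rate) != length(ref_rate))
    stop("rate vectors must share one activity grid")
  ratio <- sim_rate / ref_rate
  cv <- stats::sd(ratio) / mean(ratio)
  if (!is.na(cv) && cv > 0.02)
    warning(sprintf("efficiency ratio varies with activity (CV = %.2f%%)",
                    100 * cv))
  list(efficiency = mean(ratio), cv = cv, ratios = ratio)
}
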