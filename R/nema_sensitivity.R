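#' Sensitivity of one sleeved acquisition
#'
#' True-coincidence rate per unit activity. In simulated mode the trues are
#' identified by ground-truth labels; at the 8 MBq NEMA activity randoms
#' are negligible by construction.
#'
#' @param dataset A [listmode_dataset()].
#' @param activity_mbq Source activity (MBq).
#' @return Sensitivity in cps/MBq (0 with a warning for an empty dataset).
#' @export
sleeve_sensitivity <- function(dataset, activity_mbq) {
  if (activity_mbq <= 0) stop("activity must be positive")
  rec <- dataset$records
  n_true <- sum(rec$window == "prompt" & rec$class == "true")
  if (n_true == 0) {
    warning("no true coincidences; sensitivity is 0")
    return(0)
  }
  n_true / dataset$meta$duration_s / activity_mbq
}

#' Extrapolate sensitivity to zero sleeve thickness
#'
#' Least-squares line on (thickness, log sensitivity); the attenuation-free
#' sensitivity is `exp(intercept)` and the fitted slope is the effective
#' attenuation coefficient of the sleeve material (doubled path).
#'
#' @param thickness_mm Cumulative sleeve wall thicknesses (mm).
#' @param sensitivity Sensitivities (cps/MBq), all positive.
#' @return List with `S0` (cps/MBq at zero thickness), `slope` (1/mm), and
#'   the `lm` fit.
#' @export
extrapolate_S0 <- function(thickness_mm, sensitivity) {
  if (length(unique(thickness_mm)) < 2)
    stop("need at least 2 distinct thicknesses")
  if (any(sensitivity <= 0)) stop("sensitivities must be positive")
  fit <- stats::lm(log(sensitivity) ~ thickness_mm)
  list(S0 = exp(unname(stats::coef(fit)[1])),
       slope = unname(stats::coef(fit)[2]),
       fit = fit)
}

#' Axial sensitivity profile
#'
#' Assigns each true coincidence to the axial slice containing its LOR
#' midpoint (a single-slice-rebinning surrogate) and counts per slice.
#'
#' @param dataset A [listmode_dataset()].
#' @param geom A [scanner_geometry()].
#' @param n_slices Number of contiguous axial slices spanning the FOV.
#' @return A `data.table` with slice index, slice centre `z_mm`, and
#'   `count`.
#' @export
axial_profile <- function(dataset, geom, n_slices = 40) {
  stopifnot(n_slices >= 1)
  rec <- dataset$records
  tru <- rec[rec$window == "prompt" & rec$class == "true"]
  half <- geom$axial_fov / 2
  zmid <- (crystal_position(geom, tru$crystal1)$z +
             crystal_position(geom, tru$crystal2)$z) / 2
  edges <- seq(-half, half, length.out = n_slices + 1)
  slice <- pmin(pmax(findInterval(zmid, edges, rightmost.closed = TRUE), 1L),
                n_slices)
  data.table::data.table(
    slice = seq_len(n_slices),
    z_mm = (edges[-1] + edges[-(n_slices + 1)]) / 2,
    count = tabulate(slice, nbins = n_slices))
}
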