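#' Sort detected singles into prompt coincidences
#'
#' Multiple-window scheme with the takeAllGoods multiples policy: every
#' single opens its own window `[t, t + window]` and every geometrically
#' valid pair (opener, later single) inside the window is emitted; each
#' unordered pair is emitted at most once across windows, so no coincidence
#' is counted twice. The geometric constraint rejects pairs whose circular
#' module-sector difference is below `min_sector_diff`.
#'
#' @param singles Time-sorted detected singles `data.table`.
#' @param geom A [scanner_geometry()].
#' @param window_ps Coincidence window (ps), default 2.0115 ns.
#' @param min_sector_diff Minimum circular module difference (default 2:
#'   rejects intra-module and adjacent-module pairs).
#' @return A `data.table` of coincidences: times, crystals, energies,
#'   `dt_ps` (= t2 - t1, crystal 1 being the earlier single), `window`
#'   (`"prompt"`), and ground-truth `class` (`"true"`, `"scatter"`,
#'   `"random"`) when labels are present.
#' @export
sort_prompts <- function(singles, geom, window_ps = 2011.5,
                         min_sector_diff = 2L) {
  pair_windows(singles, geom, window_ps, min_sector_diff,
               offset_ps = 0, window_name = "prompt")
}

#' Sort detected singles into delayed coincidences
#'
#' Identical pairing logic to [sort_prompts()], with the second single's
#' time shifted by `-offset_ps` before pairing: pairs with
#' `offset <= t2 - t1 <= offset + window` are emitted and flagged
#' `"delayed"`. Their count estimates the number of random coincidences in
#' the prompt window.
#'
#' @inheritParams sort_prompts
#' @param offset_ps Delayed-window offset (ps), default 100 ns.
#' @return A `data.table` of delayed coincidences (`dt_ps` is the raw
#'   `t2 - t1`, near the offset).
#' @export
sort_delayed <- function(singles, geom, window_ps = 2011.5,
                         offset_ps = 1e5, min_sector_diff = 2L) {
  pair_windows(singles, geom, window_ps, min_sector_diff,
               offset_ps = offset_ps, window_name = "delayed")
}

empty_coincidences <- function() {
  data.table::data.table(
    t1_ps = numeric(), t2_ps = numeric(),
    crystal1 = integer(), crystal2 = integer(),
    e1_kev = numeric(), e2_kev = numeric(),
    dt_ps = numeric(), window = character(), class = character())
}

pair_windows <- function(singles, geom, window_ps, min_sector_diff,
                         offset_ps, window_name) {
  s <- data.table::as.data.table(singles)
  n <- nrow(s)
  if (n < 2) return(empty_coincidences())
  t <- s$time_ps
  if (is.unsorted(t)) stop("singles must be time-sorted")
  if (offset_ps == 0) {
    lo <- seq_len(n) + 1L
  } else {
    lo <- findInterval(t + offset_ps, t, left.open = TRUE) + 1L
  }
  hi <- findInterval(t + offset_ps + window_ps, t)
  cnt <- pmax(hi - lo + 1L, 0L)
  i <- rep.int(seq_len(n), cnt)
  if (!length(i)) return(empty_coincidences())
  j <- sequence(cnt[cnt > 0L], from = lo[cnt > 0L])
  # geometric constraint on module sectors
  per_mod <- geom$n_tang_module * geom$n_axial
  m1 <- s$crystal[i] %/% per_mod
  m2 <- s$crystal[j] %/% per_mod
  d <- abs(m1 - m2)
  d <- pmin(d, geom$n_modules - d)
  ok <- d >= min_sector_diff
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(empty_coincidences())
  has_truth <- "label" %in% names(s)
  cls <- if (has_truth)
    classify_pair(s$label[i], s$label[j], s$ann_id[i], s$ann_id[j])
  else rep(NA_character_, length(i))
  data.table::data.table(
    t1_ps = t[i], t2_ps = t[j],
    crystal1 = s$crystal[i], crystal2 = s$crystal[j],
    e1_kev = s$energy_kev[i], e2_kev = s$energy_kev[j],
    dt_ps = t[j] - t[i],
    window = window_name,
    class = cls)
}

# ground truth: same annihilation and neither scattered -> true; same
# annihilation with >=1 scattered photon -> scatter; anything else
# (different annihilations, noise) -> random
classify_pair <- function(lab1, lab2, ann1, ann2) {
  same <- !is.na(ann1) & !is.na(ann2) & ann1 == ann2
  ifelse(same & lab1 == "true" & lab2 == "true", "true",
         ifelse(same, "scatter", "random"))
}

#' Assemble a listmode dataset
#'
#' Combines prompt and delayed coincidences into one time-ordered record
#' table with acquisition metadata.
#'
#' @param prompts,delayeds Coincidence tables from [sort_prompts()] /
#'   [sort_delayed()].
#' @param duration_s Acquisition duration (seconds).
#' @param activity_bq Source activity (Bq), carried as metadata.
#' @param preset Acquisition preset name.
#' @return A `listmode_dataset`: list with `records` (data.table) and `meta`.
#' @export
listmode_dataset <- function(prompts, delayeds = empty_coincidences(),
                             duration_s = NA_real_, activity_bq = NA_real_,
                             preset = NA_character_) {
  rec <- rbind(prompts, delayeds)
  if (nrow(rec)) data.table::setorder(rec, t1_ps)
  structure(list(
    records = rec,
    meta = list(duration_s = duration_s, activity_bq = activity_bq,
                preset = preset, truncated = FALSE)),
    class = "listmode_dataset")
}

#' @export
print.listmode_dataset <- function(x, ...) {
  np <- sum(x$records$window == "prompt")
  cat(sprintf("listmode_dataset: %d records (%d prompts, %d delayeds), duration %.4g s%s\n",
              nrow(x$records), np, nrow(x$records) - np,
              x$meta$duration_s,
              if (isTRUE(x$meta$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Truncate a listmode dataset at a prompt-count cap
#'
#' Keeps records up to and including the `max_prompts`-th prompt; the
#' effective duration (time of the last kept record since acquisition
#' start) replaces the metadata duration so that all downstream rates use
#' the truncated time base.
#'
#' @param dataset A [listmode_dataset()].
#' @param max_prompts Prompt cap (default 2e6).
#' @return The (possibly) truncated dataset.
#' @export
truncate_prompts <- function(dataset, max_prompts = 2e6) {
  stopifnot(max_prompts > 0)
  rec <- dataset$records
  np <- cumsum(rec$window == "prompt")
  if (!nrow(rec) || np[nrow(rec)] <= max_prompts) return(dataset)
  cut <- which(np == max_prompts & rec$window == "prompt")[1]
  dataset$records <- rec[seq_len(cut)]
  dataset$meta$duration_s <- rec$t1_ps[cut] / 1e12
  dataset$meta$truncated <- TRUE
  dataset
}
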