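#' Kymograph calibration
#'
#' Spatial and temporal calibration of a kymograph: micrometres per pixel
#' along the space axis and seconds per frame along the time axis. The
#' defaults correspond to a typical EMCCD TIRF configuration (0.064
#' micrometres/pixel) imaged at 3-s intervals.
#'
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return An object of class `kymo_calibration`.
#' @export
kymo_calibration <- function(pixel_size = 0.064, frame_interval = 3) {
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("`pixel_size` and `frame_interval` must be positive", call. = FALSE)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval),
            class = "kymo_calibration")
}

#' Convert traced kymograph segments into dynamic events
#'
#' Each manually traced segment (a displacement in pixels over a number of
#' frames) becomes one event with a signed rate in micrometres/minute
#' (positive toward growth) and a duration in minutes. Classes are then
#' assigned and short near-stationary segments merged by [classify_pauses()].
#'
#' @param segments data.frame with columns `mt_id`, `dx_px` (signed pixel
#'   displacement), `dt_frames` (> 0) and optionally `tip_marker` (0/1 flag:
#'   tip-bound protein present during the segment). Rows are taken in order
#'   within each `mt_id`.
#' @param calib a [kymo_calibration()].
#' @param min_pause_s,max_pause_rate passed to [classify_pauses()].
#' @param classify apply [classify_pauses()] (default); set `FALSE` to get
#'   raw sign-classified events.
#' @return data.frame of events: `mt_id`, `class` (`growth`, `pause`,
#'   `shrinkage`), `rate_um_min`, `duration_min`, `tip_marker`.
#' @examples
#' seg <- data.frame(mt_id = "mt1", dx_px = 50, dt_frames = 100)
#' segments_to_events(seg, kymo_calibration(0.064, 3))
#' @export
segments_to_events <- function(segments, calib = kymo_calibration(),
                               min_pause_s = 15, max_pause_rate = 0.05,
                               classify = TRUE) {
  stopifnot(inherits(calib, "kymo_calibration"))
  segments <- as.data.frame(segments)
  needed <- c("mt_id", "dx_px", "dt_frames")
  miss <- setdiff(needed, names(segments))
  if (length(miss))
    stop("missing segment columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(segments$dt_frames <= 0))
    stop("segment durations `dt_frames` must be positive", call. = FALSE)
  if (is.null(segments$tip_marker)) segments$tip_marker <- 0L
  rate <- segments$dx_px * calib$pixel_size /
    (segments$dt_frames * calib$frame_interval) * 60
  duration <- segments$dt_frames * calib$frame_interval / 60
  ev <- data.frame(mt_id = as.character(segments$mt_id),
                   class = ifelse(rate < 0, "shrinkage", "growth"),
                   rate_um_min = rate, duration_min = duration,
                   tip_marker = as.integer(segments$tip_marker),
                   stringsAsFactors = FALSE)
  if (classify)
    ev <- classify_pauses(ev, min_pause_s = min_pause_s,
                          max_pause_rate = max_pause_rate)
  ev
}

#' Apply the pause rule and merge sub-threshold stalls
#'
#' A segment is a pause if and only if its absolute rate is at most
#' `max_pause_rate` (the detection floor for MT elongation) \emph{and} it
#' lasts at least `min_pause_s` seconds (inclusive: a 15.0-s stall is a
#' pause under the defaults). Near-stationary segments shorter than the
#' minimum duration are merged into their longer neighbouring event: the
#' merged event keeps the neighbour's class, its duration is the sum, and
#' its rate is recomputed from the combined displacement, so no observation
#' time is lost.
#'
#' @param events data.frame as produced by [segments_to_events()]
#'   (`classify = FALSE`).
#' @param min_pause_s minimum pause duration in seconds.
#' @param max_pause_rate maximum absolute rate of a pause, micrometres per
#'   minute.
#' @return Reclassified events data.frame.
#' @export
classify_pauses <- function(events, min_pause_s = 15, max_pause_rate = 0.05) {
  events <- as.data.frame(events)
  out <- list()
  for (id in unique(events$mt_id)) {
    ev <- events[events$mt_id == id, , drop = FALSE]
    slow <- abs(ev$rate_um_min) <= max_pause_rate
    long_enough <- ev$duration_min * 60 >= min_pause_s
    ev$class <- ifelse(slow & long_enough, "pause",
                       ifelse(ev$rate_um_min < 0, "shrinkage", "growth"))
    # merge short near-stationary stalls into the longer neighbour
    drop <- which(slow & !long_enough)
    while (length(drop)) {
      i <- drop[1L]
      nb <- c(if (i > 1L) i - 1L, if (i < nrow(ev)) i + 1L)
      nb <- setdiff(nb, drop)
      if (length(nb) == 0L) {
        # no mergeable neighbour: keep as its own (near-zero) growth segment
        ev$class[i] <- "growth"
        drop <- drop[-1L]
        next
      }
      j <- nb[which.max(ev$duration_min[nb])]
      disp <- ev$rate_um_min[c(i, j)] %*% ev$duration_min[c(i, j)]
      dur <- sum(ev$duration_min[c(i, j)])
      ev$rate_um_min[j] <- as.numeric(disp) / dur
      ev$duration_min[j] <- dur
      ev <- ev[-i, , drop = FALSE]
      drop <- which(abs(ev$rate_um_min) <= max_pause_rate &
                      ev$duration_min * 60 < min_pause_s)
    }
    out[[length(out) + 1L]] <- ev
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Catastrophe frequency
#'
#' Number of transitions into shrinkage (growth-to-shrinkage, and
#' pause-to-shrinkage, since transient pauses end in depolymerisation)
#' divided by the total time spent in growth and pause, in events per
#' minute.
#'
#' @param events data.frame of classified events with `mt_id` ordering
#'   events within each MT.
#' @return list with `rate_per_min` (`NA` if no growth or pause time was
#'   observed), `n_catastrophes` and `time_growing_min`.
#' @export
catastrophe_frequency <- function(events) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) stop("no events supplied", call. = FALSE)
  n_cat <- 0L
  for (id in unique(events$mt_id)) {
    cl <- events$class[events$mt_id == id]
    if (length(cl) < 2L) next
    n_cat <- n_cat + sum(cl[-length(cl)] %in% c("growth", "pause") &
                           cl[-1L] == "shrinkage")
  }
  t_grow <- sum(events$duration_min[events$class %in% c("growth", "pause")])
  list(rate_per_min = if (t_grow > 0) n_cat / t_grow else NA_real_,
       n_catastrophes = n_cat, time_growing_min = t_grow)
}

#' Categorise an MT end history
#'
#' Mirrors the manual sorting of seeds on kymographs: `fully_blocked` if no
#' growth event occurred over the whole observation window,
#' `occasional_pauses` if the end grew but paused at least `min_pauses`
#' times, otherwise `no_pauses`.
#'
#' @param events data.frame of classified events for a single MT.
#' @param min_pauses minimum number of pause events for the
#'   `occasional_pauses` category.
#' @return One of `"no_pauses"`, `"occasional_pauses"`, `"fully_blocked"`.
#' @export
end_category <- function(events, min_pauses = 1L) {
  events <- as.data.frame(events)
  if (nrow(events) == 0L) stop("empty history", call. = FALSE)
  has_growth <- any(events$class == "growth")
  n_pause <- sum(events$class == "pause")
  if (!has_growth) "fully_blocked"
  else if (n_pause >= min_pauses) "occasional_pauses"
  else "no_pauses"
}

#' Time-weighted distribution of rates
#'
#' Weights every event by its share of the total observed time (duration
#' divided by the summed duration of all events) and accumulates the
#' weighted distribution of rates. The cumulative curve answers "what
#' percentage of total time was spent at a rate of at most x" and is
#' typically plotted against a log-scaled rate axis.
#'
#' @param events data.frame with `rate_um_min` and `duration_min`.
#' @param signed use signed rates (default); `FALSE` restricts to growth
#'   events only.
#' @return An object of class `rate_distribution`: `table` (data.frame
#'   `rate_um_min`, `weight`, `cum_weight`, sorted by rate) and `cdf`, a
#'   step function of rate.
#' @export
time_weighted_rate_distribution <- function(events, signed = TRUE) {
  events <- as.data.frame(events)
  if (!signed) events <- events[events$class == "growth", , drop = FALSE]
  if (nrow(events) == 0L) stop("no events supplied", call. = FALSE)
  w <- events$duration_min / sum(events$duration_min)
  ord <- order(events$rate_um_min)
  tab <- data.frame(rate_um_min = events$rate_um_min[ord], weight = w[ord])
  tab$cum_weight <- cumsum(tab$weight)
  cdf <- function(x) vapply(x, function(xi)
    sum(tab$weight[tab$rate_um_min <= xi]), 0)
  structure(list(table = tab, cdf = cdf), class = "rate_distribution")
}

#' Normalise a FRAP intensity trace
#'
#' Divides an intensity time series by its mean pre-bleach intensity, so the
#' pre-bleach level is 1 by construction. The recovery fraction at a
#' post-bleach time point is the recovered share of the bleached intensity:
#' `(I_norm(t) - I_norm(bleach)) / (1 - I_norm(bleach))`.
#'
#' @param times time points, seconds.
#' @param intensities raw intensities, arbitrary units.
#' @param bleach_index index of the first post-bleach point (at least 3, so
#'   that two or more pre-bleach points exist).
#' @return An object of class `frap_series`: `times`, `intensities`,
#'   `normalized`, `bleach_index`, and `recovery_fraction` (same length as
#'   `times`; `NA` before the bleach).
#' @export
frap_normalize <- function(times, intensities, bleach_index) {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("`times` and `intensities` differ in length", call. = FALSE)
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 3L || bleach_index > length(times))
    stop("need at least 2 pre-bleach points before `bleach_index`",
         call. = FALSE)
  pre <- mean(intensities[seq_len(bleach_index - 1L)])
  if (!is.finite(pre) || pre <= 0)
    stop("pre-bleach mean must be positive", call. = FALSE)
  norm <- intensities / pre
  i0 <- norm[bleach_index]
  rec <- rep(NA_real_, length(times))
  if (i0 < 1) {
    post <- bleach_index:length(times)
    rec[post] <- (norm[post] - i0) / (1 - i0)
  } else {
    rec[bleach_index:length(times)] <- 0
  }
  structure(list(times = times, intensities = intensities, normalized = norm,
                 bleach_index = bleach_index, recovery_fraction = rec),
            class = "frap_series")
}

#' Average normalised FRAP curves across MTs
#'
#' @param series list of `frap_series` sharing a common time base.
#' @return data.frame with `time_s`, `mean_normalized`, `sd_normalized`, `n`.
#' @export
frap_average <- function(series) {
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, TRUE, "frap_series")))
  t0 <- series[[1L]]$times
  for (s in series)
    if (length(s$times) != length(t0) || any(abs(s$times - t0) > 1e-9))
      stop("all series must share one time base", call. = FALSE)
  mat <- do.call(rbind, lapply(series, function(s) s$normalized))
  data.frame(time_s = t0,
             mean_normalized = colMeans(mat),
             sd_normalized = if (nrow(mat) >= 2L) apply(mat, 2L, sd)
                             else rep(NA_real_, ncol(mat)),
             n = nrow(mat))
}
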