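#' Baseline statistics of ROI traces
#'
#' Computes the mean and population standard deviation (divisor `N`) of the
#' pre-stimulus baseline for every trial in a long trace tibble. The default
#' window is the full pre-onset epoch (the first 500 ms at the reference
#' 1000 fps acquisition).
#'
#' @param traces Long trace tibble ([roi_trace()] rows, possibly many trials).
#' @param window Optional inclusive 0-based frame range `c(first, last)`;
#'   must end at or before the stimulus onset.
#' @return Tibble with one row per trial: `mouse_id`, `trial_id`,
#'   `baseline_mean`, `baseline_sd`, `window_start`, `window_end`,
#'   `n_baseline`.
#' @examples
#' tr <- roi_trace(rep(c(98, 100, 102), length.out = 300), 1000, 150)
#' baseline_stats(tr)
#' @export
baseline_stats <- function(traces, window = NULL) {
  assert_trace(traces)
  trace_groups(traces) %>%
    dplyr::group_modify(function(tr, key) {
      onset <- tr$onset_frame[1]
      w <- window %||% c(0L, onset - 1L)
      if (length(w) != 2L || w[2] < w[1]) {
        abort("baseline window is empty.", class = "pawkit_config_error")
      }
      if (w[2] >= onset) {
        abort("baseline window must end before the stimulus onset.",
              class = "pawkit_config_error")
      }
      sel <- tr$intensity[tr$frame >= w[1] & tr$frame <= w[2]]
      if (length(sel) == 0L) abort("baseline window is empty.",
                                   class = "pawkit_config_error")
      tibble(baseline_mean = mean(sel), baseline_sd = pop_sd(sel),
             window_start = as.integer(w[1]), window_end = as.integer(w[2]),
             n_baseline = length(sel))
    }) %>%
    ungroup()
}

detection_threshold <- function(mean, sd, rule, thr) {
  if (rule == "sd5") {
    out <- mean - thr$sd_multiple * sd
    if (any(sd == 0)) {
      warn("degenerate baseline (sd = 0): threshold set at the baseline mean (strict drops only).",
           class = "pawkit_degenerate_baseline")
      # a hair under the mean so only strict drops qualify, not equality
      out[sd == 0] <- mean[sd == 0] - 1e-9
    }
    out
  } else {
    pmin((1 - thr$strict_fall_frac) * mean, mean - thr$strict_sd_multiple * sd)
  }
}

#' Detect paw-withdrawal events
#'
#' A withdrawal is a drop of the FTIR contact signal to or below the
#' baseline mean minus five baseline standard deviations (`rule = "sd5"`).
#' The conservative `"strict"` rule — used for pulse-train and patterned
#' stimulation where false positives are costlier — additionally requires a
#' 20% fall from baseline, i.e. the signal must reach
#' `min(0.8 * mean, mean - 4 * sd)`. Latency is the time from pulse start to
#' the first qualifying frame, reported at the frame grain in ms.
#'
#' @param traces Long trace tibble.
#' @param stats Optional precomputed [baseline_stats()]; computed on the
#'   default window otherwise.
#' @param rule `"sd5"` or `"strict"`.
#' @param thresholds Named list, see [default_thresholds()].
#' @return Tibble, one row per trial: ids, `rule`, `threshold`, `responded`,
#'   `latency_ms`, `latency_frames`, plus the baseline columns.
#' @examples
#' tr <- roi_trace(c(rep(100, 500), rep(100, 29), rep(60, 100)), 1000, 500)
#' detect_withdrawal(tr)$latency_ms
#' @export
detect_withdrawal <- function(traces, stats = NULL,
                              rule = c("sd5", "strict"),
                              thresholds = default_thresholds()) {
  rule <- match.arg(rule)
  assert_trace(traces)
  stats <- stats %||% baseline_stats(traces)
  trace_groups(traces) %>%
    dplyr::group_modify(function(tr, key) {
      st <- stats[stats$mouse_id == key$mouse_id &
                    stats$trial_id == key$trial_id, ]
      if (nrow(st) != 1L) abort("baseline stats missing for a trial.",
                                class = "pawkit_validation_error")
      onset <- tr$onset_frame[1]
      post <- tr[tr$frame >= onset, ]
      if (nrow(post) == 0L) abort("post-stimulus segment is empty.",
                                  class = "pawkit_validation_error")
      thr_val <- detection_threshold(st$baseline_mean, st$baseline_sd, rule,
                                     thresholds)
      hit <- which(post$intensity <= thr_val)
      responded <- length(hit) > 0L
      lat_fr <- if (responded) post$frame[hit[1]] - onset else NA_integer_
      tibble(rule = rule, threshold = thr_val,
             baseline_mean = st$baseline_mean, baseline_sd = st$baseline_sd,
             responded = responded,
             latency_frames = as.integer(lat_fr),
             latency_ms = lat_fr * 1000 / tr$fps[1])
    }) %>%
    ungroup()
}

#' 20-80% rise time of detected withdrawals
#'
#' Rise time — the proxy for response vigor — is the time the signal takes
#' to pass from 20% to 80% of its total fall, measured from the baseline
#' mean to the post-onset minimum, with linear interpolation between frames.
#' Non-responding trials get `NA`.
#'
#' @param traces Long trace tibble.
#' @param events Output of [detect_withdrawal()].
#' @return `events` with columns `rise_time_ms` and `rise_flag`
#'   (`"ok"`, `"no-crossing"`, or `NA` for non-responders).
#' @export
rise_time <- function(traces, events) {
  assert_trace(traces)
  per_trial <- trace_groups(traces) %>%
    dplyr::group_modify(function(tr, key) {
      ev <- events[events$mouse_id == key$mouse_id &
                     events$trial_id == key$trial_id, ]
      if (nrow(ev) != 1L || !isTRUE(ev$responded)) {
        return(tibble(rise_time_ms = NA_real_, rise_flag = NA_character_))
      }
      onset <- tr$onset_frame[1]
      seg <- tr[tr$frame >= onset, ]
      m <- ev$baseline_mean
      fall <- m - trace_floor(seg$intensity)
      if (fall <= 0) return(tibble(rise_time_ms = NA_real_,
                                   rise_flag = "no-crossing"))
      t20 <- crossing_time(seg$time_ms, seg$intensity, m - 0.2 * fall)
      t80 <- crossing_time(seg$time_ms, seg$intensity, m - 0.8 * fall)
      if (is.na(t20) || is.na(t80)) {
        return(tibble(rise_time_ms = NA_real_, rise_flag = "no-crossing"))
      }
      tibble(rise_time_ms = t80 - t20, rise_flag = "ok")
    }) %>%
    ungroup()
  left_join(events, per_trial, by = c("mouse_id", "trial_id"))
}

# response floor: minimum of the running-median (radius 2) trace, so the
# floor reflects the contact signal rather than the deepest single-frame
# noise excursion; falls back to the raw minimum for very short segments
trace_floor <- function(v, radius = 2L) {
  k <- 2L * radius + 1L
  if (length(v) < k) return(min(v))
  min(stats::runmed(v, k, endrule = "keep"))
}

# first time the series falls to or below `level`, linearly interpolated
crossing_time <- function(time, value, level) {
  idx <- which(value <= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  if (i == 1L || value[i - 1L] <= level) return(time[i])
  a <- value[i - 1L]; b <- value[i]
  time[i - 1L] + (a - level) / (a - b) * (time[i] - time[i - 1L])
}

#' Response extent and full/partial classification
#'
#' Extent is the percentage of the baseline FTIR signal removed at the
#' post-onset floor, `100 * (mean - floor) / mean`, where the floor is the
#' minimum of a running-median (radius 2) copy of the trace so that extent
#' measures the contact signal rather than single-frame noise. A trial is a
#' full
#' response when the minimum is at or below 25% of the baseline mean (a
#' drop of at least 75% of the baseline signal); a detected withdrawal that
#' stays above that level is partial; non-responders are `"none"`.
#'
#' @param traces Long trace tibble.
#' @param events Output of [detect_withdrawal()] (supplies `responded`).
#' @param window Optional inclusive post-onset frame range `c(first, last)`
#'   relative to the recording (0-based absolute frames). Defaults to the
#'   full post-onset epoch.
#' @param thresholds See [default_thresholds()] (`full_extent_frac`).
#' @return `events` with `extent_pct` and `extent_class` columns.
#' @export
classify_extent <- function(traces, events, window = NULL,
                            thresholds = default_thresholds()) {
  assert_trace(traces)
  per_trial <- trace_groups(traces) %>%
    dplyr::group_modify(function(tr, key) {
      ev <- events[events$mouse_id == key$mouse_id &
                     events$trial_id == key$trial_id, ]
      onset <- tr$onset_frame[1]
      w <- window %||% c(onset, max(tr$frame))
      seg <- tr$intensity[tr$frame >= w[1] & tr$frame <= w[2]]
      if (length(seg) == 0L) abort("extent window is empty.",
                                   class = "pawkit_config_error")
      m <- ev$baseline_mean
      if (m == 0) abort("baseline mean is zero; extent undefined.",
                        class = "pawkit_validation_error")
      mn <- trace_floor(seg)
      extent <- 100 * (m - mn) / m
      cls <- if (mn <= (1 - thresholds$full_extent_frac) * m) "full"
             else if (isTRUE(ev$responded)) "partial" else "none"
      tibble(extent_pct = extent, extent_class = cls)
    }) %>%
    ungroup()
  left_join(events, per_trial, by = c("mouse_id", "trial_id"))
}

#' Quality control of withdrawal trials
#'
#' Applies the recording-quality and plausibility screens: the baseline
#' 8-bit mean must be at least 3 (enough light to lose), the baseline
#' signal-to-noise ratio mean/SD must be at least 23 (rejects noisy
#' baselines), and a detected latency must exceed 10 ms — faster responses
#' cannot be generated by the stimulus and indicate spontaneous movement.
#'
#' @param events Event tibble with `baseline_mean`, `baseline_sd` and
#'   `latency_ms` columns.
#' @param thresholds See [default_thresholds()].
#' @param snr_direction `"mean_over_sd"` (default) or `"sd_over_mean"`; which
#'   ratio is compared against `qc_min_snr`.
#' @return `events` with logical `qc_pass` and a `qc_reasons` string
#'   (`;`-separated reason codes, `""` when passing).
#' @export
qc_trace <- function(events, thresholds = default_thresholds(),
                     snr_direction = c("mean_over_sd", "sd_over_mean")) {
  snr_direction <- match.arg(snr_direction)
  reasons <- purrr::pmap_chr(
    list(events$baseline_mean, events$baseline_sd, events$latency_ms),
    function(m, s, lat) {
      r <- character()
      if (m < thresholds$qc_min_baseline_mean) r <- c(r, "low-baseline")
      snr <- if (snr_direction == "mean_over_sd") {
        if (s == 0) Inf else m / s
      } else {
        if (m == 0) Inf else s / m
      }
      if (snr < thresholds$qc_min_snr) r <- c(r, "noisy-baseline")
      if (!is.na(lat) && lat <= thresholds$qc_min_latency_ms) {
        r <- c(r, "implausible-latency")
      }
      paste(r, collapse = ";")
    })
  mutate(events, qc_pass = reasons == "", qc_reasons = reasons)
}

#' Full per-trial withdrawal characterization
#'
#' Convenience pipeline: [detect_withdrawal()], then [rise_time()],
#' [classify_extent()] and [qc_trace()], returning one fully annotated row
#' per trial. This is what the `withdrawal` CLI subcommand writes.
#'
#' @inheritParams detect_withdrawal
#' @inheritParams qc_trace
#' @param extent_window Passed to [classify_extent()] as `window`.
#' @return Annotated event tibble.
#' @export
withdrawal_events <- function(traces, rule = c("sd5", "strict"),
                              thresholds = default_thresholds(),
                              extent_window = NULL,
                              snr_direction = "mean_over_sd") {
  rule <- match.arg(rule)
  detect_withdrawal(traces, rule = rule, thresholds = thresholds) %>%
    rise_time(traces, .) %>%
    classify_extent(traces, ., window = extent_window, thresholds = thresholds) %>%
    qc_trace(thresholds = thresholds, snr_direction = snr_direction)
}

#' Median-filter an ROI trace
#'
#' Optional running-median preprocessing (radius 2 frames by default) used
#' for presentation traces; detection latencies move by at most a couple of
#' frames under it at realistic noise.
#'
#' @param traces Long trace tibble.
#' @param radius Half-width of the running median window, in frames.
#' @return Trace tibble with smoothed intensities.
#' @export
smooth_trace <- function(traces, radius = 2L) {
  assert_trace(traces)
  trace_groups(traces) %>%
    mutate(intensity = as.numeric(stats::runmed(.data$intensity,
                                                2L * radius + 1L,
                                                endrule = "keep"))) %>%
    ungroup()
}

#' Per-pixel latency and motion-energy maps
#'
#' Applies the withdrawal-detection rule independently to every pixel of a
#' frame stack: baseline mean/SD per pixel over the pre-onset frames, then
#' the first post-onset crossing of the rule threshold. Pixels that never
#' cross get the `NaN` sentinel (-1 in integer exports). The motion-energy
#' image counts, per pixel, the consecutive frame pairs whose absolute
#' change exceeds `delta_threshold`.
#'
#' @param stack A [frame_stack()] with at least 2 baseline frames.
#' @param rule `"sd5"` or `"strict"`.
#' @param thresholds See [default_thresholds()].
#' @param delta_threshold 8-bit change threshold for the motion-energy image.
#' @return Object of class `latency_map`: list with `latency_ms` and
#'   `motion_energy` matrices (`height x width`), plus `fps` and
#'   `onset_frame`.
#' @export
pixel_latency_map <- function(stack, rule = c("sd5", "strict"),
                              thresholds = default_thresholds(),
                              delta_threshold = thresholds$delta_threshold) {
  rule <- match.arg(rule)
  stopifnot(inherits(stack, "frame_stack"))
  onset <- attr(stack, "onset_frame")
  fps <- attr(stack, "fps")
  if (onset < 2L) abort("need at least 2 baseline frames.",
                        class = "pawkit_validation_error")
  arr <- unclass(stack)
  base <- arr[seq_len(onset), , , drop = FALSE]
  m <- apply(base, c(2, 3), mean)
  s <- apply(base, c(2, 3), pop_sd)
  thr <- if (rule == "sd5") {
    t0 <- m - thresholds$sd_multiple * s
    t0[s == 0] <- m[s == 0] - 1e-9  # degenerate pixels: strict drops only
    t0
  } else {
    pmin((1 - thresholds$strict_fall_frac) * m,
         m - thresholds$strict_sd_multiple * s)
  }
  post <- arr[(onset + 1L):dim(arr)[1], , , drop = FALSE]
  cross <- sweep(post, c(2, 3), thr, `<=`)
  first_idx <- apply(cross, c(2, 3), function(v) {
    i <- which(v)
    if (length(i)) i[1] else NA_integer_
  })
  latency_ms <- (first_idx - 1L) * 1000 / fps  # first post frame = onset itself
  latency_ms[is.na(first_idx)] <- NaN
  d <- abs(arr[-1L, , , drop = FALSE] - arr[-dim(arr)[1], , , drop = FALSE])
  me <- apply(d > delta_threshold, c(2, 3), sum)
  structure(list(latency_ms = latency_ms, motion_energy = me,
                 baseline_mean = m, baseline_sd = s,
                 fps = fps, onset_frame = onset, rule = rule),
            class = "latency_map")
}

#' Plot ROI traces with detected withdrawals
#'
#' One panel per trial: the FTIR intensity trace, the detection threshold,
#' and the detected latency.
#'
#' @param traces Long trace tibble.
#' @param events Optional [detect_withdrawal()] output.
#' @return A ggplot.
#' @export
plot_withdrawal <- function(traces, events = NULL) {
  p <- ggplot(traces, aes(x = .data$time_ms, y = .data$intensity)) +
    geom_line(colour = "grey20", linewidth = 0.3) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "steelblue") +
    facet_wrap(~ mouse_id + trial_id) +
    labs(x = "time from stimulus onset (ms)", y = "FTIR intensity (8-bit)")
  if (!is.null(events)) {
    ev <- filter(events, .data$responded)
    p <- p +
      geom_hline(data = events, aes(yintercept = .data$threshold),
                 colour = "grey60", linetype = "dotted") +
      geom_vline(data = ev, aes(xintercept = .data$latency_ms),
                 colour = "firebrick")
  }
  p
}

#' @export
print.latency_map <- function(x, ...) {
  cat(sprintf("<latency_map> %d x %d px, %d responding (rule %s)\n",
              nrow(x$latency_ms), ncol(x$latency_ms),
              sum(is.finite(x$latency_ms)), x$rule))
  invisible(x)
}
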