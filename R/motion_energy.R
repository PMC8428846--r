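#' Binarized whole-body motion energy
#'
#' Whole-body movement is approximated as binarized motion energy: for each
#' pair of consecutive frames, the number of pixels whose 8-bit value
#' changed by more than `delta_threshold` (strictly; a change of exactly the
#' threshold counts as no motion). The default threshold of five 8-bit
#' values discards sensor noise at 40 fps; seven is appropriate for the
#' 400 fps high-speed view. Laser-affected frames can be excluded; they are
#' dropped before pairing, so the remaining frames are differenced across
#' the gap.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param delta_threshold Non-negative 8-bit change threshold.
#' @param excluded_frames 0-based frame indices to drop (e.g. stimulation
#'   frames).
#' @return Tibble, one row per retained frame pair: `frame` (0-based index
#'   of the later frame), `time_ms`, `pixel_change` (count), plus `fps`,
#'   `onset_frame`, `n_pixels`.
#' @examples
#' fs <- frame_stack(array(0, c(4, 8, 8)), fps = 40, onset_frame = 1)
#' binarized_motion_energy(fs)$pixel_change
#' @export
binarized_motion_energy <- function(stack, delta_threshold = 5,
                                    excluded_frames = integer()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (delta_threshold < 0) abort("`delta_threshold` must be >= 0.",
                                 class = "pawkit_config_error")
  arr <- unclass(stack)
  keep <- setdiff(seq_len(dim(arr)[1]) - 1L, as.integer(excluded_frames))
  if (length(keep) < 2L) abort("need at least 2 retained frames.",
                               class = "pawkit_validation_error")
  arr <- arr[keep + 1L, , , drop = FALSE]
  d <- abs(arr[-1L, , , drop = FALSE] - arr[-dim(arr)[1], , , drop = FALSE])
  counts <- apply(d > delta_threshold, 1L, sum)
  tibble(
    frame = keep[-1L],
    time_ms = frames_to_ms(keep[-1L], attr(stack, "onset_frame"),
                           attr(stack, "fps")),
    pixel_change = as.integer(counts),
    fps = attr(stack, "fps"),
    onset_frame = attr(stack, "onset_frame"),
    n_pixels = dim(arr)[2] * dim(arr)[3]
  )
}

#' Normalize a motion-energy trace to its baseline
#'
#' Subtracts the mean baseline pixel-change count from every value, so
#' baseline activity sits at 0 and movement is positive. For the high-speed
#' mode the counts can additionally be divided by the number of pixels per
#' frame, giving the fraction of the frame in motion.
#'
#' @param trace Output of [binarized_motion_energy()].
#' @param baseline_window Optional inclusive frame range `c(first, last)`
#'   (0-based) for the baseline; defaults to all pre-onset pairs.
#' @param per_pixel Divide by `n_pixels` (high-speed variant)?
#' @return `trace` with columns `me_norm` (normalized motion energy),
#'   `baseline_me_mean`, `baseline_me_sd` (population SD over baseline pairs
#'   of the normalized series).
#' @export
normalize_motion <- function(trace, baseline_window = NULL, per_pixel = FALSE) {
  onset <- trace$onset_frame[1]
  w <- baseline_window %||% c(min(trace$frame), onset - 1L)
  base_idx <- trace$frame >= w[1] & trace$frame <= w[2]
  if (!any(base_idx)) abort("baseline window contains no frame pairs.",
                            class = "pawkit_config_error")
  val <- trace$pixel_change
  if (per_pixel) val <- val / trace$n_pixels
  mu <- mean(val[base_idx])
  norm <- val - mu
  mutate(trace, me_norm = norm, baseline_me_mean = mu,
         baseline_me_sd = pop_sd(norm[base_idx]))
}

#' Global response detection from normalized motion energy
#'
#' A trial counts as a global response when the peak normalized motion
#' energy reaches at least `peak_k` (default 5) baseline standard
#' deviations. Movement initiation is the first post-onset time the
#' normalized trace exceeds `onset_k` (default 10) baseline SDs; the bout
#' ends when it first returns below that level, and the duration is the
#' difference. With a zero baseline SD the SD thresholds are degenerate and
#' an absolute fallback of `fallback_abs` counts is used, with a warning.
#'
#' @param trace Output of [normalize_motion()].
#' @param peak_k,onset_k Threshold multipliers in baseline SDs.
#' @param peak_window_ms Optional cap on the peak search window after onset
#'   (e.g. 100 ms for time-locked nociceptor analyses); `Inf` scans the
#'   whole post-onset epoch.
#' @param fallback_abs Absolute threshold used when the baseline SD is 0.
#' @return One-row tibble: `peak`, `peak_time_ms`, `peak_pass`,
#'   `onset_ms`, `bout_end_ms`, `bout_duration_ms`, `peak_k`, `onset_k`,
#'   `baseline_me_sd`.
#' @export
detect_global_response <- function(trace, peak_k = 5, onset_k = 10,
                                   peak_window_ms = Inf, fallback_abs = 1) {
  if (!"me_norm" %in% names(trace)) {
    abort("run normalize_motion() first.", class = "pawkit_validation_error")
  }
  s <- trace$baseline_me_sd[1]
  if (s == 0) {
    warn("baseline motion-energy SD is 0; using absolute threshold fallback.",
         class = "pawkit_degenerate_baseline")
  }
  thr_peak <- if (s > 0) peak_k * s else fallback_abs
  thr_onset <- if (s > 0) onset_k * s else fallback_abs
  post <- trace[trace$time_ms >= 0, ]
  peak_seg <- post[post$time_ms <= peak_window_ms, ]
  pk_i <- which.max(peak_seg$me_norm)
  peak <- peak_seg$me_norm[pk_i]
  above <- post$me_norm > thr_onset
  on_i <- which(above)[1]
  if (is.na(on_i)) {
    onset_ms <- end_ms <- dur <- NA_real_
  } else {
    onset_ms <- post$time_ms[on_i]
    back <- which(!above & seq_along(above) > on_i)[1]
    end_ms <- if (is.na(back)) NA_real_ else post$time_ms[back]
    dur <- end_ms - onset_ms
  }
  tibble(peak = peak, peak_time_ms = peak_seg$time_ms[pk_i],
         peak_pass = peak >= thr_peak,
         onset_ms = onset_ms, bout_end_ms = end_ms, bout_duration_ms = dur,
         peak_k = peak_k, onset_k = onset_k, baseline_me_sd = s)
}

#' Plot a normalized motion-energy trace with detected bout
#'
#' @param trace Output of [normalize_motion()].
#' @param response Optional output of [detect_global_response()]; onset and
#'   bout end are drawn when provided.
#' @return A ggplot.
#' @export
plot_motion_energy <- function(trace, response = NULL) {
  p <- ggplot(trace, aes(x = .data$time_ms, y = .data$me_norm)) +
    geom_line(colour = "grey25") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "steelblue") +
    labs(x = "time from stimulus onset (ms)",
         y = "normalized binarized motion energy (pixels)")
  if (!is.null(response) && is.finite(response$onset_ms[1])) {
    p <- p + geom_vline(xintercept = response$onset_ms[1], colour = "firebrick")
    if (is.finite(response$bout_end_ms[1])) {
      p <- p + geom_vline(xintercept = response$bout_end_ms[1],
                          colour = "firebrick", linetype = "dotted")
    }
  }
  p
}
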