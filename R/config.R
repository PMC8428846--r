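#' Calibrated stimulation spot areas
#'
#' The eight calibrated laser spot areas (mm^2) used throughout the
#' stimulation protocols, smallest (`S1`) to largest (`S8`). Power density is
#' held constant across spot sizes, so spot area is the natural measure of
#' nociceptive input size.
#'
#' @format Named numeric vector of length 8 (mm^2).
#' @export
spot_areas <- c(
  S1 = 0.0185, S2 = 0.032, S3 = 0.0809, S4 = 0.176,
  S5 = 0.338, S6 = 0.627, S7 = 1.155, S8 = 2.307
)

#' Run configuration for the analysis pipeline
#'
#' Bundles the acquisition geometry and every detection threshold in one
#' validated object so a whole run is reproducible from `(inputs, config,
#' seed)` alone.
#'
#' Times are reported in milliseconds relative to stimulus onset (onset =
#' 0 ms); frame indices are 0-based, so an event first seen at frame `f` has
#' latency `(f - onset_frame) * 1000 / fps`. Image origin is top-left with y
#' increasing downward (video convention), which fixes the sign of head-yaw
#' angles.
#'
#' @param fps Frames per second of the recording the config is applied to.
#'   Local FTIR views run at 250-1000 fps, whole-body views at 40 or 400 fps.
#' @param onset_frame 0-based index of the stimulus-onset frame.
#' @param baseline_frames Number of frames in the baseline window that ends at
#'   the stimulus onset. Default covers the first 500 ms at `fps`.
#' @param detection_rule `"sd5"` (drop to or below baseline mean minus five
#'   baseline SDs) or `"strict"` (additionally requires a 20% fall, with a
#'   four-SD floor).
#' @param thresholds Named list of scalar thresholds; unnamed entries of
#'   [default_thresholds()] are filled in.
#' @param mm_per_px Pixel pitch in mm (default 0.32, the 400 fps whole-body
#'   camera).
#' @param seed Integer seed recorded with the run.
#' @param output_dir Directory CLI results are written to.
#'
#' @return A list with class `"pawkit_config"`.
#' @examples
#' cfg <- run_config(fps = 1000, onset_frame = 500)
#' cfg$thresholds$sd_multiple
#' @export
run_config <- function(fps = 1000,
                       onset_frame = round(0.5 * fps),
                       baseline_frames = onset_frame,
                       detection_rule = c("sd5", "strict"),
                       thresholds = list(),
                       mm_per_px = 0.32,
                       seed = 1L,
                       output_dir = ".") {
  detection_rule <- match.arg(detection_rule)
  if (!is.numeric(fps) || fps <= 0) abort("`fps` must be > 0.", class = "pawkit_config_error")
  if (onset_frame < 0) abort("`onset_frame` must be >= 0.", class = "pawkit_config_error")
  if (baseline_frames > onset_frame) {
    abort("baseline window must end at or before the stimulus onset.",
          class = "pawkit_config_error")
  }
  thr <- utils::modifyList(default_thresholds(), as.list(thresholds))
  structure(
    list(fps = fps, onset_frame = as.integer(onset_frame),
         baseline_frames = as.integer(baseline_frames),
         detection_rule = detection_rule, thresholds = thr,
         mm_per_px = mm_per_px, seed = as.integer(seed),
         output_dir = output_dir),
    class = "pawkit_config"
  )
}

#' Default detection and QC thresholds
#'
#' @return Named list of the scalar thresholds used across the pipeline:
#' \describe{
#'   \item{sd_multiple}{5; withdrawal = drop at or below baseline mean minus
#'     this many baseline SDs.}
#'   \item{strict_fall_frac}{0.20; extra fractional fall required by the
#'     strict rule.}
#'   \item{strict_sd_multiple}{4; SD floor of the strict rule.}
#'   \item{full_extent_frac}{0.75; a full response removes at least 75% of the
#'     baseline signal.}
#'   \item{qc_min_baseline_mean}{3; minimum baseline 8-bit mean.}
#'   \item{qc_min_snr}{23; minimum baseline mean/SD ratio.}
#'   \item{qc_min_latency_ms}{10; latencies at or below this are implausibly
#'     fast for the stimulus and fail QC.}
#'   \item{delta_threshold}{5; 8-bit pixel-change threshold for binarized
#'     motion energy at 40 fps (use 7 for 400 fps analyses).}
#'   \item{peak_k}{5; peak normalized motion energy must reach this many
#'     baseline SDs.}
#'   \item{onset_k}{10; global onset/termination threshold in baseline SDs.}
#'   \item{p_cutoff}{0.95; pose-label likelihood cutoff.}
#'   \item{jump_px}{10; one-frame jump distance treated as a labeling glitch.}
#' }
#' @export
default_thresholds <- function() {
  list(
    sd_multiple = 5, strict_fall_frac = 0.20, strict_sd_multiple = 4,
    full_extent_frac = 0.75,
    qc_min_baseline_mean = 3, qc_min_snr = 23, qc_min_latency_ms = 10,
    delta_threshold = 5, peak_k = 5, onset_k = 10,
    p_cutoff = 0.95, jump_px = 10
  )
}

#' @export
print.pawkit_config <- function(x, ...) {
  cat("<pawkit_config>\n")
  cat(sprintf("  fps: %g, onset frame: %d, baseline frames: %d\n",
              x$fps, x$onset_frame, x$baseline_frames))
  cat(sprintf("  rule: %s, mm/px: %g, seed: %d\n", x$detection_rule,
              x$mm_per_px, x$seed))
  invisible(x)
}
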