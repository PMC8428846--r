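#' Specification of a synthetic behavioral cohort
#'
#' Collects every programmable parameter of the synthetic generators in one
#' validated list. Defaults reproduce the study conditions of the reference
#' acquisition: 1000 fps FTIR traces with a 500 ms baseline in a 1500 ms
#' trial, 8-bit baseline mean 100 with Gaussian noise SD 2, withdrawals
#' removing 75% of the contact signal with a 4 ms 20-80% fall, latencies
#' around 30 ms with 5 ms trial-to-trial and 2 ms mouse-to-mouse spread,
#' and 400 fps whole-body pose cohorts with a stimulated-paw onset near
#' 29 ms and a 20 degree head-yaw orienting component.
#'
#' @param n_mice,trials_per_mouse Cohort size (8 x 8 by default).
#' @param fps FTIR frame rate (frames/s).
#' @param trial_ms,baseline_ms Trial and baseline durations (ms); the
#'   stimulus onset frame is `baseline_ms / 1000 * fps`.
#' @param baseline_mean,noise_sd Baseline 8-bit intensity and i.i.d.
#'   Gaussian noise SD.
#' @param extent Fraction of the baseline signal removed by a full
#'   withdrawal (in `[0, 1]`).
#' @param rise_2080_ms Programmed 20-80% fall time (ms).
#' @param latency_mean_ms,latency_trial_sd_ms,latency_mouse_sd_ms Latency
#'   model: population mean, within-mouse SD, and additive mouse-level
#'   random-effect SD (ms).
#' @param p_pulse,n_pulses,isi_ms Response model: per-pulse response
#'   probability, pulses per train, inter-stimulus interval.
#' @param wholebody_fps Whole-body camera frame rate.
#' @param yaw_deg Programmed head yaw toward the stimulated side (degrees).
#' @param paw_onset_ms Programmed stimulated-paw movement onset (ms).
#' @param jitter_sd_px Frame-to-frame pose jitter SD (pixels).
#' @param pose_sd_px Trial-to-trial SD of the resting pose (pixels per part
#'   and axis); the initial-pose variability that dominates pose PCA.
#' @param magnitude_sd Log-normal SD of the per-trial movement magnitude.
#' @param direction_sd_deg Trial-to-trial SD of the paw-withdrawal movement
#'   direction about the outward axis (degrees); withdrawals share a common
#'   direction but not an identical one.
#' @param yaw_sd_deg Trial-to-trial SD of the programmed head yaw.
#' @param contra_frac Movement magnitude of the contralateral hind paw
#'   (fraction of the stimulated paw's; both hind paws move outward).
#' @param body_shift_px Magnitude of a whole-body weight-shift during the
#'   response (pixels, direction uniform per trial); moves every part
#'   coherently, so it survives part shuffling while the part-specific
#'   withdrawal pattern does not.
#' @param dropout_frac Fraction of pose labels dropped below the likelihood
#'   cutoff.
#' @param waveform `"logistic"` (sigmoidal fall, the realistic default) or
#'   `"linear"` (analytic ramp for rise-time checks).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 8, trials_per_mouse = 8,
                        fps = 1000, trial_ms = 1500, baseline_ms = 500,
                        baseline_mean = 100, noise_sd = 2,
                        extent = 0.75, rise_2080_ms = 4,
                        latency_mean_ms = 30, latency_trial_sd_ms = 5,
                        latency_mouse_sd_ms = 2,
                        p_pulse = 1, n_pulses = 1, isi_ms = 100,
                        wholebody_fps = 400, yaw_deg = 20,
                        paw_onset_ms = 29, jitter_sd_px = 0.1,
                        pose_sd_px = 3, magnitude_sd = 0.2,
                        direction_sd_deg = 25, yaw_sd_deg = 3,
                        contra_frac = 0.7, body_shift_px = 4,
                        dropout_frac = 0,
                        waveform = c("logistic", "linear")) {
  waveform <- match.arg(waveform)
  if (n_mice < 1 || trials_per_mouse < 1) {
    abort("need n_mice >= 1 and trials_per_mouse >= 1.",
          class = "pawkit_validation_error")
  }
  if (p_pulse < 0 || p_pulse > 1) abort("p_pulse must lie in [0, 1].",
                                        class = "pawkit_validation_error")
  if (extent < 0 || extent > 1) abort("extent must lie in [0, 1].",
                                      class = "pawkit_validation_error")
  if (baseline_ms >= trial_ms) abort("baseline must end before the trial does.",
                                     class = "pawkit_validation_error")
  structure(as.list(environment()), class = "cohort_spec")
}

# clean (noise-free) withdrawal waveform; the programmed latency is the frame
# at which the clean trace sits one noise-SD beyond the five-SD detection
# level, so the truth is well defined against the noise
ftir_clean_waveform <- function(time_ms, spec, latency_ms) {
  base <- spec$baseline_mean
  A <- spec$extent * base
  d <- max(6 * spec$noise_sd, 1e-6)
  if (A <= d) abort("programmed extent too small to cross the detection threshold.",
                    class = "pawkit_validation_error")
  out <- rep(base, length(time_ms))
  if (spec$waveform == "logistic") {
    s <- spec$rise_2080_ms / log(16)
    t0 <- latency_ms + s * log(A / d - 1)
    seg <- time_ms >= latency_ms
    out[seg] <- base - A / (1 + exp(-(time_ms[seg] - t0) / s))
  } else {
    # linear ramp: full fall over rise_2080_ms / 0.6, starting so that the
    # d-crossing sits exactly at latency_ms
    total <- spec$rise_2080_ms / 0.6
    t_start <- latency_ms - total * d / A
    seg <- time_ms >= t_start
    out[seg] <- pmax(base - A, base - A * (time_ms[seg] - t_start) / total)
  }
  out
}

#' Generate one synthetic FTIR withdrawal trial
#'
#' Emulates the NIR-FTIR signal time course at the stimulation site: a
#' Gaussian-noise baseline at the programmed mean, and — in responding
#' trials — a sigmoidal (or linear) fall of the programmed extent and
#' 20-80% fall time. Programmed latencies are quantized to the frame grid,
#' and the noise-free waveform is placed so that at the latency frame it
#' sits one noise-SD beyond the five-SD detection level: the first-crossing
#' latency of the detector is then comparable frame-for-frame with the
#' recorded truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (generators are deterministic given
#'   `(spec, seed)`).
#' @param mouse_id,trial_id Identifiers.
#' @param respond Force the response flag; default draws from the pulse
#'   model `1 - (1 - p_pulse)^n_pulses`.
#' @param latency_ms Force the latency; default draws from the latency
#'   model.
#' @param render_stack Also render a small frame stack in which a bright
#'   disc dims following the trace (for pixel-level tests)?
#' @param stack_px,disc_radius Stack geometry when rendering.
#' @return List: `trace` (long [roi_trace()] tibble), `truth` (one-row
#'   tibble: `responded`, `true_latency_ms`, `true_rise_ms`,
#'   `true_extent`), and `stack` (a [frame_stack()] or `NULL`).
#' @export
gen_ftir_trial <- function(spec = cohort_spec(), seed = 1,
                           mouse_id = "m1", trial_id = "t1",
                           respond = NULL, latency_ms = NULL,
                           render_stack = FALSE, stack_px = 32,
                           disc_radius = 10) {
  set.seed(seed)
  n <- round(spec$trial_ms / 1000 * spec$fps)
  onset <- round(spec$baseline_ms / 1000 * spec$fps)
  t_ms <- frames_to_ms(seq_len(n) - 1L, onset, spec$fps)
  respond <- respond %||% (runif(1) < sum_rule(spec$p_pulse, spec$n_pulses))
  if (respond) {
    latency_ms <- latency_ms %||%
      max(spec$latency_mean_ms + rnorm(1, 0, spec$latency_trial_sd_ms),
          spec$rise_2080_ms)
    latency_ms <- round(ms_to_frames(latency_ms, spec$fps)) * 1000 / spec$fps
    clean <- ftir_clean_waveform(t_ms, spec, latency_ms)
    truth <- tibble(mouse_id = mouse_id, trial_id = trial_id, responded = TRUE,
                    true_latency_ms = latency_ms,
                    true_rise_ms = spec$rise_2080_ms,
                    true_extent = spec$extent)
  } else {
    clean <- rep(spec$baseline_mean, n)
    truth <- tibble(mouse_id = mouse_id, trial_id = trial_id, responded = FALSE,
                    true_latency_ms = NA_real_, true_rise_ms = NA_real_,
                    true_extent = NA_real_)
  }
  intensity <- pmin(pmax(clean + rnorm(n, 0, spec$noise_sd), 0), 255)
  trace <- roi_trace(intensity, fps = spec$fps, onset_frame = onset,
                     mouse_id = mouse_id, trial_id = trial_id)
  stack <- NULL
  if (render_stack) {
    cx <- cy <- (stack_px + 1) / 2
    xs <- matrix(rep(seq_len(stack_px), each = stack_px), stack_px)
    ys <- matrix(rep(seq_len(stack_px), stack_px), stack_px)
    disc <- (xs - cx)^2 + (ys - cy)^2 <= disc_radius^2
    arr <- array(0, dim = c(n, stack_px, stack_px))
    for (i in seq_len(n)) {
      fr <- matrix(rnorm(stack_px^2, 10, 1), stack_px)
      fr[disc] <- clean[i] + rnorm(sum(disc), 0, spec$noise_sd)
      arr[i, , ] <- pmin(pmax(round(fr), 0), 255)
    }
    stack <- frame_stack(arr, fps = spec$fps, onset_frame = onset)
  }
  list(trace = trace, truth = truth, stack = stack)
}

#' Generate a hierarchically structured cohort of FTIR trials
#'
#' Draws `n_mice x trials_per_mouse` trials; mouse identity shifts the
#' latency by an additive Gaussian random effect of SD
#' `latency_mouse_sd_ms`, trials scatter around that with SD
#' `latency_trial_sd_ms`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List: `traces` (one long tibble, all trials) and `truth` (one
#'   row per trial, including `mouse_effect_ms`).
#' @export
gen_ftir_cohort <- function(spec = cohort_spec(), seed = 1) {
  set.seed(seed)
  mouse_eff <- rnorm(spec$n_mice, 0, spec$latency_mouse_sd_ms)
  jobs <- tidyr::expand_grid(m = seq_len(spec$n_mice),
                             t = seq_len(spec$trials_per_mouse))
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(jobs))
  p_trial <- sum_rule(spec$p_pulse, spec$n_pulses)
  resp <- runif(nrow(jobs)) < p_trial
  lat <- pmax(spec$latency_mean_ms + mouse_eff[jobs$m] +
                rnorm(nrow(jobs), 0, spec$latency_trial_sd_ms),
              spec$rise_2080_ms)
  out <- purrr::pmap(list(jobs$m, jobs$t, seeds, resp, lat),
                     function(m, t, s, r, l) {
                       gen_ftir_trial(spec, seed = s,
                                      mouse_id = sprintf("m%02d", m),
                                      trial_id = sprintf("t%02d", t),
                                      respond = r,
                                      latency_ms = if (r) l else NULL)
                     })
  truth <- purrr::map_dfr(out, "truth")
  truth$mouse_effect_ms <- mouse_eff[jobs$m]
  list(traces = purrr::map_dfr(out, "trace"), truth = truth)
}

#' Generate a synthetic whole-body trial
#'
#' A textured blob (the animal) sits on a sparsely flickering background;
#' from the programmed global onset it translates at a constant speed. An
#' optional saturated disc appears next to one hind paw during the stimulus
#' frames so stimulated-limb detection has ground truth.
#'
#' @param spec A [cohort_spec()] (`wholebody_fps` is used).
#' @param seed Integer seed.
#' @param n_frames,size_px Stack geometry.
#' @param onset_frame 0-based stimulus frame (default `n_frames %/% 3`).
#' @param move_onset_ms Programmed global movement onset (ms after
#'   stimulus).
#' @param speed_px Blob speed (pixels/frame); 0 generates a no-motion trial.
#' @param stim_side `"left"`, `"right"` or `"none"` — where the saturation
#'   disc is drawn.
#' @param flicker_rate Fraction of background pixels per frame that flip by
#'   more than the binarization threshold (gives the baseline motion-energy
#'   distribution a non-zero SD, as camera noise does).
#' @return List: `stack` ([frame_stack()]), `truth` (one-row tibble:
#'   `move_onset_ms`, `move_onset_frame`, `speed_px`, `stim_side`,
#'   `stim_frames`).
#' @export
gen_wholebody_trial <- function(spec = cohort_spec(), seed = 1,
                                n_frames = 120, size_px = 64,
                                onset_frame = n_frames %/% 3,
                                move_onset_ms = 25, speed_px = 2,
                                stim_side = c("none", "left", "right"),
                                flicker_rate = 0.002) {
  stim_side <- match.arg(stim_side)
  set.seed(seed)
  fps <- spec$wholebody_fps
  blob_w <- size_px %/% 4
  texture <- matrix(runif(blob_w^2, 60, 200), blob_w)
  x0 <- size_px %/% 3; y0 <- size_px %/% 2 - blob_w %/% 2
  move_f <- onset_frame + round(ms_to_frames(move_onset_ms, fps))
  stim_frames <- onset_frame + 0:4  # five stimulation frames
  arr <- array(0, dim = c(n_frames, size_px, size_px))
  for (i in seq_len(n_frames)) {
    f <- i - 1L
    fr <- matrix(0, size_px, size_px)
    flick <- runif(size_px^2) < flicker_rate
    fr[flick] <- 12  # above the default binarization threshold
    dx <- if (f >= move_f) round((f - move_f + 1) * speed_px) else 0
    cols <- (x0 + dx):(x0 + dx + blob_w - 1L)
    cols <- cols[cols >= 1 & cols <= size_px]
    fr[y0:(y0 + blob_w - 1L), cols] <-
      texture[, seq_along(cols), drop = FALSE]
    if (stim_side != "none" && f %in% stim_frames) {
      px <- if (stim_side == "left") y0 + blob_w + 4L else y0 - 5L
      rows <- max(1L, px - 2L):min(size_px, px + 2L)
      ccols <- max(1L, x0 + blob_w %/% 2 - 2L):min(size_px, x0 + blob_w %/% 2 + 2L)
      fr[rows, ccols] <- 255
    }
    arr[i, , ] <- fr
  }
  truth <- tibble(move_onset_ms = frames_to_ms(move_f, onset_frame, fps),
                  move_onset_frame = move_f, speed_px = speed_px,
                  stim_side = stim_side, stim_frames = list(stim_frames))
  # nominal hind-paw label positions flanking the blob (0-based image
  # coords), matching where the saturation disc is drawn per side
  labels <- tibble(part = c("left_hind_digits", "right_hind_digits"),
                   x = rep(x0 + blob_w %/% 2 - 1L, 2),
                   y = c(y0 + blob_w + 3L, y0 - 6L))
  list(stack = frame_stack(arr, fps = fps, onset_frame = onset_frame),
       truth = truth, labels = labels)
}

# default resting pose, image coordinates (origin top-left, y down);
# the mouse faces "north" (nose above the tail base)
default_pose <- function() {
  tibble(part = analysis_parts(),
         x = c(100, 85, 88, 115, 112, 100),
         y = c(60, 95, 98, 95, 98, 100))
}

#' Generate a cohort of synthetic pose tracks
#'
#' Each trial jitters the resting pose with Gaussian noise; after its
#' programmed onset the stimulated hind paw moves outward at a constant
#' rate, and the head (nose) rotates about the tail base toward the
#' stimulated side by the programmed yaw. Mouse-level Gaussian random
#' effects shift the paw onsets. Likelihoods sit near 1 except for a
#' programmed dropout fraction (below the 0.95 cutoff) and optional
#' one-frame glitch excursions.
#'
#' @param spec A [cohort_spec()]; `paw_onset_ms`, `yaw_deg`,
#'   `jitter_sd_px`, `dropout_frac` and the latency SDs are used.
#' @param seed Integer seed.
#' @param n_frames Frames per trial (default 200 at 400 fps = 500 ms).
#' @param onset_frame 0-based stimulus frame (default 40 = 100 ms baseline).
#' @param paw_speed Outward paw speed, pixels/frame.
#' @param move_frames Frames of sustained movement after onset.
#' @param n_glitches Transient one-frame excursions injected per trial
#'   (on the nose label, +15 px).
#' @param zero_effect All-quiet cohort (no movement, no yaw)?
#' @return List: `tracks` (one combined long pose tibble), `truth` (one row
#'   per trial: `stimulated_side`, `true_paw_onset_ms`, `true_yaw_deg`,
#'   `dropout_frames`, `glitch_frames` list-columns).
#' @export
gen_pose_cohort <- function(spec = cohort_spec(), seed = 1,
                            n_frames = 200, onset_frame = 40,
                            paw_speed = 1, move_frames = 30,
                            n_glitches = 0, zero_effect = FALSE) {
  set.seed(seed)
  fps <- spec$wholebody_fps
  pose0 <- default_pose()
  mouse_eff <- rnorm(spec$n_mice, 0, spec$latency_mouse_sd_ms)
  tracks <- list(); truths <- list()
  idx <- 1L
  for (m in seq_len(spec$n_mice)) for (tr in seq_len(spec$trials_per_mouse)) {
    side <- if (runif(1) < 0.5) "left" else "right"
    paw <- paste0(side, "_hind_digits")
    heel <- paste0(side, "_hind_heel")
    lat_ms <- max(spec$paw_onset_ms + mouse_eff[m] +
                    rnorm(1, 0, spec$latency_trial_sd_ms), 2.5)
    lat_f <- onset_frame + round(ms_to_frames(lat_ms, fps))
    yaw <- spec$yaw_deg + rnorm(1, 0, spec$yaw_sd_deg)
    mag <- exp(rnorm(1, 0, spec$magnitude_sd))
    # each trial starts from its own resting pose
    pose_t <- pose0
    pose_t$x <- pose_t$x + rnorm(nrow(pose_t), 0, spec$pose_sd_px)
    pose_t$y <- pose_t$y + rnorm(nrow(pose_t), 0, spec$pose_sd_px)
    df <- tidyr::expand_grid(frame = seq_len(n_frames) - 1L,
                             part = pose_t$part) %>%
      left_join(pose_t, by = "part")
    if (!zero_effect) {
      sgn <- if (side == "right") 1 else -1
      prog <- pmin(pmax(df$frame - lat_f + 1L, 0L), move_frames)
      # outward withdrawal direction, jittered per trial about the lateral axis
      dir_rad <- rnorm(1, 0, spec$direction_sd_deg) * pi / 180
      ux <- cos(dir_rad); uy <- -0.2 - sin(dir_rad)
      mv <- df$part %in% c(paw, heel)
      df$x[mv] <- df$x[mv] + sgn * prog[mv] * paw_speed * mag * ux
      df$y[mv] <- df$y[mv] + prog[mv] * paw_speed * mag * uy
      # the contralateral hind paw also moves outward (its outward = -x for a
      # right-stimulated trial), with its own direction jitter
      oside <- if (side == "right") "left" else "right"
      dir2 <- rnorm(1, 0, spec$direction_sd_deg) * pi / 180
      mag2 <- spec$contra_frac * mag
      mv2 <- df$part %in% paste0(oside, c("_hind_digits", "_hind_heel"))
      df$x[mv2] <- df$x[mv2] - sgn * prog[mv2] * paw_speed * mag2 * cos(dir2)
      df$y[mv2] <- df$y[mv2] + prog[mv2] * paw_speed * mag2 * (-0.2 - sin(dir2))
      # head yaw: rotate the nose about the tail base toward the stimulated
      # side; orienting begins promptly at the stimulus and settles within
      # yaw_ramp frames (25 ms at 400 fps)
      yaw_ramp <- 10L
      yaw_prog <- pmin(pmax(df$frame - onset_frame + 1L, 0L), yaw_ramp) / yaw_ramp
      tb <- pose_t[pose_t$part == "tail_base", ]
      nose0 <- pose_t[pose_t$part == "nose", ]
      ang0 <- atan2(nose0$y - tb$y, nose0$x - tb$x)
      len <- sqrt((nose0$x - tb$x)^2 + (nose0$y - tb$y)^2)
      ns <- df$part == "nose"
      ang <- ang0 + sgn * (yaw * pi / 180) * yaw_prog[ns]
      df$x[ns] <- tb$x + len * cos(ang)
      df$y[ns] <- tb$y + len * sin(ang)
      # whole-body weight shift in a random direction, same ramp as the paw
      shift_dir <- runif(1, 0, 2 * pi)
      shift <- spec$body_shift_px * prog / move_frames
      df$x <- df$x + shift * cos(shift_dir)
      df$y <- df$y + shift * sin(shift_dir)
    }
    n_rows <- nrow(df)
    df$x <- df$x + rnorm(n_rows, 0, spec$jitter_sd_px)
    df$y <- df$y + rnorm(n_rows, 0, spec$jitter_sd_px)
    df$likelihood <- 0.97 + 0.03 * runif(n_rows)
    dropped <- runif(n_rows) < spec$dropout_frac
    df$likelihood[dropped] <- 0.3
    glitch_f <- integer()
    if (n_glitches > 0) {
      cand <- setdiff(seq(5L, n_frames - 5L), lat_f + seq(-2L, move_frames))
      glitch_f <- sort(sample(cand, min(n_glitches, length(cand))))
      gl <- df$part == "nose" & df$frame %in% glitch_f
      df$x[gl] <- df$x[gl] + 15
    }
    tracks[[idx]] <- pose_track(df, fps = fps, onset_frame = onset_frame,
                                mouse_id = sprintf("m%02d", m),
                                trial_id = sprintf("t%02d", tr),
                                stimulated_side = side)
    truths[[idx]] <- tibble(
      mouse_id = sprintf("m%02d", m), trial_id = sprintf("t%02d", tr),
      stimulated_side = side,
      true_paw_onset_ms = if (zero_effect) NA_real_
                          else frames_to_ms(lat_f, onset_frame, fps),
      true_yaw_deg = if (zero_effect) 0 else yaw,
      true_magnitude = if (zero_effect) 0 else mag,
      mouse_effect_ms = mouse_eff[m],
      dropout_frames = list(unique(df$frame[dropped])),
      glitch_frames = list(glitch_f))
    idx <- idx + 1L
  }
  list(tracks = bind_rows(tracks), truth = bind_rows(truths))
}

#' Simulate trial outcomes of a stimulus pulse train
#'
#' Each of the `n_pulses` pulses (spaced `isi_ms` apart) independently
#' triggers a response with probability `p`; the trial latency is the onset
#' of the first triggering pulse plus a draw from the single-pulse latency
#' distribution. By construction, latencies measured relative to the
#' triggering pulse follow one distribution regardless of the train
#' frequency.
#'
#' @param p Per-pulse response probability.
#' @param n_pulses Pulses per train.
#' @param isi_ms Inter-stimulus interval (ms).
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param latency_meanlog,latency_sdlog Log-normal parameters of the
#'   latency measured from the triggering pulse (default median 50 ms,
#'   right-skewed). Kept sub-ISI so that attributing a latency to the most
#'   recent pulse recovers the triggering pulse.
#' @return Tibble: `trial`, `responded`, `first_pulse` (0-based index of
#'   the triggering pulse), `latency_ms`.
#' @export
gen_pulse_train_outcomes <- function(p, n_pulses, isi_ms, n_trials = 100,
                                     seed = 1, latency_meanlog = log(50),
                                     latency_sdlog = 0.25) {
  stopifnot(p >= 0, p <= 1, n_pulses >= 1)
  set.seed(seed)
  hits <- matrix(runif(n_trials * n_pulses) < p, n_trials, n_pulses)
  first <- apply(hits, 1L, function(h) {
    i <- which(h); if (length(i)) i[1] - 1L else NA_integer_
  })
  responded <- !is.na(first)
  lat <- rep(NA_real_, n_trials)
  lat[responded] <- first[responded] * isi_ms +
    stats::rlnorm(sum(responded), latency_meanlog, latency_sdlog)
  tibble(trial = seq_len(n_trials), responded = responded,
         first_pulse = first, latency_ms = lat)
}
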