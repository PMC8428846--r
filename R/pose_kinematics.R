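#' Filter pose labels
#'
#' Cleans DeepLabCut-style tracks the way the reference pipeline does:
#' a point is dropped when (1) its likelihood is below the confidence
#' cutoff, (2) it jumps at least `jump_px` pixels in a single frame relative
#' to the previous retained point while the next available frame returns to
#' within `jump_px` of the pre-jump position (a one-frame labeling glitch —
#' sustained jumps are genuine movement and are kept), or (3) it falls in a
#' stimulation frame (laser light corrupts the image). Removed points keep
#' their rows with `x`/`y`/`likelihood` set to `NA` and the reason recorded,
#' so no interpolation is ever implied. The operation is idempotent.
#'
#' @param track Pose-track tibble ([pose_track()]).
#' @param p_cutoff Likelihood cutoff (default 0.95).
#' @param jump_px One-frame jump threshold in pixels (default 10).
#' @param stim_frames 0-based frame indices corrupted by the stimulus.
#' @return The track with removed points set to `NA` and a `removed` column
#'   (`NA`, `"likelihood"`, `"stim_frame"` or `"jump"`).
#' @export
filter_labels <- function(track, p_cutoff = 0.95, jump_px = 10,
                          stim_frames = integer()) {
  if (!"removed" %in% names(track)) track$removed <- NA_character_
  track %>%
    group_by(across(all_of(grp_vars(track, "part")))) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      rm_reason <- df$removed
      drop <- is.na(rm_reason) & !is.na(df$likelihood) & df$likelihood < p_cutoff
      rm_reason[drop] <- "likelihood"
      stim <- is.na(rm_reason) & df$frame %in% stim_frames
      rm_reason[stim] <- "stim_frame"
      avail <- which(is.na(rm_reason) & !is.na(df$x) & !is.na(df$y))
      if (length(avail) >= 2L) {
        prev <- avail[1]
        k <- 2L
        while (k <= length(avail)) {
          i <- avail[k]
          d <- sqrt((df$x[i] - df$x[prev])^2 + (df$y[i] - df$y[prev])^2)
          if (d >= jump_px) {
            nxt <- if (k < length(avail)) avail[k + 1L] else NA_integer_
            returned <- !is.na(nxt) &&
              sqrt((df$x[nxt] - df$x[prev])^2 + (df$y[nxt] - df$y[prev])^2) < jump_px
            if (returned) {
              rm_reason[i] <- "jump"   # transient glitch
              avail <- avail[-k]       # prev unchanged; re-examine nxt next
              next
            }
          }
          prev <- i
          k <- k + 1L
        }
      }
      df$removed <- rm_reason
      df$x[!is.na(rm_reason)] <- NA_real_
      df$y[!is.na(rm_reason)] <- NA_real_
      df$likelihood[!is.na(rm_reason)] <- NA_real_
      df
    }) %>%
    ungroup() %>%
    arrange(across(all_of(grp_vars(track, c("frame", "part")))))
}

#' Trial-level pose quality control
#'
#' Rejects trials whose tracking is too poor to analyze: more than
#' `max_missing_frac` of the analysis-part labels missing after filtering
#' (stimulation-frame removals are by design and do not count), or more
#' than `max_bad_frames` frames flagged as mislabeled. Mislabeling is
#' operationalized as frames hit by the jump rule; an external list of
#' manually flagged frames can be supplied and is unioned in.
#'
#' @param track Filtered pose-track tibble (see [filter_labels()]).
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.10).
#' @param max_bad_frames Maximum tolerated mislabeled frames (default 10).
#' @param parts Parts entering the computation (default [analysis_parts()]).
#' @param manual_flags 0-based frame indices flagged by manual inspection.
#' @return One-row tibble per trial: ids, `missing_frac`, `bad_frames`,
#'   `qc_pass`, `qc_reasons`.
#' @export
qc_pose_trial <- function(track, max_missing_frac = 0.10, max_bad_frames = 10,
                          parts = analysis_parts(), manual_flags = integer()) {
  if (!"removed" %in% names(track)) {
    abort("track must be filtered with filter_labels() first.",
          class = "pawkit_validation_error")
  }
  track %>%
    filter(.data$part %in% parts) %>%
    group_by(across(all_of(grp_vars(track)))) %>%
    dplyr::group_modify(function(df, key) {
      eligible <- is.na(df$removed) | df$removed != "stim_frame"
      per_part <- tapply(is.na(df$x[eligible]), df$part[eligible], mean)
      missing <- max(per_part)  # a single unusable part breaks the kinematics
      bad <- union(unique(df$frame[!is.na(df$removed) & df$removed == "jump"]),
                   manual_flags)
      reasons <- character()
      if (missing > max_missing_frac) reasons <- c(reasons, "missing-labels")
      if (length(bad) > max_bad_frames) reasons <- c(reasons, "mislabeled-frames")
      tibble(missing_frac = missing, bad_frames = length(bad),
             qc_pass = length(reasons) == 0L,
             qc_reasons = paste(reasons, collapse = ";"))
    }) %>%
    ungroup()
}

#' Baseline pose
#'
#' Per-part mean position over `n_frames` consecutive frames immediately
#' before the stimulus onset (10 by default, matching the movement-latency
#' definition).
#'
#' @param track Pose-track tibble.
#' @param n_frames Number of pre-onset frames to average.
#' @return Tibble `part`, `x`, `y` (NA when a part is absent throughout).
#' @export
baseline_pose <- function(track, n_frames = 10L) {
  onset <- track$onset_frame[1]
  if (onset < n_frames) abort("insufficient baseline frames before onset.",
                              class = "pawkit_validation_error")
  track %>%
    filter(.data$frame >= onset - n_frames, .data$frame < onset) %>%
    group_by(.data$part) %>%
    summarise(x = mean(.data$x, na.rm = TRUE),
              y = mean(.data$y, na.rm = TRUE), .groups = "drop")
}

#' Identify the stimulated hind limb from laser saturation
#'
#' With FTIR illumination disabled during whole-body recording, the laser
#' pulse saturates pixels at the stimulation site. The saturated-pixel count
#' inside a `window_px` square window centred on each hind-paw label is
#' compared shortly before (`t_pre_ms`) and after (`t_post_ms`) stimulus
#' onset; the side with the larger increase is the stimulated limb.
#'
#' @param stack [frame_stack()] time-aligned with `track`.
#' @param track Pose-track tibble.
#' @param window_px Window side length in pixels (default 60).
#' @param t_pre_ms,t_post_ms Comparison times in ms around onset (defaults
#'   7.5 before and 5 after; rounded to the nearest frame).
#' @param sat_value Pixel value counted as saturated (default 255).
#' @return One-row tibble: `side` (`"left"`, `"right"` or `"unknown"`),
#'   `left_increase`, `right_increase`.
#' @export
detect_stimulated_limb <- function(stack, track, window_px = 60,
                                   t_pre_ms = 7.5, t_post_ms = 5,
                                   sat_value = 255) {
  stopifnot(inherits(stack, "frame_stack"))
  fps <- attr(stack, "fps")
  onset <- attr(stack, "onset_frame")
  pre_f <- max(0L, onset - as.integer(round(ms_to_frames(t_pre_ms, fps))))
  post_f <- min(n_frames(stack) - 1L,
                onset + as.integer(round(ms_to_frames(t_post_ms, fps))))
  bp <- baseline_pose(track)
  count_side <- function(side, frame_idx) {
    lbl <- bp[grepl(paste0("^", side, "_hind"), bp$part), ]
    if (nrow(lbl) == 0L || all(is.na(lbl$x))) return(NA_real_)
    cx <- mean(lbl$x, na.rm = TRUE); cy <- mean(lbl$y, na.rm = TRUE)
    h <- dim(stack)[2]; w <- dim(stack)[3]
    half <- window_px / 2
    rows <- max(1L, floor(cy - half) + 1L):min(h, ceiling(cy + half))
    cols <- max(1L, floor(cx - half) + 1L):min(w, ceiling(cx + half))
    sum(unclass(stack)[frame_idx + 1L, rows, cols] >= sat_value)
  }
  li <- count_side("left", post_f) - count_side("left", pre_f)
  ri <- count_side("right", post_f) - count_side("right", pre_f)
  side <- if (is.na(li) || is.na(ri) || (li <= 0 && ri <= 0) || li == ri) {
    "unknown"
  } else if (li > ri) "left" else "right"
  if (side == "unknown") {
    warn("stimulated limb could not be determined; flag trial for manual call.",
         class = "pawkit_unknown_limb")
  }
  tibble(side = side, left_increase = li, right_increase = ri)
}

#' Movement-onset latency of a body part
#'
#' A post-stimulus movement is meaningful when the label has moved at least
#' `min_disp_px` from its baseline position (mean of 10 consecutive
#' pre-onset frames) and keeps moving at `min_rate_px_per_frame` or more for
#' each of the following `persist_frames` frames. The latency is the time of
#' the first frame satisfying both, in ms after onset; parts that never
#' qualify return `NA`.
#'
#' @param track Pose-track tibble (ideally filtered).
#' @param parts Parts to scan (default: every part present).
#' @param baseline_frames Frames averaged for the baseline position.
#' @param min_disp_px Displacement-from-baseline threshold (default 0.5 px,
#'   about 0.16 mm on the whole-body camera).
#' @param min_rate_px_per_frame Frame-to-frame speed that must persist.
#' @param persist_frames Number of subsequent frames the speed must persist.
#' @return Tibble: ids, `part`, `onset_frame_idx` (0-based), `onset_ms`.
#' @export
movement_onset <- function(track, parts = NULL, baseline_frames = 10L,
                           min_disp_px = 0.5, min_rate_px_per_frame = 0.5,
                           persist_frames = 10L) {
  parts <- parts %||% unique(track$part)
  track %>%
    filter(.data$part %in% parts) %>%
    group_by(across(all_of(grp_vars(track, "part")))) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      onset <- df$onset_frame[1]; fps <- df$fps[1]
      base <- df[df$frame >= onset - baseline_frames & df$frame < onset, ]
      if (nrow(base) < baseline_frames) {
        abort("insufficient baseline frames for movement onset.",
              class = "pawkit_validation_error")
      }
      bx <- mean(base$x, na.rm = TRUE); by <- mean(base$y, na.rm = TRUE)
      post <- df[df$frame >= onset, ]
      disp <- sqrt((post$x - bx)^2 + (post$y - by)^2)
      step <- c(NA, sqrt(diff(post$x)^2 + diff(post$y)^2))
      qual <- NA_integer_
      for (i in which(!is.na(disp) & disp >= min_disp_px)) {
        js <- i + seq_len(persist_frames)
        if (max(js) > nrow(post)) break
        ok <- step[js]
        if (!anyNA(ok) && all(ok >= min_rate_px_per_frame)) { qual <- i; break }
      }
      if (is.na(qual)) {
        tibble(onset_frame_idx = NA_integer_, onset_ms = NA_real_)
      } else {
        f <- post$frame[qual]
        tibble(onset_frame_idx = f, onset_ms = frames_to_ms(f, onset, fps))
      }
    }) %>%
    ungroup()
}

#' Egocentric alignment of a pose track
#'
#' Expresses coordinates in the animal's own baseline frame: the baseline
#' tail-base position becomes the origin, and if the stimulated hind paw
#' lies on the left of the tail base the x axis is reflected so the
#' stimulated paw always sits at non-negative x. Because mirroring swaps
#' image left and right, paired part labels swap along with it: in aligned
#' coordinates the stimulated paw is always the right hind paw
#' (`stimulated_side` becomes `"right"`; the original side is kept in
#' `stimulated_side_original`). Translation + optional reflection only —
#' no rotation — so inter-part distances are preserved exactly.
#'
#' @param track Pose-track tibble with known `stimulated_side`.
#' @param baseline_frames Frames averaged for the baseline pose.
#' @param stimulated_side Override for the track's `stimulated_side` column.
#' @return The track with aligned `x`/`y` and a logical `reflected` column.
#' @export
egocentric_align <- function(track, baseline_frames = 10L,
                             stimulated_side = NULL) {
  side <- stimulated_side %||% track$stimulated_side[1]
  if (!side %in% c("left", "right")) {
    abort("stimulated side must be known for egocentric alignment.",
          class = "pawkit_validation_error")
  }
  bp <- baseline_pose(track, baseline_frames)
  tb <- bp[bp$part == "tail_base", ]
  if (nrow(tb) != 1L || is.na(tb$x)) {
    abort("tail base missing at baseline; cannot align.",
          class = "pawkit_validation_error")
  }
  paw <- bp[bp$part == paste0(side, "_hind_digits"), ]
  if (nrow(paw) == 0L || is.na(paw$x)) {
    paw <- bp[bp$part == paste0(side, "_hind_heel"), ]
  }
  reflect <- nrow(paw) == 1L && !is.na(paw$x) && (paw$x - tb$x) < 0
  out <- mutate(track,
                x = (.data$x - tb$x) * (if (reflect) -1 else 1),
                y = .data$y - tb$y,
                stimulated_side_original = side,
                reflected = reflect)
  if (reflect) {
    # mirroring swaps image left and right, so paired part labels swap too;
    # in aligned coordinates the stimulated paw is always the right paw
    out$part <- dplyr::case_when(
      startsWith(out$part, "left_") ~ sub("^left_", "right_", out$part),
      startsWith(out$part, "right_") ~ sub("^right_", "left_", out$part),
      TRUE ~ out$part
    )
  }
  out$stimulated_side <- "right"
  out
}

#' Per-part displacement from baseline
#'
#' Euclidean distance of each part from its baseline position, per frame,
#' with the per-part maxima inside the analysis window (300 ms after onset
#' by default). Missing points propagate as gaps.
#'
#' @param track Pose-track tibble (filtered; aligned or raw — distances are
#'   translation-invariant).
#' @param window_ms Post-onset window for maxima.
#' @param parts Parts to include.
#' @param baseline_frames Frames averaged for the baseline pose.
#' @return List of two tibbles: `series` (ids, `frame`, `time_ms`, `part`,
#'   `dist_px`) and `maxima` (ids, `part`, `max_dist_px`, `max_time_ms`).
#' @export
displacement_series <- function(track, window_ms = 300,
                                parts = NULL, baseline_frames = 10L) {
  parts <- parts %||% unique(track$part)
  ser <- track %>%
    filter(.data$part %in% parts) %>%
    group_by(across(all_of(grp_vars(track)))) %>%
    dplyr::group_modify(function(df, key) {
      bp <- baseline_pose(df, baseline_frames)
      df %>%
        left_join(bp, by = "part", suffix = c("", "_base")) %>%
        mutate(time_ms = frames_to_ms(.data$frame, .data$onset_frame, .data$fps),
               dist_px = sqrt((.data$x - .data$x_base)^2 +
                                (.data$y - .data$y_base)^2)) %>%
        select("frame", "time_ms", "part", "dist_px")
    }) %>%
    ungroup()
  maxima <- ser %>%
    filter(.data$time_ms >= 0, .data$time_ms <= window_ms,
           !is.na(.data$dist_px)) %>%
    group_by(across(all_of(grp_vars(ser, "part")))) %>%
    summarise(max_dist_px = max(.data$dist_px),
              max_time_ms = .data$time_ms[which.max(.data$dist_px)],
              .groups = "drop")
  list(series = ser, maxima = maxima)
}

#' Stimulated-paw to nose distance metrics
#'
#' Per-frame Euclidean distance between the stimulated hind-paw digits and
#' the nose, with its minimum and maximum inside the analysis window. The
#' minimum indexes orienting toward the paw, the maximum withdrawal away
#' from it.
#'
#' @param track Pose-track tibble with known stimulated side.
#' @param window_ms Post-onset analysis window (default 300 ms).
#' @param paw_part Override for the paw label (default
#'   `<stimulated_side>_hind_digits`).
#' @return List: `series` tibble (ids, `frame`, `time_ms`, `dist_px`) and
#'   `summary` one-row tibble (`min_dist_px`, `max_dist_px` and their times).
#' @export
paw_nose_metrics <- function(track, window_ms = 300, paw_part = NULL) {
  side <- track$stimulated_side[1]
  paw_part <- paw_part %||% paste0(side, "_hind_digits")
  if (!paw_part %in% track$part || !"nose" %in% track$part) {
    abort("nose and stimulated-paw labels are required.",
          class = "pawkit_validation_error")
  }
  wide <- track %>%
    filter(.data$part %in% c("nose", paw_part)) %>%
    select(all_of(c(grp_vars(track),
                    "frame", "fps", "onset_frame", "part", "x", "y"))) %>%
    tidyr::pivot_wider(names_from = "part", values_from = c("x", "y"))
  ser <- wide %>%
    mutate(time_ms = frames_to_ms(.data$frame, .data$onset_frame, .data$fps),
           dist_px = sqrt((.data[[paste0("x_", paw_part)]] - .data$x_nose)^2 +
                            (.data[[paste0("y_", paw_part)]] - .data$y_nose)^2)) %>%
    select(all_of(c(grp_vars(track), "frame", "time_ms", "dist_px")))
  win <- filter(ser, .data$time_ms >= 0, .data$time_ms <= window_ms,
                !is.na(.data$dist_px))
  if (nrow(win) == 0L) {
    summary <- tibble(min_dist_px = NA_real_, min_time_ms = NA_real_,
                      max_dist_px = NA_real_, max_time_ms = NA_real_)
  } else {
    summary <- tibble(min_dist_px = min(win$dist_px),
                      min_time_ms = win$time_ms[which.min(win$dist_px)],
                      max_dist_px = max(win$dist_px),
                      max_time_ms = win$time_ms[which.max(win$dist_px)])
  }
  list(series = ser, summary = summary)
}

#' Head-yaw series relative to the baseline body axis
#'
#' Head orientation is the angle of the tail-base-to-nose vector, expressed
#' relative to its mean baseline angle and wrapped to (-180, 180] degrees.
#' Run [egocentric_align()] first if you want the sign standardized so that
#' rotation toward the stimulated side is positive regardless of which paw
#' was stimulated. The window mean is a circular mean.
#'
#' @param track Pose-track tibble (nose and tail base present at baseline).
#' @param window_ms Post-onset window for the mean (default 300 ms).
#' @param baseline_frames Frames defining the baseline angle.
#' @return List: `series` tibble (ids, `frame`, `time_ms`, `yaw_deg`) and
#'   `mean_yaw_deg` (circular mean over the window).
#' @export
head_yaw_series <- function(track, window_ms = 300, baseline_frames = 10L) {
  need <- c("nose", "tail_base")
  if (!all(need %in% track$part)) {
    abort("nose and tail_base labels are required for head yaw.",
          class = "pawkit_validation_error")
  }
  wide <- track %>%
    filter(.data$part %in% need) %>%
    select(all_of(c(grp_vars(track),
                    "frame", "fps", "onset_frame", "part", "x", "y"))) %>%
    tidyr::pivot_wider(names_from = "part", values_from = c("x", "y"))
  onset <- track$onset_frame[1]
  dx <- wide$x_nose - wide$x_tail_base
  dy <- wide$y_nose - wide$y_tail_base
  len <- sqrt(dx^2 + dy^2)
  ang <- ifelse(len > 0, atan2(dy, dx) * 180 / pi, NA_real_)
  base_idx <- wide$frame >= onset - baseline_frames & wide$frame < onset
  base_ang <- circular_mean_deg(ang[base_idx])
  if (is.na(base_ang)) abort("baseline body axis undefined.",
                             class = "pawkit_validation_error")
  ser <- wide %>%
    mutate(time_ms = frames_to_ms(.data$frame, .data$onset_frame, .data$fps),
           yaw_deg = wrap_deg(ang - base_ang)) %>%
    select(all_of(c(grp_vars(track), "frame", "time_ms", "yaw_deg")))
  win <- ser$yaw_deg[ser$time_ms >= 0 & ser$time_ms <= window_ms &
                       !is.na(ser$yaw_deg)]
  list(series = ser, mean_yaw_deg = circular_mean_deg(win))
}

#' Pose feature vectors for dimensionality reduction
#'
#' Builds the 12-dimensional feature vector (x and y of the six analysis
#' parts, in a fixed order) from egocentrically aligned tracks, either at a
#' single time point (`at_ms`, nearest frame) or for every frame
#' (`at_ms = NULL`).
#'
#' @param tracks One combined long tibble of aligned pose tracks (several
#'   trials stacked).
#' @param at_ms Time point in ms after onset, or `NULL` for the full time
#'   course.
#' @param parts Feature parts, default [analysis_parts()].
#' @return Tibble: ids (+ `frame`, `time_ms`) and columns `<part>_x`,
#'   `<part>_y` in `parts` order.
#' @export
pose_features <- function(tracks, at_ms = 115, parts = analysis_parts()) {
  wide <- tracks %>%
    filter(.data$part %in% parts) %>%
    mutate(time_ms = frames_to_ms(.data$frame, .data$onset_frame, .data$fps)) %>%
    select(all_of(c(grp_vars(tracks), "frame", "time_ms", "part", "x", "y"))) %>%
    tidyr::pivot_wider(names_from = "part", values_from = c("x", "y"),
                       names_glue = "{part}_{.value}")
  ord <- c(paste0(rep(parts, each = 2), c("_x", "_y")))
  wide <- wide[, c(grp_vars(tracks), "frame", "time_ms", ord)]
  if (is.null(at_ms)) return(wide)
  wide %>%
    group_by(across(all_of(grp_vars(tracks)))) %>%
    filter(abs(.data$time_ms - at_ms) == min(abs(.data$time_ms - at_ms))) %>%
    dplyr::slice(1) %>%
    ungroup()
}

#' Plot aligned pose trajectories
#'
#' @param track Aligned pose-track tibble.
#' @param parts Parts to draw.
#' @return A ggplot in aligned image coordinates (y axis reversed so "up"
#'   on the plot is up in the arena).
#' @export
plot_pose <- function(track, parts = analysis_parts()) {
  df <- filter(track, .data$part %in% parts, !is.na(.data$x))
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$part)) +
    geom_path(alpha = 0.6) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px, stimulated side right)", y = "y (px)")
}
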