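#' Build an ROI intensity trace
#'
#' An ROI trace is the per-frame mean 8-bit intensity inside a circular
#' region of interest centred on the stimulation site (60 pixel diameter in
#' the reference acquisition). Traces are held in long tibbles so that
#' several trials stack with `dplyr::bind_rows()` and group naturally by
#' `(mouse_id, trial_id)`.
#'
#' @param intensity Numeric vector of per-frame mean intensities (0-255).
#' @param fps Frames per second.
#' @param onset_frame 0-based stimulus-onset frame; must leave at least two
#'   baseline frames before it.
#' @param mouse_id,trial_id Identifiers.
#' @return Tibble with columns `mouse_id`, `trial_id`, `frame`, `time_ms`
#'   (0 ms at stimulus onset), `intensity`, `fps`, `onset_frame`.
#' @examples
#' tr <- roi_trace(c(rep(100, 50), rep(60, 50)), fps = 1000, onset_frame = 50)
#' @export
roi_trace <- function(intensity, fps = 1000, onset_frame,
                      mouse_id = "m1", trial_id = "t1") {
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)) || any(intensity < 0 | intensity > 255)) {
    abort("intensities must be finite and within [0, 255].",
          class = "pawkit_validation_error")
  }
  onset_frame <- as.integer(onset_frame)
  if (onset_frame < 2L) abort("need at least 2 baseline frames before onset.",
                              class = "pawkit_validation_error")
  if (onset_frame >= length(intensity)) {
    abort("stimulus onset lies beyond the last frame.",
          class = "pawkit_config_error")
  }
  frame <- seq_along(intensity) - 1L
  tibble(
    mouse_id = mouse_id, trial_id = trial_id, frame = frame,
    time_ms = frames_to_ms(frame, onset_frame, fps),
    intensity = intensity, fps = fps, onset_frame = onset_frame
  )
}

trace_groups <- function(traces) dplyr::group_by(traces, .data$mouse_id, .data$trial_id)

assert_trace <- function(traces) {
  need <- c("mouse_id", "trial_id", "frame", "intensity", "fps", "onset_frame")
  miss <- setdiff(need, names(traces))
  if (length(miss)) {
    abort(paste0("trace table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "pawkit_format_error")
  }
  invisible(traces)
}

#' Read per-trial ROI intensity traces from CSV
#'
#' Accepts the two layouts the source-data tables come in:
#' \itemize{
#'   \item long — columns `mouse_id`, `trial_id`, `time_ms`, `intensity`;
#'   \item wide — a `time_ms` column plus one column per trial named
#'     `<mouse>.<trial>` or `<mouse>_<trial>`.
#' }
#' Stimulus onset is at `time_ms == 0`; the layout is sniffed from the
#' header. All trials in one file must share the same time base.
#'
#' @param path CSV file.
#' @param fps Frame rate used if the file has no `time_ms` column (rows are
#'   then consecutive frames with onset given by `onset_frame`).
#' @param onset_frame Fallback onset index when no time column is present.
#' @return A long trace tibble as produced by [roi_trace()].
#' @export
read_trace_table <- function(path, fps = 1000, onset_frame = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(df)
  if (all(c("trial_id", "intensity") %in% nm) && !"mouse_id" %in% nm) {
    abort("long trace table is missing the mouse_id column.",
          class = "pawkit_format_error")
  }
  if (all(c("mouse_id", "trial_id", "intensity") %in% nm)) {
    long <- df
  } else if ("time_ms" %in% nm || is.null(onset_frame)) {
    if (!"time_ms" %in% nm) {
      abort("wide trace table needs a time_ms column (or supply onset_frame).",
            class = "pawkit_format_error")
    }
    value_cols <- setdiff(nm, "time_ms")
    if (length(value_cols) == 0L) abort("no trial columns found.",
                                        class = "pawkit_format_error")
    ok <- grepl("^.+[._].+$", value_cols)
    if (!all(ok)) {
      abort(paste0("wide trial columns must be named <mouse>.<trial>; offending: ",
                   paste(value_cols[!ok], collapse = ", ")),
            class = "pawkit_format_error")
    }
    long <- tidyr::pivot_longer(df, -"time_ms", names_to = c("mouse_id", "trial_id"),
                                names_pattern = "^(.+?)[._](.+)$",
                                values_to = "intensity")
  } else {
    abort("unrecognized trace table layout.", class = "pawkit_format_error")
  }
  if (!is.numeric(long$intensity)) {
    bad <- which(is.na(suppressWarnings(as.numeric(long$intensity))))[1]
    abort(sprintf("non-numeric intensity near row %d.", bad %||% NA_integer_),
          class = "pawkit_parse_error")
  }
  split_tr <- split(long, list(long$mouse_id, long$trial_id), drop = TRUE)
  lens <- unique(vapply(split_tr, nrow, 1L))
  if (length(lens) != 1L) {
    abort("trials have unequal trace lengths and cannot be aligned.",
          class = "pawkit_format_error")
  }
  purrr::map_dfr(split_tr, function(tr) {
    if ("time_ms" %in% names(tr)) {
      dt <- diff(tr$time_ms)
      fps_i <- 1000 / stats::median(dt)
      onset_i <- sum(tr$time_ms < 0)
    } else {
      fps_i <- fps
      onset_i <- onset_frame
    }
    roi_trace(tr$intensity, fps = fps_i, onset_frame = onset_i,
              mouse_id = tr$mouse_id[1], trial_id = tr$trial_id[1])
  })
}

#' Write ROI traces to CSV
#'
#' @param traces Long trace tibble.
#' @param path Output CSV.
#' @param layout `"long"` (default) or `"wide"` (`time_ms` plus
#'   `<mouse>.<trial>` columns).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  assert_trace(traces)
  if (layout == "long") {
    out <- dplyr::select(traces, "mouse_id", "trial_id", "time_ms", "intensity")
  } else {
    out <- traces %>%
      mutate(col = paste(.data$mouse_id, .data$trial_id, sep = ".")) %>%
      select("time_ms", "col", "intensity") %>%
      tidyr::pivot_wider(names_from = "col", values_from = "intensity")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
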