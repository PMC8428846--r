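#' Build a pose track
#'
#' Markerless-tracking output for one trial: per-frame `(x, y, likelihood)`
#' for named body parts, in image coordinates (origin top-left, y downward).
#' Stored long — one row per frame per part — so dplyr verbs apply directly.
#'
#' @param df Data frame with columns `frame` (0-based), `part`, `x`, `y`,
#'   `likelihood`.
#' @param fps Frames per second (whole-body high-speed default 400).
#' @param onset_frame 0-based stimulus-onset frame.
#' @param mouse_id,trial_id Identifiers.
#' @param stimulated_side `"left"`, `"right"` or `"unknown"`.
#' @param mm_per_px Pixel pitch (mm).
#' @return Tibble with the track plus metadata columns `fps`, `onset_frame`,
#'   `stimulated_side`, `mm_per_px`.
#' @export
pose_track <- function(df, fps = 400, onset_frame, mouse_id = "m1",
                       trial_id = "t1", stimulated_side = "unknown",
                       mm_per_px = 0.32) {
  need <- c("frame", "part", "x", "y", "likelihood")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("pose data is missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "pawkit_format_error")
  lk <- df$likelihood[!is.na(df$likelihood)]
  if (any(lk < 0 | lk > 1)) abort("likelihoods must lie in [0, 1].",
                                  class = "pawkit_validation_error")
  per_part <- table(df$part)
  if (length(unique(per_part)) > 1L) {
    abort("all parts must be present in every frame.",
          class = "pawkit_validation_error")
  }
  if (!stimulated_side %in% c("left", "right", "unknown")) {
    abort("stimulated_side must be left, right or unknown.",
          class = "pawkit_validation_error")
  }
  tibble(mouse_id = mouse_id, trial_id = trial_id,
         frame = as.integer(df$frame), part = as.character(df$part),
         x = as.numeric(df$x), y = as.numeric(df$y),
         likelihood = as.numeric(df$likelihood),
         fps = fps, onset_frame = as.integer(onset_frame),
         stimulated_side = stimulated_side, mm_per_px = mm_per_px)
}

#' The six analysis body parts
#'
#' Of the 18 labeled parts, kinematics and pose PCA use the nose, the four
#' hind-paw labels (digits and heel, both sides) and the tail base.
#' @return Character vector of part names.
#' @export
analysis_parts <- function() {
  c("nose", "left_hind_digits", "left_hind_heel",
    "right_hind_digits", "right_hind_heel", "tail_base")
}

#' Read a body-part coordinate table
#'
#' Understands both the 3-row DeepLabCut wide header
#' (`scorer` / `bodyparts` / `coords` rows, one `(x, y, likelihood)` column
#' triple per part, frame index in the first column) and a flat single-header
#' layout (`<part>_x`, `<part>_y`, `<part>_likelihood`).
#'
#' @param path CSV file.
#' @param fps,onset_frame,mouse_id,trial_id,stimulated_side,mm_per_px Passed
#'   to [pose_track()].
#' @return A pose-track tibble.
#' @export
read_pose_table <- function(path, fps = 400, onset_frame = 0L,
                            mouse_id = "m1", trial_id = "t1",
                            stimulated_side = "unknown", mm_per_px = 0.32) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  dlc <- grepl("^scorer", first)
  if (dlc) {
    hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                           colClasses = "character")
    parts <- as.character(hdr[2, -1])
    coords <- as.character(hdr[3, -1])
    if (!all(c("x", "y", "likelihood") %in% unique(coords))) {
      abort("DeepLabCut header lacks x/y/likelihood coordinate rows.",
            class = "pawkit_format_error")
    }
    body <- utils::read.csv(path, header = FALSE, skip = 3)
    long <- purrr::map_dfr(unique(parts), function(p) {
      idx <- which(parts == p) + 1L
      cc <- coords[idx - 1L]
      tibble(frame = as.integer(body[[1]]), part = p,
             x = parse_num(body[[idx[cc == "x"]]], path),
             y = parse_num(body[[idx[cc == "y"]]], path),
             likelihood = parse_num(body[[idx[cc == "likelihood"]]], path))
    })
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    xy <- grep("_(x|y|likelihood)$", names(df), value = TRUE)
    parts <- unique(sub("_(x|y|likelihood)$", "", xy))
    if (length(parts) == 0L ||
        !all(paste0(rep(parts, each = 3), "_",
                    c("x", "y", "likelihood")) %in% names(df))) {
      abort("flat pose table needs <part>_x, <part>_y and <part>_likelihood columns.",
            class = "pawkit_format_error")
    }
    fr <- if ("frame" %in% names(df)) as.integer(df$frame) else seq_len(nrow(df)) - 1L
    long <- purrr::map_dfr(parts, function(p) {
      tibble(frame = fr, part = p,
             x = parse_num(df[[paste0(p, "_x")]], path),
             y = parse_num(df[[paste0(p, "_y")]], path),
             likelihood = parse_num(df[[paste0(p, "_likelihood")]], path))
    })
  }
  pose_track(long, fps = fps, onset_frame = onset_frame, mouse_id = mouse_id,
             trial_id = trial_id, stimulated_side = stimulated_side,
             mm_per_px = mm_per_px)
}

parse_num <- function(x, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA" & x != "")
  if (length(bad)) {
    abort(sprintf("non-numeric cell in '%s' at data row %d.", path, bad[1]),
          class = "pawkit_parse_error")
  }
  out
}

#' Write a pose track to CSV
#'
#' @param track Pose-track tibble.
#' @param path Output CSV.
#' @param layout `"flat"` (single header, default) or `"dlc"` (3-row
#'   DeepLabCut header).
#' @param scorer Scorer string written in DLC mode.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, layout = c("flat", "dlc"),
                             scorer = "pawkit") {
  layout <- match.arg(layout)
  parts <- unique(track$part)
  wide <- track %>%
    select("frame", "part", "x", "y", "likelihood") %>%
    tidyr::pivot_wider(names_from = "part",
                       values_from = c("x", "y", "likelihood"),
                       names_glue = "{part}_{.value}")
  ord <- c("frame", paste0(rep(parts, each = 3), "_", c("x", "y", "likelihood")))
  wide <- wide[, ord]
  if (layout == "flat") {
    readr::write_csv(wide, path, progress = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    ncols <- 3L * length(parts)
    writeLines(paste(c("scorer", rep(scorer, ncols)), collapse = ","), con)
    writeLines(paste(c("bodyparts", rep(parts, each = 3)), collapse = ","), con)
    writeLines(paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
                     collapse = ","), con)
    utils::write.table(wide, con, sep = ",", col.names = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}
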