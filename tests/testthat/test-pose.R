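glitch_track <- function(kind = c("transient", "sustained")) {
  kind <- match.arg(kind)
  tr <- static_track(n_frames = 40, onset = 20)
  sel <- tr$part == "nose" & tr$frame == 25
  tr$x[sel] <- tr$x[sel] + 12
  if (kind == "sustained") {
    sel2 <- tr$part == "nose" & tr$frame > 25
    tr$x[sel2] <- tr$x[sel2] + 12
  }
  tr
}

test_that("label filtering drops low-confidence points and transient jumps", {
  tr <- static_track()
  tr$likelihood[tr$part == "nose" & tr$frame == 7] <- 0.94
  fl <- filter_labels(tr)
  bad <- fl[fl$part == "nose" & fl$frame == 7, ]
  expect_true(is.na(bad$x) && bad$removed == "likelihood")
  expect_equal(sum(!is.na(fl$removed)), 1L)

  # one-frame 12 px excursion with return: removed as a glitch
  fg <- filter_labels(glitch_track("transient"))
  expect_equal(fg$removed[fg$part == "nose" & fg$frame == 25], "jump")
  # sustained 12 px jump: kept (genuine movement)
  fs <- filter_labels(glitch_track("sustained"))
  expect_true(all(is.na(fs$removed)))

  # stimulation frames are removed for every part
  ff <- filter_labels(tr, stim_frames = 20:24)
  expect_true(all(ff$removed[ff$frame %in% 20:24] == "stim_frame"))
})

test_that("label filtering is idempotent", {
  sim <- gen_pose_cohort(cohort_spec(n_mice = 1, trials_per_mouse = 2,
                                     dropout_frac = 0.1),
                         seed = 15, n_glitches = 3)
  once <- filter_labels(sim$tracks, stim_frames = 40:44)
  twice <- filter_labels(once, stim_frames = 40:44)
  expect_identical(once$x, twice$x)
  expect_identical(once$removed, twice$removed)
})

test_that("programmed glitch schedules are exactly the removed set", {
  sim <- gen_pose_cohort(cohort_spec(n_mice = 1, trials_per_mouse = 3),
                         seed = 27, n_glitches = 4)
  fl <- filter_labels(sim$tracks)
  for (i in 1:3) {
    id <- sim$truth$trial_id[i]
    got <- sort(fl$frame[fl$trial_id == id & !is.na(fl$removed) &
                           fl$removed == "jump"])
    expect_equal(got, sim$truth$glitch_frames[[i]])
  }
})

test_that("pose QC fails trials with excessive missingness or mislabeling", {
  tr <- static_track(n_frames = 100, onset = 20)
  fl <- filter_labels(tr)
  expect_true(qc_pose_trial(fl)$qc_pass)

  # 11% of one part missing
  tr2 <- tr
  tr2$likelihood[tr2$part == "nose" & tr2$frame < 11] <- 0.5
  q2 <- qc_pose_trial(filter_labels(tr2))
  expect_false(q2$qc_pass)
  expect_match(q2$qc_reasons, "missing-labels")

  # manual mislabel flags are honored
  q3 <- qc_pose_trial(fl, manual_flags = 0:10)
  expect_false(q3$qc_pass)
  expect_match(q3$qc_reasons, "mislabeled-frames")

  # cohort with heavy programmed dropout fails
  sim <- gen_pose_cohort(cohort_spec(n_mice = 1, trials_per_mouse = 1,
                                     dropout_frac = 0.15), seed = 5)
  expect_false(qc_pose_trial(filter_labels(sim$tracks))$qc_pass)
})

test_that("the stimulated limb is identified from laser saturation", {
  for (seed in 1:25) {
    side <- if (seed %% 2 == 0) "left" else "right"
    sim <- gen_wholebody_trial(seed = seed, stim_side = side)
    df <- tidyr::expand_grid(frame = 0:119,
                             part = c("left_hind_digits", "right_hind_digits",
                                      "tail_base", "nose"))
    df <- dplyr::left_join(
      df, dplyr::bind_rows(sim$labels,
                           tibble::tibble(part = c("tail_base", "nose"),
                                          x = c(21, 21), y = c(50, 10))),
      by = "part")
    df$likelihood <- 0.99
    trk <- pose_track(df, fps = 400,
                      onset_frame = attr(sim$stack, "onset_frame"))
    got <- detect_stimulated_limb(sim$stack, trk, window_px = 20)
    expect_equal(got$side, side)
  }
  # no saturation anywhere: unknown, flagged
  still <- gen_wholebody_trial(seed = 31, stim_side = "none")
  df <- tidyr::expand_grid(frame = 0:119,
                           part = c("left_hind_digits", "right_hind_digits"))
  df <- dplyr::left_join(df, still$labels, by = "part")
  df$likelihood <- 0.99
  trk <- pose_track(df, fps = 400, onset_frame = attr(still$stack, "onset_frame"))
  expect_warning(got <- detect_stimulated_limb(still$stack, trk, window_px = 20),
                 class = "pawkit_unknown_limb")
  expect_equal(got$side, "unknown")
})

test_that("movement onset needs both displacement and sustained motion", {
  # static track: no onset anywhere
  still <- static_track(jitter = 0.05)
  mo <- movement_onset(still, parts = "nose")
  expect_true(is.na(mo$onset_ms))

  # a part stepping 1 px at frame f then 0.6 px/frame qualifies at f
  tr <- static_track(n_frames = 60, onset = 20, jitter = 0)
  f0 <- 28L
  sel <- tr$part == "nose" & tr$frame >= f0
  tr$x[sel] <- tr$x[sel] + 1 + 0.6 * (tr$frame[sel] - f0)
  mo2 <- movement_onset(tr, parts = "nose")
  expect_equal(mo2$onset_ms, (f0 - 20) * 2.5)

  # cohort recovery within one frame in at least 95% of trials
  sim <- gen_pose_cohort(cohort_spec(n_mice = 5, trials_per_mouse = 6),
                         seed = 33)
  fl <- filter_labels(sim$tracks)
  hits <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tru <- sim$truth[i, ]
    trk <- fl[fl$mouse_id == tru$mouse_id & fl$trial_id == tru$trial_id, ]
    mo <- movement_onset(trk, parts = paste0(tru$stimulated_side,
                                             "_hind_digits"))
    isTRUE(abs(mo$onset_ms - tru$true_paw_onset_ms) <= 2.5)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("egocentric alignment is an isometry with the stimulated paw at x >= 0", {
  sim <- gen_pose_cohort(cohort_spec(n_mice = 2, trials_per_mouse = 2),
                         seed = 41)
  for (i in seq_len(nrow(sim$truth))) {
    tru <- sim$truth[i, ]
    trk <- sim$tracks[sim$tracks$mouse_id == tru$mouse_id &
                        sim$tracks$trial_id == tru$trial_id, ]
    al <- egocentric_align(trk)
    bp <- baseline_pose(al)
    tb <- bp[bp$part == "tail_base", ]
    expect_lt(abs(tb$x) + abs(tb$y), 1e-9)
    expect_gte(bp$x[bp$part == "right_hind_digits"], 0)
    expect_equal(al$stimulated_side[1], "right")
    expect_equal(al$stimulated_side_original[1], tru$stimulated_side)

    # pairwise inter-part distances at an arbitrary frame are preserved
    f <- 70L
    raw <- trk[trk$frame == f, ]
    ali <- al[al$frame == f, ]
    # aligned parts are relabeled on reflection; match on coordinates as sets
    dmat <- function(df) as.vector(dist(cbind(df$x, df$y)))
    expect_equal(sort(dmat(raw)), sort(dmat(ali)), tolerance = 1e-9)
  }
})

test_that("displacement and paw-nose metrics equal brute-force scans", {
  tr <- static_track(n_frames = 80, onset = 20, jitter = 0)
  # move the right hind digits from baseline to (+3, +4): distance 5
  sel <- tr$part == "right_hind_digits" & tr$frame >= 30
  tr$x[sel] <- tr$x[sel] + 3
  tr$y[sel] <- tr$y[sel] + 4
  ds <- displacement_series(tr)
  mx <- ds$maxima
  expect_equal(mx$max_dist_px[mx$part == "right_hind_digits"], 5)
  expect_equal(mx$max_dist_px[mx$part == "nose"], 0)
  # brute force over the series
  ser <- ds$series
  win <- ser[ser$time_ms >= 0 & ser$time_ms <= 300 & ser$part == "tail_base", ]
  expect_equal(max(win$dist_px), mx$max_dist_px[mx$part == "tail_base"])

  pn <- paw_nose_metrics(tr)
  d0 <- sqrt((115 - 100)^2 + (95 - 60)^2)
  d1 <- sqrt((118 - 100)^2 + (99 - 60)^2)
  expect_equal(pn$summary$min_dist_px, min(d0, d1))
  expect_equal(pn$summary$max_dist_px, max(d0, d1))
  expect_equal(pn$summary$max_dist_px,
               max(pn$series$dist_px[pn$series$time_ms >= 0 &
                                       pn$series$time_ms <= 300]))
})

test_that("kinematics are invariant to global translation", {
  sim <- gen_pose_cohort(cohort_spec(n_mice = 1, trials_per_mouse = 1),
                         seed = 45)
  trk <- sim$tracks
  shifted <- dplyr::mutate(trk, x = x + 37.5, y = y - 12.25)
  a <- displacement_series(trk)$maxima
  b <- displacement_series(shifted)$maxima
  expect_equal(a$max_dist_px, b$max_dist_px, tolerance = 1e-9)
  ya <- head_yaw_series(trk)
  yb <- head_yaw_series(shifted)
  expect_equal(ya$series$yaw_deg, yb$series$yaw_deg, tolerance = 1e-9)
})

test_that("head yaw measures rotation about the tail base", {
  tr <- static_track(n_frames = 80, onset = 20, jitter = 0)
  # nose translating along the baseline body axis: yaw stays 0
  sel <- tr$part == "nose" & tr$frame >= 30
  tr$y[sel] <- tr$y[sel] - 10  # straight away from the tail base
  y0 <- head_yaw_series(tr)
  expect_true(all(abs(y0$series$yaw_deg) < 1e-9))

  # nose rotated 90 degrees about the tail base reads 90
  tr2 <- static_track(n_frames = 80, onset = 20, jitter = 0)
  tb <- c(100, 100)
  sel2 <- tr2$part == "nose" & tr2$frame >= 30
  # baseline nose offset (0, -40) -> rotated (+40, 0)
  tr2$x[sel2] <- tb[1] + 40
  tr2$y[sel2] <- tb[2]
  y90 <- head_yaw_series(tr2)
  expect_equal(abs(y90$series$yaw_deg[y90$series$frame == 60]), 90,
               tolerance = 1e-9)

  # cohort-programmed 20 degree yaw toward the stimulated side is recovered
  sim <- gen_pose_cohort(cohort_spec(n_mice = 4, trials_per_mouse = 5),
                         seed = 47)
  yaws <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tru <- sim$truth[i, ]
    trk <- sim$tracks[sim$tracks$mouse_id == tru$mouse_id &
                        sim$tracks$trial_id == tru$trial_id, ]
    head_yaw_series(egocentric_align(trk))$mean_yaw_deg
  }, numeric(1))
  expect_lt(abs(mean(yaws) - 20), 2)
  expect_true(all(yaws > 0))  # always toward the stimulated side
})
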