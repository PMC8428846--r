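# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the code paths they check.

# naive triple-loop binarized motion energy (frames x height x width array)
naive_motion_energy <- function(arr, thr) {
  d <- dim(arr)
  out <- integer(d[1] - 1L)
  for (f in 2:d[1]) {
    cnt <- 0L
    for (r in seq_len(d[2])) for (cl in seq_len(d[3])) {
      if (abs(arr[f, r, cl] - arr[f - 1L, r, cl]) > thr) cnt <- cnt + 1L
    }
    out[f - 1L] <- cnt
  }
  out
}

# brute-force first-crossing scan of one intensity vector (0-based onset)
naive_first_crossing <- function(intensity, onset, threshold) {
  for (f in onset:(length(intensity) - 1L)) {
    if (intensity[f + 1L] <= threshold) return(f - onset)
  }
  NA_integer_
}

# one trial trace with a programmed step drop
step_trace <- function(baseline = 100, drop_to = 60, latency_frames = 30,
                       fps = 1000, onset = 500, n = 1500, noise_sd = 0,
                       seed = 1, mouse_id = "m1", trial_id = "t1") {
  set.seed(seed)
  x <- rep(baseline, n) + rnorm(n, 0, noise_sd)
  x[(onset + latency_frames + 1):n] <- drop_to + rnorm(n - onset - latency_frames,
                                                       0, noise_sd)
  roi_trace(pmin(pmax(x, 0), 255), fps = fps, onset_frame = onset,
            mouse_id = mouse_id, trial_id = trial_id)
}

# a static pose track with every analysis part present
static_track <- function(n_frames = 60, onset = 20, fps = 400,
                         side = "right", jitter = 0, seed = 1) {
  set.seed(seed)
  pose <- tibble::tibble(
    part = analysis_parts(),
    x = c(100, 85, 88, 115, 112, 100),
    y = c(60, 95, 98, 95, 98, 100))
  df <- tidyr::expand_grid(frame = seq_len(n_frames) - 1L, part = pose$part)
  df <- dplyr::left_join(df, pose, by = "part")
  df$x <- df$x + rnorm(nrow(df), 0, jitter)
  df$y <- df$y + rnorm(nrow(df), 0, jitter)
  df$likelihood <- 0.99
  pose_track(df, fps = fps, onset_frame = onset, stimulated_side = side)
}

# von Mises sampler (Best & Fisher 1979), used as an analytic-oracle input
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}
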