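#' Circular mean and standard deviation (degrees)
#'
#' Directions are averaged as unit vectors; the circular SD is
#' `sqrt(-2 ln R)` (R = mean resultant length), converted to degrees. `NA`s
#' are dropped.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Scalar degrees (`NA` if no finite input; for the SD, `Inf` when
#'   R = 0, i.e. perfectly non-directional).
#' @examples
#' circular_sd_deg(c(0, 90)) # 47.70
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' @rdname circular_mean_deg
#' @export
circular_sd_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  r <- deg * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  if (R == 0) return(Inf)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Probability sum rule for pulse trains
#'
#' Probability of at least one response to `n` independent pulses each with
#' per-pulse response probability `p`: `1 - (1 - p)^n`. Used to test whether
#' responses to pulse trains are explained by independent accumulation of
#' single-pulse response probability.
#'
#' @param p Per-pulse response probability in `[0, 1]`.
#' @param n Number of pulses (>= 1).
#' @return `P(X >= 1)`.
#' @examples
#' sum_rule(0.096, 5) # 0.3963
#' @export
sum_rule <- function(p, n) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].",
                                class = "pawkit_validation_error")
  if (any(n < 1)) abort("`n` must be >= 1.", class = "pawkit_validation_error")
  1 - (1 - p)^n
}

#' Pulse-matched latencies
#'
#' Re-expresses trial latencies relative to the most recent stimulus pulse
#' of a train: pulse index `i` is the largest with `i * isi <= latency`
#' (0-based, capped at `n_pulses - 1`), the residual latency is
#' `latency - i * isi`, and `latency / isi` gives the latency in
#' inter-stimulus units. If train responses are driven pulse-by-pulse, the
#' residual-latency distributions of different frequencies superimpose.
#'
#' @param latency_ms Non-negative latencies (ms).
#' @param isi_ms Inter-stimulus interval (ms, > 0).
#' @param n_pulses Pulses per train.
#' @return Tibble: `latency_ms`, `pulse_index`, `residual_ms`, `latency_isi`.
#' @examples
#' pulse_matched_latency(250, 100, 5)
#' @export
pulse_matched_latency <- function(latency_ms, isi_ms, n_pulses) {
  stopifnot(isi_ms > 0, n_pulses >= 1)
  if (any(latency_ms < 0, na.rm = TRUE)) {
    abort("latencies must be >= 0.", class = "pawkit_validation_error")
  }
  idx <- pmin(floor(latency_ms / isi_ms), n_pulses - 1)
  tibble(latency_ms = latency_ms, pulse_index = as.integer(idx),
         residual_ms = latency_ms - idx * isi_ms,
         latency_isi = latency_ms / isi_ms)
}

#' Balanced hierarchical (mouse-then-trial) bootstrap
#'
#' Uncertainty for nested behavioral data: each replicate resamples mice
#' with replacement (as many as there are mice), then resamples a balanced
#' number of trials `k` with replacement from each sampled mouse, so every
#' mouse contributes equally; the statistic (median by default, mean for
#' quantities like peak motion energy) is computed on the pooled resample.
#' Reported are the mean of the `n_boot` replicate statistics and the SD of
#' the replicate distribution as its standard error.
#'
#' @param data Data frame with one row per trial.
#' @param value Column holding the trial values (bare name or string).
#' @param mouse Column identifying the mouse.
#' @param estimator `"median"` or `"mean"`.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param k Balanced trials drawn per sampled mouse; default
#'   `round(mean trials per mouse)` so the resample size matches the data.
#' @param seed Optional integer seed for exact reproducibility.
#' @return Object of class `pawkit_boot`: `estimate`, `se`, `n_boot`,
#'   `estimator`, `k`, `n_mice`, `seed` and the replicate vector.
#' @examples
#' d <- data.frame(mouse_id = rep(c("a", "b"), each = 4), value = rnorm(8, 30))
#' hierarchical_bootstrap(d, value, n_boot = 200, seed = 1)
#' @export
hierarchical_bootstrap <- function(data, value, mouse = "mouse_id",
                                   estimator = c("median", "mean"),
                                   n_boot = 10000, k = NULL, seed = NULL) {
  estimator <- match.arg(estimator)
  vals <- dplyr::pull(data, {{ value }})
  mid <- dplyr::pull(data, {{ mouse }})
  keep <- !is.na(vals)
  vals <- vals[keep]; mid <- mid[keep]
  if (length(vals) == 0L) abort("no trial values.",
                                class = "pawkit_validation_error")
  by_mouse <- split(vals, mid)
  M <- length(by_mouse)
  lens <- lengths(by_mouse)
  k <- as.integer(k %||% round(mean(lens)))
  if (k < 1L) abort("balanced trial count k must be >= 1.",
                    class = "pawkit_validation_error")
  if (!is.null(seed)) set.seed(seed)
  flat <- unlist(by_mouse, use.names = FALSE)
  offs <- cumsum(c(0L, lens))
  stat_fun <- if (estimator == "median") stats::median else mean
  mouse_draw <- sample.int(M, M * n_boot, replace = TRUE)
  within <- ceiling(runif(M * n_boot * k) * rep(lens[mouse_draw], each = k))
  picked <- flat[rep(offs[mouse_draw], each = k) + within]
  reps <- apply(matrix(picked, nrow = M * k, ncol = n_boot), 2L, stat_fun)
  structure(list(estimate = mean(reps), se = stats::sd(reps),
                 n_boot = as.integer(n_boot), estimator = estimator,
                 k = k, n_mice = M, seed = seed, replicates = reps),
            class = "pawkit_boot")
}

#' @export
print.pawkit_boot <- function(x, ...) {
  cat(sprintf("<pawkit_boot> %s = %.4g +/- %.4g (se), %d replicates, %d mice, k = %d\n",
              x$estimator, x$estimate, x$se, x$n_boot, x$n_mice, x$k))
  invisible(x)
}

#' @export
tidy.pawkit_boot <- function(x, ...) {
  tibble(estimator = x$estimator, estimate = x$estimate, std.error = x$se)
}

#' @export
glance.pawkit_boot <- function(x, ...) {
  tibble(estimate = x$estimate, std.error = x$se, n_boot = x$n_boot,
         n_mice = x$n_mice, k = x$k)
}

# -- pose PCA -----------------------------------------------------------------

#' Principal components of the aligned pose
#'
#' Mean-centered PCA of the 12 aligned pose features (x and y of the six
#' analysis parts) across trials at a single time point, keeping the first
#' `k` components. Component signs are fixed so each component's
#' largest-magnitude loading is positive, making repeated fits and plots
#' identical.
#'
#' @param features Tibble from [pose_features()] (id columns are carried
#'   through), or a plain numeric matrix of complete rows.
#' @param k Number of components (default 3).
#' @return Object of class `pose_pca`: `loadings` (k x p), `center`,
#'   `var_explained` (fractions of total variance), `scores` tibble,
#'   `features` (column order), `n_trials`.
#' @export
fit_pose_pca <- function(features, k = 3) {
  ids <- NULL
  if (is.data.frame(features)) {
    num_cols <- setdiff(names(features),
                        c("mouse_id", "trial_id", "frame", "time_ms"))
    ids <- features[intersect(c("mouse_id", "trial_id"), names(features))]
    X <- as.matrix(features[, num_cols])
  } else {
    X <- as.matrix(features)
  }
  cc <- complete.cases(X)
  X <- X[cc, , drop = FALSE]
  if (!is.null(ids)) ids <- ids[cc, , drop = FALSE]
  if (nrow(X) < k) abort("need at least k complete rows.",
                         class = "pawkit_validation_error")
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > fit$sdev[1] * 1e-10)
  if (rank < k) {
    warn(sprintf("feature rank %d < k = %d; returning %d components.",
                 rank, k, rank))
    k <- rank
  }
  load <- t(fit$rotation[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[j, ]))
    if (load[j, i] < 0) load[j, ] <- -load[j, ]
  }
  scores <- scale(X, center = fit$center, scale = FALSE) %*% t(load)
  colnames(scores) <- paste0("PC", seq_len(k))
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  sc <- as_tibble(scores)
  if (!is.null(ids) && ncol(ids)) sc <- dplyr::bind_cols(as_tibble(ids), sc)
  structure(list(loadings = load, center = fit$center,
                 var_explained = var_frac[seq_len(k)],
                 all_var = fit$sdev^2, scores = sc,
                 features = colnames(X), k = k, n_trials = nrow(X)),
            class = "pose_pca")
}

#' @export
print.pose_pca <- function(x, ...) {
  cat(sprintf("<pose_pca> %d components over %d features, %d trials\n",
              x$k, length(x$features), x$n_trials))
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pose_pca <- function(x, ...) {
  tibble(component = rep(paste0("PC", seq_len(x$k)), each = length(x$features)),
         feature = rep(x$features, x$k),
         loading = as.vector(t(x$loadings)))
}

#' @export
glance.pose_pca <- function(x, ...) {
  out <- as.list(setNames(x$var_explained, paste0("var_PC", seq_len(x$k))))
  as_tibble(c(out, list(total = sum(x$var_explained), n_trials = x$n_trials)))
}

#' @export
autoplot.pose_pca <- function(object, ...) {
  df <- tibble(component = factor(paste0("PC", seq_len(object$k)),
                                  paste0("PC", seq_len(object$k))),
               frac = object$var_explained)
  ggplot(df, aes(x = .data$component, y = 100 * .data$frac)) +
    geom_col(fill = "steelblue") +
    labs(y = "variance explained (%)", x = NULL)
}

#' Cross-validate a pose PCA by train/test split
#'
#' Pseudo-randomly splits the trials (80:20 by default), fits the PCA on
#' the training set and reports the variance fractions its components
#' explain in both sets.
#'
#' @param features As in [fit_pose_pca()].
#' @param k Components.
#' @param train_frac Training fraction.
#' @param seed Seed for the split.
#' @return Tibble: `component`, `train_var`, `test_var`.
#' @export
pca_split_validation <- function(features, k = 3, train_frac = 0.8, seed = 1) {
  num_cols <- if (is.data.frame(features)) {
    setdiff(names(features), c("mouse_id", "trial_id", "frame", "time_ms"))
  } else colnames(features)
  X <- as.matrix(if (is.data.frame(features)) features[, num_cols] else features)
  X <- X[complete.cases(X), , drop = FALSE]
  set.seed(seed)
  n <- nrow(X)
  tr <- sort(sample.int(n, round(train_frac * n)))
  model <- fit_pose_pca(X[tr, , drop = FALSE], k = k)
  frac_in <- function(M) {
    Mc <- scale(M, center = model$center, scale = FALSE)
    sc <- Mc %*% t(model$loadings)
    tot <- sum(apply(Mc, 2, function(v) mean(v^2)))
    apply(sc, 2, function(v) mean(v^2)) / tot
  }
  tibble(component = paste0("PC", seq_len(model$k)),
         train_var = as.numeric(frac_in(X[tr, , drop = FALSE])),
         test_var = as.numeric(frac_in(X[-tr, , drop = FALSE])))
}

#' Project pose time courses onto fitted components
#'
#' Scores every frame of every trial on the components of a fitted
#' [fit_pose_pca()] model (frames with missing features are skipped) and
#' reports the fraction of total time-course variance those components
#' capture, overall and per component.
#'
#' @param features Time-course feature tibble ([pose_features()] with
#'   `at_ms = NULL`).
#' @param model A `pose_pca` object.
#' @return List: `scores` tibble (ids, `frame`, `time_ms`, `PC1..PCk`),
#'   `var_explained` (per component), `var_total`.
#' @export
project_trajectories <- function(features, model) {
  stopifnot(inherits(model, "pose_pca"))
  if (!all(model$features %in% names(features))) {
    abort("feature columns do not match the fitted model.",
          class = "pawkit_validation_error")
  }
  X <- as.matrix(features[, model$features])
  cc <- complete.cases(X)
  Xc <- scale(X[cc, , drop = FALSE], center = model$center, scale = FALSE)
  sc <- Xc %*% t(model$loadings)
  colnames(sc) <- paste0("PC", seq_len(model$k))
  ids <- features[cc, intersect(c("mouse_id", "trial_id", "frame", "time_ms"),
                                names(features))]
  tot <- sum(apply(Xc, 2, function(v) mean(v^2)))
  per <- apply(sc, 2, function(v) mean(v^2)) / tot
  resid <- Xc - sc %*% model$loadings
  var_total <- 1 - sum(apply(resid, 2, function(v) mean(v^2))) / tot
  list(scores = dplyr::bind_cols(as_tibble(ids), as_tibble(sc)),
       var_explained = per, var_total = var_total)
}

#' Direction statistics of PC-space trajectories
#'
#' Each trial's trajectory direction is the angle of its PC1-PC2
#' displacement between the start and end of the analysis window (nearest
#' available frames). The spread of directions across trials is summarized
#' by the circular mean and circular SD; a small circular SD means the
#' population moves through pose space in a common direction.
#'
#' @param scores Score tibble from [project_trajectories()].
#' @param window Two times in ms, default `c(35, 115)`.
#' @return Tibble: `circ_mean_deg`, `circ_sd_deg`, `n_trials`, `n_excluded`
#'   (zero-length displacements), plus a `directions` list-column with the
#'   per-trial angles.
#' @export
trajectory_direction_stats <- function(scores, window = c(35, 115)) {
  dirs <- scores %>%
    group_by(.data$mouse_id, .data$trial_id) %>%
    dplyr::group_modify(function(df, key) {
      i0 <- which.min(abs(df$time_ms - window[1]))
      i1 <- which.min(abs(df$time_ms - window[2]))
      dx <- df$PC1[i1] - df$PC1[i0]
      dy <- df$PC2[i1] - df$PC2[i0]
      tibble(dx = dx, dy = dy,
             dir_deg = if (dx == 0 && dy == 0) NA_real_
                       else atan2(dy, dx) * 180 / pi)
    }) %>%
    ungroup()
  ok <- dirs$dir_deg[!is.na(dirs$dir_deg)]
  tibble(circ_mean_deg = circular_mean_deg(ok),
         circ_sd_deg = circular_sd_deg(ok),
         n_trials = length(ok),
         n_excluded = sum(is.na(dirs$dir_deg)),
         directions = list(ok))
}

#' Shuffle part identities within trials
#'
#' Control for trajectory direction statistics: permutes which body part
#' each (x, y) column pair belongs to, independently per trial but
#' consistently across that trial's frames. Directional structure tied to
#' body-part identity is destroyed; trivial common-mode structure survives.
#'
#' @param features Feature tibble (single time point or time course).
#' @param parts Parts to permute among (default [analysis_parts()]).
#' @param seed Seed.
#' @return Features with shuffled part columns.
#' @export
shuffle_parts <- function(features, parts = analysis_parts(), seed = 1) {
  set.seed(seed)
  out <- features
  ids <- unique(features[, c("mouse_id", "trial_id")])
  for (r in seq_len(nrow(ids))) {
    rows <- features$mouse_id == ids$mouse_id[r] &
      features$trial_id == ids$trial_id[r]
    perm <- sample(parts)
    for (cc in c("_x", "_y")) {
      from <- paste0(parts, cc)
      to <- paste0(perm, cc)
      out[rows, to] <- features[rows, from]
    }
  }
  out
}

# -- classical tests and fits -------------------------------------------------

#' Friedman test with Dunn pairwise comparisons
#'
#' Within-subject nonparametric test for repeated measures across
#' conditions (tie-corrected Friedman chi-square on within-subject ranks),
#' followed by Dunn's pairwise signed-rank z comparisons on the rank sums.
#' No multiplicity adjustment is applied by default; set `p_adjust` to any
#' [stats::p.adjust()] method to change that.
#'
#' @param table Numeric matrix or data frame, subjects x conditions,
#'   complete (subjects with missing cells must be dropped beforehand).
#' @param p_adjust Adjustment method for the pairwise p values
#'   (default `"none"`).
#' @return List of class `friedman_dunn`: `statistic`, `df`, `p_value`,
#'   `n_subjects`, `pairwise` tibble (`cond_a`, `cond_b`, `z`, `p`,
#'   `p_adj`).
#' @export
friedman_dunn <- function(table, p_adjust = "none") {
  m <- as.matrix(table)
  if (anyNA(m)) abort("table has missing cells; drop incomplete subjects.",
                      class = "pawkit_validation_error")
  n <- nrow(m); kk <- ncol(m)
  if (n < 2L || kk < 2L) abort("need >= 2 subjects and >= 2 conditions.",
                               class = "pawkit_validation_error")
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  ties <- apply(r, 1L, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  })
  denom <- n * kk * (kk + 1) - sum(ties) / (kk - 1)
  # fully tied table (identical conditions): no evidence of any difference
  stat <- if (denom <= 0) 0 else 12 * sum((Rj - n * (kk + 1) / 2)^2) / denom
  p <- pchisq(stat, df = kk - 1, lower.tail = FALSE)
  conds <- colnames(m) %||% paste0("cond", seq_len(kk))
  pairs <- utils::combn(kk, 2)
  se <- sqrt(kk * (kk + 1) / (6 * n))
  pw <- tibble(cond_a = conds[pairs[1, ]], cond_b = conds[pairs[2, ]],
               z = (Rj[pairs[1, ]] / n - Rj[pairs[2, ]] / n) / se)
  pw$p <- 2 * pnorm(-abs(pw$z))
  pw$p_adj <- p.adjust(pw$p, method = p_adjust)
  structure(list(statistic = stat, df = kk - 1L, p_value = p,
                 n_subjects = n, pairwise = pw),
            class = "friedman_dunn")
}

#' @export
print.friedman_dunn <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.3f, df = %d, p = %.4g (n = %d subjects)\n",
              x$statistic, x$df, x$p_value, x$n_subjects))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.friedman_dunn <- function(x, ...) x$pairwise

#' @export
glance.friedman_dunn <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n_subjects = x$n_subjects)
}

#' Regression fits for dose-response style relations
#'
#' Least-squares fits in the transformed space the relation calls for:
#' `"linear"` (`y ~ x`, with Pearson's r), `"loglog"`
#' (`log y ~ log x`, power laws such as latency against input size) and
#' `"lognormal"` (`y ~ log x`; when y is strictly positive the
#' `log y ~ log x` alternative is reported alongside). R-squared is
#' computed in the fitted (transformed) space.
#'
#' @param x,y Numeric vectors (>= 3 finite pairs; positive where a log is
#'   taken).
#' @param kind `"linear"`, `"loglog"` or `"lognormal"`.
#' @return Object of class `behavior_fit`: `kind`, `coefficients`
#'   (intercept, slope), `r_squared`, `pearson_r` (linear only),
#'   `alt_r_squared` (lognormal with positive y), `n`, and the `lm` fit.
#' @export
regression_fits <- function(x, y, kind = c("linear", "loglog", "lognormal")) {
  kind <- match.arg(kind)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 finite pairs.",
                            class = "pawkit_validation_error")
  need_logx <- kind %in% c("loglog", "lognormal")
  need_logy <- kind == "loglog"
  if (need_logx && any(x <= 0)) {
    abort(paste0("log transform needs positive x; offending indices: ",
                 paste(which(x <= 0), collapse = ", ")),
          class = "pawkit_validation_error")
  }
  if (need_logy && any(y <= 0)) {
    abort(paste0("log transform needs positive y; offending indices: ",
                 paste(which(y <= 0), collapse = ", ")),
          class = "pawkit_validation_error")
  }
  xt <- if (need_logx) log(x) else x
  yt <- if (need_logy) log(y) else y
  fit <- lm(yt ~ xt)
  r2 <- summary(fit)$r.squared
  alt <- NA_real_
  if (kind == "lognormal" && all(y > 0)) {
    alt <- summary(lm(log(y) ~ xt))$r.squared
  }
  structure(list(kind = kind,
                 coefficients = setNames(coef(fit), c("intercept", "slope")),
                 r_squared = r2,
                 pearson_r = if (kind == "linear") cor(x, y) else NA_real_,
                 alt_r_squared = alt, n = length(x), fit = fit),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat(sprintf("<behavior_fit> %s: intercept %.4g, slope %.4g, R^2 = %.3f (n = %d)\n",
              x$kind, x$coefficients[1], x$coefficients[2], x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.behavior_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"), estimate = sm[, 1],
         std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' @export
glance.behavior_fit <- function(x, ...) {
  tibble(kind = x$kind, r.squared = x$r_squared, pearson_r = x$pearson_r,
         alt.r.squared = x$alt_r_squared, n = x$n)
}
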