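test_that("pose PCA matches an independent eigendecomposition", {
  set.seed(3)
  # Gaussian features with known covariance eigenvalues
  n <- 400
  ev <- c(4, 2, 1, rep(0.25, 9))
  rot <- qr.Q(qr(matrix(rnorm(144), 12)))
  X <- matrix(rnorm(n * 12), n) %*% diag(sqrt(ev)) %*% t(rot)
  colnames(X) <- paste0("f", 1:12)
  m <- fit_pose_pca(X, k = 3)
  oracle <- eigen(cov(X) * (n - 1) / n, symmetric = TRUE)
  expect_equal(m$var_explained,
               (oracle$values / sum(oracle$values))[1:3], tolerance = 1e-6)
  # loadings span the same subspace as the oracle eigenvectors
  for (j in 1:3) {
    expect_equal(abs(sum(m$loadings[j, ] * oracle$vectors[, j])), 1,
                 tolerance = 1e-6)
  }
  # sign convention makes refits identical
  expect_identical(m$loadings, fit_pose_pca(X, k = 3)$loadings)
  expect_true(all(apply(m$loadings, 1, function(v) v[which.max(abs(v))] > 0)))
})

test_that("collinear features load entirely on the first component", {
  t_ <- seq(0, 1, length.out = 50)
  X <- cbind(a = 2 * t_, b = -t_, c = 0.5 * t_ + 1)
  m <- suppressWarnings(fit_pose_pca(X, k = 2))
  expect_equal(m$var_explained[1], 1, tolerance = 1e-9)
})

test_that("train/test split validation reports both variance fractions", {
  set.seed(5)
  X <- matrix(rnorm(80 * 12), 80)
  colnames(X) <- paste0("f", 1:12)
  cv <- pca_split_validation(X, k = 3, seed = 2)
  expect_equal(nrow(cv), 3L)
  expect_true(all(cv$train_var > 0 & cv$train_var < 1))
  expect_true(all(cv$test_var > 0 & cv$test_var < 1))
})

test_that("trajectory projection is consistent with the fit", {
  sim <- gen_pose_cohort(cohort_spec(n_mice = 3, trials_per_mouse = 4),
                         seed = 7)
  al <- dplyr::group_modify(
    dplyr::group_by(sim$tracks, mouse_id, trial_id),
    ~ egocentric_align(filter_labels(.x)))
  al <- dplyr::ungroup(al)
  feats <- pose_features(al, at_ms = 115)
  m <- fit_pose_pca(feats)
  pr <- project_trajectories(feats, m)
  expect_equal(as.matrix(pr$scores[, c("PC1", "PC2", "PC3")]),
               as.matrix(m$scores[, c("PC1", "PC2", "PC3")]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # the model mean projects to the origin
  mean_row <- tibble::as_tibble(as.list(m$center))
  pr0 <- project_trajectories(mean_row, m)
  expect_equal(unlist(pr0$scores[, c("PC1", "PC2", "PC3")]),
               c(PC1 = 0, PC2 = 0, PC3 = 0), tolerance = 1e-9)

  # variance captured equals 1 - residual/total computed by brute force
  tc <- pose_features(al, at_ms = NULL)
  pr2 <- project_trajectories(tc, m)
  X <- as.matrix(tc[stats::complete.cases(tc[, m$features]), m$features])
  Xc <- scale(X, center = m$center, scale = FALSE)
  resid <- Xc - (Xc %*% t(m$loadings)) %*% m$loadings
  brute <- 1 - sum(resid^2) / sum(Xc^2)
  expect_equal(pr2$var_total, brute, tolerance = 1e-9)
})

test_that("circular statistics follow their closed forms", {
  expect_equal(circular_sd_deg(c(0, 90)),
               sqrt(-2 * log(sqrt(2) / 2)) * 180 / pi, tolerance = 1e-9)
  expect_equal(round(circular_sd_deg(c(0, 90)), 2), 47.7)
  expect_equal(circular_sd_deg(rep(45, 10)), 0)
  expect_equal(circular_mean_deg(c(350, 10)), 0, tolerance = 1e-9)
  # rotation invariance of the circular SD
  set.seed(9)
  a <- runif(50, -180, 180)
  expect_equal(circular_sd_deg(a), circular_sd_deg(a + 107), tolerance = 1e-9)

  # von Mises sample: circular SD matches the analytic value for kappa = 4
  set.seed(11)
  vm <- rvonmises(4000, 0, 4) * 180 / pi
  R <- besselI(4, 1) / besselI(4, 0)
  expect_lt(abs(circular_sd_deg(vm) - sqrt(-2 * log(R)) * 180 / pi), 1.5)
})

test_that("trajectory directions concentrate for aligned displacements", {
  sc <- tibble::tibble(mouse_id = "m", trial_id = as.character(1:5),
                       frame = 1L, time_ms = 35,
                       PC1 = 0, PC2 = 0)
  sc2 <- dplyr::mutate(sc, time_ms = 115, PC1 = 1:5, PC2 = 0, frame = 2L)
  ds <- trajectory_direction_stats(dplyr::bind_rows(sc, sc2))
  expect_equal(ds$circ_sd_deg, 0)
  expect_equal(ds$circ_mean_deg, 0)
  # two trials at 0 and 90 degrees
  sc3 <- dplyr::bind_rows(
    tibble::tibble(mouse_id = "m", trial_id = c("a", "b"), frame = 1L,
                   time_ms = 35, PC1 = 0, PC2 = 0),
    tibble::tibble(mouse_id = "m", trial_id = c("a", "b"), frame = 2L,
                   time_ms = 115, PC1 = c(1, 0), PC2 = c(0, 1)))
  expect_equal(trajectory_direction_stats(sc3)$circ_sd_deg, 47.7,
               tolerance = 0.01)
})

test_that("part shuffling degrades trajectory directionality", {
  sim <- gen_pose_cohort(cohort_spec(), seed = 11)
  al <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(sim$tracks, mouse_id, trial_id),
    ~ egocentric_align(filter_labels(.x))))
  m <- fit_pose_pca(pose_features(al, at_ms = 115))
  tc <- pose_features(al, at_ms = NULL)
  plain <- trajectory_direction_stats(project_trajectories(tc, m)$scores)
  shuf <- trajectory_direction_stats(
    project_trajectories(shuffle_parts(tc, seed = 2), m)$scores)
  expect_gt(shuf$circ_sd_deg, plain$circ_sd_deg)
})

test_that("the balanced hierarchical bootstrap behaves at its edges", {
  # constant data: estimate is the constant, zero spread
  d <- data.frame(mouse_id = rep(c("a", "b"), each = 3), value = 7)
  b <- hierarchical_bootstrap(d, value, n_boot = 500, seed = 1)
  expect_equal(b$estimate, 7)
  expect_equal(b$se, 0)

  # a single mouse with balanced k reduces to the one-level bootstrap
  d1 <- data.frame(mouse_id = "a", value = c(1, 2, 3))
  b1 <- hierarchical_bootstrap(d1, value, estimator = "mean", n_boot = 4000,
                               seed = 2)
  set.seed(3)
  naive <- replicate(4000, mean(sample(c(1, 2, 3), 3, replace = TRUE)))
  expect_lt(abs(b1$estimate - mean(naive)), 0.05)
  expect_lt(abs(b1$se - sd(naive)) / sd(naive), 0.15)
  expect_gt(suppressWarnings(ks.test(b1$replicates, naive)$p.value), 0.001)

  # exact reproducibility under a fixed seed
  b2 <- hierarchical_bootstrap(d1, value, estimator = "mean", n_boot = 100,
                               seed = 5)
  b3 <- hierarchical_bootstrap(d1, value, estimator = "mean", n_boot = 100,
                               seed = 5)
  expect_identical(b2$replicates, b3$replicates)
})

test_that("the probability sum rule is exact and monotone", {
  expect_equal(sum_rule(0.096, 5), 1 - (1 - 0.096)^5, tolerance = 1e-12)
  expect_equal(round(sum_rule(0.096, 5), 2), 0.4)
  expect_equal(sum_rule(0, 7), 0)
  expect_equal(sum_rule(1, 3), 1)
  expect_equal(sum_rule(0.3, 1), 0.3)
  ps <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(sum_rule(ps, 4)) > 0))
  expect_true(all(diff(sum_rule(0.2, 1:6)) > 0))
  expect_error(sum_rule(1.2, 3), class = "pawkit_validation_error")
})

test_that("pulse matching assigns latencies to the most recent pulse", {
  pm <- pulse_matched_latency(250, 100, 5)
  expect_equal(pm$pulse_index, 2L)
  expect_equal(pm$residual_ms, 50)
  expect_equal(pm$latency_isi, 2.5)
  pm2 <- pulse_matched_latency(50, 200, 5)
  expect_equal(pm2$pulse_index, 0L)
  expect_equal(pm2$residual_ms, 50)
  # latencies beyond the last pulse stay attributed to it
  pm3 <- pulse_matched_latency(950, 100, 5)
  expect_equal(pm3$pulse_index, 4L)
  expect_equal(pm3$residual_ms, 550)
})

test_that("the Friedman statistic matches the classical rank formula", {
  # identical conditions: no evidence
  same <- matrix(rep(c(1, 2, 3), 3), 3, 3)
  f0 <- friedman_dunn(t(same) * 0 + 5)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_value, 1)

  # strict ordering in 3 subjects x 3 conditions: statistic 6, df 2
  strict <- rbind(c(1, 2, 3), c(2, 4, 6), c(0.1, 0.5, 0.9))
  f1 <- friedman_dunn(strict)
  expect_equal(f1$statistic, 6)
  expect_equal(f1$df, 2L)
  expect_equal(nrow(f1$pairwise), 3L)

  # random tables agree with the independent implementation in stats
  set.seed(13)
  for (i in 1:5) {
    tab <- matrix(rnorm(7 * 6), 7, 6)
    if (i > 3) tab[cbind(1:3, 1:3)] <- tab[cbind(1:3, 4:6)]  # induce ties
    expect_equal(friedman_dunn(tab)$statistic,
                 unname(stats::friedman.test(tab)$statistic),
                 tolerance = 1e-9)
  }
  expect_error(friedman_dunn(matrix(c(1, NA, 2, 3), 2)),
               class = "pawkit_validation_error")
})

test_that("regression fits recover exact and noisy relations", {
  x <- 1:10
  lin <- regression_fits(x, 2 * x + 1, kind = "linear")
  expect_equal(unname(lin$coefficients), c(1, 2), tolerance = 1e-9)
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$pearson_r, 1)

  pw <- regression_fits(x, 3 * x^(-0.7), kind = "loglog")
  expect_equal(unname(pw$coefficients), c(log(3), -0.7), tolerance = 1e-9)
  expect_equal(pw$r_squared, 1)

  # noisy power law: coefficients equal the closed-form normal equations
  set.seed(17)
  y <- 3 * x^(-0.7) * exp(rnorm(10, 0, 0.2))
  fit <- regression_fits(x, y, kind = "loglog")
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% log(y))
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-9)

  ln <- regression_fits(x, log(x) * 2 + 5, kind = "lognormal")
  expect_equal(unname(ln$coefficients), c(5, 2), tolerance = 1e-9)
  expect_error(regression_fits(c(-1, 1, 2), c(1, 2, 3), kind = "loglog"),
               class = "pawkit_validation_error")
})

test_that("tidy and glance methods return well-formed tibbles", {
  d <- data.frame(mouse_id = rep(c("a", "b"), each = 4),
                  value = rnorm(8, 30))
  b <- hierarchical_bootstrap(d, value, n_boot = 200, seed = 1)
  expect_named(tidy(b), c("estimator", "estimate", "std.error"))
  expect_equal(glance(b)$n_boot, 200L)

  set.seed(19)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- fit_pose_pca(X, k = 2)
  expect_equal(nrow(tidy(m)), 6L)
  expect_true(all(c("var_PC1", "var_PC2") %in% names(glance(m))))
  expect_s3_class(autoplot(m), "ggplot")

  fit <- regression_fits(1:10, 2 * (1:10) + rnorm(10), kind = "linear")
  expect_named(tidy(fit), c("term", "estimate", "std.error", "statistic",
                            "p.value"))
  expect_equal(glance(fit)$kind, "linear")
})
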