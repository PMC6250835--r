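test_that("gap filling back-fills leading gaps and interpolates short ones", {
  p <- rbind(c(NA, NA, NA), c(NA, NA, NA), c(1, 2, 3), c(2, 3, 4))
  tr <- marker_trajectory(p, rate = 180)
  f <- fill_leading_gaps(tr)
  expect_equal(f[1, ], c(1, 2, 3))
  expect_equal(f[2, ], c(1, 2, 3))
  expect_equal(f[4, ], c(2, 3, 4))
  ## no gaps: identity
  clean <- marker_trajectory(matrix(rnorm(30), 10, 3))
  expect_equal(as.numeric(fill_leading_gaps(clean)), as.numeric(clean))
  ## single interior missing sample -> midpoint
  p2 <- rbind(c(0, 0, 0), c(NA, NA, NA), c(2, 2, 2))
  expect_equal(fill_leading_gaps(marker_trajectory(p2))[2, ], c(1, 1, 1))
  ## long interior gaps are left missing and flagged
  p3 <- matrix(1, 60, 3); p3[10:50, ] <- NA
  f3 <- fill_leading_gaps(marker_trajectory(p3, rate = 180), max_gap = 0.1)
  expect_true(anyNA(f3))
  expect_length(attr(f3, "long_gaps"), 1)
  ## trailing gaps are carried forward from the last valid value
  p4 <- rbind(c(1, 1, 1), c(2, 2, 2), c(NA, NA, NA))
  expect_equal(fill_leading_gaps(marker_trajectory(p4))[3, ], c(2, 2, 2))
  expect_error(fill_leading_gaps(marker_trajectory(matrix(NA_real_, 4, 3))),
               "no valid samples")
})

test_that("zero-phase marker filter has unit DC gain and kills 60 Hz", {
  n <- 360
  t <- (0:(n - 1)) / 180
  const <- marker_trajectory(matrix(2.5, n, 3))
  expect_equal(as.numeric(lowpass_markers(const)), rep(2.5, 3 * n),
               tolerance = 1e-9)
  ## 60 Hz at 180 Hz sampling: 10x above cutoff, squared 4th-order response
  s60 <- marker_trajectory(cbind(sin(2 * pi * 60 * t), 0, 0))
  out <- lowpass_markers(s60)
  expect_lt(max(abs(out[60:300, 1])), 0.01)
  ## linear ramp preserved away from the edges
  ramp <- marker_trajectory(cbind(t, 2 * t, 0))
  fr <- lowpass_markers(ramp)
  mid <- 90:270
  expect_lt(max(abs(fr[mid, 1] - t[mid])) / max(abs(t[mid])), 1e-6)
  expect_error(lowpass_markers(marker_trajectory(matrix(1, 5, 3))), "short")
  expect_error(lowpass_markers(marker_trajectory(rbind(matrix(1, 25, 3),
                                                       c(NA, NA, NA)))),
               "gaps")
})

test_that("Procrustes pose recovery is exact on rigid motion", {
  template <- rbind(c(0.1, 0, 0), c(-0.05, 0.0866, 0), c(-0.05, -0.0866, 0))
  ## identity
  fit0 <- procrustes_rigid(template, template)
  expect_equal(fit0$R, diag(3), tolerance = 1e-12)
  expect_equal(fit0$t, c(0, 0, 0), tolerance = 1e-12)
  ## known rigid motion, noiseless
  R <- cardan_yxz_matrix(c(25, -40, 110))
  t <- c(0.3, -0.2, 1.1)
  obs <- t(R %*% t(template)) + rep(t, each = 3)
  fit <- procrustes_rigid(template, obs)
  expect_equal(fit$R, R, tolerance = 1e-9)
  expect_equal(fit$t, t, tolerance = 1e-9)
  expect_error(procrustes_rigid(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                template), "degenerate")
})

test_that("cluster orientation error stays under 3 degrees with 1 mm noise", {
  ## Monte-Carlo oracle: 3 markers on a 10 cm arm, isotropic sigma = 1 mm
  template <- rbind(c(0.1, 0, 0), c(-0.05, 0.0866, 0), c(-0.05, -0.0866, 0))
  set.seed(42)
  errs <- replicate(1000, {
    R <- cardan_yxz_matrix(stats::runif(3, -60, 60))
    obs <- t(R %*% t(template)) + matrix(stats::rnorm(9, sd = 1e-3), 3, 3)
    fit <- procrustes_rigid(template, obs)
    Rerr <- crossprod(fit$R, R)
    acos(pmin(1, (sum(diag(Rerr)) - 1) / 2)) * 180 / pi
  })
  expect_gt(mean(errs < 3), 0.95)
})

test_that("Cardan Y-X'-Z'' decomposition inverts composition", {
  expect_equal(as.numeric(cardan_yxz(diag(3))), c(0, 0, 0))
  expect_equal(as.numeric(cardan_yxz(cardan_yxz_matrix(c(30, 0, 0)))),
               c(30, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(cardan_yxz(cardan_yxz_matrix(c(10, 20, 5)))),
               c(10, 20, 5), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:25) {
    a <- stats::runif(3, -89, 89)
    expect_equal(as.numeric(cardan_yxz(cardan_yxz_matrix(a))), a,
                 tolerance = 1e-9)
  }
  expect_warning(cardan_yxz(cardan_yxz_matrix(c(10, 90, 0))), "gimbal")
  expect_error(cardan_yxz(matrix(1, 3, 3)), "not a proper rotation")
})

test_that("joint angles recover a hinge motion with the measured excursion", {
  n <- 50
  theta <- seq(0, 53.4, length.out = n)
  ident <- list(R = rep(list(diag(3)), n), p = matrix(0, n, 3))
  child <- list(R = lapply(theta, function(a) rot_y(a * pi / 180)),
                p = matrix(0, n, 3))
  ang <- joint_angles(ident, child, joint = "hip")
  expect_equal(unname(range_of_motion(ang)[["hip_fe"]]), 53.4,
               tolerance = 1e-9)
  expect_equal(ang[, "hip_aa"], rep(0, n), tolerance = 1e-9)
  ## child == parent -> zero everywhere
  same <- joint_angles(child, child)
  expect_equal(max(abs(same)), 0, tolerance = 1e-9)
  ## sign flip negates the series exactly
  flipped <- joint_angles(ident, child, sign_map = c(-1, 1, 1), joint = "hip")
  expect_equal(flipped[, "hip_fe"], -ang[, "hip_fe"])
  expect_error(joint_angles(ident, list(R = child$R[1:3], p = child$p[1:3, ])),
               "frame count")
})

test_that("outlier screening excludes trials deviating beyond 45 degrees", {
  base <- matrix(seq(0, 60, length.out = 100), 100, 3)
  colnames(base) <- c("hip_fe", "knee_fe", "ankle_fe")
  trials <- list(base, base, base)
  res <- exclude_outlier_trials(trials, base)
  expect_length(res$retained, 3)
  expect_false(any(res$report$excluded))
  shifted <- base; shifted[, "knee_fe"] <- shifted[, "knee_fe"] + 50
  near <- base; near[, "hip_fe"] <- near[, "hip_fe"] + 44
  res2 <- exclude_outlier_trials(list(base, shifted, near), base)
  expect_equal(res2$report$excluded, c(FALSE, TRUE, FALSE))
  expect_equal(res2$report$channel[2], "knee_fe")
  expect_equal(res2$report$deviation_deg[2], 50)
  expect_error(exclude_outlier_trials(list(), base), "no trials")
})

test_that("time normalization preserves endpoints and band-limited shape", {
  lin <- matrix(seq(0, 100, length.out = 57), ncol = 1)
  tn <- time_normalize(lin)
  expect_equal(nrow(tn), 100)
  expect_equal(tn[1, 1], 0)
  expect_equal(tn[100, 1], 100)
  expect_equal(as.numeric(tn), seq(0, 100, length.out = 100), tolerance = 1e-9)
  ## constant trace
  expect_equal(as.numeric(time_normalize(matrix(7, 50, 1))), rep(7, 100))
  ## slow sine reproduced within 0.5% of amplitude
  x <- sin(2 * pi * seq(0, 1, length.out = 400))
  tn2 <- time_normalize(matrix(x, ncol = 1))
  truth <- sin(2 * pi * seq(0, 1, length.out = 100))
  expect_lt(max(abs(tn2 - truth)), 0.005)
  ## idempotence on an already-normalized series
  expect_equal(time_normalize(tn), tn, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(time_normalize(lin, start = 10, end = 5), "end event")
})

test_that("ensemble averaging is subject-first", {
  a <- matrix(10, 100, 1); b <- matrix(30, 100, 1)
  res <- ensemble_average(list(s1 = list(a), s2 = list(b)))
  expect_equal(res$mean[1, 1], 20)
  expect_equal(res$sd[1, 1], sqrt(200), tolerance = 1e-12)
  ## one subject, identical trials: SD 0
  res1 <- ensemble_average(list(s1 = list(a, a, a)))
  expect_equal(max(abs(res1$sd)), 0)
  ## unbalanced trial counts do not bias the grand mean
  res2 <- ensemble_average(list(s1 = list(a, a + 10), s2 = list(b + 10)))
  expect_equal(res2$mean[1, 1], (15 + 40) / 2)
  expect_error(ensemble_average(list(s1 = list())), "no trials")
})

test_that("range of motion is an offset-invariant span", {
  x <- matrix(c(seq(-20, 33.4, length.out = 60)), ncol = 1,
              dimnames = list(NULL, "hip_fe"))
  expect_equal(unname(range_of_motion(x)), 53.4)
  expect_equal(range_of_motion(x + 90), range_of_motion(x))
  expect_equal(unname(range_of_motion(matrix(5, 10, 1))), 0)
})

test_that("sit-to-stand events bracket the movement", {
  n <- 200
  ang <- matrix(0, n, 1, dimnames = list(NULL, "hip_fe"))
  ang[60:120, 1] <- seq(0, 50, length.out = 61)
  ang[120:n, 1] <- 50
  ev <- sts_events(ang, rate = 180)
  expect_true(ev["start"] >= 55 && ev["start"] <= 65)
  expect_true(ev["end"] >= 115 && ev["end"] <= 125)
  expect_error(sts_events(matrix(0, 50, 1)), "onset")
})

test_that("joint angles are invariant to a rigid world rotation", {
  model <- gh_model()
  trial <- gh_trial(n_frames = 12, noiseless = TRUE)
  cal <- model_calibration(model)
  kin <- trial_kinematics(trial$markers, cal, filter = FALSE)
  Rw <- cardan_yxz_matrix(c(30, 15, -20))
  rotated <- lapply(trial$markers, function(m) {
    out <- t(Rw %*% t(m))
    attr(out, "rate") <- attr(m, "rate")
    out
  })
  kin2 <- trial_kinematics(rotated, cal, filter = FALSE)
  expect_lt(max(abs(kin$angles - kin2$angles)), 1e-6)
})
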