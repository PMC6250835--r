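test_that("coordinate prefilter preserves slow content and kills 60 Hz", {
  n <- 360
  t <- (0:(n - 1)) / 180
  x <- cbind(const = rep(0.4, n), mixed = sin(2 * pi * t) +
               0.5 * sin(2 * pi * 60 * t))
  out <- prefilter_angles(x, rate = 180)
  expect_equal(dim(out), dim(x))
  expect_equal(out[, 1], rep(0.4, n), tolerance = 1e-9,
               ignore_attr = TRUE)
  mid <- 60:300
  expect_lt(max(abs(out[mid, 2] - sin(2 * pi * t[mid]))), 0.02)
  expect_error(prefilter_angles(x[1:10, ]), "short")
})

test_that("numerical derivatives match analytic ones", {
  dt <- 1 / 180
  n <- 181
  tt <- (0:(n - 1)) * dt
  ## linear: constant velocity, zero interior acceleration
  d <- derivatives(matrix(3 * tt, ncol = 1), dt)
  expect_equal(d$qd[, 1], rep(3, n), tolerance = 1e-9)
  expect_lt(max(abs(d$qdd[3:(n - 2), 1])), 1e-9)
  ## sine at 1 Hz: qdd = -w^2 q within 0.1% of w^2
  w <- 2 * pi
  ds <- derivatives(matrix(sin(w * tt), ncol = 1), dt)
  mid <- 5:(n - 4)
  expect_lt(max(abs(ds$qdd[mid, 1] + w^2 * sin(w * tt[mid]))), 0.001 * w^2)
  ## constant: all derivatives vanish
  dc <- derivatives(matrix(2, n, 1), dt)
  expect_equal(max(abs(dc$qd)), 0)
  expect_error(derivatives(matrix(1, 2, 1), dt), "3 frames")
})

test_that("gravity statics: 1 kg at 1 m horizontal gives a 9.81 Nm hinge moment", {
  pm <- pendulum_model(mass = 1, length = 1)
  q <- const_q(pm, c(hip_fe = -90), n = 3)
  id <- inverse_dynamics(pm, q, quasi_static = TRUE)
  expect_equal(unname(abs(id$moments[1, "hip_fe"])), 9.81,
               tolerance = 1e-9)
  ## rod hanging straight down: zero moment
  q0 <- const_q(pm, c(hip_fe = 0), n = 3)
  id0 <- inverse_dynamics(pm, q0, quasi_static = TRUE)
  expect_lt(abs(id0$moments[1, "hip_fe"]), 1e-9)
  ## gravity support shows up as the pelvis residual force
  expect_equal(id$residual_force[1, ], c(0, 0, 9.81), tolerance = 1e-9)
})

test_that("a ground force equal and opposite to limb weight zeroes the residual", {
  pm <- pendulum_model(mass = 2, length = 0.5)
  ## support the hanging rod at its centre of mass line of action
  n <- 3
  q <- const_q(pm, c(hip_fe = 0), n = n)
  wrench <- structure(list(grf = matrix(c(0, 0, 2 * 9.81), n, 3, byrow = TRUE),
                           cop = matrix(c(0, 0, -0.5), n, 3, byrow = TRUE),
                           rate = 180), class = "limb_wrench")
  ## the foot segment is absent here, so apply the load via the generic
  ## four-segment model instead
  model <- gh_model()
  qs <- const_q(model, sts_reference_angles()$standing, n = n)
  poses <- fk_poses(model, qs[1, ])
  weight <- sum(vapply(model$segments, `[[`, 0, "mass")) * 9.81
  coms <- vapply(names(model$segments), function(sn)
    as.numeric(poses[[sn]]$p + poses[[sn]]$R %*% model$segments[[sn]]$com),
    numeric(3))
  masses <- vapply(model$segments, `[[`, 0, "mass")
  com_all <- as.numeric(coms %*% masses / sum(masses))
  wrench2 <- structure(list(
    grf = matrix(c(0, 0, weight), n, 3, byrow = TRUE),
    cop = matrix(c(com_all[1], com_all[2], 0), n, 3, byrow = TRUE),
    rate = 180), class = "limb_wrench")
  id <- inverse_dynamics(model, qs, wrench2, quasi_static = TRUE)
  expect_lt(max(abs(id$residual_force)), 1e-9)
})

test_that("the CoP must be defined whenever substantial force is applied", {
  model <- gh_model()
  qs <- const_q(model, sts_reference_angles()$standing, n = 3)
  wrench <- structure(list(grf = matrix(c(0, 0, 100), 3, 3, byrow = TRUE),
                           cop = matrix(NA_real_, 3, 3), rate = 180),
                      class = "limb_wrench")
  expect_error(inverse_dynamics(model, qs, wrench, quasi_static = TRUE),
               "CoP undefined")
  ## below the threshold the force is dropped instead
  wrench$grf <- matrix(c(0, 0, 2), 3, 3, byrow = TRUE)
  expect_silent(inverse_dynamics(model, qs, wrench, quasi_static = TRUE))
})

test_that("pendulum power balance matches the energy change within 1%", {
  ## conservative swing: integral of moment x velocity equals the change
  ## in mechanical energy (kinetic + potential)
  pm <- pendulum_model(mass = 1.2, length = 0.8)
  rate <- 180
  n <- 181
  tt <- (0:(n - 1)) / rate
  theta <- -0.9 + 0.6 * sin(2 * pi * 0.5 * tt)
  q <- const_q(pm, c(hip_fe = 0), n = n)
  q[, "hip_fe"] <- theta
  id <- inverse_dynamics(pm, q)
  thd <- derivatives(matrix(theta, ncol = 1), 1 / rate)$qd[, 1]
  ## interior frames only (one-sided differences pollute the ends)
  i0 <- 3; i1 <- n - 2
  power <- id$moments[, "hip_fe"] * thd
  work <- sum((power[i0:(i1 - 1)] + power[(i0 + 1):i1]) / 2) / rate
  L <- 0.8; m <- 1.2
  energy <- function(i) 0.5 * m * (L * thd[i])^2 + m * 9.81 * (-L * cos(theta[i]))
  dE <- energy(i1) - energy(i0)
  expect_lt(abs(work - dE) / max(abs(dE), 0.1), 0.01)
})

test_that("quasi-static and full dynamics agree on a slow transition", {
  model <- gh_model()
  cfg <- synth_config(duration = 4, marker_noise_sd = 0, force_noise_sd = 0)
  trial <- synth_trial(model, cfg)
  cn <- coord_names(model)
  q <- trial$q[, cn]
  full <- inverse_dynamics(model, q, trial$wrench)
  qs <- inverse_dynamics(model, q, trial$wrench, quasi_static = TRUE)
  for (d in c("hip_fe", "knee_fe", "ankle_fe")) {
    rms <- sqrt(mean((full$moments[, d] - qs$moments[, d])^2))
    expect_lt(rms / sqrt(mean(full$moments[, d]^2)), 0.05)
  }
})

test_that("moments are invariant to a rigid rotation of the world frame", {
  model <- gh_model()
  trial <- gh_trial(n_frames = 10, noiseless = TRUE)
  cn <- coord_names(model)
  q <- trial$q[, cn]
  base <- inverse_dynamics(model, q, trial$wrench, quasi_static = TRUE)
  ## rotate everything by 40 degrees about the vertical axis
  phi <- 40 * pi / 180
  Rz <- rot_z(phi)
  q2 <- q
  q2[, "pelvis_rz"] <- q2[, "pelvis_rz"] + phi
  q2[, 1:3] <- t(Rz %*% t(q[, 1:3]))
  wrench2 <- trial$wrench
  wrench2$grf <- t(Rz %*% t(trial$wrench$grf))
  wrench2$cop <- t(Rz %*% t(trial$wrench$cop))
  rot <- inverse_dynamics(model, q2, wrench2, quasi_static = TRUE)
  expect_equal(rot$moments, base$moments, tolerance = 1e-9)
})

test_that("sign conventions remap deterministically", {
  m <- matrix(c(1, -2, 3, 4), 2, 2,
              dimnames = list(NULL, c("hip_fe", "knee_fe")))
  sm <- c(hip_fe = 1, knee_fe = -1)
  out <- apply_sign_convention(m, sm)
  expect_equal(out[, "hip_fe"], m[, "hip_fe"])
  expect_equal(out[, "knee_fe"], -m[, "knee_fe"])
  ## involution
  expect_equal(unclass(apply_sign_convention(out, sm))[, ], m[, ])
  expect_error(apply_sign_convention(m, c(hip_fe = 1)), "lacks")
})

test_that("moment normalization divides by body weight times leg length", {
  m <- matrix(13.56, 1, 1, dimnames = list(NULL, "hip_fe"))
  expect_equal(unname(normalize_moments(m, 27, 0.616)[1, 1]), 0.0831,
               tolerance = 1e-3)
  expect_equal(normalize_moments(m, 27, 2 * 0.616)[1, 1],
               normalize_moments(m, 27, 0.616)[1, 1] / 2)
  expect_equal(unname(normalize_moments(m * 0, 27, 0.616)[1, 1]), 0)
  expect_error(normalize_moments(m, -1, 0.616), "positive")
})
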