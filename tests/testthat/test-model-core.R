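test_that("maximal isometric force follows PCSA times the 300 kPa stress", {
  expect_equal(fmax_from_pcsa(14.11, 300), 423)
  expect_equal(fmax_from_pcsa(0, 300), 0)
  expect_equal(fmax_from_pcsa(7.62, 300), 229)
  expect_error(fmax_from_pcsa(-1), "non-negative")
  expect_error(fmax_from_pcsa(1, 0), "positive")
})

test_that("muscle parameter invariants are enforced", {
  expect_error(muscle_params("m", pcsa = -1, 0, 2, 1), "pcsa")
  expect_error(muscle_params("m", 1, 0, l_opt = 0, 1), "l_opt")
  expect_error(muscle_params("m", 1, 0, 2, tsl = -0.1), "tsl")
  expect_error(muscle_params("m", 1, 95, 2, 1), "pennation")
  m <- muscle_params("m", 14.11, 0, 2, 1)
  expect_equal(m$fmax, 423)      # computed from PCSA when not supplied
  expect_equal(mtu_rest_length(m), 3)
})

test_that("musculotendon length is a rigid polyline length", {
  pm <- pulley_model()
  ## both points on one segment: constant for any posture
  pm$muscles$rigid <- muscle_params(
    "rigid", 1, 0, 10, 10,
    path = muscle_path(c("thigh", "thigh"), rbind(c(0, 0, 0), c(0.3, 0, 0.4))),
    spanned_dofs = character())
  for (th in c(-1, 0, 0.7))
    expect_equal(mtu_length(pm, posture(pm, c(rep(0, 6), th)), "rigid"), 0.5)
  ## pulley case: length 2.0 at theta = 0 and matches the closed form
  q0 <- posture(pm)
  expect_equal(mtu_length(pm, q0, "pulley"), 2.0)
  for (th in seq(-0.8, 0.8, by = 0.2)) {
    q <- posture(pm, c(rep(0, 6), th))
    expect_equal(mtu_length(pm, q, "pulley"), pulley_length(th),
                 tolerance = 1e-12)
  }
})

test_that("polyline length respects the triangle inequality", {
  model <- gh_model()
  ref <- sts_reference_angles()
  for (s in c(0, 0.5, 1)) {
    q <- angles_to_posture(model, ref$crouched + s * (ref$standing - ref$crouched))
    poses <- fk_poses(model, q)
    for (mn in c("FDS", "RF", "SM")) {
      m <- model$muscles[[mn]]
      k <- length(m$path$segments)
      p1 <- poses[[m$path$segments[1]]]
      pk <- poses[[m$path$segments[k]]]
      ends <- sqrt(sum((as.numeric(pk$p + pk$R %*% m$path$points[k, ]) -
                        as.numeric(p1$p + p1$R %*% m$path$points[1, ]))^2))
      expect_gte(mtu_length(model, q, m), ends - 1e-12)
    }
  }
})

test_that("tendon-excursion moment arm matches the analytic pulley arm", {
  pm <- pulley_model()
  q0 <- posture(pm)
  expect_equal(abs(moment_arm(pm, q0, "pulley", "hip_fe")), 0.1,
               tolerance = 1e-6)
  ## central difference vs analytic derivative across the range
  for (th in seq(-0.6, 0.6, by = 0.3)) {
    q <- posture(pm, c(rep(0, 6), th))
    h <- 1e-6
    analytic <- -(pulley_length(th + h) - pulley_length(th - h)) / (2 * h)
    expect_equal(moment_arm(pm, q, "pulley", "hip_fe"), analytic,
                 tolerance = 1e-6)
  }
  ## a path confined to one segment has zero arm
  pm$muscles$rigid <- muscle_params(
    "rigid", 1, 0, 10, 10,
    path = muscle_path(c("thigh", "thigh"), rbind(c(0, 0, 0), c(0.3, 0, 0.4))),
    spanned_dofs = "hip_fe")
  expect_equal(moment_arm(pm, q0, "rigid", "hip_fe"), 0, tolerance = 1e-9)
  expect_error(moment_arm(pm, q0, "pulley", "hip_aa"), "not enabled")
  expect_error(moment_arm(pm, q0, "pulley", "hip_fe", step = 0), "underflow")
})

test_that("moment-arm matrix agrees with single-muscle arms", {
  model <- gh_model()
  q <- angles_to_posture(model, sts_reference_angles()$standing)
  arms <- moment_arm_matrix(model, q)
  for (mn in c("GMed", "VL", "GasL"))
    for (dn in intersect(model$muscles[[mn]]$spanned_dofs, colnames(arms)))
      expect_equal(arms[mn, dn], moment_arm(model, q, mn, dn),
                   tolerance = 1e-12)
  expect_equal(arms["VL", "hip_fe"], 0)   # does not span the hip
})

test_that("rigid-tendon fibre geometry is exact", {
  ## pennation 30 deg, l_opt 2: muscle height h = 1; p = sqrt(3) gives an
  ## optimal-length fibre with cos(pennation) = sqrt(3)/2
  m <- muscle_params("m", 10, 30, l_opt = 2, tsl = 5)
  fs <- fibre_state(5 + sqrt(3), m)
  expect_equal(fs$l_fibre, 2)
  expect_equal(fs$l_norm, 1)
  expect_equal(fs$cos_pennation, sqrt(3) / 2)
  ## pennation 0: p = l_opt
  m0 <- muscle_params("m0", 10, 0, l_opt = 3, tsl = 4)
  fs0 <- fibre_state(7, m0)
  expect_equal(fs0$l_norm, 1)
  expect_equal(fs0$cos_pennation, 1)
  ## flexor digitorum superficialis model columns at its rest length
  fds <- muscle_params("FDS", 37.16, 0, l_opt = 4.66, tsl = 21.36)
  expect_equal(fibre_state(26.02, fds)$l_norm, 1.0)
  ## projection identity: l_fibre * cos(pennation) + tsl = mtu length
  for (L in c(6.2, 7.5, 8.9)) {
    fs <- fibre_state(L, m)
    expect_equal(fs$l_fibre * fs$cos_pennation + m$tsl, L,
                 tolerance = 1e-12 * L)
  }
  expect_error(fibre_state(3, m0), "degenerate")
  ## metre input converts to the cm architecture space
  expect_equal(fibre_state(0.07, m0, units = "m")$l_norm, 1)
})

test_that("active force-length curve honours the 0.5-1.5 operating band", {
  expect_equal(active_force_length(1.0), 1.0)
  expect_equal(active_force_length(0.5), 0.0)
  expect_equal(active_force_length(1.5), 0.0)
  expect_equal(active_force_length(1.25), 0.75)
  expect_equal(active_force_length(0.2), 0)
  expect_equal(active_force_length(1.9), 0)
  l <- seq(0.5, 1.5, by = 0.01)
  f <- active_force_length(l)
  expect_equal(f, rev(f))                       # symmetric about 1
  expect_true(all(diff(f, differences = 2) < 1e-12))   # concave
})

test_that("muscle force is the activation-scaled projected capacity", {
  m <- muscle_params("m", 14.11, 0, 2, 1, fmax = 423)
  at_opt <- fibre_state(3, m)
  expect_equal(muscle_force(0, m, at_opt), 0)
  expect_equal(muscle_force(1, m, at_opt), 423)
  m2 <- muscle_params("m2", 10, 0, 2, 1, fmax = 400)
  fs <- fibre_state(3 + 0.5 * sqrt(1 - 0.75) * 2, m2)  # f_L = 0.75
  expect_equal(muscle_force(0.5, m2, fs), 0.5 * 400 * 0.75, tolerance = 1e-9)
  expect_error(muscle_force(1.2, m, at_opt), "0, 1")
})

test_that("standing tendon-slack-length tuning lands on the target boundary", {
  ## l_norm = (10 - 7)/2 = 1.5 -> tsl moves to 7.6 so l_norm = 1.2
  m <- muscle_params("m", 5, 0, l_opt = 2, tsl = 7)
  t1 <- tune_tsl_standing(m, 10)
  expect_equal(t1$tsl, 7.6, tolerance = 1e-5)
  expect_equal(fibre_state(10, t1)$l_norm, 1.2, tolerance = 1e-5)
  expect_equal(attr(t1, "tsl_adjust_pct"), 6, tolerance = 1e-3)
  ## already inside the window: untouched
  m2 <- muscle_params("m2", 5, 0, l_opt = 2, tsl = 8)
  expect_identical(tune_tsl_standing(m2, 10)$tsl, 8)
  ## idempotence
  t2 <- tune_tsl_standing(t1, 10)
  expect_equal(t2$tsl, t1$tsl, tolerance = 1e-5)
  ## unreachable target: even a zero tendon leaves the fibre too short
  m3 <- muscle_params("m3", 5, 0, l_opt = 2, tsl = 0.5)
  expect_error(tune_tsl_standing(m3, 1), "no non-negative TSL")
})

test_that("fibre-range retuning conserves musculotendon rest length", {
  ## 3 cm excursion centred at rest length with l_opt = 2: the band forces
  ## l_opt = excursion / (1.5 - 0.5) = 3, tendon shortened by 1
  m <- muscle_params("m", 5, 0, l_opt = 2, tsl = 10)
  lens <- 12 + seq(-1.5, 1.5, by = 0.25)
  r <- retune_fibre_range(m, lens)
  expect_equal(r$l_opt, 3, tolerance = 1e-6)
  expect_equal(r$tsl, 9, tolerance = 1e-6)
  expect_lt(abs((r$l_opt + r$tsl) - (m$l_opt + m$tsl)), 1e-9)
  ## series already inside the band: unchanged
  expect_identical(retune_fibre_range(m, c(11.5, 12, 12.5))$l_opt, 2)
  ## tendon too short to donate the required fibre length
  m2 <- muscle_params("m2", 5, 0, l_opt = 2, tsl = 0.5)
  expect_error(retune_fibre_range(m2, 2.5 + seq(-2, 2, by = 0.5)),
               "cannot retune")
})

test_that("subject scaling is homogeneous and averages the pelvis factor", {
  model <- gh_model()
  lens <- vapply(c("thigh", "shank", "foot"),
                 function(s) model$segments[[s]]$length, 0)
  same <- scale_model(model, as.list(lens))
  expect_equal(attr(same, "scale_factors"),
               c(pelvis = 1, thigh = 1, shank = 1, foot = 1))
  expect_equal(same$muscles$FDS$tsl, model$muscles$FDS$tsl, tolerance = 1e-9)

  uneven <- scale_model(model, list(thigh = lens[["thigh"]] * 1.0,
                                    shank = lens[["shank"]] * 1.1,
                                    foot = lens[["foot"]] * 1.2))
  expect_equal(unname(attr(uneven, "scale_factors")["pelvis"]), 1.1)

  twice <- scale_model(model, lapply(as.list(lens), `*`, 2))
  ref_q <- posture(model, check_ranges = FALSE)
  for (mn in c("GMed", "RF", "FDS")) {
    expect_equal(mtu_length(twice, ref_q, mn),
                 2 * mtu_length(model, ref_q, mn), tolerance = 1e-9)
    expect_equal(twice$muscles[[mn]]$l_opt / twice$muscles[[mn]]$tsl,
                 model$muscles[[mn]]$l_opt / model$muscles[[mn]]$tsl,
                 tolerance = 1e-9)
  }
  expect_equal(twice$segments$thigh$mass, 8 * model$segments$thigh$mass)
  expect_equal(twice$segments$thigh$inertia, 32 * model$segments$thigh$inertia)
  expect_error(scale_model(model, list(thigh = 0.2)), "shank")
})

test_that("postures validate coordinate counts and joint ranges", {
  model <- gh_model()
  expect_error(posture(model, rep(0, 3)), "coordinates")
  expect_error(posture(model, c(hip_fe = -140 * pi / 180)), "outside")
  expect_silent(posture(model, c(hip_fe = -100 * pi / 180)))
  expect_error(posture(model, c(nonsense = 1)), "unknown coordinate")
})
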