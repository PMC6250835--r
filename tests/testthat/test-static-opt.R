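test_that("a single muscle takes the load when reserves are expensive", {
  ## r = 0.02 m, Fmax = 500 N, f_L = cos = 1, tau = 5 Nm: a = tau/(r Fmax)
  arms <- matrix(0.02, 1, 1, dimnames = list("m", "dof"))
  sol <- solve_frame(arms, fcap = 500, tau = 5, R0 = 1e-4)
  expect_equal(unname(sol$activation), 0.5, tolerance = 1e-6)
  expect_lt(abs(sol$reserve), 1e-6)
  expect_equal(unname(sol$force), 250, tolerance = 1e-3)
})

test_that("two muscles share torque by the Lagrange capacity rule", {
  ## capacities k = (10, 20) Nm, tau = 10: a_i = tau k_i / sum(k^2)
  arms <- matrix(c(0.02, 0.04), 2, 1, dimnames = list(c("m1", "m2"), "dof"))
  sol <- solve_frame(arms, fcap = c(500, 500), tau = 10, R0 = 1e-4)
  expect_equal(unname(sol$activation), c(0.2, 0.4), tolerance = 1e-6)
  expect_equal(sum(c(10, 20) * sol$activation), 10, tolerance = 1e-9)
  ## monotone load property: scaling tau scales activations while unsaturated
  for (s in c(0.25, 0.5, 0.75)) {
    sols <- solve_frame(arms, fcap = c(500, 500), tau = 10 * s, R0 = 1e-4)
    expect_equal(unname(sols$activation), c(0.2, 0.4) * s, tolerance = 1e-6)
  }
})

test_that("saturated muscles cap at 1 and the reserve absorbs the rest", {
  arms <- matrix(0.02, 1, 1, dimnames = list("m", "dof"))
  sol <- solve_frame(arms, fcap = 500, tau = 25, R0 = 1e-4)
  expect_equal(unname(sol$activation), 1)
  expect_equal(unname(sol$reserve), 25 - 10, tolerance = 1e-9)
  ## zero torque, no antagonist coupling: zero activation
  sol0 <- solve_frame(arms, fcap = 500, tau = 0, R0 = 1e-4)
  expect_equal(unname(sol0$activation), 0, tolerance = 1e-9)
})

test_that("muscles with no force capacity stay silent", {
  arms <- matrix(c(0.02, 0.03), 2, 1, dimnames = list(c("live", "dead"), "dof"))
  ## second muscle at l_norm >= 1.5: f_L = 0 -> fcap 0
  sol <- solve_frame(arms, fcap = c(500, 0), tau = 5, R0 = 1e-4)
  expect_equal(unname(sol$activation["dead"]), 0)
  expect_equal(unname(sol$force["dead"]), 0)
  expect_equal(unname(sol$activation["live"]), 0.5, tolerance = 1e-6)
})

test_that("the optimum satisfies the KKT conditions under perturbation", {
  set.seed(11)
  arms <- matrix(stats::runif(12, -0.03, 0.05), 4, 3,
                 dimnames = list(paste0("m", 1:4), paste0("d", 1:3)))
  fcap <- c(400, 300, 500, 250)
  tau <- c(4, -2, 3)
  sol <- solve_frame(arms, fcap, tau, R0 = 1)
  obj <- function(a) sum(a^2) +
    sum((tau - as.numeric(crossprod(arms * fcap, a)))^2)
  base <- obj(sol$activation)
  for (i in 1:100) {
    a2 <- pmin(pmax(sol$activation + stats::rnorm(4, sd = 0.01), 0), 1)
    expect_gte(obj(a2), base - 1e-10)
  }
})

test_that("known activations are recovered exactly on a square system", {
  model <- gh_model()
  ## five muscles spanning the five enabled DOFs: a square, well-
  ## conditioned redistribution problem
  sub <- model
  sub$muscles <- model$muscles[c("GMed", "AddMag", "IP", "VL", "GasL")]
  ref <- sts_reference_angles()
  q <- const_q(sub, (ref$crouched + ref$standing) / 2, n = 4)
  a_star <- c(0.3, 0.5, 0.2, 0.4, 0.6)
  rec <- synth_recovery_case(sub, q, a_star)
  sol <- solve_trajectory(sub, q, rec$tau, R0 = 1e-4)
  expect_lt(max(abs(sweep(sol$activation, 2, a_star))), 1e-6)
})

test_that("the optimizer never does worse than the generating activations", {
  model <- gh_model()
  ref <- sts_reference_angles()
  q <- const_q(model, (ref$crouched + ref$standing) / 2, n = 2)
  set.seed(3)
  a_star <- stats::runif(length(model$muscles), 0, 0.6)
  rec <- synth_recovery_case(model, q, a_star)
  sol <- solve_trajectory(model, q, rec$tau, R0 = 1e-4)
  expect_lte(sol$objective[1], sum(a_star^2) + 1e-6)
})

test_that("moment balance holds to machine precision at every frame", {
  model <- gh_model()
  trial <- gh_trial(n_frames = 20)
  res <- run_sts_analysis(trial, model)
  jd <- names(enabled_dofs(model))
  tau <- res$moments$moments[, jd]
  sol <- res$solution
  for (i in seq_len(nrow(tau))) {
    arms <- moment_arm_matrix(model, res$q[i, coord_names(model)], jd)
    lhs <- as.numeric(crossprod(arms, sol$force[i, ])) + sol$reserve[i, ]
    expect_lt(max(abs(lhs - tau[i, ]) / pmax(1, abs(tau[i, ]))), 1e-6)
  }
})

test_that("constant posture and torque give a constant solution", {
  model <- gh_model()
  q <- const_q(model, sts_reference_angles()$standing, n = 3)
  tau <- matrix(c(3, 0.5, 0.1, 2, 4), 3, 5, byrow = TRUE,
                dimnames = list(NULL, names(enabled_dofs(model))))
  sol <- solve_trajectory(model, q, tau)
  expect_equal(sol$activation[1, ], sol$activation[3, ], tolerance = 1e-12)
  expect_equal(sol$reserve[1, ], sol$reserve[3, ], tolerance = 1e-12)
})

test_that("reserve summaries reproduce the percent-of-torque arithmetic", {
  res <- matrix(0, 10, 1, dimnames = list(NULL, "ankle_fe"))
  id <- matrix(6.65, 10, 1, dimnames = list(NULL, "ankle_fe"))
  zero <- reserve_summary(res, id)
  expect_equal(zero$avg_reserve_nm, 0)
  expect_false(zero$avg_flag || zero$peak_flag)
  ## the printed ankle figures: 1.63 Nm average over 6.65 Nm = 24.5%
  r2 <- reserve_summary(res + 1.63, id)
  expect_equal(r2$avg_pct_id, 24.5, tolerance = 1e-3)
  expect_true(r2$avg_flag)
  ## threshold boundaries: 0.9 Nm at 4% unflagged, 1.1 Nm at 4% flagged
  ok <- reserve_summary(res + 0.9, res + 22.5)
  expect_false(ok$avg_flag)
  bad <- reserve_summary(res + 1.1, res + 27.5)
  expect_true(bad$avg_flag)
})

test_that("the 20% activation / 20% body-weight reporting filter works", {
  sol <- structure(list(
    activation = cbind(quiet = rep(0.05, 5), active = c(0.05, 0.21, 0.1, 0, 0),
                       forceful = rep(0.1, 5)),
    force = cbind(quiet = rep(1, 5), active = rep(2, 5),
                  forceful = c(0, 60, 0, 0, 0)),
    muscle_names = c("quiet", "active", "forceful")),
    class = "activation_solution")
  expect_equal(muscle_report_filter(sol, body_weight = 264.87),
               c("active", "forceful"))
  all_zero <- sol
  all_zero$activation[] <- 0; all_zero$force[] <- 0
  expect_equal(muscle_report_filter(all_zero, 264.87), character(0))
  ## a constructed run where exactly k of n muscles pass
  expect_length(muscle_report_filter(sol, body_weight = 1e6), 1)
})
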