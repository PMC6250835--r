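## Frame-wise static optimization of muscle redundancy: minimize the sum
## of squared muscle activations plus squared reserve-actuator use,
## subject to exact per-DOF moment equilibrium with bounded activations.
##
## Reserve actuators are idealized torque actuators with "optimal torque"
## R0: reserve_j = R0 * b_j with unbounded b_j entering the objective as
## b_j^2. Eliminating b_j through the (hard) equilibrium constraint turns
## each frame into a strictly convex box-constrained quadratic programme
##
##   min_a  ||a||^2 + ||tau - K a||^2 / R0^2,  0 <= a <= 1,
##
## with K[j, i] = r_ij * Fmax_i * f_L(lnorm_i) * cos(pennation_i). The box
## QP is solved exactly by a primal active-set method (the objective is
## strictly convex, so the method terminates finitely at the unique
## optimum); equilibrium then holds to machine precision by construction
## of the reserves. A small R0 makes reserves expensive relative to
## muscles; the default of 1 Nm follows the usual reserve-actuator
## convention.

#' Solve a box-constrained strictly convex quadratic programme
#'
#' Minimizes \code{0.5 a' H a - c' a} subject to \code{0 <= a <= 1} by a
#' primal active-set method.
#'
#' @param H symmetric positive definite matrix.
#' @param c linear term.
#' @param max_iter iteration cap.
#' @param tol KKT tolerance.
#' @return List: \code{a} (solution), \code{iter}, \code{converged}.
#' @keywords internal
solve_box_qp <- function(H, c, max_iter = 200, tol = 1e-10) {
  n <- length(c)
  a <- rep(0.5, n)
  lower <- logical(n)   # clamped at 0
  upper <- logical(n)   # clamped at 1
  for (iter in seq_len(max_iter)) {
    free <- !(lower | upper)
    a[lower] <- 0; a[upper] <- 1
    if (any(free)) {
      rhs <- c[free] - H[free, upper, drop = FALSE] %*% rep(1, sum(upper))
      a[free] <- solve(H[free, free, drop = FALSE], rhs)
    }
    ## clamp the worst bound violation, if any
    viol_lo <- which(free & a < -tol)
    viol_hi <- which(free & a > 1 + tol)
    if (length(viol_lo) || length(viol_hi)) {
      cand <- c(viol_lo, viol_hi)
      worst <- cand[which.max(pmax(-a[cand], a[cand] - 1))]
      if (a[worst] < 0) lower[worst] <- TRUE else upper[worst] <- TRUE
      next
    }
    a <- pmin(pmax(a, 0), 1)
    ## KKT: release the most negative multiplier
    grad <- as.numeric(H %*% a - c)
    rel_lo <- which(lower & grad < -tol)
    rel_hi <- which(upper & grad > tol)
    if (!length(rel_lo) && !length(rel_hi))
      return(list(a = a, iter = iter, converged = TRUE))
    cand <- c(rel_lo, rel_hi)
    worst <- cand[which.max(abs(grad[cand]))]
    lower[worst] <- FALSE; upper[worst] <- FALSE
  }
  list(a = a, iter = max_iter, converged = FALSE)
}

#' Static optimization of a single frame
#'
#' @param arms moment-arm matrix (muscles x DOFs), m.
#' @param fcap per-muscle active force capacity at this posture,
#'   \code{Fmax * f_L(l_norm) * cos(pennation)}, N.
#' @param tau per-DOF net joint moments to reproduce, Nm.
#' @param R0 reserve-actuator optimal torque, Nm; smaller values make
#'   reserve use more expensive relative to muscle activation.
#' @param cap_tol muscles with capacity below \code{cap_tol * Fmax} are
#'   excluded from the constraint matrix (zero activation).
#' @param fmax per-muscle maximal isometric forces (for the capacity
#'   screen); defaults to \code{fcap}'s scale.
#' @return List: \code{activation}, \code{force} (N), \code{reserve}
#'   (Nm per DOF), \code{objective}, \code{converged}.
#' @export
solve_frame <- function(arms, fcap, tau, R0 = 1, cap_tol = 1e-9,
                        fmax = NULL) {
  arms <- as.matrix(arms)
  nm <- nrow(arms)
  if (length(fcap) != nm) stop("fcap length must match muscle count")
  if (is.null(fmax)) fmax <- pmax(fcap, 1)
  active <- fcap > cap_tol * pmax(fmax, 1)
  K <- t(arms[active, , drop = FALSE] * fcap[active])   # DOFs x muscles
  if (any(active)) {
    H <- 2 * diag(sum(active)) + 2 * crossprod(K) / R0^2
    cc <- as.numeric(2 * crossprod(K, tau) / R0^2)
    sol <- solve_box_qp(H, cc)
    a_act <- sol$a
    conv <- sol$converged
  } else {
    a_act <- numeric(0)
    conv <- TRUE
  }
  a <- numeric(nm)
  a[active] <- a_act
  force <- a * fcap
  reserve <- as.numeric(tau - if (any(active)) K %*% a_act else 0 * tau)
  names(reserve) <- colnames(arms)
  names(a) <- names(force) <- rownames(arms)
  list(activation = a, force = force, reserve = reserve,
       objective = sum(a^2) + sum((reserve / R0)^2), converged = conv)
}

#' Static optimization over a trajectory
#'
#' Frame-wise independent solves (static optimization has no activation
#' dynamics). Moment arms and fibre states are recomputed at every frame's
#' posture.
#'
#' @param model a [limb_model()].
#' @param q_series coordinate matrix (frames x coordinates).
#' @param tau_series moment matrix (frames x enabled joint DOFs), Nm.
#' @param R0 reserve optimal torque, Nm.
#' @param max_flagged maximum tolerated fraction of non-converged frames.
#' @return List of class \code{activation_solution}: \code{activation},
#'   \code{force}, \code{force_bw}, \code{l_norm} (frames x muscles),
#'   \code{reserve} (frames x DOFs), \code{objective}, \code{converged}
#'   (per frame), \code{dof_names}, \code{muscle_names}.
#' @export
solve_trajectory <- function(model, q_series, tau_series, R0 = 1,
                             max_flagged = 0.05) {
  q_series <- as.matrix(q_series)
  tau_series <- as.matrix(tau_series)
  n <- nrow(q_series)
  if (nrow(tau_series) != n) stop("kinematics and moments must be aligned")
  dof_names <- colnames(tau_series)
  mus <- model$muscles
  nm <- length(mus)
  act <- frc <- lno <- matrix(0, n, nm, dimnames = list(NULL, names(mus)))
  res <- matrix(0, n, length(dof_names), dimnames = list(NULL, dof_names))
  obj <- numeric(n)
  conv <- logical(n)
  fmax <- vapply(mus, `[[`, 0, "fmax")
  bw <- model$subject$mass * 9.81
  for (i in seq_len(n)) {
    q <- q_series[i, ]
    arms <- moment_arm_matrix(model, q, dof_names)
    lens <- mtu_lengths(model, q)
    ## a muscle whose MTU is shorter than its (rigid) tendon is slack:
    ## zero force capacity, normalized length reported below the operating
    ## band rather than aborting the frame
    fs <- lapply(seq_along(mus), function(k)
      tryCatch(fibre_state(lens[k], mus[[k]], units = "m"),
               error = function(e) list(
                 l_fibre = 0,
                 l_norm = (100 * lens[k] - mus[[k]]$tsl) / mus[[k]]$l_opt,
                 cos_pennation = 0)))
    fcap <- vapply(seq_along(mus), function(k)
      fmax[k] * active_force_length(fs[[k]]$l_norm) * fs[[k]]$cos_pennation, 0)
    sol <- solve_frame(arms, fcap, tau_series[i, ], R0 = R0, fmax = fmax)
    act[i, ] <- sol$activation
    frc[i, ] <- sol$force
    lno[i, ] <- vapply(fs, `[[`, 0, "l_norm")
    res[i, ] <- sol$reserve
    obj[i] <- sol$objective
    conv[i] <- sol$converged
  }
  if (mean(!conv) > max_flagged)
    stop(sprintf("static optimization failed on %.0f%% of frames",
                 100 * mean(!conv)))
  if (any(!conv))
    warning(sprintf("%d frame(s) flagged as non-converged", sum(!conv)))
  structure(list(activation = act, force = frc, force_bw = frc / bw,
                 l_norm = lno, reserve = res, objective = obj,
                 converged = conv, dof_names = dof_names,
                 muscle_names = names(mus)),
            class = "activation_solution")
}

#' Reserve-actuator summary against inverse-dynamics torques
#'
#' Cycle averages and peaks of absolute reserve and inverse-dynamics
#' torques per DOF, the reserve as a percentage of the inverse-dynamics
#' value (computed from unrounded series), and flags for exceeding the
#' conventional acceptability thresholds (reserve > \code{max_nm} Nm or
#' > \code{max_pct} % of the inverse-dynamics torque).
#'
#' @param sol an \code{activation_solution} (or reserve matrix).
#' @param id_moments a \code{joint_moment_series} (or moment matrix), Nm.
#' @param max_nm absolute reserve threshold, Nm.
#' @param max_pct relative reserve threshold, percent of ID torque.
#' @return Data.frame, one row per DOF: \code{avg_reserve_nm},
#'   \code{peak_reserve_nm}, \code{avg_id_nm}, \code{peak_id_nm},
#'   \code{avg_pct_id}, \code{peak_pct_id}, \code{avg_flag},
#'   \code{peak_flag}.
#' @export
reserve_summary <- function(sol, id_moments, max_nm = 1, max_pct = 5) {
  res <- if (inherits(sol, "activation_solution")) sol$reserve
         else as.matrix(sol)
  id <- if (inherits(id_moments, "joint_moment_series")) id_moments$moments
        else as.matrix(id_moments)
  if (nrow(res) != nrow(id)) stop("reserve and ID series must be aligned")
  out <- lapply(colnames(res), function(dn) {
    ar <- mean(abs(res[, dn])); pr <- max(abs(res[, dn]))
    ai <- mean(abs(id[, dn])); pi <- max(abs(id[, dn]))
    ap <- 100 * ar / ai; pp <- 100 * pr / pi
    data.frame(dof = dn, avg_reserve_nm = ar, peak_reserve_nm = pr,
               avg_id_nm = ai, peak_id_nm = pi,
               avg_pct_id = ap, peak_pct_id = pp,
               avg_flag = ar > max_nm || ap > max_pct,
               peak_flag = pr > max_nm || pp > max_pct)
  })
  do.call(rbind, out)
}

#' Reporting filter for simulated muscles
#'
#' A muscle is reported when its peak activation exceeds
#' \code{act_thresh} or its peak force exceeds \code{force_thresh} body
#' weights over the cycle.
#'
#' @param sol an \code{activation_solution}.
#' @param body_weight subject body weight, N.
#' @param act_thresh activation threshold.
#' @param force_thresh force threshold, body weights.
#' @return Character vector of reported muscle names.
#' @export
muscle_report_filter <- function(sol, body_weight, act_thresh = 0.2,
                                 force_thresh = 0.2) {
  peak_a <- apply(sol$activation, 2, max)
  peak_f <- apply(sol$force, 2, max)
  sol$muscle_names[peak_a > act_thresh | peak_f > force_thresh * body_weight]
}
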