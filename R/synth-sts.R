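## Synthetic sit-to-stand trial generator. Emulates the statistical
## structure of measured greyhound StS trials -- proximal-to-distal joint
## extension inside per-joint timing windows, a hindlimb vertical GRF
## approaching one body weight near 20% StS with a small craniad pulse at
## 15%, a craniad centre-of-pressure excursion, and additive marker and
## force noise -- so every pipeline stage can be exercised and validated
## against known ground truth without motion-capture data.

#' Synthetic trial configuration
#'
#' Defaults follow the measured study conditions: duration 1.14 s (between
#' -trial jitter SD 0.16 s), hip extension over 0-20% StS, knee over
#' 10-50%, ankle over 25-60%, flexion/extension excursions of 53.4, 78.5
#' and 88.7 degrees, vertical GRF peaking at 1.0 body weight at 20% StS,
#' a craniad pulse at 15% StS, and a 0.4 m craniad CoP excursion.
#'
#' @param duration trial duration, s.
#' @param duration_sd between-trial duration jitter SD, s.
#' @param windows list of per-joint timing windows, percent StS.
#' @param crouched,standing named joint-angle vectors, degrees.
#' @param grf_peak_bw vertical GRF peak, body weights.
#' @param grf_peak_pct percent StS of the vertical peak.
#' @param craniad_pulse_bw amplitude of the craniad force pulse, BW.
#' @param craniad_pulse_pct percent StS of the craniad pulse.
#' @param share_crouched,share_standing hindlimb share of body weight
#'   before and after the transition (the hindlimbs take over early).
#' @param cop_excursion craniad CoP travel, m.
#' @param marker_noise_sd marker noise SD, m.
#' @param force_noise_sd force noise SD, N.
#' @param angle_jitter_sd between-trial range-of-motion jitter SD, deg.
#' @param rate marker sampling rate, Hz.
#' @param seed integer seed; all of the trial's randomness flows from it.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(duration = 1.14, duration_sd = 0.16,
                         windows = list(hip = c(0, 20), knee = c(10, 50),
                                        ankle = c(25, 60)),
                         crouched = NULL, standing = NULL,
                         grf_peak_bw = 1.0, grf_peak_pct = 20,
                         craniad_pulse_bw = 0.1, craniad_pulse_pct = 15,
                         share_crouched = 0.45, share_standing = 0.55,
                         cop_excursion = 0.4,
                         marker_noise_sd = 0.001, force_noise_sd = 2,
                         angle_jitter_sd = 0, rate = 180, seed = 1L) {
  ref <- sts_reference_angles()
  if (is.null(crouched)) crouched <- ref$crouched
  if (is.null(standing)) standing <- ref$standing
  for (w in windows)
    if (w[1] < 0 || w[2] > 100 || w[1] >= w[2])
      stop("timing windows must satisfy 0 <= start < end <= 100")
  stopifnot(marker_noise_sd >= 0, force_noise_sd >= 0, duration_sd >= 0)
  structure(list(duration = duration, duration_sd = duration_sd,
                 windows = windows, crouched = crouched, standing = standing,
                 grf_peak_bw = grf_peak_bw, grf_peak_pct = grf_peak_pct,
                 craniad_pulse_bw = craniad_pulse_bw,
                 craniad_pulse_pct = craniad_pulse_pct,
                 share_crouched = share_crouched,
                 share_standing = share_standing,
                 cop_excursion = cop_excursion,
                 marker_noise_sd = marker_noise_sd,
                 force_noise_sd = force_noise_sd,
                 angle_jitter_sd = angle_jitter_sd,
                 rate = rate, seed = as.integer(seed)),
            class = "synth_config")
}

## logistic transition normalized to hit exactly 0/1 at the window edges,
## constant outside (the measured windows bound where each joint moves)
sigmoid_window <- function(pct, window) {
  c0 <- window[1]; c1 <- window[2]
  mid <- (c0 + c1) / 2
  k <- 2 * log(99) / (c1 - c0)       # 1% tails at the window edges
  raw <- stats::plogis(k * (pct - mid))
  lo <- stats::plogis(k * (c0 - mid)); hi <- stats::plogis(k * (c1 - mid))
  s <- (raw - lo) / (hi - lo)
  pmin(pmax(s, 0), 1)
}

#' Synthetic joint-angle profiles
#'
#' Each joint's extension follows a smooth monotone sigmoid confined to
#' its timing window, from the crouched to the standing angle; endpoint
#' values are exact and the extension rate is zero outside the window.
#'
#' @param cfg a [synth_config()].
#' @param n_frames number of frames (default: duration x rate).
#' @return Matrix (frames x joint coordinates, degrees) with attributes
#'   \code{"pct_sts"} and \code{"rate"}.
#' @export
synth_joint_angles <- function(cfg, n_frames = NULL) {
  if (is.null(n_frames)) n_frames <- max(2L, round(cfg$duration * cfg$rate))
  pct <- seq(0, 100, length.out = n_frames)
  cn <- names(cfg$crouched)
  out <- matrix(0, n_frames, length(cn), dimnames = list(NULL, cn))
  for (j in cn) {
    joint <- sub("_.*$", "", j)
    w <- cfg$windows[[joint]]
    if (is.null(w)) w <- c(0, 100)
    s <- sigmoid_window(pct, w)
    out[, j] <- cfg$crouched[[j]] + s * (cfg$standing[[j]] - cfg$crouched[[j]])
  }
  attr(out, "pct_sts") <- pct
  attr(out, "rate") <- cfg$rate
  out
}

#' Synthetic combined-hindlimb ground reaction force
#'
#' The vertical force rises from the crouched hindlimb share of body
#' weight to the configured peak at the configured percent of StS, then
#' settles to the standing share; a small craniad (positive X) pulse is
#' centred at 15% StS; the mediolateral channel is zero-mean noise.
#'
#' @param cfg a [synth_config()].
#' @param body_mass subject mass, kg.
#' @param n_frames frames (default duration x rate).
#' @param noise add seeded Gaussian noise of SD \code{force_noise_sd}.
#' @return A [force_plate_record()] at the marker rate with attribute
#'   \code{"pct_sts"}; forces in N (combined hindlimbs).
#' @export
synth_grf <- function(cfg, body_mass, n_frames = NULL, noise = TRUE) {
  if (is.null(n_frames)) n_frames <- max(2L, round(cfg$duration * cfg$rate))
  pct <- seq(0, 100, length.out = n_frames)
  bw <- body_mass * 9.81
  base <- cfg$share_crouched +
    sigmoid_window(pct, c(5, 60)) * (cfg$share_standing - cfg$share_crouched)
  bump <- exp(-0.5 * ((pct - cfg$grf_peak_pct) / 8)^2)
  fz <- base + bump * (cfg$grf_peak_bw - base[which.max(bump)])
  ## force the configured peak exactly at the configured instant
  fz <- fz / max(fz) * cfg$grf_peak_bw
  fx <- cfg$craniad_pulse_bw * exp(-0.5 * ((pct - cfg$craniad_pulse_pct) / 5)^2)
  f <- cbind(fx, 0, fz) * bw
  if (noise && cfg$force_noise_sd > 0) {
    withr_seed <- cfg$seed + 1L
    f <- f + matrix(rnorm_seeded(3 * n_frames, sd = cfg$force_noise_sd,
                                 seed = withr_seed), n_frames, 3)
  }
  rec <- force_plate_record(f, rate = cfg$rate, plate = "hind")
  attr(rec, "pct_sts") <- pct
  rec
}

rnorm_seeded <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Pelvis trajectory that pins the toe to the ground
#'
#' For each frame, the pelvis translation that keeps the toe (distal end
#' of the foot) at a fixed ground point; pelvis rotation stays zero. This
#' yields a consistent rising motion without a contact model.
#'
#' @param model a [limb_model()].
#' @param angles joint-angle matrix, degrees.
#' @param toe_point toe position in the foot frame, m.
#' @param toe_target fixed world position of the toe.
#' @return Matrix (frames x 6) of pelvis coordinates.
#' @export
solve_pelvis_track <- function(model, angles,
                               toe_point = c(0, 0, -0.16),
                               toe_target = c(0, 0.04, 0)) {
  n <- nrow(angles)
  out <- matrix(0, n, 6,
                dimnames = list(NULL, c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                                        "pelvis_ry", "pelvis_rx", "pelvis_rz")))
  for (i in seq_len(n)) {
    q0 <- angles_to_posture(model, angles[i, ])
    poses <- fk_poses(model, q0)
    toe0 <- point_in_world(poses, "foot", toe_point)
    out[i, 1:3] <- toe_target - toe0
  }
  out
}

#' Synthetic marker trajectories by forward kinematics
#'
#' @param model a [limb_model()].
#' @param q_series coordinate matrix (frames x coordinates).
#' @param cfg a [synth_config()] (noise and seed).
#' @param noise add seeded marker noise.
#' @param gap_markers marker names given leading gaps.
#' @param gap_frac fraction of initial frames blanked on those markers.
#' @return Named list of [marker_trajectory()] matrices.
#' @export
synth_markers <- function(model, q_series, cfg, noise = TRUE,
                          gap_markers = character(), gap_frac = 0.1) {
  bad <- setdiff(gap_markers, names(model$markers))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  n <- nrow(q_series)
  pos <- lapply(seq_len(n), function(i)
    marker_positions(model, q_series[i, ]))
  out <- list()
  k <- 0L
  for (mn in names(model$markers)) {
    k <- k + 1L
    xyz <- t(vapply(pos, function(p) p[mn, ], numeric(3)))
    if (noise && cfg$marker_noise_sd > 0)
      xyz <- xyz + matrix(rnorm_seeded(3 * n, sd = cfg$marker_noise_sd,
                                       seed = cfg$seed + 100L + k), n, 3)
    if (mn %in% gap_markers && gap_frac > 0)
      xyz[seq_len(max(1L, floor(gap_frac * n))), ] <- NA_real_
    out[[mn]] <- marker_trajectory(xyz, name = mn, rate = cfg$rate)
  }
  out
}

#' Generate a complete synthetic sit-to-stand trial
#'
#' Assembles ground-truth joint angles, a toe-pinned pelvis trajectory,
#' forward-kinematic markers with noise, the combined-hindlimb GRF, the
#' single-limb wrench with a foot-midline CoP, and all ground truth
#' needed by recovery tests.
#'
#' @param model a [limb_model()].
#' @param cfg a [synth_config()].
#' @param gap_markers markers given leading gaps (e.g. \code{"MTHM"}
#'   emulating a hidden medial foot marker in the crouch).
#' @return List of class \code{synth_trial}: \code{q} (coordinates,
#'   frames x ncoord), \code{angles_deg}, \code{markers}, \code{wrench}
#'   (single-limb, composite CoP), \code{grf_combined}, \code{cfg},
#'   \code{model}.
#' @export
synth_trial <- function(model, cfg = synth_config(),
                        gap_markers = character()) {
  angles <- synth_joint_angles(cfg)
  if (cfg$angle_jitter_sd > 0) {
    jit <- rnorm_seeded(ncol(angles), sd = cfg$angle_jitter_sd,
                        seed = cfg$seed + 7L)
    angles <- sweep(angles, 2, jit * (angles[1, ] != angles[nrow(angles), ]),
                    `+`)
  }
  pelvis <- solve_pelvis_track(model, angles)
  q <- cbind(pelvis, angles * pi / 180)
  colnames(q) <- c(colnames(pelvis), colnames(angles))
  q <- q[, coord_names(model)]
  markers <- synth_markers(model, q, cfg, gap_markers = gap_markers)
  grf <- synth_grf(cfg, model$subject$mass)
  wrench <- split_bilateral(grf)
  pct <- attr(angles, "pct_sts")
  ## CoP travels craniad from the heel (tarsus) toward the toe as the foot
  ## goes from plantigrade to digitigrade; the paws stay planted, so the
  ## travel is bounded by the foot, capped at the configured excursion.
  noiseless <- synth_markers(model, q, cfg, noise = FALSE)
  heel_x <- (noiseless$AnkleL[, 1] + noiseless$AnkleM[, 1]) / 2
  toe_x <- (noiseless$MTHL[, 1] + noiseless$MTHM[, 1]) / 2
  s <- sigmoid_window(pct, c(0, 35))
  cop_x <- heel_x + (0.05 + 0.9 * s) * (toe_x - heel_x)
  travel <- cop_x - cop_x[1]
  cop_x <- cop_x[1] + pmin(travel, cfg$cop_excursion)
  wrench$cop <- cbind(cop_x, 0.04, 0)
  wrench <- compose_cop(wrench, noiseless[c("AnkleL", "AnkleM", "MTHL", "MTHM")])
  structure(list(q = q, angles_deg = angles, markers = markers,
                 wrench = wrench, grf_combined = grf, cfg = cfg,
                 model = model),
            class = "synth_trial")
}

#' Build a recovery case for the static optimizer
#'
#' Given known activations, emits the exact joint moments those
#' activations produce through the muscle model, so the optimizer can be
#' tested for exact redistribution (identifiability on square
#' well-conditioned systems; objective optimality on redundant ones).
#'
#' @param model a [limb_model()].
#' @param q_series coordinate matrix (frames x coordinates).
#' @param a_star activation matrix (frames x muscles, model order) or a
#'   single vector recycled over frames.
#' @param dof_names DOFs to include (default: enabled joint DOFs).
#' @return List: \code{tau} (frames x DOFs, Nm), \code{a_star}.
#' @export
synth_recovery_case <- function(model, q_series, a_star,
                                dof_names = names(enabled_dofs(model))) {
  q_series <- as.matrix(q_series)
  n <- nrow(q_series)
  if (is.null(dim(a_star)))
    a_star <- matrix(a_star, n, length(a_star), byrow = TRUE)
  if (any(a_star < 0 | a_star > 1)) stop("a_star must lie in [0, 1]")
  mus <- model$muscles
  tau <- matrix(0, n, length(dof_names), dimnames = list(NULL, dof_names))
  for (i in seq_len(n)) {
    q <- q_series[i, ]
    arms <- moment_arm_matrix(model, q, dof_names)
    lens <- mtu_lengths(model, q)
    fcap <- vapply(seq_along(mus), function(k) {
      fs <- fibre_state(lens[k], mus[[k]], units = "m")
      mus[[k]]$fmax * active_force_length(fs$l_norm) * fs$cos_pennation
    }, 0)
    tau[i, ] <- as.numeric(crossprod(arms, a_star[i, ] * fcap))
  }
  list(tau = tau, a_star = a_star)
}
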