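## End-to-end analysis: markers -> joint angles -> inverse dynamics ->
## static optimization -> summaries, in the published processing order.

#' Cluster calibration templates from a model
#'
#' The ideal static calibration: each segment's cluster marker positions
#' expressed in the segment's anatomical frame, as a perfect standing
#' reference trial would provide.
#'
#' @param model a [limb_model()].
#' @param clusters named list of cluster marker names per segment
#'   (default [greyhound_clusters()]).
#' @return A \code{static_calibration}.
#' @export
model_calibration <- function(model, clusters = greyhound_clusters()) {
  out <- lapply(names(clusters), function(seg) {
    template <- t(vapply(clusters[[seg]], function(mn) {
      mk <- model$markers[[mn]]
      if (is.null(mk) || mk$segment != seg)
        stop("cluster marker missing or on wrong segment: ", mn)
      mk$pos
    }, numeric(3)))
    rownames(template) <- clusters[[seg]]
    template
  })
  names(out) <- names(clusters)
  class(out) <- "static_calibration"
  out
}

## Cardan sign maps turning raw Y-X'-Z'' angles into
## extension/abduction/external-rotation-positive joint angles for the
## default model's axis orientations.
joint_sign_maps <- function() {
  list(hip = c(1, 1, -1), knee = c(-1, 1, -1), ankle = c(1, 1, -1))
}

#' Joint angles and pelvis pose from marker trajectories
#'
#' Fills gaps, low-pass filters the markers (zero phase), fits each
#' segment's cluster pose by Procrustes, and decomposes the relative
#' rotations into Cardan Y-X'-Z'' joint angles with
#' extension/abduction/external-rotation positive.
#'
#' @param markers named list of [marker_trajectory()] matrices.
#' @param calibration a \code{static_calibration}.
#' @param cfg a [run_config()].
#' @param filter apply the marker low-pass filter.
#' @return List: \code{angles} (frames x 9, degrees), \code{q} (full
#'   coordinate matrix incl. pelvis, radians/metres), \code{poses}.
#' @export
trial_kinematics <- function(markers, calibration, cfg = run_config(),
                             filter = TRUE) {
  markers <- lapply(markers, fill_leading_gaps)
  if (filter)
    markers <- lapply(markers, lowpass_markers,
                      order = cfg$marker_filter_order,
                      cutoff = cfg$marker_cutoff_hz)
  poses <- lapply(calibration, function(tmpl) segment_pose(markers, tmpl))
  sm <- joint_sign_maps()
  ang <- cbind(
    joint_angles(poses$pelvis, poses$thigh, sm$hip, "hip"),
    joint_angles(poses$thigh, poses$shank, sm$knee, "knee"),
    joint_angles(poses$shank, poses$foot, sm$ankle, "ankle"))
  n <- nrow(ang)
  pel <- t(vapply(seq_len(n), function(i)
    c(poses$pelvis$p[i, ], cardan_yxz(poses$pelvis$R[[i]]) * pi / 180),
    numeric(6)))
  colnames(pel) <- c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                     "pelvis_ry", "pelvis_rx", "pelvis_rz")
  q <- cbind(pel, ang * pi / 180)
  list(angles = ang, q = q, poses = poses)
}

#' Run the full sit-to-stand analysis on a trial
#'
#' Markers are converted to joint angles, prefiltered, passed through
#' inverse dynamics with the single-limb wrench, and the resulting
#' moments are redistributed over the muscles by static optimization.
#'
#' @param trial a \code{synth_trial} (or a list with \code{markers} and
#'   \code{wrench}).
#' @param model a [limb_model()].
#' @param cfg a [run_config()].
#' @param use_markers recover kinematics from the (noisy) markers; when
#'   FALSE the trial's ground-truth coordinates are used directly.
#' @return List of class \code{sts_analysis}: \code{angles}, \code{q},
#'   \code{moments} (\code{joint_moment_series}), \code{moments_norm},
#'   \code{solution} (\code{activation_solution}), \code{reserves}
#'   (summary data.frame), \code{reported_muscles}, \code{rom}.
#' @export
run_sts_analysis <- function(trial, model, cfg = run_config(),
                             use_markers = TRUE) {
  if (use_markers) {
    kin <- trial_kinematics(trial$markers, model_calibration(model), cfg)
    q <- kin$q
    angles <- kin$angles
  } else {
    q <- trial$q
    angles <- trial$angles_deg
  }
  cn <- coord_names(model)
  extra <- c("knee_aa", "knee_rot", "ankle_aa", "ankle_rot")
  missing <- setdiff(union(cn, extra), colnames(q))
  if (length(missing)) {
    q <- cbind(q, matrix(0, nrow(q), length(missing),
                         dimnames = list(NULL, missing)))
  }
  q_id <- prefilter_angles(q, rate = cfg$marker_rate_hz,
                           order = cfg$id_filter_order,
                           cutoff = cfg$id_cutoff_hz)
  id <- inverse_dynamics(model, q_id, trial$wrench, rate = cfg$marker_rate_hz)
  joint_dofs <- names(enabled_dofs(model))
  sol <- solve_trajectory(model, q_id, id$moments[, joint_dofs, drop = FALSE],
                          R0 = cfg$reserve_r0_nm)
  bw <- cfg$body_mass_kg * cfg$g
  structure(list(
    angles = angles, q = q_id, moments = id,
    moments_norm = normalize_moments(id, cfg$body_mass_kg, cfg$leg_length_m,
                                     cfg$g),
    solution = sol,
    reserves = reserve_summary(sol, id$moments[, joint_dofs, drop = FALSE],
                               max_nm = cfg$reserve_max_nm,
                               max_pct = cfg$reserve_max_pct),
    reported_muscles = muscle_report_filter(sol, bw,
                                            cfg$report_activation,
                                            cfg$report_force_bw),
    rom = range_of_motion(angles)),
    class = "sts_analysis")
}

#' @export
print.sts_analysis <- function(x, ...) {
  cat("<sts_analysis>\n")
  cat(sprintf("  frames: %d   reported muscles (>20%% act or >20%% BW): %d\n",
              nrow(x$q), length(x$reported_muscles)))
  rom <- x$rom[grep("_fe$", names(x$rom))]
  cat("  flexion/extension ROM (deg):",
      paste(sprintf("%s %.1f", names(rom), rom), collapse = ", "), "\n")
  fl <- x$reserves[x$reserves$avg_flag | x$reserves$peak_flag, "dof"]
  cat("  reserve flags:", if (length(fl)) paste(fl, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
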