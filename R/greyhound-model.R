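## Default greyhound hindlimb model.
##
## Four segments (pelvis -> thigh -> shank -> foot) in a straight-limb
## reference pose with the limb hanging along -Z; X cranial, Y toward the
## animal's left (this is a left hindlimb), Z up. Segment frames sit at the
## proximal joint. Joint flexion is negative and extension positive for
## every flexion/extension coordinate (axes are oriented accordingly), so
## increasing angles mean extension throughout.
##
## The 29 musculotendon actuators take their architecture (PCSA, pennation,
## optimal fibre length, Fmax) from the packaged dissection table; their
## via-point paths are synthetic geometry chosen to reproduce the
## functional anatomy (which joints each muscle crosses, extensor vs.
## flexor arms of plausible magnitude). Tendon slack lengths are calibrated
## against this geometry with the package's own procedures: TSL is set so
## the fibre sits at optimal length in the standing posture, then optimal
## fibre length is grown (conserving musculotendon rest length) wherever a
## crouch-to-stand sweep would leave the admissible 0.5-1.5 operating band
## -- the same two-stage calibration used when the architecture table was
## assembled.

rod_inertia <- function(mass, length, radius = length / 10) {
  ix <- mass * (3 * radius^2 + length^2) / 12
  diag(c(ix, ix, mass * radius^2 / 2))
}

#' Default joint angles bracketing the sit-to-stand motion
#'
#' Crouched (start) and standing (end) joint angles, degrees, chosen so the
#' flexion/extension excursions equal the mean measured ranges of motion
#' (hip 53.4, knee 78.5, ankle 88.7 degrees).
#'
#' @return List with numeric vectors \code{crouched} and \code{standing}.
#' @export
sts_reference_angles <- function() {
  standing <- c(hip_fe = -20, hip_aa = 0, hip_rot = 0,
                knee_fe = -30, ankle_fe = -40)
  crouched <- standing + c(hip_fe = -53.4, hip_aa = 0, hip_rot = 0,
                           knee_fe = -78.5, ankle_fe = -88.7)
  list(crouched = crouched, standing = standing)
}

#' Joint-angle vector (degrees) to a model posture
#'
#' @param model a [limb_model()].
#' @param angles_deg named vector of joint coordinates in degrees; missing
#'   coordinates are zero.
#' @param pelvis optional length-6 pelvis coordinate vector
#'   (tx, ty, tz, ry, rx, rz; m and rad).
#' @return A [posture()].
#' @export
angles_to_posture <- function(model, angles_deg, pelvis = NULL) {
  q <- stats::setNames(angles_deg * pi / 180, names(angles_deg))
  if (!is.null(pelvis)) {
    names(pelvis) <- c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                       "pelvis_ry", "pelvis_rx", "pelvis_rz")
    q <- c(pelvis, q)
  }
  posture(model, q)
}

greyhound_segments <- function() {
  list(
    body_segment("pelvis", mass = 6.0, com = c(0.02, 0, 0),
                 inertia = rod_inertia(6.0, 0.15), length = 0.15),
    body_segment("thigh", mass = 1.45, com = c(0, 0, -0.115),
                 inertia = rod_inertia(1.45, 0.23), length = 0.23),
    body_segment("shank", mass = 0.55, com = c(0, 0, -0.125),
                 inertia = rod_inertia(0.55, 0.25), length = 0.25),
    body_segment("foot", mass = 0.27, com = c(0, 0, -0.08),
                 inertia = rod_inertia(0.27, 0.16), length = 0.16))
}

greyhound_joints <- function() {
  ax_fe_pos <- c(0, 1, 0); ax_fe_neg <- c(0, -1, 0)
  ax_aa <- c(1, 0, 0); ax_rot <- c(0, 0, -1)
  list(
    hip = list(parent = "pelvis", child = "thigh",
               location = c(0, 0.04, -0.05),
               dofs = list(
                 joint_dof("hip", ax_fe_pos, "flexion_extension",
                           range = c(-110, 30)),
                 joint_dof("hip", ax_aa, "ad_abduction", range = c(-45, 45)),
                 joint_dof("hip", ax_rot, "int_ext_rotation",
                           range = c(-45, 45)))),
    knee = list(parent = "thigh", child = "shank",
                location = c(0, 0, -0.23),
                dofs = list(
                  joint_dof("knee", ax_fe_neg, "flexion_extension",
                            range = c(-135, 15)),
                  joint_dof("knee", ax_aa, "ad_abduction", enabled = FALSE,
                            range = c(-45, 45)),
                  joint_dof("knee", ax_rot, "int_ext_rotation",
                            enabled = FALSE, range = c(-45, 45)))),
    ankle = list(parent = "shank", child = "foot",
                 location = c(0, 0, -0.25),
                 dofs = list(
                   joint_dof("ankle", ax_fe_pos, "flexion_extension",
                             range = c(-140, 20)),
                   joint_dof("ankle", ax_aa, "ad_abduction", enabled = FALSE,
                             range = c(-45, 45)),
                   joint_dof("ankle", ax_rot, "int_ext_rotation",
                             enabled = FALSE, range = c(-45, 45)))))
}

greyhound_markers <- function() {
  mk <- function(segment, pos) list(segment = segment, pos = pos)
  list(
    ## anatomical landmarks
    Hip    = mk("thigh", c(0, 0.055, 0)),
    KneeL  = mk("thigh", c(0, 0.03, -0.23)),
    KneeM  = mk("thigh", c(0, -0.03, -0.23)),
    AnkleL = mk("shank", c(0, 0.025, -0.25)),
    AnkleM = mk("shank", c(0, -0.025, -0.25)),
    MTHL   = mk("foot", c(0, 0.02, -0.16)),
    MTHM   = mk("foot", c(0, -0.02, -0.16)),
    Sacrum = mk("pelvis", c(0, 0, 0.01)),
    ## rigid technical clusters (three markers per segment)
    pelvis_c1 = mk("pelvis", c(0.05, 0.05, 0.03)),
    pelvis_c2 = mk("pelvis", c(-0.05, 0.03, 0.05)),
    pelvis_c3 = mk("pelvis", c(0.00, -0.03, 0.07)),
    thigh_c1 = mk("thigh", c(0.03, 0.05, -0.07)),
    thigh_c2 = mk("thigh", c(-0.03, 0.06, -0.12)),
    thigh_c3 = mk("thigh", c(0.00, 0.07, -0.17)),
    shank_c1 = mk("shank", c(0.03, 0.035, -0.07)),
    shank_c2 = mk("shank", c(-0.025, 0.045, -0.13)),
    shank_c3 = mk("shank", c(0.00, 0.055, -0.19)),
    foot_c1 = mk("foot", c(0.025, 0.025, -0.04)),
    foot_c2 = mk("foot", c(-0.02, 0.03, -0.08)),
    foot_c3 = mk("foot", c(0.00, 0.04, -0.12)))
}

#' Technical marker clusters of the default model
#'
#' @return Named list: for each segment, the three cluster marker names.
#' @export
greyhound_clusters <- function() {
  list(pelvis = paste0("pelvis_c", 1:3), thigh = paste0("thigh_c", 1:3),
       shank = paste0("shank_c", 1:3), foot = paste0("foot_c", 1:3))
}

## via-point geometry: segments + points (m) per muscle, and the joint DOFs
## each muscle can span (including nominally locked non-sagittal DOFs).
greyhound_paths <- function() {
  hip3 <- c("hip_fe", "hip_aa", "hip_rot")
  knee3 <- c("knee_fe", "knee_aa", "knee_rot")
  ankle3 <- c("ankle_fe", "ankle_aa", "ankle_rot")
  p <- function(segments, points, dofs)
    list(path = muscle_path(segments, matrix(points, ncol = 3, byrow = TRUE)),
         dofs = dofs)
  list(
    GMed = p(c("pelvis", "thigh"),
             c(-0.065, 0.05, 0.00, -0.03, 0.045, -0.07), hip3),
    GSup = p(c("pelvis", "thigh"),
             c(-0.075, 0.05, -0.01, -0.03, 0.04, -0.09), hip3),
    GInt = p(c("pelvis", "thigh"),
             c(-0.055, 0.05, -0.01, -0.025, 0.045, -0.05), hip3),
    AddMag = p(c("pelvis", "thigh"),
               c(-0.045, 0.01, -0.06, -0.015, -0.01, -0.15), hip3),
    AddBrev = p(c("pelvis", "thigh"),
                c(-0.035, 0.01, -0.06, -0.012, -0.012, -0.08), hip3),
    Pect = p(c("pelvis", "thigh"),
             c(0.005, 0.01, -0.065, -0.008, -0.012, -0.09), hip3),
    IP = p(c("pelvis", "thigh"),
           c(0.08, 0.02, -0.02, 0.008, -0.01, -0.03), hip3),
    ObtExt = p(c("pelvis", "thigh"),
               c(-0.035, 0.01, -0.07, -0.012, 0.012, -0.05), hip3),
    ObtInt = p(c("pelvis", "thigh"),
               c(-0.04, 0.02, -0.065, -0.01, 0.014, -0.03), hip3),
    QF = p(c("pelvis", "thigh"),
           c(-0.04, 0.015, -0.07, -0.015, 0.01, -0.08), hip3),
    TFL1 = p(c("pelvis", "thigh"),
             c(0.045, 0.05, -0.01, 0.015, 0.04, -0.10), hip3),
    BF2 = p(c("pelvis", "thigh", "shank"),
            c(-0.06, 0.03, -0.03, -0.025, 0.02, -0.21, -0.018, 0.01, -0.03),
            c(hip3, knee3)),
    BF1 = p(c("pelvis", "thigh", "shank"),
            c(-0.065, 0.03, -0.035, -0.025, 0.02, -0.215, -0.018, 0.01, -0.05),
            c(hip3, knee3)),
    SM = p(c("pelvis", "thigh", "shank"),
           c(-0.06, 0.02, -0.045, -0.022, -0.005, -0.21, -0.012, -0.008, -0.025),
           c(hip3, knee3)),
    ST = p(c("pelvis", "thigh", "shank"),
           c(-0.065, 0.025, -0.04, -0.024, 0.00, -0.215, -0.014, -0.006, -0.045),
           c(hip3, knee3)),
    Gra = p(c("pelvis", "thigh", "shank"),
            c(-0.025, 0.005, -0.065, -0.018, -0.012, -0.21, -0.01, -0.012, -0.03),
            c(hip3, knee3)),
    RF = p(c("pelvis", "thigh", "thigh", "thigh", "shank"),
           c(0.05, 0.03, -0.03, 0.025, 0.00, -0.20, 0.028, 0.00, -0.225,
             0.022, 0.00, -0.245, 0.018, 0.00, -0.025),
           c(hip3, knee3)),
    Sart = p(c("pelvis", "thigh", "shank"),
             c(0.04, 0.03, -0.02, 0.01, -0.012, -0.21, 0.008, -0.01, -0.03),
             c(hip3, knee3)),
    Sart2 = p(c("pelvis", "thigh", "shank"),
              c(0.04, 0.035, -0.015, 0.013, -0.01, -0.21, 0.012, -0.008, -0.025),
              c(hip3, knee3)),
    VL = p(c("thigh", "thigh", "thigh", "shank"),
           c(0.015, 0.02, -0.05, 0.028, 0.01, -0.225, 0.022, 0.008, -0.245,
             0.018, 0.00, -0.025), knee3),
    VM = p(c("thigh", "thigh", "thigh", "shank"),
           c(0.015, -0.02, -0.05, 0.028, -0.01, -0.225, 0.022, -0.008, -0.245,
             0.018, 0.00, -0.025), knee3),
    FDS = p(c("thigh", "shank", "foot", "foot", "foot"),
            c(-0.02, 0.005, -0.20, -0.025, 0.00, -0.12,
              -0.015, 0.00, 0.035, -0.018, 0.00, 0.005, 0.00, 0.00, -0.15),
            c(knee3, ankle3)),
    GasL = p(c("thigh", "shank", "foot"),
             c(-0.02, 0.015, -0.21, -0.02, 0.01, -0.05, -0.015, 0.005, 0.035),
             c(knee3, ankle3)),
    GasM = p(c("thigh", "shank", "foot"),
             c(-0.02, -0.01, -0.21, -0.02, -0.008, -0.05, -0.015, -0.005, 0.035),
             c(knee3, ankle3)),
    FDP = p(c("shank", "shank", "foot", "foot", "foot"),
            c(-0.018, -0.005, -0.06, -0.016, -0.005, -0.23,
              -0.012, -0.005, 0.03, -0.008, -0.003, -0.03,
              -0.005, 0.00, -0.155), ankle3),
    TibCran = p(c("shank", "shank", "foot", "foot"),
                c(0.02, 0.005, -0.05, 0.018, 0.005, -0.23,
                  0.015, 0.005, -0.02, 0.012, 0.005, -0.06), ankle3),
    ExtDigLong = p(c("thigh", "shank", "shank", "foot", "foot"),
                   c(0.01, 0.01, -0.225, 0.012, 0.005, -0.10,
                     0.012, 0.004, -0.23, 0.01, 0.00, -0.02,
                     0.008, 0.00, -0.14), c(knee3, ankle3)),
    ExtDigLat = p(c("shank", "shank", "foot", "foot"),
                  c(0.01, 0.015, -0.10, 0.012, 0.01, -0.23,
                    0.01, 0.008, -0.02, 0.008, 0.008, -0.13), ankle3),
    PerLong = p(c("shank", "shank", "foot", "foot"),
                c(0.01, 0.02, -0.08, -0.008, 0.018, -0.24,
                  -0.01, 0.012, 0.01, -0.006, 0.008, -0.04), ankle3))
}

#' Build the default greyhound hindlimb model
#'
#' @param muscle_table architecture table (see [read_muscle_table()]).
#' @param subject list with \code{mass} (kg) and \code{leg_length} (m);
#'   defaults to the study population mean (27 kg, hip height 0.616 m).
#' @param calibrate_tsl calibrate tendon slack lengths and fibre operating
#'   ranges against the model geometry (recommended; the tabulated TSLs
#'   belong to the dissection geometry, not to these via-point paths).
#' @param n_sweep number of postures in the crouch-to-stand calibration
#'   sweep.
#' @return A [limb_model()] with 29 calibrated musculotendon actuators.
#' @export
greyhound_model <- function(muscle_table = read_muscle_table(),
                            subject = list(mass = 27, leg_length = 0.616),
                            calibrate_tsl = TRUE, n_sweep = 21) {
  paths <- greyhound_paths()
  muscles <- lapply(names(paths), function(ab) {
    row <- muscle_table[muscle_table$abbreviation == ab, ]
    if (nrow(row) != 1) stop("architecture missing for muscle ", ab)
    muscle_params(ab, pcsa = row$pcsa_cm2, pennation_opt = row$pennation_deg,
                  l_opt = row$fibre_opt_model_cm, tsl = row$tsl_model_cm,
                  fmax = row$fmax_N, path = paths[[ab]]$path,
                  spanned_dofs = paths[[ab]]$dofs)
  })
  model <- limb_model(greyhound_segments(), greyhound_joints(),
                      muscles = muscles, markers = greyhound_markers(),
                      subject = subject)
  if (calibrate_tsl) model <- calibrate_model_tsl(model, n_sweep = n_sweep)
  model
}

#' Calibrate tendon slack lengths against the model geometry
#'
#' Two-stage calibration over a crouch-to-stand posture sweep: (1) set each
#' muscle's TSL so the fibre is at optimal length in the standing posture
#' (then nudge into the 0.8-1.2 standing window with
#' [tune_tsl_standing()]); (2) where the sweep leaves the 0.5-1.5 operating
#' band, grow optimal fibre length at constant musculotendon rest length
#' with [retune_fibre_range()].
#'
#' @param model a [limb_model()].
#' @param n_sweep number of sweep postures.
#' @return The calibrated model; attribute \code{"tsl_calibration"} holds a
#'   per-muscle data.frame of the adjustments.
#' @export
calibrate_model_tsl <- function(model, n_sweep = 21) {
  ref <- sts_reference_angles()
  sweep <- lapply(seq(0, 1, length.out = n_sweep), function(s)
    angles_to_posture(model, ref$crouched + s * (ref$standing - ref$crouched)))
  standing <- sweep[[n_sweep]]
  log <- list()
  for (mn in names(model$muscles)) {
    m <- model$muscles[[mn]]
    len_stand <- 100 * mtu_length(model, standing, m)
    ## stage 1: fibre at optimal length when standing
    m$tsl <- max(len_stand - m$l_opt * cos(m$pennation_opt * pi / 180), 0.01)
    m <- tune_tsl_standing(m, len_stand)
    ## stage 2: keep the whole sweep inside the 0.5-1.5 band
    lens <- vapply(sweep, function(q) 100 * mtu_length(model, q, m), 0)
    m2 <- retune_fibre_range(m, lens)
    log[[mn]] <- data.frame(
      muscle = mn, tsl_cm = m2$tsl, l_opt_cm = m2$l_opt,
      fibre_grown_cm = m2$l_opt - m$l_opt,
      l_norm_stand = fibre_state(len_stand, m2)$l_norm,
      l_norm_min = min(vapply(lens, function(L) fibre_state(L, m2)$l_norm, 0)),
      l_norm_max = max(vapply(lens, function(L) fibre_state(L, m2)$l_norm, 0)))
    model$muscles[[mn]] <- m2
  }
  attr(model, "tsl_calibration") <- do.call(rbind, log)
  model
}
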