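## Shared fixtures: tiny analytic models plus one cached full greyhound
## model (building it calibrates 29 tendon slack lengths, so reuse it).

.fixture_env <- new.env(parent = emptyenv())

gh_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- greyhound_model()
  .fixture_env$model
}

gh_trial <- function(n_frames = 80, seed = 1, noiseless = FALSE) {
  key <- paste0("trial_", n_frames, "_", seed, "_", noiseless)
  if (is.null(.fixture_env[[key]])) {
    cfg <- if (noiseless)
      synth_config(seed = seed, marker_noise_sd = 0, force_noise_sd = 0)
    else synth_config(seed = seed)
    model <- gh_model()
    tr <- synth_trial(model, cfg)
    if (n_frames < nrow(tr$q)) {
      keep <- round(seq(1, nrow(tr$q), length.out = n_frames))
      tr$q <- tr$q[keep, ]
      tr$angles_deg <- tr$angles_deg[keep, ]
      tr$markers <- lapply(tr$markers, function(m) {
        out <- m[keep, , drop = FALSE]
        attr(out, "rate") <- attr(m, "rate"); attr(out, "name") <- attr(m, "name")
        out
      })
      tr$wrench$grf <- tr$wrench$grf[keep, ]
      tr$wrench$cop <- tr$wrench$cop[keep, ]
    }
    .fixture_env[[key]] <- tr
  }
  .fixture_env[[key]]
}

## one-hinge model carrying the analytic pulley muscle: via points at
## (-1, 0, 0.1) on the fixed segment and (+1, 0, 0.1) on the rotating one,
## hinge through the origin with axis perpendicular to their plane
pulley_model <- function(offset = 0.1) {
  segs <- list(
    body_segment("pelvis", 1, c(0, 0, 0), diag(3) * 1e-4, 1),
    body_segment("thigh", 1, c(0, 0, -0.5), diag(3) * 1e-4, 1))
  joints <- list(hip = list(
    parent = "pelvis", child = "thigh", location = c(0, 0, 0),
    dofs = list(joint_dof("hip", c(0, 1, 0), "flexion_extension"))))
  mus <- muscle_params("pulley", pcsa = 1, pennation_opt = 0,
                       l_opt = 10, tsl = 190,
                       path = muscle_path(c("pelvis", "thigh"),
                                          rbind(c(-1, 0, offset),
                                                c(1, 0, offset))),
                       spanned_dofs = "hip_fe")
  limb_model(segs, joints, muscles = list(mus))
}

## analytic length of the pulley muscle as a function of the hinge angle
pulley_length <- function(theta, offset = 0.1) {
  p <- c(-1, offset)
  cth <- cos(theta); sth <- sin(theta)
  q <- c(cth + offset * sth, -sth + offset * cth)
  sqrt(sum((q - p)^2))
}

## single hinged rod with a point mass at its far end (statics and
## pendulum-energy oracles); pelvis is a near-massless root
pendulum_model <- function(mass = 1, length = 1) {
  segs <- list(
    body_segment("pelvis", 1e-9, c(0, 0, 0), diag(3) * 0, 0.01),
    body_segment("thigh", mass, c(0, 0, -length), diag(3) * 0, length))
  joints <- list(hip = list(
    parent = "pelvis", child = "thigh", location = c(0, 0, 0),
    dofs = list(joint_dof("hip", c(0, 1, 0), "flexion_extension"))))
  limb_model(segs, joints)
}

## coordinate matrix for a model held at fixed joint angles (degrees)
const_q <- function(model, angles_deg, n = 1) {
  q <- unclass(angles_to_posture(model, angles_deg))
  out <- matrix(rep(q, each = n), n, length(q))
  colnames(out) <- names(q)
  out
}
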