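## Musculoskeletal model core: data structures for a four-segment hindlimb
## (pelvis -> thigh -> shank -> foot), a rigid-tendon Hill muscle model,
## tendon-excursion moment arms, tendon-slack-length calibration and
## subject scaling.
##
## Unit conventions: muscle architecture (optimal fibre length, tendon slack
## length, PCSA) is carried in cm / cm^2 as customarily tabulated from
## dissection; all geometry (via points, markers, segment dimensions) and
## dynamics are SI (m, kg, s, N, Nm). Conversions happen only at the
## documented boundaries (see `fibre_state()`).

SIGMA_MAX_DEFAULT <- 300   # maximal isometric muscle stress, kN m^-2

#' Maximal isometric force from PCSA
#'
#' Applies the constant maximal isometric muscle stress (default
#' 300 kN m^-2) to a physiological cross-sectional area and rounds to the
#' nearest newton, the precision at which architecture tables print Fmax.
#' No pennation factor is applied.
#'
#' @param pcsa physiological cross-sectional area, cm^2.
#' @param sigma_max maximal isometric muscle stress, kN m^-2.
#' @return Maximal isometric force in N, rounded to the nearest newton.
#' @examples
#' fmax_from_pcsa(14.11)  # 423 N (adductor magnus)
#' fmax_from_pcsa(7.62)   # 229 N (semimembranosus)
#' @export
fmax_from_pcsa <- function(pcsa, sigma_max = SIGMA_MAX_DEFAULT) {
  if (any(pcsa < 0)) stop("pcsa must be non-negative")
  if (sigma_max <= 0) stop("sigma_max must be positive")
  round(pcsa * 1e-4 * sigma_max * 1e3)
}

#' Construct a muscle path from via points
#'
#' A musculotendon path is a polyline of via points, each fixed in a body
#' segment's frame. Wrapping surfaces are deliberately not modelled: 2-4
#' well-placed via points preserve the tendon-excursion moment-arm
#' mechanics that inverse-dynamics-based analyses need.
#'
#' @param segments character vector: the segment carrying each via point,
#'   ordered proximal to distal.
#' @param points numeric matrix (n x 3) of via-point positions in the
#'   corresponding segment frames, metres.
#' @return An object of class \code{muscle_path}.
#' @export
muscle_path <- function(segments, points) {
  points <- as.matrix(points)
  if (length(segments) < 2 || nrow(points) != length(segments))
    stop("a muscle path needs >= 2 via points, one segment per point")
  if (ncol(points) != 3) stop("via points must be 3-vectors")
  structure(list(segments = as.character(segments), points = points),
            class = "muscle_path")
}

#' Construct musculotendon unit parameters
#'
#' Architecture follows dissection convention: PCSA in cm^2, optimal fibre
#' length and tendon slack length in cm, pennation at optimal fibre length
#' in degrees. When \code{fmax} is omitted it is computed as
#' PCSA x sigma_max (see [fmax_from_pcsa()]); printed table values may be
#' supplied verbatim instead.
#'
#' @param name muscle identifier (abbreviation).
#' @param pcsa PCSA, cm^2 (> 0).
#' @param pennation_opt pennation angle at optimal fibre length, degrees.
#' @param l_opt optimal fibre length, cm (> 0).
#' @param tsl tendon slack length, cm (>= 0).
#' @param fmax maximal isometric force, N; computed from PCSA if NULL.
#' @param path a [muscle_path()], or NULL for architecture-only use.
#' @param spanned_dofs character vector of joint-DOF identifiers the muscle
#'   spans (e.g. \code{"knee_fe"}).
#' @param sigma_max stress constant used when computing fmax, kN m^-2.
#' @return An object of class \code{muscle_params}.
#' @export
muscle_params <- function(name, pcsa, pennation_opt, l_opt, tsl,
                          fmax = NULL, path = NULL,
                          spanned_dofs = character(),
                          sigma_max = SIGMA_MAX_DEFAULT) {
  if (pcsa <= 0) stop("pcsa must be positive")
  if (l_opt <= 0) stop("l_opt must be positive")
  if (tsl < 0) stop("tsl must be non-negative")
  if (pennation_opt < 0 || pennation_opt >= 90)
    stop("pennation_opt must lie in [0, 90) degrees")
  if (is.null(fmax)) fmax <- fmax_from_pcsa(pcsa, sigma_max)
  if (!is.null(path) && !inherits(path, "muscle_path"))
    stop("path must be a muscle_path")
  structure(list(name = name, pcsa = pcsa, pennation_opt = pennation_opt,
                 fmax = fmax, l_opt = l_opt, tsl = tsl, path = path,
                 spanned_dofs = spanned_dofs),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle %s> PCSA %.2f cm^2, pennation %g deg, Fmax %g N, l_opt %.2f cm, TSL %.2f cm\n",
    x$name, x$pcsa, x$pennation_opt, x$fmax, x$l_opt, x$tsl))
  invisible(x)
}

#' Musculotendon rest length (cm)
#' @param muscle a [muscle_params()] object.
#' @export
mtu_rest_length <- function(muscle) muscle$l_opt + muscle$tsl

#' Construct a joint degree of freedom
#'
#' @param joint one of \code{"hip"}, \code{"knee"}, \code{"ankle"}.
#' @param axis unit 3-vector in the parent segment frame.
#' @param kind \code{"flexion_extension"}, \code{"ad_abduction"} or
#'   \code{"int_ext_rotation"}.
#' @param enabled logical; disabled DOFs are locked at zero.
#' @param range allowed coordinate range, degrees.
#' @return An object of class \code{joint_dof}.
#' @export
joint_dof <- function(joint, axis, kind, enabled = TRUE,
                      range = c(-180, 180)) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("dof axis must be a unit vector")
  kind <- match.arg(kind,
                    c("flexion_extension", "ad_abduction", "int_ext_rotation"))
  structure(list(joint = joint, axis = as.numeric(axis), kind = kind,
                 enabled = isTRUE(enabled), range = range,
                 name = paste0(joint, "_", dof_suffix(kind))),
            class = "joint_dof")
}

dof_suffix <- function(kind) {
  c(flexion_extension = "fe", ad_abduction = "aa", int_ext_rotation = "rot")[kind]
}

#' Construct a body segment
#'
#' @param name segment name (pelvis, thigh, shank or foot).
#' @param mass segment mass, kg (> 0).
#' @param com centre of mass in the segment frame, m.
#' @param inertia 3x3 symmetric inertia tensor about the com, kg m^2.
#' @param length characteristic segment length, m.
#' @param density_assumed metadata: tissue density assumed when the inertial
#'   properties were derived from imaging, kg m^-3.
#' @return An object of class \code{body_segment}.
#' @export
body_segment <- function(name, mass, com, inertia, length,
                         density_assumed = 1060) {
  inertia <- as.matrix(inertia)
  if (mass <= 0) stop("segment mass must be positive")
  if (length <= 0) stop("segment length must be positive")
  if (max(abs(inertia - t(inertia))) > 1e-12) stop("inertia must be symmetric")
  if (min(eigen(inertia, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("inertia must be positive semidefinite")
  structure(list(name = name, mass = mass, com = as.numeric(com),
                 inertia = inertia, length = length,
                 density_assumed = density_assumed),
            class = "body_segment")
}

#' Assemble a hindlimb model
#'
#' The chain is pelvis -> thigh -> shank -> foot, articulated by hip, knee
#' and ankle joints with up to three rotational DOFs each; the pelvis root
#' carries six free coordinates (translation then Y-X-Z rotation). The
#' ground frame convention is X cranial, Y toward the animal's left, Z
#' vertical, with all joint angles zero in the straight-limb reference
#' pose.
#'
#' @param segments named list of [body_segment()] in chain order
#'   pelvis, thigh, shank, foot.
#' @param joints named list (hip, knee, ankle), each with fields
#'   \code{parent}, \code{child}, \code{location} (joint centre in the
#'   parent frame, m) and \code{dofs} (list of [joint_dof()], applied in
#'   order with moving axes).
#' @param muscles list of [muscle_params()] with paths attached.
#' @param markers named list: each marker is \code{list(segment =, pos =)}
#'   with \code{pos} in the segment frame, m.
#' @param gravity gravity vector, m s^-2.
#' @param sigma_max muscle stress constant, kN m^-2.
#' @param subject list with \code{mass} (kg) and \code{leg_length} (m).
#' @return An object of class \code{limb_model}.
#' @export
limb_model <- function(segments, joints, muscles = list(),
                       markers = list(), gravity = c(0, 0, -9.81),
                       sigma_max = SIGMA_MAX_DEFAULT,
                       subject = list(mass = 27, leg_length = 0.616)) {
  seg_names <- vapply(segments, `[[`, "", "name")
  names(segments) <- seg_names
  for (m in muscles) {
    if (is.null(m$path)) stop("model muscles need via-point paths")
    bad <- setdiff(m$path$segments, seg_names)
    if (length(bad))
      stop(sprintf("muscle %s has via points on unknown segment(s): %s",
                   m$name, paste(bad, collapse = ", ")))
  }
  for (mk in markers) {
    if (!mk$segment %in% seg_names)
      stop(sprintf("marker on unknown segment %s", mk$segment))
  }
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  model <- structure(
    list(segments = segments, joints = joints, muscles = muscles,
         markers = markers, gravity = as.numeric(gravity),
         sigma_max = sigma_max, subject = subject),
    class = "limb_model")
  model
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("<limb_model> %d segments, %d muscles, %d enabled joint DOFs\n",
              length(x$segments), length(x$muscles),
              length(enabled_dofs(x))))
  invisible(x)
}

#' Enabled joint DOFs of a model
#'
#' @param model a [limb_model()].
#' @return Named list of enabled [joint_dof()]s in chain order.
#' @export
enabled_dofs <- function(model) {
  out <- list()
  for (j in model$joints) {
    for (d in j$dofs) if (d$enabled) out[[d$name]] <- d
  }
  out
}

#' Coordinate names of a model
#'
#' Six pelvis coordinates (tx, ty, tz translation in m; ry, rx, rz rotation
#' in rad) followed by one coordinate per enabled joint DOF (rad).
#' @param model a [limb_model()].
#' @export
coord_names <- function(model) {
  c("pelvis_tx", "pelvis_ty", "pelvis_tz",
    "pelvis_ry", "pelvis_rx", "pelvis_rz",
    names(enabled_dofs(model)))
}

#' Construct a posture (generalized coordinate vector)
#'
#' @param model a [limb_model()].
#' @param q numeric vector ordered per [coord_names()]; pelvis translation
#'   in m, all rotations in rad. May be named, in which case missing
#'   coordinates default to zero.
#' @param check_ranges check joint coordinates against declared DOF ranges
#'   (with 5 degrees of slack).
#' @return Named numeric vector of class \code{posture}.
#' @export
posture <- function(model, q = NULL, check_ranges = TRUE) {
  cn <- coord_names(model)
  full <- stats::setNames(numeric(length(cn)), cn)
  if (!is.null(q)) {
    if (is.null(names(q))) {
      if (length(q) != length(cn))
        stop(sprintf("posture needs %d coordinates (%d given)",
                     length(cn), length(q)))
      full[] <- q
    } else {
      bad <- setdiff(names(q), cn)
      if (length(bad)) stop("unknown coordinate(s): ", paste(bad, collapse = ", "))
      full[names(q)] <- q
    }
  }
  if (check_ranges) {
    dofs <- enabled_dofs(model)
    for (nm in names(dofs)) {
      deg <- full[nm] * 180 / pi
      r <- dofs[[nm]]$range
      if (deg < r[1] - 5 || deg > r[2] + 5)
        stop(sprintf("coordinate %s = %.1f deg outside declared range [%g, %g] +/- 5",
                     nm, deg, r[1], r[2]))
    }
  }
  class(full) <- "posture"
  full
}

## ---- forward kinematics ----------------------------------------------------

#' Segment poses at a posture (forward kinematics)
#'
#' @param model a [limb_model()].
#' @param q a [posture()] (or plain named vector over [coord_names()]).
#' @return Named list per segment: \code{R} (3x3 world rotation) and
#'   \code{p} (world position of the segment-frame origin, m).
#' @export
fk_poses <- function(model, q) {
  q <- unclass(q)
  R_pel <- rot_y(q[["pelvis_ry"]]) %*% rot_x(q[["pelvis_rx"]]) %*%
    rot_z(q[["pelvis_rz"]])
  poses <- list(pelvis = list(
    R = R_pel, p = c(q[["pelvis_tx"]], q[["pelvis_ty"]], q[["pelvis_tz"]])))
  for (j in model$joints) {
    par <- poses[[j$parent]]
    if (is.null(par)) stop("joint parent segment missing: ", j$parent)
    Rj <- diag(3)
    for (d in j$dofs) {
      if (!d$enabled) next
      Rj <- Rj %*% rot_axis(d$axis, q[[d$name]])
    }
    poses[[j$child]] <- list(R = par$R %*% Rj,
                             p = par$p + par$R %*% j$location)
  }
  poses
}

#' World position of a point fixed in a segment
#' @keywords internal
point_in_world <- function(poses, segment, pos_local) {
  pose <- poses[[segment]]
  if (is.null(pose)) stop("unknown segment: ", segment)
  as.numeric(pose$p + pose$R %*% pos_local)
}

#' World positions of all model markers at a posture
#'
#' @param model a [limb_model()].
#' @param q a [posture()].
#' @return Matrix (n_markers x 3) with marker names as rownames.
#' @export
marker_positions <- function(model, q) {
  poses <- fk_poses(model, q)
  out <- t(vapply(model$markers,
                  function(mk) point_in_world(poses, mk$segment, mk$pos),
                  numeric(3)))
  rownames(out) <- names(model$markers)
  out
}

## ---- musculotendon geometry ------------------------------------------------

#' Musculotendon length at a posture
#'
#' Polyline length of the muscle's via points expressed in the ground
#' frame: the sum of Euclidean distances between consecutive posed points.
#'
#' @param model a [limb_model()].
#' @param q a [posture()].
#' @param muscle a [muscle_params()] with a path, or a muscle name in the
#'   model.
#' @return Length in metres.
#' @export
mtu_length <- function(model, q, muscle) {
  muscle <- resolve_muscle(model, muscle)
  poses <- fk_poses(model, q)
  pts <- vapply(seq_along(muscle$path$segments), function(i)
    point_in_world(poses, muscle$path$segments[i], muscle$path$points[i, ]),
    numeric(3))
  d <- diff(t(pts))
  sum(sqrt(rowSums(d^2)))
}

resolve_muscle <- function(model, muscle) {
  if (is.character(muscle)) {
    if (!muscle %in% names(model$muscles)) stop("unknown muscle: ", muscle)
    muscle <- model$muscles[[muscle]]
  }
  if (is.null(muscle$path)) stop("muscle has no via-point path")
  muscle
}

#' Moment arm by tendon excursion
#'
#' The moment arm of a muscle about a joint coordinate is the negative
#' partial derivative of musculotendon length with respect to that
#' coordinate, evaluated by central finite difference. With coordinates
#' oriented so that extension (abduction, external rotation) is positive, a
#' positive arm means the muscle's tension produces a positive moment.
#'
#' @param model a [limb_model()].
#' @param q a [posture()].
#' @param muscle a [muscle_params()] or muscle name.
#' @param dof a [joint_dof()] or enabled coordinate name.
#' @param step finite-difference step, rad.
#' @return Moment arm in metres.
#' @export
moment_arm <- function(model, q, muscle, dof, step = 1e-4) {
  muscle <- resolve_muscle(model, muscle)
  dof_name <- if (is.character(dof)) dof else dof$name
  dofs <- enabled_dofs(model)
  if (!dof_name %in% names(dofs))
    stop("dof not enabled in model: ", dof_name)
  if (step <= .Machine$double.eps) stop("finite-difference step underflow")
  qp <- qm <- unclass(q)
  qp[dof_name] <- qp[dof_name] + step
  qm[dof_name] <- qm[dof_name] - step
  -(mtu_length(model, qp, muscle) - mtu_length(model, qm, muscle)) / (2 * step)
}

#' Musculotendon lengths of all model muscles at a posture
#'
#' One forward-kinematics pass shared by every muscle.
#'
#' @param model a [limb_model()].
#' @param q a [posture()].
#' @return Named vector of lengths, m.
#' @export
mtu_lengths <- function(model, q) {
  poses <- fk_poses(model, q)
  vapply(model$muscles, function(m) {
    pts <- vapply(seq_along(m$path$segments), function(i)
      point_in_world(poses, m$path$segments[i], m$path$points[i, ]),
      numeric(3))
    sum(sqrt(rowSums(diff(t(pts))^2)))
  }, 0)
}

#' Moment-arm matrix at a posture
#'
#' Central-difference tendon-excursion arms for every muscle about every
#' requested coordinate; a muscle's arm is zero about coordinates it does
#' not span.
#'
#' @param model a [limb_model()].
#' @param q a [posture()].
#' @param dof_names coordinates to differentiate against (default: all
#'   enabled joint DOFs).
#' @param step finite-difference step, rad.
#' @return Matrix (n_muscles x n_dofs) of moment arms, m.
#' @export
moment_arm_matrix <- function(model, q, dof_names = names(enabled_dofs(model)),
                              step = 1e-4) {
  spans <- lapply(model$muscles, `[[`, "spanned_dofs")
  out <- matrix(0, length(model$muscles), length(dof_names),
                dimnames = list(names(model$muscles), dof_names))
  qv <- unclass(q)
  for (dn in dof_names) {
    qp <- qm <- qv
    qp[dn] <- qp[dn] + step
    qm[dn] <- qm[dn] - step
    arm <- -(mtu_lengths(model, qp) - mtu_lengths(model, qm)) / (2 * step)
    mask <- vapply(spans, function(s) dn %in% s, TRUE)
    out[mask, dn] <- arm[mask]
  }
  out
}

## ---- rigid-tendon Hill muscle mechanics ------------------------------------

#' Fibre state under the rigid-tendon assumption
#'
#' With an inextensible tendon of length TSL and a constant muscle height
#' \code{h = l_opt * sin(pennation_opt)}, the fibre length at a given
#' musculotendon length is \code{sqrt(h^2 + (L - TSL)^2)}.
#'
#' @param mtu_len musculotendon length.
#' @param muscle a [muscle_params()].
#' @param units units of \code{mtu_len}: \code{"cm"} (architecture space,
#'   default) or \code{"m"}.
#' @return List of class \code{fibre_state}: \code{l_fibre} (cm),
#'   \code{l_norm}, \code{cos_pennation}.
#' @examples
#' m <- muscle_params("demo", 10, 30, l_opt = 2, tsl = 5)
#' fibre_state(5 + sqrt(3), m)   # l_norm = 1, cos = sqrt(3)/2
#' @export
fibre_state <- function(mtu_len, muscle, units = c("cm", "m")) {
  units <- match.arg(units)
  if (units == "m") mtu_len <- mtu_len * 100
  h <- muscle$l_opt * sin(muscle$pennation_opt * pi / 180)
  p <- mtu_len - muscle$tsl
  if (p <= 0 && h == 0)
    stop(sprintf("degenerate fibre geometry for muscle %s: MTU length %.3f cm <= TSL %.3f cm",
                 muscle$name, mtu_len, muscle$tsl))
  l_fibre <- sqrt(h^2 + p^2)
  structure(list(l_fibre = l_fibre, l_norm = l_fibre / muscle$l_opt,
                 cos_pennation = max(p, 0) / l_fibre),
            class = "fibre_state")
}

#' Active force-length scaling
#'
#' A symmetric parabola with maximum 1 at normalized fibre length 1,
#' vanishing at 0.5 and 1.5 -- the operating bounds outside which fibres of
#' a conventional Hill model cannot generate active force.
#'
#' @param l_norm normalized fibre length (fibre length / optimal length).
#' @return Scale factor in \code{[0, 1]}.
#' @export
active_force_length <- function(l_norm) {
  pmax(0, 1 - ((l_norm - 1) / 0.5)^2)
}

#' Active tendon-direction muscle force
#'
#' \code{F = a * Fmax * f_L(l_norm) * cos(pennation)}: activation-scaled
#' maximal isometric force, shaped by the active force-length curve and
#' projected onto the tendon line of action. No passive element and no
#' force-velocity scaling.
#'
#' @param activation activation in \code{[0, 1]}.
#' @param muscle a [muscle_params()].
#' @param fs a [fibre_state()].
#' @return Force in N.
#' @export
muscle_force <- function(activation, muscle, fs) {
  if (any(activation < -1e-12 | activation > 1 + 1e-12))
    stop("activation must lie in [0, 1]")
  activation * muscle$fmax * active_force_length(fs$l_norm) * fs$cos_pennation
}

## ---- tendon slack length calibration ---------------------------------------

#' Tune tendon slack length against a standing posture
#'
#' If the muscle's normalized fibre length in the standing reference
#' posture lies inside \code{target}, the muscle is returned unchanged.
#' Otherwise TSL is adjusted by bisection (tolerance 1e-6 cm) so the
#' normalized length sits on the nearest target boundary; optimal fibre
#' length is untouched. The adjustment is reported as a percentage of
#' musculotendon length in attribute \code{"tsl_adjust_pct"} (0 when
#' unchanged).
#'
#' @param muscle a [muscle_params()].
#' @param standing_mtu_len musculotendon length in the standing posture, cm.
#' @param target acceptance interval for standing normalized fibre length.
#' @param tol bisection tolerance, cm.
#' @return The (possibly adjusted) [muscle_params()].
#' @export
tune_tsl_standing <- function(muscle, standing_mtu_len,
                              target = c(0.8, 1.2), tol = 1e-6) {
  if (target[1] <= 0 || target[2] <= target[1])
    stop("target must be an interval inside (0, Inf)")
  ln0 <- fibre_state(standing_mtu_len, muscle)$l_norm
  if (ln0 >= target[1] && ln0 <= target[2]) {
    attr(muscle, "tsl_adjust_pct") <- 0
    return(muscle)
  }
  bound <- if (ln0 > target[2]) target[2] else target[1]
  ln_at <- function(tsl) {
    m2 <- muscle; m2$tsl <- tsl
    fibre_state(standing_mtu_len, m2)$l_norm
  }
  ## l_norm is strictly decreasing in tsl on [0, standing_mtu_len)
  lo <- 0
  hi <- standing_mtu_len * (1 - 1e-12)
  if (ln_at(lo) < bound || ln_at(hi) > bound)
    stop(sprintf("no non-negative TSL places muscle %s at normalized length %.2f",
                 muscle$name, bound))
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (ln_at(mid) > bound) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  new_tsl <- (lo + hi) / 2
  adj <- abs(new_tsl - muscle$tsl) / standing_mtu_len * 100
  muscle$tsl <- new_tsl
  attr(muscle, "tsl_adjust_pct") <- adj
  muscle
}

#' Retune optimal fibre length against an operating range
#'
#' If the normalized fibre length over a series of musculotendon lengths
#' leaves the admissible \code{[0.5, 1.5]} operating band, the optimal
#' fibre length is increased by the minimum amount that brings the whole
#' series back inside, with TSL shortened by the same amount so the
#' musculotendon rest length (l_opt + TSL) is conserved.
#'
#' @param muscle a [muscle_params()].
#' @param mtu_len_series musculotendon lengths over the motion, cm.
#' @param band admissible normalized fibre length band.
#' @return The (possibly adjusted) [muscle_params()], with attribute
#'   \code{"fibre_adjust_pct"}: |delta l_opt| as % of mean MTU length.
#' @export
retune_fibre_range <- function(muscle, mtu_len_series, band = c(0.5, 1.5)) {
  if (!length(mtu_len_series)) stop("mtu_len_series is empty")
  range_ok <- function(delta) {
    m2 <- muscle
    m2$l_opt <- muscle$l_opt + delta
    m2$tsl <- muscle$tsl - delta
    ln <- tryCatch(
      vapply(mtu_len_series, function(L) fibre_state(L, m2)$l_norm, 0),
      error = function(e) NULL)   # degenerate fibre geometry: out of band
    !is.null(ln) && min(ln) >= band[1] && max(ln) <= band[2]
  }
  if (range_ok(0)) {
    attr(muscle, "fibre_adjust_pct") <- 0
    return(muscle)
  }
  hi <- muscle$tsl   # delta may not exceed tsl (tsl' >= 0)
  if (hi <= 0 || !range_ok(hi * (1 - 1e-12))) {
    ## one last chance: the exact boundary
    if (!(hi > 0 && range_ok(hi)))
      stop(sprintf("cannot retune muscle %s: required optimal fibre length exceeds MTU rest length",
                   muscle$name))
  }
  lo <- 0
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (range_ok(mid)) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  delta <- hi
  muscle$l_opt <- muscle$l_opt + delta
  muscle$tsl <- muscle$tsl - delta
  attr(muscle, "fibre_adjust_pct") <- delta / mean(mtu_len_series) * 100
  muscle
}

## ---- subject scaling -------------------------------------------------------

#' Scale a model to a subject
#'
#' Per-segment scale factors are subject length / model length for thigh,
#' shank and foot; the pelvis factor is the arithmetic mean of the three
#' limb factors (its own landmarks are unmeasurable externally). Geometry
#' (via points, markers, joint locations, segment dimensions) scales per
#' segment; masses scale with factor^3 and inertia with factor^5 (uniform
#' density). Musculotendon rest lengths are recomputed from the scaled
#' geometry in the reference pose, and each muscle's l_opt and TSL are
#' rescaled proportionally to preserve their ratio.
#'
#' @param model a [limb_model()].
#' @param subject_segment_lengths named numeric: \code{thigh}, \code{shank},
#'   \code{foot} lengths of the subject, m.
#' @return The scaled [limb_model()], with attribute \code{"scale_factors"}.
#' @export
scale_model <- function(model, subject_segment_lengths) {
  need <- c("thigh", "shank", "foot")
  if (!all(need %in% names(subject_segment_lengths)))
    stop("subject segment lengths required for: ",
         paste(setdiff(need, names(subject_segment_lengths)), collapse = ", "))
  f <- vapply(need, function(s)
    subject_segment_lengths[[s]] / model$segments[[s]]$length, 0)
  if (any(f <= 0)) stop("subject segment lengths must be positive")
  factors <- c(pelvis = mean(f), f)

  ref_q <- posture(model, check_ranges = FALSE)
  rest0 <- vapply(model$muscles, function(m) mtu_length(model, ref_q, m), 0)

  new <- model
  for (sn in names(new$segments)) {
    s <- new$segments[[sn]]
    fs <- factors[[sn]]
    s$length <- s$length * fs
    s$com <- s$com * fs
    s$mass <- s$mass * fs^3
    s$inertia <- s$inertia * fs^5
    new$segments[[sn]] <- s
  }
  for (jn in names(new$joints)) {
    j <- new$joints[[jn]]
    j$location <- j$location * factors[[j$parent]]
    new$joints[[jn]] <- j
  }
  for (mn in names(new$markers)) {
    mk <- new$markers[[mn]]
    mk$pos <- mk$pos * factors[[mk$segment]]
    new$markers[[mn]] <- mk
  }
  for (mn in names(new$muscles)) {
    m <- new$muscles[[mn]]
    m$path$points <- m$path$points *
      vapply(m$path$segments, function(s) factors[[s]], 0)
    new$muscles[[mn]] <- m
  }
  rest1 <- vapply(new$muscles, function(m) mtu_length(new, ref_q, m), 0)
  for (mn in names(new$muscles)) {
    r <- rest1[[mn]] / rest0[[mn]]
    new$muscles[[mn]]$l_opt <- new$muscles[[mn]]$l_opt * r
    new$muscles[[mn]]$tsl <- new$muscles[[mn]]$tsl * r
  }
  attr(new, "scale_factors") <- factors
  new
}
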