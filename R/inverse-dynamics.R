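## Newton-Euler inverse dynamics of the pelvis -> thigh -> shank -> foot
## chain: per-DOF net joint moments from joint kinematics and the
## single-limb ground-reaction wrench, with free pelvis residuals
## absorbing the unmodelled remainder of the animal.

#' Zero-phase Butterworth prefilter for generalized coordinates
#'
#' Applied to joint angles before differentiation (3rd order, 6 Hz by
#' convention for inverse dynamics input).
#'
#' @param series coordinate matrix (frames x coordinates).
#' @param rate sampling rate, Hz.
#' @param order filter order.
#' @param cutoff cutoff, Hz.
#' @return Filtered matrix of the same shape.
#' @export
prefilter_angles <- function(series, rate = 180, order = 3, cutoff = 6) {
  x <- as.matrix(series)
  if (nrow(x) < 20) stop("series too short to filter")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- apply(x, 2, function(col) zp_filtfilt(bf, col, pad = round(10 * rate / cutoff)))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' First and second time derivatives of a coordinate series
#'
#' Central differences in the interior, one-sided at the ends.
#'
#' @param q coordinate matrix (frames x coordinates) or vector.
#' @param dt sample interval, s.
#' @return List with \code{qd} and \code{qdd}, same shape as \code{q}.
#' @export
derivatives <- function(q, dt) {
  q <- as.matrix(q)
  n <- nrow(q)
  if (n < 3) stop("need at least 3 frames to differentiate")
  d1 <- function(x) {
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  }
  qd <- apply(q, 2, d1)
  qdd <- apply(qd, 2, d1)
  dim(qd) <- dim(qdd) <- dim(q)
  dimnames(qd) <- dimnames(qdd) <- dimnames(q)
  list(qd = qd, qdd = qdd)
}

## forward kinematics with per-DOF world axes and joint centres
fk_detail <- function(model, q) {
  q <- unclass(q)
  R_pel <- rot_y(q[["pelvis_ry"]]) %*% rot_x(q[["pelvis_rx"]]) %*%
    rot_z(q[["pelvis_rz"]])
  poses <- list(pelvis = list(
    R = R_pel, p = c(q[["pelvis_tx"]], q[["pelvis_ty"]], q[["pelvis_tz"]])))
  axes <- list()
  joint_pos <- list()
  for (jn in names(model$joints)) {
    j <- model$joints[[jn]]
    par <- poses[[j$parent]]
    pj <- as.numeric(par$p + par$R %*% j$location)
    joint_pos[[jn]] <- pj
    Racc <- par$R
    Rj <- diag(3)
    for (d in j$dofs) {
      if (!d$enabled) next
      axes[[d$name]] <- list(axis = as.numeric(Racc %*% Rj %*% d$axis),
                             joint = jn, child = j$child)
      Rj <- Rj %*% rot_axis(d$axis, q[[d$name]])
    }
    poses[[j$child]] <- list(R = par$R %*% Rj, p = pj)
  }
  list(poses = poses, axes = axes, joint_pos = joint_pos)
}

#' Inverse dynamics of the hindlimb chain
#'
#' Recursive Newton-Euler over foot -> shank -> thigh -> pelvis with the
#' ground-reaction force applied at the centre of pressure. Per-DOF
#' moments are the projection of the inter-segmental torque (applied by
#' the parent on the child) onto the joint axis; because the model's
#' coordinates are extension/abduction/external-rotation positive, so are
#' the moments. The force and torque required at the pelvis from the rest
#' of the animal are reported as residuals.
#'
#' @param model a [limb_model()].
#' @param q_series coordinate matrix (frames x coordinates, columns named
#'   per [coord_names()]).
#' @param wrench a \code{limb_wrench} time-aligned with \code{q_series}
#'   (\code{grf} n x 3 N, \code{cop} n x 3 m), or NULL for gravity-only.
#' @param rate sampling rate, Hz.
#' @param quasi_static logical: zero all velocities and accelerations
#'   (gravity + external load statics).
#' @param min_force vertical force below which the GRF is treated as zero
#'   when its CoP is undefined, N.
#' @return List of class \code{joint_moment_series}: \code{moments}
#'   (frames x enabled joint DOFs, Nm), \code{residual_force} and
#'   \code{residual_torque} (frames x 3, pelvis), \code{rate}.
#' @export
inverse_dynamics <- function(model, q_series, wrench = NULL, rate = 180,
                             quasi_static = FALSE, min_force = 5) {
  q_series <- as.matrix(q_series)
  n <- nrow(q_series)
  cn <- coord_names(model)
  if (is.null(colnames(q_series)) || !all(cn %in% colnames(q_series)))
    stop("q_series must carry all model coordinates as columns")
  segs <- model$segments
  seg_names <- names(segs)
  for (s in segs) if (s$mass <= 0) stop("segment mass must be positive")
  dt <- 1 / rate

  fk <- lapply(seq_len(n), function(i)
    fk_detail(model, q_series[i, cn]))
  dof_names <- names(fk[[1]]$axes)

  ## world kinematics of each segment
  com_w <- lapply(seg_names, function(sn) {
    t(vapply(fk, function(f)
      as.numeric(f$poses[[sn]]$p + f$poses[[sn]]$R %*% segs[[sn]]$com),
      numeric(3)))
  })
  names(com_w) <- seg_names

  zero3 <- matrix(0, n, 3)
  if (quasi_static || n < 3) {
    acc <- stats::setNames(rep(list(zero3), length(seg_names)), seg_names)
    omega <- alpha <- acc
  } else {
    acc <- lapply(com_w, function(p) derivatives(p, dt)$qdd)
    omega <- lapply(seg_names, function(sn) {
      w <- matrix(0, n, 3)
      for (i in 2:(n - 1)) {
        Rdot <- (fk[[i + 1]]$poses[[sn]]$R - fk[[i - 1]]$poses[[sn]]$R) / (2 * dt)
        W <- Rdot %*% t(fk[[i]]$poses[[sn]]$R)
        w[i, ] <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
      }
      w[1, ] <- w[2, ]; w[n, ] <- w[n - 1, ]
      w
    })
    names(omega) <- seg_names
    alpha <- lapply(omega, function(w) derivatives(w, dt)$qd)
  }

  g <- model$gravity
  moments <- matrix(0, n, length(dof_names),
                    dimnames = list(NULL, dof_names))
  res_f <- res_t <- zero3
  child_of <- c(pelvis = "thigh", thigh = "shank", shank = "foot")

  for (i in seq_len(n)) {
    f <- fk[[i]]
    grf_i <- if (is.null(wrench)) c(0, 0, 0) else wrench$grf[i, ]
    cop_i <- if (is.null(wrench) || is.null(wrench$cop)) rep(NA_real_, 3)
             else wrench$cop[i, ]
    if (sqrt(sum(grf_i^2)) >= min_force && anyNA(cop_i))
      stop(sprintf("frame %d: ground force %.1f N applied but CoP undefined",
                   i, sqrt(sum(grf_i^2))))
    if (anyNA(cop_i)) grf_i <- c(0, 0, 0)

    f_child <- t_child <- c(0, 0, 0)   # force/torque from child on segment
    child_joint_pos <- NULL
    for (sn in rev(seg_names)) {
      s <- segs[[sn]]
      R <- f$poses[[sn]]$R
      Iw <- R %*% s$inertia %*% t(R)
      w <- omega[[sn]][i, ]; al <- alpha[[sn]][i, ]
      rc <- com_w[[sn]][i, ]
      ## proximal attachment point
      rp <- if (sn == "pelvis") f$poses$pelvis$p else f$joint_pos[[
        names(model$joints)[vapply(model$joints, function(j) j$child == sn, TRUE)]]]
      ext_f <- f_child
      ext_t <- t_child
      ext_m <- if (!is.null(child_joint_pos))
        cross3(child_joint_pos - rc, f_child) else c(0, 0, 0)
      if (sn == "foot" && !anyNA(cop_i)) {
        ext_f <- ext_f + grf_i
        ext_m <- ext_m + cross3(cop_i - rc, grf_i)
      }
      fp <- s$mass * acc[[sn]][i, ] - s$mass * g - ext_f
      tp <- as.numeric(Iw %*% al) + cross3(w, as.numeric(Iw %*% w)) -
        ext_t - ext_m - cross3(rp - rc, fp)
      if (sn == "pelvis") {
        res_f[i, ] <- fp
        res_t[i, ] <- tp
      } else {
        for (dn in dof_names) {
          if (f$axes[[dn]]$child == sn)
            moments[i, dn] <- sum(tp * f$axes[[dn]]$axis)
        }
      }
      ## reaction passed to the parent
      f_child <- -fp
      t_child <- -tp
      child_joint_pos <- rp
    }
  }
  structure(list(moments = moments, residual_force = res_f,
                 residual_torque = res_t, rate = rate),
            class = "joint_moment_series")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Apply a sign convention to moment series
#'
#' Deterministic per-DOF sign remapping (e.g. to make extensor, abductor
#' and external-rotator moments positive when the underlying axes are not
#' already oriented that way). The map is recorded in attribute
#' \code{"sign_map"}.
#'
#' @param moments a \code{joint_moment_series} or plain matrix.
#' @param sign_map named numeric vector of +/-1 per DOF column.
#' @return Object of the same type with remapped columns.
#' @export
apply_sign_convention <- function(moments, sign_map) {
  m <- if (inherits(moments, "joint_moment_series")) moments$moments
       else as.matrix(moments)
  missing <- setdiff(colnames(m), names(sign_map))
  if (length(missing))
    stop("sign map lacks DOF(s): ", paste(missing, collapse = ", "))
  m <- sweep(m, 2, sign_map[colnames(m)], `*`)
  if (inherits(moments, "joint_moment_series")) {
    moments$moments <- m
    attr(moments, "sign_map") <- sign_map
    moments
  } else {
    attr(m, "sign_map") <- sign_map
    m
  }
}

#' Normalize moments by body weight times leg length
#'
#' @param moments a \code{joint_moment_series} or matrix, Nm.
#' @param body_mass subject mass, kg.
#' @param leg_length hindlimb leg length (standing hip height), m.
#' @param g gravitational acceleration, m s^-2.
#' @return Dimensionless moment matrix.
#' @export
normalize_moments <- function(moments, body_mass, leg_length, g = 9.81) {
  if (body_mass <= 0 || leg_length <= 0)
    stop("body mass and leg length must be positive")
  m <- if (inherits(moments, "joint_moment_series")) moments$moments
       else as.matrix(moments)
  m / (body_mass * g * leg_length)
}
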