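## Marker-based joint kinematics: gap filling, zero-phase low-pass
## filtering, rigid cluster pose fitting (orthogonal Procrustes), Cardan
## Y-X'-Z'' joint angles, outlier screening, time normalization and
## subject-first ensemble averaging.
##
## A marker trajectory is an n x 3 matrix of positions (m) with attributes
## "rate" (Hz) and "name"; missing samples are NA rows. A marker set is a
## named list of such matrices sharing one time base.

#' Construct a marker trajectory
#'
#' @param xyz n x 3 matrix of positions, metres; gaps as NA rows.
#' @param name marker name.
#' @param rate sampling rate, Hz.
#' @return The matrix with attributes \code{name} and \code{rate}.
#' @export
marker_trajectory <- function(xyz, name = "marker", rate = 180) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("marker trajectory must be n x 3")
  ok <- stats::complete.cases(xyz)
  if (any(!is.finite(xyz[ok, ]))) stop("non-finite marker positions")
  structure(xyz, name = name, rate = rate)
}

traj_rate <- function(traj) {
  r <- attr(traj, "rate")
  if (is.null(r)) 180 else r
}

#' Fill marker gaps
#'
#' Leading missing samples are replaced by the first valid value (the
#' crouched limb is stationary before a hidden marker appears, so constant
#' back-fill is appropriate); trailing gaps by the last valid value.
#' Interior gaps up to \code{max_gap} seconds are linearly interpolated;
#' longer interior gaps are left missing and flagged in attribute
#' \code{"long_gaps"}.
#'
#' @param traj a [marker_trajectory()].
#' @param max_gap maximum interior gap to interpolate, s.
#' @return The filled trajectory.
#' @export
fill_leading_gaps <- function(traj, max_gap = 0.1) {
  valid <- stats::complete.cases(traj)
  if (!any(valid)) stop("marker has no valid samples")
  rate <- traj_rate(traj)
  out <- traj
  idx <- which(valid)
  first <- idx[1]; last <- idx[length(idx)]
  if (first > 1) out[seq_len(first - 1), ] <- rep(out[first, ], each = first - 1)
  n <- nrow(out)
  if (last < n) out[(last + 1):n, ] <- rep(out[last, ], each = n - last)
  long_gaps <- list()
  if (length(idx) > 1) {
    gaps <- which(diff(idx) > 1)
    for (g in gaps) {
      a <- idx[g]; b <- idx[g + 1]
      run <- (a + 1):(b - 1)
      if (length(run) / rate <= max_gap) {
        w <- (run - a) / (b - a)
        out[run, ] <- (1 - w) %o% traj[a, ] + w %o% traj[b, ]
      } else {
        long_gaps[[length(long_gaps) + 1]] <- c(start = a + 1, end = b - 1)
      }
    }
  }
  attr(out, "long_gaps") <- long_gaps
  out
}

#' Zero-phase filtering with odd-reflection edge padding
#'
#' Forward-backward filtering; the signal is extended at both ends by an
#' odd (point-mirrored) reflection long enough to absorb the filter
#' transients, so constants and linear trends pass through unchanged and
#' DC gain is exactly one.
#'
#' @param bf a filter object from [signal::butter()].
#' @param x numeric vector.
#' @param pad padding length (samples); capped at \code{length(x) - 1}.
#' @return Filtered vector of the same length.
#' @keywords internal
zp_filtfilt <- function(bf, x, pad = 90) {
  n <- length(x)
  L <- min(n - 1, pad)
  head_ext <- 2 * x[1] - x[(L + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - L)]
  y <- signal::filtfilt(bf, c(head_ext, x, tail_ext))
  y[(L + 1):(L + n)]
}

#' Zero-phase Butterworth low-pass filter for marker data
#'
#' Forward-backward (zero-phase) filtering so event timing is not shifted;
#' the effective attenuation is the squared single-pass magnitude
#' response. DC gain is exactly one.
#'
#' @param traj a [marker_trajectory()] (or plain numeric matrix/vector).
#' @param order filter order (single pass).
#' @param cutoff cutoff frequency, Hz.
#' @param rate sampling rate, Hz (default: the trajectory's).
#' @return The filtered trajectory.
#' @export
lowpass_markers <- function(traj, order = 4, cutoff = 6, rate = NULL) {
  if (is.null(rate)) rate <- traj_rate(traj)
  x <- as.matrix(traj)
  if (anyNA(x)) stop("fill gaps before filtering")
  if (nrow(x) < 20) stop("signal too short for filter warm-up")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- apply(x, 2, function(col) zp_filtfilt(bf, col, pad = round(10 * rate / cutoff)))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  attr(out, "name") <- attr(traj, "name")
  attr(out, "rate") <- rate
  out
}

## ---- rigid cluster pose -----------------------------------------------------

#' Least-squares rigid transform between point sets (Kabsch)
#'
#' Finds rotation R (det +1) and translation t minimizing
#' ||R template + t - observed||^2.
#'
#' @param template k x 3 matrix of local (calibration) positions.
#' @param observed k x 3 matrix of observed world positions.
#' @param cond_tol degeneracy threshold on the ratio of the second-largest
#'   to largest singular value of the centred template (collinear clusters
#'   have no unique pose).
#' @return List with \code{R} (3x3) and \code{t} (3-vector).
#' @export
procrustes_rigid <- function(template, observed, cond_tol = 1e-6) {
  template <- as.matrix(template); observed <- as.matrix(observed)
  if (nrow(template) < 3) stop("need >= 3 markers for a rigid pose")
  ca <- colMeans(template); cb <- colMeans(observed)
  A <- sweep(template, 2, ca); B <- sweep(observed, 2, cb)
  sv_a <- svd(A)$d
  if (sv_a[2] < cond_tol * max(sv_a[1], .Machine$double.eps))
    stop("degenerate (collinear) marker cluster")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

#' Build a static cluster calibration from a reference trial
#'
#' Relates each segment's technical cluster (TCS) to its anatomical
#' coordinate system (ACS): given the marker positions of one standing
#' reference frame and the ACS pose of each segment in that frame, the
#' cluster geometry is stored in ACS coordinates, so a later Procrustes
#' fit of the observed cluster directly yields the ACS pose.
#'
#' @param static_markers named list of 3-vectors (or 1 x 3 matrices): world
#'   marker positions in the reference frame.
#' @param clusters named list: per segment, the cluster marker names.
#' @param acs_poses named list: per segment, \code{list(R =, p =)}, the ACS
#'   pose in the reference frame.
#' @return Named list of class \code{static_calibration}: per segment, a
#'   template matrix (cluster positions in ACS coordinates).
#' @export
static_calibration <- function(static_markers, clusters, acs_poses) {
  out <- lapply(names(clusters), function(seg) {
    nm <- clusters[[seg]]
    missing <- setdiff(nm, names(static_markers))
    if (length(missing))
      stop("static trial lacks marker(s): ", paste(missing, collapse = ", "))
    world <- do.call(rbind, lapply(static_markers[nm], as.numeric))
    pose <- acs_poses[[seg]]
    template <- t(crossprod(pose$R, t(sweep(world, 2, pose$p))))
    rownames(template) <- nm
    template
  })
  names(out) <- names(clusters)
  class(out) <- "static_calibration"
  out
}

#' Segment pose series from a marker cluster
#'
#' Per-frame orthogonal Procrustes fit of the calibrated cluster template
#' to the observed cluster markers.
#'
#' @param marker_set named list of [marker_trajectory()] matrices.
#' @param template k x 3 calibration template (cluster positions in the
#'   segment's anatomical frame) with marker rownames.
#' @return List of class \code{segment_pose_series}: \code{R} (list of 3x3
#'   per frame), \code{p} (n x 3 matrix).
#' @export
segment_pose <- function(marker_set, template) {
  nm <- rownames(template)
  missing <- setdiff(nm, names(marker_set))
  if (length(missing))
    stop("marker set lacks cluster marker(s): ", paste(missing, collapse = ", "))
  n <- nrow(marker_set[[nm[1]]])
  Rs <- vector("list", n)
  ps <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    obs <- do.call(rbind, lapply(marker_set[nm], function(m) m[i, ]))
    fit <- procrustes_rigid(template, obs)
    Rs[[i]] <- fit$R
    ps[i, ] <- fit$t
  }
  structure(list(R = Rs, p = ps), class = "segment_pose_series")
}

#' Joint angle series from parent and child pose series
#'
#' Per frame, the relative rotation parent' x child is decomposed into
#' Cardan Y-X'-Z'' angles (flexion/extension, ad/abduction,
#' internal/external rotation); signs are remapped so extension, abduction
#' and external rotation increase, and each channel is unwrapped.
#'
#' @param parent,child \code{segment_pose_series} with equal frame counts.
#' @param sign_map numeric length-3 vector of +/-1 applied to (y, x, z).
#' @param joint label used for column names.
#' @return n x 3 matrix (degrees) with columns \code{<joint>_fe},
#'   \code{<joint>_aa}, \code{<joint>_rot}.
#' @export
joint_angles <- function(parent, child, sign_map = c(1, 1, 1),
                         joint = "joint") {
  if (length(parent$R) != length(child$R))
    stop("parent and child pose series differ in frame count")
  n <- length(parent$R)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    R_rel <- crossprod(parent$R[[i]], child$R[[i]])
    out[i, ] <- cardan_yxz(R_rel) * sign_map
  }
  out <- apply(out, 2, unwrap_deg)
  dim(out) <- c(n, 3)
  colnames(out) <- paste0(joint, c("_fe", "_aa", "_rot"))
  out
}

## ---- trial screening, normalization, averaging ------------------------------

#' Screen outlier trials against a group mean
#'
#' A trial is excluded when, for any channel, its deviation from the group
#' mean exceeds \code{threshold} degrees; the deviation statistic is the
#' maximum over the cycle (default) or the cycle mean.
#'
#' @param trials list of angle matrices on a common percent-StS grid.
#' @param group_mean matrix of the same shape.
#' @param threshold exclusion threshold, degrees.
#' @param stat \code{"max"} (pointwise) or \code{"mean"} deviation.
#' @return List: \code{retained} (trials), \code{report} (data.frame with
#'   per-trial worst channel and peak deviation, and whether excluded).
#' @export
exclude_outlier_trials <- function(trials, group_mean, threshold = 45,
                                   stat = c("max", "mean")) {
  if (!length(trials)) stop("no trials given")
  stat <- match.arg(stat)
  rows <- lapply(seq_along(trials), function(i) {
    dev <- abs(trials[[i]] - group_mean)
    per_chan <- apply(dev, 2, if (stat == "max") max else mean)
    worst <- which.max(per_chan)
    data.frame(trial = i, channel = colnames(group_mean)[worst],
               deviation_deg = per_chan[worst],
               excluded = per_chan[worst] > threshold)
  })
  report <- do.call(rbind, rows)
  list(retained = trials[!report$excluded], report = report)
}

#' Time-normalize a series to a percent-StS grid
#'
#' Linear interpolation of every channel onto \code{n_points} equally
#' spaced points from the start to the end event, both included; endpoint
#' values are preserved exactly.
#'
#' @param series numeric matrix (frames x channels) or vector.
#' @param n_points grid size (default 100).
#' @param start,end event frame indices (default: whole series).
#' @return Matrix (\code{n_points} x channels) with attribute
#'   \code{"pct_sts"}, the 0-100 grid.
#' @export
time_normalize <- function(series, n_points = 100, start = 1,
                           end = NROW(series)) {
  series <- as.matrix(series)
  if (end <= start) stop("end event must come after start event")
  if (nrow(series) < 2) stop("need at least two frames")
  xi <- seq(start, end, length.out = n_points)
  out <- apply(series, 2, function(col)
    stats::approx(seq_len(nrow(series)), col, xout = xi)$y)
  dim(out) <- c(n_points, ncol(series))
  colnames(out) <- colnames(series)
  attr(out, "pct_sts") <- seq(0, 100, length.out = n_points)
  out
}

#' Detect sit-to-stand start and end events
#'
#' Start: first frame where any channel's extension velocity exceeds
#' \code{vel_thresh} deg/s sustained for \code{sustain} seconds. End: first
#' frame after which every channel stays within \code{end_tol} degrees of
#' its final value.
#'
#' @param series angle matrix, degrees, extension increasing.
#' @param rate sampling rate, Hz.
#' @param vel_thresh velocity threshold, deg/s.
#' @param sustain sustain time, s.
#' @param end_tol settling tolerance, deg.
#' @return Integer vector \code{c(start, end)}.
#' @export
sts_events <- function(series, rate = 180, vel_thresh = 5, sustain = 0.05,
                       end_tol = 2) {
  series <- as.matrix(series)
  n <- nrow(series)
  vel <- rbind(diff(series), 0) * rate
  k <- max(1L, round(sustain * rate))
  fast <- apply(vel, 1, function(v) any(v > vel_thresh))
  start <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (fast[i]) run + 1L else 0L
    if (run >= k) { start <- i - k + 1L; break }
  }
  if (is.na(start)) stop("no sit-to-stand onset found")
  final <- series[n, ]
  settled <- apply(series, 1, function(r) all(abs(r - final) <= end_tol))
  end <- n
  for (i in n:start) {
    if (!settled[i]) { end <- min(i + 1L, n); break }
  }
  c(start = start, end = max(end, start + 1L))
}

#' Subject-first ensemble average
#'
#' Trials are averaged within each subject first, then the subject means
#' are averaged, so unbalanced trial counts do not bias the grand mean.
#' The SD is the between-subject standard deviation (n-1).
#'
#' @param trials_by_subject named list: per subject, a list of angle
#'   matrices on a common grid.
#' @return List with \code{mean} and \code{sd} matrices.
#' @export
ensemble_average <- function(trials_by_subject) {
  if (!length(trials_by_subject)) stop("no subjects given")
  subject_means <- lapply(trials_by_subject, function(trials) {
    if (!length(trials)) stop("subject with no trials")
    Reduce(`+`, trials) / length(trials)
  })
  grand <- Reduce(`+`, subject_means) / length(subject_means)
  if (length(subject_means) > 1) {
    sq <- Reduce(`+`, lapply(subject_means, function(m) (m - grand)^2))
    sd <- sqrt(sq / (length(subject_means) - 1))
  } else {
    sd <- grand * 0
  }
  list(mean = grand, sd = sd)
}

#' Range of motion per channel
#'
#' @param series angle matrix (frames x channels), degrees.
#' @return Named vector of max - min per channel.
#' @export
range_of_motion <- function(series) {
  series <- as.matrix(series)
  if (!nrow(series)) stop("empty series")
  apply(series, 2, function(col) max(col) - min(col))
}
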