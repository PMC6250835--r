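## Force-plate processing: de-meaning against an unloaded baseline,
## zero-phase low-pass filtering, decimation to the motion-capture rate,
## bilateral splitting under the symmetry assumption, and a composite
## centre of pressure constrained to the foot midline.

#' Construct a force-plate record
#'
#' @param force n x 3 matrix of plate forces (craniocaudal, mediolateral,
#'   vertical), N.
#' @param cop n x 3 matrix of plate centre-of-pressure positions, m
#'   (lab frame), or NULL.
#' @param rate sampling rate, Hz.
#' @param plate plate label.
#' @return List of class \code{force_plate_record}.
#' @export
force_plate_record <- function(force, cop = NULL, rate = 1800,
                               plate = "hind") {
  force <- as.matrix(force)
  if (ncol(force) != 3) stop("force must be n x 3")
  if (any(!is.finite(force))) stop("non-finite force samples")
  structure(list(force = force, cop = cop, rate = rate, plate = plate),
            class = "force_plate_record")
}

#' Preprocess a raw force-plate record
#'
#' Subtracts the per-channel mean of an unloaded baseline window, applies
#' a zero-phase 4th-order Butterworth low-pass (6 Hz), and decimates to
#' the motion-capture rate by keeping every \code{rate/rate_out}-th sample
#' (decimation after the 6 Hz filter needs no further anti-aliasing).
#'
#' @param raw a [force_plate_record()].
#' @param cutoff low-pass cutoff, Hz.
#' @param order filter order.
#' @param rate_out output rate, Hz; must divide the input rate.
#' @param baseline_window unloaded window at the start of the record used
#'   for de-meaning, s; NULL skips de-meaning.
#' @return A [force_plate_record()] at \code{rate_out}.
#' @export
preprocess_grf <- function(raw, cutoff = 6, order = 4, rate_out = 180,
                           baseline_window = 0.2) {
  dec <- raw$rate / rate_out
  if (dec != round(dec)) stop("output rate must divide the plate rate")
  f <- raw$force
  if (!is.null(baseline_window)) {
    nb <- round(baseline_window * raw$rate)
    if (nb < 1 || nb > nrow(f)) stop("baseline window outside the record")
    f <- sweep(f, 2, colMeans(f[seq_len(nb), , drop = FALSE]))
  }
  bf <- signal::butter(order, cutoff / (raw$rate / 2), type = "low")
  f <- apply(f, 2, function(col) zp_filtfilt(bf, col, pad = round(10 * raw$rate / cutoff)))
  keep <- seq(1, nrow(f), by = dec)
  cop <- raw$cop
  if (!is.null(cop)) cop <- cop[keep, , drop = FALSE]
  force_plate_record(f[keep, , drop = FALSE], cop = cop, rate = rate_out,
                     plate = raw$plate)
}

#' Split a bilateral hindlimb plate record into one limb's wrench
#'
#' Both hindfeet stand on one plate; assuming left-right symmetry the
#' vertical and craniocaudal components are halved and the mediolateral
#' component is set to zero.
#'
#' @param hind_plate a processed [force_plate_record()].
#' @param valid flag: both hindfeet on the plate for the whole trial.
#' @return List of class \code{limb_wrench}: \code{grf} (n x 3, N),
#'   \code{cop} (n x 3 or NULL), \code{rate}.
#' @export
split_bilateral <- function(hind_plate, valid = TRUE) {
  if (!isTRUE(valid))
    stop("trial invalid: both hindfeet must stay on the hindlimb plate")
  grf <- hind_plate$force
  grf[, 1] <- grf[, 1] / 2
  grf[, 2] <- 0
  grf[, 3] <- grf[, 3] / 2
  structure(list(grf = grf, cop = hind_plate$cop, rate = hind_plate$rate),
            class = "limb_wrench")
}

#' Composite centre of pressure on the foot midline
#'
#' The craniocaudal CoP coordinate comes from the plate; the mediolateral
#' coordinate is obtained by projecting onto the foot midline (the line
#' through the ankle and lateral metatarsal head markers, averaged with
#' their medial counterparts when present), and the vertical coordinate is
#' the plate surface height. Frames with vertical force below
#' \code{min_force} have no meaningful CoP and are flagged.
#'
#' @param wrench a \code{limb_wrench} whose \code{cop} holds the plate CoP
#'   (only column 1, craniocaudal, is used).
#' @param markers named list of marker trajectories including
#'   \code{AnkleL} and \code{MTHL} (optionally \code{AnkleM},
#'   \code{MTHM}).
#' @param plate_z plate surface height, m.
#' @param min_force vertical force threshold for a defined CoP, N.
#' @return The wrench with \code{cop} replaced by the composite CoP and
#'   attributes \code{"cop_defined"} (logical per frame) and
#'   \code{"cop_param"} (midline parameter t, 0 at ankle, 1 at the
#'   metatarsal head).
#' @export
compose_cop <- function(wrench, markers, plate_z = 0, min_force = 5) {
  need <- c("AnkleL", "MTHL")
  if (!all(need %in% names(markers)))
    stop("foot midline needs markers: ", paste(need, collapse = ", "))
  ank <- markers$AnkleL
  mth <- markers$MTHL
  if ("AnkleM" %in% names(markers)) ank <- (ank + markers$AnkleM) / 2
  if ("MTHM" %in% names(markers)) mth <- (mth + markers$MTHM) / 2
  n <- nrow(wrench$grf)
  cop <- matrix(NA_real_, n, 3)
  tpar <- rep(NA_real_, n)
  defined <- wrench$grf[, 3] >= min_force
  for (i in seq_len(n)) {
    if (!defined[i]) next
    a <- ank[i, ]; b <- mth[i, ]
    d <- b - a
    if (sqrt(sum(d[1:2]^2)) < 0.01)
      stop("degenerate foot midline (markers < 1 cm apart in the plane)")
    x <- wrench$cop[i, 1]
    t <- if (abs(d[1]) > 1e-9) (x - a[1]) / d[1] else 0.5
    cop[i, ] <- c(x, a[2] + t * d[2], plate_z)
    tpar[i] <- t
  }
  wrench$cop <- cop
  attr(wrench, "cop_defined") <- defined
  attr(wrench, "cop_param") <- tpar
  wrench
}

#' Body-weight normalization of forces
#'
#' @param wrench a \code{limb_wrench} (or plain force matrix).
#' @param body_mass subject mass, kg.
#' @param g gravitational acceleration, m s^-2.
#' @return The force array divided by body weight (dimensionless).
#' @export
normalize_forces <- function(wrench, body_mass, g = 9.81) {
  if (body_mass <= 0) stop("body mass must be positive")
  f <- if (inherits(wrench, "limb_wrench")) wrench$grf else as.matrix(wrench)
  f / (body_mass * g)
}
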