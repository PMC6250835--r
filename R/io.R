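## Text I/O: TRC marker files, MOT/STO labelled time series, YAML model
## and run configuration. All files are tab-delimited with period decimal
## separators and UNIX newlines.

#' Write marker trajectories to a TRC file
#'
#' @param markers named list of [marker_trajectory()] matrices (m).
#' @param path output path.
#' @param rate sampling rate, Hz.
#' @param units \code{"m"} or \code{"mm"}.
#' @export
write_trc <- function(markers, path, rate = NULL, units = "m") {
  if (!length(markers)) stop("no markers to write")
  if (is.null(rate)) rate <- traj_rate(markers[[1]])
  n <- nrow(markers[[1]])
  scale <- if (units == "mm") 1000 else 1
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
  w("PathFileType", "4", "(X/Y/Z)", basename(path))
  w("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
    "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames")
  w(format(rate), format(rate), n, length(markers), units, format(rate),
    1, n)
  hdr <- c("Frame#", "Time",
           unlist(lapply(names(markers), function(nm) c(nm, "", ""))))
  w(paste(hdr, collapse = "\t"))
  sub <- c("", "", unlist(lapply(seq_along(markers), function(i)
    paste0(c("X", "Y", "Z"), i))))
  w(paste(sub, collapse = "\t"))
  tm <- (seq_len(n) - 1) / rate
  dat <- do.call(cbind, lapply(markers, function(m) as.matrix(m) * scale))
  for (i in seq_len(n)) {
    w(paste(c(i, format(tm[i], trim = TRUE),
              formatC(dat[i, ], format = "g", digits = 10)),
            collapse = "\t"))
  }
  invisible(path)
}

#' Read a TRC marker file
#'
#' Units are honoured (mm converted to metres); blank cells become NA
#' (marker gaps).
#'
#' @param path TRC path.
#' @return Named list of [marker_trajectory()] matrices in metres, with
#'   attribute \code{"rate"}.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6 || !startsWith(lines[1], "PathFileType"))
    stop("malformed TRC header (line 1)")
  meta <- strsplit(lines[3], "\t")[[1]]
  hdr2 <- strsplit(lines[2], "\t")[[1]]
  rate <- as.numeric(meta[match("DataRate", hdr2)])
  n_markers <- as.integer(meta[match("NumMarkers", hdr2)])
  units <- meta[match("Units", hdr2)]
  names_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- names_row[seq(3, by = 3, length.out = n_markers)]
  if (anyNA(marker_names) || any(marker_names == ""))
    stop("TRC header: NumMarkers does not match the marker name row (line 4)")
  dat <- lines[-(1:5)]
  dat <- dat[nzchar(dat)]
  rows <- strsplit(dat, "\t")
  ncol_expect <- 2 + 3 * n_markers
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < ncol_expect)
      rows[[i]] <- c(rows[[i]], rep("", ncol_expect - length(rows[[i]])))
    if (length(rows[[i]]) > ncol_expect)
      stop(sprintf("TRC data line %d: %d columns, expected %d",
                   i + 5, length(rows[[i]]), ncol_expect))
  }
  num <- t(vapply(rows, function(r)
    suppressWarnings(as.numeric(replace(r, r == "", NA))), numeric(ncol_expect)))
  scale <- if (identical(units, "mm")) 1e-3 else 1
  out <- list()
  for (k in seq_len(n_markers)) {
    cols <- 2 + (3 * (k - 1)) + 1:3
    out[[marker_names[k]]] <- marker_trajectory(num[, cols] * scale,
                                                name = marker_names[k],
                                                rate = rate)
  }
  attr(out, "rate") <- rate
  out
}

#' Write a labelled time series to an STO/MOT file
#'
#' @param data matrix (frames x channels) with column names.
#' @param path output path.
#' @param time time vector (s); default from \code{rate}.
#' @param rate used when \code{time} is NULL.
#' @param name header name field.
#' @param header extra \code{key=value} header lines (e.g. a serialized
#'   run configuration for provenance).
#' @export
write_sto <- function(data, path, time = NULL, rate = 180,
                      name = "series", header = character()) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("STO data needs column names")
  if (is.null(time)) time <- (seq_len(nrow(data)) - 1) / rate
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(name,
               paste0("nRows=", nrow(data)),
               paste0("nColumns=", ncol(data) + 1),
               header,
               "endheader",
               paste(c("time", colnames(data)), collapse = "\t")),
             con, sep = "\n")
  for (i in seq_len(nrow(data)))
    writeLines(paste(formatC(c(time[i], data[i, ]), format = "g",
                             digits = 12), collapse = "\t"),
               con, sep = "\n")
  invisible(path)
}

#' Read an STO/MOT file
#'
#' @param path file path.
#' @return Matrix (frames x channels) with attribute \code{"time"};
#'   header lines (before \code{endheader}) in attribute \code{"header"}.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stop("STO file lacks an 'endheader' line")
  cols <- strsplit(lines[end + 1], "\t")[[1]]
  if (cols[1] != "time") stop("first STO column must be time")
  body <- lines[-(seq_len(end + 1))]
  body <- body[nzchar(body)]
  num <- t(vapply(strsplit(body, "\t"), as.numeric, numeric(length(cols))))
  if (nrow(num) > 1 && any(diff(num[, 1]) <= 0))
    stop("STO time column must be strictly increasing")
  out <- num[, -1, drop = FALSE]
  colnames(out) <- cols[-1]
  attr(out, "time") <- num[, 1]
  attr(out, "header") <- lines[seq_len(end - 1)]
  out
}

## ---- model / run configuration ---------------------------------------------

#' Serialize a limb model to a YAML config
#'
#' The config is a complete, lossless description: segments (inertial
#' properties), joints (locations, DOF axes, ranges, enabled flags),
#' markers, and muscles (architecture + via-point paths).
#'
#' @param model a [limb_model()].
#' @param path output path.
#' @export
write_model_config <- function(model, path) {
  ser <- list(
    subject = model$subject,
    gravity = model$gravity,
    sigma_max = model$sigma_max,
    segments = lapply(model$segments, function(s)
      list(name = s$name, mass = s$mass, com = s$com,
           inertia = as.numeric(s$inertia), length = s$length,
           density_assumed = s$density_assumed)),
    joints = lapply(model$joints, function(j)
      list(parent = j$parent, child = j$child, location = j$location,
           dofs = lapply(j$dofs, function(d)
             list(joint = d$joint, axis = d$axis, kind = d$kind,
                  enabled = d$enabled, range = d$range)))),
    markers = lapply(model$markers, function(mk)
      list(segment = mk$segment, pos = mk$pos)),
    muscles = lapply(model$muscles, function(m)
      list(name = m$name, pcsa = m$pcsa, pennation_opt = m$pennation_opt,
           fmax = m$fmax, l_opt = m$l_opt, tsl = m$tsl,
           spanned_dofs = as.list(m$spanned_dofs),
           path = list(segments = as.list(m$path$segments),
                       points = as.numeric(t(m$path$points))))))
  writeLines(yaml::as.yaml(ser, precision = 15), path)
  invisible(path)
}

#' Read a limb model from a YAML config
#'
#' @param path config path written by [write_model_config()].
#' @return A [limb_model()].
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  segments <- lapply(y$segments, function(s)
    body_segment(s$name, s$mass, unlist(s$com),
                 matrix(unlist(s$inertia), 3, 3), s$length,
                 s$density_assumed))
  joints <- lapply(y$joints, function(j)
    list(parent = j$parent, child = j$child, location = unlist(j$location),
         dofs = lapply(j$dofs, function(d)
           joint_dof(d$joint, unlist(d$axis), d$kind, d$enabled,
                     unlist(d$range)))))
  markers <- lapply(y$markers, function(mk)
    list(segment = mk$segment, pos = unlist(mk$pos)))
  muscles <- lapply(y$muscles, function(m)
    muscle_params(m$name, m$pcsa, m$pennation_opt, m$l_opt, m$tsl,
                  fmax = m$fmax,
                  path = muscle_path(unlist(m$path$segments),
                                     matrix(unlist(m$path$points),
                                            ncol = 3, byrow = TRUE)),
                  spanned_dofs = unlist(m$spanned_dofs)))
  limb_model(segments, joints, muscles = muscles, markers = markers,
             gravity = unlist(y$gravity), sigma_max = y$sigma_max,
             subject = y$subject)
}

#' Run configuration with the study's default constants
#'
#' Consolidates every tunable threshold of the pipeline; defaults follow
#' the processing conventions the package implements (marker filter 4th
#' order 6 Hz, inverse-dynamics prefilter 3rd order 6 Hz, 45 degree
#' outlier screen, 20% activation / 20% BW reporting filter, 1 Nm / 5%
#' reserve thresholds, reserve optimal torque 1 Nm).
#'
#' @param ... overrides of the defaults.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(marker_filter_order = 4, marker_cutoff_hz = 6,
              grf_filter_order = 4, grf_cutoff_hz = 6,
              id_filter_order = 3, id_cutoff_hz = 6,
              marker_rate_hz = 180, plate_rate_hz = 1800,
              outlier_threshold_deg = 45,
              report_activation = 0.2, report_force_bw = 0.2,
              reserve_max_nm = 1, reserve_max_pct = 5,
              reserve_r0_nm = 1,
              body_mass_kg = 27, leg_length_m = 0.616, g = 9.81,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Serialize a run configuration into STO header lines
#' @param cfg a [run_config()].
#' @keywords internal
config_header <- function(cfg) {
  vapply(names(cfg), function(k)
    paste0("config_", k, "=", paste(format(cfg[[k]]), collapse = ",")), "")
}
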