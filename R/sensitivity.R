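## Perturbation studies: tendon slack length +/-10%, inclusion of the
## nominally locked non-sagittal knee/ankle rotations, and paired
## comparison of simulation runs.

#' Perturb tendon slack lengths
#'
#' Multiplies every muscle's TSL by \code{1 + factor} (optimal fibre
#' lengths unchanged). With a rigid tendon this shifts every muscle's
#' normalized operating range by \code{factor * tsl / l_opt}, which is
#' substantial for short-fibred, long-tendoned distal muscles.
#'
#' @param model a [limb_model()].
#' @param factor fractional change, e.g. \code{0.10} or \code{-0.10};
#'   must lie in \code{[-0.5, 0.5]}.
#' @param muscles names to perturb (default: all).
#' @return The perturbed model; attribute \code{"tsl_perturbation"}
#'   records the factor and muscle set.
#' @export
perturb_tsl <- function(model, factor, muscles = names(model$muscles)) {
  if (factor < -0.5 || factor > 0.5)
    stop("TSL perturbation factor must lie in [-0.5, 0.5]")
  for (mn in muscles) {
    tsl <- model$muscles[[mn]]$tsl * (1 + factor)
    if (tsl < 0) stop("perturbation drives TSL negative for ", mn)
    model$muscles[[mn]]$tsl <- tsl
  }
  attr(model, "tsl_perturbation") <- list(factor = factor, muscles = muscles)
  model
}

#' Enable or zero the non-sagittal knee and ankle rotations
#'
#' Nominal processing fixes knee and ankle ad/abduction and
#' internal/external rotation to zero (these joints permit little such
#' motion anatomically, and marker-based estimates of them are
#' uncertain). Enabling uses the measured channels and adds the DOFs to
#' the model and the optimization.
#'
#' @param model a [limb_model()].
#' @param q_series coordinate matrix including measured
#'   \code{knee_aa/knee_rot/ankle_aa/ankle_rot} columns (required when
#'   enabling).
#' @param enable logical.
#' @return List: \code{model} (DOFs toggled), \code{q_series} (non-sagittal
#'   columns zeroed, or populated from the measured channels).
#' @export
toggle_nonsagittal <- function(model, q_series, enable = FALSE) {
  ns <- c("knee_aa", "knee_rot", "ankle_aa", "ankle_rot")
  for (jn in c("knee", "ankle")) {
    for (k in seq_along(model$joints[[jn]]$dofs)) {
      d <- model$joints[[jn]]$dofs[[k]]
      if (d$kind != "flexion_extension")
        model$joints[[jn]]$dofs[[k]]$enabled <- enable
    }
  }
  q_series <- as.matrix(q_series)
  if (enable) {
    missing <- setdiff(ns, colnames(q_series))
    if (length(missing))
      stop("measured 3D channels required: ", paste(missing, collapse = ", "))
  } else if (any(ns %in% colnames(q_series))) {
    q_series[, intersect(ns, colnames(q_series))] <- 0
  }
  list(model = model, q_series = q_series)
}

#' Compare two simulation runs
#'
#' Per-muscle percent change in cycle-average and peak activation between
#' runs \code{a} (baseline) and \code{b}; baselines below
#' \code{abs_guard} are reported as absolute differences instead (percent
#' change of a near-zero baseline is meaningless). Per-DOF changes in
#' average absolute reserve torque are reported alongside.
#'
#' @param a,b \code{activation_solution}s on the same muscle set and grid.
#' @param abs_guard baseline activation below which absolute differences
#'   are reported.
#' @return List: \code{muscles} (data.frame of changes), \code{reserves}
#'   (data.frame of per-DOF average-reserve changes).
#' @export
compare_runs <- function(a, b, abs_guard = 1e-3) {
  if (!identical(a$muscle_names, b$muscle_names))
    stop("runs cover different muscle sets")
  if (nrow(a$activation) != nrow(b$activation))
    stop("runs are on different grids")
  ch <- function(base, new) {
    if (base < abs_guard) c(new - base, NA) else c(NA, (new - base) / base * 100)
  }
  rows <- lapply(a$muscle_names, function(mn) {
    am <- mean(a$activation[, mn]); bm <- mean(b$activation[, mn])
    ap <- max(a$activation[, mn]); bp <- max(b$activation[, mn])
    cm <- ch(am, bm); cp <- ch(ap, bp)
    data.frame(muscle = mn, avg_base = am, avg_new = bm,
               avg_change_abs = cm[1], avg_change_pct = cm[2],
               peak_base = ap, peak_new = bp,
               peak_change_abs = cp[1], peak_change_pct = cp[2])
  })
  resv <- lapply(a$dof_names, function(dn) {
    ra <- mean(abs(a$reserve[, dn])); rb <- mean(abs(b$reserve[, dn]))
    data.frame(dof = dn, avg_reserve_base_nm = ra, avg_reserve_new_nm = rb,
               change_nm = rb - ra)
  })
  list(muscles = do.call(rbind, rows), reserves = do.call(rbind, resv))
}

#' Run a named sensitivity variant of a solved trial
#'
#' @param model nominal [limb_model()].
#' @param q_series coordinate matrix.
#' @param tau_series inverse-dynamics moments aligned with
#'   \code{q_series}.
#' @param variant one of \code{"nominal"}, \code{"tsl_plus10"},
#'   \code{"tsl_minus10"}, \code{"unconstrained_3d"}.
#' @param R0 reserve optimal torque, Nm.
#' @param wrench,rate passed to [inverse_dynamics()] when the variant
#'   changes the model DOF set (unconstrained_3d recomputes moments).
#' @return List of class \code{sensitivity_run}: \code{label},
#'   \code{model}, \code{solution}, \code{summary} (reserve summary),
#'   \code{tau}.
#' @export
run_variant <- function(model, q_series, tau_series, variant = "nominal",
                        R0 = 1, wrench = NULL, rate = 180) {
  variant <- match.arg(variant, c("nominal", "tsl_plus10", "tsl_minus10",
                                  "unconstrained_3d"))
  q <- as.matrix(q_series)
  tau <- as.matrix(tau_series)
  mod <- switch(variant,
                nominal = model,
                tsl_plus10 = perturb_tsl(model, 0.10),
                tsl_minus10 = perturb_tsl(model, -0.10),
                unconstrained_3d = model)
  if (variant == "unconstrained_3d") {
    tg <- toggle_nonsagittal(model, q, enable = TRUE)
    mod <- tg$model
    q <- tg$q_series
    id <- inverse_dynamics(mod, q, wrench, rate = rate)
    tau <- id$moments
  }
  sol <- solve_trajectory(mod, q, tau, R0 = R0)
  structure(list(label = variant, model = mod, solution = sol,
                 summary = reserve_summary(sol, tau), tau = tau),
            class = "sensitivity_run")
}
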