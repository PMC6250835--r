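## Reader and audit arithmetic for the dissection-based greyhound hindlimb
## muscle architecture table shipped with the package.

#' Read a muscle architecture table
#'
#' The CSV carries, per musculotendon unit: the joint(s) crossed, full
#' muscle name, abbreviation, PCSA (cm^2), pennation angle (deg), maximal
#' isometric force (N, as printed from PCSA x 300 kN m^-2), a literature
#' Fmax for comparison (with a grouping key for entries the literature
#' reports combined), and measured vs. model optimal fibre length and
#' tendon slack length (cm). Printed Fmax values are kept verbatim rather
#' than recomputed, since the published table applies no pennation factor.
#'
#' @param path CSV path; default: the packaged greyhound hindlimb table.
#' @return A data.frame, one row per musculotendon unit.
#' @export
read_muscle_table <- function(path = system.file(
  "extdata", "greyhound_hindlimb_muscles.csv", package = "standup")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("joint", "muscle", "abbreviation", "pcsa_cm2", "pennation_deg",
            "fmax_N", "fibre_opt_measured_cm", "tsl_measured_cm",
            "fibre_opt_model_cm", "tsl_model_cm")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("muscle table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Architecture-table row as muscle parameters
#'
#' @param tab a muscle table from [read_muscle_table()].
#' @param abbrev muscle abbreviation.
#' @param which use the \code{"model"} (default) or \code{"measured"}
#'   fibre/TSL columns.
#' @return A [muscle_params()] (no path attached).
#' @export
muscle_from_table <- function(tab, abbrev, which = c("model", "measured")) {
  which <- match.arg(which)
  row <- tab[tab$abbreviation == abbrev, ]
  if (nrow(row) != 1) stop("muscle not found in table: ", abbrev)
  lo <- if (which == "model") row$fibre_opt_model_cm else row$fibre_opt_measured_cm
  ts <- if (which == "model") row$tsl_model_cm else row$tsl_measured_cm
  muscle_params(abbrev, pcsa = row$pcsa_cm2,
                pennation_opt = row$pennation_deg,
                l_opt = lo, tsl = ts, fmax = row$fmax_N)
}

#' Measured-vs-literature strength ratios
#'
#' Ratio of (possibly group-summed) measured Fmax to the literature Fmax.
#' Muscles that the literature reports as one combined entry share a
#' \code{lit_group} key and are summed before dividing.
#'
#' @param tab a muscle table from [read_muscle_table()].
#' @return Data.frame with columns \code{label}, \code{fmax_measured_N},
#'   \code{fmax_lit_N}, \code{ratio}; one row per muscle or combined group
#'   with a literature value.
#' @export
strength_ratios <- function(tab) {
  tab <- tab[!is.na(tab$fmax_lit_N), ]
  key <- ifelse(is.na(tab$lit_group) | tab$lit_group == "",
                tab$abbreviation, tab$lit_group)
  agg <- lapply(split(tab, key), function(g)
    data.frame(label = if (nrow(g) > 1) unique(g$lit_group) else g$abbreviation,
               fmax_measured_N = sum(g$fmax_N),
               fmax_lit_N = unique(g$fmax_lit_N)))
  out <- do.call(rbind, agg)
  out$ratio <- out$fmax_measured_N / out$fmax_lit_N
  rownames(out) <- out$label
  out
}

#' Audit of the model-vs-measured fibre-length retuning
#'
#' For every muscle whose model optimal fibre length differs from the
#' measured one, reports the absolute change as a percentage of the
#' measured musculotendon length (measured fibre + measured TSL).
#'
#' @param tab a muscle table from [read_muscle_table()].
#' @return Data.frame (one row per retuned muscle) with
#'   \code{delta_fibre_cm}, \code{mtu_len_cm}, \code{pct_of_mtu}, plus
#'   attributes \code{"mean_pct"} and \code{"sd_pct"}.
#' @export
fibre_retune_audit <- function(tab) {
  changed <- tab[abs(tab$fibre_opt_model_cm - tab$fibre_opt_measured_cm) > 1e-9, ]
  out <- data.frame(
    abbreviation = changed$abbreviation,
    delta_fibre_cm = abs(changed$fibre_opt_model_cm - changed$fibre_opt_measured_cm),
    mtu_len_cm = changed$fibre_opt_measured_cm + changed$tsl_measured_cm)
  out$pct_of_mtu <- out$delta_fibre_cm / out$mtu_len_cm * 100
  attr(out, "mean_pct") <- mean(out$pct_of_mtu)
  attr(out, "sd_pct") <- stats::sd(out$pct_of_mtu)
  out
}

#' Audit of the model-vs-measured TSL tuning
#'
#' Reports, for every muscle whose model TSL differs from the measured one
#' (excluding the fibre-retuned muscles, whose TSL change mirrors the
#' fibre change), the absolute TSL change as a percentage of measured
#' musculotendon length.
#'
#' @param tab a muscle table from [read_muscle_table()].
#' @return Data.frame with attribute \code{"mean_pct"}.
#' @export
tsl_tune_audit <- function(tab) {
  fibre_changed <- abs(tab$fibre_opt_model_cm - tab$fibre_opt_measured_cm) > 1e-9
  changed <- tab[!fibre_changed &
                   abs(tab$tsl_model_cm - tab$tsl_measured_cm) > 1e-9, ]
  out <- data.frame(
    abbreviation = changed$abbreviation,
    delta_tsl_cm = abs(changed$tsl_model_cm - changed$tsl_measured_cm),
    mtu_len_cm = changed$fibre_opt_measured_cm + changed$tsl_measured_cm)
  out$pct_of_mtu <- out$delta_tsl_cm / out$mtu_len_cm * 100
  attr(out, "mean_pct") <- mean(out$pct_of_mtu)
  attr(out, "sd_pct") <- stats::sd(out$pct_of_mtu)
  out
}
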