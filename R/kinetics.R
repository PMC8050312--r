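# Centre-of-pressure computation from force-plate wrenches.
#
# Sign convention (fixed package-wide, AMTI-style axes): right-handed
# laboratory frame with x anterior, y left, z up; the wrench (force F,
# moment M) is expressed about the plate-surface origin. The centre of
# pressure on a horizontal plane a height d above the surface is the point
# p = (px, py, d) about which the horizontal moment components vanish:
#   M - p x F has zero x and y components
# which gives px = -My/Fz + d Fx/Fz and py = Mx/Fz + d Fy/Fz. All CoP
# formulas below are derived from this single zero-moment contract.

#' Force-plate wrench time series
#'
#' @param force n-by-3 matrix of force components (N): x anterior, y left,
#'   z vertical up.
#' @param moment n-by-3 matrix of moments (N m) about the plate-surface
#'   origin.
#' @param fs Sampling rate in Hz.
#' @param surface_height Height of the plate surface above the laboratory
#'   floor in m.
#' @return A `plate_wrench` object.
#' @export
plate_wrench <- function(force, moment, fs, surface_height = 0) {
  force <- as.matrix(force); moment <- as.matrix(moment)
  if (ncol(force) != 3L || ncol(moment) != 3L) {
    stop_user("force and moment must each have 3 columns (x, y, z)")
  }
  if (nrow(force) != nrow(moment)) {
    stop_user("force and moment series have different lengths")
  }
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  check_number(surface_height, "surface_height", lower = 0)
  colnames(force) <- c("Fx", "Fy", "Fz")
  colnames(moment) <- c("Mx", "My", "Mz")
  structure(list(force = force, moment = moment, fs = fs,
                 surface_height = surface_height), class = "plate_wrench")
}

new_cop_series <- function(x, y, valid, reference_height, fs) {
  x <- unname(x); y <- unname(y); valid <- unname(valid)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  structure(list(x = x, y = y, valid = valid,
                 reference_height = reference_height, fs = fs),
            class = "cop_series")
}

#' Centre of pressure at the plate surface
#'
#' Returns the point on the plate surface about which the horizontal
#' components of the wrench's moment vanish: `x = -My/Fz`, `y = Mx/Fz`.
#' Samples whose vertical force falls below `fz_threshold` are masked
#' invalid (near-zero load makes the CoP numerically meaningless).
#'
#' @param w A [plate_wrench()].
#' @param fz_threshold Minimum |Fz| in N for a sample to be valid
#'   (default 10 N, standard posturography practice).
#' @return A `cop_series` (fields `x`, `y`, `valid`, `reference_height`,
#'   `fs`).
#' @export
cop_from_wrench <- function(w, fz_threshold = 10) {
  stopifnot(inherits(w, "plate_wrench"))
  fz <- w$force[, "Fz"]
  valid <- is.finite(fz) & abs(fz) >= fz_threshold
  if (!any(valid)) stop_user("no stance detected: all samples below the ",
                             fz_threshold, " N vertical-force threshold")
  new_cop_series(x = -w$moment[, "My"] / fz, y = w$moment[, "Mx"] / fz,
                 valid = valid, reference_height = w$surface_height,
                 fs = w$fs)
}

#' Centre of pressure on an elevated plane ("force structure")
#'
#' Re-expresses the wrench's zero-horizontal-moment point on a virtual
#' plane `delta_h` above the plate surface, compensating for apparatus
#' (e.g. a constraint device or matching block) interposed between foot
#' and plate: `x' = x + delta_h * Fx / Fz`, `y' = y + delta_h * Fy / Fz`.
#'
#' @inheritParams cop_from_wrench
#' @param delta_h Height of the virtual plane above the plate surface in m.
#' @return A `cop_series` with `reference_height` raised by `delta_h`.
#' @export
project_cop_to_height <- function(w, delta_h, fz_threshold = 10) {
  stopifnot(inherits(w, "plate_wrench"))
  check_number(delta_h, "delta_h")
  base <- cop_from_wrench(w, fz_threshold = fz_threshold)
  fz <- w$force[, "Fz"]
  new_cop_series(x = base$x + delta_h * w$force[, "Fx"] / fz,
                 y = base$y + delta_h * w$force[, "Fy"] / fz,
                 valid = base$valid,
                 reference_height = w$surface_height + delta_h,
                 fs = w$fs)
}

#' Combined (global) centre of pressure of two plates
#'
#' Per-sample load-weighted mean of two per-limb CoP series expressed at
#' the same reference height:
#' `u = (u_a * Fz_a + u_b * Fz_b) / (Fz_a + Fz_b)`.
#' The result always lies on the segment joining the two inputs.
#'
#' @param cop_a,cop_b `cop_series` at identical `reference_height`.
#' @param fz_a,fz_b Vertical force series (N) of the two plates.
#' @param fz_threshold Samples whose total vertical force is below this are
#'   masked invalid.
#' @return A `cop_series` at the shared reference height.
#' @export
combine_cop <- function(cop_a, fz_a, cop_b, fz_b, fz_threshold = 10) {
  stopifnot(inherits(cop_a, "cop_series"), inherits(cop_b, "cop_series"))
  if (abs(cop_a$reference_height - cop_b$reference_height) > 1e-9) {
    stop_user("reference-height mismatch (", cop_a$reference_height, " vs ",
              cop_b$reference_height, "): project both CoPs to a common ",
              "plane first")
  }
  if (length(cop_a$x) != length(cop_b$x)) {
    stop_user("CoP series have different lengths")
  }
  # a limb whose own CoP is invalid (unloaded) gets zero weight; samples
  # where neither limb is valid, or the total load is sub-threshold, are
  # masked
  wa_raw <- ifelse(cop_a$valid, fz_a, 0)
  wb_raw <- ifelse(cop_b$valid, fz_b, 0)
  tot <- wa_raw + wb_raw
  valid <- (cop_a$valid | cop_b$valid) & is.finite(tot) &
    abs(tot) >= fz_threshold
  wa <- wa_raw / tot
  xa <- ifelse(cop_a$valid, cop_a$x, 0); xb <- ifelse(cop_b$valid, cop_b$x, 0)
  ya <- ifelse(cop_a$valid, cop_a$y, 0); yb <- ifelse(cop_b$valid, cop_b$y, 0)
  new_cop_series(x = wa * xa + (1 - wa) * xb,
                 y = wa * ya + (1 - wa) * yb,
                 valid = valid, reference_height = cop_a$reference_height,
                 fs = cop_a$fs)
}

#' Inter-limb vertical load share
#'
#' Fraction of the total vertical ground-reaction force carried by limb A,
#' `share = Fz_a / (Fz_a + Fz_b)`, per sample, with zero-total-load samples
#' masked.
#'
#' @param fz_a,fz_b Non-negative vertical force series (N).
#' @param fz_threshold Samples with total load below this are masked.
#' @return List with `share` (per-sample fraction, NA where masked),
#'   `mean_share` (trial mean over valid samples), and `valid`.
#' @export
weight_share <- function(fz_a, fz_b, fz_threshold = 1e-9) {
  if (any(fz_a < 0, na.rm = TRUE) || any(fz_b < 0, na.rm = TRUE)) {
    stop_user("vertical forces must be non-negative")
  }
  tot <- fz_a + fz_b
  valid <- is.finite(tot) & tot >= fz_threshold
  share <- ifelse(valid, fz_a / tot, NA_real_)
  list(share = share, mean_share = mean(share[valid]), valid = valid)
}

#' Pin axis location along the foot
#'
#' Linear interpolation between the ankle joint centre and the distal head
#' of the 5th metatarsal: `ankle + fraction * (met5 - ankle)`.
#'
#' @param ankle,met5 Numeric points in m (any matching length).
#' @param fraction Interpolation fraction in `[0, 1]` (default 0.66).
#' @return Point of the pin axis, same shape as the inputs.
#' @export
pin_location <- function(ankle, met5, fraction = 0.66) {
  check_number(fraction, "fraction", lower = 0, upper = 1)
  if (length(ankle) != length(met5)) {
    stop_user("ankle and met5 must have the same length")
  }
  ankle + fraction * (met5 - ankle)
}
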