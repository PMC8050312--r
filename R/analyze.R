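# End-to-end analysis of one recorded trial: wrenches -> per-limb and
# combined CoP (with height projection where apparatus sits between foot
# and plate), markers -> segmental CoM -> acceleration, then the kinetic
# and kinematic inverted-pendulum correlations.

#' Analysis settings
#'
#' @param marker_cutoff Zero-phase low-pass cutoff (Hz) for markers and
#'   plate signals (default 10).
#' @param acc_cutoff Cutoff (Hz) before double differentiation (default 5).
#' @param fz_threshold Minimum vertical force (N) for valid CoP samples.
#' @param movement `"path"` or `"range"` for the kinematic movement
#'   statistic.
#' @param filter_order Butterworth order per pass.
#' @return List of validated settings.
#' @export
analysis_settings <- function(marker_cutoff = 10, acc_cutoff = 5,
                              fz_threshold = 10, movement = "path",
                              filter_order = 4) {
  check_number(marker_cutoff, "marker_cutoff", lower = 0, strict_lower = TRUE)
  check_number(acc_cutoff, "acc_cutoff", lower = 0, strict_lower = TRUE)
  check_number(fz_threshold, "fz_threshold", lower = 0)
  check_choice(movement, "movement", c("path", "range"))
  list(marker_cutoff = marker_cutoff, acc_cutoff = acc_cutoff,
       fz_threshold = fz_threshold, movement = movement,
       filter_order = filter_order)
}

filter_wrench <- function(w, cutoff, order) {
  f <- apply(w$force, 2, lowpass, cutoff = cutoff, fs = w$fs, order = order)
  m <- apply(w$moment, 2, lowpass, cutoff = cutoff, fs = w$fs, order = order)
  plate_wrench(f, m, fs = w$fs, surface_height = w$surface_height)
}

filter_markers <- function(mk, cutoff, order) {
  lp <- function(mat) apply(mat, 2, lowpass, cutoff = cutoff, fs = mk$fs,
                            order = order)
  marker_set(mk$labels, lp(mk$x), lp(mk$y), lp(mk$z), mk$fs)
}

# per-limb CoP at the common support surface, projecting over any
# apparatus height difference
limb_cop_at_support <- function(w, support_height, fz_threshold) {
  dh <- support_height - w$surface_height
  if (abs(dh) < 1e-12) {
    cop_from_wrench(w, fz_threshold = fz_threshold)
  } else {
    project_cop_to_height(w, dh, fz_threshold = fz_threshold)
  }
}

#' Analyse one quiet-standing trial
#'
#' Runs the full chain on a [trial_recording()]: low-passes plate signals
#' and markers, extracts per-limb CoPs (projected to the support surface
#' when a device elevates the feet above the plates), combines them into
#' the global CoP, estimates the segmental CoM and its filtered
#' acceleration, and computes the six kinetic (3 limbs x 2 directions) and
#' two kinematic correlations.
#'
#' @param recording A [trial_recording()].
#' @param anthro Anthropometric table for [segmental_com()].
#' @param settings An [analysis_settings()] list.
#' @return data.frame of trial-level correlation results (8 rows).
#' @export
analyze_trial <- function(recording, anthro = default_anthropometric_table(),
                          settings = analysis_settings()) {
  stopifnot(inherits(recording, "trial_recording"))
  s <- settings
  ord <- s$filter_order
  wl <- filter_wrench(recording$left_wrench, s$marker_cutoff, ord)
  wr <- filter_wrench(recording$right_wrench, s$marker_cutoff, ord)
  sup <- recording$support_height
  cop_l <- limb_cop_at_support(wl, sup, s$fz_threshold)
  cop_r <- limb_cop_at_support(wr, sup, s$fz_threshold)
  cop_tot <- combine_cop(cop_l, wl$force[, "Fz"], cop_r, wr$force[, "Fz"],
                         fz_threshold = s$fz_threshold)
  mk <- filter_markers(recording$markers, s$marker_cutoff, ord)
  com_pos <- segmental_com(mk, table = anthro)
  com <- com_series(com_pos$ap, com_pos$ml, fs = recording$fs,
                    cutoff = s$acc_cutoff)

  role_of <- recording$limb_roles # list(left = role, right = role)
  cops <- list(left = cop_l, right = cop_r, total = cop_tot)
  rows <- list()
  for (side in c("left", "right", "total")) {
    limb <- if (side == "total") "total" else role_of[[side]]
    for (dir in c("AP", "ML")) {
      rows[[length(rows) + 1L]] <- kinetic_ip_corr(
        cops[[side]], com, direction = dir, limb = limb,
        condition = recording$condition, subject_id = recording$subject_id,
        trial_id = recording$trial_id, group = recording$group)
    }
  }
  for (dir in c("AP", "ML")) {
    hm <- marker_height_excursion(mk, direction = dir,
                                  support_height = sup,
                                  movement = s$movement)
    rows[[length(rows) + 1L]] <- kinematic_ip_corr(
      hm, direction = dir, condition = recording$condition,
      subject_id = recording$subject_id, trial_id = recording$trial_id,
      group = recording$group)
  }
  do.call(rbind, rows)
}

#' Analyse a list of trials
#'
#' @param trials List of [trial_recording()]s or `synthetic_trial`s.
#' @param ... Passed to [analyze_trial()].
#' @return Long-format data.frame, one row per trial x definition x
#'   direction x limb, suitable for [summary_table()] or export to
#'   external ANOVA tools.
#' @export
analyze_cohort <- function(trials, ...) {
  rows <- lapply(trials, function(tr) {
    rec <- if (inherits(tr, "synthetic_trial")) tr$recording else tr
    analyze_trial(rec, ...)
  })
  do.call(rbind, rows)
}
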