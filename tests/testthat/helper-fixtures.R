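# Shared fixtures, built in code at test time.

# short default trial config for unit tests (full 60 s trials are
# exercised in test-acceptance.R)
quick_config <- function(duration = 10, seed = 11, condition = "EO",
                         group = "TPU", noise_sd = 0.03,
                         within_foot_noise_sd = 5e-4,
                         marker_noise_sd = 3e-4, init_offset = c(0, 0),
                         pin_side = "left", block_height = 0, ...) {
  trial_config(
    duration = duration, fs = 100, condition = condition, group = group,
    seed = seed,
    controller = controller_params(noise_sd = noise_sd,
                                   within_foot_noise_sd = within_foot_noise_sd),
    geometry = stance_geometry(pin_side = pin_side,
                               block_height = block_height),
    marker_noise_sd = marker_noise_sd, init_offset = init_offset, ...)
}

# noiseless decaying-oscillation trial: deterministic sway from an initial
# CoM offset, no noise anywhere
noiseless_config <- function(duration = 10, init_ap = 0.02, init_ml = 0.01,
                             ...) {
  quick_config(duration = duration, noise_sd = 0,
               within_foot_noise_sd = 0, marker_noise_sd = 0,
               init_offset = c(init_ap, init_ml), ...)
}

# measured-chain (d = CoP - CoM, acc) pairs for one direction of a
# recording, mirroring analyze_trial's kinetic path on the combined CoP
measured_kinetic_pair <- function(recording, direction = "AP",
                                  settings = analysis_settings()) {
  wl <- recording$left_wrench; wr <- recording$right_wrench
  lp <- function(mat, fs) apply(mat, 2, pincontrol::lowpass,
                                cutoff = settings$marker_cutoff, fs = fs,
                                order = settings$filter_order)
  wlf <- plate_wrench(lp(wl$force, wl$fs), lp(wl$moment, wl$fs), wl$fs,
                      wl$surface_height)
  wrf <- plate_wrench(lp(wr$force, wr$fs), lp(wr$moment, wr$fs), wr$fs,
                      wr$surface_height)
  sup <- recording$support_height
  to_sup <- function(w) {
    if (abs(sup - w$surface_height) < 1e-12) cop_from_wrench(w)
    else project_cop_to_height(w, sup - w$surface_height)
  }
  ct <- combine_cop(to_sup(wlf), wlf$force[, "Fz"], to_sup(wrf),
                    wrf$force[, "Fz"])
  mk <- recording$markers
  mkf <- marker_set(mk$labels, lp(mk$x, mk$fs), lp(mk$y, mk$fs),
                    lp(mk$z, mk$fs), mk$fs)
  com_pos <- segmental_com(mkf)
  com <- com_series(com_pos$ap, com_pos$ml, fs = recording$fs,
                    cutoff = settings$acc_cutoff)
  if (direction == "AP") {
    list(d = ct$x - com$ap, acc = com$acc_ap)
  } else {
    list(d = ct$y - com$ml, acc = com$acc_ml)
  }
}

# full two-group correlation-result design used by summary-table tests
fabricate_results <- function() {
  # full two-group design: 8 TPU + 7 AB subjects x 3 conditions x 3 trials
  rows <- list()
  counter <- 0
  for (grp in c("TPU", "AB_constrained")) {
    n_sub <- if (grp == "TPU") 8 else 7
    for (s in seq_len(n_sub)) for (cond in c("EO", "EC", "FB")) {
      for (t in 1:3) {
        counter <- counter + 1
        base <- ((counter * 37) %% 100) / 250 # deterministic variety
        for (dir in c("AP", "ML")) {
          for (limb in c("unconstrained_intact", "constrained_prosthetic",
                         "total")) {
            rows[[length(rows) + 1]] <- data.frame(
              r = if (limb == "constrained_prosthetic") base else -0.5 + base,
              n_samples = 6000, direction = dir, limb = limb,
              definition = "kinetic", condition = cond,
              subject_id = paste0(grp, s), trial_id = paste0(cond, t),
              group = grp)
          }
          rows[[length(rows) + 1]] <- data.frame(
            r = 0.85 + base / 10, n_samples = 18, direction = dir,
            limb = NA_character_, definition = "kinematic",
            condition = cond, subject_id = paste0(grp, s),
            trial_id = paste0(cond, t), group = grp)
        }
      }
    }
  }
  do.call(rbind, rows)
}

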