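# Sway generator: control law, limb allocation, markers, cohort scheme.

test_that("pd_cop_command is the stated PD law", {
  p <- controller_params(kp = 1.5, kd = 0.3)
  expect_equal(pd_cop_command(0, 0, p), 0)
  expect_equal(pd_cop_command(0.01, 0, p), 0.015)
  expect_equal(pd_cop_command(0.01, 0.02, p, noise_sample = 0.001),
               1.5 * 0.01 + 0.3 * 0.02 + 0.001)
  expect_error(pd_cop_command(NaN, 0, p), "non-finite")
})

test_that("identical config and seed reproduce the trial bit for bit", {
  a <- simulate_trial(quick_config(duration = 5, seed = 99))
  b <- simulate_trial(quick_config(duration = 5, seed = 99))
  expect_identical(a$recording$left_wrench, b$recording$left_wrench)
  expect_identical(a$recording$markers, b$recording$markers)
  expect_identical(a$truth_com, b$truth_com)
  c <- simulate_trial(quick_config(duration = 5, seed = 100))
  expect_false(identical(a$truth_com$ap, c$truth_com$ap))
})

test_that("equilibrium start without noise is a flagged fixed point", {
  cfg <- quick_config(duration = 5, noise_sd = 0, within_foot_noise_sd = 0,
                      marker_noise_sd = 0)
  expect_message(tr <- simulate_trial(cfg), "degenerate")
  expect_true(tr$degenerate)
  expect_equal(sd(tr$truth_com$ap), 0)
  expect_equal(sd(tr$truth_total_cop$x), 0)
})

test_that("closed loop stays bounded and stationary; divergence is diagnosed", {
  tr <- simulate_trial(quick_config(duration = 60, seed = 1))
  expect_lt(max(abs(tr$truth_com$ap)), 0.1)
  # stationarity: time-mean of (total CoP - CoM) within 2 mm per direction
  expect_lt(abs(mean(tr$truth_total_cop$x - tr$truth_com$ap)), 2e-3)
  expect_lt(abs(mean(tr$truth_total_cop$y - tr$truth_com$ml)), 2e-3)
  # an unstable configuration errors naming the gains
  bad <- trial_config(duration = 10, seed = 1,
                      controller = controller_params(kp = 1.06, kd = 0,
                                                     delay = 0.6))
  expect_error(simulate_trial(bad), "unstable configuration.*kp")
})

test_that("vertical force conservation, pin invariance, dynamics consistency", {
  cfg <- quick_config(duration = 10, seed = 3)
  tr <- simulate_trial(cfg)
  fz_sum <- tr$recording$left_wrench$force[, "Fz"] +
    tr$recording$right_wrench$force[, "Fz"]
  m_g <- cfg$pendulum$body_mass * cfg$pendulum$gravity
  expect_lt(max(abs(fz_sum - m_g)), 1e-9)
  # pin limb CoP has exactly zero variance
  expect_equal(sd(tr$truth_cop_left$x), 0)
  expect_equal(sd(tr$truth_cop_left$y), 0)
  # pendulum relation reconstructs the stored truth acceleration
  g_h <- cfg$pendulum$gravity / cfg$pendulum$com_height
  expect_lt(max(abs(g_h * (tr$truth_com$ap - tr$truth_total_cop$x) -
                      tr$truth_com$acc_ap)), 1e-8)
  expect_lt(max(abs(g_h * (tr$truth_com$ml - tr$truth_total_cop$y) -
                      tr$truth_com$acc_ml)), 1e-8)
})

test_that("allocate_limb_wrenches: symmetry, pin constancy, reconstruction", {
  geom_free <- stance_geometry(pin_side = "none")
  mid_ml <- 0 # midpoint of the two foot centres
  al <- allocate_limb_wrenches(u_ap = rep(0.01, 4), u_ml = rep(mid_ml, 4),
                               share = 0.5, geometry = geom_free, mass = 80)
  expect_equal(al$left$force, al$right$force)
  expect_equal(al$left$force[, "Fz"], rep(0.5 * 80 * 9.81, 4))
  expect_equal(al$cop_left$x, al$cop_right$x)
  # pinned side constant at the pin axis for arbitrary commands
  geom_pin <- stance_geometry(pin_side = "left")
  u <- seq(-0.01, 0.03, length.out = 50)
  alp <- allocate_limb_wrenches(u_ap = u, u_ml = 0.3 * u, share = 0.6,
                                geometry = geom_pin, mass = 80)
  pin_ap <- geom_pin$ankle_offset_ap + 0.66 * geom_pin$ankle_to_met5
  expect_equal(alp$cop_left$x, rep(pin_ap, 50))
  expect_equal(sd(alp$cop_left$y), 0)
  expect_false(any(alp$saturated))
  # combined CoP from the emitted wrenches reproduces the command exactly
  cl <- cop_from_wrench(alp$left); cr <- cop_from_wrench(alp$right)
  cc <- combine_cop(cl, alp$left$force[, "Fz"], cr, alp$right$force[, "Fz"])
  expect_lt(max(abs(cc$x - u)), 1e-9)
  expect_lt(max(abs(cc$y - 0.3 * u)), 1e-9)
  # an out-of-foot command is clamped and flagged
  al_sat <- allocate_limb_wrenches(u_ap = 0.4, u_ml = 0, share = 0.6,
                                   geometry = geom_pin, mass = 80)
  expect_true(al_sat$saturated[1])
  b <- geom_pin$ankle_offset_ap + 0.75 * geom_pin$foot_length
  expect_equal(al_sat$cop_right$x[1], b)
  expect_error(allocate_limb_wrenches(0, 0, share = 1.2,
                                      geometry = geom_pin, mass = 80),
               "share")
})

test_that("elevated support: wrench moments encode the block height", {
  geom <- stance_geometry(pin_side = "left", block_height = 0.08)
  al <- allocate_limb_wrenches(u_ap = c(0.01, 0.02), u_ml = c(0, 0.01),
                               share = 0.6, geometry = geom, mass = 80,
                               accel_ap = c(0.1, -0.2), accel_ml = 0.05)
  # at the plate surface the CoP differs by the shear lever arm; projected
  # to the support plane it recovers the per-limb CoP
  pr <- project_cop_to_height(al$right, 0.08)
  expect_equal(pr$x, al$cop_right$x, tolerance = 1e-12)
  expect_equal(pr$y, al$cop_right$y, tolerance = 1e-12)
  plain <- cop_from_wrench(al$right)
  expect_gt(max(abs(plain$x - al$cop_right$x)), 0) # projection matters
})

test_that("synthetic markers follow the rigid small-angle pendulum map", {
  h <- synthetic_com_height(1.80)
  layout <- data.frame(label = c("m1", "m2", "m3", "m4"),
                       height_frac = c(0.4, 0.8, 1.2, 1.6) * h / 1.80,
                       ap_offset = 0, ml_offset = 0)
  com_ap <- 0.02 * sin(2 * pi * 0.3 * seq(0, 10, by = 0.01))
  mk <- generate_marker_set(com_ap, com_ap * 0, com_height = h,
                            body_height = 1.80, fs = 100, layout = layout,
                            noise_sd = 0)
  # excursions in exact height ratio 0.4 : 0.8 : 1.2 : 1.6
  amp <- unname(apply(mk$x, 2, max) - apply(mk$x, 2, min))
  expect_equal(amp / amp[1], c(1, 2, 3, 4), tolerance = 1e-12)
  # marker at CoM height reproduces the CoM; marker at height 0 is still
  layout2 <- data.frame(label = c("at_com", "at_floor", "mid"),
                        height_frac = c(h / 1.80, 0, 0.5),
                        ap_offset = 0, ml_offset = 0)
  mk2 <- generate_marker_set(com_ap, com_ap * 0, h, 1.80, 100,
                             layout = layout2, noise_sd = 0)
  expect_equal(mk2$x[, "at_com"], com_ap, tolerance = 1e-12)
  expect_equal(mk2$x[, "at_floor"], rep(0, length(com_ap)))
  expect_error(generate_marker_set(com_ap, com_ap, h, 1.80, 100,
                                   layout = layout[0, ]), "empty")
  bad <- transform(layout2, height_frac = c(1.5, 0, 0.5))
  expect_error(generate_marker_set(com_ap, com_ap, h, 1.80, 100,
                                   layout = bad), "1.2")
})

test_that("cohort generation: size, determinism, condition mapping", {
  base <- quick_config(duration = 5)
  co <- make_cohort(base, n_subjects = 2, trials_per_condition = 3,
                    master_seed = 5)
  expect_length(co, 2 * 3 * 3)
  man <- attr(co, "manifest")
  expect_equal(nrow(man), 18)
  expect_equal(sort(unique(man$condition)), c("EC", "EO", "FB"))
  co2 <- make_cohort(base, n_subjects = 2, trials_per_condition = 3,
                     master_seed = 5)
  expect_identical(co[[1]]$truth_com, co2[[1]]$truth_com)
  expect_identical(co[[18]]$recording$markers, co2[[18]]$recording$markers)
  # EC inflates sway noise relative to EO for the same subject
  sd_by <- function(cond) {
    idx <- which(man$condition == cond & man$subject_id == man$subject_id[1])
    mean(sapply(co[idx], function(t) sd(t$truth_com$acc_ap)))
  }
  expect_gt(sd_by("EC"), sd_by("EO"))
})

test_that("FB feedback pulls the load share towards 0.5", {
  base <- quick_config(duration = 30)
  co <- make_cohort(base, n_subjects = 2, trials_per_condition = 2,
                    master_seed = 21)
  man <- attr(co, "manifest")
  for (s in unique(man$subject_id)) {
    dev <- function(cond) {
      idx <- which(man$condition == cond & man$subject_id == s)
      mean(sapply(co[idx], function(t) {
        # intact limb is the right plate (pin defaults to left)
        ws <- weight_share(t$recording$right_wrench$force[, "Fz"],
                           t$recording$left_wrench$force[, "Fz"])
        abs(ws$mean_share - 0.5)
      }))
    }
    expect_lt(dev("FB"), dev("EO"))
  }
})
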