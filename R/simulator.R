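# Synthetic quiet-standing trial generator.
#
# A single-segment inverted pendulum, acc = (g/h) (x - u), is stabilized
# independently in the anteroposterior (AP) and mediolateral (ML)
# directions by a delayed-PD centre-of-pressure command with low-pass
# shaped exploratory noise. The command is realized through two limbs:
#
#   AP: the controller limb moves its within-foot CoP; a pinned limb (when
#       present) contributes a fixed CoP at the pin axis.
#   ML: per-limb CoPs stay near the respective foot centres and control is
#       exerted by modulating the inter-limb load share ("load/unload"),
#       which is the mechanism consistent with near-zero per-limb but
#       strongly negative total ML correlations.
#
# Integration is fixed-step semi-implicit Euler at fs * internal_oversample
# (1000 Hz by default), decimated to the output rate.

#' Delayed-PD centre-of-pressure command
#'
#' `u = ref + kp * (com_pos_delayed - ref) + kd * com_vel_delayed + noise`.
#'
#' @param com_pos_delayed Delayed CoM position (m).
#' @param com_vel_delayed Delayed CoM velocity (m s^-1).
#' @param params A [controller_params()].
#' @param noise_sample Additive exploratory noise sample (m).
#' @param ref Regulated set point (m), default 0.
#' @return Commanded total CoP in m.
#' @export
pd_cop_command <- function(com_pos_delayed, com_vel_delayed, params,
                           noise_sample = 0, ref = 0) {
  stopifnot(inherits(params, "controller_params"))
  vals <- c(com_pos_delayed, com_vel_delayed, noise_sample, ref)
  if (!all(is.finite(vals))) stop_user("non-finite input to pd_cop_command")
  ref + params$kp * (com_pos_delayed - ref) +
    params$kd * com_vel_delayed + noise_sample
}

# per-limb geometry helper: foot centres, pin point, AP clamp bounds
limb_layout <- function(geometry) {
  half <- geometry$stance_width / 2
  centre_ml <- c(left = half, right = -half)
  b <- foot_ap_bounds(geometry)
  ap0 <- geometry$ankle_offset_ap
  list(centre_ml = centre_ml,
       centre_ap = c(left = ap0 + 0.25 * geometry$foot_length,
                     right = ap0 + 0.25 * geometry$foot_length),
       ap_lo = ap0 + b$heel_rel, ap_hi = ap0 + b$toe_rel,
       pin_ap = ap0 + geometry$pin_fraction * geometry$ankle_to_met5)
}

#' Distribute a total CoP command over two force plates
#'
#' Given realized total CoP, inter-limb load share and inertial shear,
#' constructs per-limb plate wrenches whose load-weighted combined CoP
#' reproduces the total exactly: the pinned limb's CoP is held at the pin
#' axis, the controller limb's within-foot CoP absorbs the AP command (and
#' is clamped to the foot bounds, with clamping flagged), and mediolateral
#' per-limb CoPs stay at the foot centres plus jitter with the share doing
#' the combining. Vertical dynamics are quasi-static:
#' `Fz = share * m * g` per limb.
#'
#' @param u_ap,u_ml Total CoP command series (m) at the support surface.
#' @param share Fraction of body weight on the controller (unconstrained /
#'   intact) limb, or on the left limb when `pin_side == "none"`.
#' @param geometry A [stance_geometry()].
#' @param mass Body mass (kg).
#' @param accel_ap,accel_ml CoM acceleration series (m s^-2) generating the
#'   horizontal inertial shear `m * acc`, split by share.
#' @param gravity Gravitational acceleration (m s^-2).
#' @param jitter Optional list of within-foot CoP jitter series (m):
#'   `ap_left`, `ap_right`, `ml_left`, `ml_right` (zeros when omitted;
#'   pinned-limb entries are ignored, the pin CoP never moves).
#' @param fs Sampling rate (Hz) stamped on the emitted series.
#' @return List with `left` and `right` [plate_wrench()]s (surface height
#'   0), per-limb `cop_left` / `cop_right` (`cop_series` at the support
#'   surface, i.e. `block_height` above the plates), the realized combined
#'   total (`u_ap`, `u_ml`), and a logical `saturated` flag per sample.
#' @export
allocate_limb_wrenches <- function(u_ap, u_ml, share, geometry, mass,
                                   accel_ap = 0, accel_ml = 0,
                                   gravity = 9.81, jitter = NULL, fs = 100) {
  stopifnot(inherits(geometry, "stance_geometry"))
  n <- length(u_ap)
  if (length(u_ml) != n) stop_user("u_ap and u_ml have different lengths")
  share <- rep_len(share, n)
  if (any(share <= 0 | share >= 1)) stop_user("share must lie strictly in (0, 1)")
  accel_ap <- rep_len(accel_ap, n); accel_ml <- rep_len(accel_ml, n)
  zeros <- numeric(n)
  jit <- list(ap_left = zeros, ap_right = zeros,
              ml_left = zeros, ml_right = zeros)
  for (nm in names(jitter %||% list())) jit[[nm]] <- rep_len(jitter[[nm]], n)
  lay <- limb_layout(geometry)
  pin <- geometry$pin_side
  cop <- list(left = list(ap = zeros, ml = zeros),
              right = list(ap = zeros, ml = zeros))
  saturated <- rep(FALSE, n)

  if (pin != "none") {
    ctrl <- if (pin == "left") "right" else "left"
    # pinned limb: fixed CoP at the pin axis
    cop[[pin]]$ap <- rep(lay$pin_ap, n)
    cop[[pin]]$ml <- rep(lay$centre_ml[[pin]], n)
    # controller limb AP solves the exact combination, then clamps
    raw <- (u_ap - (1 - share) * lay$pin_ap) / share
    cl <- clamp(raw, lay$ap_lo, lay$ap_hi)
    saturated <- abs(cl - raw) > 1e-9
    cop[[ctrl]]$ap <- cl
    # controller limb ML absorbs the share-weighted residual exactly
    cop[[ctrl]]$ml <- (u_ml - (1 - share) * lay$centre_ml[[pin]]) / share
    sh <- list(); sh[[ctrl]] <- share; sh[[pin]] <- 1 - share
  } else {
    wsum_ap <- share * jit$ap_left + (1 - share) * jit$ap_right
    for (s in c("left", "right")) {
      raw <- u_ap + jit[[paste0("ap_", s)]] - wsum_ap
      cl <- clamp(raw, lay$ap_lo, lay$ap_hi)
      saturated <- saturated | abs(cl - raw) > 1e-9
      cop[[s]]$ap <- cl
    }
    base_ml <- c(left = lay$centre_ml[["left"]], right = lay$centre_ml[["right"]])
    resid <- u_ml - (share * (base_ml[["left"]] + jit$ml_left) +
                       (1 - share) * (base_ml[["right"]] + jit$ml_right))
    cop$left$ml <- base_ml[["left"]] + jit$ml_left + resid
    cop$right$ml <- base_ml[["right"]] + jit$ml_right + resid
    sh <- list(left = share, right = 1 - share)
  }

  dh <- geometry$block_height
  wrench <- list()
  for (s in c("left", "right")) {
    fz <- sh[[s]] * mass * gravity
    fx <- sh[[s]] * mass * accel_ap
    fy <- sh[[s]] * mass * accel_ml
    px <- cop[[s]]$ap; py <- cop[[s]]$ml
    # pure force acting at the contact point (px, py, dh): M = p x F
    mx <- py * fz - dh * fy
    my <- dh * fx - px * fz
    mz <- px * fy - py * fx
    wrench[[s]] <- plate_wrench(force = cbind(fx, fy, fz),
                                moment = cbind(mx, my, mz),
                                fs = fs, surface_height = 0)
  }
  mk_cop <- function(s) new_cop_series(cop[[s]]$ap, cop[[s]]$ml,
                                       valid = rep(TRUE, n),
                                       reference_height = dh, fs = fs)
  real <- list(
    u_ap = share * cop[[if (pin == "none") "left" else if (pin == "left") "right" else "left"]]$ap +
      (1 - share) * cop[[if (pin == "none") "right" else pin]]$ap,
    u_ml = u_ml
  )
  list(left = wrench$left, right = wrench$right,
       cop_left = mk_cop("left"), cop_right = mk_cop("right"),
       u_ap = real$u_ap, u_ml = real$u_ml, saturated = saturated)
}

#' Rigid-pendulum synthetic marker trajectories
#'
#' Small-angle mapping of the pendulum state onto a marker layout: each
#' marker's horizontal displacement is `(height above support / h)` times
#' the CoM displacement, plus independent Gaussian noise; heights are
#' constant. Uses the current RNG stream.
#'
#' @param com_ap,com_ml CoM horizontal position series (m).
#' @param com_height Pendulum length h (m).
#' @param body_height Stature (m); layout heights are fractions of it.
#' @param fs Sampling rate (Hz).
#' @param layout Marker layout data.frame (`label`, `height_frac`,
#'   `ap_offset`, `ml_offset`); see [default_marker_layout()].
#' @param support_height Height of the support surface above the floor (m).
#' @param noise_sd Marker noise SD (m).
#' @return A [marker_set()].
#' @export
generate_marker_set <- function(com_ap, com_ml, com_height, body_height,
                                fs, layout = default_marker_layout(body_height),
                                support_height = 0, noise_sd = 0) {
  if (nrow(layout) == 0L) stop_user("empty marker layout")
  if (any(layout$height_frac < 0 | layout$height_frac > 1.2)) {
    stop_user("layout heights must lie in [0, 1.2] * body height")
  }
  n <- length(com_ap)
  m <- nrow(layout)
  ratio <- layout$height_frac * body_height / com_height
  noise <- function() {
    if (noise_sd > 0) matrix(stats::rnorm(n * m, 0, noise_sd), n, m)
    else matrix(0, n, m)
  }
  x <- outer(com_ap, ratio) +
    matrix(layout$ap_offset, n, m, byrow = TRUE) + noise()
  y <- outer(com_ml, ratio) +
    matrix(layout$ml_offset, n, m, byrow = TRUE) + noise()
  z <- matrix(support_height + layout$height_frac * body_height,
              n, m, byrow = TRUE) + noise()
  marker_set(labels = layout$label, x = x, y = y, z = z, fs = fs)
}

#' Simulate one quiet-standing trial
#'
#' Integrates the delayed-PD pendulum, realizes the CoP command through the
#' two limbs, and emits a full [trial_recording()] (per-plate wrenches and
#' markers) together with ground truth. Identical `config` (including
#' `seed`) reproduces identical output.
#'
#' @param config A [trial_config()].
#' @return List of class `synthetic_trial`: `recording`
#'   ([trial_recording()]), `truth_com` ([com_series()]-like ground truth
#'   with exact velocity/acceleration), `truth_total_cop` (realized
#'   combined CoP at the support surface), `truth_cop_left`/`_right`,
#'   `truth_share`, `saturation_count`, `degenerate` flag, and `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  pend <- config$pendulum; ctrlp <- config$controller; geom <- config$geometry
  g_over_h <- pend$gravity / pend$com_height
  fs <- config$fs
  os <- config$internal_oversample
  fsi <- fs * os
  dt <- 1 / fsi
  n_out <- as.integer(round(config$duration * fs))
  n_int <- n_out * os
  dsteps <- as.integer(round(ctrlp$delay * fsi))

  noise_sd <- ctrlp$noise_sd *
    if (config$condition == "EC") ctrlp$ec_noise_multiplier else 1
  shape_noise <- function(sd, cutoff) {
    if (sd <= 0) return(numeric(n_int))
    causal_lowpass(stats::rnorm(n_int, 0, sd), cutoff, fsi, order = 2)
  }
  n_ap <- shape_noise(noise_sd, ctrlp$noise_cutoff)
  n_ml <- shape_noise(noise_sd, ctrlp$noise_cutoff)
  wfn <- ctrlp$within_foot_noise_sd
  jit <- list(ap_left = shape_noise(wfn, 10), ap_right = shape_noise(wfn, 10),
              ml_left = shape_noise(wfn, 10), ml_right = shape_noise(wfn, 10))
  pin <- geom$pin_side
  if (pin != "none") { # the pin never moves
    jit[[paste0("ap_", pin)]] <- numeric(n_int)
    jit[[paste0("ml_", pin)]] <- numeric(n_int)
  }
  ctrl <- switch(pin, left = "right", right = "left", none = "left")
  lay <- limb_layout(geom)
  y_ctrl_c <- lay$centre_ml[[ctrl]]
  y_other_c <- lay$centre_ml[[if (ctrl == "left") "right" else "left"]]
  jit_ml_ctrl <- jit[[paste0("ml_", ctrl)]]
  jit_ml_other <- jit[[paste0("ml_", if (ctrl == "left") "right" else "left")]]
  jit_ap_ctrl <- jit[[paste0("ap_", ctrl)]]
  jit_ap_other <- jit[[paste0("ap_", if (ctrl == "left") "right" else "left")]]

  kp <- ctrlp$kp; kd <- ctrlp$kd
  a0 <- config$mean_load_share
  ref_ml0 <- a0 * y_ctrl_c + (1 - a0) * y_other_c
  fb_gain <- if (config$condition == "FB") ctrlp$fb_share_gain else 0

  x_ap <- numeric(n_int); v_ap <- numeric(n_int)
  x_ml <- numeric(n_int); v_ml <- numeric(n_int)
  u_ap_real <- numeric(n_int); u_ml_real <- numeric(n_int)
  share <- numeric(n_int)
  cop_ctrl_ap <- numeric(n_int)
  sat <- 0L
  x_ap[1] <- config$init_offset[1]
  x_ml[1] <- ref_ml0 + config$init_offset[2]
  ref_ml <- ref_ml0
  ap_lo <- lay$ap_lo; ap_hi <- lay$ap_hi; pin_ap <- lay$pin_ap
  bound <- 0.5 # divergence guard (m from the regulated point)

  for (n in seq_len(n_int)) {
    d <- n - dsteps
    if (d < 1L) {
      xd_ap <- x_ap[1]; vd_ap <- 0; xd_ml <- x_ml[1]; vd_ml <- 0
    } else {
      xd_ap <- x_ap[d]; vd_ap <- v_ap[d]
      xd_ml <- x_ml[d]; vd_ml <- v_ml[d]
    }
    # ML: load/unload control through the share
    u_ml_cmd <- ref_ml + kp * (xd_ml - ref_ml) + kd * vd_ml + n_ml[n]
    y_ctrl <- y_ctrl_c + jit_ml_ctrl[n]
    y_other <- y_other_c + jit_ml_other[n]
    a <- (u_ml_cmd - y_other) / (y_ctrl - y_other)
    a <- if (a < 0.05) 0.05 else if (a > 0.95) 0.95 else a
    u_ml <- a * y_ctrl + (1 - a) * y_other
    if (fb_gain > 0) ref_ml <- ref_ml + fb_gain * (a - 0.5) * (y_other_c - y_ctrl_c) * dt
    # AP: within-foot CoP of the controller limb (pin fixed when present)
    u_ap_cmd <- kp * xd_ap + kd * vd_ap + n_ap[n]
    if (pin != "none") {
      raw <- (u_ap_cmd - (1 - a) * pin_ap) / a + jit_ap_ctrl[n]
      cl <- if (raw < ap_lo) ap_lo else if (raw > ap_hi) ap_hi else raw
      if (cl != raw) sat <- sat + 1L
      u_ap <- a * cl + (1 - a) * pin_ap
      cop_ctrl_ap[n] <- cl
    } else {
      uL <- u_ap_cmd + jit_ap_ctrl[n]
      uR <- u_ap_cmd + jit_ap_other[n]
      u_ap <- a * uL + (1 - a) * uR
      cop_ctrl_ap[n] <- uL
    }
    share[n] <- a
    u_ap_real[n] <- u_ap
    u_ml_real[n] <- u_ml
    # semi-implicit Euler
    acc_ap <- g_over_h * (x_ap[n] - u_ap)
    acc_ml <- g_over_h * (x_ml[n] - u_ml)
    if (n < n_int) {
      v_ap[n + 1L] <- v_ap[n] + dt * acc_ap
      x_ap[n + 1L] <- x_ap[n] + dt * v_ap[n + 1L]
      v_ml[n + 1L] <- v_ml[n] + dt * acc_ml
      x_ml[n + 1L] <- x_ml[n] + dt * v_ml[n + 1L]
      if (abs(x_ap[n + 1L]) > bound || abs(x_ml[n + 1L] - ref_ml0) > bound) {
        stop_user("unstable configuration: CoM diverged beyond ", bound,
                  " m at t = ", format((n + 1) * dt, digits = 4),
                  " s (kp = ", kp, ", kd = ", kd, ", delay = ", ctrlp$delay,
                  " s)")
      }
    }
  }

  keep <- seq(1L, n_int, by = os)
  tr_ap <- x_ap[keep]; tr_ml <- x_ml[keep]
  tr_u_ap <- u_ap_real[keep]; tr_u_ml <- u_ml_real[keep]
  tr_share <- share[keep]
  truth_acc_ap <- g_over_h * (tr_ap - tr_u_ap)
  truth_acc_ml <- g_over_h * (tr_ml - tr_u_ml)

  alloc <- allocate_limb_wrenches(
    u_ap = tr_u_ap, u_ml = tr_u_ml, share = tr_share, geometry = geom,
    mass = pend$body_mass, accel_ap = truth_acc_ap, accel_ml = truth_acc_ml,
    gravity = pend$gravity,
    jitter = list(ap_left = jit$ap_left[keep], ap_right = jit$ap_right[keep],
                  ml_left = jit$ml_left[keep], ml_right = jit$ml_right[keep]),
    fs = fs)

  layout <- default_marker_layout(config$body_height, geom$stance_width)
  markers <- generate_marker_set(
    com_ap = tr_ap, com_ml = tr_ml, com_height = pend$com_height,
    body_height = config$body_height, fs = fs, layout = layout,
    support_height = geom$block_height, noise_sd = config$marker_noise_sd)

  roles <- list()
  roles[[if (pin == "none") "right" else pin]] <- "constrained_prosthetic"
  roles[[ctrl]] <- "unconstrained_intact"

  recording <- trial_recording(
    subject_id = config$subject_id, trial_id = config$trial_id,
    group = config$group, condition = config$condition,
    fs = fs, duration = config$duration,
    left_wrench = alloc$left, right_wrench = alloc$right,
    markers = markers, limb_roles = roles,
    support_height = geom$block_height, seed = config$seed)

  truth_com <- structure(
    list(ap = tr_ap, ml = tr_ml,
         vel_ap = v_ap[keep], vel_ml = v_ml[keep],
         acc_ap = truth_acc_ap, acc_ml = truth_acc_ml, fs = fs),
    class = "com_series")
  degenerate <- stats::sd(tr_ap) == 0 && stats::sd(tr_ml) == 0
  if (degenerate) message("degenerate trial: CoM constant throughout")

  structure(list(
    recording = recording,
    truth_com = truth_com,
    truth_total_cop = new_cop_series(tr_u_ap, tr_u_ml,
                                     valid = rep(TRUE, n_out),
                                     reference_height = geom$block_height,
                                     fs = fs),
    truth_cop_left = alloc$cop_left, truth_cop_right = alloc$cop_right,
    truth_share = tr_share,
    saturation_count = sat, degenerate = degenerate,
    config = config), class = "synthetic_trial")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters around `base_config` (documented truncated
#' normal / log-normal jitter; see the methods vignette), then simulates
#' `trials_per_condition` trials in each condition with deterministic
#' per-trial seeds derived from `master_seed` by a counter scheme
#' (`master_seed + subject * 1000 + condition * 100 + trial`).
#'
#' @param base_config A [trial_config()] supplying the group and defaults.
#' @param n_subjects Number of subjects (>= 1).
#' @param trials_per_condition Trials per condition per subject (default 3).
#' @param master_seed Integer master seed.
#' @param conditions Conditions to simulate (default EO, EC, FB).
#' @return List of `synthetic_trial` objects with a `manifest` attribute
#'   (data.frame: subject, condition, trial, seed).
#' @export
make_cohort <- function(base_config, n_subjects = 8,
                        trials_per_condition = 3, master_seed = 1,
                        conditions = c("EO", "EC", "FB")) {
  stopifnot(inherits(base_config, "trial_config"))
  if (n_subjects < 1) stop_user("n_subjects must be >= 1")
  rnorm_clip <- function(mean, sd, lo, hi) clamp(stats::rnorm(1, mean, sd), lo, hi)
  trials <- list()
  manifest <- list()
  for (s in seq_len(n_subjects)) {
    subj_seed <- (master_seed + s * 1000L) %% .Machine$integer.max
    set.seed(subj_seed)
    body_height <- rnorm_clip(1.80, 0.055, 1.65, 1.95)
    body_mass <- rnorm_clip(81, 12, 55, 110)
    kp <- rnorm_clip(base_config$controller$kp, 0.02, 1.04, 1.12)
    kd <- rnorm_clip(base_config$controller$kd, 0.05, 0.25, 0.45)
    delay <- rnorm_clip(base_config$controller$delay, 0.02, 0.10, 0.20)
    # clipped log-normal keeps every subject inside the quiet-stance
    # regime (large draws push rare excursions past the recoverable CoP
    # authority, i.e. the stander falls)
    noise_sd <- clamp(stats::rlnorm(1, log(base_config$controller$noise_sd), 0.2),
                      0.5 * base_config$controller$noise_sd,
                      1.25 * base_config$controller$noise_sd)
    share0 <- if (base_config$group == "AB_free") {
      rnorm_clip(0.5, 0.03, 0.42, 0.58)
    } else {
      rnorm_clip(base_config$mean_load_share, 0.04, 0.52, 0.70)
    }
    subj_id <- sprintf("%s%02d", substr(base_config$group, 1, 2), s)
    pend <- pendulum_params(body_mass = body_mass,
                            com_height = synthetic_com_height(body_height),
                            gravity = base_config$pendulum$gravity)
    ctrl <- controller_params(
      kp = kp, kd = kd, delay = delay, noise_sd = noise_sd,
      noise_cutoff = base_config$controller$noise_cutoff,
      fb_share_gain = base_config$controller$fb_share_gain,
      ec_noise_multiplier = base_config$controller$ec_noise_multiplier,
      within_foot_noise_sd = base_config$controller$within_foot_noise_sd)
    for (ci in seq_along(conditions)) {
      for (t in seq_len(trials_per_condition)) {
        trial_seed <- (master_seed + s * 1000L + ci * 100L + t) %%
          .Machine$integer.max
        # a trial in which the stander "falls" (CoM beyond the
        # recoverable CoP authority) is re-recorded with a derived seed,
        # as a laboratory would repeat a failed quiet-stance trial
        sim <- NULL
        for (attempt in 0:4) {
          cfg <- trial_config(
            duration = base_config$duration, fs = base_config$fs,
            condition = conditions[ci], group = base_config$group,
            mean_load_share = share0,
            seed = (trial_seed + 7919L * attempt) %% .Machine$integer.max,
            pendulum = pend, controller = ctrl,
            geometry = base_config$geometry, body_height = body_height,
            marker_noise_sd = base_config$marker_noise_sd,
            internal_oversample = base_config$internal_oversample,
            subject_id = subj_id,
            trial_id = sprintf("%s_%d", conditions[ci], t))
          sim <- tryCatch(simulate_trial(cfg), pc_user_error = function(e) e)
          if (!inherits(sim, "condition")) break
        }
        if (inherits(sim, "condition")) {
          stop_user("subject ", subj_id, " cannot complete ",
                    conditions[ci], " trial ", t, " (5 falls in a row): ",
                    conditionMessage(sim))
        }
        trials[[length(trials) + 1L]] <- sim
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject_id = subj_id, group = base_config$group,
          condition = conditions[ci], trial = t, seed = sim$config$seed,
          retries = attempt)
      }
    }
  }
  attr(trials, "manifest") <- do.call(rbind, manifest)
  trials
}
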