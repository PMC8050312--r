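# Parameter objects for the sway simulator.
#
# The simulated stander is a single-segment inverted pendulum supported by
# two limbs on parallel force plates. Laboratory frame: x anterior (AP),
# y left (ML), z up, origin on the floor between the plates at the
# anteroposterior equilibrium point of the centre of mass.

#' Inverted-pendulum body parameters
#'
#' @param body_mass Body mass in kg.
#' @param com_height Pendulum length h in m: height of the centre of mass
#'   above the support surface. The small-sway dynamics are
#'   `acc = (g / h) * (com - cop)`.
#' @param gravity Gravitational acceleration in m s^-2.
#' @return A validated `pendulum_params` list.
#' @export
pendulum_params <- function(body_mass = 81, com_height = NULL, gravity = 9.81) {
  com_height <- com_height %||% synthetic_com_height(1.80)
  check_number(body_mass, "body_mass", lower = 0, strict_lower = TRUE)
  check_number(com_height, "com_height", lower = 0, upper = 2.0,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(gravity, "gravity", lower = 0, strict_lower = TRUE)
  structure(list(body_mass = body_mass, com_height = com_height,
                 gravity = gravity), class = "pendulum_params")
}

#' Delayed-PD sway controller parameters
#'
#' The controller limb drives the total centre of pressure with a delayed
#' proportional-derivative law on the centre of mass,
#' `u(t) = kp * x(t - delay) + kd * v(t - delay) + n(t)`,
#' where `n` is exploratory noise: white noise of standard deviation
#' `noise_sd` (at the internal integration rate) passed through a causal
#' second-order low-pass at `noise_cutoff`. The default cutoff of 5 Hz
#' spans the band that quiet-stance centre-of-mass acceleration actually
#' occupies (and that the analysis chain retains); a much narrower band
#' would make sway position and acceleration almost perfectly coherent,
#' which human data contradict. Closed-loop stability of
#' `acc = (g/h) (x - u)` requires `kp > 1`.
#'
#' @param kp Dimensionless proportional gain on delayed CoM position (> 1).
#' @param kd Derivative gain in s on delayed CoM velocity.
#' @param delay Feedback dead time in s.
#' @param noise_sd SD in m of the exploratory CoP noise before low-pass
#'   (specified at the internal integration rate; see the methods vignette).
#' @param noise_cutoff Low-pass cutoff in Hz applied to the noise.
#' @param fb_share_gain Integral gain in s^-1 pulling the inter-limb load
#'   share towards 0.5; active only in the FB condition.
#' @param ec_noise_multiplier Noise inflation factor (> 1) applied in the
#'   eyes-closed condition.
#' @param within_foot_noise_sd SD in m of within-foot per-limb CoP jitter
#'   before its 10 Hz low-pass; forced to zero on a pinned limb.
#' @return A validated `controller_params` list.
#' @export
controller_params <- function(kp = 1.06, kd = 0.35, delay = 0.15,
                              noise_sd = 0.03, noise_cutoff = 5,
                              fb_share_gain = 0.1, ec_noise_multiplier = 1.5,
                              within_foot_noise_sd = 5e-4) {
  check_number(kp, "kp", lower = 1, strict_lower = TRUE)
  check_number(kd, "kd", lower = 0)
  check_number(delay, "delay", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(noise_cutoff, "noise_cutoff", lower = 0, strict_lower = TRUE)
  check_number(fb_share_gain, "fb_share_gain", lower = 0)
  check_number(ec_noise_multiplier, "ec_noise_multiplier", lower = 1)
  check_number(within_foot_noise_sd, "within_foot_noise_sd", lower = 0)
  structure(list(kp = kp, kd = kd, delay = delay, noise_sd = noise_sd,
                 noise_cutoff = noise_cutoff, fb_share_gain = fb_share_gain,
                 ec_noise_multiplier = ec_noise_multiplier,
                 within_foot_noise_sd = within_foot_noise_sd),
            class = "controller_params")
}

#' Stance geometry and pin placement
#'
#' Feet are modelled as anteroposterior segments with the ankle 25% of the
#' foot length from the heel. A pinned limb contributes a fixed centre of
#' pressure at `pin_fraction` of the ankle-to-fifth-metatarsal distance
#' anterior of the ankle joint centre (default 66%, matching the anterior
#' CoP shift reported under prosthetic feet).
#'
#' @param stance_width Mediolateral distance between foot centres in m.
#' @param foot_length Foot length in m.
#' @param ankle_to_met5 Ankle joint centre to distal head of the 5th
#'   metatarsal, in m.
#' @param pin_fraction Fraction (0..1) of `ankle_to_met5` at which the pin
#'   axis sits anterior of the ankle.
#' @param pin_side `"left"`, `"right"`, or `"none"` (no constrained limb).
#' @param block_height Height in m of the constraint device / matching
#'   block interposed between foot and force plate (0 = foot on plate).
#' @param ankle_offset_ap Anteroposterior position of the ankle joint line
#'   in the laboratory frame, in m (negative = posterior of the CoM
#'   equilibrium).
#' @return A validated `stance_geometry` list.
#' @export
stance_geometry <- function(stance_width = 0.25, foot_length = 0.25,
                            ankle_to_met5 = 0.15, pin_fraction = 0.66,
                            pin_side = "left", block_height = 0,
                            ankle_offset_ap = -0.06) {
  check_number(stance_width, "stance_width", lower = 0, strict_lower = TRUE)
  check_number(foot_length, "foot_length", lower = 0, strict_lower = TRUE)
  check_number(ankle_to_met5, "ankle_to_met5", lower = 0, strict_lower = TRUE)
  check_number(pin_fraction, "pin_fraction", lower = 0, upper = 1)
  check_choice(pin_side, "pin_side", c("left", "right", "none"))
  check_number(block_height, "block_height", lower = 0)
  check_number(ankle_offset_ap, "ankle_offset_ap")
  g <- structure(list(stance_width = stance_width, foot_length = foot_length,
                      ankle_to_met5 = ankle_to_met5,
                      pin_fraction = pin_fraction, pin_side = pin_side,
                      block_height = block_height,
                      ankle_offset_ap = ankle_offset_ap),
                 class = "stance_geometry")
  b <- foot_ap_bounds(g)
  pin_rel <- pin_fraction * ankle_to_met5
  if (pin_side != "none" && (pin_rel < b$heel_rel || pin_rel > b$toe_rel)) {
    stop_user("pin CoP (", format(pin_rel), " m anterior of ankle) lies ",
              "outside the foot bounds [", format(b$heel_rel), ", ",
              format(b$toe_rel), "]")
  }
  g
}

# anteroposterior foot bounds relative to the ankle joint (ankle at 25% of
# foot length from the heel)
foot_ap_bounds <- function(geometry) {
  list(heel_rel = -0.25 * geometry$foot_length,
       toe_rel = 0.75 * geometry$foot_length)
}

#' Full configuration of one synthetic quiet-standing trial
#'
#' @param duration Trial duration in s (default 60).
#' @param fs Output sampling rate in Hz (default 100).
#' @param condition `"EO"` (eyes open), `"EC"` (eyes closed; exploratory
#'   noise inflated by `ec_noise_multiplier`), or `"FB"` (weight-bearing
#'   feedback; slow integral regulation of the load share towards 0.5).
#' @param group `"TPU"` (prosthesis-user mode, pinned limb),
#'   `"AB_constrained"` (able-bodied with mechanical pin device, elevated
#'   by `block_height`), or `"AB_free"` (no constraint).
#' @param mean_load_share Habitual fraction of body weight on the
#'   unconstrained/intact limb (0..1 exclusive).
#' @param seed Integer seed; identical config + seed reproduces the trial
#'   bit for bit.
#' @param pendulum,controller,geometry Component parameter objects.
#' @param body_height Stature in m (used for the synthetic marker layout).
#' @param marker_noise_sd SD in m of independent Gaussian marker noise.
#' @param init_offset Length-2 numeric `c(ap, ml)` initial CoM offset from
#'   equilibrium in m (default zero: noise excites the sway).
#' @param internal_oversample Internal integration runs at
#'   `fs * internal_oversample` (default 10, i.e. 1000 Hz) and is decimated
#'   to `fs`.
#' @param subject_id,trial_id Metadata labels carried through the analysis.
#' @return A validated `trial_config` list.
#' @export
trial_config <- function(duration = 60, fs = 100, condition = "EO",
                         group = "TPU", mean_load_share = 0.6, seed = 1,
                         pendulum = pendulum_params(),
                         controller = controller_params(),
                         geometry = stance_geometry(),
                         body_height = 1.80, marker_noise_sd = 3e-4,
                         init_offset = c(0, 0), internal_oversample = 10,
                         subject_id = "S01", trial_id = "T01") {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) {
    stop_user("duration * fs must be an integer sample count")
  }
  check_choice(condition, "condition", c("EO", "EC", "FB"))
  check_choice(group, "group", c("TPU", "AB_constrained", "AB_free"))
  check_number(mean_load_share, "mean_load_share", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(seed, "seed")
  stopifnot(inherits(pendulum, "pendulum_params"),
            inherits(controller, "controller_params"),
            inherits(geometry, "stance_geometry"))
  check_number(body_height, "body_height", lower = 1.2, upper = 2.2)
  check_number(marker_noise_sd, "marker_noise_sd", lower = 0)
  if (length(init_offset) != 2L || !all(is.finite(init_offset))) {
    stop_user("init_offset must be two finite numbers c(ap, ml)")
  }
  check_number(internal_oversample, "internal_oversample", lower = 1)
  if (group %in% c("TPU", "AB_constrained") && geometry$pin_side == "none") {
    stop_user("group ", group, " requires a pinned limb (geometry$pin_side)")
  }
  if (group == "AB_free" && geometry$pin_side != "none") {
    stop_user("group AB_free requires geometry$pin_side = 'none'")
  }
  structure(list(duration = duration, fs = fs, condition = condition,
                 group = group, mean_load_share = mean_load_share,
                 seed = as.integer(seed), pendulum = pendulum,
                 controller = controller, geometry = geometry,
                 body_height = body_height,
                 marker_noise_sd = marker_noise_sd,
                 init_offset = as.numeric(init_offset),
                 internal_oversample = as.integer(internal_oversample),
                 subject_id = subject_id, trial_id = trial_id),
            class = "trial_config")
}

#' Default reduced synthetic marker layout
#'
#' A sagittal "stick body" of 18 markers spanning toe to vertex, with
#' left/right pairs offset mediolaterally. Heights are fractions of body
#' height; anteroposterior offsets are zero so the mass-weighted segmental
#' centre of mass coincides exactly with the pendulum centre of mass (the
#' full 69-marker set of a laboratory protocol is supported by
#' [segmental_com()] but not required by the generator).
#'
#' @param body_height Stature in m.
#' @param stance_width Mediolateral distance between the feet in m.
#' @return data.frame with columns `label`, `height_frac`, `ap_offset`,
#'   `ml_offset` (offsets in m).
#' @export
default_marker_layout <- function(body_height = 1.80, stance_width = 0.25) {
  half <- stance_width / 2
  central <- data.frame(
    label = c("vertex", "c7", "sacrum", "midhip"),
    height_frac = c(1.000, 0.870, 0.600, 0.530),
    ml_offset = 0
  )
  pairs <- data.frame(
    base = c("shoulder", "elbow", "wrist", "hip", "knee", "ankle", "toe"),
    height_frac = c(0.818, 0.630, 0.485, 0.530, 0.285, 0.039, 0.000),
    ml_offset = c(0.18, 0.21, 0.22, 0.09, 0.12, half, half)
  )
  sided <- do.call(rbind, lapply(c("L", "R"), function(s) {
    sgn <- if (s == "L") 1 else -1
    data.frame(label = paste0(pairs$base, "_", s),
               height_frac = pairs$height_frac,
               ml_offset = sgn * pairs$ml_offset)
  }))
  out <- rbind(central, sided)
  out$ap_offset <- 0
  out[, c("label", "height_frac", "ap_offset", "ml_offset")]
}

#' Default 13-segment anthropometric table
#'
#' Segment mass fractions and longitudinal centre-of-mass fractions in the
#' style of standard cadaver-derived tables (de Leva-type male values,
#' hands merged into the forearms), keyed to the reduced synthetic marker
#' layout. `com_fraction` is measured from the proximal marker towards the
#' distal marker.
#'
#' @return data.frame with columns `segment`, `mass_fraction`,
#'   `com_fraction`, `proximal`, `distal`; mass fractions sum to 1.
#' @export
default_anthropometric_table <- function() {
  tab <- data.frame(
    segment = c("head", "thorax_abdomen", "pelvis",
                "thigh_L", "thigh_R", "shank_L", "shank_R",
                "foot_L", "foot_R", "upperarm_L", "upperarm_R",
                "forearmhand_L", "forearmhand_R"),
    mass_fraction = c(0.0694, 0.3229, 0.1117,
                      0.1416, 0.1416, 0.0433, 0.0433,
                      0.0137, 0.0137, 0.0271, 0.0271,
                      0.0223, 0.0223),
    com_fraction = c(0.5, 0.5, 0.5,
                     0.433, 0.433, 0.433, 0.433,
                     0.5, 0.5, 0.436, 0.436,
                     0.600, 0.600),
    proximal = c("vertex", "c7", "sacrum",
                 "hip_L", "hip_R", "knee_L", "knee_R",
                 "ankle_L", "ankle_R", "shoulder_L", "shoulder_R",
                 "elbow_L", "elbow_R"),
    distal = c("c7", "sacrum", "midhip",
               "knee_L", "knee_R", "ankle_L", "ankle_R",
               "toe_L", "toe_R", "elbow_L", "elbow_R",
               "wrist_L", "wrist_R")
  )
  stopifnot(abs(sum(tab$mass_fraction) - 1) < 1e-6)
  tab
}

#' Centre-of-mass height implied by the synthetic body
#'
#' Mass-weighted mean height of the default segmental model, used as the
#' default pendulum length so that segmental CoM estimation on noiseless
#' synthetic markers recovers the true pendulum CoM exactly.
#'
#' @param body_height Stature in m.
#' @param layout Marker layout (default [default_marker_layout()]).
#' @param table Anthropometric table
#'   (default [default_anthropometric_table()]).
#' @return CoM height above the support surface in m.
#' @export
synthetic_com_height <- function(body_height = 1.80,
                                 layout = default_marker_layout(body_height),
                                 table = default_anthropometric_table()) {
  h <- stats::setNames(layout$height_frac, layout$label)
  seg_h <- h[table$proximal] +
    table$com_fraction * (h[table$distal] - h[table$proximal])
  as.numeric(sum(table$mass_fraction * seg_h)) * body_height
}
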