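# Inverted-pendulum correlation statistics and their aggregation.
#
# Model conformance is scored with Pearson's r. Kinetic definition:
# r between d(t) = CoP(t) - CoM(t) and the CoM horizontal acceleration;
# under pure pendulum dynamics acc = (g/h)(CoM - CoP) this r is exactly
# -1, so negative r denotes conformance (matching the reported sign
# convention). Kinematic definition: r across markers between mean height
# above the support surface and total linear movement; rigid-pendulum
# motion makes movement proportional to height, r = +1.

result_row <- function(r, n, direction, limb, definition, condition,
                       subject_id, trial_id, group) {
  data.frame(r = r, n_samples = n, direction = direction, limb = limb,
             definition = definition, condition = condition,
             subject_id = subject_id, trial_id = trial_id, group = group,
             stringsAsFactors = FALSE)
}

#' Kinetic inverted-pendulum correlation
#'
#' Pearson r between the CoP-CoM difference and the CoM horizontal
#' acceleration over the jointly valid samples of a trial.
#'
#' @param cop A `cop_series` (per-limb or combined).
#' @param com A `com_series` (positions + accelerations).
#' @param direction `"AP"` or `"ML"`.
#' @param limb Limb role label: `"constrained_prosthetic"`,
#'   `"unconstrained_intact"`, or `"total"`.
#' @param condition,subject_id,trial_id,group Metadata carried into the
#'   result.
#' @return One-row data.frame (`r`, `n_samples`, plus metadata).
#' @export
kinetic_ip_corr <- function(cop, com, direction = c("AP", "ML"),
                            limb = "total", condition = NA_character_,
                            subject_id = NA_character_,
                            trial_id = NA_character_,
                            group = NA_character_) {
  stopifnot(inherits(cop, "cop_series"), inherits(com, "com_series"))
  direction <- match.arg(direction)
  cop_h <- if (direction == "AP") cop$x else cop$y
  com_h <- if (direction == "AP") com$ap else com$ml
  acc <- if (direction == "AP") com$acc_ap else com$acc_ml
  if (length(cop_h) != length(com_h)) {
    stop_user("CoP and CoM series are not aligned (different lengths)")
  }
  ok <- cop$valid & is.finite(com_h) & is.finite(acc)
  if (sum(ok) < 3L) stop_user("fewer than 3 jointly valid samples")
  d <- cop_h[ok] - com_h[ok]
  a <- acc[ok]
  if (stats::sd(d) == 0 || stats::sd(a) == 0) {
    stop_user("degenerate trial: zero variance in ",
              if (stats::sd(d) == 0) "CoP-CoM difference" else "acceleration")
  }
  result_row(stats::cor(d, a), sum(ok), direction, limb, "kinetic",
             condition, subject_id, trial_id, group)
}

#' Kinematic inverted-pendulum correlation
#'
#' Pearson r across markers between mean height above the support surface
#' and total linear movement in one direction.
#'
#' @param height_movement data.frame with columns `mean_height` and
#'   `movement`, one row per marker (see [marker_height_excursion()]).
#' @inheritParams kinetic_ip_corr
#' @return One-row data.frame (`r`, `n_samples` = marker count, metadata).
#' @export
kinematic_ip_corr <- function(height_movement, direction = c("AP", "ML"),
                              condition = NA_character_,
                              subject_id = NA_character_,
                              trial_id = NA_character_,
                              group = NA_character_) {
  direction <- match.arg(direction)
  h <- height_movement$mean_height
  m <- height_movement$movement
  if (length(h) < 3L) stop_user("fewer than 3 markers")
  if (stats::sd(h) == 0) stop_user("degenerate: all marker heights equal")
  if (stats::sd(m) == 0) {
    stop_user("degenerate: all marker movements equal (pure translation)")
  }
  result_row(stats::cor(h, m), length(h), direction, NA_character_,
             "kinematic", condition, subject_id, trial_id, group)
}

#' Fisher-z aggregation of correlation coefficients
#'
#' Variance-stabilizing aggregation: each r is transformed with
#' `z = atanh(r)`, the mean and a t-based 95% CI (`k - 1` df) are formed on
#' the z scale, and all three are back-transformed with `tanh`. With a
#' single value the CI is undefined (returned as `NA`). Values with
#' `|r| = 1` are clamped to `1 - 1e-9` with a warning.
#'
#' @param rs Numeric vector of correlation coefficients in `[-1, 1]`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean_r`, `ci_low`, `ci_high`, `k` (all back on the r
#'   scale).
#' @export
fisher_aggregate <- function(rs, conf_level = 0.95) {
  if (length(rs) == 0L) stop_user("empty input to fisher_aggregate")
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) {
    stop_user("correlations must be finite and within [-1, 1]")
  }
  if (any(abs(rs) == 1)) {
    warning("|r| = 1 clamped to 1 - 1e-9 before the Fisher transform")
    rs <- sign(rs) * pmin(abs(rs), 1 - 1e-9)
  }
  z <- atanh(rs)
  k <- length(z)
  mz <- mean(z)
  if (k == 1L) {
    return(list(mean_r = tanh(mz), ci_low = NA_real_, ci_high = NA_real_,
                k = 1L))
  }
  half <- stats::qt(1 - (1 - conf_level) / 2, df = k - 1) *
    stats::sd(z) / sqrt(k)
  list(mean_r = tanh(mz), ci_low = tanh(mz - half),
       ci_high = tanh(mz + half), k = k)
}

#' Group summary of correlation results
#'
#' Aggregates trial-level correlations into a summary in the layout of a
#' direction x group x limb x condition table of back-transformed means
#' with 95% CIs. Two-stage aggregation (default): within each subject and
#' cell, the trial r's are averaged on the Fisher-z scale; the subject
#' means are then aggregated across subjects with [fisher_aggregate()].
#' Single-stage pools all trial r's directly. Kinetic cells span 2
#' directions x groups x 3 limbs x 3 conditions; kinematic cells have no
#' limb factor. Empty cells are reported as `NA` rows with a warning, not
#' dropped.
#'
#' @param results data.frame of trial-level results as produced by
#'   [kinetic_ip_corr()] / [kinematic_ip_corr()] / [analyze_trial()].
#' @param two_stage Average trials within subject on the z scale first
#'   (default `TRUE`).
#' @param conf_level Confidence level for the CIs.
#' @return data.frame of class `summary_table`: `definition`, `direction`,
#'   `group`, `limb`, `condition`, `mean_r`, `ci_low`, `ci_high`,
#'   `n_subjects`.
#' @export
summary_table <- function(results, two_stage = TRUE, conf_level = 0.95) {
  needed <- c("r", "direction", "limb", "definition", "condition",
              "subject_id", "group")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop_user("results lack column(s): ", paste(missing, collapse = ", "))
  }
  # CSV round trips turn the kinematic rows' absent limb into ""
  results$limb[!is.na(results$limb) & results$limb == ""] <- NA_character_
  if (any(is.na(results$condition)) || any(is.na(results$subject_id)) ||
      any(is.na(results$group))) {
    stop_user("every result must carry complete grouping metadata ",
              "(condition, subject_id, group)")
  }
  groups <- unique(results$group)
  limbs <- c("unconstrained_intact", "constrained_prosthetic", "total")
  conditions <- c("EC", "EO", "FB")
  grid_kin <- expand.grid(definition = "kinetic", direction = c("AP", "ML"),
                          group = groups, limb = limbs,
                          condition = conditions, stringsAsFactors = FALSE)
  grid_kim <- expand.grid(definition = "kinematic",
                          direction = c("AP", "ML"), group = groups,
                          limb = NA_character_, condition = conditions,
                          stringsAsFactors = FALSE)
  grid <- rbind(grid_kin, grid_kim)
  # Table-2 style row order: AP before ML, intact / pros / total
  grid <- grid[order(grid$definition, grid$direction,
                     match(grid$limb, limbs), grid$group,
                     match(grid$condition, conditions)), ]
  agg_cell <- function(def, dir, grp, limb, cond) {
    sel <- results$definition == def & results$direction == dir &
      results$group == grp & results$condition == cond &
      (if (is.na(limb)) is.na(results$limb) else
         !is.na(results$limb) & results$limb == limb)
    sub <- results[sel, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (two_stage) {
      zs <- tapply(atanh(clamp(sub$r, -1 + 1e-9, 1 - 1e-9)),
                   sub$subject_id, mean)
      fisher_aggregate(tanh(as.numeric(zs)), conf_level = conf_level)
    } else {
      res <- fisher_aggregate(sub$r, conf_level = conf_level)
      res$k <- length(unique(sub$subject_id))
      res
    }
  }
  out <- grid
  out$mean_r <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  out$n_subjects <- 0L
  empty <- character()
  for (i in seq_len(nrow(out))) {
    res <- agg_cell(out$definition[i], out$direction[i], out$group[i],
                    out$limb[i], out$condition[i])
    if (is.null(res)) {
      empty <- c(empty, paste(out$definition[i], out$direction[i],
                              out$group[i], out$limb[i], out$condition[i],
                              sep = "/"))
      next
    }
    out$mean_r[i] <- res$mean_r
    out$ci_low[i] <- res$ci_low
    out$ci_high[i] <- res$ci_high
    out$n_subjects[i] <- res$k
  }
  if (length(empty)) {
    warning("empty summary cells: ", paste(empty, collapse = "; "))
  }
  rownames(out) <- NULL
  class(out) <- c("summary_table", "data.frame")
  out
}
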