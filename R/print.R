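#' @export
print.synthetic_trial <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synthetic_trial> %s %s %s | %g s @ %g Hz | seed %d\n",
              cfg$group, cfg$condition, cfg$subject_id, cfg$duration,
              cfg$fs, cfg$seed))
  cat(sprintf("  pin: %s | mean load share %.3f | CoM SD AP %.1f mm, ML %.1f mm\n",
              cfg$geometry$pin_side, mean(x$truth_share),
              1000 * stats::sd(x$truth_com$ap),
              1000 * stats::sd(x$truth_com$ml)))
  if (x$saturation_count > 0) {
    cat("  within-foot CoP saturation events:", x$saturation_count, "\n")
  }
  if (x$degenerate) cat("  (degenerate: constant trial)\n")
  invisible(x)
}

#' @export
print.summary_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$limb[is.na(y$limb)] <- "-"
  for (col in c("mean_r", "ci_low", "ci_high")) y[[col]] <- round(y[[col]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s %s/%s | %g s @ %g Hz | %d markers\n",
              x$group, x$condition, x$subject_id, x$trial_id, x$duration,
              x$fs, length(x$markers$labels)))
  cat(sprintf("  limb roles: left = %s, right = %s | support height %.3f m\n",
              x$limb_roles$left, x$limb_roles$right, x$support_height))
  invisible(x)
}
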