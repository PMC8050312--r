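# Whole-body centre of mass from markers, differentiation, and marker
# height/excursion statistics for the kinematic inverted-pendulum test.

#' Labelled 3-D marker trajectories
#'
#' @param labels Character vector of marker labels (length m).
#' @param x,y,z n-by-m numeric matrices of marker coordinates in m
#'   (laboratory frame: x anterior, y left, z up from the floor). `NA`
#'   entries mark gaps.
#' @param fs Sampling rate in Hz.
#' @return A `marker_set` object.
#' @export
marker_set <- function(labels, x, y, z, fs) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  m <- length(labels)
  if (ncol(x) != m || ncol(y) != m || ncol(z) != m) {
    stop_user("coordinate matrices must have one column per label")
  }
  if (nrow(x) != nrow(y) || nrow(x) != nrow(z)) {
    stop_user("coordinate matrices have different sample counts")
  }
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  colnames(x) <- colnames(y) <- colnames(z) <- labels
  structure(list(labels = labels, x = x, y = y, z = z, fs = fs),
            class = "marker_set")
}

# linear interpolation of NA gaps up to max_gap consecutive samples
fill_gaps <- function(v, max_gap, label) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  runs <- r$lengths[r$values]
  if (any(runs > max_gap)) {
    stop_user("marker '", label, "' has a gap of ", max(runs),
              " samples (longest allowed: ", max_gap, ")")
  }
  idx <- which(!is.na(v))
  if (length(idx) < 2L) stop_user("marker '", label, "' is almost entirely missing")
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Segmental whole-body centre of mass
#'
#' Anthropometric CoM estimate
#' `CoM = sum_s massfrac_s * (proximal_s + comfrac_s * (distal_s - proximal_s))`
#' over the segments of `table`. Gaps up to `max_gap` samples are linearly
#' interpolated; longer gaps and missing segment markers are errors.
#'
#' @param markers A [marker_set()].
#' @param table Anthropometric table (default
#'   [default_anthropometric_table()]): columns `segment`, `mass_fraction`,
#'   `com_fraction`, `proximal`, `distal`.
#' @param max_gap Longest interpolatable gap in samples (default 10).
#' @return List of class `com_position` with numeric vectors `ap`, `ml`,
#'   `z` (m) and `fs`.
#' @export
segmental_com <- function(markers, table = default_anthropometric_table(),
                          max_gap = 10) {
  stopifnot(inherits(markers, "marker_set"))
  if (abs(sum(table$mass_fraction) - 1) > 1e-6) {
    stop_user("anthropometric mass fractions must sum to 1")
  }
  need <- unique(c(table$proximal, table$distal))
  missing <- setdiff(need, markers$labels)
  if (length(missing)) {
    seg <- table$segment[table$proximal %in% missing |
                           table$distal %in% missing][1]
    stop_user("missing marker(s) ", paste(missing, collapse = ", "),
              " required by segment '", seg, "'")
  }
  n <- nrow(markers$x)
  acc <- list(ap = numeric(n), ml = numeric(n), z = numeric(n))
  axes <- c(ap = "x", ml = "y", z = "z")
  cleaned <- list()
  get_clean <- function(axis, lab) {
    key <- paste(axis, lab)
    if (is.null(cleaned[[key]])) {
      cleaned[[key]] <<- fill_gaps(markers[[axis]][, lab], max_gap, lab)
    }
    cleaned[[key]]
  }
  for (i in seq_len(nrow(table))) {
    mf <- table$mass_fraction[i]; cf <- table$com_fraction[i]
    for (ax in names(axes)) {
      p <- get_clean(axes[[ax]], table$proximal[i])
      d <- get_clean(axes[[ax]], table$distal[i])
      acc[[ax]] <- acc[[ax]] + mf * (p + cf * (d - p))
    }
  }
  structure(c(acc, list(fs = markers$fs)), class = "com_position")
}

#' Horizontal CoM acceleration by filtered double differentiation
#'
#' Low-passes the position series (zero-phase Butterworth, default 5 Hz,
#' order 4) and applies a central second difference; the two endpoint
#' samples use one-sided second-order stencils. Filter settings are
#' recorded as attributes.
#'
#' @param pos Numeric position series in m.
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass cutoff in Hz before differentiation (default 5).
#' @param order Butterworth order (default 4).
#' @return Acceleration series in m s^-2, same length as `pos`, with
#'   attributes `cutoff` and `order`.
#' @export
com_acceleration <- function(pos, fs, cutoff = 5, order = 4) {
  if (length(pos) < 5L) stop_user("position series too short (need >= 5 samples)")
  xf <- lowpass(pos, cutoff = cutoff, fs = fs, order = order)
  n <- length(xf)
  acc <- numeric(n)
  acc[2:(n - 1)] <- (xf[3:n] - 2 * xf[2:(n - 1)] + xf[1:(n - 2)]) * fs^2
  acc[1] <- (2 * xf[1] - 5 * xf[2] + 4 * xf[3] - xf[4]) * fs^2
  acc[n] <- (2 * xf[n] - 5 * xf[n - 1] + 4 * xf[n - 2] - xf[n - 3]) * fs^2
  attr(acc, "cutoff") <- cutoff
  attr(acc, "order") <- order
  acc
}

#' Full CoM kinematics (position, velocity, acceleration)
#'
#' Convenience wrapper producing the `com_series` consumed by the kinetic
#' correlation: horizontal positions plus filtered first and second
#' derivatives.
#'
#' @param ap,ml Horizontal CoM position series in m.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff in Hz for the pre-differentiation low-pass.
#' @return List of class `com_series` with `ap`, `ml` (positions),
#'   `vel_ap`, `vel_ml`, `acc_ap`, `acc_ml`, `fs`.
#' @export
com_series <- function(ap, ml, fs, cutoff = 5) {
  n <- length(ap)
  if (length(ml) != n) stop_user("ap and ml series have different lengths")
  d1 <- function(x) {
    v <- numeric(n)
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
    v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) * fs / 2
    v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) * fs / 2
    v
  }
  structure(list(ap = ap, ml = ml,
                 vel_ap = d1(lowpass(ap, cutoff, fs)),
                 vel_ml = d1(lowpass(ml, cutoff, fs)),
                 acc_ap = com_acceleration(ap, fs, cutoff = cutoff),
                 acc_ml = com_acceleration(ml, fs, cutoff = cutoff),
                 fs = fs, cutoff = cutoff),
            class = "com_series")
}

#' Per-marker mean height and total linear movement
#'
#' For each marker: time-mean of its height above the support surface, and
#' its total linear movement in the stated horizontal direction, defined as
#' the 1-D path length `sum(|diff(position)|)` (option `"range"` gives the
#' peak-to-peak excursion instead).
#'
#' @param markers A [marker_set()].
#' @param direction `"AP"` or `"ML"`.
#' @param support_height Height of the support surface above the floor in m
#'   (subtracted from marker heights).
#' @param movement `"path"` (default) or `"range"`.
#' @return data.frame with columns `label`, `mean_height` (m),
#'   `movement` (m).
#' @export
marker_height_excursion <- function(markers, direction = c("AP", "ML"),
                                    support_height = 0,
                                    movement = c("path", "range")) {
  stopifnot(inherits(markers, "marker_set"))
  direction <- match.arg(direction)
  movement <- match.arg(movement)
  if (length(markers$labels) < 3L) {
    stop_user("need at least 3 markers (correlation undefined below that)")
  }
  horiz <- if (direction == "AP") markers$x else markers$y
  mv <- apply(horiz, 2, function(v) {
    if (movement == "path") sum(abs(diff(v))) else diff(range(v))
  })
  data.frame(label = markers$labels,
             mean_height = colMeans(markers$z) - support_height,
             movement = as.numeric(mv), row.names = NULL)
}
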