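# Canonical trial file format: one CSV per trial (time, per-plate
# Fx..Mz, marker x/y/z columns) plus a JSON sidecar carrying metadata and
# units. Inspectable and diff-able by design.

SCHEMA_VERSION <- "1.0"
PLATE_COLS <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")

#' One recorded quiet-standing trial
#'
#' @param subject_id,trial_id,group,condition Metadata labels.
#' @param fs Sampling rate in Hz.
#' @param duration Trial duration in s.
#' @param left_wrench,right_wrench Per-plate [plate_wrench()]s.
#' @param markers A [marker_set()] (may have zero markers).
#' @param limb_roles Named list mapping `left` / `right` to
#'   `"constrained_prosthetic"` / `"unconstrained_intact"` (exactly one
#'   side per role).
#' @param support_height Height in m of the common support surface above
#'   the plate surfaces (0 when the feet stand directly on the plates).
#' @param seed Generator seed (NA for measured data).
#' @return A validated `trial_recording`.
#' @export
trial_recording <- function(subject_id, trial_id, group, condition, fs,
                            duration, left_wrench, right_wrench, markers,
                            limb_roles, support_height = 0, seed = NA) {
  stopifnot(inherits(left_wrench, "plate_wrench"),
            inherits(right_wrench, "plate_wrench"),
            inherits(markers, "marker_set"))
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- nrow(left_wrench$force)
  if (nrow(right_wrench$force) != n ||
      (length(markers$labels) > 0 && nrow(markers$x) != n)) {
    stop_user("wrench and marker series must share the sample count")
  }
  roles <- unlist(limb_roles[c("left", "right")])
  if (!setequal(roles, c("constrained_prosthetic", "unconstrained_intact"))) {
    stop_user("limb_roles must assign exactly one side to each of ",
              "'constrained_prosthetic' and 'unconstrained_intact'")
  }
  structure(list(subject_id = subject_id, trial_id = trial_id,
                 group = group, condition = condition, fs = fs,
                 duration = duration, left_wrench = left_wrench,
                 right_wrench = right_wrench, markers = markers,
                 limb_roles = as.list(limb_roles),
                 support_height = support_height, seed = seed),
            class = "trial_recording")
}

#' Write a trial to CSV + JSON sidecar
#'
#' Writes `<stem>.csv` (one row per sample: `time`, `left_Fx` ..
#' `right_Mz`, `<label>_x/_y/_z`) and `<stem>.json` (schema version,
#' units, metadata, seed, package version). Numbers are written with 17
#' significant digits so a read round-trip is exact to double precision.
#'
#' @param recording A [trial_recording()].
#' @param stem Output path without extension.
#' @return Invisibly, the CSV path.
#' @export
write_trial <- function(recording, stem) {
  stopifnot(inherits(recording, "trial_recording"))
  n <- nrow(recording$left_wrench$force)
  cols <- list(time = (seq_len(n) - 1) / recording$fs)
  for (side in c("left", "right")) {
    w <- recording[[paste0(side, "_wrench")]]
    mat <- cbind(w$force, w$moment)
    for (j in seq_along(PLATE_COLS)) {
      cols[[paste0(side, "_", PLATE_COLS[j])]] <- mat[, j]
    }
  }
  mk <- recording$markers
  for (lab in mk$labels) {
    cols[[paste0(lab, "_x")]] <- mk$x[, lab]
    cols[[paste0(lab, "_y")]] <- mk$y[, lab]
    cols[[paste0(lab, "_z")]] <- mk$z[, lab]
  }
  dt <- data.table::as.data.table(cols)
  csv <- paste0(stem, ".csv")
  dir.create(dirname(csv), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    data.table::fwrite(dt, csv, scipen = 0)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_user("cannot write ", csv)
  meta <- list(
    schema_version = SCHEMA_VERSION,
    units = list(length = "m", force = "N", moment = "N.m", time = "s"),
    subject_id = recording$subject_id, trial_id = recording$trial_id,
    group = recording$group, condition = recording$condition,
    fs = recording$fs, duration = recording$duration,
    n_samples = n,
    limb_roles = recording$limb_roles,
    surface_height = list(left = recording$left_wrench$surface_height,
                          right = recording$right_wrench$surface_height),
    support_height = recording$support_height,
    marker_labels = as.list(mk$labels),
    seed = if (is.na(recording$seed)) NULL else recording$seed,
    software = paste0("pincontrol ",
                      as.character(utils::packageVersion("pincontrol"))))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(csv)
}

#' Read a trial written by [write_trial()]
#'
#' Validates schema version, units and column presence; errors name the
#' missing column or mismatched unit.
#'
#' @param stem Path without extension (or the `.csv` path).
#' @return A [trial_recording()].
#' @export
read_trial <- function(stem) {
  stem <- sub("\\.csv$", "", stem)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  if (!file.exists(csv)) stop_user("file not found: ", csv)
  if (!file.exists(js)) stop_user("sidecar not found: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION)) {
    stop_user("unrecognized schema version '", meta$schema_version, "'")
  }
  expected_units <- c(length = "m", force = "N", moment = "N.m")
  for (u in names(expected_units)) {
    if (!identical(meta$units[[u]], expected_units[[u]])) {
      stop_user("unit mismatch for ", u, ": file declares '",
                meta$units[[u]], "', expected '", expected_units[[u]], "'")
    }
  }
  dt <- data.table::fread(csv)
  need <- c("time",
            paste0("left_", PLATE_COLS), paste0("right_", PLATE_COLS))
  labs <- as.character(unlist(meta$marker_labels %||% character()))
  need_mk <- as.vector(t(outer(labs, c("_x", "_y", "_z"), paste0)))
  missing <- setdiff(c(need, need_mk), names(dt))
  if (length(missing)) {
    stop_user("missing column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(dt)
  if (!is.null(meta$n_samples) && n != meta$n_samples) {
    stop_user("ragged file: ", n, " rows, sidecar declares ", meta$n_samples)
  }
  get_w <- function(side) {
    mat <- as.matrix(dt[, paste0(side, "_", PLATE_COLS), with = FALSE])
    plate_wrench(mat[, 1:3], mat[, 4:6], fs = meta$fs,
                 surface_height = meta$surface_height[[side]])
  }
  mk <- if (length(labs)) {
    marker_set(labs,
               as.matrix(dt[, paste0(labs, "_x"), with = FALSE]),
               as.matrix(dt[, paste0(labs, "_y"), with = FALSE]),
               as.matrix(dt[, paste0(labs, "_z"), with = FALSE]),
               fs = meta$fs)
  } else {
    marker_set(character(), matrix(0, n, 0), matrix(0, n, 0),
               matrix(0, n, 0), fs = meta$fs)
  }
  trial_recording(subject_id = meta$subject_id, trial_id = meta$trial_id,
                  group = meta$group, condition = meta$condition,
                  fs = meta$fs, duration = meta$duration,
                  left_wrench = get_w("left"), right_wrench = get_w("right"),
                  markers = mk, limb_roles = as.list(meta$limb_roles),
                  support_height = meta$support_height,
                  seed = meta$seed %||% NA)
}

#' Write a cohort of trials plus a manifest
#'
#' @param trials List of `synthetic_trial` or [trial_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path (`manifest.json` inside `dir`;
#'   lists one file stem per trial with its metadata).
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    rec <- if (inherits(tr, "synthetic_trial")) tr$recording else tr
    stem <- sprintf("trial_%03d_%s_%s", i, rec$subject_id, rec$trial_id)
    write_trial(rec, file.path(dir, stem))
    entries[[i]] <- list(file = stem, subject_id = rec$subject_id,
                         trial_id = rec$trial_id, group = rec$group,
                         condition = rec$condition,
                         seed = if (is.na(rec$seed)) NULL else rec$seed)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION,
                            n_trials = length(trials), trials = entries),
                       path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read all trials listed in a cohort manifest
#'
#' @param dir Directory containing `manifest.json` and the trial files.
#' @return List of [trial_recording()]s.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop_user("manifest not found: ", path)
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(man$trials, function(e) read_trial(file.path(dir, e$file)))
}

#' Minimal TOML configuration reader
#'
#' Supports the flat subset used by the trial configuration: `[section]`
#' headers, `key = value` pairs with string (quoted), boolean
#' (`true`/`false`) and numeric values, and `#` comments.
#'
#' @param path Path to a TOML file.
#' @return Nested named list (top-level keys plus one list per section).
#' @export
read_config_toml <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      out[[section]] <- out[[section]] %||% list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L) stop_user("cannot parse config line: '", raw, "'")
    key <- m[2]; val <- trimws(m[3])
    parsed <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop_user("cannot parse config value: '", val, "'")
      num
    }
    if (is.null(section)) out[[key]] <- parsed
    else out[[section]][[key]] <- parsed
  }
  out
}

#' Build a [trial_config()] from a parsed configuration list
#'
#' Top-level keys map to [trial_config()] arguments; `[pendulum]`,
#' `[controller]` and `[geometry]` sections map to the respective
#' parameter constructors. Unknown keys are an error.
#'
#' @param conf Named list as returned by [read_config_toml()].
#' @return A [trial_config()].
#' @export
config_from_list <- function(conf) {
  take <- function(lst, fun, name) {
    lst <- lst %||% list()
    known <- names(formals(fun))
    unknown <- setdiff(names(lst), known)
    if (length(unknown)) {
      stop_user("unknown ", name, " key(s): ", paste(unknown, collapse = ", "))
    }
    do.call(fun, lst)
  }
  top <- conf[setdiff(names(conf),
                      c("pendulum", "controller", "geometry", "cohort"))]
  args <- c(top, list(
    pendulum = take(conf$pendulum, pendulum_params, "pendulum"),
    controller = take(conf$controller, controller_params, "controller"),
    geometry = take(conf$geometry, stance_geometry, "geometry")))
  take(args, trial_config, "trial")
}
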