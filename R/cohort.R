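# Cohort-level simulation and the on-disk CSV dataset layout.

.exclusion_reasons <- c("accelerometer_failure", "calorimeter_malfunction",
                        "no_steady_state", "participant_absent_or_incomplete")

#' Configuration of a simulated study cohort
#'
#' @param n_participants Number of participants (default 18).
#' @param dropout Probability that a scheduled trial is excluded
#'   (accelerometer/calorimeter failure, failed steady state, absence);
#'   default 34/216, the study's exclusion rate.
#' @param prop_male,prop_right_handed Passed to [generate_participants()].
#' @param gain_jitter Half-width of the uniform per-axis device gain error
#'   (0 = perfectly calibrated devices).
#' @param offset_jitter_g Half-width of the uniform per-axis offset error, g.
#' @param kj_per_l_o2 Energy equivalent of oxygen for Schofield REE.
#' @param trial Trial-level parameters from [trial_config()].
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 18, dropout = 34 / 216,
                          prop_male = 10 / 18, prop_right_handed = 0.9,
                          gain_jitter = 0, offset_jitter_g = 0,
                          kj_per_l_o2 = 20.9, trial = trial_config()) {
  stopifnot(n_participants >= 1, dropout >= 0, dropout < 1,
            gain_jitter >= 0, gain_jitter <= 0.1,
            offset_jitter_g >= 0, offset_jitter_g <= 0.1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Read or write a cohort configuration as YAML
#' @param path File path.
#' @param config A [cohort_config()].
#' @return `read_config_yaml()` returns a `cohort_config`;
#'   `write_config_yaml()` returns `path` invisibly.
#' @export
write_config_yaml <- function(path, config = cohort_config()) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  trial <- do.call(trial_config, raw$trial %||% list())
  raw$trial <- NULL
  do.call(cohort_config, c(raw, list(trial = trial)))
}

#' Generate a complete synthetic study cohort
#'
#' Schedules every participant x activity trial (18 x 12 = 216 under the
#' defaults), simulates each recording with [generate_trial()], draws one
#' calibration error per participant and wrist from the configured jitter
#' ranges, and marks each trial excluded independently with the configured
#' dropout probability, with a sampled exclusion reason.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is deterministic given
#'   (config, seed).
#' @return A list of class `study_cohort`: `participants`, `trials` (named
#'   `"<id>_<activity>"`), `manifest` (participant, activity,
#'   exclusion_flag), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  profiles <- activity_profiles()
  n <- config$n_participants
  with_local_seed(seed, {
    sub <- function() sample.int(.Machine$integer.max, 1)
    participants <- generate_participants(
      n, seed = sub(), prop_male = config$prop_male,
      prop_right_handed = config$prop_right_handed)
    # one miscalibration draw per participant's device pair
    errs <- lapply(seq_len(n), function(i) calibration_error(
      gain = stats::runif(3, 1 - config$gain_jitter,
                          1 + config$gain_jitter),
      offset = stats::runif(3, -config$offset_jitter_g,
                            config$offset_jitter_g)))
    trials <- list()
    manifest <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(profiles))) {
        prof <- profiles[j, ]
        tr <- generate_trial(participants[i, ], prof,
                             err = errs[[i]], seed = sub(),
                             config = config$trial)
        excl <- if (stats::runif(1) < config$dropout)
          sample(.exclusion_reasons, 1) else NA_character_
        tr$exclusion_flag <- excl
        key <- paste(participants$id[i], prof$code, sep = "_")
        trials[[key]] <- tr
        manifest[[key]] <- data.frame(
          participant = participants$id[i], activity = prof$code,
          exclusion_flag = excl, stringsAsFactors = FALSE)
      }
    }
    structure(list(
      participants = participants,
      trials = trials,
      manifest = do.call(rbind, c(manifest, list(make.row.names = FALSE))),
      config = config,
      seed = seed
    ), class = "study_cohort")
  })
}

#' @export
print.study_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<study_cohort>", nrow(x$participants), "participants,",
      nrow(m), "scheduled trials,", sum(!is.na(m$exclusion_flag)),
      "excluded (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Write a simulated cohort to the CSV dataset layout
#'
#' Layout: `participants.csv`; `trials.csv` (the manifest with
#' `exclusion_flag`); per trial and wrist
#' `raw_<id>_<activity>_<side>.csv` (t_s, ax_g, ay_g, az_g) and
#' `counts_<id>_<activity>_<side>.csv` (epoch_start_s, va, ml, ap; epochs
#' half-open \[t, t+5)); per trial `gas_<id>_<activity>.csv` (t_s on the
#' 15-s grid, vo2_ml_min, hr_bpm).
#'
#' @param cohort A `study_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "study_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  fw(cohort$participants, "participants.csv")
  fw(cohort$manifest, "trials.csv")
  for (key in names(cohort$trials)) {
    tr <- cohort$trials[[key]]
    for (side in c("left", "right")) {
      fw(tr$raw[[side]], sprintf("raw_%s_%s.csv", key, side))
      fw(tr$counts[[side]], sprintf("counts_%s_%s.csv", key, side))
    }
    fw(tr$gas, sprintf("gas_%s.csv", key))
  }
  invisible(dir)
}

#' @noRd
read_trial_files <- function(dir, participant_id, activity_code,
                             profiles = activity_profiles()) {
  key <- paste(participant_id, activity_code, sep = "_")
  fr <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing dataset file: ", f)
    data.table::fread(path, data.table = FALSE)
  }
  prof <- get_profile(activity_code, profiles)
  structure(list(
    participant_id = participant_id,
    activity_code = activity_code,
    duration_s = prof$duration_s,
    raw = list(left = fr(sprintf("raw_%s_left.csv", key)),
               right = fr(sprintf("raw_%s_right.csv", key))),
    counts = list(left = fr(sprintf("counts_%s_left.csv", key)),
                  right = fr(sprintf("counts_%s_right.csv", key))),
    gas = fr(sprintf("gas_%s.csv", key)),
    exclusion_flag = NA_character_,
    sim = NULL
  ), class = "trial_recording")
}
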