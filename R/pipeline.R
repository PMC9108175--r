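# End-to-end orchestration: simulate a dataset directory, then evaluate the
# seven cut-point sets against the calorimetry-style ground truth.

#' Simulate a cohort and write it as a dataset directory
#'
#' Runs [generate_cohort()] and [write_dataset()], then writes
#' `manifest.yaml` recording the seed, scheduled/excluded trial counts and
#' an MD5 hash of the configuration, so identical (config, seed) runs are
#' recognisably identical.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (required).
#' @param dir Output dataset directory.
#' @return The cohort (invisibly); the dataset is on disk under `dir`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed, dir) {
  cohort <- generate_cohort(config, seed)
  write_dataset(cohort, dir)
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  write_config_yaml(cfg_file, config)
  yaml::write_yaml(list(
    seed = seed,
    n_participants = config$n_participants,
    scheduled_trials = nrow(cohort$manifest),
    excluded_trials = sum(!is.na(cohort$manifest$exclusion_flag)),
    config_md5 = unname(tools::md5sum(cfg_file))
  ), file.path(dir, "manifest.yaml"))
  invisible(cohort)
}

#' Evaluate the cut-point sets on a dataset directory
#'
#' Runs the full processing chain on a dataset in the package's CSV layout:
#' per-trial autocalibration and windowed feature extraction
#' ([summarize_trial()]), Youth METs and ground-truth labels from measured
#' VO2 ([schofield_ree()], [youth_mets()], [label_intensity()]),
#' classification with every cut-point set ([classify_trial()]), and
#' agreement analysis ([weighted_kappa()], [per_class_accuracy()],
#' [direction_summary()]). Trials flagged in the manifest or failing the
#' steady-state check are dropped before the agreement analysis.
#'
#' @param dir Dataset directory (from [simulate_cohort()] or real data in
#'   the same layout).
#' @param out_dir Optional report directory; when given, writes
#'   `features.csv`, `mets.csv`, `predictions.csv`, `agreement.csv`,
#'   `confusion_<set>.csv`, `direction.csv` and `run_log.txt`.
#' @param cutpoints Cut-point registry (default [builtin_cutpoints()]).
#' @param weighting Kappa weighting scheme.
#' @return A list of class `cutpoint_evaluation` with elements `features`,
#'   `mets`, `predictions`, `agreement`, `confusion` (named list of
#'   matrices), `direction`, `n_analyzable`, `n_dropped`.
#' @export
evaluate_dataset <- function(dir, out_dir = NULL,
                             cutpoints = builtin_cutpoints(),
                             weighting = c("linear", "quadratic",
                                           "unweighted")) {
  weighting <- match.arg(weighting)
  t0 <- Sys.time()
  fr <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing dataset file: ", f)
    data.table::fread(path, data.table = FALSE)
  }
  participants <- fr("participants.csv")
  manifest <- fr("trials.csv")
  profiles <- activity_profiles()

  excl <- manifest$exclusion_flag
  excl[excl == ""] <- NA  # CSV round trip stores NA as the empty string
  keep <- is.na(excl)
  feat_rows <- list(); met_rows <- list()
  for (i in which(keep)) {
    pid <- manifest$participant[i]; act <- manifest$activity[i]
    p <- participants[participants$id == pid, , drop = FALSE]
    if (nrow(p) != 1) stop("participant ", pid, " not in participants.csv")
    trial <- read_trial_files(dir, pid, act, profiles)
    feats <- summarize_trial(trial)
    feats <- cbind(participant = pid, activity = act, feats)
    feat_rows[[length(feat_rows) + 1L]] <- feats

    ree <- schofield_ree(p$sex, p$age, p$mass_kg, p$height_m)
    mets <- youth_mets(feats$mean_vo2[1], p$mass_kg, ree)
    posture <- get_profile(act, profiles)$posture
    met_rows[[length(met_rows) + 1L]] <- data.frame(
      participant = pid, activity = act, mean_vo2 = feats$mean_vo2[1],
      youth_mets = mets,
      true_label = as.character(label_intensity(mets, posture)),
      steady_state = feats$steady_state[1],
      handedness = p$handedness, stringsAsFactors = FALSE)
  }
  if (length(met_rows) == 0)
    stop("no analyzable trials: every trial is excluded or unsteady")
  features <- do.call(rbind, feat_rows)
  mets <- do.call(rbind, met_rows)
  n_dropped <- sum(!keep) + sum(!mets$steady_state)
  analyzable <- mets[mets$steady_state, , drop = FALSE]
  if (nrow(analyzable) == 0)
    stop("no analyzable trials: every trial is excluded or unsteady")

  pred_rows <- list()
  for (i in seq_len(nrow(analyzable))) {
    tr <- analyzable[i, ]
    fx <- features[features$participant == tr$participant &
                     features$activity == tr$activity, ]
    for (j in seq_len(nrow(cutpoints))) {
      set <- cutpoints[j, ]
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        participant = tr$participant, activity = tr$activity,
        cutpoint = set$name,
        predicted_label = as.character(
          classify_trial(fx, set, tr$handedness)),
        true_label = tr$true_label, stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, pred_rows)

  agree_rows <- list(); confusion <- list(); dir_rows <- list()
  for (nm in cutpoints$name) {
    sub <- predictions[predictions$cutpoint == nm, ]
    cm <- confusion_matrix(sub$true_label, sub$predicted_label)
    kap <- weighted_kappa(cm, weighting)
    acc <- per_class_accuracy(cm)
    confusion[[nm]] <- cm
    agree_rows[[nm]] <- data.frame(
      cutpoint = nm, n = kap$n, kappa = kap$kappa, se = kap$se,
      ci_lo = kap$ci95[1], ci_hi = kap$ci95[2], weighting = kap$weighting,
      rating = kap$landis_koch,
      acc_sed = acc["SED"], acc_lpa = acc["LPA"],
      acc_mpa = acc["MPA"], acc_vpa = acc["VPA"],
      stringsAsFactors = FALSE, row.names = NULL)
    ds <- direction_summary(sub$true_label, sub$predicted_label,
                            sub$activity)
    dir_rows[[nm]] <- cbind(cutpoint = nm, ds)
  }
  agreement <- do.call(rbind, c(agree_rows, list(make.row.names = FALSE)))
  direction <- do.call(rbind, c(dir_rows, list(make.row.names = FALSE)))

  out <- structure(list(
    features = features, mets = mets, predictions = predictions,
    agreement = agreement, confusion = confusion, direction = direction,
    n_analyzable = nrow(analyzable), n_dropped = n_dropped,
    weighting = weighting
  ), class = "cutpoint_evaluation")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fw <- function(x, f) data.table::fwrite(x, file.path(out_dir, f))
    fw(features, "features.csv")
    fw(mets, "mets.csv")
    fw(predictions, "predictions.csv")
    fw(agreement, "agreement.csv")
    fw(direction, "direction.csv")
    for (nm in names(confusion)) {
      cm <- confusion[[nm]]
      pct <- 100 * cm / pmax(rowSums(cm), 1)
      fw(data.frame(measured = rownames(cm), cm, check.names = FALSE,
                    row.names = NULL,
                    stats::setNames(as.data.frame(round(pct, 1)),
                                    paste0("pct_", colnames(cm)))),
         sprintf("confusion_%s.csv", nm))
    }
    writeLines(c(
      sprintf("dataset: %s", normalizePath(dir)),
      sprintf("weighting: %s", weighting),
      sprintf("scheduled trials: %d", nrow(manifest)),
      sprintf("excluded by manifest: %d", sum(!keep)),
      sprintf("failed steady state: %d", sum(!mets$steady_state)),
      sprintf("analyzable trials: %d", nrow(analyzable)),
      sprintf("elapsed_s: %.1f", as.numeric(Sys.time() - t0, units = "secs"))
    ), file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.cutpoint_evaluation <- function(x, ...) {
  cat("<cutpoint_evaluation>", x$n_analyzable, "analyzable trials (",
      x$n_dropped, "dropped );", x$weighting, "weighted kappa\n")
  print(x$agreement[, c("cutpoint", "kappa", "ci_lo", "ci_hi", "rating")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
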