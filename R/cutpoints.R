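#' The seven built-in youth wrist cut-point sets
#'
#' Registry of the seven published youth-specific intensity cut-point sets
#' for wrist-worn ActiGraph output: four Crouter sets (dominant wrist,
#' counts per 5 s; thresholds from ROC analysis or from inverting a linear
#' MET regression), two Chandler ROC sets (non-dominant wrist, counts per
#' 5 s) and the Hildebrand ENMO set (non-dominant wrist, m*g* per 1 s).
#'
#' Each set keeps its published boundary semantics verbatim rather than a
#' shared convention: the Crouter sets call a value sedentary when it is
#' less than or equal to the SED threshold (`sed_rule = "le"`), while the
#' Chandler and Hildebrand sets use a strict less-than (`sed_rule = "lt"`).
#' Moderate and vigorous are `>=` their thresholds for every set. The two
#' Crouter regression sets additionally carry the linear MET prediction
#' equation (`reg_intercept`, `reg_slope`), exposed through
#' [regression_mets()] and [invert_regression()]; classification itself
#' always uses the printed count thresholds.
#'
#' @return A data.frame with columns `name`, `metric` (`"va"`, `"vm"`,
#'   `"enmo"`), `epoch_s`, `wrist` (`"dominant"`/`"nondominant"`),
#'   `sed_upper`, `sed_rule`, `lpa_lower`, `mpa_lower`, `vpa_lower`,
#'   `reg_intercept`, `reg_slope`.
#' @examples
#' builtin_cutpoints()[, c("name", "metric", "wrist", "vpa_lower")]
#' @export
builtin_cutpoints <- function() {
  out <- data.frame(
    name     = c("CR_ROC_VA", "CR_ROC_VM", "CR_REG_VA", "CR_REG_VM",
                 "CH_ROC_VA", "CH_ROC_VM", "HD_ENMO"),
    metric   = c("va", "vm", "va", "vm", "va", "vm", "enmo"),
    epoch_s  = c(5, 5, 5, 5, 5, 5, 1),
    wrist    = c("dominant", "dominant", "dominant", "dominant",
                 "nondominant", "nondominant", "nondominant"),
    sed_upper = c(105, 275, 35, 100, 161, 305, 35.6),
    sed_rule  = c("le", "le", "le", "le", "lt", "lt", "lt"),
    lpa_lower = c(105, 275, 35, 100, 162, 306, 35.6),
    mpa_lower = c(262, 416, 361, 610, 530, 818, 201.4),
    vpa_lower = c(565, 778, 1130, 1810, 1462, 1969, 707.0),
    reg_intercept = c(NA, NA, 1.592, 1.475, NA, NA, NA),
    reg_slope     = c(NA, NA, 0.0039, 0.0025, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$sed_upper <= out$mpa_lower),
            all(out$mpa_lower < out$vpa_lower))
  out
}

#' @noRd
get_cutpoint <- function(name, sets = builtin_cutpoints()) {
  i <- match(name, sets$name)
  if (is.na(i)) stop("unknown cut-point set: ", name)
  sets[i, , drop = FALSE]
}

#' Predicted Youth METs from a Crouter regression cut-point set
#'
#' Evaluates the linear MET prediction equation carried by the two Crouter
#' regression sets: METs = intercept + slope * counts per 5 s.
#'
#' @param x Counts per 5 s, non-negative (vectorised).
#' @param set One row of the cut-point registry (see [builtin_cutpoints()]),
#'   or a set name.
#' @return Predicted Youth METs.
#' @examples
#' regression_mets(0, "CR_REG_VA")    # the intercept, 1.592
#' regression_mets(250, "CR_REG_VA")  # 2.567
#' @export
regression_mets <- function(x, set) {
  set <- as_cutpoint_row(set)
  if (is.na(set$reg_slope)) stop(set$name, " has no regression equation")
  if (any(x < 0)) stop("counts must be non-negative")
  set$reg_intercept + set$reg_slope * x
}

#' Count threshold implied by a MET boundary under a Crouter regression
#'
#' Inverts the linear MET equation of a regression cut-point set at a MET
#' boundary and rounds to the nearest integer count, reproducing the printed
#' moderate and vigorous count thresholds at 3 and 6 METs.
#'
#' @param set A regression cut-point set (row or name).
#' @param met_boundary Youth MET boundary; must not lie below the equation's
#'   intercept.
#' @return Counts per 5 s, integer.
#' @examples
#' invert_regression("CR_REG_VA", 3) # 361
#' invert_regression("CR_REG_VM", 6) # 1810
#' @export
invert_regression <- function(set, met_boundary) {
  set <- as_cutpoint_row(set)
  if (is.na(set$reg_slope)) stop(set$name, " has no regression equation")
  if (met_boundary < set$reg_intercept)
    stop("MET boundary ", met_boundary, " lies below the intercept ",
         set$reg_intercept)
  round((met_boundary - set$reg_intercept) / set$reg_slope)
}

#' Classify a metric value with one cut-point set
#'
#' Applies a set's thresholds to a window-mean metric value, honouring the
#' set's own boundary semantics (see [builtin_cutpoints()]).
#'
#' @param x Metric value(s) in the set's units (counts per 5 s or m*g*).
#' @param set Cut-point set row or name.
#' @return Ordered factor over SED < LPA < MPA < VPA.
#' @export
classify_value <- function(x, set) {
  set <- as_cutpoint_row(set)
  if (any(!is.finite(x))) stop("metric values must be finite")
  sed <- if (set$sed_rule == "le") x <= set$sed_upper else x < set$sed_upper
  lab <- ifelse(x >= set$vpa_lower, "VPA",
         ifelse(x >= set$mpa_lower, "MPA",
         ifelse(sed, "SED", "LPA")))
  intensity_factor(lab)
}

#' Classify one trial's features with one cut-point set
#'
#' Selects the wrist the set was calibrated for (dominant wrist = the
#' handedness side, non-dominant = the other side), picks the set's metric
#' from the trial's window-mean features and classifies it.
#'
#' @param features A data.frame of features for one trial with columns
#'   `side` (`"left"`/`"right"`), `mean_va`, `mean_vm`, `mean_enmo`.
#' @param set Cut-point set row or name.
#' @param handedness `"left"` or `"right"`.
#' @return Ordered intensity label (length 1).
#' @export
classify_trial <- function(features, set, handedness) {
  set <- as_cutpoint_row(set)
  handedness <- match.arg(handedness, c("left", "right"))
  side <- wrist_side(set$wrist, handedness)
  row <- features[features$side == side, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("features must contain exactly one row for side '", side, "'")
  col <- c(va = "mean_va", vm = "mean_vm", enmo = "mean_enmo")[[set$metric]]
  if (is.null(row[[col]]) || is.na(row[[col]]))
    stop("feature '", col, "' missing for side '", side, "'")
  classify_value(row[[col]], set)
}

#' @noRd
wrist_side <- function(wrist, handedness) {
  if (wrist == "dominant") handedness
  else if (handedness == "left") "right" else "left"
}

#' @noRd
as_cutpoint_row <- function(set) {
  if (is.character(set)) return(get_cutpoint(set))
  stopifnot(is.data.frame(set), nrow(set) == 1L)
  set
}

#' Read or write a cut-point registry as YAML
#'
#' User-supplied cut-point sets can replace or extend the built-in registry;
#' the YAML layout mirrors the registry columns, one named entry per set.
#'
#' @param path File path.
#' @param sets Registry data.frame (defaults to [builtin_cutpoints()]).
#' @return `read_cutpoints_yaml()` returns a registry data.frame;
#'   `write_cutpoints_yaml()` returns `path` invisibly.
#' @export
write_cutpoints_yaml <- function(path, sets = builtin_cutpoints()) {
  entries <- lapply(seq_len(nrow(sets)), function(i) {
    row <- as.list(sets[i, setdiff(names(sets), "name")])
    row[!vapply(row, is.na, logical(1))]
  })
  names(entries) <- sets$name
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_cutpoints_yaml
#' @export
read_cutpoints_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  template <- builtin_cutpoints()[0, ]
  rows <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    data.frame(
      name = nm, metric = e$metric, epoch_s = e$epoch_s, wrist = e$wrist,
      sed_upper = e$sed_upper, sed_rule = e$sed_rule,
      lpa_lower = e$lpa_lower, mpa_lower = e$mpa_lower,
      vpa_lower = e$vpa_lower,
      reg_intercept = e$reg_intercept %||% NA_real_,
      reg_slope = e$reg_slope %||% NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- rbind(template, do.call(rbind, rows))
  stopifnot(all(out$sed_upper <= out$mpa_lower),
            all(out$mpa_lower < out$vpa_lower),
            all(is.na(out$reg_slope) | out$reg_slope > 0))
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
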