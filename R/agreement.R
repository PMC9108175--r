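#' Confusion matrix of measured vs predicted intensity
#'
#' Tallies paired intensity labels into a 4x4 matrix with measured
#' (calorimetry) intensity on the rows and predicted intensity on the
#' columns, in the fixed order SED, LPA, MPA, VPA.
#'
#' @param truth,predicted Equal-length label sequences (character or
#'   factors over the four intensity levels).
#' @return 4x4 integer matrix, rows = measured, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  tab <- table(measured = intensity_factor(truth),
               predicted = intensity_factor(predicted))
  m <- matrix(as.integer(tab), nrow = 4,
              dimnames = list(measured = intensity_levels(),
                              predicted = intensity_levels()))
  m
}

#' @noRd
disagreement_weights <- function(weighting, k = 4) {
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  switch(weighting,
         linear = d,
         quadratic = d^2,
         unweighted = (d > 0) * 1,
         stop("unknown weighting: ", weighting))
}

#' Landis-Koch qualitative rating of a kappa value
#'
#' Conventional bands: poor (0-0.2), fair (0.2-0.4), moderate (0.4-0.6),
#' substantial (0.6-0.8), almost perfect (0.8-1.0). Values below 0 are
#' rated poor.
#'
#' @param kappa Kappa value(s).
#' @return Character rating(s).
#' @export
landis_koch <- function(kappa) {
  cut_pts <- c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf)
  labs <- c("poor", "fair", "moderate", "substantial", "almost perfect")
  as.character(cut(kappa, cut_pts, labs, right = FALSE))
}

#' Weighted Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement for the ordinal 4-level intensity scale:
#' kappa_w = 1 - sum(w * o) / sum(w * e), with disagreement weights w
#' (linear |i-j|/3, quadratic ((i-j)/3)^2, or 0/1 unweighted), observed
#' cell proportions o and expected proportions e from the row x column
#' marginal products. The standard error follows the Fleiss-Cohen-Everitt
#' large-sample formula and the 95 % interval is the normal interval
#' clipped to \[-1, 1\].
#'
#' @param m 4x4 confusion matrix from [confusion_matrix()].
#' @param weighting `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @param conf_level Confidence level for the interval.
#' @return List with `kappa`, `se`, `ci95` (length-2), `weighting`,
#'   `landis_koch` and `n`. For a degenerate matrix in which all mass sits
#'   in a single row-and-column cell, kappa is undefined and returned as
#'   `NA` with `degenerate = TRUE`.
#' @examples
#' m <- confusion_matrix(c("SED", "LPA", "MPA"), c("SED", "LPA", "LPA"))
#' weighted_kappa(m)$kappa
#' @export
weighted_kappa <- function(m, weighting = c("linear", "quadratic",
                                            "unweighted"),
                           conf_level = 0.95) {
  weighting <- match.arg(weighting)
  n <- sum(m)
  if (n < 2) stop("need at least 2 paired observations")
  o <- m / n
  r <- rowSums(o); cc <- colSums(o)
  e <- outer(r, cc)
  w <- disagreement_weights(weighting, nrow(m))
  exp_dis <- sum(w * e)
  if (exp_dis == 0) {
    # single occupied row and column: no chance disagreement, kappa undefined
    return(list(kappa = NA_real_, se = NA_real_, ci95 = c(NA_real_, NA_real_),
                weighting = weighting, landis_koch = NA_character_,
                n = n, degenerate = TRUE))
  }
  kappa <- 1 - sum(w * o) / exp_dis

  # Fleiss, Cohen & Everitt large-sample SE, in agreement weights v = 1 - w
  v <- 1 - w
  pe <- sum(v * e)
  vbar_row <- as.vector(v %*% cc)   # row-conditional expected agreement
  vbar_col <- as.vector(r %*% v)
  term <- outer(vbar_row, vbar_col, "+")
  num <- sum(o * (v - term * (1 - kappa))^2) - (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(num, 0) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * z * se))
  list(kappa = kappa, se = se, ci95 = ci, weighting = weighting,
       landis_koch = landis_koch(kappa), n = n, degenerate = FALSE)
}

#' Per-class classification accuracy
#'
#' Correct predictions divided by total predictions within each measured
#' intensity class (the diagonal over the row sum). Classes with no
#' measured trials are reported as `NA`, not 0.
#'
#' @param m Confusion matrix from [confusion_matrix()].
#' @return Named numeric vector over SED, LPA, MPA, VPA.
#' @export
per_class_accuracy <- function(m) {
  rs <- rowSums(m)
  acc <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  names(acc) <- rownames(m)
  acc
}

#' Per-activity misclassification direction
#'
#' For each structured activity, the fractions of trials whose predicted
#' intensity over-estimates, matches, or under-estimates the measured
#' intensity under the SED < LPA < MPA < VPA ordering.
#'
#' @param truth,predicted Paired label sequences.
#' @param activity Activity code per trial.
#' @return Data.frame with columns `activity`, `n`, `over`, `correct`,
#'   `under`; the three fractions sum to 1 within each activity.
#' @export
direction_summary <- function(truth, predicted, activity) {
  if (length(truth) != length(predicted) ||
      length(truth) != length(activity))
    stop("truth, predicted and activity must have equal length")
  known <- activity_profiles()$code
  if (!all(activity %in% known))
    stop("unknown activity code(s): ",
         paste(setdiff(activity, known), collapse = ", "))
  ti <- as.integer(intensity_factor(truth))
  pi <- as.integer(intensity_factor(predicted))
  rows <- lapply(split(seq_along(ti), activity), function(idx) {
    data.frame(
      activity = activity[idx[1]],
      n = length(idx),
      over = mean(pi[idx] > ti[idx]),
      correct = mean(pi[idx] == ti[idx]),
      under = mean(pi[idx] < ti[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$activity, known)), , drop = FALSE]
}
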