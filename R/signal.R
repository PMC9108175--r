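#' Vector magnitude of tri-axial activity counts
#'
#' Euclidean norm of the per-axis activity counts in an epoch:
#' sqrt(va^2 + ml^2 + ap^2).
#'
#' @param va,ml,ap Per-axis counts, non-negative (vectorised).
#' @return Counts (same epoch basis as the inputs).
#' @examples
#' vector_magnitude(3, 4, 0) # 5
#' @export
vector_magnitude <- function(va, ml, ap) {
  if (any(c(va, ml, ap) < 0)) stop("counts must be non-negative")
  sqrt(va^2 + ml^2 + ap^2)
}

#' ENMO of a calibrated raw acceleration series
#'
#' Per sample, the Euclidean norm of the calibrated tri-axial acceleration
#' minus 1 g (removing the static gravity component), with negative values
#' rounded up to zero; averaged over epochs and reported in m*g*.
#'
#' @param raw Data.frame with columns `t_s`, `ax_g`, `ay_g`, `az_g`
#'   (acceleration in g).
#' @param epoch_s Epoch length in seconds (default 1).
#' @return Data.frame with `epoch_start_s` (half-open epochs
#'   \[t, t + epoch_s)) and `enmo_mg`.
#' @examples
#' raw <- data.frame(t_s = (0:29) / 30, ax_g = 1.2, ay_g = 0, az_g = 0)
#' compute_enmo(raw)$enmo_mg # 200 m*g*
#' @export
compute_enmo <- function(raw, epoch_s = 1) {
  norm_g <- sqrt(raw$ax_g^2 + raw$ay_g^2 + raw$az_g^2)
  enmo_g <- pmax(0, norm_g - 1)
  epoch <- floor(raw$t_s / epoch_s) * epoch_s
  sums <- rowsum(cbind(enmo_g, 1), epoch)
  data.frame(
    epoch_start_s = as.numeric(rownames(sums)),
    enmo_mg = sums[, 1] / sums[, 2] * 1000,
    row.names = NULL
  )
}

#' Identity calibration parameters
#' @return A calibration parameter list with unit gains and zero offsets.
#' @export
identity_calibration <- function() {
  list(gain = c(1, 1, 1), offset = c(0, 0, 0),
       converged = FALSE, residual = NA_real_, n_still = 0L)
}

#' Autocalibrate a raw acceleration series to local gravity
#'
#' Estimates per-axis gain and offset so that non-movement periods lie on
#' the unit gravity sphere. Still periods are non-overlapping windows
#' (default 10 s) in which every axis has a standard deviation below
#' `still_sd_mg`; their per-axis means are the calibration points. Gains
#' and offsets are fitted by iteratively re-projecting the calibrated
#' points onto the unit sphere and regressing, per axis, the projection on
#' the raw points, until the root-mean-square sphere residual changes by
#' less than `tol` (or `max_iter` is reached).
#'
#' The fit needs both enough still windows (default 10) and orientation
#' diversity — a device resting in a single posture gives one point on the
#' sphere, which cannot separate gain from offset. When either requirement
#' fails the identity calibration is returned with `converged = FALSE`.
#'
#' @param raw Data.frame with `t_s`, `ax_g`, `ay_g`, `az_g`; at least 60 s.
#' @param window_s Still-window length, s.
#' @param still_sd_mg Per-axis SD threshold defining "still", m*g*.
#' @param min_windows Minimum number of still windows.
#' @param min_spread_g Minimum per-axis range of the still-point cloud, g.
#' @param max_iter,tol Iteration controls.
#' @return List with `gain` (length 3), `offset` (g, length 3),
#'   `converged`, `residual` (g) and `n_still`.
#' @export
autocalibrate <- function(raw, window_s = 10, still_sd_mg = 13,
                          min_windows = 10, min_spread_g = 0.3,
                          max_iter = 100, tol = 1e-6) {
  dur <- max(raw$t_s) - min(raw$t_s)
  if (dur < 60) stop("series must cover at least 60 s; got ", round(dur, 1))
  acc <- as.matrix(raw[, c("ax_g", "ay_g", "az_g")])
  win <- floor((raw$t_s - min(raw$t_s)) / window_s)
  nk <- as.vector(rowsum(rep(1, nrow(acc)), win))
  sums <- rowsum(acc, win)
  sumsq <- rowsum(acc^2, win)
  means <- sums / nk
  vars <- (sumsq - nk * means^2) / pmax(nk - 1, 1)
  sds <- sqrt(pmax(vars, 0))
  still <- nk >= 2 & apply(sds, 1, max) < still_sd_mg / 1000
  pts <- means[still, , drop = FALSE]
  out <- identity_calibration()
  out$n_still <- sum(still)
  if (sum(still) < min_windows) return(out)
  spread <- apply(pts, 2, function(x) diff(range(x)))
  if (any(spread < min_spread_g)) return(out)

  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(pts, 2, gain, "*"), 2, offset, "+")
    r <- sqrt(rowSums(cal^2))
    target <- cal / r
    for (a in 1:3) {
      fit <- stats::lm.fit(cbind(1, pts[, a]), target[, a])
      offset[a] <- fit$coefficients[1]
      gain[a] <- fit$coefficients[2]
    }
    res <- sqrt(mean((r - 1)^2))
    if (abs(res_prev - res) < tol) {
      return(list(gain = gain, offset = offset, converged = TRUE,
                  residual = res, n_still = out$n_still))
    }
    res_prev <- res
  }
  list(gain = gain, offset = offset, converged = FALSE,
       residual = res_prev, n_still = out$n_still)
}

#' Apply calibration parameters to a raw series
#'
#' @param raw Data.frame with `t_s`, `ax_g`, `ay_g`, `az_g`.
#' @param cal Parameters from [autocalibrate()] (or
#'   [identity_calibration()]).
#' @return The calibrated data.frame.
#' @export
apply_calibration <- function(raw, cal) {
  out <- raw
  out$ax_g <- cal$gain[1] * raw$ax_g + cal$offset[1]
  out$ay_g <- cal$gain[2] * raw$ay_g + cal$offset[2]
  out$az_g <- cal$gain[3] * raw$az_g + cal$offset[3]
  out
}

#' Analysis window of a structured activity trial
#'
#' All trials are summarised over minutes 2.5-4.5 from trial start, except
#' lying down, which uses minutes 7.0-9.0 of its 10-min trial. Windows are
#' half-open \[start, end) in seconds and always 120 s long.
#'
#' @param activity_code Activity code (e.g. `"RU"`, `"LD"`).
#' @param duration_s Optional trial duration; an error is raised when the
#'   trial is too short to cover the window.
#' @return Numeric `c(start, end)` in seconds.
#' @examples
#' analysis_window("RU") # 150 270
#' analysis_window("LD") # 420 540
#' @export
analysis_window <- function(activity_code, duration_s = NULL) {
  w <- if (identical(activity_code, "LD")) c(420, 540) else c(150, 270)
  if (!is.null(duration_s) && duration_s < w[2])
    stop("trial lasts ", duration_s, " s but the analysis window ends at ",
         w[2], " s")
  w
}

#' Steady-state check on heart rate and oxygen uptake
#'
#' A trial is in steady state when, within the analysis window, heart rate
#' stays within +/- 5 bpm of its window mean and VO2 stays within 10 % of
#' its window mean.
#'
#' @param hr Heart-rate samples in the window, bpm.
#' @param vo2 VO2 samples in the window, ml/min.
#' @param hr_tol_bpm,vo2_tol_frac Tolerances (defaults 5 bpm and 0.10).
#' @return Logical flag.
#' @export
steady_state_check <- function(hr, vo2, hr_tol_bpm = 5, vo2_tol_frac = 0.10) {
  if (length(hr) < 2 || length(vo2) < 2)
    stop("steady-state check needs at least 2 samples in the window")
  hr_ok <- max(abs(hr - mean(hr))) <= hr_tol_bpm
  vo2_ok <- max(abs(vo2 - mean(vo2))) <= vo2_tol_frac * mean(vo2)
  hr_ok && vo2_ok
}

#' Window-mean features of one trial recording
#'
#' Computes, per wrist, the analysis-window means of VA counts per 5 s, VM
#' counts per 5 s (VM formed per epoch from the tri-axial counts) and 1-s
#' ENMO from the calibrated raw signal, together with the window-mean VO2
#' and the steady-state flag.
#'
#' @param trial A trial recording from [generate_trial()] (or any list with
#'   the same `raw`, `counts`, `gas`, `activity_code`, `duration_s` fields).
#' @param cal Optional named list `list(left = , right = )` of calibration
#'   parameters. When `NULL`, each side is autocalibrated from its own raw
#'   series and the identity is used if that does not converge.
#' @return Data.frame with one row per side: `side`, `mean_va`, `mean_vm`,
#'   `mean_enmo`, `mean_vo2`, `steady_state`.
#' @export
summarize_trial <- function(trial, cal = NULL) {
  w <- analysis_window(trial$activity_code, trial$duration_s)
  gas <- trial$gas[trial$gas$t_s >= w[1] & trial$gas$t_s < w[2], ]
  if (nrow(gas) == 0) stop("no gas-exchange samples in the analysis window")
  ss <- steady_state_check(gas$hr_bpm, gas$vo2_ml_min)
  rows <- lapply(c("left", "right"), function(side) {
    cts <- trial$counts[[side]]
    cts <- cts[cts$epoch_start_s >= w[1] & cts$epoch_start_s < w[2], ]
    if (nrow(cts) == 0) stop("no count epochs in the analysis window")
    side_cal <- if (is.null(cal)) {
      ac <- autocalibrate(trial$raw[[side]])
      if (ac$converged) ac else identity_calibration()
    } else cal[[side]]
    enmo <- compute_enmo(apply_calibration(trial$raw[[side]], side_cal))
    enmo <- enmo[enmo$epoch_start_s >= w[1] & enmo$epoch_start_s < w[2], ]
    data.frame(
      side = side,
      mean_va = mean(cts$va),
      mean_vm = mean(vector_magnitude(cts$va, cts$ml, cts$ap)),
      mean_enmo = mean(enmo$enmo_mg),
      mean_vo2 = mean(gas$vo2_ml_min),
      steady_state = ss,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
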