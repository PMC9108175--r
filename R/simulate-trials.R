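# Trial-level simulation: one laboratory activity trial = correlated
# left/right wrist raw signal and epoch counts, plus a gas-exchange and
# heart-rate trace consistent with a drawn Youth-MET value.

#' Simulation parameters for a single trial
#'
#' Collects the tunable constants of the trial generator. The defaults are
#' the package's standing choices; none of them is activity-specific (the
#' activity-specific targets live in [activity_profiles()]).
#'
#' @param latent_loading Correlation between a trial's latent intensity
#'   factor (which sets the Youth-MET draw) and its accelerometer-metric
#'   draws. Movement metrics and energy expenditure are both driven by how
#'   vigorously the child actually moved, so they are coupled (default 0.7).
#' @param lr_correlation Left/right wrist correlation of the metric draws
#'   (default 0.8); must be at least `latent_loading^2`.
#' @param zero_sigma Log-scale SD of the non-zero branch for zero-median
#'   (zero-inflated) metrics.
#' @param within_trial_sd Log-scale SD of the epoch-to-epoch jitter around
#'   a trial's count level.
#' @param vo2_tau_s,hr_tau_s Mono-exponential on-kinetics time constants of
#'   VO2 and heart rate, s.
#' @param vo2_noise_sd Multiplicative (log-scale) noise SD of the 15-s VO2
#'   samples.
#' @param hr_noise_sd Additive noise SD of the 15-s heart-rate samples, bpm.
#' @param hr_intercept,hr_slope Affine map from Youth METs to plateau heart
#'   rate, bpm (plateau = intercept + slope * METs).
#' @param raw_hz Raw sampling rate (30 Hz).
#' @param raw_noise_mg Per-axis raw sensor noise SD, m*g*.
#' @param osc_freq_range Frequency range of the movement oscillation, Hz.
#' @return Named list of parameters.
#' @export
trial_config <- function(latent_loading = 0.7, lr_correlation = 0.8,
                         zero_sigma = 0.5, within_trial_sd = 0.15,
                         vo2_tau_s = 45, hr_tau_s = 30,
                         vo2_noise_sd = 0.02, hr_noise_sd = 1.2,
                         hr_intercept = 65, hr_slope = 12.5,
                         raw_hz = 30, raw_noise_mg = 2,
                         osc_freq_range = c(1, 3)) {
  stopifnot(latent_loading >= 0, latent_loading <= 1,
            lr_correlation >= latent_loading^2, lr_correlation <= 1)
  as.list(environment())
}

# (median, q1, q3) -> lognormal parameters. For a positive median the
# log-median is mu and sigma is solved from the IQR width,
#   exp(mu + z75 s) - exp(mu - z75 s) = q3 - q1
# which closes to s = asinh((q3 - q1) / (2 median)) / z75. A zero median
# switches to a zero-inflated lognormal with inflation 1/2, whose upper
# quartile is the median of the non-zero branch (mu = log(q3)).
#' @noRd
lognormal_from_quartiles <- function(median, q1, q3, zero_sigma = 0.5) {
  z75 <- stats::qnorm(0.75)
  if (median > 0) {
    list(zero_inflated = FALSE, mu = log(median),
         sigma = asinh((q3 - q1) / (2 * median)) / z75)
  } else {
    stopifnot(q3 > 0)
    list(zero_inflated = TRUE, mu = log(q3), sigma = zero_sigma)
  }
}

# Map a standard-normal latent value to the metric scale. The zero-inflated
# branch ties zeros to the low half of the latent, so quiet trials are the
# ones with zero counts.
#' @noRd
latent_to_metric <- function(z, par) {
  if (!par$zero_inflated) return(exp(par$mu + par$sigma * z))
  ifelse(z < 0, 0,
         exp(par$mu + par$sigma *
               stats::qnorm(pmax(2 * stats::pnorm(z) - 1, 1e-12))))
}

#' Generate one synthetic activity trial recording
#'
#' Simulates a complete trial for one participant and one activity:
#' (a) a trial Youth-MET value drawn from the activity's
#' Normal(met_mean, met_sd) truncated at 1.0;
#' (b) a breath-analyser-style VO2 trace on the 15-s grid that ramps
#' mono-exponentially from rest to the plateau implied by the drawn METs,
#' the participant's mass and Schofield REE, with small multiplicative
#' noise;
#' (c) heart rate as an affine map of METs with its own (faster) ramp and
#' additive noise;
#' (d) per-5-s VA/ML/AP count triplets whose trial level is a lognormal
#' draw matched to the activity's median/IQR (VM >= VA enforced; the ML
#' and AP axes split the VM residual evenly);
#' (e) 30-Hz tri-axial raw acceleration: gravity along a random orientation
#' plus an oscillation scaled so the windowed ENMO matches a lognormal draw
#' from the activity's ENMO median/IQR, then distorted by the device's
#' calibration error.
#'
#' All random draws are coupled through a per-trial latent intensity factor
#' (see [trial_config()]), and the left and right wrists are correlated
#' copies.
#'
#' @param participant One row of [generate_participants()] output.
#' @param profile One row of [activity_profiles()].
#' @param err A [calibration_error()] (identity by default).
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @param config Parameters from [trial_config()].
#' @return A list of class `trial_recording` with fields `participant_id`,
#'   `activity_code`, `duration_s`, `raw` (`$left`, `$right`), `counts`
#'   (`$left`, `$right`), `gas` (`t_s`, `vo2_ml_min`, `hr_bpm`),
#'   `exclusion_flag` (`NA` = retained), and `sim` (the drawn ground-truth
#'   quantities: `mets`, per-side ENMO targets and count levels).
#' @export
generate_trial <- function(participant, profile, err = calibration_error(),
                           seed, config = trial_config()) {
  stopifnot(inherits(err, "calibration_error"))
  p <- participant; prof <- profile
  dur <- prof$duration_s
  with_local_seed(seed, {
    # latent intensity: truncated-normal MET draw, kept as a z-score
    z_lo <- stats::pnorm((1 - prof$met_mean) / prof$met_sd)
    z0 <- stats::qnorm(stats::runif(1, z_lo, 1))
    mets <- prof$met_mean + prof$met_sd * z0

    a <- config$latent_loading
    b <- sqrt(config$lr_correlation - a^2)
    cc <- sqrt(1 - config$lr_correlation)
    e_mov <- stats::rnorm(1)
    z_side <- function() a * z0 + b * e_mov + cc * stats::rnorm(1)

    par_va <- lognormal_from_quartiles(prof$va_median, prof$va_q1,
                                       prof$va_q3, config$zero_sigma)
    par_vm <- lognormal_from_quartiles(prof$vm_median, prof$vm_q1,
                                       prof$vm_q3, config$zero_sigma)
    par_en <- lognormal_from_quartiles(prof$enmo_median, prof$enmo_q1,
                                       prof$enmo_q3, config$zero_sigma)

    n_ep <- dur / 5
    sw <- config$within_trial_sd
    sides <- list()
    sim <- list(mets = mets)
    for (side in c("left", "right")) {
      lv_va <- latent_to_metric(z_side(), par_va)
      lv_vm <- latent_to_metric(z_side(), par_vm)
      en_target <- latent_to_metric(z_side(), par_en)
      jit <- function() exp(stats::rnorm(n_ep, 0, sw) - sw^2 / 2)
      va <- round(lv_va * jit())
      vm <- pmax(round(lv_vm * jit()), va)
      lat <- sqrt(pmax(vm^2 - va^2, 0) / 2)
      counts <- data.frame(epoch_start_s = seq(0, dur - 5, by = 5),
                           va = va, ml = round(lat), ap = round(lat))
      sides[[side]] <- list(
        counts = counts,
        raw = simulate_raw_signal(dur, en_target, err, config)
      )
      sim[[paste0("enmo_target_", side)]] <- en_target
      sim[[paste0("va_level_", side)]] <- lv_va
      sim[[paste0("vm_level_", side)]] <- lv_vm
    }

    structure(list(
      participant_id = p$id,
      activity_code = prof$code,
      duration_s = dur,
      raw = list(left = sides$left$raw, right = sides$right$raw),
      counts = list(left = sides$left$counts, right = sides$right$counts),
      gas = simulate_gas_trace(p, mets, dur, config),
      exclusion_flag = NA_character_,
      sim = sim
    ), class = "trial_recording")
  })
}

# Gravity along a random fixed orientation plus a half-wave-rectified
# sinusoidal burst along that orientation (loading phases of a rhythmic
# movement). The burst is non-negative, so the sample norm is 1 + s and the
# window-mean ENMO is exactly mean(s) = amplitude / pi at any amplitude;
# amplitude = pi * target. Small isotropic sensor noise on top; the
# calibration error distorts the result.
#' @noRd
simulate_raw_signal <- function(dur, enmo_target_mg, err, config) {
  hz <- config$raw_hz
  n <- dur * hz
  t <- (seq_len(n) - 1) / hz
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  amp <- pi * enmo_target_mg / 1000
  f <- stats::runif(1, config$osc_freq_range[1], config$osc_freq_range[2])
  phase <- stats::runif(1, 0, 2 * pi)
  s <- amp * pmax(sin(2 * pi * f * t + phase), 0)
  acc <- outer(1 + s, u) +
    matrix(stats::rnorm(3 * n, 0, config$raw_noise_mg / 1000), ncol = 3)
  distort_raw(data.frame(t_s = t, ax_g = acc[, 1], ay_g = acc[, 2],
                         az_g = acc[, 3]), err)
}

# VO2 (ml/min) and HR (bpm) on the 15-s grid: rest-to-plateau
# mono-exponential on-kinetics; plateau VO2 = METs x REE x mass.
#' @noRd
simulate_gas_trace <- function(participant, mets, dur, config) {
  ree <- schofield_ree(participant$sex, participant$age,
                       participant$mass_kg, participant$height_m)
  t <- seq(0, dur - 15, by = 15)
  vo2_rest <- ree$ree_vo2 * participant$mass_kg
  vo2_plateau <- mets * vo2_rest
  vo2 <- vo2_rest + (vo2_plateau - vo2_rest) * (1 - exp(-t / config$vo2_tau_s))
  vo2 <- vo2 * exp(stats::rnorm(length(t), 0, config$vo2_noise_sd))
  hr_rest <- config$hr_intercept + config$hr_slope
  hr_plateau <- config$hr_intercept + config$hr_slope * mets
  hr <- hr_rest + (hr_plateau - hr_rest) * (1 - exp(-t / config$hr_tau_s)) +
    stats::rnorm(length(t), 0, config$hr_noise_sd)
  data.frame(t_s = t, vo2_ml_min = vo2, hr_bpm = hr)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> participant", x$participant_id,
      "activity", x$activity_code, sprintf("(%d s)", x$duration_s), "\n")
  cat("  drawn Youth METs:", round(x$sim$mets, 2),
      if (!is.na(x$exclusion_flag)) paste0("[excluded: ", x$exclusion_flag,
                                           "]") else "", "\n")
  invisible(x)
}
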