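# Reference anthropometry: CDC-growth-chart-style median body mass (kg) and
# height (m) by completed year of age and sex, used only to make the
# Schofield REE prediction realistic for simulated participants.
.anthro_reference <- data.frame(
  age = rep(8:18, 2),
  sex = rep(c("male", "female"), each = 11),
  mass_kg = c(25.6, 28.6, 31.9, 35.9, 40.6, 45.8, 51.0, 56.0, 60.9, 64.4, 66.9,
              25.8, 29.0, 32.9, 37.2, 41.5, 45.8, 49.4, 52.0, 53.9, 55.0, 56.7),
  height_m = c(1.280, 1.335, 1.385, 1.435, 1.490, 1.560, 1.635, 1.695, 1.730,
               1.750, 1.760,
               1.275, 1.330, 1.385, 1.445, 1.510, 1.570, 1.600, 1.615, 1.625,
               1.630, 1.632),
  stringsAsFactors = FALSE
)

#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic participant cohort
#'
#' Draws a cohort of children and adolescents matching the validation
#' study's demographics: ages from Normal(14.6, 2.4) truncated to
#' \[8, 18\] years, a 10:8 male:female ratio by default, body mass and
#' height from age- and sex-indexed reference medians with lognormal
#' spread, and right-handedness with probability 0.9.
#'
#' @param n Number of participants (default 18).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @param prop_male Expected proportion of males (default 10/18); the
#'   realised male count is `round(n * prop_male)`.
#' @param prop_right_handed Probability of right-handedness.
#' @param mass_cv,height_cv Lognormal coefficients of variation around the
#'   reference medians.
#' @return Data.frame with columns `id`, `age`, `sex`, `mass_kg`,
#'   `height_m`, `handedness`.
#' @examples
#' head(generate_participants(18, seed = 1))
#' @export
generate_participants <- function(n = 18, seed, prop_male = 10 / 18,
                                  prop_right_handed = 0.9,
                                  mass_cv = 0.15, height_cv = 0.04) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  with_local_seed(seed, {
    age <- rnorm_trunc(n, 14.6, 2.4, lower = 8, upper = 18)
    n_male <- round(n * prop_male)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    idx <- function(a, s) {
      ref <- .anthro_reference[.anthro_reference$sex == s, ]
      list(mass = stats::approx(ref$age, ref$mass_kg, a, rule = 2)$y,
           ht = stats::approx(ref$age, ref$height_m, a, rule = 2)$y)
    }
    mass <- numeric(n); height <- numeric(n)
    for (i in seq_len(n)) {
      ref <- idx(age[i], sex[i])
      mass[i] <- ref$mass * exp(stats::rnorm(1, 0, mass_cv))
      height[i] <- ref$ht * exp(stats::rnorm(1, 0, height_cv))
    }
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age,
      sex = sex,
      mass_kg = mass,
      height_m = height,
      handedness = ifelse(stats::runif(n) < prop_right_handed,
                          "right", "left"),
      stringsAsFactors = FALSE
    )
  })
}

#' Per-axis accelerometer calibration error
#'
#' Describes the miscalibration of a simulated device: the device reports
#' accelerations `a` such that `gain * a + offset` recovers the true
#' signal, which is exactly the model the autocalibration stage fits.
#'
#' @param gain Per-axis gain, each in \[0.9, 1.1\].
#' @param offset Per-axis offset in g, each within +/- 0.1 g.
#' @return A `calibration_error` list.
#' @export
calibration_error <- function(gain = c(1, 1, 1), offset = c(0, 0, 0)) {
  stopifnot(length(gain) == 3, length(offset) == 3,
            all(gain >= 0.9 & gain <= 1.1), all(abs(offset) <= 0.1))
  structure(list(gain = gain, offset = offset),
            class = "calibration_error")
}

#' @noRd
distort_raw <- function(raw, err) {
  out <- raw
  out$ax_g <- (raw$ax_g - err$offset[1]) / err$gain[1]
  out$ay_g <- (raw$ay_g - err$offset[2]) / err$gain[2]
  out$az_g <- (raw$az_g - err$offset[3]) / err$gain[3]
  out
}

#' Synthetic static-posture recording for calibration checks
#'
#' Concatenates a sequence of still holds in well-spread random
#' orientations, each with small sensor noise — the orientation-rich,
#' low-movement input the autocalibration sphere fit needs. Useful for
#' parameter-recovery experiments together with [calibration_error()].
#'
#' @param n_postures Number of distinct orientations (default 12).
#' @param hold_s Hold duration per posture, s (default 20, aligned with the
#'   10-s still-window grid).
#' @param noise_mg Per-axis sensor noise SD, m*g*.
#' @param hz Sampling rate.
#' @param seed Integer seed.
#' @return Data.frame with `t_s`, `ax_g`, `ay_g`, `az_g`.
#' @export
simulate_static_postures <- function(n_postures = 12, hold_s = 20,
                                     noise_mg = 3, hz = 30, seed = 1) {
  with_local_seed(seed, {
    n_per <- round(hold_s * hz)
    or <- matrix(stats::rnorm(3 * n_postures), ncol = 3)
    or <- or / sqrt(rowSums(or^2))
    acc <- or[rep(seq_len(n_postures), each = n_per), ] +
      matrix(stats::rnorm(3 * n_postures * n_per, 0, noise_mg / 1000),
             ncol = 3)
    n <- nrow(acc)
    data.frame(t_s = (seq_len(n) - 1) / hz,
               ax_g = acc[, 1], ay_g = acc[, 2], az_g = acc[, 3])
  })
}
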