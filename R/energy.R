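#' Ordered physical-activity intensity levels
#'
#' The four-level ordinal intensity scale used throughout: sedentary (SED) <
#' light (LPA) < moderate (MPA) < vigorous (VPA).
#'
#' @return Character vector of the four level names in increasing order.
#' @export
intensity_levels <- function() c("SED", "LPA", "MPA", "VPA")

#' @noRd
intensity_factor <- function(x) {
  factor(as.character(x), levels = intensity_levels(), ordered = TRUE)
}

# Schofield (1985) weight-and-height resting-metabolic-rate equations for
# children, MJ/day; mass in kg, height in m. One row per sex x age band.
.schofield_wh <- data.frame(
  sex       = c("male", "male", "female", "female"),
  band      = c("3-10", "10-18", "3-10", "10-18"),
  age_lo    = c(3, 10, 3, 10),
  age_hi    = c(10, 18, 10, 18),
  coef_mass = c(0.082, 0.068, 0.071, 0.035),
  coef_ht   = c(0.545, 0.574, 0.677, 1.948),
  intercept = c(1.736, 2.157, 1.553, 0.837),
  stringsAsFactors = FALSE
)

#' Predicted resting energy expenditure (Schofield)
#'
#' Predicts resting energy expenditure (REE) from sex, age, body mass and
#' height with the Schofield weight-and-height equations for children, using
#' the 3-10 y band below age 10 and the 10-18 y band from age 10, and
#' converts the MJ/day prediction to a resting oxygen uptake in
#' ml O2 kg^-1 min^-1 via the energy equivalent of oxygen.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years; must lie in \[3, 18\].
#' @param mass_kg Body mass in kg.
#' @param height_m Height in m.
#' @param kj_per_l_o2 Energy equivalent of oxygen in kJ per litre O2
#'   (default 20.9).
#' @return A list with `ree_mj_day` (MJ/day), `ree_vo2`
#'   (ml O2 kg^-1 min^-1) and `equation_band` (`"3-10"` or `"10-18"`).
#' @examples
#' schofield_ree("male", 14, 60, 1.70)
#' @export
schofield_ree <- function(sex, age, mass_kg, height_m, kj_per_l_o2 = 20.9) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(age) || age < 3 || age > 18)
    stop("age must be in [3, 18] years; got ", age)
  if (mass_kg <= 0 || height_m <= 0)
    stop("mass and height must be positive")
  band <- if (age < 10) "3-10" else "10-18"
  row <- .schofield_wh[.schofield_wh$sex == sex & .schofield_wh$band == band, ]
  mj_day <- row$coef_mass * mass_kg + row$coef_ht * height_m + row$intercept
  # MJ/day -> L O2/day -> ml O2/kg/min
  l_o2_day <- mj_day * 1000 / kj_per_l_o2
  ree_vo2 <- l_o2_day * 1000 / mass_kg / 1440
  list(ree_mj_day = mj_day, ree_vo2 = ree_vo2, equation_band = band)
}

#' Youth METs from measured oxygen uptake
#'
#' A Youth MET expresses a trial's mass-relative oxygen uptake as a multiple
#' of the child's predicted resting energy expenditure, rather than the
#' adult 3.5 ml kg^-1 min^-1 convention.
#'
#' @param mean_vo2 Mean oxygen uptake over the analysis window, ml/min.
#' @param mass_kg Body mass in kg.
#' @param ree A prediction from [schofield_ree()] (or any list with a
#'   positive `ree_vo2`).
#' @return Youth METs (unitless).
#' @export
youth_mets <- function(mean_vo2, mass_kg, ree) {
  if (any(mass_kg <= 0)) stop("mass must be positive")
  if (ree$ree_vo2 <= 0) stop("resting VO2 must be positive")
  (mean_vo2 / mass_kg) / ree$ree_vo2
}

#' Ground-truth intensity label from Youth METs and posture
#'
#' Sedentary requires both a lying or sitting posture and mean energy
#' expenditure below 1.5 Youth METs; an upright trial below 1.5 METs is
#' light. Light is \[1.5, 3) METs, moderate \[3, 6), vigorous >= 6.
#'
#' @param mets Youth METs, positive.
#' @param posture `"lying"`, `"sitting"` or `"upright"`.
#' @return Ordered factor over SED < LPA < MPA < VPA (vectorised over
#'   `mets`).
#' @examples
#' label_intensity(1.3, "lying")    # SED
#' label_intensity(1.2, "upright")  # LPA: posture gate
#' label_intensity(3.0, "upright")  # MPA: boundary is inclusive
#' @export
label_intensity <- function(mets, posture) {
  posture <- match.arg(posture, c("lying", "sitting", "upright"))
  if (any(!is.finite(mets)) || any(mets <= 0)) stop("mets must be positive")
  lab <- ifelse(mets >= 6, "VPA",
         ifelse(mets >= 3, "MPA",
         ifelse(mets >= 1.5, "LPA",
                if (posture %in% c("lying", "sitting")) "SED" else "LPA")))
  intensity_factor(lab)
}
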