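#' Built-in catalogue of the 12 structured activity trials
#'
#' Returns the laboratory activity catalogue used throughout the package: 12
#' structured activities spanning sedentary to vigorous intensity, each with
#' its posture, trial duration and the trial-level distribution targets the
#' synthetic cohort generator emulates — mean and SD of directly measured
#' Youth METs, and median/IQR of vertical-axis (VA) counts per 5 s,
#' vector-magnitude (VM) counts per 5 s, and ENMO in m*g*.
#'
#' Postures: lying down is `lying`; handwriting and the seated computer game
#' are `sitting`; all other activities are `upright`. Every trial lasts
#' 300 s except lying down (600 s).
#'
#' @return A data.frame with one row per activity and columns `code`,
#'   `activity`, `posture`, `duration_s`, `met_mean`, `met_sd`, `va_median`,
#'   `va_q1`, `va_q3`, `vm_median`, `vm_q1`, `vm_q3`, `enmo_median`,
#'   `enmo_q1`, `enmo_q3`. Codes: LD, HW, CG, LN, TC, SW, CW, DA, FW, TW,
#'   BB, RU.
#' @examples
#' profs <- activity_profiles()
#' profs[profs$code == "RU", c("met_mean", "va_median", "enmo_median")]
#' @export
activity_profiles <- function() {
  # Columns after posture/duration: MET mean, MET SD, then median/q1/q3 for
  # VA counts/5 s, VM counts/5 s and ENMO (m*g*).
  tab <- rbind(
    list("LD", "Lying down",     "lying",   600, 1.3, 0.3,    0,    0,   20,    0,    0,   56,  21.3, 10.7,  25.1),
    list("HW", "Handwriting",    "sitting", 300, 1.5, 0.2,    7,    2,    9,   35,   24,   56,   0.0,  0.0,  20.7),
    list("CG", "Computer game",  "sitting", 300, 1.4, 0.2,    5,    0,   11,   22,    5,   37,   8.5,  1.8,  21.1),
    list("LN", "Laundry task",   "upright", 300, 2.4, 0.4, 1039,  922, 1222, 1583, 1470, 1732, 290.1, 163.9, 334.2),
    list("TC", "Throw and catch","upright", 300, 2.6, 0.7,  520,  459,  624,  923,  783, 1089,  55.9, 33.6,  83.6),
    list("SW", "Sweeping floor", "upright", 300, 2.9, 0.5,  394,  307,  462,  573,  462,  622,  26.1, 18.9,  62.8),
    list("CW", "Comfortable walk","upright",300, 3.7, 0.6,  250,  220,  287,  327,  287,  381,  67.6, 30.7, 101.2),
    list("DA", "Dance",          "upright", 300, 4.3, 0.8, 1663, 1310, 1903, 2151, 1962, 2418, 156.8, 130.0, 255.5),
    list("FW", "Fast walk",      "upright", 300, 4.7, 0.8,  294,  253,  335,  415,  364,  537, 119.5, 77.0, 181.0),
    list("TW", "Treadmill walk", "upright", 300, 5.2, 0.9,  283,  213,  337,  393,  341,  521, 144.6, 96.5, 232.0),
    list("BB", "Basketball",     "upright", 300, 7.2, 1.5, 1246, 1045, 1444, 1930, 1692, 2196, 450.2, 296.5, 598.0),
    list("RU", "Run",            "upright", 300, 9.7, 2.3, 1392, 1156, 1477, 1804, 1595, 1983, 558.7, 396.5, 740.5)
  )
  out <- data.frame(
    code        = unlist(tab[, 1]),
    activity    = unlist(tab[, 2]),
    posture     = unlist(tab[, 3]),
    duration_s  = unlist(tab[, 4]),
    met_mean    = unlist(tab[, 5]),
    met_sd      = unlist(tab[, 6]),
    va_median   = unlist(tab[, 7]),
    va_q1       = unlist(tab[, 8]),
    va_q3       = unlist(tab[, 9]),
    vm_median   = unlist(tab[, 10]),
    vm_q1       = unlist(tab[, 11]),
    vm_q3       = unlist(tab[, 12]),
    enmo_median = unlist(tab[, 13]),
    enmo_q1     = unlist(tab[, 14]),
    enmo_q3     = unlist(tab[, 15]),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$code), all(out$met_mean > 0))
  out
}

#' @noRd
get_profile <- function(code, profiles = activity_profiles()) {
  i <- match(code, profiles$code)
  if (is.na(i)) stop("unknown activity code: ", code)
  profiles[i, , drop = FALSE]
}
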