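# Shared fixtures built in code.

fixture_participant <- function() {
  data.frame(id = "P001", age = 14, sex = "male", mass_kg = 60,
             height_m = 1.70, handedness = "right",
             stringsAsFactors = FALSE)
}

fixture_profile <- function(code) {
  profs <- activity_profiles()
  profs[profs$code == code, , drop = FALSE]
}

# A hand-built trial with fully controlled values: constant counts, a quiet
# raw signal and constant gas exchange.
fixture_constant_trial <- function(va = 250, ml = 0, ap = 0, vo2 = 900,
                                   hr = 120, duration = 300,
                                   code = "CW") {
  t_raw <- seq(0, duration - 1 / 30, by = 1 / 30)
  raw <- data.frame(t_s = t_raw, ax_g = 1, ay_g = 0, az_g = 0)
  counts <- data.frame(epoch_start_s = seq(0, duration - 5, by = 5),
                       va = va, ml = ml, ap = ap)
  gas <- data.frame(t_s = seq(0, duration - 15, by = 15),
                    vo2_ml_min = vo2, hr_bpm = hr)
  structure(list(participant_id = "P001", activity_code = code,
                 duration_s = duration,
                 raw = list(left = raw, right = raw),
                 counts = list(left = counts, right = counts),
                 gas = gas, exclusion_flag = NA_character_, sim = NULL),
            class = "trial_recording")
}

identity_cal_pair <- function() {
  list(left = identity_calibration(), right = identity_calibration())
}
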