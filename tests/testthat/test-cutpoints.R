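test_that("the registry carries the seven published sets verbatim", {
  cp <- builtin_cutpoints()
  expect_equal(nrow(cp), 7)
  expect_false(anyDuplicated(cp$name) > 0)

  get <- function(nm) cp[cp$name == nm, ]
  expect_equal(unlist(get("CR_ROC_VA")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(105, 262, 565))
  expect_equal(unlist(get("CR_ROC_VM")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(275, 416, 778))
  expect_equal(unlist(get("CR_REG_VA")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(35, 361, 1130))
  expect_equal(unlist(get("CR_REG_VM")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(100, 610, 1810))
  expect_equal(unlist(get("CH_ROC_VA")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(161, 530, 1462))
  expect_equal(unlist(get("CH_ROC_VM")[c("sed_upper", "mpa_lower",
                                         "vpa_lower")], use.names = FALSE),
               c(305, 818, 1969))
  expect_equal(unlist(get("HD_ENMO")[c("sed_upper", "mpa_lower",
                                       "vpa_lower")], use.names = FALSE),
               c(35.6, 201.4, 707.0))
  expect_equal(get("CR_REG_VA")$reg_intercept, 1.592)
  expect_equal(get("CR_REG_VA")$reg_slope, 0.0039)
  expect_equal(get("CR_REG_VM")$reg_intercept, 1.475)
  expect_equal(get("CR_REG_VM")$reg_slope, 0.0025)

  # wear-side conventions
  expect_true(all(cp$wrist[grepl("^CR_", cp$name)] == "dominant"))
  expect_true(all(cp$wrist[!grepl("^CR_", cp$name)] == "nondominant"))
  expect_equal(get("HD_ENMO")$epoch_s, 1)
})

test_that("the regression equations evaluate and invert consistently", {
  expect_equal(regression_mets(0, "CR_REG_VA"), 1.592)
  expect_equal(regression_mets(250, "CR_REG_VA"), 2.567)
  expect_equal(regression_mets(1583, "CR_REG_VM"), 5.4325)
  expect_error(regression_mets(100, "CR_ROC_VA"), "regression")
  expect_error(regression_mets(-5, "CR_REG_VA"), "non-negative")

  expect_identical(invert_regression("CR_REG_VA", 3), 361)
  expect_identical(invert_regression("CR_REG_VA", 6), 1130)
  expect_identical(invert_regression("CR_REG_VM", 3), 610)
  expect_identical(invert_regression("CR_REG_VM", 6), 1810)
  expect_identical(invert_regression("CR_REG_VA", 1.592), 0)
  expect_error(invert_regression("CR_REG_VA", 1.0), "intercept")
})

test_that("classification honours each set's boundary semantics", {
  expect_equal(as.character(classify_value(250, "CR_ROC_VA")), "LPA")
  expect_equal(as.character(classify_value(290.1, "HD_ENMO")), "MPA")
  expect_equal(as.character(classify_value(1583, "CR_ROC_VM")), "VPA")
  # Crouter: SED <= threshold
  expect_equal(as.character(classify_value(105, "CR_ROC_VA")), "SED")
  expect_equal(as.character(classify_value(105.1, "CR_ROC_VA")), "LPA")
  # Chandler/Hildebrand: SED strictly below threshold
  expect_equal(as.character(classify_value(160.9, "CH_ROC_VA")), "SED")
  expect_equal(as.character(classify_value(161, "CH_ROC_VA")), "LPA")
  expect_equal(as.character(classify_value(35.6, "HD_ENMO")), "LPA")
  expect_equal(as.character(classify_value(35.5, "HD_ENMO")), "SED")
})

test_that("classification is monotone in the metric for every set", {
  grid <- seq(0, 2500, by = 2.5)
  for (nm in builtin_cutpoints()$name) {
    codes <- as.integer(classify_value(grid, nm))
    expect_true(all(diff(codes) >= 0), info = nm)
  }
})

test_that("the wrist the set was calibrated for is selected", {
  feats <- data.frame(side = c("left", "right"),
                      mean_va = c(50, 600), mean_vm = c(50, 600),
                      mean_enmo = c(10, 400))
  # right-handed: Crouter (dominant) reads the right wrist -> VPA
  expect_equal(as.character(classify_trial(feats, "CR_ROC_VA", "right")),
               "VPA")
  # right-handed: Hildebrand (non-dominant) reads the left wrist -> SED
  expect_equal(as.character(classify_trial(feats, "HD_ENMO", "right")),
               "SED")
  # left-handed flips both
  expect_equal(as.character(classify_trial(feats, "CR_ROC_VA", "left")),
               "SED")
  expect_equal(as.character(classify_trial(feats, "HD_ENMO", "left")),
               "MPA")
  expect_error(classify_trial(feats[1, ], "CR_ROC_VA", "right"), "side")
})

test_that("Table-3 median features reproduce the direction claims", {
  profs <- activity_profiles()
  sets <- builtin_cutpoints()
  med_label <- function(code, nm) {
    p <- profs[profs$code == code, ]
    set <- sets[sets$name == nm, ]
    x <- switch(set$metric, va = p$va_median, vm = p$vm_median,
                enmo = p$enmo_median)
    as.character(classify_value(x, set))
  }
  # slow walking (true MPA) underestimated as LPA by every set
  for (nm in sets$name) expect_equal(med_label("CW", nm), "LPA", info = nm)
  # laundry (true LPA) overestimated as MPA or VPA by every set
  for (nm in sets$name)
    expect_true(med_label("LN", nm) %in% c("MPA", "VPA"), info = nm)
  # Hildebrand: walking trials LPA, basketball and running only MPA
  expect_equal(med_label("FW", "HD_ENMO"), "LPA")
  expect_equal(med_label("TW", "HD_ENMO"), "LPA")
  expect_equal(med_label("BB", "HD_ENMO"), "MPA")
  expect_equal(med_label("RU", "HD_ENMO"), "MPA")
})

test_that("a YAML registry round-trips and validates", {
  path <- tempfile(fileext = ".yaml")
  write_cutpoints_yaml(path)
  back <- read_cutpoints_yaml(path)
  cp <- builtin_cutpoints()
  expect_equal(back[order(back$name), ], cp[order(cp$name), ],
               ignore_attr = TRUE)
})
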