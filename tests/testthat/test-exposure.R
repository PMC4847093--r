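# Exposure scoring: attribute scores, route assignment cascade, the
# permeability QSPR, equation structure and its invariants.

test_that("lifestage and concentration scores follow the reporting bins", {
  expect_equal(score_lifestage("under_three"), 3)
  expect_equal(score_lifestage("three_to_twelve"), 1)
  expect_equal(score_lifestage("under_three"),
               score_lifestage("under_three")) # pure, no hidden state
  expect_equal(score_concentration(c("lt100", "100-500", "500-1000",
                                     "1000-5000", "5000-10000", "gt10000")),
               c(0.5, 1, 1.5, 2, 2.5, 3))
  expect_equal(score_concentration(">10,000"), 3)
  expect_error(score_lifestage("adult"), "invalid")
  expect_error(score_concentration("250 ppm"), "invalid")
})

test_that("duration and skin-application scores follow the segment sets", {
  expect_equal(score_duration("Clothing"), 3)
  expect_equal(score_duration("Toys/Games"), 1)
  expect_equal(score_duration("Arts/Crafts/Needlework"), 1)
  expect_warning(got <- score_duration("Mystery Segment"), "unknown")
  expect_equal(got, 1)
  expect_equal(score_applied_to_skin("Beauty/Personal Care/Hygiene"), 3)
  expect_equal(score_applied_to_skin("Clothing"), 1)
  expect_equal(score_applied_to_skin("Kitchen Merchandise"), 1)
})

test_that("property scores bin at the documented cutoffs", {
  expect_equal(score_solubility(c(0.0005, 0.005, 0.5)), c(1, 2, 3))
  expect_equal(score_solubility(c(0.001, 0.01)), c(2, 3)) # lower-inclusive
  expect_error(score_solubility(0), "positive")
  expect_equal(score_vapor_pressure(c(0.01, 1, 100)), c(1, 2, 3))
  expect_equal(score_vapor_pressure(c(0.075, 32)), c(2, 2))
  expect_error(score_vapor_pressure(-1), "non-negative")
  expect_equal(score_kp(c(1e-3, 5e-3, 1e-2)), c(1, 2, 3))
  expect_equal(score_kp(c(3.395e-3, 6.7e-3)), c(1, 2)) # half-open upward
  expect_error(score_kp(0), "positive")
})

test_that("permeability QSPR matches hand evaluations", {
  expect_equal(compute_kp(0, 0), 10^-2.72, tolerance = 1e-12)
  expect_equal(compute_kp(2, 100), 10^-1.91, tolerance = 1e-12)
  expect_equal(compute_kp(0, 500), 10^-5.77, tolerance = 1e-12)
  expect_error(compute_kp(1, -10), "non-negative")
})

test_that("absorption scoring handles percents, unknown rate, and missing", {
  expect_equal(score_absorption(3), 1)
  expect_equal(score_absorption("unknown_rate"), 2)
  expect_equal(score_absorption(c(5, 7, 10, 50)), c(1, 2, 2, 3))
  expect_equal(score_absorption(0.5), 1) # below 1% floors at 1
  expect_true(is.na(score_absorption(NA_real_)))
  expect_error(score_absorption(150), "within")
  # alternative binning: anything above 5% scores 3
  alt <- default_rules(overrides = list(absorption_high_above_5 = TRUE))
  expect_equal(score_absorption(c(3, 7, 50), alt), c(1, 3, 3))
})

test_that("route cascade reproduces the documented assignments", {
  shirt <- assign_exposure_routes("Clothing", target_age = "under_three")
  expect_equal(c(shirt$dermal_mf, shirt$oral_mf, shirt$inhalation_mf),
               c(3, 2, 1))
  paint <- assign_exposure_routes("Arts/Crafts/Needlework", brick = "paint")
  expect_equal(c(paint$inhalation_mf, paint$dermal_mf, paint$oral_mf),
               c(3, 2, 1))
  kitchen <- assign_exposure_routes("Kitchen Merchandise",
                                    target_age = "three_to_twelve")
  expect_equal(c(kitchen$oral_mf, kitchen$dermal_mf, kitchen$inhalation_mf),
               c(3, 2, 1))
  blower <- assign_exposure_routes("Stationery/Office Machinery/Occasion Supplies",
                                   brick = "party blower",
                                   target_age = "three_to_twelve")
  expect_equal(c(blower$oral_mf, blower$inhalation_mf, blower$dermal_mf),
               c(3, 3, 2))
  fragrance <- assign_exposure_routes("Beauty/Personal Care/Hygiene",
                                      brick = "fragrance")
  expect_equal(c(fragrance$dermal_mf, fragrance$inhalation_mf,
                 fragrance$oral_mf), c(3, 3, 1))
  pacifier <- assign_exposure_routes("Baby Care", brick = "pacifier",
                                     target_age = "under_three")
  expect_equal(c(pacifier$oral_mf, pacifier$dermal_mf,
                 pacifier$inhalation_mf), c(3, 2, 1))
  kitchen_toy <- assign_exposure_routes("Toys/Games", brick = "kitchen toy")
  expect_equal(kitchen_toy$oral_mf, 3)
  expect_equal(kitchen_toy$dermal_mf, 2)
})

test_that("route assignment invariants hold across all inputs", {
  ages <- c("under_three", "three_to_twelve")
  bricks <- c(NA, "paint", "party blower", "fragrance", "pacifier",
              "kitchen toy")
  for (seg in cspa_segments()) {
    for (age in ages) {
      for (brick in bricks) {
        r <- assign_exposure_routes(seg, brick, age)
        mfs <- c(r$oral_mf, r$dermal_mf, r$inhalation_mf)
        expect_true(all(mfs %in% 1:3))
        expect_lte(sum(mfs == 3), 2) # at most two primaries
      }
    }
  }
})

test_that("route components average property and absorption, or fall back", {
  expect_equal(route_component(3, 3, 2), 7.5)
  expect_equal(route_component(2, 3, NA), 6)
  expect_equal(route_component(1, 1, 1), 1)
  expect_equal(route_component(2, NA, 2), 4) # property missing, observed only
  expect_error(route_component(2, NA, NA), "neither")
})

test_that("exposure equation reproduces hand-computed cases", {
  profs <- bundled_profiles()
  # formaldehyde in an under-3 shirt at 100-500 ppm:
  # (3+3+1+1) + oral 2*(3+2)/2 + dermal 3*(1+3)/2 + inhalation 1*(3+3)/2
  rep <- make_report("formaldehyde", "Clothing", "under_three", "100-500")
  b <- exposure_score(rep, chemical_profile(profs, "formaldehyde"))
  expect_equal(b$total, 22)
  expect_equal(b$oral$component, 5)
  expect_equal(b$dermal$component, 6)
  expect_equal(b$inhalation$component, 3)
  # all-minimum chemical (molybdenum: S=Kp=VP=1, no absorption data) in a
  # 3+ short-term arts product below 100 ppm: 3.5 + (1 + 3 + 1)
  rep2 <- make_report("molybdenum", "Arts/Crafts/Needlework",
                      "three_to_twelve", "lt100")
  b2 <- exposure_score(rep2, chemical_profile(profs, "molybdenum"))
  expect_equal(b2$total, 8.5)
})

test_that("breakdown total always equals the recomputed sum of its parts", {
  fx <- scenario_fixture("edge_cases")
  for (i in seq_len(nrow(fx$reports))) {
    prof <- chemical_profile(fx$profiles, fx$reports$chemical_id[i])
    b <- suppressWarnings(
      exposure_score(fx$reports[i, ], prof)
    )
    expect_equal(b$total,
                 b$ls + b$ex + b$a + b$con + b$oral$component +
                   b$dermal$component + b$inhalation$component)
    for (route in c("oral", "dermal", "inhalation")) {
      expect_gte(b[[route]]$tk_average, 1)
      expect_lte(b[[route]]$tk_average, 3)
    }
  }
})

test_that("raw property values are scored only when no score is present", {
  prof <- validate_profiles(data.frame(
    chemical_id = "synthetic_raw", solubility_score = 1,
    water_solubility_mol_l = 0.5,       # would score 3; the score 1 wins
    vapor_pressure_mmhg = 100,          # scores 3
    log_kow = 2, molecular_weight = 100 # Kp 1.23e-2 -> score 3
  ))
  rep <- make_report("synthetic_raw", "Toys/Games", "three_to_twelve", "lt100")
  b <- exposure_score(rep, prof)
  expect_equal(b$oral$property, 1)
  expect_equal(b$inhalation$property, 3)
  expect_equal(b$dermal$property, 3)
})

test_that("missing dermal permeability falls back to observed absorption", {
  profs <- bundled_profiles()
  rep <- make_report("antimony", "Clothing", "three_to_twelve", "lt100")
  b <- exposure_score(rep, chemical_profile(profs, "antimony"))
  expect_true(is.na(b$dermal$property))
  expect_equal(b$dermal$component, 3 * 2) # MF 3 x observed absorption 2
})

test_that("exposure is monotone in concentration and lifestage", {
  profs <- bundled_profiles()
  bins <- concentration_bins()
  for (chem in c("styrene", "molybdenum", "butyl_paraben")) {
    prof <- chemical_profile(profs, chem)
    totals <- vapply(bins, function(bin) {
      exposure_score(make_report(chem, "Toys/Games", "three_to_twelve", bin),
                     prof)$total
    }, numeric(1))
    expect_equal(unname(diff(totals)), rep(0.5, 5)) # one bin = +0.5 exactly
    for (seg in c("Clothing", "Kitchen Merchandise")) {
      lo <- exposure_score(make_report(chem, seg, "three_to_twelve", "lt100"),
                           prof)$total
      hi <- exposure_score(make_report(chem, seg, "under_three", "lt100"),
                           prof)$total
      expect_gte(hi, lo)
    }
  }
})

test_that("implementation agrees with the brute-force oracle on the full grid", {
  profs <- bundled_profiles()
  ages <- c("under_three", "three_to_twelve")
  bins <- concentration_bins()
  n_checked <- 0L
  for (seg in cspa_segments()) {
    for (age in ages) {
      for (bin in bins) {
        reps <- lapply(profs$chemical_id, make_report, segment = seg,
                       target_age = age, concentration_bin = bin)
        for (k in seq_len(nrow(profs))) {
          prof <- profs[k, ]
          got <- exposure_score(reps[[k]], prof)$total
          want <- oracle_exposure(seg, age, bin, as.list(prof))
          expect_identical(got, want)
          expect_gte(got, 6.5)
          expect_lte(got, 36)
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  expect_equal(n_checked, 11L * 2L * 6L * 21L)
})
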