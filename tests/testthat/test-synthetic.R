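test_that("generated encounters hit the target complexity mix within binomial error", {
  s <- generator_settings(seed = 21, n_encounters = 1e4, prop_basic_target = 0.60)
  enc <- generate_encounters(s)
  frac <- mean(classify_visit(enc) == "basic")
  expect_lt(abs(frac - 0.60), 3 * sqrt(0.6 * 0.4 / 1e4))
  # boundary: all-basic generation
  enc1 <- generate_encounters(generator_settings(seed = 21, n_encounters = 500,
                                                 prop_basic_target = 1))
  expect_true(all(classify_visit(enc1) == "basic"))
})

test_that("every generated record is classified into its generating stratum", {
  for (seed in c(1, 5, 77)) {
    enc <- generate_encounters(generator_settings(seed = seed, n_encounters = 2000))
    expect_identical(classify_visit(enc), enc$stratum)
  }
  # constraints that make strata recoverable
  enc <- generate_encounters(generator_settings(seed = 2, n_encounters = 3000))
  basic <- enc[enc$stratum == "basic", ]
  expect_true(all(basic$iv_therapies == 0))
  expect_true(all((basic$lab_panels > 0) + (basic$radiology_studies > 0) <= 1))
  adv <- enc[enc$stratum == "advanced", ]
  expect_true(all(adv$iv_therapies >= 1 |
                    ((adv$lab_panels > 0) & (adv$radiology_studies > 0))))
})

test_that("generation is reproducible and settings are validated", {
  s <- generator_settings(seed = 8, n_encounters = 400)
  expect_identical(generate_encounters(s), generate_encounters(s))
  expect_error(generator_settings(n_encounters = 0), "positive")
  expect_error(generator_settings(prop_basic_target = 1.2), "\\[0, 1\\]")
  expect_error(generator_settings(cost_scale = c(default = -1)), "positive")
  expect_error(generator_settings(basic_rates = list(p_diagnostic = 1.4,
                                                     p_lab_given_diagnostic = 0.5,
                                                     mean_oral_meds = 1,
                                                     p_new_rx = 0.5)),
               "probabilities")
})

test_that("utilization summaries are per-stratum means over classified visits", {
  enc <- data.frame(encounter_id = c("a", "b", "c"),
                    lab_panels = c(1L, 0L, 1L),
                    radiology_studies = c(0L, 0L, 1L),
                    iv_therapies = c(0L, 0L, 2L),
                    oral_medications = c(2L, 0L, 1L),
                    new_prescription = c(TRUE, FALSE, FALSE))
  u <- encounters_to_utilization(enc)
  expect_equal(u$n_visits, c(2L, 1L))            # partition of the records
  expect_equal(u$mean_lab_panels[u$stratum == "basic"], 0.5)
  expect_equal(u$mean_iv_therapies[u$stratum == "advanced"], 2)
  # empty stratum: count 0 with absent means
  adv_only <- enc[3, ]
  u2 <- encounters_to_utilization(adv_only)
  expect_equal(u2$n_visits[u2$stratum == "basic"], 0L)
  expect_true(is.na(u2$mean_lab_panels[u2$stratum == "basic"]))
  expect_error(encounters_to_utilization(enc[0, ]), "non-empty")
})

test_that("config generation scales PERT triples and keeps the schema valid", {
  template <- mih_template()
  s1 <- generator_settings(seed = 1, cost_scale = c(default = 1))
  expect_equal(generate_config(s1, template)$elements, template$elements)
  s2 <- generator_settings(seed = 1,
                           cost_scale = c(personnel_paramedics = 2, default = 1))
  cfg2 <- generate_config(s2, template)
  p0 <- mihcost:::get_element(template, "personnel_paramedics")$pert
  p2 <- mihcost:::get_element(cfg2, "personnel_paramedics")$pert
  expect_equal(c(p2$min, p2$mode, p2$max), 2 * c(p0$min, p0$mode, p0$max))
  expect_equal(mihcost:::get_element(cfg2, "fuel"),
               mihcost:::get_element(template, "fuel"))
  # visit mix follows the settings
  s3 <- generator_settings(seed = 1, n_encounters = 400, prop_basic_target = 0.7)
  cfg3 <- generate_config(s3, template)
  expect_equal(cfg3$visit_mix$annual_visits$mode, 400)
  expect_equal(cfg3$visit_mix$prop_basic, 0.7)
  expect_s3_class(validate_config(cfg3), "mih_config")
})

test_that("calibration is a fixed point at the template's own medians and is deterministic", {
  template <- mih_template()
  sim <- mih_simulate(template, iterations = 1000, seed = 1)
  own <- c(basic = median(sim$basic), advanced = median(sim$advanced))
  cal <- calibrate_config(template, targets = own, tolerance = 0.02,
                          iterations = 1000, seed = 1)
  expect_true(attr(cal, "converged"))
  expect_equal(unname(attr(cal, "scales")), c(1, 1, 1))
  expect_equal(attr(cal, "evaluations"), 1L)
  cal2 <- calibrate_config(template, targets = own, tolerance = 0.02,
                           iterations = 1000, seed = 1)
  expect_identical(attr(cal, "scales"), attr(cal2, "scales"))
  expect_error(calibrate_config(template, targets = c(basic = -5, advanced = 10)),
               "positive")
})
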