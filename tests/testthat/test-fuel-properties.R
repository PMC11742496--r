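# ADU-to-property correlations, cold-flow descriptors, and compliance.

test_that("each correlation returns its intercept at ADU zero", {
  expect_equal(kinematic_viscosity(0), 5.20)
  expect_equal(specific_gravity(0), 0.87)
  expect_equal(cetane_number(0), 62.87)
  expect_equal(iodine_value(0), 12.71)
  expect_equal(higher_heating_value(0), 38.53)
  expect_equal(cloud_point(0, "printed"), 19.99)
  expect_equal(cloud_point(0, "reconstructed"), 19.994)
})

test_that("correlations reproduce the reference panel at the two profile ADUs", {
  # optimized ADU 0.6950, control ADU 0.7853
  expect_equal(kinematic_viscosity(0.6950), 4.761455, tolerance = 1e-9)
  expect_equal(kinematic_viscosity(0.7853), 4.7044757, tolerance = 1e-9)
  expect_equal(cetane_number(0.6950), 58.23, tolerance = 0.02)
  expect_equal(cetane_number(0.7853), 57.63, tolerance = 0.02)
  expect_equal(iodine_value(0.6950), 64.40, tolerance = 0.02)
  expect_equal(iodine_value(0.7853), 71.11, tolerance = 0.02)
  expect_equal(higher_heating_value(0.6950), 39.75, tolerance = 0.02)
  expect_equal(higher_heating_value(0.7853), 39.91, tolerance = 0.02)
  expect_equal(cloud_point(0.6950), 10.71, tolerance = 0.02)
  expect_equal(cloud_point(0.7853), 9.51, tolerance = 0.02)
  # the printed cloud-point slope cannot reach the published cloud points
  expect_equal(cloud_point(0.6950, "printed"), 17.66, tolerance = 0.005)
})

test_that("negative ADU is a domain error everywhere", {
  expect_error(kinematic_viscosity(-0.1), "non-negative")
  expect_error(cloud_point(-1), "non-negative")
  expect_error(fuel_panel_from_adu(-0.5), "non-negative")
})

test_that("panel affine identities hold over fuzzed ADU values", {
  set.seed(23)
  a <- stats::runif(1000, 0, 3)
  expect_true(all(abs(kinematic_viscosity(a) + 0.631 * a - 5.20) < 1e-9))
  expect_true(all(abs(cetane_number(a) + 6.67 * a - 62.87) < 1e-9))
  expect_true(all(abs(iodine_value(a) - 74.37 * a - 12.71) < 1e-9))
  expect_true(all(abs(higher_heating_value(a) - 1.760 * a - 38.53) < 1e-9))
  expect_true(all(abs(specific_gravity(a) - 0.0055 * a - 0.87) < 1e-9))
})

test_that("CN, KV, Cp decrease and IV, SG, HHV increase with ADU", {
  a <- sort(stats::runif(100, 0, 2))
  expect_true(all(diff(cetane_number(a)) < 0))
  expect_true(all(diff(kinematic_viscosity(a)) < 0))
  expect_true(all(diff(cloud_point(a)) < 0))
  expect_true(all(diff(cloud_point(a, "printed")) < 0))
  expect_true(all(diff(iodine_value(a)) > 0))
  expect_true(all(diff(specific_gravity(a)) > 0))
  expect_true(all(diff(higher_heating_value(a)) > 0))
})

test_that("the two cloud-point variants agree at zero and diverge linearly", {
  expect_lt(abs(cloud_point(0, "printed") - cloud_point(0, "reconstructed")),
            0.004 + 1e-12)
  a <- seq(0.1, 2, by = 0.1)
  gap <- cloud_point(a, "printed") - cloud_point(a, "reconstructed")
  expect_equal(gap, -0.004 + (13.356 - 3.35) * a)
})

test_that("full panel from the reference profiles matches the published panel", {
  opt <- fuel_panel(make_optimized_profile())
  expect_equal(round(opt$adu, 2), 0.70)
  expect_equal(opt$cn, 58.23, tolerance = 0.005)
  expect_equal(opt$iv, 64.40, tolerance = 0.005)
  expect_equal(opt$cp, 10.71, tolerance = 0.005)
  expect_equal(opt$hhv, 39.75, tolerance = 0.005)
  expect_equal(opt$kv, 4.76, tolerance = 0.005)
  ctl <- fuel_panel(make_control_profile())
  expect_equal(round(ctl$adu, 2), 0.79)
  expect_equal(ctl$cn, 57.63, tolerance = 0.005)
  expect_equal(ctl$iv, 71.11, tolerance = 0.005)
  expect_equal(ctl$cp, 9.51, tolerance = 0.005)
  expect_equal(ctl$hhv, 39.91, tolerance = 0.005)
  # panel ADU equals the brute-force lookup oracle
  expect_equal(opt$adu, oracle_adu(optimized_acids))
  expect_equal(ctl$adu, oracle_adu(control_acids))
})

test_that("a pure-saturate profile returns every intercept", {
  p <- fuel_panel(fa_profile("sat", "sat", "C16:0", 100))
  expect_equal(p$adu, 0)
  expect_equal(p$cn, 62.87)
  expect_equal(p$iv, 12.71)
  expect_equal(p$kv, 5.20)
  expect_equal(p$hhv, 38.53)
})

test_that("cold-flow descriptors follow the literature formulas", {
  stearic <- fa_profile("s", "s", "C18:0", 100)
  aux <- auxiliary_cold_flow(stearic)
  expect_equal(aux$sv, 560 * 100 / 284.48, tolerance = 1e-9)  # ~196.85
  expect_equal(aux$lcsf, 50)
  expect_equal(aux$provenance, "literature-form, not paper-verified")

  opt <- auxiliary_cold_flow(make_optimized_profile())
  expect_equal(opt$lcsf, 0.1 * 39.84 + 0.5 * 1.22 + 1 * 1.39)  # 5.984
  expect_equal(opt$cfpp, 3.1417 * 5.984 - 16.477, tolerance = 1e-9)

  unsat <- auxiliary_cold_flow(fa_profile("u", "u", "C20:5n3", 90))
  expect_equal(unsat$lcsf, 0)
  expect_equal(unsat$cfpp, -16.477)
})

test_that("a quantified acid absent from the MW lookup is a named error", {
  p <- fa_profile("x", "x", c("C16:0", "C19:0"), c(50, 10))
  expect_error(auxiliary_cold_flow(p), "C19:0")
})

test_that("compliance verdicts reproduce the published standards structure", {
  # published optimized panel values
  rep <- check_compliance(fuel_panel_from_adu(0.5547))
  bounded <- rep[rep$property %in% c("cn", "kv", "iv"), ]
  expect_true(all(bounded$en14214 == "pass"))
  expect_true(rep$astm_d6751[rep$property == "cn"] == "pass")
  expect_true(rep$astm_d6751[rep$property == "kv"] == "pass")
  expect_true(rep$astm_d6751[rep$property == "sg"] == "pass")
  # informational rows are not-applicable, never failures
  expect_true(all(rep$en14214[rep$property %in% c("adu", "cp", "hhv", "sg")] ==
                    "not-applicable"))
  expect_true(all(rep$astm_d6751[rep$property %in% c("adu", "cp", "hhv", "iv")] ==
                    "not-applicable"))
})

test_that("sub-threshold cetane fails both standards; mid KV splits them", {
  low_cn <- fuel_panel_from_adu((62.87 - 46.0) / 6.67)  # CN exactly 46
  rep <- check_compliance(low_cn)
  expect_equal(rep$en14214[rep$property == "cn"], "fail")
  expect_equal(rep$astm_d6751[rep$property == "cn"], "fail")

  # KV 5.5: outside EN 14214's [3.5, 5.0], inside ASTM's [1.9, 6.0]
  p <- fuel_panel_from_adu(0)
  p$kv <- 5.5
  rep2 <- check_compliance(p)
  expect_equal(rep2$en14214[rep2$property == "kv"], "fail")
  expect_equal(rep2$astm_d6751[rep2$property == "kv"], "pass")
})

test_that("compliance is monotone in CN: raising CN never flips pass to fail", {
  cn_seq <- seq(40, 70, by = 1)
  verdicts <- vapply(cn_seq, function(cn) {
    p <- fuel_panel_from_adu(0.5)
    p$cn <- cn
    r <- check_compliance(p)
    r$en14214[r$property == "cn"]
  }, "")
  passed <- verdicts == "pass"
  expect_true(all(diff(as.integer(passed)) >= 0))
})
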