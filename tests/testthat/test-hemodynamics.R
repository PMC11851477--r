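test_that("Poiseuille resistance reproduces the reference capillary value and scalings", {
  r_cap <- poiseuille_resistance(capillary_geometry())
  expect_equal(signif(r_cap, 3), 1.43e16)

  # r^4 scaling: doubling the diameter divides resistance by 16
  g <- capillary_geometry()
  g2 <- vessel_geometry(diameter = 2 * g$diameter, length = g$length,
                        wall_thickness = g$wall_thickness,
                        viscosity = g$viscosity, density = g$density,
                        reference_pressure = g$reference_pressure)
  expect_equal(poiseuille_resistance(g2), r_cap / 16)

  # constants cancel: d = 2 m (radius 1 m), l = pi m, eta = 1/8 Pa.s -> R = 1
  g3 <- vessel_geometry(diameter = 2000, length = pi, wall_thickness = 1,
                        viscosity = 1 / 8, density = 1060,
                        reference_pressure = 1)
  expect_equal(poiseuille_resistance(g3), 1.0)

  expect_error(vessel_geometry(diameter = -1, length = 1, wall_thickness = 1,
                               viscosity = 1, density = 1, reference_pressure = 1),
               class = "capfit_invalid_input")
})

test_that("Poiseuille resistance is homogeneous in viscosity, length and diameter", {
  set.seed(11)
  for (i in 1:25) {
    g <- vessel_geometry(diameter = runif(1, 0.001, 10), length = runif(1, 1e-4, 1),
                         wall_thickness = 0.1, viscosity = runif(1, 1e-4, 0.1),
                         density = 1060, reference_pressure = 25)
    k <- runif(1, 0.5, 3)
    r0 <- poiseuille_resistance(g)
    scale_field <- function(field, k) {
      gg <- unclass(g); gg[[field]] <- gg[[field]] * k
      do.call(vessel_geometry, gg)
    }
    expect_rel_equal(poiseuille_resistance(scale_field("viscosity", k)), k * r0, 1e-12)
    expect_rel_equal(poiseuille_resistance(scale_field("length", k)), k * r0, 1e-12)
    expect_rel_equal(poiseuille_resistance(scale_field("diameter", k)), r0 / k^4, 1e-12)
  }
})

test_that("Poiseuille flow and pressure conversion follow the linear laws", {
  r_cap <- poiseuille_resistance(capillary_geometry())
  expect_equal(signif(poiseuille_flow(mmhg_to_pa(25), r_cap), 3), 2.34e-13)
  expect_equal(poiseuille_flow(0, r_cap), 0)
  expect_equal(poiseuille_flow(1, 4), 0.25)
  expect_error(poiseuille_flow(1, 0), class = "capfit_invalid_input")

  expect_equal(mmhg_to_pa(0), 0)
  expect_equal(mmhg_to_pa(25), 3333.05)
  expect_equal(mmhg_to_pa(120), 15998.64)

  # superposition in the driving pressure
  set.seed(12)
  p1 <- runif(5, 1, 200); p2 <- runif(5, 1, 200)
  expect_equal(poiseuille_flow(mmhg_to_pa(p1[1] + p2[1]), r_cap),
               poiseuille_flow(mmhg_to_pa(p1[1]), r_cap) +
                 poiseuille_flow(mmhg_to_pa(p2[1]), r_cap))
})

test_that("ABI computation and classification follow the printed strata", {
  expect_equal(round(compute_abi(200, 150), 2), 1.33)
  expect_equal(round(compute_abi(160, 140), 2), 1.14)
  expect_equal(compute_abi(120, 120), 1.0)
  expect_error(compute_abi(100, 0), class = "capfit_invalid_input")

  expect_identical(classify_abi(0.6), "moderate")
  expect_identical(classify_abi(0.3), "severe")
  expect_identical(classify_abi(0.4), "severe")     # inclusive boundary
  expect_identical(classify_abi(1.0), "normal")
  expect_identical(classify_abi(1.4), "moenckeberg")
  expect_identical(classify_abi(1.35), "unclassified")
  expect_identical(classify_abi(0.8), "unclassified")
  expect_identical(classify_abi(0.405), "unclassified")
  expect_error(classify_abi(0), class = "capfit_invalid_input")
})

test_that("patient records validate the ABI consistency invariant", {
  expect_silent(patient_record("X", 160, 100, 0.6, 1))
  expect_error(patient_record("X", 160, 100, 0.7, 1),
               class = "capfit_invalid_input")
  pats <- fixture_patients()
  expect_named(pats, c("A", "B", "C"))
  expect_equal(pats$B$ankle_systolic, 160)
})

test_that("limb-pressure scaling reproduces the per-patient profiles", {
  pats <- fixture_patients()
  profs <- lapply(pats, limb_scaled_profile)

  expect_equal(signif(profs$A$capillary_pressure, 4), 20.83)
  expect_equal(signif(profs$B$capillary_pressure, 4), 33.33)
  expect_equal(signif(profs$C$capillary_pressure, 4), 41.67)
  expect_equal(signif(profs$A$arterial_flow, 3), 4.42e-4)
  expect_equal(signif(profs$B$arterial_flow, 3), 7.07e-4)
  expect_equal(signif(profs$C$arterial_flow, 3), 8.83e-4)
  expect_equal(signif(profs$A$capillary_flow, 3), 1.95e-13)
  expect_equal(signif(profs$B$capillary_flow, 3), 3.12e-13)
  expect_equal(signif(profs$C$capillary_flow, 3), 3.90e-13)
  for (p in profs) {
    expect_gt(p$capillary_resistance, p$arterial_resistance)
    expect_true(p$arterial_flow >= 0 && p$capillary_flow >= 0)
  }

  # ankle = 120 mmHg is the identity on the baseline
  base <- artery_capillary_baseline()
  ref <- limb_scaled_profile(patient_record("ref", 120, 120, 1.0, 0.1))
  expect_equal(ref$capillary_pressure, base$capillary_pressure)
  expect_equal(ref$arterial_flow, base$arterial_flow)
  expect_equal(ref$capillary_flow, base$capillary_flow)
  expect_equal(ref$arterial_resistance, base$arterial_resistance)

  expect_error(limb_scaled_profile(pats$A, baseline = list(arterial_flow = 1)),
               class = "capfit_config_error")
})

test_that("ABI-scaled capillary flows reproduce the reference flow table", {
  expect_equal(signif(abi_scaled_capillary_flow(100), 6), 1.94856e-13)
  expect_equal(signif(abi_scaled_capillary_flow(160), 6), 3.11769e-13)
  expect_equal(signif(abi_scaled_capillary_flow(200), 6), 3.89712e-13)
  expect_equal(signif(abi_scaled_capillary_flow(120), 6), 2.33827e-13)
})
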