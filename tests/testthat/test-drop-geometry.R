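D5 <- c(Ca = 7.9e-10, FuraFree = 4e-10, FuraBound = 4e-10,
        FluoFree = 4e-10, FluoBound = 4e-10)

test_that("drop volume and diameter are consistent through the spherical relation", {
  d <- drop_spec(volume_pL = 4000)
  expect_equal(d$diameter_um, (6 * 4000e3 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(d$diameter_um, 197, tolerance = 1e-2)
  d2 <- drop_spec(diameter_um = 100)
  expect_equal(d2$volume_pL, pi * 1e6 / 6 / 1e3)
  expect_error(drop_spec(volume_pL = 4000, diameter_um = 100), "disagree")
})

test_that("sphere voxelisation conserves volume and scales with spacing", {
  lat <- discretize_sphere(4, 10, D5)
  expect_equal(2 * lat$radius_um, 196.95, tolerance = 1e-3)
  expect_lt(abs(lattice_volume(lat) * 1e9 - 4) / 4, 0.05)
  lat2 <- discretize_sphere(4, 5, D5)
  ratio <- nrow(lat2$compartments) / nrow(lat$compartments)
  expect_gt(ratio, 6); expect_lt(ratio, 10)
  expect_error(discretize_sphere(0.001, 10, D5), "coarse")
})

test_that("voxel couplings carry the Fickian hop rate for each species", {
  lat <- discretize_sphere(0.5, 10, D5)
  expect_equal(unique(lat$rates[, "Ca"]), 7.9e-10 / (10e-6)^2)
  expect_equal(unique(lat$rates[, "FluoFree"]), 4e-10 / (10e-6)^2)
  # transport is symmetric: every directed edge has its reverse
  key <- paste(lat$couplings$from, lat$couplings$to)
  rev <- paste(lat$couplings$to, lat$couplings$from)
  expect_true(all(rev %in% key))
})

test_that("surface caps hold all substrate and leave the interior empty", {
  lat <- discretize_sphere(4, 10, D5)
  n_main <- nrow(lat$compartments)
  init <- apply_pei_initial_condition(lat, drop_spec(volume_pL = 60, count = 3L),
                                      0.1, "surface_caps")
  expect_equal(init$amount_mol, 3 * 60e-12 * 0.1)   # 18 pmol
  expect_true(all(init$conc[1, seq_len(n_main)] == 0))
  cap_ids <- (n_main + 1):nrow(init$lattice$compartments)
  expect_true(all(init$conc[1, cap_ids] == 0.1))
  # cap volumes normalised: each drop's cells sum to 60 pL
  expect_equal(sum(init$lattice$compartments$volume_pL[cap_ids]), 180,
               tolerance = 1e-9)
  # substrate amount recoverable from concentration x volume
  amt <- sum(init$conc[1, ] * init$lattice$compartments$volume_pL * 1e-12)
  expect_equal(amt, 18e-12, tolerance = 1e-12)
})

test_that("cone jets place the substrate inside the drop, conserving the amount", {
  lat <- discretize_sphere(4.18, 10, D5)
  init <- apply_pei_initial_condition(lat, drop_spec(volume_pL = 60, count = 3L),
                                      0.1, "cone_jets")
  amt <- sum(init$conc[1, ] * lat$compartments$volume_pL * 1e-12)
  expect_equal(amt, 18e-12, tolerance = 1e-15)
  # no new compartments in cone mode
  expect_identical(nrow(init$lattice$compartments), nrow(lat$compartments))
  # substrate sits in the upper hemisphere (contact sites at 45 degrees)
  loaded <- which(init$conc[1, ] > 0)
  expect_true(all(lat$compartments$z_um[loaded] > 0))
})

test_that("a vanishing cone depth degenerates to a surface-shell distribution", {
  lat <- discretize_sphere(4.18, 10, D5)
  init <- apply_pei_initial_condition(lat, drop_spec(volume_pL = 60, count = 3L),
                                      0.1, "cone_jets", cone_depth_frac = 1e-9)
  loaded <- which(init$conc[1, ] > 0)
  r <- with(lat$compartments[loaded, ], sqrt(x_um^2 + y_um^2 + z_um^2))
  expect_true(all(r > lat$radius_um - 2 * lat$h_um))
})

test_that("cap placement is deterministic and rejects impossible layouts", {
  lat <- discretize_sphere(1, 10, D5)
  pei <- drop_spec(volume_pL = 30, count = 2L)
  a <- apply_pei_initial_condition(lat, pei, 0.1, "surface_caps")
  b <- apply_pei_initial_condition(lat, pei, 0.1, "surface_caps")
  expect_identical(a$conc, b$conc)
  expect_error(
    apply_pei_initial_condition(lat, drop_spec(volume_pL = 600, count = 2L),
                                0.1, "surface_caps"),
    "below the main-drop volume")
})

test_that("the Weber number is rho v^2 L / sigma with its scaling laws", {
  expect_equal(weber_number(1000, 1.5, 200e-6, 0.072), 6.25)
  expect_equal(weber_number(1000, 3, 200e-6, 0.072) /
                 weber_number(1000, 1.5, 200e-6, 0.072), 4)
  expect_lt(weber_number(1000, 1.5, 200e-6, 1e9), 1e-8)
  expect_error(weber_number(-1, 1, 1, 1), "rho")
})

test_that("the mass-flow chain has v/L transfer rates and conserves volume", {
  ade <- drop_spec(diameter_um = 200)
  pei <- drop_spec(volume_pL = 60, count = 3L)
  lat <- build_mass_flow_model(ade, pei, v_rel = 1.5, n_compartments = 2L)
  expect_equal(lat$L_mix_um, 100)
  expect_equal(lat$transfer_rate_s, 1.5e4)
  expect_equal(sum(lat$compartments$volume_pL),
               ade$volume_pL + 3 * 60, tolerance = 1e-9)
  expect_false(any(colnames(lat$rates) != ".all"))
  expect_error(build_mass_flow_model(ade, pei, 50, 10), "range")
  expect_error(build_mass_flow_model(ade, pei, 1.5, 1), "n_compartments")
  # the documented collision velocities are accepted
  expect_silent(build_mass_flow_model(ade, pei, 1, 10))
  expect_silent(build_mass_flow_model(ade, pei, 2, 10))
})
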