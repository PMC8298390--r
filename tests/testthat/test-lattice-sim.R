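test_that("diffusion hop rate is D/h^2 with the expected scaling", {
  expect_equal(diffusion_hop_rate(7.9e-10, 10e-6), 7.9)
  expect_equal(diffusion_hop_rate(7.9e-10, 5e-6) /
                 diffusion_hop_rate(7.9e-10, 10e-6), 4)
  expect_error(diffusion_hop_rate(0, 1e-6), "D")
  expect_error(diffusion_hop_rate(1e-9, 0), "h")
})

test_that("transport-only dynamics leave volume-averaged concentrations constant", {
  net <- reaction_network(data.frame(name = "X", role = "inert"))
  comp <- data.frame(id = 1:2, x_um = c(0, 10), y_um = 0, z_um = 0,
                     volume_pL = c(1, 1))
  lat <- lattice(comp, data.frame(from = c(1L, 2L), to = c(2L, 1L)),
                 matrix(5, 2, 1, dimnames = list(NULL, ".all")))
  st <- sim_state(matrix(c(500L, 500L), 1, 2, dimnames = list("X", NULL)),
                  n_scale = 1e15)
  tr <- simulate_ssa(lat, net, st, t_end = 1, seed = 3)
  expect_equal(length(unique(tr$X)), 1L)   # exact: totals are conserved
  expect_gt(attr(tr, "n_events"), 0)
})

test_that("SSA relaxes to the closed-form binding equilibrium", {
  net <- single_dye_network(kd = 9e-5)
  lat <- single_compartment(1000)          # 1 pL
  conc <- matrix(c(1.5e-3, 1e-3, 0), ncol = 1,
                 dimnames = list(c("Ca", "DyeFree", "DyeBound"), NULL))
  st <- state_from_concentrations(conc, lat, particle_target = 3e4)
  tr <- simulate_ssa(lat, net, st, t_end = 2e-3, seed = 11)
  eq <- equilibrium_state(net, c(Ca = 1.5e-3, Dye = 1e-3))
  target <- eq$concentrations[["DyeBound"]]    # ~0.874 mM
  tail_mean <- mean(tail(tr$DyeBound, 50))
  expect_lt(abs(tail_mean - target), 3 * ssa_conc_se(target, st$n_scale, 1e-12))
})

test_that("a single particle hopping between two compartments occupies each half the time", {
  net <- reaction_network(data.frame(name = "X", role = "inert"))
  comp <- data.frame(id = 1:2, x_um = c(0, 10), y_um = 0, z_um = 0,
                     volume_pL = c(1, 1))
  lat <- lattice(comp, data.frame(from = c(1L, 2L), to = c(2L, 1L)),
                 matrix(10, 2, 1, dimnames = list(NULL, ".all")))
  st <- sim_state(matrix(c(1L, 0L), 1, 2, dimnames = list("X", NULL)),
                  n_scale = 1e12)
  tr <- simulate_ssa(lat, net, st, t_end = 400,
                     record_times = seq(0.2, 400, by = 0.2),
                     seed = 5, snapshots = TRUE)
  occ <- vapply(attr(tr, "snapshots"), function(m) m[1, 1], integer(1))
  # two-state symmetric Markov chain: stationary occupancy 1/2;
  # samples 0.2 s apart at hop rate 10/s are effectively independent
  mc_se <- 0.5 / sqrt(length(occ))
  expect_lt(abs(mean(occ) - 0.5), 3 * mc_se)
})

test_that("identical seeds give bit-identical trajectories, different seeds differ", {
  net <- single_dye_network()
  lat <- single_compartment(10)
  conc <- matrix(c(1e-3, 5e-4, 0), ncol = 1,
                 dimnames = list(c("Ca", "DyeFree", "DyeBound"), NULL))
  st <- state_from_concentrations(conc, lat, particle_target = 2000)
  a <- simulate_ssa(lat, net, st, t_end = 1e-3, seed = 7)
  b <- simulate_ssa(lat, net, st, t_end = 1e-3, seed = 7)
  c <- simulate_ssa(lat, net, st, t_end = 1e-3, seed = 8)
  expect_identical(a$DyeBound, b$DyeBound)
  expect_false(identical(a$DyeBound, c$DyeBound))
})

test_that("moiety totals are invariant over any trajectory, exactly", {
  net <- build_dye_network()
  lat <- discretize_sphere(0.5, 10, c(Ca = 7.9e-10, FuraFree = 4e-10,
                                      FuraBound = 4e-10, FluoFree = 4e-10,
                                      FluoBound = 4e-10))
  n <- nrow(lat$compartments)
  conc <- matrix(0, 5, n, dimnames = list(
    c("Ca", "FuraFree", "FuraBound", "FluoFree", "FluoBound"), NULL))
  conc["Ca", 1:3] <- 5e-3
  conc["FuraFree", ] <- 5e-4
  conc["FluoFree", ] <- 5e-4
  st <- state_from_concentrations(conc, lat, particle_target = 5000)
  tr <- simulate_ssa(lat, net, st, t_end = 0.05, seed = 9)
  fc <- attr(tr, "final_counts")
  start <- st$counts
  expect_identical(sum(fc[c("Ca", "FuraBound", "FluoBound"), ]),
                   sum(start[c("Ca", "FuraBound", "FluoBound"), ]))
  expect_identical(sum(fc[c("FuraFree", "FuraBound"), ]),
                   sum(start[c("FuraFree", "FuraBound"), ]))
  expect_identical(sum(fc[c("FluoFree", "FluoBound"), ]),
                   sum(start[c("FluoFree", "FluoBound"), ]))
})

test_that("the deterministic rate equations hit the equilibrium endpoint", {
  net <- single_dye_network(kd = 9e-5)
  tr <- simulate_wellmixed_ode(net, c(Ca = 1.5e-3, DyeFree = 1e-3),
                               t_end = 0.1)
  eq <- equilibrium_state(net, c(Ca = 1.5e-3, Dye = 1e-3))
  expect_equal(tail(tr$DyeBound, 1), eq$concentrations[["DyeBound"]],
               tolerance = 1e-5)
  # conserved moieties constant along the whole solution
  expect_equal(tr$Ca + tr$DyeBound, rep(1.5e-3, nrow(tr)), tolerance = 1e-7)
  expect_equal(tr$DyeFree + tr$DyeBound, rep(1e-3, nrow(tr)), tolerance = 1e-7)
})

test_that("a reaction-free network yields a constant ODE solution", {
  net <- reaction_network(data.frame(name = "X", role = "inert"))
  tr <- simulate_wellmixed_ode(net, c(X = 2e-3), t_end = 1)
  expect_equal(tr$X, rep(2e-3, nrow(tr)), tolerance = 1e-10)
})

test_that("SSA matches the ODE solution within 3 standard errors at large counts", {
  net <- single_dye_network(kd = 9e-5)
  lat <- single_compartment(1000)
  conc <- matrix(c(1.5e-3, 1e-3, 0), ncol = 1,
                 dimnames = list(c("Ca", "DyeFree", "DyeBound"), NULL))
  st <- state_from_concentrations(conc, lat, particle_target = 6e4)
  # >= 1e4 particles for every species present
  expect_true(all(rowSums(st$counts)[c("Ca", "DyeFree")] >= 1e4))
  rt <- seq(2e-5, 1e-3, length.out = 25)
  tr <- simulate_ssa(lat, net, st, t_end = 1e-3, record_times = rt, seed = 13)
  ode <- simulate_wellmixed_ode(net, c(Ca = 1.5e-3, DyeFree = 1e-3),
                                t_end = 1e-3, record_times = rt)
  se <- ssa_conc_se(pmax(ode$DyeBound, 1e-6), st$n_scale, 1e-12)
  expect_true(all(abs(tr$DyeBound - ode$DyeBound) < 3 * se))
})

test_that("early absorption fills the remaining record grid and is flagged", {
  net <- single_dye_network()
  lat <- single_compartment(10)
  # nothing can ever react: only free dye present, no ligand
  st <- sim_state(matrix(c(0L, 100L, 0L), ncol = 1,
                         dimnames = list(c("Ca", "DyeFree", "DyeBound"), NULL)),
                  n_scale = 1e12)
  tr <- simulate_ssa(lat, net, st, t_end = 1, seed = 2)
  expect_identical(attr(tr, "status"), "absorbed")
  expect_equal(nrow(tr), 200L)
  expect_equal(length(unique(tr$DyeFree)), 1L)
})

test_that("halving the spacing refines the equilibration time by less than 20%", {
  # full-size drop: 20 vs 10 voxels across the diameter
  run_h <- function(h) {
    cfg <- mixing_config("diffusion_only", h_um = h, t_end = 12,
                         record_n = 150L, particle_target = 8000, seed = 21)
    max(run_regime(cfg)$equilibration_time)
  }
  t_coarse <- run_h(20)
  t_fine <- run_h(10)
  expect_lt(abs(t_fine - t_coarse) / t_fine, 0.20)
})
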