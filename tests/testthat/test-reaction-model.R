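test_that("the dye network carries the template species, reactions and Kd map", {
  net <- build_dye_network(4e-7, 9e-5)
  expect_s3_class(net, "reaction_network")
  expect_setequal(net$species$name,
                  c("Ca", "FuraFree", "FuraBound", "FluoFree", "FluoBound"))
  expect_length(net$reactions, 4L)
  expect_equal(net$kd_map, c(Fura = 4e-7, Fluo = 9e-5))
  # off-rates derived from Kd: k_off = Kd * k_on, checked via the pair scan
  info <- dropmix:::dye_pairs(net)
  kds <- vapply(info$pairs, `[[`, numeric(1), "kd")
  expect_equal(unname(kds[c("FuraBound", "FluoBound")]), c(4e-7, 9e-5),
               tolerance = 1e-9)
})

test_that("off-rate equals Kd times on-rate for explicit arguments", {
  net <- build_dye_network(kd_fura = 4e-7, kon_fura = 1e8)
  unbind <- Filter(function(r) length(r$reactants) == 1L &&
                     names(r$reactants) == "FuraBound", net$reactions)[[1]]
  expect_equal(unbind$rate, 40)
})

test_that("degenerate binding parameters are rejected by name", {
  expect_error(build_dye_network(kd_fluo = 0), "kd_fluo")
  expect_error(build_dye_network(kon_fura = -1), "kon_fura")
})

test_that("reactions must balance conserved moieties", {
  sp <- data.frame(name = c("A", "B"), role = c("ligand", "inert"))
  moi <- rbind(A = c(A = 1), B = c(A = 0))
  expect_error(
    reaction_network(sp, list(reaction(c(A = 1L), c(B = 1L), 1)), moi),
    "balance")
})

test_that("equilibrium matches the single-dye quadratic closed form", {
  # x^2 - (Ca + D + Kd) x + Ca D = 0, smaller root; cross-checked by a
  # brute-force scan of the conservation residual on a 1e-6 M grid
  ca <- 1.5e-3; d <- 1e-3; kd <- 9e-5
  b <- ca + d + kd
  quad <- (b - sqrt(b^2 - 4 * ca * d)) / 2
  grid <- seq(0, min(ca, d), by = 1e-6)
  resid <- (ca - grid) * (d - grid) - kd * grid
  scan <- grid[which.min(abs(resid))]
  expect_equal(quad, 0.874255e-3, tolerance = 1e-4)
  expect_equal(scan, quad, tolerance = 2e-3)

  eq <- equilibrium_state(single_dye_network(kd), c(Ca = ca, Dye = d))
  expect_equal(unname(eq$concentrations["DyeBound"]), quad, tolerance = 1e-6)
})

test_that("equilibrium limits: no ligand and vanishing affinity", {
  net <- single_dye_network()
  eq0 <- equilibrium_state(net, c(Ca = 0, Dye = 1e-3))
  expect_equal(unname(eq0$concentrations["DyeBound"]), 0)
  weak <- equilibrium_state(single_dye_network(kd = 1e3),
                            c(Ca = 1e-3, Dye = 1e-3))
  expect_lt(weak$concentrations["DyeBound"], 1e-8)
})

test_that("equilibrium conserves mass to 1e-12 relative and obeys Kd", {
  net <- build_dye_network()
  tot <- c(Ca = 4.3e-3, Fura = 0.96e-3, Fluo = 0.96e-3)
  eq <- equilibrium_state(net, tot)
  cc <- eq$concentrations
  expect_equal(cc[["Ca"]] + cc[["FuraBound"]] + cc[["FluoBound"]],
               tot[["Ca"]], tolerance = 1e-12)
  expect_equal(cc[["FuraFree"]] + cc[["FuraBound"]], tot[["Fura"]],
               tolerance = 1e-12)
  expect_equal(cc[["FluoFree"]] + cc[["FluoBound"]], tot[["Fluo"]],
               tolerance = 1e-12)
  expect_equal(cc[["Ca"]] * cc[["FuraFree"]] / cc[["FuraBound"]], 4e-7,
               tolerance = 1e-6)
  expect_equal(cc[["Ca"]] * cc[["FluoFree"]] / cc[["FluoBound"]], 9e-5,
               tolerance = 1e-6)
})

test_that("equilibrium agrees with exhaustive grid minimisation on random draws", {
  set.seed(101)
  for (i in 1:100) {
    ca <- 10^stats::runif(1, -5, -2)
    d1 <- 10^stats::runif(1, -5, -2); d2 <- 10^stats::runif(1, -5, -2)
    kd1 <- 10^stats::runif(1, -8, -3); kd2 <- 10^stats::runif(1, -8, -3)
    net <- build_dye_network(kd1, kd2)
    eq <- equilibrium_state(net, c(Ca = ca, Fura = d1, Fluo = d2))
    ref <- grid_equilibrium(ca, d1, d2, kd1, kd2)
    scale <- max(ca, d1, d2)
    expect_lt(abs(eq$concentrations[["FuraBound"]] - ref[1]) / scale, 1e-4)
    expect_lt(abs(eq$concentrations[["FluoBound"]] - ref[2]) / scale, 1e-4)
  }
})

test_that("bound dye is monotone non-decreasing in total calcium", {
  net <- build_dye_network()
  ca_grid <- c(1e-6, 1e-5, 1e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2)
  bound <- vapply(ca_grid, function(ca)
    sum(equilibrium_state(net, c(Ca = ca, Fura = 1e-3, Fluo = 1e-3)
                          )$concentrations[c("FuraBound", "FluoBound")]),
    numeric(1))
  expect_true(all(diff(bound) >= -1e-15))
})

test_that("a network round-trips through its declarative config", {
  net <- build_dye_network(3e-7, 8e-5, 5e7, 2e8)
  net2 <- network_from_config(network_to_config(net))
  expect_equal(net2$kd_map, net$kd_map)
  expect_equal(length(net2$reactions), length(net$reactions))
  expect_equal(vapply(net2$reactions, `[[`, numeric(1), "rate"),
               vapply(net$reactions, `[[`, numeric(1), "rate"))
})
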