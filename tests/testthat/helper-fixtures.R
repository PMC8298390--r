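# shared fixtures: small networks, lattices and independent oracles

# single-dye binding network (ligand Ca, one free/bound dye pair)
single_dye_network <- function(kd = 9e-5, kon = 1e8) {
  reaction_network(
    data.frame(name = c("Ca", "DyeFree", "DyeBound"),
               role = c("ligand", "dye_free", "dye_bound"),
               stringsAsFactors = FALSE),
    list(reaction(c(Ca = 1L, DyeFree = 1L), c(DyeBound = 1L), kon),
         reaction(c(DyeBound = 1L), c(Ca = 1L, DyeFree = 1L), kd * kon)),
    rbind(Ca = c(Ca = 1, Dye = 0), DyeFree = c(0, 1), DyeBound = c(1, 1)))
}

# one well-mixed compartment of the given volume (pL), no couplings
single_compartment <- function(volume_pL = 1000) {
  lattice(data.frame(id = 1L, x_um = 0, y_um = 0, z_um = 0,
                     volume_pL = volume_pL),
          data.frame(from = integer(0), to = integer(0)),
          matrix(numeric(0), 0, 1, dimnames = list(NULL, ".all")))
}

# independent equilibrium oracle for two competing dyes: exhaustive scan of
# the free-calcium conservation residual |x + sum_d Dtot_d x/(x+Kd_d) - Ca|
# on a log-spaced grid with zoom refinement. (A 2-D grid over the two bound
# concentrations is unusable here: when both dyes bind strongly the residual
# surface is nearly flat along the partition direction, so no feasible 2-D
# grid resolves the minimum; the 1-D enumeration over the shared free-ligand
# variable is exact to grid resolution and uses no root-bracketing logic.)
grid_equilibrium <- function(ca_tot, d1_tot, d2_tot, kd1, kd2, n = 4001L) {
  resid <- function(x)
    abs(x + d1_tot * x / (x + kd1) + d2_tot * x / (x + kd2) - ca_tot)
  lo <- ca_tot * 1e-12; hi <- ca_tot
  for (pass in 1:6) {
    x <- exp(seq(log(lo), log(hi), length.out = n))
    i <- which.min(resid(x))
    lo <- x[max(i - 1L, 1L)]
    hi <- x[min(i + 1L, n)]
  }
  x_best <- exp((log(lo) + log(hi)) / 2)
  c(d1_tot * x_best / (x_best + kd1), d2_tot * x_best / (x_best + kd2))
}

# binomial-scale standard error of a volume-averaged SSA concentration
ssa_conc_se <- function(conc, n_scale, volume_L) {
  n <- pmax(conc * n_scale * volume_L, 10)
  sqrt(n) / (n_scale * volume_L)
}
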