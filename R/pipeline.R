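#' Configuration for one mixing-regime simulation
#'
#' Bundles geometry, chemistry and numerical settings for a single run of
#' [run_regime()]. Defaults reproduce the calcium-indicator validation
#' conditions: a 4 nL main drop carrying 1 mM each of Fura Red and Fluo-5N,
#' three 60 pL substrate drops of 100 mM CaCl2, indicator dissociation
#' constants 400 nM (Fura Red) and 90 uM (Fluo-5N), diffusion-influenced
#' on-rates 1e8 /M/s, and free-solution diffusion coefficients
#' (Ca 7.9e-10 m^2/s, dyes 4e-10 m^2/s).
#'
#' @param regime `"diffusion_only"` (substrate drops resting on the main
#'   drop, Fickian transport only), `"cone_jet"` (substrate pre-distributed
#'   in collision-formed cones, then Fickian transport), or `"mass_flow"`
#'   (chain of compartments with inertial mass transfer at `v_rel / L_mix`).
#' @param ade,pei [drop_spec()]s of the main and substrate drops.
#' @param c_substrate substrate (CaCl2) concentration in the drops, mol/L.
#' @param dye_conc named molar concentrations of the free dyes in the main
#'   drop.
#' @param kd_fura,kd_fluo,kon_fura,kon_fluo binding parameters passed to
#'   [build_dye_network()].
#' @param D named diffusion coefficients, m^2/s.
#' @param h_um lattice spacing for the voxelised regimes, um.
#' @param v_rel,n_compartments mass-flow chain parameters.
#' @param t_end simulated time, s; `NULL` picks 10 s for the diffusive
#'   regimes and 10 ms for mass flow.
#' @param record_n number of recorded time points.
#' @param threshold equilibration threshold fraction, in (0, 1).
#' @param particle_target simulated particles for the most abundant species.
#' @param seed RNG seed.
#' @param cone_depth_frac cone depth fraction for `cone_jet`.
#' @return a list of class `mixing_config`.
#' @export
mixing_config <- function(regime = c("diffusion_only", "cone_jet", "mass_flow"),
                          ade = drop_spec(volume_pL = 4000),
                          pei = drop_spec(volume_pL = 60, count = 3L),
                          c_substrate = 0.1,
                          dye_conc = c(FuraFree = 1e-3, FluoFree = 1e-3),
                          kd_fura = 4e-7, kd_fluo = 9e-5,
                          kon_fura = 1e8, kon_fluo = 1e8,
                          D = c(Ca = 7.9e-10, FuraFree = 4e-10,
                                FuraBound = 4e-10, FluoFree = 4e-10,
                                FluoBound = 4e-10),
                          h_um = 10, v_rel = 1.5, n_compartments = 10L,
                          t_end = NULL, record_n = 300L, threshold = 0.9,
                          particle_target = 1e5, seed = 1L,
                          cone_depth_frac = 0.5) {
  regime <- match.arg(regime)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in the open interval (0, 1)", call. = FALSE)
  check_nonneg(c_substrate, "c_substrate")
  check_nonneg(dye_conc, "dye_conc")
  if (is.null(t_end))
    t_end <- if (regime == "mass_flow") 10e-3 else 10
  structure(
    list(regime = regime, ade = ade, pei = pei, c_substrate = c_substrate,
         dye_conc = dye_conc, kd_fura = kd_fura, kd_fluo = kd_fluo,
         kon_fura = kon_fura, kon_fluo = kon_fluo, D = D, h_um = h_um,
         v_rel = v_rel, n_compartments = n_compartments, t_end = t_end,
         record_n = as.integer(record_n), threshold = threshold,
         particle_target = particle_target, seed = as.integer(seed),
         cone_depth_frac = cone_depth_frac),
    class = "mixing_config")
}

# internal: merged-drop totals (mol/L) for the asymptote oracle
merged_totals <- function(config) {
  v_ade <- config$ade$volume_pL * config$ade$count * 1e-12
  v_pei <- config$pei$volume_pL * config$pei$count * 1e-12
  v_tot <- v_ade + v_pei
  c(Ca = config$c_substrate * v_pei / v_tot,
    Fura = unname(config$dye_conc["FuraFree"]) * v_ade / v_tot,
    Fluo = unname(config$dye_conc["FluoFree"]) * v_ade / v_tot)
}

#' Run one mixing regime end to end
#'
#' Assembles the geometry and reaction network for the requested regime,
#' runs the stochastic engine, and extracts the equilibration time of each
#' Ca-bound dye from the volume-averaged trajectory. The asymptote used for
#' the threshold is the closed-form competitive-binding equilibrium of the
#' merged drop ([equilibrium_state()]); if the threshold is not reached
#' within `t_end` the run is extended once (4x) before being flagged.
#'
#' @param config a [mixing_config()].
#' @return object of class `mixing_result`: list with `trajectory`,
#'   `equilibration_time` (named seconds per bound species, each with
#'   attribute `reached`), `asymptote`, `config`, `regime`.
#' @export
run_regime <- function(config) {
  stopifnot(inherits(config, "mixing_config"))
  network <- build_dye_network(config$kd_fura, config$kd_fluo,
                               config$kon_fura, config$kon_fluo)
  sp <- network$species$name
  v_ade_pL <- config$ade$volume_pL * config$ade$count
  v_pei_pL <- config$pei$volume_pL * config$pei$count

  if (config$regime == "diffusion_only") {
    lat0 <- discretize_sphere(v_ade_pL / 1e3, config$h_um, config$D)
    init <- apply_pei_initial_condition(lat0, config$pei, config$c_substrate,
                                        "surface_caps")
    lat <- init$lattice
    n_main <- nrow(lat0$compartments)
    conc <- matrix(0, length(sp), nrow(lat$compartments),
                   dimnames = list(sp, NULL))
    conc["Ca", ] <- init$conc[1, ]
    for (s in names(config$dye_conc))
      conc[s, seq_len(n_main)] <- config$dye_conc[[s]]
  } else if (config$regime == "cone_jet") {
    v_tot_nL <- (v_ade_pL + v_pei_pL) / 1e3
    lat <- discretize_sphere(v_tot_nL, config$h_um, config$D)
    init <- apply_pei_initial_condition(lat, config$pei, config$c_substrate,
                                        "cone_jets",
                                        cone_depth_frac = config$cone_depth_frac)
    conc <- matrix(0, length(sp), nrow(lat$compartments),
                   dimnames = list(sp, NULL))
    conc["Ca", ] <- init$conc[1, ]
    dil <- v_ade_pL / (v_ade_pL + v_pei_pL)
    for (s in names(config$dye_conc))
      conc[s, ] <- config$dye_conc[[s]] * dil
  } else {                                        # mass_flow
    lat <- build_mass_flow_model(config$ade, config$pei, config$v_rel,
                                 config$n_compartments)
    conc <- matrix(0, length(sp), nrow(lat$compartments),
                   dimnames = list(sp, NULL))
    # substrate enters through the first compartment of the chain
    amount <- v_pei_pL * 1e-12 * config$c_substrate
    conc["Ca", 1] <- amount / (lat$compartments$volume_pL[1] * 1e-12)
    dil <- v_ade_pL / (v_ade_pL + v_pei_pL)
    for (s in names(config$dye_conc))
      conc[s, ] <- config$dye_conc[[s]] * dil
  }

  state <- state_from_concentrations(conc, lat, config$particle_target)
  eq <- equilibrium_state(network, merged_totals(config))
  bound_sp <- network$species$name[network$species$role == "dye_bound"]

  run_once <- function(t_end) {
    rt <- seq(t_end / config$record_n, t_end, length.out = config$record_n)
    simulate_ssa(lat, network, state, t_end, rt, seed = config$seed)
  }
  measure <- function(traj) {
    et <- lapply(bound_sp, function(s)
      equilibration_time(traj, s, config$threshold,
                         asymptote = eq$concentrations[[s]]))
    list(times = stats::setNames(vapply(et, as.numeric, numeric(1)), bound_sp),
         reached = stats::setNames(vapply(et, attr, logical(1), "reached"),
                                   bound_sp))
  }
  traj <- run_once(config$t_end)
  m <- measure(traj)
  if (!all(m$reached)) {                          # extend once
    traj <- run_once(4 * config$t_end)
    m <- measure(traj)
  }
  times <- m$times
  reached <- m$reached
  structure(list(trajectory = traj, equilibration_time = times,
                 reached = stats::setNames(reached, bound_sp),
                 asymptote = eq$concentrations[bound_sp],
                 threshold = config$threshold,
                 config = config, regime = config$regime,
                 seed = config$seed),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat("Mixing regime:", x$regime, "\n")
  for (s in names(x$equilibration_time))
    cat(sprintf("  %s: %s equilibration (%.0f%% of asymptote) at %.4g s%s\n",
                s, x$regime, 100 * x$threshold, x$equilibration_time[[s]],
                if (x$reached[[s]]) "" else "  [not reached]"))
  invisible(x)
}

#' Time to reach a fraction of the asymptotic concentration
#'
#' Returns the first time at which the volume-averaged concentration of a
#' species reaches `threshold` times its asymptotic value, with linear
#' interpolation between recorded samples. If no asymptote is supplied it is
#' estimated as the mean of the final 10% of samples, after checking that
#' this tail is stationary (relative drift between its two halves below 1%).
#'
#' @param traj a `trajectory`.
#' @param species species (column) name.
#' @param threshold fraction in the open interval (0, 1).
#' @param asymptote optional known asymptotic concentration (mol/L).
#' @return time in seconds with attribute `reached`; when the threshold is
#'   never reached the last trajectory time is returned with
#'   `reached = FALSE`.
#' @examples
#' # pure exponential rise: t90 = -tau * log(0.1) = 2.303 tau
#' tt <- seq(0, 2, by = 0.001)
#' tr <- structure(data.frame(time_s = tt, X = 1 - exp(-tt / 0.15)),
#'                 class = c("trajectory", "data.frame"))
#' equilibration_time(tr, "X", 0.9, asymptote = 1)
#' @export
equilibration_time <- function(traj, species, threshold, asymptote = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in the open interval (0, 1)", call. = FALSE)
  if (!species %in% names(traj))
    stop("species not found in trajectory: ", species, call. = FALSE)
  y <- traj[[species]]
  tt <- traj$time_s
  if (!length(y)) stop("empty trajectory", call. = FALSE)
  if (is.null(asymptote)) {
    k <- max(2L, ceiling(0.1 * length(y)))
    tail_y <- y[(length(y) - k + 1L):length(y)]
    h1 <- mean(tail_y[seq_len(floor(k / 2))])
    h2 <- mean(tail_y[(floor(k / 2) + 1L):k])
    asymptote <- mean(tail_y)
    if (asymptote > 0 && abs(h2 - h1) / asymptote > 0.01)
      warning("trajectory tail is not stationary; asymptote estimate ",
              "may be biased", call. = FALSE)
  }
  target <- threshold * asymptote
  if (y[1] >= target) {
    out <- 0
    attr(out, "reached") <- TRUE
    return(out)
  }
  idx <- which(y >= target)
  if (!length(idx)) {
    out <- tt[length(tt)]
    attr(out, "reached") <- FALSE
    return(out)
  }
  i <- idx[1]
  t_prev <- if (i == 1L) 0 else tt[i - 1L]
  y_prev <- if (i == 1L) y[1] else y[i - 1L]
  out <- if (y[i] > y_prev)
    t_prev + (target - y_prev) / (y[i] - y_prev) * (tt[i] - t_prev)
  else tt[i]
  attr(out, "reached") <- TRUE
  out
}

#' Compare mixing regimes on a common footing
#'
#' Runs each configuration, tabulates equilibration times, and resamples
#' every trajectory onto a common time grid for side-by-side plotting or
#' serialisation.
#'
#' @param configs list of [mixing_config()]s (at least 2 unless a single
#'   config is explicitly acceptable) sharing the same binding parameters.
#' @param grid_n number of points of the common time grid.
#' @return object of class `regime_report`: list with `table`
#'   (regime x species equilibration times), `trajectories` (resampled),
#'   and `results` (the full [run_regime()] outputs).
#' @export
compare_regimes <- function(configs, grid_n = 200L) {
  if (!length(configs)) stop("no configurations given", call. = FALSE)
  key <- function(cf) c(cf$kd_fura, cf$kd_fluo, cf$kon_fura, cf$kon_fluo)
  if (length(configs) > 1L) {
    k0 <- key(configs[[1]])
    for (cf in configs[-1])
      if (!isTRUE(all.equal(key(cf), k0)))
        stop("configurations do not share network parameters", call. = FALSE)
  }
  results <- lapply(configs, run_regime)
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(regime = r$regime, species = names(r$equilibration_time),
               equilibration_s = as.numeric(r$equilibration_time),
               reached = as.logical(r$reached), threshold = r$threshold,
               seed = r$seed, row.names = NULL)))
  t_max <- max(vapply(results, function(r) max(r$trajectory$time_s),
                      numeric(1)))
  grid <- seq(t_max / grid_n, t_max, length.out = grid_n)
  trajectories <- lapply(results, function(r) {
    out <- data.frame(time_s = grid)
    for (s in setdiff(names(r$trajectory), "time_s"))
      out[[s]] <- stats::approx(r$trajectory$time_s, r$trajectory[[s]],
                                grid, rule = 2)$y
    out
  })
  names(trajectories) <- vapply(results, `[[`, "", "regime")
  structure(list(table = tab, trajectories = trajectories,
                 results = results),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Regime comparison:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Serialise a regime report (or any report list) to JSON
#' @param report a `regime_report`, `plan_report` or plain list.
#' @param file output path.
#' @export
write_report_json <- function(report, file) {
  x <- if (inherits(report, "regime_report"))
    list(table = report$table, trajectories = report$trajectories)
  else unclass(report)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}
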