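#' Construct a simulation state
#'
#' Holds integer particle counts per (species, compartment) together with the
#' particle scaling. Real molecule numbers in a 4 nL drop are ~1e12, far too
#' many to simulate event-by-event; counts are therefore scaled so that the
#' most abundant species holds a configurable number of simulated particles
#' while all concentrations are preserved. `n_scale` is the effective number
#' of simulated particles per mole, so that
#' `concentration = counts / (n_scale * volume_L)`. Relative fluctuations are
#' inflated by the scaling; means are unbiased.
#'
#' @param counts integer matrix, species x compartments; row names are
#'   species names.
#' @param n_scale simulated particles per mole.
#' @param time current time, s.
#' @return object of class `sim_state`.
#' @export
sim_state <- function(counts, n_scale, time = 0) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  check_positive(n_scale, "n_scale")
  structure(list(counts = counts, n_scale = n_scale, time = time),
            class = "sim_state")
}

#' Build a simulation state from per-compartment concentrations
#'
#' Particles are apportioned to compartments deterministically by the
#' largest-remainder rule so that the per-species totals are exact and the
#' build is reproducible without a random-number draw.
#'
#' @param conc numeric matrix, species x compartments, mol/L.
#' @param lat the [lattice()] supplying compartment volumes.
#' @param particle_target simulated particle count assigned to the most
#'   abundant species (default 1e5).
#' @return a [sim_state()].
#' @export
state_from_concentrations <- function(conc, lat, particle_target = 1e5) {
  stopifnot(is.matrix(conc), !is.null(rownames(conc)),
            ncol(conc) == nrow(lat$compartments))
  check_positive(particle_target, "particle_target")
  vol <- lat$compartments$volume_pL * 1e-12
  moles <- sweep(conc, 2, vol, `*`)               # species x comp
  max_moles <- max(rowSums(moles))
  if (max_moles <= 0) stop("no substance present", call. = FALSE)
  n_scale <- particle_target / max_moles
  counts <- matrix(0L, nrow(conc), ncol(conc), dimnames = dimnames(conc))
  for (i in seq_len(nrow(conc)))
    counts[i, ] <- apportion_counts(moles[i, ] * n_scale)
  sim_state(counts, n_scale)
}

# internal: largest-remainder apportionment of sum(round(total)) particles
# over bins proportional to the (real-valued) weights
apportion_counts <- function(w) {
  total <- round(sum(w))
  base <- floor(w)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(w - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(w - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Exact stochastic simulation on a compartmental lattice
#'
#' Runs the Gillespie direct method over the joint set of reaction channels
#' (per compartment) and transport channels (per coupling, per species):
#' waiting times are exponential in the total propensity and channels are
#' selected by inverse-transform sampling. Bimolecular propensities in a
#' compartment of volume V are `k * nA * nB / (n_scale * V)`; transport
#' propensities are `hop_rate * n`. The algorithm samples the chemical master
#' equation of the compartmental system exactly.
#'
#' @param lat a [lattice()].
#' @param network a [reaction_network()].
#' @param initial a [sim_state()]; row names of its counts must cover the
#'   network species.
#' @param t_end end time, s (must be positive).
#' @param record_times increasing vector of times (s) at which the
#'   volume-averaged concentrations are recorded; defaults to 200 evenly
#'   spaced points up to `t_end`.
#' @param seed integer RNG seed; the same seed and configuration reproduce
#'   the trajectory bit for bit.
#' @param max_events event budget before the run is flagged and truncated.
#' @param snapshots if TRUE, keep per-compartment counts at each record time.
#' @return object of class `trajectory`: data.frame `time_s` plus one
#'   volume-averaged molar column per species, with attributes `status`
#'   (`"ok"`, `"absorbed"`, `"event_budget"`), `n_events`, `seed`,
#'   `final_counts`, and optionally `snapshots`.
#' @export
simulate_ssa <- function(lat, network, initial, t_end,
                         record_times = NULL, seed = 1L,
                         max_events = Inf, snapshots = FALSE) {
  check_positive(t_end, "t_end")
  sp <- network$species$name
  if (!all(sp %in% rownames(initial$counts)))
    stop("initial state lacks counts for: ",
         paste(setdiff(sp, rownames(initial$counts)), collapse = ", "),
         call. = FALSE)
  counts <- initial$counts[sp, , drop = FALSE]
  if (ncol(counts) != nrow(lat$compartments))
    stop("initial counts do not match the lattice compartments",
         call. = FALSE)
  if (is.null(record_times))
    record_times <- seq(t_end / 200, t_end, length.out = 200)
  record_times <- sort(record_times)
  if (any(record_times <= 0) || max(record_times) > t_end + 1e-12)
    stop("record_times must lie in (0, t_end]", call. = FALSE)

  enc <- encode_reactions(network)
  csr <- couplings_to_csr(lat, sp)

  storage.mode(counts) <- "integer"
  set.seed(as.integer(seed))
  res <- .ssa_core(
    counts,
    lat$compartments$volume_pL * 1e-12,
    enc$s1, enc$s2, enc$rate, enc$delta,
    csr$ptr, csr$to, csr$rates,
    initial$n_scale, record_times,
    if (is.finite(max_events)) max_events else 1e18,
    isTRUE(snapshots)
  )

  out <- data.frame(time_s = record_times)
  conc <- res$concentrations
  colnames(conc) <- sp
  out <- cbind(out, as.data.frame(conc))
  rownames(res$final_counts) <- sp
  structure(out, class = c("trajectory", "data.frame"),
            status = res$status, n_events = res$n_events, seed = seed,
            n_scale = initial$n_scale,
            volume_L = lattice_volume(lat),
            final_counts = res$final_counts,
            snapshots = if (isTRUE(snapshots)) res$snapshots)
}

# internal: encode reactions for the C++ core (0-based species indices)
encode_reactions <- function(network) {
  sp <- network$species$name
  n_reac <- length(network$reactions)
  s1 <- s2 <- integer(n_reac)
  rate <- numeric(n_reac)
  delta <- matrix(0L, length(sp), n_reac)
  for (j in seq_len(n_reac)) {
    r <- network$reactions[[j]]
    idx <- rep(match(names(r$reactants), sp), r$reactants)
    s1[j] <- idx[1] - 1L
    s2[j] <- if (length(idx) > 1L) idx[2] - 1L else -1L
    rate[j] <- r$rate
    for (s in names(r$reactants))
      delta[match(s, sp), j] <- delta[match(s, sp), j] - as.integer(r$reactants[[s]])
    for (s in names(r$products))
      delta[match(s, sp), j] <- delta[match(s, sp), j] + as.integer(r$products[[s]])
  }
  list(s1 = s1, s2 = s2, rate = rate, delta = delta)
}

# internal: compress directed couplings into CSR form ordered by source
couplings_to_csr <- function(lat, species_names) {
  n_comp <- nrow(lat$compartments)
  cp <- lat$couplings
  rates <- expand_rates(lat, species_names)
  if (nrow(cp)) {
    ord <- order(cp$from)
    cp <- cp[ord, , drop = FALSE]
    rates <- rates[ord, , drop = FALSE]
    ptr <- cumsum(c(0L, tabulate(cp$from, nbins = n_comp)))
  } else {
    ptr <- integer(n_comp + 1L)
  }
  list(ptr = as.integer(ptr), to = as.integer(cp$to) - 1L, rates = rates)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x), "time points over",
      format(max(x$time_s), digits = 4), "s; species:",
      paste(setdiff(names(x), "time_s"), collapse = ", "), "\n")
  cat("  status:", attr(x, "status"), " events:",
      format(attr(x, "n_events"), big.mark = ","), "\n")
  invisible(x)
}

#' Plot volume-averaged concentrations of a trajectory
#' @param x a `trajectory`.
#' @param species which species to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trajectory <- function(x, species = setdiff(names(x), "time_s"), ...) {
  graphics::matplot(x$time_s, as.matrix(x[species]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "volume-averaged conc (M)", ...)
  graphics::legend("bottomright", legend = species, lty = 1,
                   col = seq_along(species), bty = "n")
  invisible(x)
}

#' Write a trajectory as CSV
#' @param traj a `trajectory`.
#' @param file output path; columns `time_s` plus one molar column per species.
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}
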