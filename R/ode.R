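#' Deterministic well-mixed mass-action integration
#'
#' Integrates the deterministic rate equations of a reaction network in a
#' single well-mixed volume. Serves as the large-count oracle for the
#' stochastic engine: by the law of large numbers the volume-averaged SSA
#' concentrations converge to this solution as particle counts grow.
#'
#' @param network a [reaction_network()].
#' @param conc0 named numeric vector of initial concentrations, mol/L.
#' @param t_end end time, s.
#' @param record_times output grid (default 200 points up to `t_end`).
#' @param rtol,atol integration tolerances passed to [deSolve::lsoda()].
#' @return a `trajectory` data.frame (`time_s` + one column per species)
#'   with attribute `status = "ok"`.
#' @export
simulate_wellmixed_ode <- function(network, conc0, t_end,
                                   record_times = NULL,
                                   rtol = 1e-8, atol = 1e-14) {
  check_positive(t_end, "t_end")
  check_nonneg(conc0, "conc0")
  sp <- network$species$name
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0[names(conc0)] <- conc0
  if (is.null(record_times))
    record_times <- seq(t_end / 200, t_end, length.out = 200)

  # stoichiometry matrix and rate law per reaction
  n_reac <- length(network$reactions)
  nu <- matrix(0, length(sp), n_reac, dimnames = list(sp, NULL))
  for (j in seq_len(n_reac)) {
    r <- network$reactions[[j]]
    for (s in names(r$reactants)) nu[s, j] <- nu[s, j] - r$reactants[[s]]
    for (s in names(r$products)) nu[s, j] <- nu[s, j] + r$products[[s]]
  }
  rhs <- function(t, y, parms) {
    v <- vapply(seq_len(n_reac), function(j) {
      r <- network$reactions[[j]]
      network$reactions[[j]]$rate *
        prod(pmax(y[names(r$reactants)], 0) ^ r$reactants)
    }, numeric(1))
    list(as.numeric(nu %*% v))
  }
  sol <- deSolve::lsoda(y0, c(0, record_times), rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed; istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  out <- as.data.frame(sol[-1, , drop = FALSE])
  names(out)[1] <- "time_s"
  structure(out, class = c("trajectory", "data.frame"),
            status = "ok", n_events = NA_real_, seed = NA_integer_)
}
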