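#' Per-particle diffusion hop rate between adjacent compartments
#'
#' On a grid of spacing `h` the first-order rate at which a particle with
#' diffusion coefficient `D` hops to one given neighbouring compartment is
#' `D / h^2` (the standard finite-volume discretisation of Fickian
#' diffusion; summing over the 2d neighbours of a d-dimensional grid
#' recovers the mean-squared-displacement law).
#'
#' @param D diffusion coefficient, m^2/s.
#' @param h compartment spacing, m.
#' @return hop rate towards one neighbour, 1/s.
#' @examples
#' diffusion_hop_rate(7.9e-10, 10e-6)  # 7.9 s^-1
#' @export
diffusion_hop_rate <- function(D, h) {
  check_positive(D, "D")
  check_positive(h, "h")
  D / h^2
}

#' Construct a compartmental lattice
#'
#' A lattice is a set of well-mixed compartments (with centroid coordinates
#' and volumes) connected by directed transport couplings. Each coupling
#' carries a per-particle, per-species rate (1/s): `D/h^2` hops for Fickian
#' diffusion, or a uniform `v/L` rate for hydrodynamic mass flow.
#'
#' @param compartments data.frame with columns `id` (1..n), `x_um`, `y_um`,
#'   `z_um`, `volume_pL`.
#' @param couplings data.frame with integer columns `from`, `to`
#'   (directed; compartment ids).
#' @param rates numeric matrix, `nrow(couplings)` x species, of per-particle
#'   transport rates (1/s); column names are species names. A single-column
#'   matrix named `".all"` applies to every species.
#' @return object of class `lattice`.
#' @export
lattice <- function(compartments, couplings, rates) {
  stopifnot(is.data.frame(compartments),
            all(c("id", "x_um", "y_um", "z_um", "volume_pL") %in%
                  names(compartments)))
  if (any(compartments$volume_pL <= 0))
    stop("compartment volumes must be positive", call. = FALSE)
  if (!identical(as.integer(compartments$id),
                 seq_len(nrow(compartments))))
    stop("compartment ids must be 1..n in order", call. = FALSE)
  couplings <- as.data.frame(couplings)
  if (nrow(couplings)) {
    if (!all(c(couplings$from, couplings$to) %in% compartments$id))
      stop("couplings reference unknown compartments", call. = FALSE)
    if (!is.matrix(rates) || nrow(rates) != nrow(couplings))
      stop("rates must be a matrix with one row per coupling", call. = FALSE)
    if (any(rates < 0))
      stop("hop rates must be non-negative", call. = FALSE)
  } else {
    rates <- matrix(numeric(0), 0, 1, dimnames = list(NULL, ".all"))
  }
  structure(list(compartments = compartments, couplings = couplings,
                 rates = rates),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat("Compartmental lattice:", nrow(x$compartments), "compartments,",
      nrow(x$couplings), "directed couplings\n")
  cat("  total volume:",
      format(sum(x$compartments$volume_pL) / 1e3, digits = 6), "nL\n")
  invisible(x)
}

#' Total lattice volume in litres
#' @param lat a [lattice()].
#' @return volume in L.
#' @export
lattice_volume <- function(lat) sum(lat$compartments$volume_pL) * 1e-12

# internal: expand the per-coupling rate matrix to one column per species
# in the order given
expand_rates <- function(lat, species_names) {
  r <- lat$rates
  n_edge <- nrow(lat$couplings)
  out <- matrix(0, n_edge, length(species_names),
                dimnames = list(NULL, species_names))
  if (!n_edge) return(out)
  if (identical(colnames(r), ".all")) {
    out[] <- r[, 1]
  } else {
    known <- intersect(colnames(r), species_names)
    out[, known] <- r[, known]
  }
  out
}

#' Write a lattice to a pair of CSV files
#'
#' @param lat a [lattice()].
#' @param comp_file,coupling_file output paths; the coupling file carries one
#'   rate column per species.
#' @return invisibly, the compartment data.frame.
#' @export
write_lattice_csv <- function(lat, comp_file, coupling_file) {
  utils::write.csv(lat$compartments, comp_file, row.names = FALSE)
  utils::write.csv(cbind(lat$couplings, as.data.frame(lat$rates)),
                   coupling_file, row.names = FALSE)
  invisible(lat$compartments)
}
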