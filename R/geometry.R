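#' Specify a dispensed drop population
#'
#' Either volume or diameter may be given; the other is derived from the
#' spherical relation `V = pi * d^3 / 6`. If both are given they must agree
#' to 0.1%.
#'
#' @param volume_pL drop volume, pL.
#' @param diameter_um drop diameter, um.
#' @param count number of drops (default 1).
#' @return object of class `drop_spec` with fields `volume_pL`,
#'   `diameter_um`, `count`.
#' @examples
#' drop_spec(volume_pL = 4000)$diameter_um   # ~197 um, the 4 nL ADE drop
#' @export
drop_spec <- function(volume_pL = NULL, diameter_um = NULL, count = 1L) {
  if (is.null(volume_pL) && is.null(diameter_um))
    stop("give volume_pL or diameter_um", call. = FALSE)
  if (!is.null(volume_pL)) check_positive(volume_pL, "volume_pL")
  if (!is.null(diameter_um)) check_positive(diameter_um, "diameter_um")
  if (count < 1 || count != round(count))
    stop("count must be a positive integer", call. = FALSE)
  # 1 pL = 1e6 um^3... no: 1 um^3 = 1e-15 L = 1e-3 pL, so 1 pL = 1e3 um^3
  if (is.null(diameter_um))
    diameter_um <- (6 * volume_pL * 1e3 / pi)^(1 / 3)
  else if (is.null(volume_pL))
    volume_pL <- pi * diameter_um^3 / 6 / 1e3
  else {
    v_check <- pi * diameter_um^3 / 6 / 1e3
    if (abs(v_check - volume_pL) > 1e-3 * volume_pL)
      stop("volume and diameter disagree by more than 0.1%", call. = FALSE)
  }
  structure(list(volume_pL = volume_pL, diameter_um = diameter_um,
                 count = as.integer(count)),
            class = "drop_spec")
}

#' @export
print.drop_spec <- function(x, ...) {
  cat(sprintf("Drop: %d x %.4g pL (diameter %.4g um)\n",
              x$count, x$volume_pL, x$diameter_um))
  invisible(x)
}

# internal: cubic-grid cell centers (um) whose centers fall inside a sphere
# of radius R centered at `center`
sphere_cells <- function(R_um, h_um, center = c(0, 0, 0)) {
  n <- ceiling(R_um / h_um) + 1L
  ax <- (-n:n) * h_um
  g <- expand.grid(x = ax + center[1], y = ax + center[2], z = ax + center[3])
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g[d2 <= R_um^2, , drop = FALSE]
}

# internal: directed face-adjacency couplings among cells on a common grid
face_couplings <- function(xyz, h_um) {
  key <- function(p) paste(round(p[, 1] / h_um), round(p[, 2] / h_um),
                           round(p[, 3] / h_um))
  idx <- stats::setNames(seq_len(nrow(xyz)), key(xyz))
  from <- to <- integer(0)
  for (d in 1:3) for (s in c(-1, 1)) {
    nb <- xyz
    nb[, d] <- nb[, d] + s * h_um
    j <- idx[key(nb)]
    keep <- !is.na(j)
    from <- c(from, which(keep))
    to <- c(to, unname(j[keep]))
  }
  data.frame(from = from, to = to)
}

#' Voxelise a spherical drop into a cubic-compartment lattice
#'
#' Cells of spacing `h` whose centers fall inside the sphere become
#' compartments; nearest-neighbour (face) couplings carry Fickian hop rates
#' `D/h^2` per species.
#'
#' @param volume_nL sphere volume, nL.
#' @param h_um compartment spacing, um.
#' @param D named numeric vector of diffusion coefficients (m^2/s) per
#'   species; species missing from `D` do not diffuse.
#' @return a [lattice()] with extra fields `h_um`, `radius_um`, `D`.
#' @examples
#' lat <- discretize_sphere(4, 10, c(Ca = 7.9e-10))
#' lat$radius_um * 2   # ~197 um diameter
#' @export
discretize_sphere <- function(volume_nL, h_um, D) {
  check_positive(volume_nL, "volume_nL")
  check_positive(h_um, "h_um")
  stopifnot(is.numeric(D), !is.null(names(D)))
  R <- (3 * volume_nL * 1e6 / (4 * pi))^(1 / 3)   # um (1 nL = 1e6 um^3)
  if (2 * R / h_um < 3)
    stop("h too coarse: fewer than 3 voxels across the drop diameter",
         call. = FALSE)
  cells <- sphere_cells(R, h_um)
  vol_pL <- rep(h_um^3 / 1e3, nrow(cells))
  if (abs(sum(vol_pL) - volume_nL * 1e3) > 0.05 * volume_nL * 1e3)
    stop("voxelisation misses the requested volume by more than 5%",
         call. = FALSE)
  comp <- data.frame(id = seq_len(nrow(cells)),
                     x_um = cells$x, y_um = cells$y, z_um = cells$z,
                     volume_pL = vol_pL)
  cp <- face_couplings(cells, h_um)
  rates <- outer(rep(1, nrow(cp)), D / (h_um * 1e-6)^2)
  colnames(rates) <- names(D)
  lat <- lattice(comp, cp, rates)
  lat$h_um <- h_um
  lat$radius_um <- R
  lat$D <- D
  lat
}

#' Weber number of a droplet collision
#'
#' `We = rho * v^2 * L / sigma`, the ratio of inertial to surface-tension
#' forces, which governs whether a collision merges drops and drives
#' internal jetting.
#'
#' @param rho liquid density, kg/m^3.
#' @param v relative velocity, m/s.
#' @param L characteristic length (drop diameter), m.
#' @param sigma surface tension, N/m.
#' @return dimensionless Weber number.
#' @examples
#' weber_number(1000, 1.5, 200e-6, 0.072)  # 6.25
#' @export
weber_number <- function(rho, v, L, sigma) {
  check_positive(rho, "rho")
  check_positive(v, "v")
  check_positive(L, "L")
  check_positive(sigma, "sigma")
  rho * v^2 * L / sigma
}

# internal: unit vectors for PEI contact sites — evenly spaced on a latitude
# ring at `polar_deg` from the top pole
site_directions <- function(n_sites, polar_deg = 45, azimuth0 = 0) {
  th <- polar_deg * pi / 180
  phi <- azimuth0 + 2 * pi * (seq_len(n_sites) - 1) / n_sites
  cbind(x = sin(th) * cos(phi), y = sin(th) * sin(phi),
        z = rep(cos(th), n_sites))
}

#' Place picoliter substrate drops onto a voxelised main drop
#'
#' Builds the initial substrate distribution for the diffusion-only
#' (`surface_caps`) and partial-mix (`cone_jets`) regimes. Contact sites are
#' evenly spaced on a latitude ring 45 degrees from the top pole.
#'
#' * `surface_caps`: each substrate drop is voxelised as a small sphere on
#'   the same grid, resting on the main drop at its contact site with a
#'   finite wetting overlap (`contact_depth_frac` of the drop radius, so the
#'   contact area is a physical constant, not a lattice artefact); its cells
#'   are appended as new compartments (volumes normalised so each drop's
#'   cells sum exactly to its volume) and face-coupled to the main lattice.
#'   All substrate starts in the caps; the main-drop interior holds none.
#' * `cone_jets`: the substrate is placed inside conical regions extending
#'   from the contact sites into the main drop (apex pointing inward, depth
#'   `cone_depth_frac` of the radius, base radius chosen so each cone's
#'   nominal volume equals the drop volume); no compartments are added.
#'
#' @param lat a [discretize_sphere()] lattice of the main drop.
#' @param pei a [drop_spec()] for the substrate drops (count >= 1).
#' @param c_substrate substrate concentration in the drops, mol/L.
#' @param mode `"surface_caps"` or `"cone_jets"`.
#' @param substrate species name carrying the substrate (default `"Ca"`).
#' @param cone_depth_frac cone depth as a fraction of the main-drop radius.
#' @param contact_depth_frac wetting-overlap depth of a resting substrate
#'   drop, as a fraction of its radius (surface_caps mode).
#' @param polar_deg,azimuth0 contact-site ring geometry.
#' @return object of class `initial_state`: list with `lattice` (possibly
#'   augmented), `conc` (1-row matrix of substrate molarity per
#'   compartment), `amount_mol` (total substrate), `mode`, `sites`.
#' @export
apply_pei_initial_condition <- function(lat, pei, c_substrate,
                                        mode = c("surface_caps", "cone_jets"),
                                        substrate = "Ca",
                                        cone_depth_frac = 0.5,
                                        contact_depth_frac = 0.3,
                                        polar_deg = 45, azimuth0 = 0) {
  mode <- match.arg(mode)
  check_positive(c_substrate, "c_substrate")
  if (pei$count < 1L) stop("pei$count must be >= 1", call. = FALSE)
  v_main_nL <- lattice_volume(lat) * 1e9
  if (pei$count * pei$volume_pL >= v_main_nL * 1e3)
    stop("total substrate-drop volume must be below the main-drop volume",
         call. = FALSE)
  h <- lat$h_um
  R <- lat$radius_um
  dirs <- site_directions(pei$count, polar_deg, azimuth0)
  amount_mol <- pei$count * pei$volume_pL * 1e-12 * c_substrate

  if (mode == "surface_caps") {
    r_pei <- pei$diameter_um / 2
    main_xyz <- as.matrix(lat$compartments[, c("x_um", "y_um", "z_um")])
    claimed <- character(0)
    all_cells <- NULL
    drop_of <- integer(0)
    for (k in seq_len(pei$count)) {
      ctr <- dirs[k, ] * (R + r_pei * (1 - contact_depth_frac))
      ctr <- round(ctr / h) * h                     # snap to grid
      cells <- sphere_cells(r_pei, h, ctr)
      key <- paste(round(cells$x / h), round(cells$y / h), round(cells$z / h))
      inside_main <- rowSums(cells^2) <= R^2
      cells <- cells[!inside_main, , drop = FALSE]
      key <- key[!inside_main]
      if (!nrow(cells))
        stop("substrate drop ", k, " could not be placed (no cells)",
             call. = FALSE)
      if (any(key %in% claimed))
        stop("substrate drops overlap; reduce count or size", call. = FALSE)
      claimed <- c(claimed, key)
      all_cells <- rbind(all_cells, cells)
      drop_of <- c(drop_of, rep(k, nrow(cells)))
    }
    n_main <- nrow(lat$compartments)
    # per-drop volume normalisation: each cap sums exactly to its drop volume
    vol_pL <- numeric(nrow(all_cells))
    for (k in seq_len(pei$count))
      vol_pL[drop_of == k] <- pei$volume_pL / sum(drop_of == k)
    comp <- rbind(lat$compartments,
                  data.frame(id = n_main + seq_len(nrow(all_cells)),
                             x_um = all_cells$x, y_um = all_cells$y,
                             z_um = all_cells$z, volume_pL = vol_pL))
    all_xyz <- as.matrix(comp[, c("x_um", "y_um", "z_um")])
    cp <- face_couplings(as.data.frame(all_xyz), h)
    rates <- outer(rep(1, nrow(cp)), lat$D / (h * 1e-6)^2)
    colnames(rates) <- names(lat$D)
    aug <- lattice(comp, cp, rates)
    aug$h_um <- h; aug$radius_um <- R; aug$D <- lat$D
    # every cap must touch the main drop
    cap_ids <- n_main + seq_len(nrow(all_cells))
    touching <- unique(drop_of[match(
      intersect(cp$from[cp$to <= n_main], cap_ids), cap_ids)])
    if (length(touching) < pei$count)
      stop("a substrate drop is not in contact with the main drop",
           call. = FALSE)
    conc <- matrix(0, 1, nrow(comp), dimnames = list(substrate, NULL))
    conc[1, cap_ids] <- c_substrate
    lat_out <- aug
  } else {                                         # cone_jets
    depth <- cone_depth_frac * R
    base_r <- if (depth > 0)
      sqrt(3 * pei$volume_pL * 1e3 / (pi * depth)) else 0
    xyz <- as.matrix(lat$compartments[, c("x_um", "y_um", "z_um")])
    conc <- matrix(0, 1, nrow(lat$compartments),
                   dimnames = list(substrate, NULL))
    for (k in seq_len(pei$count)) {
      u <- dirs[k, ]
      apex <- (R - depth) * u
      rel <- sweep(xyz, 2, apex)
      t_ax <- rel %*% u                            # axial distance from apex
      rad2 <- rowSums(rel^2) - t_ax^2
      sel <- which(t_ax >= 0 & t_ax <= depth &
                     rad2 <= (base_r * pmax(t_ax, 0) / max(depth, 1e-9))^2)
      if (!length(sel)) {
        # degenerate cone: fall back to the cell nearest the contact point
        sel <- which.min(colSums((t(xyz) - R * u)^2))
      }
      vols <- lat$compartments$volume_pL[sel] * 1e-12
      conc[1, sel] <- conc[1, sel] +
        (pei$volume_pL * 1e-12 * c_substrate) / sum(vols)
    }
    lat_out <- lat
  }
  structure(list(lattice = lat_out, conc = conc, amount_mol = amount_mol,
                 mode = mode, substrate = substrate, sites = dirs),
            class = "initial_state")
}

#' Compartment chain for collision-driven (inertial) mass-flow mixing
#'
#' Idealises the merged drop immediately after collision as a chain of
#' equal-volume compartments with proportional mass transfer between
#' neighbours at a per-particle rate `v_rel / L_mix`, where
#' `L_mix = main-drop diameter / n_compartments`. There are no Fickian
#' couplings; the model provides a lower bound on mixing time for transport
#' controlled purely by hydrodynamic flow.
#'
#' @param ade [drop_spec()] of the main drop.
#' @param pei [drop_spec()] of the substrate drops (their total volume is
#'   added to the chain).
#' @param v_rel collision relative velocity, m/s (accepted range 0.1-10).
#' @param n_compartments chain length (>= 2).
#' @return a [lattice()] with fields `L_mix_um`, `transfer_rate_s` and
#'   `h_um = L_mix_um`.
#' @examples
#' lat <- build_mass_flow_model(drop_spec(4000), drop_spec(60, count = 3), 1.5, 10)
#' lat$transfer_rate_s   # v/L = 1.5 / 20e-6 = 7.5e4 s^-1
#' @export
build_mass_flow_model <- function(ade, pei, v_rel, n_compartments = 10L) {
  if (v_rel < 0.1 || v_rel > 10)
    stop("v_rel outside the physical range 0.1-10 m/s", call. = FALSE)
  if (n_compartments < 2 || n_compartments != round(n_compartments))
    stop("n_compartments must be an integer >= 2", call. = FALSE)
  v_tot_pL <- ade$volume_pL * ade$count + pei$volume_pL * pei$count
  L_mix_um <- ade$diameter_um / n_compartments
  rate <- v_rel / (L_mix_um * 1e-6)
  n <- as.integer(n_compartments)
  comp <- data.frame(id = seq_len(n),
                     x_um = (seq_len(n) - 0.5) * L_mix_um,
                     y_um = 0, z_um = 0,
                     volume_pL = rep(v_tot_pL / n, n))
  cp <- data.frame(from = c(seq_len(n - 1), seq_len(n - 1) + 1L),
                   to = c(seq_len(n - 1) + 1L, seq_len(n - 1)))
  rates <- matrix(rate, nrow(cp), 1, dimnames = list(NULL, ".all"))
  lat <- lattice(comp, cp, rates)
  lat$L_mix_um <- L_mix_um
  lat$transfer_rate_s <- rate
  lat$h_um <- L_mix_um
  lat
}
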