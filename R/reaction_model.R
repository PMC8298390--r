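#' Construct a mass-action reaction network
#'
#' A network is a set of named species, each carrying a moiety composition
#' (how many copies of each conserved group — e.g. the calcium ion or a dye
#' scaffold — the species contains), plus a list of mass-action reactions.
#' Every reaction must balance each moiety between its two sides.
#'
#' @param species data.frame with columns `name` and `role`
#'   (`"ligand"`, `"dye_free"`, `"dye_bound"` or `"inert"`).
#' @param reactions list of reactions as built by [reaction()].
#' @param moieties integer matrix, species x conserved moieties; row names are
#'   species names. Defaults to the identity (each species its own moiety),
#'   which is only correct when there are no reactions.
#' @param kd_map optional named numeric vector of dissociation constants
#'   (mol/L) per dye.
#' @return an object of class `reaction_network`.
#' @seealso [build_dye_network()] for the calcium/Fura-Red/Fluo-5N template.
#' @export
reaction_network <- function(species, reactions = list(), moieties = NULL,
                             kd_map = numeric()) {
  stopifnot(is.data.frame(species), all(c("name", "role") %in% names(species)))
  species$name <- as.character(species$name)
  if (anyDuplicated(species$name))
    stop("species names must be unique", call. = FALSE)
  ok_roles <- c("ligand", "dye_free", "dye_bound", "inert")
  if (!all(species$role %in% ok_roles))
    stop("species role must be one of: ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  if (is.null(moieties)) {
    moieties <- diag(nrow(species))
    dimnames(moieties) <- list(species$name, species$name)
  }
  if (!all(rownames(moieties) == species$name))
    stop("moiety matrix rows must match species names", call. = FALSE)

  for (r in reactions) {
    all_sp <- c(names(r$reactants), names(r$products))
    unknown <- setdiff(all_sp, species$name)
    if (length(unknown))
      stop("reaction references unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    # moiety balance: reactant-side moiety counts equal product-side counts
    lhs <- colSums(moieties[names(r$reactants), , drop = FALSE] * r$reactants)
    rhs <- colSums(moieties[names(r$products), , drop = FALSE] * r$products)
    if (!isTRUE(all.equal(lhs, rhs, tolerance = 1e-12)))
      stop("reaction does not balance conserved moieties", call. = FALSE)
  }

  structure(
    list(species = species, reactions = reactions,
         moieties = moieties, kd_map = kd_map),
    class = "reaction_network"
  )
}

#' Define a single mass-action reaction
#'
#' @param reactants,products named integer vectors of stoichiometries
#'   (names are species). An empty vector is allowed on at most one side.
#' @param rate rate constant: 1/s for unimolecular, 1/(M s) for bimolecular
#'   reactions (the engine converts to per-compartment propensities).
#' @return a list of class `reaction`.
#' @export
reaction <- function(reactants, products, rate) {
  check_positive(rate, "rate")
  for (v in list(reactants, products)) {
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        stop("stoichiometry vectors must be named by species", call. = FALSE)
      if (any(v != as.integer(v)) || any(v <= 0))
        stop("stoichiometries must be positive integers", call. = FALSE)
    }
  }
  order <- sum(reactants)
  if (order < 1L || order > 2L)
    stop("only unimolecular and bimolecular reactions are supported",
         call. = FALSE)
  structure(list(reactants = reactants, products = products,
                 rate = rate, order = order),
            class = "reaction")
}

#' Build the two-dye competitive calcium-binding network
#'
#' Five species — free calcium, free and Ca-bound Fura Red, free and Ca-bound
#' Fluo-5N — with reversible binding for each dye. Off-rates are derived from
#' the dissociation constants as `k_off = Kd * k_on`, so detailed balance is
#' built in. Default dissociation constants are the indicator values:
#' Fura Red 400 nM, Fluo-5N 90 uM; default on-rates are a literature-typical
#' diffusion-influenced 1e8 /M/s (absolute kinetic outputs scale with this
#' choice; all four constants are configurable).
#'
#' @param kd_fura,kd_fluo dissociation constants, mol/L.
#' @param kon_fura,kon_fluo bimolecular on-rates, 1/(M s).
#' @return a [reaction_network()] with species `Ca`, `FuraFree`, `FuraBound`,
#'   `FluoFree`, `FluoBound` and four reactions.
#' @examples
#' net <- build_dye_network()
#' net$kd_map                       # c(Fura = 4e-7, Fluo = 9e-5)
#' @export
build_dye_network <- function(kd_fura = 4e-7, kd_fluo = 9e-5,
                              kon_fura = 1e8, kon_fluo = 1e8) {
  check_positive(kd_fura, "kd_fura")
  check_positive(kd_fluo, "kd_fluo")
  check_positive(kon_fura, "kon_fura")
  check_positive(kon_fluo, "kon_fluo")

  species <- data.frame(
    name = c("Ca", "FuraFree", "FuraBound", "FluoFree", "FluoBound"),
    role = c("ligand", "dye_free", "dye_bound", "dye_free", "dye_bound"),
    stringsAsFactors = FALSE
  )
  # conserved moieties: the calcium ion and each dye scaffold
  moieties <- rbind(
    Ca        = c(Ca = 1, Fura = 0, Fluo = 0),
    FuraFree  = c(Ca = 0, Fura = 1, Fluo = 0),
    FuraBound = c(Ca = 1, Fura = 1, Fluo = 0),
    FluoFree  = c(Ca = 0, Fura = 0, Fluo = 1),
    FluoBound = c(Ca = 1, Fura = 0, Fluo = 1)
  )
  reactions <- list(
    reaction(c(Ca = 1L, FuraFree = 1L), c(FuraBound = 1L), kon_fura),
    reaction(c(FuraBound = 1L), c(Ca = 1L, FuraFree = 1L), kd_fura * kon_fura),
    reaction(c(Ca = 1L, FluoFree = 1L), c(FluoBound = 1L), kon_fluo),
    reaction(c(FluoBound = 1L), c(Ca = 1L, FluoFree = 1L), kd_fluo * kon_fluo)
  )
  reaction_network(species, reactions, moieties,
                   kd_map = c(Fura = kd_fura, Fluo = kd_fluo))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:",
      nrow(x$species), "species,", length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    side <- function(v) if (!length(v)) "0" else
      paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
            sep = "", collapse = " + ")
    cat(sprintf("  %s -> %s   (k = %.4g)\n",
                side(r$reactants), side(r$products), r$rate))
  }
  if (length(x$kd_map))
    cat("  Kd:", paste(names(x$kd_map), "=",
                       format(x$kd_map, digits = 4), "M", collapse = ", "), "\n")
  invisible(x)
}

# internal: identify (free, bound, Kd) triples for every dye in a network.
# Relies on the dye-template structure: a single ligand species plus
# free/bound pairs linked by a binding and an unbinding reaction.
dye_pairs <- function(network) {
  sp <- network$species
  ligand <- sp$name[sp$role == "ligand"]
  if (length(ligand) != 1L)
    stop("network must have exactly one ligand species", call. = FALSE)
  pairs <- list()
  for (r in network$reactions) {
    re <- names(r$reactants); pr <- names(r$products)
    if (length(re) == 2L && ligand %in% re && length(pr) == 1L) {
      free <- setdiff(re, ligand); bound <- pr
      # find matching unbinding reaction for Kd = k_off / k_on
      koff <- NA_real_
      for (r2 in network$reactions)
        if (identical(names(r2$reactants), bound) &&
            setequal(names(r2$products), re)) koff <- r2$rate
      if (is.na(koff))
        stop("binding reaction for ", bound, " has no reverse reaction",
             call. = FALSE)
      pairs[[bound]] <- list(free = free, bound = bound,
                             kd = koff / r$rate)
    }
  }
  list(ligand = ligand, pairs = pairs)
}

#' Closed-form equilibrium of the competitive dye-binding system
#'
#' Solves the coupled conservation and dissociation-constant equations for a
#' single ligand competing for any number of dyes. The free-ligand
#' concentration is the unique root of the monotone function
#' `x + sum_d Dtot_d * x / (x + Kd_d) - Ltot` on `[0, Ltot]`, located by
#' Brent bracketing to a relative tolerance of 1e-12.
#'
#' @param network a [reaction_network()] with dye-template structure.
#' @param totals named numeric vector of total concentrations (mol/L) per
#'   conserved moiety, e.g. `c(Ca = 1.5e-3, Fura = 1e-3, Fluo = 1e-3)`.
#' @return object of class `equilibrium_state`: list with `concentrations`
#'   (mol/L per species) and `totals` (echo).
#' @examples
#' net <- build_dye_network()
#' eq <- equilibrium_state(net, c(Ca = 4.3e-3, Fura = 1e-3, Fluo = 1e-3))
#' eq$concentrations["FuraBound"]
#' @export
equilibrium_state <- function(network, totals) {
  check_nonneg(totals, "totals")
  info <- dye_pairs(network)
  moi <- colnames(network$moieties)
  if (!all(names(totals) %in% moi))
    stop("totals names must be conserved moieties: ",
         paste(moi, collapse = ", "), call. = FALSE)
  full <- stats::setNames(numeric(length(moi)), moi)
  full[names(totals)] <- totals
  ltot <- full[[info$ligand]]

  dtot <- vapply(info$pairs, function(p) {
    # the moiety of the free dye species identifies its total
    m <- which(network$moieties[p$free, ] > 0)
    full[[colnames(network$moieties)[m]]]
  }, numeric(1))
  kd <- vapply(info$pairs, `[[`, numeric(1), "kd")

  conc <- stats::setNames(numeric(nrow(network$species)),
                          network$species$name)
  if (ltot <= 0) {
    free_l <- 0
  } else {
    g <- function(x) x + sum(dtot * x / (x + kd)) - ltot
    free_l <- stats::uniroot(g, c(0, ltot), tol = 1e-12 * max(ltot, 1e-30),
                             maxiter = 1000L)$root
  }
  conc[info$ligand] <- free_l
  for (i in seq_along(info$pairs)) {
    p <- info$pairs[[i]]
    bound <- dtot[i] * free_l / (free_l + kd[i])
    conc[p$bound] <- bound
    conc[p$free] <- dtot[i] - bound
  }
  # enforce exact ligand mass balance (root solved to 1e-12 relative)
  conc[info$ligand] <- ltot - sum(conc[vapply(info$pairs, `[[`, "", "bound")])
  structure(list(concentrations = conc, totals = full),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium concentrations (mol/L):\n")
  print(signif(x$concentrations, 6))
  invisible(x)
}

#' Serialise a reaction network to a declarative configuration list
#'
#' The list round-trips through JSON/YAML and [network_from_config()].
#' @param network a [reaction_network()].
#' @return a plain list with unit-tagged entries.
#' @export
network_to_config <- function(network) {
  list(
    species = network$species,
    moieties = list(matrix = unname(network$moieties),
                    species = rownames(network$moieties),
                    names = colnames(network$moieties)),
    reactions = lapply(network$reactions, function(r) {
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           rate = r$rate,
           rate_unit = if (r$order == 2L) "1/(M*s)" else "1/s")
    }),
    kd_map = as.list(network$kd_map), kd_unit = "M"
  )
}

#' Rebuild a reaction network from its configuration list
#' @param config list as produced by [network_to_config()].
#' @return a [reaction_network()].
#' @export
network_from_config <- function(config) {
  m <- config$moieties$matrix
  moi <- if (is.matrix(m)) m else
    matrix(unlist(m), nrow = length(unlist(config$moieties$species)),
           byrow = TRUE)
  dimnames(moi) <- list(unlist(config$moieties$species),
                        unlist(config$moieties$names))
  reactions <- lapply(config$reactions, function(r)
    reaction(unlist(r$reactants), unlist(r$products), r$rate))
  species <- as.data.frame(config$species, stringsAsFactors = FALSE)
  reaction_network(species, reactions, moi,
                   kd_map = unlist(config$kd_map))
}
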