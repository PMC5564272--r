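#' Define chemical species
#'
#' A species table describes every solute that can occur inside a droplet.
#' Molecular weight governs the inter-droplet diffusion rate (flux scales as
#' `1/MW`); `exchangeable` switches that transfer off entirely for trapped
#' species (e.g. long polymers); `osmotically_active` controls whether the
#' species contributes to a droplet's osmolarity and hence to water flux.
#'
#' @param name Character, species label (unique within a population).
#' @param molecular_weight Numeric, g/mol, strictly positive.
#' @param exchangeable Logical; can the species transfer between droplets
#'   through the oil phase?
#' @param osmotically_active Logical; does the species count toward
#'   osmolarity?
#'
#' @return A tibble with one row per species and columns `name`,
#'   `molecular_weight`, `exchangeable`, `osmotically_active`.
#' @examples
#' species(c("glycylglycine"), 132.12, exchangeable = FALSE)
#' @export
species <- function(name, molecular_weight, exchangeable = TRUE,
                    osmotically_active = TRUE) {
  stopifnot(is.character(name), length(name) >= 1)
  out <- tibble::tibble(
    name = name,
    molecular_weight = as.numeric(molecular_weight),
    exchangeable = vctrs_recycle_lgl(exchangeable, length(name)),
    osmotically_active = vctrs_recycle_lgl(osmotically_active, length(name))
  )
  validate_species(out)
  out
}

vctrs_recycle_lgl <- function(x, n) {
  x <- as.logical(x)
  if (length(x) == 1) rep(x, n) else x
}

validate_species <- function(sp) {
  if (anyDuplicated(sp$name)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (any(!is.finite(sp$molecular_weight)) || any(sp$molecular_weight <= 0)) {
    stop("molecular_weight must be positive and finite", call. = FALSE)
  }
  invisible(sp)
}

#' Define a reaction with mass-action kinetics
#'
#' Reactions run independently inside each droplet. The rate law is
#' mass-action on concentrations in mol/L:
#' `rate = rate_constant * prod(c_s^order_s) * c_catalyst` (the catalyst
#' factor only when a catalyst is set). By default the kinetic order of each
#' reactant equals its stoichiometric count; `rate_orders` overrides this for
#' reactions whose empirical rate law differs from the stoichiometry, as in
#' step-growth condensation where ten monomers are consumed per chain but the
#' rate is second order in monomer.
#'
#' Monomer-equivalent mass must balance: the total molecular weight on each
#' side must agree to 1e-9 relative (checked when the reaction is attached to
#' a population, where molecular weights are known).
#'
#' @param reactants Named numeric vector, species -> stoichiometric count.
#' @param products Named numeric vector, species -> stoichiometric count.
#' @param rate_constant Rate constant in concentration/time units matching
#'   the total kinetic order (per second, with concentrations in mol/L).
#' @param catalyst Optional species name whose concentration multiplies the
#'   rate; the catalyst is not consumed.
#' @param rate_orders Optional named numeric vector overriding the kinetic
#'   order of individual reactants.
#' @return An object of class `droplet_reaction`.
#' @examples
#' # 10 M -> P, second order in monomer
#' reaction(c(monomer = 10), c(polymer = 1), 1e-5, rate_orders = c(monomer = 2))
#' @export
reaction <- function(reactants, products, rate_constant, catalyst = NULL,
                     rate_orders = NULL) {
  stopifnot(
    is.numeric(reactants), !is.null(names(reactants)),
    is.numeric(products), !is.null(names(products)),
    is.numeric(rate_constant), length(rate_constant) == 1, rate_constant >= 0
  )
  orders <- reactants
  if (!is.null(rate_orders)) {
    stopifnot(all(names(rate_orders) %in% names(reactants)))
    orders[names(rate_orders)] <- rate_orders
  }
  structure(
    list(
      reactants = reactants,
      products = products,
      rate_constant = rate_constant,
      catalyst = catalyst,
      rate_orders = orders
    ),
    class = "droplet_reaction"
  )
}

#' @export
print.droplet_reaction <- function(x, ...) {
  lhs <- paste(x$reactants, names(x$reactants), collapse = " + ")
  rhs <- paste(x$products, names(x$products), collapse = " + ")
  cat(sprintf(
    "<droplet_reaction> %s -> %s  (k = %g%s)\n", lhs, rhs, x$rate_constant,
    if (is.null(x$catalyst)) "" else paste0(", catalyst ", x$catalyst)
  ))
  invisible(x)
}

# net stoichiometric change per species for one reaction event
reaction_net <- function(rx) {
  sp <- union(names(rx$reactants), names(rx$products))
  net <- stats::setNames(numeric(length(sp)), sp)
  net[names(rx$reactants)] <- net[names(rx$reactants)] - rx$reactants
  net[names(rx$products)] <- net[names(rx$products)] + rx$products
  net
}

validate_reaction <- function(rx, sp) {
  involved <- unique(c(names(rx$reactants), names(rx$products), rx$catalyst))
  missing <- setdiff(involved, sp$name)
  if (length(missing)) {
    stop("reaction references undefined species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mw <- stats::setNames(sp$molecular_weight, sp$name)
  m_in <- sum(rx$reactants * mw[names(rx$reactants)])
  m_out <- sum(rx$products * mw[names(rx$products)])
  if (abs(m_in - m_out) > 1e-9 * max(m_in, m_out)) {
    stop(sprintf(
      "reaction is not mass balanced: reactant mass %.6g vs product mass %.6g",
      m_in, m_out
    ), call. = FALSE)
  }
  invisible(rx)
}

#' Default autocatalytic condensation chemistry
#'
#' Two species and two reactions emulating polymer formation from a simple
#' dipeptide-like precursor: an exchangeable monomer (132 g/mol) and a trapped
#' decamer (1320 g/mol, osmotically active). Initiation `10 M -> P` is second
#' order in monomer; autocatalytic growth `10 M -> P` is first order in
#' monomer and catalysed by the polymer. Condensation lowers the particle
#' count inside a droplet, but because the polymer is trapped while monomer
#' re-equilibrates across droplets through the oil, droplets that polymerise
#' faster end up with a net osmolarity advantage and grow.
#'
#' @param k_init Initiation rate constant (L/mol/s), default 1e-6.
#' @param k_auto Autocatalytic rate constant (L/mol/s), default 1.3e-4.
#'   The defaults are slow on purpose: the conversion e-fold time must stay
#'   above the monomer re-equilibration time (about 1.3e4 s for 30 um
#'   droplets) times the chain length, or the transient local monomer
#'   deficit outweighs the trapped-polymer osmolyte gain.
#' @param chain_length Monomers per polymer chain, default 10.
#' @param monomer_mw Monomer molecular weight in g/mol, default 132
#'   (glycylglycine-like).
#' @return A list with elements `species` (tibble) and `reactions` (list of
#'   `droplet_reaction`).
#' @export
default_chemistry <- function(k_init = 1e-6, k_auto = 1.3e-4, chain_length = 10,
                              monomer_mw = 132) {
  sp <- species(
    name = c("monomer", "polymer"),
    molecular_weight = c(monomer_mw, chain_length * monomer_mw),
    exchangeable = c(TRUE, FALSE),
    osmotically_active = c(TRUE, TRUE)
  )
  rx <- list(
    reaction(c(monomer = chain_length), c(polymer = 1), k_init,
             rate_orders = c(monomer = 2)),
    reaction(c(monomer = chain_length), c(polymer = 1), k_auto,
             catalyst = "polymer", rate_orders = c(monomer = 1))
  )
  list(species = sp, reactions = rx)
}
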