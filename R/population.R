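#' Environment (bath) parameters for a co-incubating population
#'
#' The continuous oil phase is treated as a well-mixed mean-field bath:
#' every droplet exchanges water and permeable solutes with the area-weighted
#' population mean. `e_state` is a dimensionless scalar describing external
#' conditions; `delta_e` is the per-generation change applied by the
#' evolution loop and reported alongside the Price transmission term.
#'
#' @param k_w Water permeability, um * L / (mol * s): volume flux per unit
#'   droplet area per unit osmolarity difference.
#' @param k_s Solute exchange base rate, um/s, at the reference molecular
#'   weight `mw_ref`; the effective coefficient for a species of weight MW is
#'   `k_s * mw_ref / MW` (flux inversely proportional to molecular weight).
#' @param mw_ref Reference molecular weight, g/mol.
#' @param e_state Dimensionless environment scalar.
#' @param delta_e Per-generation environment change.
#' @return A list of class `droplet_environment`.
#' @export
environment_spec <- function(k_w = 0.01, k_s = 0.001, mw_ref = 100,
                             e_state = 0, delta_e = 0) {
  stopifnot(k_w >= 0, k_s >= 0, mw_ref > 0)
  structure(
    list(k_w = k_w, k_s = k_s, mw_ref = mw_ref,
         e_state = e_state, delta_e = delta_e),
    class = "droplet_environment"
  )
}

#' Assemble a droplet population
#'
#' The central container: a tibble of droplets (one row each) together with
#' the species table, the reaction network and the bath environment. Droplet
#' columns are `id`, `radius_um`, `generation`, `parent_ids` (list column)
#' plus one numeric column per species holding the absolute amount in mol.
#'
#' @param droplets Tibble/data frame with columns `id`, `radius_um` and one
#'   column per species (mol). `generation` and `parent_ids` are filled with
#'   defaults if absent.
#' @param species Species tibble from [species()].
#' @param reactions List of [reaction()] objects (may be empty).
#' @param environment Bath parameters from [environment_spec()].
#' @param time Simulation time, s.
#' @return An object of class `droplet_population`.
#' @examples
#' sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
#' d <- new_droplets(4, radius_um = 30, amounts_M = c(glycylglycine = 0.05),
#'                   species = sp)
#' pop <- droplet_population(d, sp)
#' pop
#' @export
droplet_population <- function(droplets, species,
                               reactions = list(),
                               environment = environment_spec(),
                               time = 0) {
  droplets <- tibble::as_tibble(droplets)
  if (!"generation" %in% names(droplets)) droplets$generation <- 0L
  if (!"parent_ids" %in% names(droplets)) {
    droplets$parent_ids <- rep(list(character(0)), nrow(droplets))
  }
  stopifnot(all(c("id", "radius_um") %in% names(droplets)))
  validate_species(species)
  missing_cols <- setdiff(species$name, names(droplets))
  for (s in missing_cols) droplets[[s]] <- 0
  droplets <- droplets[, c("id", "radius_um", "generation", "parent_ids",
                           species$name)]
  for (rx in reactions) validate_reaction(rx, species)
  pop <- structure(
    list(
      droplets = droplets, species = species, reactions = reactions,
      environment = environment, time = time,
      log = list(clipped_mass_g = 0,
                 extinctions = tibble::tibble(time_s = numeric(),
                                              droplet_id = character()))
    ),
    class = "droplet_population"
  )
  validate_population(pop, allow_empty = TRUE)
  pop
}

validate_population <- function(pop, allow_empty = FALSE) {
  d <- pop$droplets
  if (!allow_empty && nrow(d) == 0) {
    stop("population is empty", call. = FALSE)
  }
  if (anyDuplicated(d$id)) stop("droplet ids must be unique", call. = FALSE)
  if (nrow(d) > 0) {
    if (any(!is.finite(d$radius_um)) || any(d$radius_um <= 0)) {
      stop("droplet radii must be positive", call. = FALSE)
    }
    amt <- as.matrix(d[, pop$species$name, drop = FALSE])
    if (any(amt < 0)) stop("species amounts must be non-negative", call. = FALSE)
  }
  invisible(pop)
}

#' Build a droplet table
#'
#' Convenience constructor for the per-droplet tibble: `n` droplets of given
#' radius with compositions specified as concentrations, converted to
#' absolute amounts using each droplet's volume.
#'
#' @param n Number of droplets.
#' @param radius_um Radius (um), scalar or length `n`.
#' @param amounts_M Named numeric vector of concentrations (mol/L) applied to
#'   every droplet; amounts are `conc * volume_L`.
#' @param species Species tibble; all names in `amounts_M` must appear in it.
#' @param id_prefix Prefix for generated droplet ids.
#' @param generation Generation index stored on each droplet.
#' @return A tibble suitable for [droplet_population()].
#' @export
new_droplets <- function(n, radius_um, amounts_M = NULL, species = NULL,
                         id_prefix = "d", generation = 0L) {
  r <- rep_len(radius_um, n)
  d <- tibble::tibble(
    id = sprintf("%s%04d", id_prefix, seq_len(n)),
    radius_um = r,
    generation = as.integer(generation),
    parent_ids = rep(list(character(0)), n)
  )
  v_l <- volume_um3(r) * 1e-15
  if (!is.null(amounts_M)) {
    if (!is.null(species)) stopifnot(all(names(amounts_M) %in% species$name))
    for (s in names(amounts_M)) d[[s]] <- amounts_M[[s]] * v_l
  }
  if (!is.null(species)) {
    for (s in setdiff(species$name, names(d))) d[[s]] <- 0
  }
  d
}

#' @export
print.droplet_population <- function(x, ...) {
  cat(sprintf(
    "<droplet_population> %d droplets, %d species, %d reactions, t = %g s\n",
    nrow(x$droplets), nrow(x$species), length(x$reactions), x$time
  ))
  print(x$droplets, n = 5)
  invisible(x)
}

#' Extract the droplet table from a population
#' @param population A `droplet_population`.
#' @return The droplet tibble.
#' @export
droplets <- function(population) population$droplets

# geometry helpers: radii in um, volumes in um^3, areas in um^2
volume_um3 <- function(radius_um) (4 / 3) * pi * radius_um^3
area_um2 <- function(radius_um) 4 * pi * radius_um^2
radius_from_volume <- function(volume_um3) (3 * volume_um3 / (4 * pi))^(1 / 3)

UM3_PER_L <- 1e15 # 1 L = 1e15 um^3

amounts_matrix <- function(pop) {
  m <- as.matrix(pop$droplets[, pop$species$name, drop = FALSE])
  rownames(m) <- pop$droplets$id
  m
}

# replace droplet radii/amounts, keeping metadata columns
set_state <- function(pop, radius_um, amounts) {
  pop$droplets$radius_um <- radius_um
  pop$droplets[, pop$species$name] <- as.data.frame(amounts)
  pop
}
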