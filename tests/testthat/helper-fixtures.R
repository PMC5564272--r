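# fixtures built in code; all stochastic helpers take an explicit seed

# two-droplet oracle system: trapped solute vs pure water, equal radii
two_droplet_pop <- function(radius_um = 30, conc_M = 0.05, k_w = 0.01) {
  glygly_population(n = 2, radius_um = radius_um, conc_M = conc_M,
                    mix = "mixed", environment = environment_spec(k_w = k_w))
}

# mixed population with reacting chemistry plus an inert tracer species
mixed_reacting_pop <- function(n = 100, radius_um = 30, seed = 1) {
  set.seed(seed)
  chem <- default_chemistry()
  sp <- dplyr::bind_rows(chem$species, species("tracer", 200))
  d <- new_droplets(n, radius_um, species = sp)
  v_l <- (4 / 3) * pi * d$radius_um^3 * 1e-15
  half <- seq_len(n) <= n / 2
  d$monomer[half] <- 0.05 * v_l[half]
  d$tracer[half] <- 0.01 * v_l[half]
  droplet_population(d, sp, chem$reactions)
}

total_volume <- function(pop) sum((4 / 3) * pi * pop$droplets$radius_um^3)

monomer_equiv_mass <- function(pop) {
  mw <- stats::setNames(pop$species$molecular_weight, pop$species$name)
  sum(vapply(pop$species$name,
             function(s) sum(pop$droplets[[s]]) * mw[[s]], numeric(1)))
}

# random admissible generation record for Price-identity fuzzing
random_record <- function(n = 12) {
  w <- stats::rpois(n, 1.2)
  if (all(w == 0)) w[sample.int(n, 1)] <- 1
  z <- stats::rnorm(n, 60, 3)
  parents <- tibble::tibble(id = sprintf("p%03d", seq_len(n)), z_um = z, w = w)
  off <- purrr::map_dfr(seq_len(n), function(i) {
    if (w[i] == 0) return(NULL)
    tibble::tibble(parent_id = parents$id[i],
                   z_um = z[i] + stats::rnorm(w[i], 0, 2))
  })
  list(parents = parents, offspring = off, delta_e = stats::rnorm(1))
}

price_residual_scale <- function(pt) {
  max(abs(pt$w_bar * pt$delta_z_bar), abs(pt$cov_term),
      abs(pt$transmission_term), 1)
}

# polydisperse population for imaging fixtures
imaging_population <- function(n = 50, mean_um = 30, sd_um = 3, seed = 1) {
  set.seed(seed)
  sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
  r <- stats::rnorm(n, mean_um, sd_um)
  r[r < 6] <- 6
  d <- new_droplets(n, r, c(glycylglycine = 0.05), sp)
  droplet_population(d, sp)
}
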