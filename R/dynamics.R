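#' Droplet osmolarity
#'
#' Total concentration of osmotically active solute per droplet,
#' `sum(amount_mol) / volume_L`, with droplet volumes converted from um^3
#' (1 um^3 = 1e-15 L). Osmolarity differences drive water flux between
#' co-incubated droplets: droplets with higher osmotic pressure grow at the
#' expense of their neighbours.
#'
#' @param population A `droplet_population`.
#' @return A tibble with columns `id` and `osmolarity_M` (mol/L).
#' @examples
#' sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
#' d <- new_droplets(2, 30, c(glycylglycine = 0.05), sp)
#' osmolarity(droplet_population(d, sp))
#' @export
osmolarity <- function(population) {
  validate_population(population)
  tibble::tibble(
    id = population$droplets$id,
    osmolarity_M = osmolarity_vec(
      population$droplets$radius_um, amounts_matrix(population),
      population$species
    )
  )
}

osmolarity_vec <- function(radius_um, amounts, sp) {
  if (any(radius_um <= 0)) stop("invalid droplet: non-positive radius", call. = FALSE)
  v_l <- volume_um3(radius_um) / UM3_PER_L
  active <- sp$osmotically_active
  if (!any(active)) return(rep(0, length(radius_um)))
  unname(rowSums(amounts[, active, drop = FALSE])) / v_l
}

#' Osmotic water exchange rates
#'
#' Mean-field law for water flux through the oil phase:
#' `dV_i/dt = k_w * A_i * (Pi_i - Pi_bar)` with `Pi_bar` the area-weighted
#' mean osmolarity over the population. The area weighting makes the fluxes
#' sum exactly to zero, so total dispersed volume is conserved.
#'
#' @param population A `droplet_population`.
#' @return A tibble with columns `id` and `dV_dt_um3_s`.
#' @export
water_exchange_rates <- function(population) {
  validate_population(population)
  r <- population$droplets$radius_um
  rates <- water_rates_vec(r, amounts_matrix(population),
                           population$species, population$environment)
  tibble::tibble(id = population$droplets$id, dV_dt_um3_s = rates)
}

water_rates_vec <- function(radius_um, amounts, sp, env) {
  a <- area_um2(radius_um)
  pi_i <- osmolarity_vec(radius_um, amounts, sp)
  # uniform populations exchange nothing, exactly (null control)
  if (max(pi_i) == min(pi_i)) return(numeric(length(radius_um)))
  pi_bar <- sum(a * pi_i) / sum(a)
  env$k_w * a * (pi_i - pi_bar)
}

#' Molecular-weight-dependent solute exchange rates
#'
#' Exchangeable species relax toward the area-weighted mean concentration of
#' the population with a coefficient inversely proportional to molecular
#' weight: `dn_ik/dt = k_s * (mw_ref / MW_k) * A_i * (cbar_k - c_ik)`, with
#' concentrations in mol/um^3 internally. Non-exchangeable (trapped) species
#' have exactly zero rates. Per species the rates sum to zero, so total
#' amounts are conserved.
#'
#' @param population A `droplet_population`.
#' @return A tibble with columns `id`, `species`, `dn_dt_mol_s`.
#' @export
solute_exchange_rates <- function(population) {
  validate_population(population)
  rates <- solute_rates_mat(population$droplets$radius_um,
                            amounts_matrix(population),
                            population$species, population$environment)
  tibble::tibble(
    id = rep(population$droplets$id, times = nrow(population$species)),
    species = rep(population$species$name, each = nrow(population$droplets)),
    dn_dt_mol_s = as.vector(rates)
  )
}

solute_rates_mat <- function(radius_um, amounts, sp, env) {
  n <- length(radius_um)
  v <- volume_um3(radius_um)
  a <- area_um2(radius_um)
  a_sum <- sum(a)
  out <- matrix(0, n, nrow(sp), dimnames = list(NULL, sp$name))
  for (k in which(sp$exchangeable)) {
    c_k <- amounts[, k] / v # mol/um^3
    if (max(c_k) == min(c_k)) next # uniform: exactly zero flux
    cbar <- sum(a * c_k) / a_sum
    out[, k] <- env$k_s * (env$mw_ref / sp$molecular_weight[k]) * a * (cbar - c_k)
  }
  out
}

#' Per-droplet reaction rates
#'
#' Mass-action kinetics evaluated per droplet:
#' `rate = k * prod(c_s^order_s) * c_catalyst` (mol/L/s), converted to
#' amount rates by the droplet volume in litres. Monomer-equivalent mass is
#' conserved because every reaction is mass balanced.
#'
#' @param population A `droplet_population`.
#' @return A tibble with columns `id`, `species`, `dn_dt_mol_s`.
#' @export
reaction_rates <- function(population) {
  validate_population(population)
  rates <- reaction_rates_mat(population$droplets$radius_um,
                              amounts_matrix(population),
                              population$species, population$reactions)
  tibble::tibble(
    id = rep(population$droplets$id, times = nrow(population$species)),
    species = rep(population$species$name, each = nrow(population$droplets)),
    dn_dt_mol_s = as.vector(rates)
  )
}

reaction_rates_mat <- function(radius_um, amounts, sp, reactions) {
  n <- length(radius_um)
  out <- matrix(0, n, nrow(sp), dimnames = list(NULL, sp$name))
  if (!length(reactions)) return(out)
  v_l <- volume_um3(radius_um) / UM3_PER_L
  conc <- sweep(amounts, 1, v_l, `/`) # mol/L
  for (rx in reactions) {
    validate_reaction(rx, sp)
    rate <- rep(rx$rate_constant, n)
    for (s in names(rx$rate_orders)) {
      rate <- rate * conc[, s]^rx$rate_orders[[s]]
    }
    if (!is.null(rx$catalyst)) rate <- rate * conc[, rx$catalyst]
    net <- reaction_net(rx)
    for (s in names(net)) out[, s] <- out[, s] + net[[s]] * rate * v_l
  }
  out
}

#' Largest stable Euler step for a population
#'
#' Stability bound for the explicit integrator:
#' `dt <= 0.1 * min_i(V_i / (k_w * A_i * Pi_max + eps))`, i.e. no droplet may
#' exchange more than a tenth of its volume per step at the worst-case
#' osmolarity difference.
#'
#' @param population A `droplet_population`.
#' @return Upper bound on `dt` in seconds.
#' @export
stable_dt <- function(population) {
  r <- population$droplets$radius_um
  pi_max <- max(osmolarity_vec(r, amounts_matrix(population),
                               population$species))
  stable_dt_vec(r, pi_max, population$environment$k_w)
}

stable_dt_vec <- function(radius_um, pi_max, k_w) {
  # V / A = r / 3
  0.1 * min(radius_um / 3) / (k_w * pi_max + 1e-30)
}

EXTINCTION_RADIUS_UM <- 0.5

#' Advance a population by one Euler step
#'
#' Operator splitting: reactions are advanced per droplet, then water and
#' solute exchange fluxes are applied, both forward Euler. Amounts are
#' clipped at zero (clipped monomer-equivalent mass is accumulated in the
#' population log), radii are recomputed from volumes, and droplets whose
#' radius falls below the 0.5 um extinction floor are removed and logged.
#'
#' @param population A `droplet_population`.
#' @param dt Time step in seconds; must be positive and below [stable_dt()].
#' @return The advanced `droplet_population`.
#' @export
step_dynamics <- function(population, dt) {
  validate_population(population)
  stopifnot(dt > 0)
  if (dt > stable_dt(population)) {
    stop(sprintf(
      "dt = %g s exceeds the stability bound %g s; reduce dt",
      dt, stable_dt(population)
    ), call. = FALSE)
  }
  st <- kernel_step(
    population$droplets$radius_um, amounts_matrix(population),
    population$species, population$reactions, population$environment, dt
  )
  population <- apply_kernel_state(population, st, dt)
  population
}

# one Euler step on raw state; returns list(r, amt, clipped_g)
kernel_step <- function(r, amt, sp, rx, env, dt) {
  v <- volume_um3(r)
  clipped <- 0
  if (length(rx)) {
    dn <- reaction_rates_mat(r, amt, sp, rx)
    amt <- amt + dn * dt
    if (any(amt < 0)) {
      clipped <- clipped - sum(sweep(pmin(amt, 0), 2, sp$molecular_weight, `*`))
      amt[amt < 0] <- 0
    }
  }
  dn_x <- solute_rates_mat(r, amt, sp, env)
  dv <- water_rates_vec(r, amt, sp, env)
  amt <- amt + dn_x * dt
  if (any(amt < 0)) {
    clipped <- clipped - sum(sweep(pmin(amt, 0), 2, sp$molecular_weight, `*`))
    amt[amt < 0] <- 0
  }
  # recompute radii only where volume changed, so exact fixed points stay exact
  moved <- dv != 0
  if (any(moved)) {
    r[moved] <- radius_from_volume(v[moved] + dv[moved] * dt)
  }
  list(r = r, amt = amt, clipped_g = clipped)
}

apply_kernel_state <- function(population, st, dt) {
  population <- set_state(population, st$r, st$amt)
  population$time <- population$time + dt
  population$log$clipped_mass_g <- population$log$clipped_mass_g + st$clipped_g
  extinct <- which(st$r < EXTINCTION_RADIUS_UM)
  if (length(extinct)) {
    population$log$extinctions <- dplyr::bind_rows(
      population$log$extinctions,
      tibble::tibble(time_s = population$time,
                     droplet_id = population$droplets$id[extinct])
    )
    population$droplets <- population$droplets[-extinct, ]
  }
  population
}

#' Incubate a population and record its trajectory
#'
#' Repeatedly applies [step_dynamics()] for `duration` seconds, sampling the
#' full per-droplet state every `sample_every` seconds. The summary includes
#' the polydispersity ratio s/d (standard deviation of radius over mean
#' radius) at each sample, the readout used to monitor osmosis-driven
#' coarsening.
#'
#' @param population A `droplet_population`.
#' @param duration Total simulated time, s.
#' @param dt Euler step, s (default: half the initial stability bound,
#'   capped at `duration`).
#' @param sample_every Sampling interval, s; `NULL` samples only the start
#'   and end states.
#' @return An object of class `incubation_result`: a list with `population`
#'   (final state), `trajectory` (tibble: time_s, droplet_id, generation,
#'   radius_um, one amount column per species) and `summary` (tibble: time_s,
#'   n_droplets, mean_radius_um, sd_radius_um, s_over_d).
#' @examples
#' sp <- species("glycylglycine", 132.12, exchangeable = FALSE)
#' d <- new_droplets(10, 30, c(glycylglycine = 0.05), sp)
#' d$glycylglycine[6:10] <- 0 # half pure water
#' run <- incubate(droplet_population(d, sp), duration = 1000, dt = 10,
#'                 sample_every = 500)
#' run$summary
#' @export
incubate <- function(population, duration, dt = NULL, sample_every = NULL) {
  validate_population(population)
  stopifnot(duration > 0)
  if (is.null(dt)) dt <- min(0.5 * stable_dt(population), duration)
  if (is.null(sample_every)) sample_every <- duration
  steps_per_sample <- max(1L, as.integer(round(sample_every / dt)))
  n_steps <- as.integer(ceiling(duration / dt))

  # raw-state fast loop; tibbles are only materialised at sample points
  sp <- population$species
  rx <- population$reactions
  env <- population$environment
  r <- population$droplets$radius_um
  amt <- amounts_matrix(population)
  alive <- seq_len(nrow(population$droplets))
  t_now <- population$time
  clipped <- 0
  ext_t <- numeric(0)
  ext_id <- character(0)

  raw_snapshot <- function() {
    d <- population$droplets[alive, ]
    tibble::tibble(
      time_s = t_now, droplet_id = d$id, generation = d$generation,
      radius_um = r
    ) |>
      dplyr::bind_cols(tibble::as_tibble(amt))
  }
  raw_summary <- function() {
    pd <- if (length(r) >= 2) polydispersity(r) else
      tibble::tibble(s_um = NA_real_, d_um = mean(r), s_over_d = NA_real_)
    tibble::tibble(time_s = t_now, n_droplets = length(r),
                   mean_radius_um = pd$d_um, sd_radius_um = pd$s_um,
                   s_over_d = pd$s_over_d)
  }

  samples <- list(raw_snapshot())
  stats_rows <- list(raw_summary())
  step_i <- 0L
  while (step_i < n_steps && length(r) > 0) {
    chunk <- min(steps_per_sample, n_steps - step_i)
    for (j in seq_len(chunk)) {
      pi_max <- max(osmolarity_vec(r, amt, sp))
      if (dt > stable_dt_vec(r, pi_max, env$k_w)) {
        stop(sprintf("dt = %g s exceeds the stability bound during incubation", dt),
             call. = FALSE)
      }
      st <- kernel_step(r, amt, sp, rx, env, dt)
      r <- st$r
      amt <- st$amt
      clipped <- clipped + st$clipped_g
      t_now <- t_now + dt
      extinct <- which(r < EXTINCTION_RADIUS_UM)
      if (length(extinct)) {
        ext_t <- c(ext_t, rep(t_now, length(extinct)))
        ext_id <- c(ext_id, population$droplets$id[alive[extinct]])
        r <- r[-extinct]
        amt <- amt[-extinct, , drop = FALSE]
        alive <- alive[-extinct]
        if (length(r) == 0) break
      }
    }
    step_i <- step_i + chunk
    samples[[length(samples) + 1L]] <- raw_snapshot()
    stats_rows[[length(stats_rows) + 1L]] <- raw_summary()
  }

  population$droplets <- population$droplets[alive, ]
  if (length(r)) population <- set_state(population, r, amt)
  population$time <- t_now
  population$log$clipped_mass_g <- population$log$clipped_mass_g + clipped
  if (length(ext_id)) {
    population$log$extinctions <- dplyr::bind_rows(
      population$log$extinctions,
      tibble::tibble(time_s = ext_t, droplet_id = ext_id)
    )
  }
  structure(
    list(
      population = population,
      trajectory = dplyr::bind_rows(samples),
      summary = dplyr::bind_rows(stats_rows)
    ),
    class = "incubation_result"
  )
}

snapshot_droplets <- function(pop) {
  d <- pop$droplets
  tibble::tibble(
    time_s = pop$time, droplet_id = d$id, generation = d$generation,
    radius_um = d$radius_um
  ) |>
    dplyr::bind_cols(d[, pop$species$name, drop = FALSE])
}

snapshot_summary <- function(pop) {
  r <- pop$droplets$radius_um
  pd <- if (length(r) >= 2) polydispersity(r) else
    tibble::tibble(s_um = NA_real_, d_um = mean(r), s_over_d = NA_real_)
  tibble::tibble(
    time_s = pop$time, n_droplets = length(r),
    mean_radius_um = pd$d_um, sd_radius_um = pd$s_um, s_over_d = pd$s_over_d
  )
}

#' @export
print.incubation_result <- function(x, ...) {
  cat(sprintf(
    "<incubation_result> %d samples over %g s; final n = %d, s/d = %.4g\n",
    nrow(x$summary), max(x$summary$time_s) - min(x$summary$time_s),
    utils::tail(x$summary$n_droplets, 1), utils::tail(x$summary$s_over_d, 1)
  ))
  invisible(x)
}
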