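#' Platform configuration
#'
#' All tunable parameters of the recursive evolution loop. Defaults describe
#' the reference scenario: 100 droplets of 30 um mean radius (2% CV) loaded
#' with 50 mM monomer and the default autocatalytic condensation chemistry,
#' incubated 2e5 s per generation, thresholded at a 60 um diameter, with
#' survivors fused to one fresh feedstock droplet and split once (partition
#' noise SD 0.1) for 10 generations.
#'
#' @param n_droplets Population size per generation (>= 2).
#' @param init_radius_um Mean initial radius, um.
#' @param init_radius_cv Coefficient of variation of the initial radius
#'   (normal law truncated at zero).
#' @param composition List of composition classes, each a list with
#'   `fraction` (of the population) and `concentrations_M` (named vector,
#'   mol/L). Class counts are deterministic (largest-remainder rounding).
#' @param chemistry List with `species` tibble and `reactions` list, e.g.
#'   [default_chemistry()].
#' @param environment Bath parameters, see [environment_spec()].
#' @param incubation_time_s Incubation (growth) phase duration per
#'   generation, s.
#' @param dt_s Euler step, s.
#' @param size_threshold_um Diameter threshold f, um: droplets with
#'   `D >= f` are selected (individual mode).
#' @param selection_mode `"individual"` or `"subpopulation"` (droplets
#'   partitioned into equal-width diameter bins; a bin is kept iff its mean
#'   diameter reaches f).
#' @param subpop_bins Number of bins in subpopulation mode.
#' @param split_fraction Volume fraction of the first child at splitting,
#'   in (0, 1).
#' @param partition_noise_sd SD of the relative partitioning noise applied
#'   to each species at splitting (heritable variation source).
#' @param feedstock_concentrations_M Composition of fresh feedstock droplets
#'   (named vector, mol/L); by default fresh monomer only.
#' @param n_generations Number of generations for [run_recursion()].
#' @param sample_every_s Trajectory sampling interval during incubation.
#' @param seed Integer seed making the whole recursion reproducible.
#' @return A list of class `platform_config`.
#' @export
platform_config <- function(n_droplets = 100,
                            init_radius_um = 30,
                            init_radius_cv = 0.02,
                            composition = list(list(
                              fraction = 1,
                              concentrations_M = c(monomer = 0.05)
                            )),
                            chemistry = default_chemistry(),
                            environment = environment_spec(),
                            incubation_time_s = 2e5,
                            dt_s = 40,
                            size_threshold_um = 60,
                            selection_mode = c("individual", "subpopulation"),
                            subpop_bins = 4,
                            split_fraction = 0.5,
                            partition_noise_sd = 0.1,
                            feedstock_concentrations_M = c(monomer = 0.05),
                            n_generations = 10,
                            sample_every_s = NULL,
                            seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(
    n_droplets >= 2, init_radius_um > 0, init_radius_cv >= 0,
    incubation_time_s > 0, dt_s > 0, size_threshold_um > 0,
    split_fraction > 0, split_fraction < 1, partition_noise_sd >= 0,
    n_generations >= 1, subpop_bins >= 1
  )
  fr <- vapply(composition, function(cl) cl$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("composition class fractions must sum to 1", call. = FALSE)
  }
  referenced <- unique(c(
    unlist(lapply(composition, function(cl) names(cl$concentrations_M))),
    names(feedstock_concentrations_M)
  ))
  undefined <- setdiff(referenced, chemistry$species$name)
  if (length(undefined)) {
    stop("composition/feedstock reference undefined species: ",
         paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      n_droplets = as.integer(n_droplets), init_radius_um = init_radius_um,
      init_radius_cv = init_radius_cv, composition = composition,
      chemistry = chemistry, environment = environment,
      incubation_time_s = incubation_time_s, dt_s = dt_s,
      size_threshold_um = size_threshold_um, selection_mode = selection_mode,
      subpop_bins = as.integer(subpop_bins), split_fraction = split_fraction,
      partition_noise_sd = partition_noise_sd,
      feedstock_concentrations_M = feedstock_concentrations_M,
      n_generations = as.integer(n_generations),
      sample_every_s = sample_every_s, seed = as.integer(seed)
    ),
    class = "platform_config"
  )
}

draw_radii <- function(n, mean_um, cv) {
  if (cv == 0) return(rep(mean_um, n))
  r <- stats::rnorm(n, mean_um, cv * mean_um)
  while (any(r <= 0)) {
    bad <- r <= 0
    r[bad] <- stats::rnorm(sum(bad), mean_um, cv * mean_um)
  }
  r
}

#' Generate a droplet population from a platform configuration
#'
#' Radii are drawn from a truncated normal law (mean `init_radius_um`, CV
#' `init_radius_cv`); compositions follow the configured composition classes
#' with deterministic class counts. Draws come from R's global RNG stream,
#' so a fixed seed yields identical populations.
#'
#' @param config A `platform_config`.
#' @param n Number of droplets (default `config$n_droplets`).
#' @param generation Generation index stored on the droplets.
#' @param id_prefix Prefix for droplet ids.
#' @return A `droplet_population`.
#' @export
generate_droplets <- function(config, n = config$n_droplets,
                              generation = 0L,
                              id_prefix = sprintf("g%d-", generation)) {
  stopifnot(n >= 1)
  r <- draw_radii(n, config$init_radius_um, config$init_radius_cv)
  sp <- config$chemistry$species
  d <- tibble::tibble(
    id = sprintf("%s%04d", id_prefix, seq_len(n)),
    radius_um = r,
    generation = as.integer(generation),
    parent_ids = rep(list(character(0)), n)
  )
  for (s in sp$name) d[[s]] <- 0
  fr <- vapply(config$composition, function(cl) cl$fraction, numeric(1))
  counts <- diff(c(0L, round(cumsum(fr) * n)))
  v_l <- volume_um3(r) / UM3_PER_L
  idx_end <- cumsum(counts)
  idx_start <- c(1L, utils::head(idx_end, -1) + 1L)
  for (k in seq_along(config$composition)) {
    if (counts[k] == 0) next
    rows <- idx_start[k]:idx_end[k]
    conc <- config$composition[[k]]$concentrations_M
    for (s in names(conc)) d[[s]][rows] <- conc[[s]] * v_l[rows]
  }
  droplet_population(d, sp, config$chemistry$reactions, config$environment)
}

#' Size-threshold selection
#'
#' Partitions a population by the diameter threshold f. In individual mode a
#' droplet is kept iff its diameter `D = 2 r` is at least f (ties kept). In
#' subpopulation mode droplets are first grouped into `bins` equal-width
#' diameter bins (emulating passive fractionation into sub-populations) and
#' a whole bin is kept iff its mean diameter is at least f.
#'
#' @param population A `droplet_population` (non-empty).
#' @param f Diameter threshold, um.
#' @param mode `"individual"` or `"subpopulation"`.
#' @param bins Number of bins in subpopulation mode.
#' @return A list with `selected` and `discarded` `droplet_population`
#'   objects (either may be empty); their droplet tables partition the
#'   input.
#' @export
sort_by_size <- function(population, f,
                         mode = c("individual", "subpopulation"), bins = 4) {
  mode <- match.arg(mode)
  validate_population(population)
  d <- 2 * population$droplets$radius_um
  keep <- if (mode == "individual") {
    d >= f
  } else {
    rng <- range(d)
    if (diff(rng) == 0) {
      rep(d[1] >= f, length(d))
    } else {
      bin <- cut(d, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                 include.lowest = TRUE, labels = FALSE)
      bin_mean <- tapply(d, bin, mean)
      as.vector(bin_mean[as.character(bin)] >= f)
    }
  }
  list(
    selected = subset_population(population, keep),
    discarded = subset_population(population, !keep)
  )
}

subset_population <- function(pop, keep) {
  pop$droplets <- pop$droplets[keep, ]
  pop
}

#' Fuse two droplets
#'
#' Volume and every species amount are strictly additive; the fused radius
#' is the cube root of the summed cubes. The lineage records both parents.
#'
#' @param a,b One-row droplet tibbles (as in `droplets(pop)`).
#' @param species Species tibble (names of the amount columns).
#' @param id Id for the fused droplet.
#' @return A one-row droplet tibble.
#' @export
fuse_droplets <- function(a, b, species, id = paste0(a$id, "+", b$id)) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  out <- a
  out$id <- id
  out$radius_um <- (a$radius_um^3 + b$radius_um^3)^(1 / 3)
  out$parent_ids <- list(c(a$id, b$id))
  for (s in species$name) out[[s]] <- a[[s]] + b[[s]]
  out
}

#' Split a droplet in two
#'
#' The first child receives exactly the volume fraction `fraction`; each
#' species is partitioned with fraction `fraction * (1 + eta)`,
#' `eta ~ N(0, noise_sd)`, clamped so both children receive a non-negative
#' amount. Totals are conserved exactly. Children inherit the parent's
#' lineage and `generation + 1`.
#'
#' @param droplet One-row droplet tibble.
#' @param species Species tibble.
#' @param fraction Volume fraction of the first child, in (0, 1).
#' @param noise_sd SD of the relative partitioning noise.
#' @param ids Character vector of two child ids.
#' @return A two-row droplet tibble.
#' @export
split_droplet <- function(droplet, species, fraction = 0.5, noise_sd = 0,
                          ids = paste0(droplet$id, c(".1", ".2"))) {
  stopifnot(nrow(droplet) == 1, fraction > 0, fraction < 1)
  v <- volume_um3(droplet$radius_um)
  out <- droplet[c(1, 1), ]
  out$id <- ids
  out$radius_um <- radius_from_volume(c(fraction, 1 - fraction) * v)
  out$generation <- droplet$generation + 1L
  out$parent_ids <- rep(list(droplet$id), 2)
  for (s in species$name) {
    eta <- if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
    phi <- min(max(fraction * (1 + eta), 0), 1)
    total <- droplet[[s]]
    out[[s]] <- c(phi * total, total - phi * total)
  }
  out
}

#' Run one generation of the evolution loop
#'
#' Pipeline: incubate -> record end-of-incubation diameters `z_i` ->
#' size-threshold selection -> each survivor fused with one fresh feedstock
#' droplet -> each fused droplet split once (two offspring) -> offspring
#' pooled and uniformly subsampled / topped up with fresh droplets to
#' restore the population size. Fitness `w_i` is the number of a parent's
#' offspring present in the returned population (0 for discarded droplets).
#' The environment scalar is advanced by `delta_e`.
#'
#' If no droplet passes the threshold the next generation starts from fresh
#' feedstock only, with a warning; the population never empties.
#'
#' @param population A `droplet_population`.
#' @param config A `platform_config`.
#' @param generation Index of the generation being run (offspring carry
#'   `generation + 1`).
#' @return A list with `population` (next generation) and `record`
#'   (a `generation_record`: `generation`, `parents` tibble (`id`, `z_um`,
#'   `w`), `offspring` tibble (`id`, `parent_id`, `z_um`), `delta_e`,
#'   `population_size`, `n_survivors`, `n_fresh`).
#' @export
run_generation <- function(population, config, generation = 0L) {
  inc <- incubate(population, config$incubation_time_s, dt = config$dt_s)
  endpop <- inc$population
  if (nrow(endpop$droplets) == 0) {
    stop("population went extinct during incubation", call. = FALSE)
  }
  parents <- tibble::tibble(
    id = endpop$droplets$id,
    z_um = 2 * endpop$droplets$radius_um,
    w = 0
  )
  srt <- sort_by_size(endpop, config$size_threshold_um,
                      mode = config$selection_mode, bins = config$subpop_bins)
  surv <- srt$selected$droplets
  sp <- config$chemistry$species
  n_surv <- nrow(surv)
  offspring <- NULL
  if (n_surv > 0) {
    feed <- generate_droplets(config, n = n_surv,
                              generation = surv$generation[1],
                              id_prefix = sprintf("f%d-", generation + 1L))
    kids <- vector("list", n_surv)
    for (i in seq_len(n_surv)) {
      fused <- fuse_droplets(surv[i, ], feed$droplets[i, ], sp,
                             id = sprintf("fz%d-%04d", generation + 1L, i))
      kids[[i]] <- split_droplet(
        fused, sp, fraction = config$split_fraction,
        noise_sd = config$partition_noise_sd,
        ids = sprintf("g%d-%04d", generation + 1L, 2 * i - c(1L, 0L))
      )
      # Price bookkeeping: the surviving incubated droplet is the parent
      kids[[i]]$price_parent <- surv$id[i]
    }
    offspring <- dplyr::bind_rows(kids)
  } else {
    warning("no droplets passed the size threshold; continuing from fresh feedstock",
            call. = FALSE)
  }
  n_target <- config$n_droplets
  if (!is.null(offspring) && nrow(offspring) > n_target) {
    offspring <- offspring[sort(sample.int(nrow(offspring), n_target)), ]
  }
  n_fresh <- n_target - if (is.null(offspring)) 0L else nrow(offspring)
  if (n_fresh > 0) {
    fresh <- generate_droplets(config, n = n_fresh,
                               generation = generation + 1L,
                               id_prefix = sprintf("n%d-", generation + 1L))
    fresh_d <- fresh$droplets
    fresh_d$price_parent <- NA_character_
    offspring <- dplyr::bind_rows(offspring, fresh_d)
  }
  w_counts <- table(offspring$price_parent[!is.na(offspring$price_parent)])
  parents$w <- as.numeric(w_counts[parents$id])
  parents$w[is.na(parents$w)] <- 0
  off_tbl <- tibble::tibble(
    id = offspring$id,
    parent_id = offspring$price_parent,
    z_um = 2 * offspring$radius_um
  )[!is.na(offspring$price_parent), ]
  offspring$price_parent <- NULL
  next_pop <- droplet_population(
    offspring, sp, config$chemistry$reactions, endpop$environment,
    time = endpop$time
  )
  next_pop$environment$e_state <-
    next_pop$environment$e_state + next_pop$environment$delta_e
  next_pop$log <- endpop$log
  record <- structure(
    list(
      generation = generation, parents = parents, offspring = off_tbl,
      delta_e = config$environment$delta_e,
      population_size = nrow(next_pop$droplets),
      n_survivors = n_surv, n_fresh = n_fresh,
      s_over_d = if (nrow(parents) >= 2) polydispersity(parents$z_um / 2)$s_over_d
                 else NA_real_
    ),
    class = "generation_record"
  )
  list(population = next_pop, record = record)
}

#' Run the full multi-generation recursion
#'
#' Seeds the RNG from `config$seed`, generates the founding population and
#' iterates [run_generation()] for `config$n_generations` generations,
#' scoring each with the Price decomposition and the polydispersity of the
#' end-of-incubation radii. Fully reproducible: identical seeds give
#' identical outputs.
#'
#' @param config A `platform_config`.
#' @return An object of class `evolution_run`: a list with `records`
#'   (list of `generation_record`), `summary` (one tibble row per
#'   generation: generation, n_parents, n_survivors, n_fresh, z_bar_um,
#'   w_bar, delta_z_bar, cov_term, transmission_term, delta_e, s_over_d,
#'   identity_residual), `droplets` (per-generation parent table),
#'   `lineage` (child id -> parent ids) and `config`.
#' @examples
#' \donttest{
#' cfg <- platform_config(n_droplets = 20, n_generations = 3,
#'                        incubation_time_s = 2000, seed = 7)
#' run <- run_recursion(cfg)
#' tidy(run)
#' }
#' @export
run_recursion <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  set.seed(config$seed)
  pop <- generate_droplets(config)
  records <- vector("list", config$n_generations)
  rows <- vector("list", config$n_generations)
  parent_tables <- vector("list", config$n_generations)
  lineage <- list()
  for (g in seq_len(config$n_generations)) {
    res <- run_generation(pop, config, generation = g - 1L)
    rec <- res$record
    records[[g]] <- rec
    pop <- res$population
    pt <- tryCatch(tidy(price_decomposition(rec)), error = function(e) {
      tibble::tibble(w_bar = NA_real_, delta_z_bar = NA_real_,
                     cov_term = NA_real_, transmission_term = NA_real_,
                     identity_residual = NA_real_)
    })
    rows[[g]] <- tibble::tibble(
      generation = g - 1L,
      n_parents = nrow(rec$parents),
      n_survivors = rec$n_survivors,
      n_fresh = rec$n_fresh,
      z_bar_um = mean(rec$parents$z_um),
      w_bar = pt$w_bar,
      delta_z_bar = pt$delta_z_bar,
      cov_term = pt$cov_term,
      transmission_term = pt$transmission_term,
      delta_e = rec$delta_e,
      s_over_d = rec$s_over_d,
      identity_residual = pt$identity_residual
    )
    parent_tables[[g]] <- dplyr::mutate(rec$parents, generation = g - 1L,
                                        .before = 1)
    lineage[[g]] <- tibble::tibble(
      child_id = pop$droplets$id,
      parent_ids = vapply(pop$droplets$parent_ids,
                          function(p) paste(p, collapse = ";"), character(1)),
      generation = g
    )
  }
  structure(
    list(
      records = records,
      summary = dplyr::bind_rows(rows),
      droplets = dplyr::bind_rows(parent_tables),
      lineage = dplyr::bind_rows(lineage),
      config = config
    ),
    class = "evolution_run"
  )
}

#' @export
print.evolution_run <- function(x, ...) {
  cat(sprintf("<evolution_run> %d generations x %d droplets (seed %d)\n",
              nrow(x$summary), x$config$n_droplets, x$config$seed))
  print(x$summary, n = 10)
  invisible(x)
}

#' @rdname run_recursion
#' @param x An `evolution_run`.
#' @param ... Unused.
#' @method tidy evolution_run
#' @export
tidy.evolution_run <- function(x, ...) x$summary

#' @rdname run_recursion
#' @method glance evolution_run
#' @export
glance.evolution_run <- function(x, ...) {
  z <- x$summary$z_bar_um
  tr <- if (length(z) >= 3) evolution_trend(z) else
    tibble::tibble(direction = NA_real_, frac_increases = NA_real_,
                   kendall_tau = NA_real_, evolving = NA)
  tibble::tibble(
    n_generations = nrow(x$summary),
    z_bar_first_um = z[1],
    z_bar_final_um = z[length(z)],
    kendall_tau = tr$kendall_tau,
    frac_increases = tr$frac_increases,
    evolving = tr$evolving
  )
}
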