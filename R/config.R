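#' Load a run configuration from YAML
#'
#' Reads a structured scenario description (species, reactions, platform
#' parameters, environment, sampling, imaging and metrics blocks) and
#' returns a fully validated configuration with every default filled in.
#' Unknown keys are an error (typo safety), and every species referenced by
#' a reaction, composition class or the feedstock must be defined in the
#' `species` block.
#'
#' A minimal config needs only `scenario` and `seed`; everything else
#' defaults to the reference autocatalytic scenario of [platform_config()].
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: list with `scenario`, `seed`,
#'   `output_dir`, `platform` (a [platform_config()]), `sampling`,
#'   `imaging`, `metrics` and `config_hash`.
#' @seealso [save_config()] for the (lossless) inverse.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

TOP_KEYS <- c("scenario", "seed", "output_dir", "environment", "species",
              "reactions", "platform", "sampling", "imaging", "metrics")
PLATFORM_KEYS <- c("n_droplets", "init_radius_um", "init_radius_cv",
                   "composition", "incubation_time_s", "dt_s",
                   "size_threshold_um", "selection_mode", "subpop_bins",
                   "split_fraction", "partition_noise_sd",
                   "feedstock_concentrations_M", "n_generations")

check_keys <- function(block, allowed, path) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s) at %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

build_run_config <- function(raw) {
  check_keys(raw, TOP_KEYS, "<top level>")
  if (is.null(raw$scenario)) stop("config must name a scenario", call. = FALSE)
  if (is.null(raw$seed)) stop("config must set a seed", call. = FALSE)

  env_block <- raw$environment %||% list()
  check_keys(env_block, c("k_w", "k_s", "mw_ref", "e_state", "delta_e"),
             "environment")
  env <- do.call(environment_spec, env_block)

  chem <- if (is.null(raw$species)) {
    default_chemistry()
  } else {
    sp <- purrr::map_dfr(raw$species, function(s) {
      check_keys(s, c("name", "molecular_weight", "exchangeable",
                      "osmotically_active"), paste0("species/", s$name %||% "?"))
      tibble::tibble(
        name = s$name, molecular_weight = s$molecular_weight,
        exchangeable = s$exchangeable %||% TRUE,
        osmotically_active = s$osmotically_active %||% TRUE
      )
    })
    validate_species(sp)
    rx <- purrr::map(raw$reactions %||% list(), function(r) {
      check_keys(r, c("reactants", "products", "rate_constant", "catalyst",
                      "rate_orders"), "reactions/<entry>")
      out <- reaction(unlist(r$reactants), unlist(r$products),
                      r$rate_constant, catalyst = r$catalyst,
                      rate_orders = if (length(r$rate_orders)) unlist(r$rate_orders))
      validate_reaction(out, sp)
      out
    })
    list(species = sp, reactions = rx)
  }

  pl <- raw$platform %||% list()
  check_keys(pl, PLATFORM_KEYS, "platform")
  if (!is.null(pl$composition)) {
    pl$composition <- purrr::map(pl$composition, function(cl) {
      check_keys(cl, c("fraction", "concentrations_M"), "platform/composition")
      conc <- unlist(cl$concentrations_M)
      if (is.null(conc)) conc <- stats::setNames(numeric(0), character(0))
      undefined <- setdiff(names(conc), chem$species$name)
      if (length(undefined)) {
        stop("composition references undefined species: ",
             paste(undefined, collapse = ", "), call. = FALSE)
      }
      list(fraction = cl$fraction, concentrations_M = conc)
    })
  }
  if (!is.null(pl$feedstock_concentrations_M)) {
    pl$feedstock_concentrations_M <- unlist(pl$feedstock_concentrations_M)
    undefined <- setdiff(names(pl$feedstock_concentrations_M), chem$species$name)
    if (length(undefined)) {
      stop("feedstock references undefined species: ",
           paste(undefined, collapse = ", "), call. = FALSE)
    }
  }
  platform <- do.call(platform_config, c(
    pl, list(chemistry = chem, environment = env, seed = raw$seed)
  ))

  sampling <- raw$sampling %||% list()
  check_keys(sampling, "sample_every_s", "sampling")
  sampling$sample_every_s <- sampling$sample_every_s %||%
    (platform$incubation_time_s / 20)

  imaging <- raw$imaging %||% list()
  check_keys(imaging, c("scale_um_per_px", "frame_size_px", "noise_sd",
                        "render_every_s"), "imaging")
  imaging <- list(
    scale_um_per_px = imaging$scale_um_per_px %||% 1,
    frame_size_px = imaging$frame_size_px %||% 512,
    noise_sd = imaging$noise_sd %||% 8,
    render_every_s = imaging$render_every_s %||%
      (platform$incubation_time_s / 4)
  )

  metrics <- raw$metrics %||% list()
  check_keys(metrics, c("sd_convention", "trend_cutoff"), "metrics")
  metrics <- list(
    sd_convention = metrics$sd_convention %||% "sample",
    trend_cutoff = metrics$trend_cutoff %||% 0.6
  )
  stopifnot(metrics$sd_convention %in% c("sample", "population"))

  cfg <- structure(
    list(
      scenario = raw$scenario,
      seed = as.integer(raw$seed),
      output_dir = raw$output_dir %||% "dropevolve-out",
      platform = platform,
      sampling = sampling,
      imaging = imaging,
      metrics = metrics
    ),
    class = "run_config"
  )
  cfg$config_hash <- rlang::hash(cfg[setdiff(names(cfg), "config_hash")])
  cfg
}

#' Save a run configuration as YAML
#'
#' Writes the fully normalised configuration (all defaults explicit) so
#' that `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- config$platform
  chem <- p$chemistry
  raw <- list(
    scenario = config$scenario,
    seed = config$seed,
    output_dir = config$output_dir,
    environment = unclass(p$environment),
    species = purrr::pmap(chem$species, function(name, molecular_weight,
                                                 exchangeable,
                                                 osmotically_active) {
      list(name = name, molecular_weight = molecular_weight,
           exchangeable = exchangeable,
           osmotically_active = osmotically_active)
    }),
    reactions = purrr::map(chem$reactions, function(r) {
      out <- list(reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  rate_constant = r$rate_constant,
                  rate_orders = as.list(r$rate_orders))
      if (!is.null(r$catalyst)) out$catalyst <- r$catalyst
      out
    }),
    platform = list(
      n_droplets = p$n_droplets, init_radius_um = p$init_radius_um,
      init_radius_cv = p$init_radius_cv,
      composition = purrr::map(p$composition, function(cl) {
        list(fraction = cl$fraction,
             concentrations_M = as.list(cl$concentrations_M))
      }),
      incubation_time_s = p$incubation_time_s, dt_s = p$dt_s,
      size_threshold_um = p$size_threshold_um,
      selection_mode = p$selection_mode, subpop_bins = p$subpop_bins,
      split_fraction = p$split_fraction,
      partition_noise_sd = p$partition_noise_sd,
      feedstock_concentrations_M = as.list(p$feedstock_concentrations_M),
      n_generations = p$n_generations
    ),
    sampling = config$sampling,
    imaging = config$imaging,
    metrics = config$metrics
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> scenario '%s' (seed %d, hash %s)\n  %d droplets x %d generations, f = %g um, mode %s\n",
    x$scenario, x$seed, x$config_hash, x$platform$n_droplets,
    x$platform$n_generations, x$platform$size_threshold_um,
    x$platform$selection_mode
  ))
  invisible(x)
}
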