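#' Write a tibble as CSV with a provenance header
#'
#' Every tabular artifact carries comment lines recording the seed and the
#' config hash so any run can be re-identified and reproduced. Read such
#' files back with [read_run_csv()].
#'
#' @param df A data frame.
#' @param path Output path.
#' @param seed Integer seed used for the run.
#' @param config_hash Hash of the run configuration (see [load_config()]).
#' @return Invisibly, `path`.
#' @export
write_run_csv <- function(df, path, seed = NA_integer_,
                          config_hash = NA_character_) {
  con <- file(path, "w")
  writeLines(c(
    sprintf("# dropevolve %s", as.character(utils::packageVersion("dropevolve"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash)
  ), con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
read_run_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Export an incubation result
#'
#' Writes `trajectory.csv` (per-droplet, per-sample state: time_s,
#' droplet_id, generation, radius_um, one amount column per species) and
#' `summary.csv` (per-sample population statistics including s/d).
#'
#' @param result An `incubation_result` from [incubate()].
#' @param dir Output directory (created if needed).
#' @param seed,config_hash Provenance recorded in the file headers.
#' @return Invisibly, the paths written.
#' @export
export_incubation <- function(result, dir, seed = NA_integer_,
                              config_hash = NA_character_) {
  stopifnot(inherits(result, "incubation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    trajectory = file.path(dir, "trajectory.csv"),
    summary = file.path(dir, "summary.csv")
  )
  traj <- result$trajectory
  traj$parent_ids <- NULL
  write_run_csv(traj, paths[["trajectory"]], seed, config_hash)
  write_run_csv(result$summary, paths[["summary"]], seed, config_hash)
  invisible(paths)
}

#' Export an evolution run
#'
#' Writes `generations.csv` (one row per generation: Price terms, mean
#' trait, polydispersity), `droplets.csv` (one row per droplet per
#' generation: trait z and realised fitness w) and `lineage.csv`
#' (child id -> parent ids).
#'
#' @param run An `evolution_run` from [run_recursion()].
#' @param dir Output directory (created if needed).
#' @param config_hash Provenance recorded in the file headers (the seed
#'   comes from the run's own config).
#' @return Invisibly, the paths written.
#' @export
export_run <- function(run, dir, config_hash = NA_character_) {
  stopifnot(inherits(run, "evolution_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- run$config$seed
  paths <- c(
    generations = file.path(dir, "generations.csv"),
    droplets = file.path(dir, "droplets.csv"),
    lineage = file.path(dir, "lineage.csv")
  )
  write_run_csv(run$summary, paths[["generations"]], seed, config_hash)
  write_run_csv(run$droplets, paths[["droplets"]], seed, config_hash)
  write_run_csv(run$lineage, paths[["lineage"]], seed, config_hash)
  invisible(paths)
}
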