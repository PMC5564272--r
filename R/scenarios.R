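#' The glycylglycine / pure-water co-incubation scenario
#'
#' Builds the model system for osmosis-driven coarsening: a monodisperse
#' population in which half the droplets carry 50 mM glycylglycine and half
#' are pure water ("mixed"), or an unmixed control containing only one
#' class. The dipeptide is treated as non-exchangeable on the emulated
#' timescale (water permeates the oil phase orders of magnitude faster than
#' the solute), so the glycylglycine droplets keep their osmotic advantage
#' and grow at the expense of their water neighbours, while unmixed
#' controls show no exchange at all.
#'
#' @param n Number of droplets.
#' @param radius_um Initial radius (um); all droplets identical
#'   (monodisperse) unless `cv > 0`.
#' @param conc_M Glycylglycine concentration in the loaded class, mol/L
#'   (default 0.05 = 50 mM).
#' @param mix `"mixed"` (half and half), `"glycylglycine"` (unmixed, all
#'   loaded) or `"water"` (unmixed, all pure water).
#' @param cv Coefficient of variation of the initial radii; draws come from
#'   R's global RNG stream when `cv > 0`.
#' @param environment Bath parameters.
#' @return A `droplet_population` (no reactions).
#' @examples
#' pop <- glygly_population(n = 20)
#' osmolarity(pop)
#' @export
glygly_population <- function(n = 100, radius_um = 30, conc_M = 0.05,
                              mix = c("mixed", "glycylglycine", "water"),
                              cv = 0, environment = environment_spec()) {
  mix <- match.arg(mix)
  sp <- species("glycylglycine", 132.12, exchangeable = FALSE,
                osmotically_active = TRUE)
  r <- draw_radii(n, radius_um, cv)
  d <- tibble::tibble(
    id = sprintf("d%04d", seq_len(n)),
    radius_um = r,
    generation = 0L,
    parent_ids = rep(list(character(0)), n),
    glycylglycine = 0
  )
  loaded <- switch(mix,
    mixed = seq_len(n) <= n / 2,
    glycylglycine = rep(TRUE, n),
    water = rep(FALSE, n)
  )
  d$glycylglycine[loaded] <- conc_M * volume_um3(r[loaded]) / UM3_PER_L
  droplet_population(d, sp, environment = environment)
}

#' Which class a droplet of the glycylglycine scenario belongs to
#'
#' Classifies droplets of a [glygly_population()] trajectory by whether they
#' started with solute, using the initial amounts in the trajectory.
#'
#' @param trajectory The `trajectory` tibble of an [incubate()] result on a
#'   glycylglycine population.
#' @return The trajectory with an added `class` column
#'   (`"glycylglycine"`/`"water"`).
#' @export
label_glygly_classes <- function(trajectory) {
  t0 <- min(trajectory$time_s)
  init <- trajectory[trajectory$time_s == t0, ]
  loaded <- init$droplet_id[init$glycylglycine > 0]
  dplyr::mutate(trajectory,
                class = ifelse(.data$droplet_id %in% loaded,
                               "glycylglycine", "water"))
}
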