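#' Polydispersity of a droplet population
#'
#' The coarsening readout: `s` = standard deviation of droplet radius
#' (sample convention, n-1 denominator, configurable), `d` = mean radius,
#' and their ratio s/d. A monodisperse population has s/d = 0; osmotic
#' coarsening of a mixed population drives s/d upward over time.
#'
#' @param radii_um Numeric vector of radii (um), length >= 2, all positive.
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"` (n).
#' @return A one-row tibble with columns `s_um`, `d_um`, `s_over_d`.
#' @examples
#' polydispersity(c(3, 4, 5)) # s = 1, d = 4, s/d = 0.25
#' @export
polydispersity <- function(radii_um, sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (length(radii_um) < 2) {
    stop("polydispersity needs at least 2 radii", call. = FALSE)
  }
  if (any(!is.finite(radii_um)) || any(radii_um <= 0)) {
    stop("radii must be positive and finite", call. = FALSE)
  }
  s <- stats::sd(radii_um)
  if (sd_convention == "population") {
    s <- s * sqrt((length(radii_um) - 1) / length(radii_um))
  }
  d <- mean(radii_um)
  tibble::tibble(s_um = s, d_um = d, s_over_d = s / d)
}

#' Price decomposition of one generation of trait change
#'
#' Splits the between-generation change in mean trait into a selection term
#' and a transmission term via the Price identity
#' `w_bar * delta_z_bar = Cov(w, z) + E(w * delta_z)`,
#' where `w_i` is realised fitness (offspring count), `z_i` the parent
#' trait, `delta_z_i` the mean offspring trait minus the parent trait
#' (defined only for parents with offspring; its fitness-weighted term is
#' zero otherwise), and all moments are population moments (divide by n) so
#' that the identity holds exactly. The environment change `delta_e`
#' attributed to the generation is reported alongside the transmission term
#' as an annotation; it does not enter the algebra.
#'
#' @param record A `generation_record` from [run_generation()], or any list
#'   with `parents` (tibble: `id`, `z_um`, `w`), `offspring` (tibble:
#'   `parent_id`, `z_um`) and optionally `delta_e`.
#' @return An object of class `price_terms` with fields `w_bar`,
#'   `z_bar_parent`, `z_bar_offspring`, `delta_z_bar`, `cov_term`,
#'   `transmission_term`, `delta_e`, `identity_residual`, `n_parents`.
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' rec <- list(
#'   parents = tibble::tibble(id = letters[1:4], z_um = c(1, 2, 3, 2),
#'                            w = c(0, 1, 2, 1)),
#'   offspring = tibble::tibble(parent_id = c("b", "c", "c", "d"),
#'                              z_um = c(2, 3, 3, 2)),
#'   delta_e = 0
#' )
#' tidy(price_decomposition(rec)) # cov_term 0.5, delta_z_bar 0.5
#' @export
price_decomposition <- function(record) {
  p <- tibble::as_tibble(record$parents)
  o <- tibble::as_tibble(record$offspring)
  stopifnot(all(c("id", "z_um", "w") %in% names(p)),
            all(c("parent_id", "z_um") %in% names(o)))
  if (any(p$w < 0)) stop("fitness must be non-negative", call. = FALSE)
  if (all(p$w == 0)) {
    stop("price decomposition undefined: all fitnesses are zero", call. = FALSE)
  }
  n <- nrow(p)
  w <- p$w
  z <- p$z_um
  w_bar <- mean(w)
  z_bar <- mean(z)
  # mean offspring trait per parent (NA for parents without offspring)
  off_mean <- tapply(o$z_um, factor(o$parent_id, levels = p$id), mean)
  dz <- as.numeric(off_mean) - z
  wdz <- ifelse(w > 0 & !is.na(dz), w * dz, 0)
  # centered population covariance: exactly zero under uniform fitness
  cov_term <- mean((w - w_bar) * (z - z_bar))
  transmission_term <- mean(wdz)
  z_bar_off <- sum(ifelse(w > 0 & !is.na(off_mean), w * as.numeric(off_mean), 0)) / sum(w)
  delta_z_bar <- z_bar_off - z_bar
  residual <- w_bar * delta_z_bar - cov_term - transmission_term
  structure(
    list(
      w_bar = w_bar, z_bar_parent = z_bar, z_bar_offspring = z_bar_off,
      delta_z_bar = delta_z_bar, cov_term = cov_term,
      transmission_term = transmission_term,
      delta_e = record$delta_e %||% 0,
      identity_residual = residual, n_parents = n
    ),
    class = "price_terms"
  )
}

#' @export
print.price_terms <- function(x, ...) {
  cat(sprintf(
    paste0("<price_terms> n = %d parents\n",
           "  w_bar = %.4g, delta_z_bar = %.4g\n",
           "  selection Cov(w,z) = %.4g, transmission E(w dz) = %.4g",
           " (delta_e = %g)\n  identity residual = %.3g\n"),
    x$n_parents, x$w_bar, x$delta_z_bar, x$cov_term, x$transmission_term,
    x$delta_e, x$identity_residual
  ))
  invisible(x)
}

#' @rdname price_decomposition
#' @param x A `price_terms` object.
#' @param ... Unused.
#' @method tidy price_terms
#' @export
tidy.price_terms <- function(x, ...) {
  tibble::tibble(
    n_parents = x$n_parents, w_bar = x$w_bar,
    z_bar_parent = x$z_bar_parent, z_bar_offspring = x$z_bar_offspring,
    delta_z_bar = x$delta_z_bar, cov_term = x$cov_term,
    transmission_term = x$transmission_term, delta_e = x$delta_e,
    identity_residual = x$identity_residual
  )
}

#' Trend test for a per-generation trait series
#'
#' Evolution in the platform is confirmed by a successive change in the
#' trait across generations. The test reports the fraction of successive
#' strict increases and a Kendall rank correlation between generation index
#' and the series, and flags the series as "evolving" when the correlation
#' is positive and the fraction reaches the cutoff.
#'
#' @param x Numeric series (one value per generation), length >= 3.
#' @param cutoff Minimum fraction of successive strict increases required to
#'   flag evolution (default 0.6).
#' @return A one-row tibble: `direction` (-1/0/1), `frac_increases`,
#'   `kendall_tau`, `evolving`.
#' @examples
#' evolution_trend(c(1, 3, 2, 4, 5)) # frac 0.75, positive tau
#' @export
evolution_trend <- function(x, cutoff = 0.6) {
  if (length(x) < 3) stop("trend test needs at least 3 generations", call. = FALSE)
  d <- diff(x)
  frac <- mean(d > 0)
  tau <- suppressWarnings(
    stats::cor(seq_along(x), x, method = "kendall")
  )
  if (is.na(tau)) tau <- 0 # constant series
  tibble::tibble(
    direction = sign(tau),
    frac_increases = frac,
    kendall_tau = tau,
    evolving = tau > 0 && frac >= cutoff
  )
}
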