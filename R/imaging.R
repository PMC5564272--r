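#' Render a synthetic micrograph of a droplet monolayer
#'
#' Draws each droplet as a dark interface ring with a slightly brighter
#' interior on a mid-grey background, the contrast convention of brightfield
#' droplet micrographs, plus additive Gaussian pixel noise clipped to the
#' 8-bit range. Droplets are placed by seeded greedy dart-throwing so that
#' no two circles overlap and every circle lies fully inside the frame; the
#' ground-truth geometry is stored with the frame.
#'
#' @param population A `droplet_population` (may be empty).
#' @param scale_um_per_px Microns per pixel.
#' @param frame_size_px Frame side length in pixels (square frame).
#' @param noise_sd Gaussian noise SD in 8-bit intensity units.
#' @param ring_width_px Width of the dark interface ring, px.
#' @param gap_px Minimum gap enforced between circles, px.
#' @param max_attempts Dart-throwing attempts per droplet before giving up.
#' @return An object of class `synthetic_frame`: list with `pixels`
#'   (integer matrix, first index x, second y, values 0-255), `scale_um_per_px`,
#'   `ground_truth` (tibble: droplet_id, x_px, y_px, radius_px, border),
#'   `time_s`.
#' @export
render_frame <- function(population, scale_um_per_px = 1, frame_size_px = 512,
                         noise_sd = 0, ring_width_px = 3, gap_px = 4,
                         max_attempts = 2000) {
  stopifnot(scale_um_per_px > 0, frame_size_px >= 16)
  d <- population$droplets
  r_px <- d$radius_um / scale_um_per_px
  if (any(r_px <= 2) && nrow(d) > 0) {
    stop("droplet radii must exceed 2 px at this scale", call. = FALSE)
  }
  bg <- 128; interior <- 153; ring <- 38
  px <- matrix(bg, frame_size_px, frame_size_px)
  placed <- tibble::tibble(droplet_id = character(), x_px = numeric(),
                           y_px = numeric(), radius_px = numeric(),
                           border = logical())
  overflow <- 0L
  ord <- order(r_px, decreasing = TRUE) # place big droplets first
  for (i in ord) {
    r_i <- r_px[i]
    # cushion: ring half-width plus room for detector-side smoothing, so a
    # legally placed circle can never produce a border-touching component
    margin <- r_i + ring_width_px / 2 + 5
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      x <- stats::runif(1, margin, frame_size_px - margin)
      y <- stats::runif(1, margin, frame_size_px - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$x_px - x)^2 + (placed$y_px - y)^2) >
              placed$radius_px + r_i + ring_width_px + gap_px)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      overflow <- overflow + 1L
      next
    }
    px <- draw_droplet(px, x, y, r_i, ring_width_px, interior, ring)
    placed <- dplyr::bind_rows(placed, tibble::tibble(
      droplet_id = d$id[i], x_px = x, y_px = y, radius_px = r_i,
      border = FALSE
    ))
  }
  if (overflow > 0) {
    stop(sprintf("frame too small: %d droplet(s) could not be placed", overflow),
         call. = FALSE)
  }
  if (noise_sd > 0) {
    px <- px + matrix(stats::rnorm(length(px), 0, noise_sd),
                      nrow(px), ncol(px))
  }
  px <- matrix(as.integer(pmin(pmax(round(px), 0), 255)),
               frame_size_px, frame_size_px)
  structure(
    list(pixels = px, scale_um_per_px = scale_um_per_px,
         ground_truth = placed, time_s = population$time),
    class = "synthetic_frame"
  )
}

draw_droplet <- function(px, x, y, r, ring_w, interior, ring) {
  n <- nrow(px)
  half <- ring_w / 2
  lo_x <- max(1L, floor(x - r - half)); hi_x <- min(n, ceiling(x + r + half))
  lo_y <- max(1L, floor(y - r - half)); hi_y <- min(n, ceiling(y + r + half))
  xs <- lo_x:hi_x; ys <- lo_y:hi_y
  dist <- sqrt(outer((xs - x)^2, (ys - y)^2, `+`))
  block <- px[xs, ys]
  block[dist < r - half] <- interior
  block[abs(dist - r) <= half] <- ring
  px[xs, ys] <- block
  px
}

#' Detect droplets in a synthetic micrograph
#'
#' Detection pipeline: Gaussian smoothing -> global threshold by
#' between-class variance maximisation (Otsu) picking out the dark
#' interface rings -> fill enclosed regions -> connected components ->
#' discard components touching the frame border or smaller than `min_area`.
#' Each component's center is its centroid; its radius is the mean of the
#' outer equivalent radius `sqrt(filled_area / pi)` and the inner
#' equivalent radius `sqrt(enclosed_area / pi)`, which cancels the
#' interface-width bias for a symmetric ring. Results are sorted by
#' descending radius.
#'
#' @param frame A `synthetic_frame`, or an integer/numeric matrix of 8-bit
#'   grayscale intensities.
#' @param sigma Gaussian smoothing SD, px.
#' @param min_area Minimum component area, px.
#' @return A tibble with columns `x_px`, `y_px`, `radius_px`, `area_px`
#'   (possibly zero rows).
#' @export
detect_droplets <- function(frame, sigma = 1, min_area = 25) {
  px <- if (inherits(frame, "synthetic_frame")) frame$pixels else frame
  stopifnot(is.matrix(px))
  img <- EBImage::Image(px / 255)
  sm <- EBImage::gblur(img, sigma = sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1), levels = 256)
  ring_mask <- EBImage::imageData(sm) < thr
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(ring_mask * 1)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
  n_lab <- max(lab)
  if (n_lab == 0) return(empty_detections())
  # border-touching labels
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[idx]
  area <- tabulate(labv, n_lab)
  ring_area <- tabulate(labv[ring_mask[idx]], n_lab)
  cx <- as.numeric(rowsum(idx[, 1], labv)) / area
  cy <- as.numeric(rowsum(idx[, 2], labv)) / area
  keep <- area >= min_area & !(seq_len(n_lab) %in% border_labels)
  if (!any(keep)) return(empty_detections())
  r_outer <- sqrt(area[keep] / pi)
  inner <- pmax(area[keep] - ring_area[keep], 0)
  r_inner <- sqrt(inner / pi)
  out <- tibble::tibble(
    x_px = cx[keep], y_px = cy[keep],
    radius_px = (r_outer + r_inner) / 2,
    area_px = area[keep]
  )
  out[order(out$radius_px, decreasing = TRUE), ]
}

empty_detections <- function() {
  tibble::tibble(x_px = numeric(), y_px = numeric(), radius_px = numeric(),
                 area_px = numeric())
}

#' Track coarsening across a sequence of frames
#'
#' Runs [detect_droplets()] on each frame, converts detected radii to
#' microns and summarises each time point with the mean radius and the
#' polydispersity ratio s/d. Frames with fewer than two detections get `NA`
#' statistics but do not stop the run.
#'
#' @param frames List of `synthetic_frame` objects, time-ordered, sharing a
#'   common scale.
#' @param sigma,min_area Passed to [detect_droplets()].
#' @return A tibble with columns `time_s`, `n_detected`, `mean_radius_um`,
#'   `s_over_d`.
#' @export
track_coarsening <- function(frames, sigma = 1, min_area = 25) {
  stopifnot(length(frames) >= 2)
  scales <- vapply(frames, function(f) f$scale_um_per_px, numeric(1))
  if (length(unique(scales)) != 1) {
    stop("frames must share a common scale", call. = FALSE)
  }
  purrr::map_dfr(frames, function(f) {
    det <- detect_droplets(f, sigma = sigma, min_area = min_area)
    r_um <- det$radius_px * f$scale_um_per_px
    if (nrow(det) >= 2) {
      pd <- polydispersity(r_um)
      tibble::tibble(time_s = f$time_s, n_detected = nrow(det),
                     mean_radius_um = pd$d_um, s_over_d = pd$s_over_d)
    } else {
      tibble::tibble(time_s = f$time_s, n_detected = nrow(det),
                     mean_radius_um = if (nrow(det)) r_um else NA_real_,
                     s_over_d = NA_real_)
    }
  })
}

#' Write / read a synthetic frame as 8-bit grayscale TIFF
#'
#' The micron-per-pixel scale and time stamp travel in a small YAML sidecar
#' (`<path>.yml`) next to the image, so a written frame round-trips.
#' Ground truth is not stored in the image; use the CSV exporters for that.
#'
#' @param frame A `synthetic_frame`.
#' @param path Output file path.
#' @return `write_frame_tiff` invisibly returns `path`; `read_frame_tiff`
#'   returns a `synthetic_frame` (empty ground truth).
#' @export
write_frame_tiff <- function(frame, path) {
  # tiff expects [row = y, col = x] in [0, 1]
  tiff::writeTIFF(t(frame$pixels) / 255, path, bits.per.sample = 8,
                  compression = "none")
  yaml::write_yaml(list(scale_um_per_px = frame$scale_um_per_px,
                        time_s = frame$time_s),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  scale <- 1; t_s <- 0
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    scale <- meta$scale_um_per_px %||% 1
    t_s <- meta$time_s %||% 0
  }
  structure(
    list(pixels = matrix(as.integer(round(t(img) * 255)),
                         ncol(img), nrow(img)),
         scale_um_per_px = scale,
         ground_truth = tibble::tibble(droplet_id = character(),
                                       x_px = numeric(), y_px = numeric(),
                                       radius_px = numeric(),
                                       border = logical()),
         time_s = t_s),
    class = "synthetic_frame"
  )
}

#' @export
print.synthetic_frame <- function(x, ...) {
  cat(sprintf(
    "<synthetic_frame> %dx%d px at %g um/px, %d droplets, t = %g s\n",
    nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px,
    nrow(x$ground_truth), x$time_s
  ))
  invisible(x)
}
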