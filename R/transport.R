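#' Rotate a direction by a scattering deflection
#'
#' Returns a unit vector making polar angle `theta` with `direction`, with
#' azimuth `phi` measured in a deterministic local frame: the frame is built
#' by crossing `direction` with the global axis of smallest absolute
#' component (which is never parallel to it), so results are reproducible.
#'
#' @param direction unit 3-vector.
#' @param theta polar deflection in radians.
#' @param phi azimuth in radians.
#' @return a unit 3-vector.
#' @export
rotate_direction <- function(direction, theta, phi) {
  stopifnot(length(direction) == 3,
            abs(sqrt(sum(direction^2)) - 1) < 1e-9)
  d <- direction
  k <- which.min(abs(d))
  a <- c(0, 0, 0); a[k] <- 1
  e1 <- c(d[2] * a[3] - d[3] * a[2],
          d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  out <- cos(theta) * d + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
  out / sqrt(sum(out^2))
}

#' Classify a photon history by its scatter counts
#'
#' `"primary"` if it never scattered, `"rayleigh_only"` if it underwent only
#' Rayleigh events, `"compton_involved"` otherwise.
#'
#' @param n_rayleigh,n_compton non-negative event counts.
#' @return a character scalar.
#' @export
scatter_class <- function(n_rayleigh, n_compton) {
  stopifnot(n_rayleigh >= 0, n_compton >= 0)
  if (n_rayleigh == 0 && n_compton == 0) "primary"
  else if (n_compton == 0) "rayleigh_only"
  else "compton_involved"
}

#' Run a single photon history (reference implementation)
#'
#' The photon life-cycle: repeatedly sample a free-flight interaction point
#' ([sample_interaction()]); on escape return the exit state and scatter
#' class; otherwise absorb with probability `mu_t / (mu_t + mu_s)` or
#' scatter ([sample_scatter()] + [rotate_direction()]) and continue. This is
#' a plain-R reference of the compiled engine in [simulate_transport()],
#' intended for small-n checks.
#'
#' @param origin,direction launch position (cm) and unit direction; the
#'   photon should start on or outside the phantom moving toward it.
#' @param phantom an [phantom()].
#' @param physics a [scatter_physics()].
#' @param max_events safety cap on scatter events (default 1e4); a capped
#'   history is returned as absorbed with `capped = TRUE`.
#' @return a list with `status` (`"escaped"` or `"absorbed"`), `class`
#'   (see [scatter_class()]), `position`, `direction`, `n_rayleigh`,
#'   `n_compton`, `capped`.
#' @export
run_history <- function(origin, direction, phantom, physics,
                        max_events = 1e4) {
  stopifnot(inherits(physics, "scatter_physics"))
  pos <- origin; dir <- direction
  nR <- 0L; nC <- 0L
  repeat {
    hit <- sample_interaction(phantom, pos, dir)
    if (hit$escaped) {
      segs <- trace_segments(phantom, pos, dir)
      t_exit <- if (nrow(segs)) segs$t_exit[nrow(segs)] else 0
      return(list(status = "escaped",
                  class = scatter_class(nR, nC),
                  position = pos + t_exit * dir, direction = dir,
                  n_rayleigh = nR, n_compton = nC, capped = FALSE))
    }
    m <- hit$material
    if (stats::runif(1) < m$mu_t / (m$mu_t + m$mu_s))
      return(list(status = "absorbed", class = scatter_class(nR, nC),
                  position = hit$position, direction = dir,
                  n_rayleigh = nR, n_compton = nC, capped = FALSE))
    ev <- sample_scatter(1, m, physics$compton, physics$rayleigh,
                         physics$weight)
    dir <- rotate_direction(dir, ev$theta, ev$phi)
    if (ev$event == "rayleigh") nR <- nR + 1L else nC <- nC + 1L
    pos <- hit$position
    if (nR + nC >= max_events)
      return(list(status = "absorbed", class = scatter_class(nR, nC),
                  position = pos, direction = dir,
                  n_rayleigh = nR, n_compton = nC, capped = TRUE))
  }
}

.class_names <- c("primary", "rayleigh_only", "compton_involved")

# flatten phantom geometry for the compiled engine; material index 1 is the
# background, inclusions follow in order
.flatten_phantom <- function(phantom) {
  mats <- c(list(phantom$background$material),
            lapply(phantom$inclusions, `[[`, "material"))
  ninc <- length(phantom$inclusions)
  inc_lo <- matrix(0, ninc, 3); inc_hi <- matrix(0, ninc, 3)
  for (j in seq_len(ninc)) {
    inc_lo[j, ] <- phantom$inclusions[[j]]$lo
    inc_hi[j, ] <- phantom$inclusions[[j]]$hi
  }
  list(bg_lo = phantom$background$lo, bg_hi = phantom$background$hi,
       inc_lo = inc_lo, inc_hi = inc_hi,
       inc_mat = seq_len(ninc),            # 0-based after subtracting 1
       mu_t = vapply(mats, `[[`, 0, "mu_t"),
       mu_s = vapply(mats, `[[`, 0, "mu_s"),
       beta = vapply(mats, `[[`, 0, "beta"),
       mat_names = vapply(mats, `[[`, "", "name"))
}

#' Monte Carlo transport run
#'
#' Launches `n_photons` parallel-beam photons (+z, uniform over the
#' background's lateral extent, entering at its low-z face), transports each
#' through the phantom (absorb / Rayleigh / Compton), and offers every
#' escaping photon to every detector configuration, each with its own
#' collimator gate, distance and grid. Images are accumulated per scatter
#' class and normalized to counts per launched photon. Runs with the same
#' seed produce bit-identical results.
#'
#' @param phantom an [phantom()].
#' @param physics a [scatter_physics()].
#' @param detectors list of [detector_config()]s.
#' @param n_photons number of histories.
#' @param seed integer seed for R's RNG.
#' @param max_events safety cap on scatter events per history.
#' @return an object of class `scatter_run`: list with `images` (one
#'   `n_u x n_v x 3` array per detector, per-launched-photon units, class
#'   slices named `primary`, `rayleigh_only`, `compton_involved`), `tally`
#'   (launched / absorbed / escaped / capped counts, escaped and detected
#'   per class), `detectors`, `n_photons`, `seed`.
#' @export
simulate_transport <- function(phantom, physics, detectors, n_photons,
                               seed = 1L, max_events = 1e4) {
  stopifnot(inherits(phantom, "xray_phantom"),
            inherits(physics, "scatter_physics"),
            length(detectors) >= 1, n_photons >= 1)
  for (d in detectors) stopifnot(inherits(d, "detector_config"))
  g <- .flatten_phantom(phantom)
  plane_z <- vapply(detectors, function(d)
    phantom$background$hi[3] + d$distance, 0)
  set.seed(seed)
  res <- cpp_simulate(
    n_photons = as.double(n_photons),
    bg_lo = g$bg_lo, bg_hi = g$bg_hi, bg_mat = 0L,
    inc_lo = g$inc_lo, inc_hi = g$inc_hi,
    inc_mat = as.integer(g$inc_mat),
    mu_t = g$mu_t, mu_s = g$mu_s, beta = g$beta,
    alpha = physics$compton$alpha, env_c = physics$env_compton,
    ray_l = physics$rayleigh$l, ray_c2 = physics$rayleigh$c2,
    env_r = physics$env_rayleigh,
    sin_weight = physics$weight == "sintheta",
    det_cos_half = vapply(detectors, function(d)
      cos(d$collimator$acceptance_half_angle), 0),
    det_plane_z = plane_z,
    det_nu = vapply(detectors, function(d) d$grid$n_u, 0L),
    det_nv = vapply(detectors, function(d) d$grid$n_v, 0L),
    det_pitch = vapply(detectors, function(d) d$grid$pitch, 0),
    det_cx = vapply(detectors, function(d) d$grid$center[1], 0),
    det_cy = vapply(detectors, function(d) d$grid$center[2], 0),
    det_H = vapply(detectors, function(d)
      if (d$septa) d$collimator$aspect_ratio * d$grid$pitch else 0, 0),
    max_events = as.integer(max_events))
  stopifnot(res$launched == res$absorbed + res$escaped)
  images <- lapply(res$images, function(img) {
    dimnames(img) <- list(NULL, NULL, .class_names)
    img / res$launched
  })
  names(images) <- vapply(detectors, function(d)
    sprintf("aspect%g_d%g", d$collimator$aspect_ratio, d$distance), "")
  detected <- res$detected
  dimnames(detected) <- list(names(images), .class_names)
  detected_single <- stats::setNames(res$detected_single, names(images))
  names(res$escaped_by_class) <- .class_names
  structure(list(
    images = images,
    tally = list(launched = res$launched, absorbed = res$absorbed,
                 escaped = res$escaped, capped = res$capped,
                 escaped_by_class = res$escaped_by_class,
                 detected = detected, detected_single = detected_single),
    detectors = detectors, n_photons = n_photons, seed = seed,
    materials = g$mat_names), class = "scatter_run")
}

#' @export
print.scatter_run <- function(x, ...) {
  t <- x$tally
  cat(sprintf("<scatter_run>  %g photons (seed %d)\n", t$launched, x$seed))
  cat(sprintf("  absorbed %g (%.2f%%)   escaped %g (%.2f%%)   capped %g\n",
              t$absorbed, 100 * t$absorbed / t$launched,
              t$escaped, 100 * t$escaped / t$launched, t$capped))
  cat("  escaped by class:",
      paste(sprintf("%s=%g", names(t$escaped_by_class), t$escaped_by_class),
            collapse = "  "), "\n")
  cat("  detected (counts):\n")
  print(t$detected)
  invisible(x)
}

#' Extract an image from a transport run
#'
#' @param run a `scatter_run` from [simulate_transport()].
#' @param detector detector index or name.
#' @param classes scatter classes to sum: any subset of `"primary"`,
#'   `"rayleigh_only"`, `"compton_involved"`, or the shorthands `"total"`
#'   (all three) and `"scatter"` (the two scattered classes).
#' @return an `n_u x n_v` matrix in counts per launched photon.
#' @export
run_image <- function(run, detector = 1,
                      classes = "total") {
  stopifnot(inherits(run, "scatter_run"))
  img <- run$images[[detector]]
  if (identical(classes, "total")) classes <- .class_names
  if (identical(classes, "scatter"))
    classes <- c("rayleigh_only", "compton_involved")
  stopifnot(all(classes %in% .class_names))
  out <- img[, , classes[1]]
  for (cl in classes[-1]) out <- out + img[, , cl]
  out
}

#' Plot a detector image
#'
#' @param x a `scatter_run`.
#' @param detector detector index or name.
#' @param classes passed to [run_image()].
#' @param ... further arguments to [graphics::image()].
#' @export
plot.scatter_run <- function(x, detector = 1, classes = "total", ...) {
  img <- run_image(x, detector, classes)
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                  col = grDevices::gray.colors(256), asp = 1,
                  xlab = "u (pixel)", ylab = "v (pixel)", ...)
  invisible(x)
}
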