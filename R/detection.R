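#' Anti-scatter collimator specification
#'
#' Ideal binary angular gate: a photon is accepted iff its direction makes an
#' angle with the collimator axis (+z, normal to the detector everywhere) of
#' at most `arctan(1 / aspect_ratio)`, where the aspect ratio is the grid
#' height over the cell aperture, H/D. No septal penetration or partial
#' shadowing is modelled.
#'
#' @param aspect_ratio H/D, > 0 (e.g. 50 for the high-collimation and 10 for
#'   the low-collimation acquisition).
#' @return an object of class `collimator_spec` with fields `aspect_ratio`
#'   and `acceptance_half_angle` (radians).
#' @export
collimator_spec <- function(aspect_ratio) {
  stopifnot(is.numeric(aspect_ratio), aspect_ratio > 0)
  structure(list(aspect_ratio = aspect_ratio,
                 acceptance_half_angle = atan(1 / aspect_ratio)),
            class = "collimator_spec")
}

#' @export
print.collimator_spec <- function(x, ...) {
  cat(sprintf("<collimator>  aspect ratio %g  half-angle %.3f deg\n",
              x$aspect_ratio, x$acceptance_half_angle * 180 / pi))
  invisible(x)
}

#' Detector pixel grid
#'
#' @param n_u,n_v pixel counts (default 60 x 60, the reduced test scale; the
#'   full-resolution configuration is 600 x 600 at 0.02 cm pitch).
#' @param pitch pixel pitch in cm (default 0.2).
#' @param center lateral (x, y) center of the grid in cm.
#' @return an object of class `detector_grid`.
#' @export
detector_grid <- function(n_u = 60, n_v = 60, pitch = 0.2,
                          center = c(0, 0)) {
  stopifnot(n_u >= 1, n_v >= 1, pitch > 0, length(center) == 2)
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 pitch = pitch, center = as.numeric(center)),
            class = "detector_grid")
}

#' Detector configuration: grid + collimator + object-detector distance
#'
#' The Monte Carlo scoring applies the collimator in two stages: the binary
#' angular gate ([accept()]) and, when `septa = TRUE` (the default), the
#' ideal-grid septal rule — the photon must enter and leave the grid of
#' height `H = aspect_ratio * pitch` within the same cell, otherwise a
#' septum absorbs it. The septal rule is what makes the scoring consistent
#' with the per-cell angular limits of the analytic single-scattering model
#' ([angular_limits()]); with `septa = FALSE` the full acceptance cone is
#' scored regardless of cell boundaries.
#'
#' @param collimator a [collimator_spec()].
#' @param distance object-detector distance in cm (from the phantom exit
#'   face to the detector plane).
#' @param grid a [detector_grid()].
#' @param septa apply the septal cell-confinement rule (default `TRUE`).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(collimator, distance, grid = detector_grid(),
                            septa = TRUE) {
  stopifnot(inherits(collimator, "collimator_spec"),
            inherits(grid, "detector_grid"), distance > 0)
  structure(list(collimator = collimator, distance = distance, grid = grid,
                 septa = isTRUE(septa)),
            class = "detector_config")
}

#' Collimator acceptance test
#'
#' @param direction unit 3-vector (or matrix with 3 columns), photon exit
#'   direction(s).
#' @param collimator a [collimator_spec()].
#' @return logical: accepted (angle to +z within the acceptance half-angle).
#' @export
accept <- function(direction, collimator) {
  stopifnot(inherits(collimator, "collimator_spec"))
  d <- if (is.matrix(direction)) direction else matrix(direction, ncol = 3)
  dz <- d[, 3] / sqrt(rowSums(d^2))
  dz >= cos(collimator$acceptance_half_angle)
}

#' Score an escaping photon onto a detector
#'
#' Propagates the straight exit ray to the detector plane and returns the
#' half-open pixel bin it lands in, or `NULL` when the photon moves away
#' from the detector, fails the collimator gate, or misses the grid.
#'
#' @param position 3-vector, exit position in cm.
#' @param direction unit 3-vector, exit direction.
#' @param grid a [detector_grid()].
#' @param plane_z detector plane z in cm.
#' @param collimator a [collimator_spec()].
#' @return integer `c(u, v)` (1-based pixel indices) or `NULL`.
#' @export
score_photon <- function(position, direction, grid, plane_z, collimator) {
  if (direction[3] <= 0) return(NULL)
  if (!accept(direction, collimator)) return(NULL)
  t <- (plane_z - position[3]) / direction[3]
  px <- position[1] + t * direction[1]
  py <- position[2] + t * direction[2]
  iu <- floor((px - (grid$center[1] - grid$n_u * grid$pitch / 2)) / grid$pitch)
  iv <- floor((py - (grid$center[2] - grid$n_v * grid$pitch / 2)) / grid$pitch)
  if (iu < 0 || iu >= grid$n_u || iv < 0 || iv >= grid$n_v) return(NULL)
  as.integer(c(iu + 1, iv + 1))
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

#' Dark-field image by collimation subtraction
#'
#' Elementwise `IL - IH`: the low-collimation image (primary + small-angle
#' scatter) minus the high-collimation image (primary only), leaving the
#' small-angle-scattering (dark-field) signal. Negative pixels (noise) are
#' retained; their count is attached as attribute `n_negative`.
#'
#' @param image_low,image_high matrices on identical grids with identical
#'   normalization (counts per launched photon).
#' @return the difference matrix with attribute `n_negative`.
#' @export
darkfield_subtract <- function(image_low, image_high) {
  .check_same_shape(image_low, image_high)
  out <- image_low - image_high
  attr(out, "n_negative") <- sum(out < 0)
  out
}

#' Dark-field image by distance subtraction
#'
#' Elementwise `near - far` for two acquisitions with the same collimator at
#' a short and a long object-detector distance. In a parallel beam the
#' primary image is distance-invariant, so the difference isolates the
#' (distance-dependent) scatter distribution.
#'
#' @param image_near,image_far matrices on identical grids with identical
#'   normalization.
#' @return the difference matrix with attribute `n_negative`.
#' @export
distance_subtract <- function(image_near, image_far) {
  .check_same_shape(image_near, image_far)
  out <- image_near - image_far
  attr(out, "n_negative") <- sum(out < 0)
  out
}

# logical pixel mask of the lateral box [lo, hi] on a grid, with an optional
# erosion margin in pixels (positive shrinks the region)
.region_mask <- function(grid, lo, hi, margin = 0) {
  u <- grid$center[1] + ((seq_len(grid$n_u) - 0.5) - grid$n_u / 2) * grid$pitch
  v <- grid$center[2] + ((seq_len(grid$n_v) - 0.5) - grid$n_v / 2) * grid$pitch
  m <- margin * grid$pitch
  outer(u >= lo[1] + m & u <= hi[1] - m,
        v >= lo[2] + m & v <= hi[2] - m, FUN = "&")
}

#' Per-region image statistics
#'
#' Mean and variance of pixel values inside the projected shadow of each
#' phantom inclusion, and inside the background (the phantom footprint minus
#' the dilated inclusion shadows). Masks are eroded by `margin` pixels so
#' that scatter blur at region edges does not contaminate the statistics.
#'
#' @param image matrix of pixel values.
#' @param phantom the [phantom()] that was imaged.
#' @param grid the [detector_grid()] the image was scored on.
#' @param margin erosion margin in pixels (default 1).
#' @return a data.frame with columns `region`, `beta`, `n_pixels`, `mean`,
#'   `var`, ordered as background first then inclusions.
#' @export
region_stats <- function(image, phantom, grid, margin = 1) {
  stopifnot(inherits(phantom, "xray_phantom"), inherits(grid, "detector_grid"))
  if (!identical(dim(image), c(grid$n_u, grid$n_v)))
    stop("image shape does not match the grid")
  bg <- phantom$background
  bg_mask <- .region_mask(grid, bg$lo, bg$hi, margin)
  rows <- list()
  for (inc in phantom$inclusions) {
    msk <- .region_mask(grid, inc$lo, inc$hi, margin)
    if (!any(msk)) stop("empty region mask for '", inc$material$name,
                        "' (margin too large?)")
    bg_mask <- bg_mask & !.region_mask(grid, inc$lo, inc$hi, -margin)
    rows[[inc$material$name]] <-
      data.frame(region = inc$material$name, beta = inc$material$beta,
                 n_pixels = sum(msk), mean = mean(image[msk]),
                 var = stats::var(image[msk]))
  }
  if (!any(bg_mask)) stop("empty background region mask")
  out <- rbind(
    data.frame(region = bg$material$name, beta = bg$material$beta,
               n_pixels = sum(bg_mask), mean = mean(image[bg_mask]),
               var = stats::var(image[bg_mask])),
    do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
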