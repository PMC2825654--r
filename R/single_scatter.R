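#' Collimated-cell acceptance geometry
#'
#' The geometry linking one scattering point to one detector cell behind an
#' anti-scatter grid: grid height `H`, cell aperture `D`, distance `R` from
#' the scattering point to the detector plane, and lateral offset `r` from
#' the scattering point's beam axis to the cell center (all cm).
#'
#' @param H grid (collimator) height in cm, >= 0.
#' @param D detector cell aperture in cm, > 0.
#' @param R scattering-point-to-detector distance in cm, must exceed `H`.
#' @param r lateral offset in cm, >= 0.
#' @return an object of class `acceptance_geometry`.
#' @export
acceptance_geometry <- function(H, D, R, r) {
  stopifnot(H >= 0, D > 0, r >= 0)
  if (R <= H)
    stop("geometry error: need R > H (got R = ", R, ", H = ", H, ")")
  structure(list(H = H, D = D, R = R, r = r), class = "acceptance_geometry")
}

#' Angular acceptance limits for a collimated detector cell
#'
#' The polar and azimuthal limits within which a photon scattered at the
#' given point passes the grid into the cell:
#' `theta1 = arctan((r - D/2) / (R - H))`, `theta2 = arctan((r + D/2) / R)`,
#' `phi2 = -phi1 = arctan(D / (2 r))`. Degenerate cases: `theta1` is clamped
#' to 0 when negative (the polar angle is non-negative), and for the on-axis
#' cell (r < D/2) the cell subtends the full azimuth, so `phi2 - phi1` is
#' taken as `2*pi`.
#'
#' @param geom an [acceptance_geometry()].
#' @return a list with `theta1`, `theta2`, `phi1`, `phi2` (radians) and
#'   `full_azimuth` (logical).
#' @export
angular_limits <- function(geom) {
  stopifnot(inherits(geom, "acceptance_geometry"))
  th1 <- atan((geom$r - geom$D / 2) / (geom$R - geom$H))
  th2 <- atan((geom$r + geom$D / 2) / geom$R)
  full <- geom$r < geom$D / 2
  ph2 <- if (full) pi else atan(geom$D / (2 * geom$r))
  list(theta1 = max(th1, 0), theta2 = th2, phi1 = -ph2, phi2 = ph2,
       full_azimuth = full)
}

# quiet core: (phi2-phi1)/(2*pi) * [CDF(theta2) - CDF(theta1)], clamped
.acceptance_prob <- function(th1, th2, ph1, ph2, mat, physics) {
  if (th1 >= th2) return(0)
  p <- (ph2 - ph1) / (2 * pi) *
    (.mixture_cdf(th2, mat, physics) - .mixture_cdf(th1, mat, physics))
  min(max(p, 0), 1)
}

#' Probability that a scattered photon is accepted into a detector cell
#'
#' `(1/(2*pi)) * (phi2 - phi1) * int_{theta1}^{theta2} p(theta) d(theta)`,
#' where `p(theta)` is the material's combined angular density
#' ([angular_pdf()]); the azimuthal integrand does not depend on `theta`, so
#' the double integral factorizes. Evaluated by adaptive quadrature of the
#' mixture density; clamped to `[0, 1]`. Returns 0 with a
#' warning when `theta1 >= theta2` (cell unreachable under the
#' approximation).
#'
#' @param limits output of [angular_limits()] (or a list with `theta1`,
#'   `theta2`, `phi1`, `phi2`).
#' @param material an [material()].
#' @param physics a [scatter_physics()].
#' @return a probability in `[0, 1]`.
#' @export
acceptance_probability <- function(limits, material, physics) {
  stopifnot(inherits(material, "xray_material"),
            inherits(physics, "scatter_physics"))
  if (limits$theta1 >= limits$theta2) {
    warning("theta1 >= theta2: cell unreachable, returning 0")
    return(0)
  }
  pol <- stats::integrate(function(th)
    angular_pdf(th, material, physics$compton, physics$rayleigh,
                weight = physics$weight),
    limits$theta1, limits$theta2, rel.tol = 1e-10, abs.tol = 1e-13,
    subdivisions = 400L)$value
  min(max((limits$phi2 - limits$phi1) / (2 * pi) * pol, 0), 1)
}

# acceptance at radial offsets r (vectorized): the collimated-cell limits
# theta1 = atan((r - D/2)/(R - H)) clamped at 0, theta2 = atan((r + D/2)/R),
# azimuth window 2*atan(D/(2 r)) (full 2*pi for the on-axis cell)
.acceptance_at_r <- function(r, R, H, D, materials, physics) {
  th1 <- pmax(atan((r - D / 2) / (R - H)), 0)
  th2 <- atan((r + D / 2) / R)
  dphi <- ifelse(r < D / 2, 2 * pi, 2 * atan(D / (2 * pmax(r, D / 4))))
  open <- th1 < th2
  A <- matrix(0, length(r), length(materials))
  for (m in seq_along(materials)) {
    b <- materials[[m]]$beta
    cdf <- function(th) b * physics$cdf_rayleigh(th) +
      (1 - b) * physics$cdf_compton(th)
    A[open, m] <- dphi[open] / (2 * pi) * (cdf(th2[open]) - cdf(th1[open]))
  }
  pmin(pmax(A, 0), 1)
}

# lateral acceptance kernel for one depth: for each integer cell offset
# (du, dv) from the scattering column, the Eq-7 acceptance averaged over
# n_sub x n_sub source sub-positions within the column (the lateral
# integral of the volume integral; plain cell-center evaluation aliases
# badly when the kernel spans only a few cells). Offsets with zero
# acceptance for every material are dropped.
.acceptance_kernel <- function(R, H, D, pitch, materials, physics,
                               n_sub = 4L) {
  r_max <- if (H > 0) D * (R - H / 2) / H else Inf
  k <- ceiling(r_max / pitch + 1)
  off <- expand.grid(du = -k:k, dv = -k:k)
  sub <- (seq_len(n_sub) - 0.5) / n_sub - 0.5
  so <- expand.grid(ox = sub, oy = sub)
  A <- matrix(0, nrow(off), length(materials))
  for (s in seq_len(nrow(so))) {
    r <- pitch * sqrt((off$du - so$ox[s])^2 + (off$dv - so$oy[s])^2)
    A <- A + .acceptance_at_r(r, R, H, D, materials, physics)
  }
  A <- A / nrow(so)
  keep <- rowSums(A) > 0
  list(du = off$du[keep], dv = off$dv[keep], A = A[keep, , drop = FALSE])
}

# MC-estimated kernels for all depths at once: per scattering-event
# component (Rayleigh / Compton), draw a pool of angles from the physics
# samplers plus uniform azimuths and in-cell source offsets, trace them
# through the exact grid geometry (angular gate + septal cell confinement)
# with cpp_collimator_kernel, and mix the two component kernels with each
# material's beta. Uses an isolated, fixed-seed RNG stream so tables are
# deterministic and the caller's RNG state is untouched.
.mc_kernels <- function(R_vec, H, D, pitch, tan_gate, materials, physics,
                        n_mc, mc_seed = 271828L) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  set.seed(mc_seed)
  sw <- physics$weight == "sintheta"
  pool <- function(th) {
    phi <- 2 * pi * stats::runif(n_mc)
    list(tanth = tan(pmin(th, pi / 2 - 1e-9)),
         cosphi = cos(phi), sinphi = sin(phi),
         sx = stats::runif(n_mc), sy = stats::runif(n_mc))
  }
  pr <- pool(cpp_sample_rayleigh(n_mc, physics$rayleigh$l,
                                 physics$rayleigh$c2,
                                 physics$env_rayleigh, sw))
  pc <- pool(cpp_sample_compton(n_mc, physics$compton$alpha,
                                physics$env_compton, sw))
  kmax <- as.integer(ceiling(max(R_vec) * tan_gate / pitch + 2))
  count <- function(p)
    array(cpp_collimator_kernel(p$tanth, p$cosphi, p$sinphi, p$sx, p$sy,
                                R_vec, H, pitch, tan_gate, kmax),
          c(2 * kmax + 1, 2 * kmax + 1, length(R_vec))) / n_mc
  Kr <- count(pr); Kc <- count(pc)
  off <- expand.grid(du = -kmax:kmax, dv = -kmax:kmax)
  lapply(seq_along(R_vec), function(iz) {
    A <- vapply(materials, function(m)
      m$beta * as.vector(Kr[, , iz]) + (1 - m$beta) * as.vector(Kc[, , iz]),
      numeric(nrow(off)))
    keep <- rowSums(A) > 0
    list(du = off$du[keep], dv = off$dv[keep], A = A[keep, , drop = FALSE])
  })
}

#' Precompute the acceptance-probability table
#'
#' For each scattering depth (default 250 levels of 0.02 cm over the 5 cm
#' phantom thickness) and each material, tabulates the probability that a
#' photon scattered at that depth passes the grid into detector cells. The
#' `prob` matrix holds the on-axis-cell entries (r = 0, full azimuth) from
#' the factorized quadrature of the collimated-cell limits; the per-cell
#' lateral `kernels` that the imaging integrator uses are computed either by
#' Monte Carlo over the exact grid geometry (`method = "mc"`, the default:
#' angular gate plus septal cell confinement, matching the transport
#' engine's scoring) or from the approximate analytic limits averaged over
#' source sub-positions (`method = "eq7"`). The `total` matrix sums each
#' kernel over all reachable cells — the per-event probability of being
#' detected anywhere — and is non-increasing in the grid height `H`.
#'
#' @param phantom an [phantom()]; sets the depth range and material list.
#' @param grid a [detector_grid()]; its pitch is the cell aperture `D`.
#' @param collimator a [collimator_spec()]; the grid height is
#'   `H = aspect_ratio * D`.
#' @param distance object-detector distance in cm.
#' @param physics a [scatter_physics()].
#' @param depth_step depth resolution in cm (default 0.02).
#' @param method kernel estimator: `"mc"` (exact geometry, Monte Carlo) or
#'   `"eq7"` (analytic angular limits).
#' @param n_mc Monte Carlo draws per scattering component for
#'   `method = "mc"` (default 1e6).
#' @param n_sub lateral supersampling factor for `method = "eq7"`
#'   (default 4).
#' @return an object of class `acceptance_table` with fields `depths`
#'   (voxel-center depths below the entry face), `materials`, `prob`
#'   (n_depth x n_material, on-axis cell), `total` (n_depth x n_material,
#'   summed over cells), `kernels` (per-depth lateral kernels), and the
#'   geometry (`H`, `D`, `distance`, `pitch`).
#' @export
build_acceptance_table <- function(phantom, grid, collimator, distance,
                                   physics, depth_step = 0.02,
                                   method = c("mc", "eq7"),
                                   n_mc = 1e6, n_sub = 4L) {
  method <- match.arg(method)
  stopifnot(inherits(phantom, "xray_phantom"),
            inherits(grid, "detector_grid"),
            inherits(collimator, "collimator_spec"),
            inherits(physics, "scatter_physics"), depth_step > 0)
  bg <- phantom$background
  thickness <- bg$hi[3] - bg$lo[3]
  n_depth <- round(thickness / depth_step)
  if (abs(n_depth * depth_step - thickness) > 1e-9)
    stop("phantom thickness ", thickness,
         " cm is not divisible by depth_step ", depth_step)
  D <- grid$pitch
  H <- collimator$aspect_ratio * D
  plane_z <- bg$hi[3] + distance
  depths <- (seq_len(n_depth) - 0.5) * depth_step
  mats <- c(list(bg$material), lapply(phantom$inclusions, `[[`, "material"))
  names(mats) <- vapply(mats, `[[`, "", "name")
  mats <- mats[!duplicated(names(mats))]
  R_vec <- plane_z - (bg$lo[3] + depths)
  if (any(R_vec <= H))
    stop("geometry error: scattering-point distance R = ", min(R_vec),
         " cm does not exceed the grid height H = ", H, " cm")
  prob <- matrix(0, n_depth, length(mats),
                 dimnames = list(NULL, names(mats)))
  for (iz in seq_len(n_depth)) {
    lim <- angular_limits(acceptance_geometry(H, D, R_vec[iz], 0))
    for (m in seq_along(mats))
      prob[iz, m] <- .acceptance_prob(lim$theta1, lim$theta2, lim$phi1,
                                      lim$phi2, mats[[m]], physics)
  }
  kernels <- if (method == "mc") {
    .mc_kernels(R_vec, H, D, grid$pitch,
                tan(collimator$acceptance_half_angle), mats, physics, n_mc)
  } else {
    lapply(seq_len(n_depth), function(iz)
      .acceptance_kernel(R_vec[iz], H, D, grid$pitch, mats, physics, n_sub))
  }
  tot <- vapply(kernels, function(k) colSums(k$A), numeric(length(mats)))
  total <- if (is.matrix(tot)) t(tot) else matrix(tot, ncol = 1)
  colnames(total) <- names(mats)
  structure(list(depths = depths, materials = mats, prob = prob,
                 total = total, kernels = kernels,
                 H = H, D = D, distance = distance, pitch = grid$pitch,
                 depth_step = depth_step, method = method,
                 n_mc = n_mc, n_sub = n_sub,
                 n_u = grid$n_u, n_v = grid$n_v),
            class = "acceptance_table")
}

#' @export
print.acceptance_table <- function(x, ...) {
  cat(sprintf(paste0("<acceptance_table>  %d depths x %d materials  ",
                     "(H = %g cm, D = %g cm, distance = %g cm)\n"),
              nrow(x$prob), ncol(x$prob), x$H, x$D, x$distance))
  invisible(x)
}

# material index volume (n_u x n_v x n_depth): 0 = outside the background
# laterally, 1 = background, 1 + j = inclusion j
.material_volume <- function(phantom, grid, depths) {
  bg <- phantom$background
  u <- grid$center[1] + ((seq_len(grid$n_u) - 0.5) - grid$n_u / 2) * grid$pitch
  v <- grid$center[2] + ((seq_len(grid$n_v) - 0.5) - grid$n_v / 2) * grid$pitch
  z <- bg$lo[3] + depths
  vol <- array(0L, c(grid$n_u, grid$n_v, length(depths)))
  in_u <- u >= bg$lo[1] & u <= bg$hi[1]
  in_v <- v >= bg$lo[2] & v <= bg$hi[2]
  vol[in_u, in_v, ] <- 1L
  for (j in seq_along(phantom$inclusions)) {
    inc <- phantom$inclusions[[j]]
    iu <- u >= inc$lo[1] & u <= inc$hi[1]
    iv <- v >= inc$lo[2] & v <= inc$hi[2]
    iz <- z >= inc$lo[3] & z <= inc$hi[3]
    vol[iu, iv, iz] <- 1L + j
  }
  vol
}

#' Analytic single-scattering dark-field image
#'
#' The single-scattering forward model: for every detector cell, the
#' attenuated volume integral
#' `f(H) = sum_voxels I0 * w_in * w_out * mu_s * acceptance`, where `w_in`
#' is the Beer-Lambert attenuation from the source to the voxel, `w_out`
#' the attenuation from the voxel to the detector (axial path), `mu_s` the
#' local scattering coefficient, and the acceptance the precomputed
#' per-(depth, material) collimated-cell probabilities distributed over the
#' table's lateral kernel. `I0` is the per-launched-photon column flux
#' (pixel area over source area), matching the Monte Carlo normalization.
#'
#' @param phantom an [phantom()].
#' @param grid a [detector_grid()].
#' @param collimator a [collimator_spec()].
#' @param distance object-detector distance in cm.
#' @param physics a [scatter_physics()].
#' @param table an [build_acceptance_table()] result; built on the fly when
#'   `NULL`. Supplying a table built for a different geometry is an error.
#' @param depth_step depth resolution in cm when building the table.
#' @return an `n_u x n_v` matrix, expected detected single-scatter counts
#'   per launched photon.
#' @export
single_scatter_image <- function(phantom, grid, collimator, distance,
                                 physics, table = NULL, depth_step = 0.02) {
  stopifnot(inherits(phantom, "xray_phantom"),
            inherits(grid, "detector_grid"))
  if (is.null(table))
    table <- build_acceptance_table(phantom, grid, collimator, distance,
                                    physics, depth_step)
  stopifnot(inherits(table, "acceptance_table"))
  if (table$distance != distance || table$pitch != grid$pitch ||
      table$n_u != grid$n_u || table$n_v != grid$n_v ||
      abs(table$H - collimator$aspect_ratio * grid$pitch) > 1e-12)
    stop("acceptance table was built for a different geometry")
  bg <- phantom$background
  dz <- table$depth_step
  n_depth <- length(table$depths)
  vol <- .material_volume(phantom, grid, table$depths)
  mats <- table$materials
  # per-volume-index coefficient lookups (index 0 -> vacuum)
  mat_of_vol <- c(list(NULL), list(bg$material),
                  lapply(phantom$inclusions, `[[`, "material"))
  mu_tot_lut <- c(0, vapply(mat_of_vol[-1], function(m) m$mu_t + m$mu_s, 0))
  mu_s_lut <- c(0, vapply(mat_of_vol[-1], `[[`, 0, "mu_s"))
  col_lut <- c(0L, match(vapply(mat_of_vol[-1], `[[`, "", "name"),
                         names(mats)))
  mu_tot_vol <- array(mu_tot_lut[vol + 1L], dim(vol))
  mu_s_vol <- array(mu_s_lut[vol + 1L], dim(vol))
  # cumulative optical depth through full voxels, per column
  cum <- array(0, dim(vol))
  run <- matrix(0, grid$n_u, grid$n_v)
  for (iz in seq_len(n_depth)) {
    run <- run + mu_tot_vol[, , iz] * dz
    cum[, , iz] <- run
  }
  total_od <- cum[, , n_depth]
  # incident flux per column: pixel area / source area inside the footprint
  src_area <- (bg$hi[1] - bg$lo[1]) * (bg$hi[2] - bg$lo[2])
  I0 <- matrix(0, grid$n_u, grid$n_v)
  I0[.region_mask(grid, bg$lo, bg$hi, 0)] <- grid$pitch^2 / src_area
  img <- matrix(0, grid$n_u, grid$n_v)
  for (iz in seq_len(n_depth)) {
    mu <- mu_tot_vol[, , iz]
    w_in <- exp(-(cum[, , iz] - 0.5 * mu * dz))
    w_out <- exp(-(total_od - cum[, , iz] + 0.5 * mu * dz))
    emis <- I0 * w_in * w_out * mu_s_vol[, , iz] * dz
    ker <- table$kernels[[iz]]
    ids <- vol[, , iz]
    for (m in seq_along(mats)) {
      sel <- which(col_lut[ids + 1L] == m, arr.ind = FALSE)
      if (!length(sel)) next
      e_m <- matrix(0, grid$n_u, grid$n_v)
      e_m[sel] <- emis[sel]
      for (kk in seq_along(ker$du)) {
        a <- ker$A[kk, m]
        if (a == 0) next
        du <- ker$du[kk]; dv <- ker$dv[kk]
        su <- seq_len(grid$n_u); sv <- seq_len(grid$n_v)
        tu <- su + du; tv <- sv + dv
        ok_u <- tu >= 1 & tu <= grid$n_u
        ok_v <- tv >= 1 & tv <= grid$n_v
        img[tu[ok_u], tv[ok_v]] <- img[tu[ok_u], tv[ok_v]] +
          a * e_m[su[ok_u], sv[ok_v]]
      }
    }
  }
  img
}
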