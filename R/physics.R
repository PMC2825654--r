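#' Compton scattering model
#'
#' Describes incoherent (Compton) scattering of a monoenergetic photon by the
#' Klein-Nishina differential cross-section. The only physical parameter is
#' the photon energy; `alpha` is its ratio to the electron rest energy
#' (511 keV). The classical electron radius `r_e` is kept at 1 internally:
#' only normalized angular densities enter the transport.
#'
#' @param energy_keV photon energy in keV (default 50).
#' @param r_e classical electron radius scale factor (default 1).
#' @return an object of class `compton_model`.
#' @export
compton_model <- function(energy_keV = 50, r_e = 1) {
  stopifnot(energy_keV >= 0, r_e > 0)
  structure(list(energy_keV = energy_keV, alpha = energy_keV / 511.0,
                 r_e = r_e),
            class = "compton_model")
}

#' Rayleigh scattering model
#'
#' Coherent (Rayleigh) scattering with the analytic form-factor approximation
#' `F(theta) = c1 * theta^l * exp(-c2 * theta)` in place of tabulated atomic
#' form factors. `c1` cancels when the angular density is normalized and is
#' kept for completeness; `l >= 0` controls the forward suppression (`l > 0`
#' gives zero density at theta = 0) and `c2 > 0` the large-angle decay.
#' Use [calibrate_form_factor()] to choose `c2` for a target mean
#' scattering angle.
#'
#' @param c1 form-factor amplitude (default 1).
#' @param l form-factor exponent, >= 0 (default 2).
#' @param c2 form-factor decay rate per radian, > 0.
#' @param r_e classical electron radius scale factor (default 1).
#' @return an object of class `rayleigh_model`.
#' @export
rayleigh_model <- function(c1 = 1, l = 2, c2, r_e = 1) {
  if (!is.numeric(c2) || length(c2) != 1 || c2 <= 0)
    stop("'c2' must be a single positive number")
  stopifnot(l >= 0, c1 >= 0, r_e > 0)
  structure(list(c1 = c1, l = l, c2 = c2, r_e = r_e),
            class = "rayleigh_model")
}

#' X-ray material
#'
#' The three-parameter description of X-ray--matter interaction used
#' throughout: absorption coefficient `mu_t` (probability of photoelectric
#' absorption per unit path length, 1/cm), scattering coefficient `mu_s`
#' (probability of a scattering event per unit path length, 1/cm), and the
#' Rayleigh fraction `beta` (probability that a scattering event is coherent
#' rather than Compton). The Rayleigh and Compton scattering coefficients are
#' `mu_s_r = beta * mu_s` and `mu_s_c = (1 - beta) * mu_s`.
#'
#' @param name label for the material.
#' @param mu_t absorption coefficient, 1/cm, >= 0.
#' @param mu_s scattering coefficient, 1/cm, >= 0.
#' @param beta Rayleigh fraction in `[0, 1]`.
#' @return an object of class `xray_material`.
#' @seealso [material_from_components()]
#' @export
material <- function(name, mu_t, mu_s, beta) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(mu_t) || mu_t < 0) stop("'mu_t' must be >= 0")
  if (!is.numeric(mu_s) || mu_s < 0) stop("'mu_s' must be >= 0")
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop("material '", name, "': 'beta' must lie in [0, 1]")
  structure(list(name = name, mu_t = mu_t, mu_s = mu_s, beta = beta),
            class = "xray_material")
}

#' @describeIn material build a material from its Rayleigh and Compton
#'   scattering coefficients `mu_s_r`, `mu_s_c` (so `mu_s = mu_s_r + mu_s_c`
#'   and `beta = mu_s_r / mu_s`).
#' @param mu_s_r Rayleigh scattering coefficient, 1/cm.
#' @param mu_s_c Compton scattering coefficient, 1/cm.
#' @export
material_from_components <- function(name, mu_t, mu_s_r, mu_s_c) {
  stopifnot(mu_s_r >= 0, mu_s_c >= 0)
  mu_s <- mu_s_r + mu_s_c
  beta <- if (mu_s > 0) mu_s_r / mu_s else 0
  material(name, mu_t, mu_s, beta)
}

#' @export
print.xray_material <- function(x, ...) {
  cat(sprintf("<material '%s'>  mu_t = %g  mu_s = %g  beta = %g  (1/cm)\n",
              x$name, x$mu_t, x$mu_s, x$beta))
  invisible(x)
}

.check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi))
    stop("'theta' must lie in [0, pi]")
}

#' Klein-Nishina differential cross-section
#'
#' `(r_e^2/2) * (1 + cos^2(theta) + alpha^2 (1-cos theta)^2 /
#' (1 + alpha (1-cos theta))) / (1 + alpha (1-cos theta))^2`.
#' At `alpha = 0` this reduces to the Thomson cross-section
#' `(r_e^2/2)(1 + cos^2 theta)`.
#'
#' @param theta polar scattering angle(s) in radians, in `[0, pi]`.
#' @param model a [compton_model()].
#' @return differential cross-section values (units of `r_e^2`).
#' @export
compton_dcs <- function(theta, model) {
  stopifnot(inherits(model, "compton_model"))
  .check_theta(theta)
  a <- model$alpha
  cth <- cos(theta)
  k <- 1 + a * (1 - cth)
  model$r_e^2 / 2 * (1 + cth^2 + a^2 * (1 - cth)^2 / k) / k^2
}

#' Rayleigh differential cross-section
#'
#' `(r_e^2/2) * (1 + cos^2 theta) * F(theta)^2` with the analytic form factor
#' `F = c1 * theta^l * exp(-c2 * theta)`.
#'
#' @param theta polar scattering angle(s) in radians, in `[0, pi]`.
#' @param model a [rayleigh_model()].
#' @return differential cross-section values (units of `r_e^2`).
#' @export
rayleigh_dcs <- function(theta, model) {
  stopifnot(inherits(model, "rayleigh_model"))
  .check_theta(theta)
  cth <- cos(theta)
  FF <- model$c1 * theta^model$l * exp(-model$c2 * theta)
  model$r_e^2 / 2 * (1 + cth^2) * FF^2
}

# angular weight for the chosen normalization convention:
# "dtheta" integrates the cross-section over d(theta) directly (the
# convention the transport and beta accounting follow); "sintheta" adds the
# solid-angle Jacobian and is available for sensitivity checks.
.weight_fun <- function(weight = c("dtheta", "sintheta")) {
  weight <- match.arg(weight)
  if (weight == "dtheta") function(th) rep(1, length(th)) else sin
}

# normalization constant int_0^pi dcs(theta) * w(theta) d(theta)
.norm_const <- function(dcs, weight = "dtheta") {
  w <- .weight_fun(weight)
  stats::integrate(function(th) dcs(th) * w(th), 0, pi,
                   rel.tol = 1e-10, abs.tol = 1e-13,
                   subdivisions = 400L)$value
}

#' Combined angular scattering density
#'
#' The per-event density of the polar scattering angle for a material:
#' a `beta`-weighted mixture of the normalized Rayleigh and Klein-Nishina
#' densities, `p(theta) = beta * p_r(theta) + (1 - beta) * p_c(theta)`,
#' each component normalized to integrate to 1 over `[0, pi]` under the chosen
#' convention (`"dtheta"`: no solid-angle Jacobian, the default convention
#' used throughout; `"sintheta"`: with the Jacobian, for sensitivity checks).
#'
#' @param theta polar angle(s) in radians.
#' @param material an [material()].
#' @param compton a [compton_model()].
#' @param rayleigh a [rayleigh_model()].
#' @param weight normalization convention, `"dtheta"` or `"sintheta"`.
#' @return density values; integrates to 1 over `[0, pi]` under the
#'   corresponding measure.
#' @export
angular_pdf <- function(theta, material, compton, rayleigh,
                        weight = c("dtheta", "sintheta")) {
  weight <- match.arg(weight)
  stopifnot(inherits(material, "xray_material"))
  .check_theta(theta)
  w <- .weight_fun(weight)
  nc <- .norm_const(function(th) compton_dcs(th, compton), weight)
  nr <- if (material$beta > 0)
    .norm_const(function(th) rayleigh_dcs(th, rayleigh), weight)
  else 1
  b <- material$beta
  b * rayleigh_dcs(theta, rayleigh) * w(theta) / nr +
    (1 - b) * compton_dcs(theta, compton) * w(theta) / nc
}

# constant rejection envelope: max of the (possibly sin-weighted)
# unnormalized density over `[0, pi]`, with a small safety factor
.envelope <- function(dcs, weight = "dtheta") {
  w <- .weight_fun(weight)
  f <- function(th) dcs(th) * w(th)
  grid <- seq(0, pi, length.out = 2048)
  i <- which.max(f(grid))
  lo <- grid[max(1, i - 2)]; hi <- grid[min(length(grid), i + 2)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  max(opt$objective, f(grid[i])) * (1 + 1e-9)
}

#' Sample scattering events for a material
#'
#' Draws `n` scattering events: each is Rayleigh with probability `beta`
#' (otherwise Compton), with polar angle `theta` drawn from the corresponding
#' normalized angular density by rejection sampling against a constant
#' envelope, and azimuth `phi` uniform on `[0, 2*pi)`. Uses R's global RNG;
#' call `set.seed()` first for reproducibility. This is the same sampler the
#' transport engine uses.
#'
#' @param n number of events.
#' @inheritParams angular_pdf
#' @return a data.frame with columns `event` (factor, `"rayleigh"` or
#'   `"compton"`), `theta`, `phi` (radians).
#' @export
sample_scatter <- function(n, material, compton, rayleigh,
                           weight = c("dtheta", "sintheta")) {
  weight <- match.arg(weight)
  stopifnot(inherits(material, "xray_material"), n >= 1)
  sw <- weight == "sintheta"
  is_r <- stats::runif(n) < material$beta
  theta <- numeric(n)
  nr <- sum(is_r)
  if (nr > 0) {
    env_r <- .envelope(function(th) rayleigh_dcs(th, rayleigh), weight)
    theta[is_r] <- cpp_sample_rayleigh(nr, rayleigh$l, rayleigh$c2, env_r, sw)
  }
  if (nr < n) {
    env_c <- .envelope(function(th) compton_dcs(th, compton), weight)
    theta[!is_r] <- cpp_sample_compton(n - nr, compton$alpha, env_c, sw)
  }
  data.frame(event = factor(ifelse(is_r, "rayleigh", "compton"),
                            levels = c("rayleigh", "compton")),
             theta = theta,
             phi = 2 * pi * stats::runif(n))
}

# mean polar angle of the normalized Rayleigh density for decay rate c2
.rayleigh_mean_angle <- function(c2, l, weight = "dtheta") {
  m <- rayleigh_model(c1 = 1, l = l, c2 = c2)
  w <- .weight_fun(weight)
  num <- stats::integrate(function(th) th * rayleigh_dcs(th, m) * w(th),
                          0, pi, rel.tol = 1e-11, subdivisions = 400L)$value
  den <- stats::integrate(function(th) rayleigh_dcs(th, m) * w(th),
                          0, pi, rel.tol = 1e-11, subdivisions = 400L)$value
  num / den
}

#' Calibrate the Rayleigh form factor to a target mean scattering angle
#'
#' Finds the decay rate `c2` such that the normalized Rayleigh angular
#' density has the requested mean polar angle (root finding on the quadrature
#' mean; tolerance 1e-6 rad). The mean is strictly decreasing in `c2`, so the
#' root is unique. `c1` is stored as 1 since it cancels under normalization.
#'
#' @param target_mean_angle desired mean polar angle in radians,
#'   in (0, pi/2).
#' @param l form-factor exponent (default 2).
#' @param weight normalization convention (see [angular_pdf()]).
#' @return a calibrated [rayleigh_model()].
#' @export
calibrate_form_factor <- function(target_mean_angle, l = 2,
                                  weight = c("dtheta", "sintheta")) {
  weight <- match.arg(weight)
  stopifnot(target_mean_angle > 0, target_mean_angle < pi / 2, l >= 0)
  f <- function(c2) .rayleigh_mean_angle(c2, l, weight) - target_mean_angle
  lo <- 1e-6
  if (f(lo) < 0)
    stop("calibration failure: target mean angle ", target_mean_angle,
         " rad exceeds the uncalibrated (c2 -> 0) mean ",
         signif(.rayleigh_mean_angle(lo, l, weight), 6), " rad")
  hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 4
  if (f(hi) > 0)
    stop("calibration failure: no root bracketed for c2 in (0, ", hi, "]")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  m <- rayleigh_model(c1 = 1, l = l, c2 = root)
  achieved <- .rayleigh_mean_angle(root, l, weight)
  if (abs(achieved - target_mean_angle) > 1e-6)
    stop("calibration failure: residual ", achieved - target_mean_angle,
         " rad exceeds 1e-6")
  m
}

#' Rayleigh fraction from cross-sections
#'
#' Computes `beta = sigma_r / (sigma_r + N_e * sigma_c)` where
#' `sigma_r = 2*pi * int_0^pi p_r(theta) d(theta)` and similarly for the
#' Klein-Nishina cross-section, with `N_e` free electrons per atom weighting
#' the per-electron Compton term. This is the helper that relates the
#' per-material `beta` input to underlying cross-sections; the transport
#' itself takes `beta` directly.
#'
#' @param compton a [compton_model()].
#' @param rayleigh a [rayleigh_model()].
#' @param N_e number of electrons per atom, >= 0.
#' @param weight normalization convention (see [angular_pdf()]).
#' @return the Rayleigh fraction in `[0, 1]`.
#' @export
beta_from_cross_sections <- function(compton, rayleigh, N_e,
                                     weight = c("dtheta", "sintheta")) {
  weight <- match.arg(weight)
  stopifnot(N_e >= 0)
  sr <- 2 * pi * .norm_const(function(th) rayleigh_dcs(th, rayleigh), weight)
  sc <- 2 * pi * .norm_const(function(th) compton_dcs(th, compton), weight)
  if (sr + N_e * sc == 0) return(0)
  sr / (sr + N_e * sc)
}

#' Scattering physics bundle
#'
#' Convenience container tying together a Compton model, a (calibrated)
#' Rayleigh model, the normalization convention, rejection envelopes, and
#' interpolated cumulative distributions of both normalized angular
#' densities. This is what the transport engine and the single-scattering
#' model consume.
#'
#' @param energy_keV photon energy in keV (default 50).
#' @param l Rayleigh form-factor exponent (default 2).
#' @param target_mean_angle target mean Rayleigh scattering angle in radians
#'   (default 4.3 degrees); ignored when `c2` is given.
#' @param c2 optional explicit form-factor decay rate; when `NULL` (default)
#'   it is calibrated to `target_mean_angle`.
#' @param weight normalization convention (see [angular_pdf()]).
#' @param n_cdf grid size for the tabulated cumulative densities.
#' @return an object of class `scatter_physics`.
#' @export
scatter_physics <- function(energy_keV = 50, l = 2,
                            target_mean_angle = 4.3 * pi / 180,
                            c2 = NULL,
                            weight = c("dtheta", "sintheta"),
                            n_cdf = 4096L) {
  weight <- match.arg(weight)
  cm <- compton_model(energy_keV)
  rm <- if (is.null(c2)) calibrate_form_factor(target_mean_angle, l, weight)
        else rayleigh_model(c1 = 1, l = l, c2 = c2)
  w <- .weight_fun(weight)
  grid <- seq(0, pi, length.out = n_cdf)
  cdf_of <- function(dcs) {
    y <- dcs(grid) * w(grid)
    cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(grid)))
    stats::approxfun(grid, cum / cum[length(cum)], yleft = 0, yright = 1)
  }
  structure(list(
    compton = cm, rayleigh = rm, weight = weight,
    env_compton = .envelope(function(th) compton_dcs(th, cm), weight),
    env_rayleigh = .envelope(function(th) rayleigh_dcs(th, rm), weight),
    cdf_compton = cdf_of(function(th) compton_dcs(th, cm)),
    cdf_rayleigh = cdf_of(function(th) rayleigh_dcs(th, rm))
  ), class = "scatter_physics")
}

#' @export
print.scatter_physics <- function(x, ...) {
  cat(sprintf(paste0("<scatter_physics>  E = %g keV (alpha = %.5f)  ",
                     "form factor: theta^%g * exp(-%.4f * theta)  [%s]\n"),
              x$compton$energy_keV, x$compton$alpha, x$rayleigh$l,
              x$rayleigh$c2, x$weight))
  invisible(x)
}

# mixture CDF of the polar angle for a material under a physics bundle
.mixture_cdf <- function(theta, mat, physics) {
  b <- mat$beta
  b * physics$cdf_rayleigh(theta) + (1 - b) * physics$cdf_compton(theta)
}
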