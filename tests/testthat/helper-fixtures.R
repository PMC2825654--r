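## shared fixtures, built once per test run and cached

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## calibrated 50 keV physics bundle (4.3 degree mean Rayleigh angle, l = 2)
acc_physics <- function() cached("physics", scatter_physics())

acc_phantom <- function() cached("phantom", build_table1_phantom())

## the reduced-scale reference run: 60x60 detector at 0.2 cm pitch,
## collimators {50 @ 2.5 cm, 10 @ 2.5 cm, 10 @ 17.5 cm}, 1e7 histories
acc_run <- function() cached("run", {
  dets <- list(detector_config(collimator_spec(50), 2.5),
               detector_config(collimator_spec(10), 2.5),
               detector_config(collimator_spec(10), 17.5))
  simulate_transport(acc_phantom(), acc_physics(), dets, 1e7, seed = 42)
})

## matching analytic single-scattering image (ratio 10, 2.5 cm)
acc_ss_image <- function() cached("ss", {
  single_scatter_image(acc_phantom(), detector_grid(), collimator_spec(10),
                       2.5, acc_physics())
})

## chi-squared goodness of fit of sampled angles against a (possibly
## unnormalized) density, using equal-mass bins from sample quantiles and
## bin masses from independent quadrature
chisq_gof_p <- function(theta, dens, n_bins = 30) {
  breaks <- unique(c(0, stats::quantile(theta, seq_len(n_bins - 1) / n_bins),
                     pi))
  counts <- table(cut(theta, breaks, include.lowest = TRUE))
  total <- stats::integrate(dens, 0, pi, rel.tol = 1e-10)$value
  probs <- vapply(seq_len(length(breaks) - 1), function(i)
    stats::integrate(dens, breaks[i], breaks[i + 1],
                     rel.tol = 1e-9)$value / total, 0)
  suppressWarnings(stats::chisq.test(as.vector(counts),
                                     p = probs / sum(probs))$p.value)
}
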