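test_that("Klein-Nishina cross-section matches the closed form", {
  cm <- compton_model(50)
  expect_equal(cm$alpha, 50 / 511)

  ## forward-scatter limit: the alpha-dependent term vanishes
  expect_equal(compton_dcs(0, cm), 1.0)
  expect_equal(compton_dcs(0, compton_model(511)), 1.0)

  ## Thomson limit at 90 degrees
  thomson <- compton_model(0)
  expect_equal(compton_dcs(pi / 2, thomson), 0.5)
  th <- seq(0, pi, length.out = 101)
  expect_equal(compton_dcs(th, thomson), (1 + cos(th)^2) / 2)

  ## backscatter at 50 keV, frozen from 30-digit arbitrary-precision
  ## evaluation of the formula
  expect_equal(compton_dcs(pi, cm), 0.71065562717992117, tolerance = 1e-14)

  expect_error(compton_dcs(-0.1, cm), "theta")
  expect_error(compton_dcs(pi + 0.1, cm), "theta")
})

test_that("Rayleigh cross-section follows the analytic form factor", {
  rm <- rayleigh_model(c1 = 1, l = 2, c2 = 30)
  expect_equal(rayleigh_dcs(0, rm), 0)

  ## c2 -> 0+, l = 0: form factor -> 1, Thomson shape
  rm0 <- rayleigh_model(c1 = 1, l = 0, c2 = 1e-12)
  th <- seq(0, pi, length.out = 7)
  expect_equal(rayleigh_dcs(th, rm0), (1 + cos(th)^2) / 2, tolerance = 1e-9)

  ## independent arithmetic at the calibrated decay rate
  cal <- calibrate_form_factor(4.3 * pi / 180, l = 2)
  t0 <- 4.3 * pi / 180
  expect_equal(rayleigh_dcs(t0, cal),
               0.5 * (1 + cos(t0)^2) * (t0^2 * exp(-cal$c2 * t0))^2)

  expect_error(rayleigh_model(c2 = -1), "c2")
  expect_error(rayleigh_dcs(2 * pi, rm), "theta")
})

test_that("combined angular density is a beta mixture and normalizes", {
  phys <- acc_physics()
  cm <- phys$compton; rm <- phys$rayleigh
  nc <- integrate(function(t) compton_dcs(t, cm), 0, pi,
                  rel.tol = 1e-10)$value
  nr <- integrate(function(t) rayleigh_dcs(t, rm), 0, pi,
                  rel.tol = 1e-10)$value

  th <- c(0.01, 0.05, 0.3, 1, 2.5)
  m0 <- material("compton_only", 0.1, 0.1, 0)
  expect_equal(angular_pdf(th, m0, cm, rm), compton_dcs(th, cm) / nc)
  m1 <- material("rayleigh_only", 0.1, 0.1, 1)
  expect_equal(angular_pdf(th, m1, cm, rm), rayleigh_dcs(th, rm) / nr)

  ## water mixture at 0.05 rad, frozen from arbitrary-precision quadrature
  water <- table1_materials()$water
  expect_equal(angular_pdf(0.05, water, cm, rm), 1.4015097130807993,
               tolerance = 1e-7)

  ## normalization holds for every material under both conventions
  for (mat in table1_materials()) {
    for (w in c("dtheta", "sintheta")) {
      total <- integrate(function(t) angular_pdf(t, mat, cm, rm, weight = w),
                         0, pi, rel.tol = 1e-9)$value
      expect_equal(total, 1, tolerance = 1e-6)
    }
  }
})

test_that("form-factor calibration hits the target mean angle", {
  target <- 4.3 * pi / 180
  cal <- calibrate_form_factor(target, l = 2)

  ## independent quadrature of the mean
  num <- integrate(function(t) t * rayleigh_dcs(t, cal), 0, pi,
                   rel.tol = 1e-11)$value
  den <- integrate(function(t) rayleigh_dcs(t, cal), 0, pi,
                   rel.tol = 1e-11)$value
  expect_lt(abs(num / den - target), 1e-6)

  ## frozen decay rate from an independent root-find
  expect_equal(cal$c2, 33.266576187362984, tolerance = 1e-6)

  ## mean angle is strictly decreasing in c2
  mean_of <- function(c2) {
    m <- rayleigh_model(l = 2, c2 = c2)
    integrate(function(t) t * rayleigh_dcs(t, m), 0, pi)$value /
      integrate(function(t) rayleigh_dcs(t, m), 0, pi)$value
  }
  expect_gt(mean_of(20), mean_of(50))

  ## targets at or beyond 90 degrees are rejected up front
  expect_error(calibrate_form_factor(1.6, l = 2))
})

test_that("scatter sampler agrees with the target densities", {
  phys <- acc_physics()
  pure_r <- material("pure_r", 0, 1, 1)
  set.seed(42)
  s <- sample_scatter(1e6, pure_r, phys$compton, phys$rayleigh)
  expect_true(all(s$event == "rayleigh"))

  ## mean recovery within 3 standard errors
  target <- 4.3 * pi / 180
  se <- sd(s$theta) / sqrt(length(s$theta))
  expect_lt(abs(mean(s$theta) - target), 3 * se)

  ## chi-squared agreement for the calibrated Rayleigh density
  p_r <- chisq_gof_p(s$theta, function(t) rayleigh_dcs(t, phys$rayleigh))
  expect_gt(p_r, 0.01)

  ## Compton at 50 keV
  pure_c <- material("pure_c", 0, 1, 0)
  set.seed(43)
  sc <- sample_scatter(2e5, pure_c, phys$compton, phys$rayleigh)
  p_c <- chisq_gof_p(sc$theta, function(t) compton_dcs(t, phys$compton))
  expect_gt(p_c, 0.01)

  ## Thomson limit
  set.seed(44)
  st <- sample_scatter(2e5, pure_c, compton_model(0), phys$rayleigh)
  p_t <- chisq_gof_p(st$theta, function(t) (1 + cos(t)^2) / 2)
  expect_gt(p_t, 0.01)

  ## Bernoulli split of event types
  half <- material("half", 0, 1, 0.5)
  set.seed(45)
  sh <- sample_scatter(1e6, half, phys$compton, phys$rayleigh)
  frac <- mean(sh$event == "rayleigh")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e6))
  expect_true(all(sh$phi >= 0 & sh$phi < 2 * pi))
})

test_that("Rayleigh fraction from cross-sections matches quadrature", {
  phys <- acc_physics()
  cm <- phys$compton; rm <- phys$rayleigh

  ## no coherent scattering at all
  expect_equal(beta_from_cross_sections(cm, rayleigh_model(c1 = 0, c2 = 30),
                                        N_e = 10), 0)
  ## no electrons: everything is Rayleigh
  expect_equal(beta_from_cross_sections(cm, rm, N_e = 0), 1)

  ## N_e = 10 at the calibrated form factor, frozen from independent
  ## arbitrary-precision quadrature (the calibrated coherent cross-section
  ## is tiny because theta^4 exp(-2 c2 theta) concentrates near zero)
  expect_equal(beta_from_cross_sections(cm, rm, N_e = 10),
               9.1879293088051886e-10, tolerance = 1e-5)
})

test_that("material constructors enforce the coefficient contracts", {
  w <- material_from_components("water", 0.028, 0.014, 0.168)
  expect_equal(w$mu_s, 0.182)
  expect_equal(w$beta, 0.014 / 0.182)
  expect_error(material("bad", 0.1, 0.1, 1.5), "beta")
  expect_error(material("bad", -1, 0.1, 0.5), "mu_t")
})
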