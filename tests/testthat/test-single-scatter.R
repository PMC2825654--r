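test_that("angular limits follow the collimated-cell geometry", {
  ## r = D/2, H = 0: theta1 = 0, theta2 = arctan(D / R)
  lim <- angular_limits(acceptance_geometry(H = 0, D = 0.2, R = 2.5, r = 0.1))
  expect_equal(lim$theta1, 0)
  expect_equal(lim$theta2, atan(0.2 / 2.5))

  ## off-axis cell: direct arctan evaluation of every limit
  lim2 <- angular_limits(acceptance_geometry(H = 1, D = 0.2, R = 2.5, r = 0.3))
  expect_equal(lim2$theta1, atan(0.2 / 1.5))
  expect_equal(lim2$theta2, atan(0.4 / 2.5))
  expect_equal(lim2$phi2, atan(0.2 / 0.6))
  expect_equal(lim2$phi1, -lim2$phi2)

  ## on-axis cell subtends the full azimuth
  lim3 <- angular_limits(acceptance_geometry(H = 1, D = 0.2, R = 2.5, r = 0))
  expect_true(lim3$full_azimuth)
  expect_equal(lim3$phi2 - lim3$phi1, 2 * pi)
  expect_equal(lim3$theta1, 0)   # negative arctan clamped

  expect_error(acceptance_geometry(H = 3, D = 0.2, R = 2.5, r = 0),
               "R > H")
})

test_that("cell acceptance probability matches a Monte Carlo hit count", {
  phys <- acc_physics()
  water <- table1_materials()$water
  lim <- angular_limits(acceptance_geometry(H = 2, D = 0.2, R = 4, r = 0.3))
  p <- acceptance_probability(lim, water, phys)

  ## the paper-style statistical estimate: draw (theta, phi) and count hits
  set.seed(53)
  n <- 1e6
  s <- sample_scatter(n, water, phys$compton, phys$rayleigh)
  phi <- ifelse(s$phi > pi, s$phi - 2 * pi, s$phi)   # wrap to (-pi, pi]
  hit <- s$theta >= lim$theta1 & s$theta <= lim$theta2 &
    phi >= lim$phi1 & phi <= lim$phi2
  expect_lt(abs(p - mean(hit)), 3 * sqrt(p * (1 - p) / n) + 1e-5)

  ## degenerate limits
  expect_warning(
    p0 <- acceptance_probability(list(theta1 = 0.2, theta2 = 0.2,
                                      phi1 = -1, phi2 = 1), water, phys),
    "unreachable")
  expect_equal(p0, 0)
  full <- acceptance_probability(list(theta1 = 0, theta2 = pi,
                                      phi1 = -pi, phi2 = pi), water, phys)
  expect_equal(full, 1, tolerance = 1e-6)
})

test_that("factorized quadrature equals the 2-D double integral", {
  skip_if_not_installed("pracma")
  phys <- acc_physics()
  water <- table1_materials()$water
  cases <- list(c(0.00, 0.08, -pi, pi),
                c(0.02, 0.10, -0.5, 0.5),
                c(0.05, 0.30, -1.2, 1.2))
  for (cs in cases) {
    lim <- list(theta1 = cs[1], theta2 = cs[2], phi1 = cs[3], phi2 = cs[4])
    p_fact <- acceptance_probability(lim, water, phys)
    p_2d <- pracma::integral2(
      function(th, ph)
        matrix(angular_pdf(as.vector(th), water, phys$compton,
                           phys$rayleigh), nrow(th), ncol(th)) / (2 * pi),
      lim$theta1, lim$theta2, lim$phi1, lim$phi2, reltol = 1e-10)$Q
    expect_equal(p_fact, p_2d, tolerance = 1e-8)
  }
})

test_that("acceptance table has the reference shape and valid entries", {
  phys <- acc_physics()
  ph <- acc_phantom()
  tab <- build_acceptance_table(ph, detector_grid(), collimator_spec(10),
                                2.5, phys, n_mc = 2e4)
  ## 250 depths (5 cm / 0.02 cm) x 5 materials
  expect_equal(dim(tab$prob), c(250L, 5L))
  expect_equal(dim(tab$total), c(250L, 5L))
  expect_equal(colnames(tab$prob), c("water", paste0("cube", 1:4)))
  expect_true(all(tab$prob >= 0 & tab$prob <= 1))
  expect_true(all(tab$total >= 0 & tab$total <= 1))

  ## the high-beta cube accepts more than the low-beta cube at small angles
  expect_true(all(tab$total[, "cube4"] > tab$total[, "cube1"]))

  ## deterministic: same physics, same table
  tab2 <- build_acceptance_table(ph, detector_grid(), collimator_spec(10),
                                 2.5, phys, n_mc = 2e4)
  expect_identical(tab$total, tab2$total)
})

test_that("total acceptance is non-increasing in the grid height", {
  phys <- acc_physics()
  w <- table1_materials()$water
  slab <- phantom(box_region(c(-5, -5, -2.5), c(5, 5, 2.5), w))
  grid <- detector_grid()
  totals <- lapply(c(5, 10, 20), function(a)
    build_acceptance_table(slab, grid, collimator_spec(a), 7.5, phys,
                           depth_step = 0.25, n_mc = 1e5)$total)
  ## aspect up => H up => every entry down (same draw pool: exact subsets)
  expect_true(all(totals[[2]] <= totals[[1]]))
  expect_true(all(totals[[3]] <= totals[[2]]))
})

test_that("single-scattering image obeys its structural limits", {
  phys <- acc_physics()
  grid <- detector_grid()
  col10 <- collimator_spec(10)

  ## no scattering coefficient, no image
  dead <- phantom(box_region(c(-5, -5, -2.5), c(5, 5, 2.5),
                             material("absorbing", 0.1, 0, 0)))
  img0 <- single_scatter_image(dead, grid, col10, 2.5, phys,
                               depth_step = 0.25)
  expect_equal(max(abs(img0)), 0)

  ## optically thin limit: interior pixels equal the projected
  ## mu_s * acceptance sum (attenuation factors -> 1)
  eps <- 1e-3
  thin_mat <- material("thin_water", 0.028 * eps, 0.182 * eps, 0.014 / 0.182)
  thin <- phantom(box_region(c(-5, -5, -2.5), c(5, 5, 2.5), thin_mat))
  tab <- build_acceptance_table(thin, grid, col10, 2.5, phys,
                                depth_step = 0.1, n_mc = 2e5)
  img <- single_scatter_image(thin, grid, col10, 2.5, phys, table = tab,
                              depth_step = 0.1)
  expected <- (0.2^2 / 100) * sum(0.182 * eps * 0.1 * tab$total[, 1])
  interior <- img[16:45, 16:45]
  expect_equal(mean(interior) / expected, 1, tolerance = 0.01)
  expect_lt(max(abs(interior / expected - 1)), 0.05)

  ## mismatched geometry is refused
  expect_error(
    single_scatter_image(thin, grid, collimator_spec(20), 2.5, phys,
                         table = tab),
    "different geometry")
})

test_that("image brightness is non-increasing in collimator height", {
  phys <- acc_physics()
  ph <- acc_phantom()
  grid <- detector_grid()
  imgs <- lapply(c(5, 10), function(a)
    single_scatter_image(ph, grid, collimator_spec(a), 2.5, phys,
                         depth_step = 0.25))
  expect_true(all(imgs[[2]] <= imgs[[1]] + 1e-15))
  expect_lt(mean(imgs[[2]]), mean(imgs[[1]]))
})
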